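---
title: "Models and methods behind earspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind earspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earspan)
```

earspan re-implements, as a tested pipeline, the quantitative core of a
life-course study of hearing in the *Drosophila* antennal ear: biophysical
model fitting of sound-receiver fluctuations and transducer gating, an
age-variability screen over gene-by-age count matrices, qPCR relative
quantification, and sound-evoked behaviour and survival analysis. Every
input the pipeline consumes can be generated synthetically with recorded
ground truth, so each stage is testable end to end without instrument data.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish.

## The sound receiver as a driven harmonic oscillator

The fly's antennal sound receiver behaves, near its working point, as a
damped harmonic oscillator with total linear stiffness $K$ (N/m), best
frequency $f_0$ (Hz) and quality factor $Q$. Free (unstimulated) receiver
motion is driven by thermal force noise plus active energy injection by the
auditory neurons. earspan models the active process as an *effective
temperature*: the receiver obeys

$$m\ddot x + \gamma \dot x + Kx = \xi(t), \qquad
  S_\xi^{\text{one-sided}} = 4\gamma k_B T_{\text{eff}},$$

with $m = K/(2\pi f_0)^2$ and $\gamma = \sqrt{mK}/Q$. A passive (dead or
terminally aged) receiver has $T_{\text{eff}} = T$ and mean elastic energy
$k_BT$ (equipartition); an active receiver has
$K\langle x^2\rangle = k_B T_{\text{eff}}$. The *power gain*
$G = E_{\text{eff}} - 1$ (in $k_BT$ units, with
$E_{\text{eff}} = K\langle x^2\rangle / k_BT$) is therefore zero for a
passive receiver by construction. A feedback-motor model would be needed to
reproduce mechanisms; the effective temperature reproduces the observable
this pipeline quantifies (energy gain), which is why it was chosen.

**Simulation.** `simulate_fluctuations()` advances the state $(x, v)$ with
the exact Gaussian one-step update of the linear SDE: the propagator is the
matrix exponential $e^{M\,dt}$ and the step-noise covariance is
$\Sigma_\infty - A\Sigma_\infty A^\top$, where $\Sigma_\infty =
\mathrm{diag}(k_BT_{\text{eff}}/K,\; k_BT_{\text{eff}}/m)$ is the exact
stationary covariance. Unlike explicit stochastic integrators (e.g.
Euler–Maruyama, whose stationary variance is inflated by
$\mathcal O(\gamma\,dt/m)$ — a few percent at these parameters), the exact
update satisfies equipartition at machine precision for any step, which
matters because the passive-null test asks whether the mean fitted gain of
dead receivers is statistically zero. The internal step is nevertheless
kept at or below $1/(50 f_0)$, the trace is initialised from the stationary
law, and a burn-in of $20\,Q/f_0$ seconds is discarded. The position
component of the two-dimensional recursion is an AR(2) process, which lets
the whole trace be generated by `stats::filter` rather than an R-level
loop. All generators are deterministic given their `seed` and restore the
caller's RNG state.

**Spectral estimation.** `estimate_psd()` computes a Welch-averaged,
one-sided velocity PSD (Hann window, 1-s segments, 50% overlap by default)
normalised so that $\int S_v\,df$ equals the velocity variance (checked to
2% in the tests). Velocity is taken from the recording when present and
otherwise recovered by central differencing of the displacement.

**SHO fitting.** `fit_sho()` fits
$$S_v(f) = \frac{a f^2}{(f_0^2-f^2)^2 + (f_0 f/Q)^2}$$
by least squares on the log-PSD (the log stabilises the heavy dynamic range
of velocity spectra; parameters are fitted on the log scale to enforce
positivity; initial values come from the PSD argmax, the half-power
bandwidth and the peak height). Two refinements remove small but
consequential biases:

* *Alias-aware model.* Point-sampled velocity traces fold the slowly
  decaying $\sim 1/f^2$ spectral tail across the Nyquist frequency. The
  fitted model (`sho_velocity_psd()`) therefore includes the first three
  alias images $S(2kf_N \pm f)$. Without this, the fitted energy of a
  passive receiver is biased upward by several tenths of a percent.
* *Two-pass band and linear amplitude.* When no band is given, a wide-band
  pilot fit locates the peak and the final fit is restricted to the pilot's
  half-power region, where the SHO form dominates and the window-leakage
  skirts are excluded; the band depends on the data only through the smooth
  pilot estimates, avoiding noisy bin-level band selection. The amplitude
  $a$ is then re-estimated on the *linear* scale,
  $\hat a = \sum S_i m_i / \sum m_i^2$ with $m$ the fitted unit-amplitude
  shape, because the averaged periodogram is unbiased in expectation while
  its log carries a chi-squared offset of order $1/n_{\text{segments}}$
  that would propagate into the energy.

The effective energy follows from the analytic displacement variance of the
fitted SHO, $\langle x^2\rangle = aQ/(8\pi f_0^3)$, and equipartition:
$E_{\text{eff}} = K\langle x^2\rangle/(k_BT)$. The absolute calibration
requires the receiver stiffness $K$, which rides along in the recording
metadata (in the laboratory it is a calibration constant of the setup). An
alternative definition of gain — against a measured dead-receiver spectrum
rather than theoretical equipartition — exists in the literature; the
equipartition definition is used here and makes $G = 0$ exact for the
passive system.

`summarize_lifecourse()` takes per-individual fits grouped by age and
returns per-age medians ("median fits"), the gain trajectory normalised to
% of its maximum median, and unadjusted two-sided Mann–Whitney U tests
between consecutive ages (raw p-values, as is conventional for these
comparisons). `f0_stability_gate()` implements the physiological-integrity
criterion of at most 20% best-frequency change between the recordings
bracketing an experiment.

**Problem sizes.** Parameter-recovery simulations use 60-s recordings at
10 kHz over a grid $f_0 \in \{150, 250, 400\}$ Hz $\times\; Q \in
\{0.8, 1.5, 3\}$ with $T_{\text{eff}}/T \in \{3, 5, 10\}$; the passive null
uses 50 independent 60-s simulations at $Q = 1$, the terminal-phenotype
value. These sizes give sub-percent standard errors on $f_0$ and a few
percent on $Q$ and $G$.

## Transducer gating: the gating-spring model

Direct mechanotransducer gating makes the receiver's slope stiffness dip
near each channel population's set point (gating compliance). With two
populations $j \in \{s, i\}$ (sensitive, linked to hearing; insensitive,
linked to wind/gravity sensing),

$$K(X) = K_{\text{steady}} + K_{\text{GS}}
  - \sum_j \frac{N_j z_j^2}{k_BT}\, p_j(X)\bigl(1 - p_j(X)\bigr), \qquad
  p_j(X) = \frac{1}{1 + e^{-z_j (X - X_{0,j})/k_BT}},$$

where $N_j$ is the channel count, $z_j$ the single-channel gating force and
$X_{0,j}$ the set point. The dip depth at the set point is exactly
$N_j z_j^2 / (4 k_B T)$ — the receiver's "nonlinearity depth".

`fit_gating_spring()` performs bounded nonlinear least squares
(`minpack.lm::nlsLM`, log-scale positivity for $N$, $z$, $K$) with
initialisation from the data: dips are located on a running-median smooth,
$z$ is initialised from the dip width ($z \approx 4k_BT/\text{width}$) and
$N$ from the dip depth. Three robustness measures matter in practice:

* a *model-selection guard*: if no dip exceeds three times the point-noise
  MAD, a constant fit with $N = 0$ is returned instead of a spurious
  compliance;
* *multi-start*: overlapping compliances can merge into one detected dip,
  so shoulder-split start configurations are always tried and the best
  sum-of-squares solution kept;
* *label convention*: populations are labelled sensitive/insensitive by
  $z_s > z_i$, which resolves the permutation symmetry of the model (the
  sensitive channels have the larger single-channel gating force at all
  ages). Both set points are free parameters; no symmetry between forcing
  directions is imposed.

$K_{\text{steady}}$ and $K_{\text{GS}}$ enter the curve only through their
sum, so a single stiffness curve identifies only
$K_{\text{total}} = K_{\text{steady}} + K_{\text{GS}}$; the fit reports
that sum, and decomposing it requires extra information (a series-spring
relation from asymptotic compliance) that a lone curve does not contain.

**Identifiability and the synthetic truth.** The default synthetic truth is
$N_s = 80$, $z_s = 50$ fN, $N_i = 800$, $z_i = 15$ fN,
$K_{\text{total}} = 60\ \mu$N/m, set points at 0 and 300 nm — magnitudes in
line with published two-population fits for this receiver, in which the
insensitive population is roughly an order of magnitude more numerous and
both compliance dips are of comparable depth (here 12.3 and 11.1 $\mu$N/m).
This matters for testing: with measurement noise at 2% of
$K_{\text{total}}$ and 200 grid points, a Fisher-information (Cramér–Rao)
analysis shows that a much smaller insensitive population (e.g. a 2.8
$\mu$N/m dip) would be unidentifiable at the tested precision by *any*
estimator, i.e. the synthetic conditions must resemble real receivers for
recovery testing to be meaningful. Recovery is assessed both as the
accuracy of the median estimate across 50 noise realisations (a bias check;
all parameters within a few percent) and as per-seed median absolute errors
(which, for $N_s$, sit near the information bound of roughly 10–15% under
these conditions).

`fit_cap()` summarises compound-action-potential response curves: per-level
medians first, then a least-squares double sigmoid
$\mathrm{CAP}(|X|) = \sum_j A_j/(1 + e^{-(|X|-X_{50,j})/w_j})$ with
populations labelled by half-point order; a singular two-sigmoid fit (e.g. a
truly single-population curve) falls back to one sigmoid with $A_i = 0$.
Decreasing level medians beyond three times the replicate spread raise a
warning flag rather than an error.

`nz_homeostasis()` quantifies the homeostatic compensation between channel
number and gating force. Because the conserved quantity is multiplicative
($Nz^2 \approx$ const keeps the nonlinearity depth fixed), the correlation
is computed between $\log N$ and $\log z$ (Pearson); an exactly conserved
family gives $r = -1$ identically. The coefficient of variation of $Nz^2$
is reported as the stabilised-nonlinearity statistic.

## The age-variable transcriptome

`pairwise_de()` compares two ages on a gene-by-sample count matrix. The
test is deliberately a transparent stand-in, not a re-implementation of any
specific DE package: counts are normalised by median-of-ratios size
factors, each gene gets a pooled method-of-moments negative-binomial
dispersion ($\widehat\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)$, floored
at Poisson), and a Wald statistic on the log fold change with delta-method
standard error $\sqrt{(1/\mu_a + \alpha)/n_a + (1/\mu_b + \alpha)/n_b}$ is
referred to a $t$ distribution with $n_a + n_b - 2$ degrees of freedom.
The $t$ reference (rather than the normal) is what keeps the test
calibrated at 3 replicates per age, at a known cost in power; the
acceptance simulations verify false-discovery control on null matrices and
$\ge 80\%$ raw-p power on 4-fold spikes at means $\ge 500$ with dispersion
0.05. BH adjustment is applied across genes; genes all-zero in both groups
get $\log_2\mathrm{FC} = 0$, $p = 1$.

`classify_age_variable()` applies the screen's filter: a gene is
age-variable iff, in at least one pairwise comparison, its fold change
exceeds 1.5 *strictly* (in either direction), its BH FDR is below 10% and
its raw p below 0.05. A fold change of exactly 1.5 is excluded (the
criterion is printed as ">1.5-fold"), whereas the extreme-gene list of
submission round III includes exactly 4-fold genes (printed as "at least
4-times"); `prepare_submission_lists()` keeps both boundary conventions,
and round II's ">10,000 reads" is interpreted as mean size-factor-normalised
count across the gene's samples, strictly greater. The DE module accepts a
sex column but pools sexes by default.

`go_enrichment()` scores a target set against term sets with
$(b/n)/(B/N)$ — $b$ the intersection, $n$ the target size, $B$ the term
size, $N$ the background — and a plain hypergeometric upper-tail p-value
$P(X \ge b)$ (not a rank-based minimum-hypergeometric statistic; the score
formula is the published one). `ortholog_overlap()` recomputes
conserved/expressed/age-variable percentages of foreign gene panels through
an ortholog map, rounding to the precision the corresponding printed tables
use. `filter_tf_candidates()` restricts an external motif-enrichment table
to expressed genes with NES $\ge 2.5$ (inclusive at the threshold).

The synthetic count generator (`simulate_counts()`) produces
negative-binomial matrices over the five study ages (days 1, 5, 10, 25, 50,
3 replicates each by default) with log-normal baseline means (log2 mean 7,
sd 2 — a realistic bulk RNA-Seq abundance spread), dispersion 0.05, and a
configurable fraction of genes whose mean changes by a fixed fold at
exactly one age transition, with ground truth recorded. It emulates the
count structure of the design, not read-level artefacts: no GC or length
bias, no batch structure, no correlated gene modules. Passing tests
therefore establish the filter's statistical calibration, not robustness to
those real-data artefacts.

## qPCR relative quantification

`relative_quantification()` implements $\Delta\Delta Ct$ with the
endogenous control (default *SdhA*) averaged per (condition, biological
replicate); RQ $= 2^{-\Delta\Delta Ct}$ is computed per technical
replicate, then averaged with standard deviations per biological replicate
and across them. Two sign conventions are provided because they genuinely
differ: the `"printed"` convention computes
$\Delta\Delta Ct = \Delta Ct_{\text{control}} - \Delta Ct_{\text{kd}}$, under
which a knockdown that *raises* the target's Ct yields RQ $> 1$; the
`"standard"` (Livak) convention is its negative and yields RQ $< 1$ for the
same plate. Published knockdown figures in this field show RQ $< 1$,
suggesting the standard convention in actual use even where the equations
are printed the other way; earspan implements both, defaults to the printed
form for fidelity, and corrects neither silently. RQ is invariant to
adding a constant to every Ct on the plate.

## Sound-evoked behaviour and survival

`simulate_activity()` emulates beam-break monitors under the hourly
playback schedule: minutes 0–14 of each hour are the stimulus window,
minutes 45–59 the baseline window (the silent quarter-hour directly
preceding the next stimulus), the half-hour between is unanalysed.
Counts are Poisson at `lambda_base * rho` in the stimulus window and
`lambda_base` elsewhere (default 1 beam break/min and `rho = 2`, a
response magnitude that a healthy male shows to courtship song).
`sound_response()` sums each window per hour and tube, collapses hours to a
single median per tube (cancelling circadian variation), and compares
stimulus against baseline across tubes with a paired test: a paired t-test
when Shapiro–Wilk does not reject normality of the paired differences at
$\alpha = 0.05$, otherwise a Wilcoxon signed-rank test — a decision rule
that mirrors the mixed use of both tests in practice. Analysis requires at
least 12 complete hours; the study design records 48 h from the first light
transition. Calibration uses 500 null seeds (rejection rate $0.05 \pm
0.02$) and 100 effect seeds (2$\times$ stimulus detected in $\ge 95\%$) at
12 tubes.

`survival_analysis()` turns per-day death counts into a survival curve;
median lifespan is the first day on which the fraction alive drops below
one half (infinite when more than half the cohort outlives the
observation). The synthetic cohorts use a constant daily hazard (geometric
death times), which reproduces a realistic median around
$\ln 2 / \text{hazard}$ but not the age-accelerating (Gompertz) mortality
of real cohorts — adequate for testing the curve arithmetic and the
healthspan/lifespan alignment, not for demographic inference.

## Pipeline, I/O and conventions

All tables are plain tab-delimited text (gzip accepted transparently) with
`#` metadata headers; `read_table_schema()` validates column presence and
types and names the offending column and row on failure. Units are fixed
package-wide: displacement m, force N, stiffness N/m, temperature K (bath
default 294.15 K, i.e. the 21 °C of the recordings), energies in $k_BT$
with $k_B = 1.380649\times 10^{-23}$ J/K; tables report nm, fN and
$\mu$N/m where those are the natural magnitudes. `run_pipeline()` executes
every stage the manifest provides records for, records per-stage errors
without aborting independent stages, and emits a deterministic JSON report.
Threshold defaults in `default_config()` are the study's printed values
(1.5-fold, 10% FDR, p 0.05, 10,000 reads, 4-fold, NES 2.5).

## Known limitations

* The active process is an effective temperature; no motor-feedback
  dynamics, spontaneous oscillations, or frequency-dependent activity.
* The free-fluctuation sample rate is not documented for the original
  recordings; 10 kHz is assumed (the actuated-response digitisation rate
  was 100 kHz, and 10 kHz is far above $20 f_0$ for all study ages).
* $K_{\text{steady}}$ vs $K_{\text{GS}}$ are reported only as their sum.
* The DE stand-in makes no claim of numeric agreement with any specific DE
  package; its guarantees are the simulation-based calibrations above.
* GO term p-values are plain hypergeometric tails; ortholog maps and term
  annotations are inputs, not inferred.
* Survival uses constant hazard in simulation and no censoring machinery
  beyond the observation horizon.
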