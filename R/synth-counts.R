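#' Specification for a synthetic gene-by-age count matrix
#'
#' Emulates an RNA-Seq design sampling the second antennal segment at a series
#' of ages (default days 1, 5, 10, 25, 50). Counts are negative-binomial; a
#' `spike_fraction` of genes change their mean by `spike_fc`-fold at exactly
#' one (randomly assigned) age transition and are recorded as ground truth.
#'
#' @param n_genes number of genes
#' @param ages ordered age labels in days
#' @param reps_per_age biological replicates per age (>= 2)
#' @param baseline_log2_mean,baseline_log2_sd log2-normal distribution of
#'   baseline gene means (counts)
#' @param dispersion NB dispersion `alpha` (var = mu + alpha*mu^2); 0 = Poisson
#' @param spike_fraction fraction of genes spiked, in [0, 1]
#' @param spike_fc fold change applied to spiked genes (> 1); direction (up or
#'   down) is random per gene
#' @param seed integer seed
#' @return an object of class `count_sim_spec`
#' @export
count_sim_spec <- function(n_genes = 2000, ages = c(1, 5, 10, 25, 50),
                           reps_per_age = 3, baseline_log2_mean = 7,
                           baseline_log2_sd = 2, dispersion = 0.05,
                           spike_fraction = 0.1, spike_fc = 4, seed = 1L) {
  if (reps_per_age < 2) stop("reps_per_age must be >= 2")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop("spike_fraction must be in [0, 1]")
  if (spike_fc <= 1) stop("spike_fc must be > 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_genes = n_genes, ages = ages, reps_per_age = reps_per_age,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 dispersion = dispersion, spike_fraction = spike_fraction,
                 spike_fc = spike_fc, seed = seed),
            class = "count_sim_spec")
}

#' Simulate a gene-by-sample count matrix across ages
#'
#' @param spec a [count_sim_spec()] object
#' @return an `age_series_counts`: list with integer matrix `counts` (genes x
#'   samples), data.frame `samples` (sample_id, age_day, sex, replicate), and
#'   `truth` (per-gene spike flag, transition and direction)
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  n_ages <- length(spec$ages)
  n_samp <- n_ages * spec$reps_per_age
  genes <- sprintf("gene%05d", seq_len(spec$n_genes))
  samples <- data.frame(
    sample_id = sprintf("d%s_r%d", rep(spec$ages, each = spec$reps_per_age),
                        rep(seq_len(spec$reps_per_age), n_ages)),
    age_day = rep(spec$ages, each = spec$reps_per_age),
    sex = "pooled",
    replicate = rep(seq_len(spec$reps_per_age), n_ages),
    stringsAsFactors = FALSE)

  with_seed(spec$seed, {
    base_mu <- 2^rnorm(spec$n_genes, spec$baseline_log2_mean,
                       spec$baseline_log2_sd)
    n_spike <- round(spec$spike_fraction * spec$n_genes)
    spiked <- seq_len(spec$n_genes) %in%
      sample.int(spec$n_genes, n_spike)
    transition <- ifelse(spiked, sample.int(n_ages - 1L, spec$n_genes,
                                            replace = TRUE), NA_integer_)
    up <- ifelse(spiked, sample(c(TRUE, FALSE), spec$n_genes, replace = TRUE),
                 NA)
    # per-gene, per-age mean: fold change applied from the transition onwards
    mu <- matrix(base_mu, spec$n_genes, n_ages)
    for (g in which(spiked)) {
      after <- (transition[g] + 1L):n_ages
      mu[g, after] <- mu[g, after] *
        if (up[g]) spec$spike_fc else 1 / spec$spike_fc
    }
    mu_samp <- mu[, rep(seq_len(n_ages), each = spec$reps_per_age),
                  drop = FALSE]
    counts <- if (spec$dispersion > 0) {
      matrix(rnbinom(length(mu_samp), mu = mu_samp,
                     size = 1 / spec$dispersion),
             spec$n_genes, n_samp)
    } else {
      matrix(rpois(length(mu_samp), mu_samp), spec$n_genes, n_samp)
    }
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, samples$sample_id)

  truth <- data.frame(gene = genes, spiked = spiked,
                      transition_from = spec$ages[transition],
                      transition_to = spec$ages[transition + 1L],
                      direction = ifelse(is.na(up), NA,
                                         ifelse(up, "up", "down")),
                      base_mean = base_mu,
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, truth = truth,
                 spec = spec),
            class = "age_series_counts")
}
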