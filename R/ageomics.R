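#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: per-sample median of count ratios to the
#' per-gene geometric mean, over genes expressed in every sample. Falls back
#' to total-count scaling when too few all-positive genes exist.
#'
#' @param counts integer matrix, genes x samples
#' @return numeric vector of size factors, one per sample (geometric mean 1)
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= 50) {
    lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2,
                function(cl) exp(stats::median(log(cl) - lgm)))
  } else {
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  sf / exp(mean(log(sf)))
}

#' Pairwise differential-expression test between two ages
#'
#' Per-gene negative-binomial comparison of two age groups on size-factor
#' normalised counts: group means, a pooled method-of-moments dispersion
#' (`var = mu + alpha*mu^2`), and a Wald statistic on the log fold change
#' with standard error `sqrt((1/mu_a + alpha)/n_a + (1/mu_b + alpha)/n_b)`
#' (delta method). The statistic is referred to a t distribution with
#' `n_a + n_b - 2` degrees of freedom, which keeps the test calibrated at the
#' small replicate numbers typical of these designs; p-values are BH-adjusted
#' across genes. Genes with all-zero counts in both groups get
#' `log2fc = 0, p = 1`.
#'
#' @param counts an `age_series_counts` (from [simulate_counts()] or
#'   [read_counts()]), or a list with `counts` matrix and `samples` sheet
#' @param pair numeric length-2: the two ages to compare `(age_a, age_b)`;
#'   fold changes are b relative to a
#' @return a `de_comparison` data.frame: `gene`, `base_mean`, `log2fc`,
#'   `pvalue`, `fdr`, with the pair label as attribute `pair`
#' @export
pairwise_de <- function(counts, pair) {
  m <- counts$counts
  ss <- counts$samples
  stopifnot(is.matrix(m), !is.null(ss$age_day))
  a <- which(ss$age_day == pair[1])
  b <- which(ss$age_day == pair[2])
  if (length(a) == 0 || length(b) == 0)
    stop("age label missing from sample sheet: ",
         paste(pair[c(length(a) == 0, length(b) == 0)], collapse = ", "))
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicates per age group")

  sf <- size_factors(m)
  y <- sweep(m, 2, sf, "/")
  ya <- y[, a, drop = FALSE]
  yb <- y[, b, drop = FALSE]
  na <- length(a)
  nb <- length(b)
  mu_a <- rowMeans(ya)
  mu_b <- rowMeans(yb)
  va <- apply(ya, 1, stats::var)
  vb <- apply(yb, 1, stats::var)
  # pooled method-of-moments NB dispersion, floored at Poisson
  mu_pool <- (mu_a * na + mu_b * nb) / (na + nb)
  v_pool <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
  alpha <- pmax(0, (v_pool - mu_pool) / mu_pool^2)
  alpha[!is.finite(alpha)] <- 0

  eps <- 0.5
  lfc <- log(mu_b + eps) - log(mu_a + eps)
  se <- sqrt((1 / (mu_a + eps) + alpha) / na + (1 / (mu_b + eps) + alpha) / nb)
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  zero <- mu_a == 0 & mu_b == 0
  lfc[zero] <- 0
  p[zero] <- 1
  out <- data.frame(gene = rownames(m),
                    base_mean = (mu_a + mu_b) / 2,
                    log2fc = lfc / log(2),
                    pvalue = p,
                    fdr = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pair") <- sprintf("d%s_vs_d%s", pair[1], pair[2])
  class(out) <- c("de_comparison", "data.frame")
  out
}

#' Classify genes as age-variable across pairwise comparisons
#'
#' A gene is age-variable iff in at least one comparison its fold change
#' exceeds `fc_threshold` (strictly, in either direction), its BH FDR is
#' below `fdr_threshold` and its raw p below `p_threshold`. The complement
#' of the age-variable set within the expressed genes is the
#' constant-expression set.
#'
#' @param comparisons list of `de_comparison` data.frames over the same genes
#' @param fc_threshold linear fold-change threshold (strict `>`), default 1.5
#' @param fdr_threshold FDR threshold (strict `<`), default 0.10
#' @param p_threshold raw p threshold (strict `<`), default 0.05
#' @return an `age_variable_set`: list with `variable` (gene ids),
#'   `constant` (gene ids), `expressed` (all gene ids), and `qualifying`
#'   (data.frame of gene x comparison hits with direction)
#' @export
classify_age_variable <- function(comparisons, fc_threshold = 1.5,
                                  fdr_threshold = 0.10, p_threshold = 0.05) {
  if (length(comparisons) < 1) stop("need >= 1 comparison")
  if (fc_threshold <= 0 || fdr_threshold <= 0 || fdr_threshold > 1 ||
      p_threshold <= 0 || p_threshold > 1)
    stop("threshold out of range")
  genes <- comparisons[[1]]$gene
  hits <- NULL
  for (cmp in comparisons) {
    stopifnot(identical(cmp$gene, genes))
    pass <- 2^abs(cmp$log2fc) > fc_threshold &
      cmp$fdr < fdr_threshold & cmp$pvalue < p_threshold
    if (any(pass)) {
      hits <- rbind(hits, data.frame(
        gene = cmp$gene[pass],
        comparison = attr(cmp, "pair") %||% "unnamed",
        direction = ifelse(cmp$log2fc[pass] > 0, "up", "down"),
        log2fc = cmp$log2fc[pass],
        stringsAsFactors = FALSE))
    }
  }
  variable <- unique(hits$gene)
  structure(list(variable = variable,
                 constant = setdiff(genes, variable),
                 expressed = genes,
                 qualifying = hits),
            class = "age_variable_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print age_variable_set
print.age_variable_set <- function(x, ...) {
  n <- length(x$expressed)
  nv <- length(x$variable)
  cat(sprintf("age_variable_set: %d of %d genes age-variable (%s%% constant)\n",
              nv, n, format(round(100 * (n - nv) / n))))
  invisible(x)
}

#' Gene-ontology enrichment of a target gene set
#'
#' For each term, with `b` the intersection of target and term, `n` the
#' target size, `B` the term size and `N` the background size, the enrichment
#' score is `(b/n)/(B/N)` and the p-value the hypergeometric upper tail
#' `P(X >= b)`. Term sets are intersected with the background first; results
#' are sorted by p.
#'
#' @param target character vector of gene ids (subset of background)
#' @param term_sets named list of character vectors (term -> genes)
#' @param background character vector of gene ids (the gene universe)
#' @return data.frame: `term`, `b`, `n`, `B`, `N`, `enrichment`, `p_value`
#' @export
go_enrichment <- function(target, term_sets, background) {
  target <- unique(target)
  background <- unique(background)
  if (length(target) == 0 || length(background) == 0)
    stop("empty target or background")
  if (!all(target %in% background))
    stop("target must be a subset of the background")
  N <- length(background)
  n <- length(target)
  rows <- lapply(names(term_sets), function(tm) {
    term_genes <- intersect(unique(term_sets[[tm]]), background)
    B <- length(term_genes)
    b <- length(intersect(target, term_genes))
    enr <- if (B == 0) NA_real_ else (b / n) / (B / N)
    p <- if (B == 0) 1 else
      stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
    data.frame(term = tm, b = b, n = n, B = B, N = N,
               enrichment = enr, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}

#' Overlap of a foreign gene panel with expressed / age-variable fly genes
#'
#' Maps a panel of foreign (e.g. mammalian deafness) genes onto fly genes via
#' an ortholog table, then counts how many panel genes are conserved-and-
#' expressed and how many of those are age-variable. Percentages are reported
#' both as exact fractions and rounded to `digits` decimals, matching the
#' precision used when such tables are printed.
#'
#' @param mapping data.frame with columns `fly_gene`, `foreign_gene`;
#'   duplicate rows are collapsed with a warning
#' @param expressed character vector of expressed fly genes
#' @param age_variable character vector of age-variable fly genes
#' @param panel character vector of foreign panel genes
#' @param digits decimals for the printed percentages (0 or 1 typical)
#' @return an `ortholog_overlap`: list of integer counts
#'   (`panel_size`, `conserved_expressed`, `age_variable`) and percentages
#'   (`pct_conserved_expressed`, `pct_age_variable_of_conserved`,
#'   `pct_age_variable_of_panel`)
#' @export
ortholog_overlap <- function(mapping, expressed, age_variable, panel,
                             digits = 1) {
  stopifnot(all(c("fly_gene", "foreign_gene") %in% names(mapping)))
  if (anyDuplicated(mapping)) {
    warning("duplicate mapping rows collapsed")
    mapping <- unique(mapping)
  }
  panel <- unique(panel)
  n_panel <- length(panel)
  m <- mapping[mapping$foreign_gene %in% panel, , drop = FALSE]
  cons_expr <- unique(m$foreign_gene[m$fly_gene %in% expressed])
  av <- unique(m$foreign_gene[m$fly_gene %in% intersect(age_variable,
                                                        expressed)])
  av <- intersect(av, cons_expr)
  pct <- function(num, den) if (den == 0) 0 else round(100 * num / den, digits)
  structure(list(panel_size = n_panel,
                 conserved_expressed = length(cons_expr),
                 age_variable = length(av),
                 pct_conserved_expressed = pct(length(cons_expr), n_panel),
                 pct_age_variable_of_conserved = pct(length(av),
                                                     length(cons_expr)),
                 pct_age_variable_of_panel = pct(length(av), n_panel)),
            class = "ortholog_overlap")
}

#' Prepare gene lists for motif-enrichment submission
#'
#' Three submission rounds of age-variable genes: round I intersects with the
#' configured hearing-relevant GO categories (trafficking, structural, dynein
#' motors, receptors); round II takes the most highly expressed age-variable
#' genes (mean normalised count strictly > `reads_threshold`); round III
#' takes the most extreme genes (maximal |fold change| >= `fc_extreme`, i.e.
#' at least `fc_extreme`-fold up or down, in >= 1 comparison).
#'
#' @param age_variable an `age_variable_set` from [classify_age_variable()]
#' @param counts the `age_series_counts` the comparisons came from (round II)
#' @param go_groups named list of GO category gene vectors (round I)
#' @param comparisons list of `de_comparison` data.frames (round III)
#' @param round "I", "II" or "III"
#' @param reads_threshold round-II expression threshold (strict `>`)
#' @param fc_extreme round-III linear fold-change threshold (inclusive `>=`)
#' @return character vector of gene ids (one id per line when written)
#' @export
prepare_submission_lists <- function(age_variable, counts = NULL,
                                     go_groups = NULL, comparisons = NULL,
                                     round = c("I", "II", "III"),
                                     reads_threshold = 10000,
                                     fc_extreme = 4) {
  round <- match.arg(round)
  av <- age_variable$variable
  if (round == "I") {
    if (is.null(go_groups)) stop("round I needs go_groups")
    out <- character()
    for (g in names(go_groups)) {
      sel <- intersect(av, go_groups[[g]])
      if (length(sel) == 0) warning("empty GO category: ", g)
      out <- union(out, sel)
    }
    return(out)
  }
  if (round == "II") {
    if (is.null(counts)) stop("round II needs counts")
    m <- counts$counts
    y <- sweep(m, 2, size_factors(m), "/")
    mean_expr <- rowMeans(y)
    return(intersect(av, rownames(m)[mean_expr > reads_threshold]))
  }
  if (is.null(comparisons)) stop("round III needs comparisons")
  genes <- comparisons[[1]]$gene
  max_abs_l2 <- Reduce(pmax, lapply(comparisons, function(cmp) abs(cmp$log2fc)))
  intersect(av, genes[2^max_abs_l2 >= fc_extreme])
}

#' Filter candidate transcription factors from a motif-enrichment table
#'
#' Retains candidates that are expressed (part of the expressed gene
#' universe) and whose normalised enrichment score meets the threshold
#' (inclusive `>=`).
#'
#' @param candidates data.frame with at least columns `gene` and `NES`
#' @param expressed character vector of expressed gene ids
#' @param nes_threshold NES cut-off, default 2.5
#' @return the filtered data.frame
#' @export
filter_tf_candidates <- function(candidates, expressed, nes_threshold = 2.5) {
  if (!all(c("gene", "NES") %in% names(candidates)))
    stop("candidate table must have 'gene' and 'NES' columns")
  candidates[candidates$gene %in% expressed &
               candidates$NES >= nes_threshold, , drop = FALSE]
}
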