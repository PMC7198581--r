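# DE stand-in, age-variable filter, enrichment, overlap tables, gene lists

test_that("identical count vectors in both groups give log2FC = 0, p = 1", {
  m <- matrix(rep(c(5L, 100L, 0L, 17L), 6), nrow = 4)
  rownames(m) <- paste0("g", 1:4)
  colnames(m) <- paste0("s", 1:6)
  cs <- list(counts = m,
             samples = data.frame(sample_id = colnames(m),
                                  age_day = rep(c(1, 5), each = 3)))
  de <- pairwise_de(cs, c(1, 5))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$pvalue == 1))
  expect_true(all(de$fdr == 1))
})

test_that("null simulation controls the FDR and keeps raw p calibrated", {
  sp <- count_sim_spec(n_genes = 2000, ages = c(1, 5), reps_per_age = 3,
                       spike_fraction = 0, dispersion = 0.05, seed = 51)
  de <- pairwise_de(simulate_counts(sp), c(1, 5))
  n <- nrow(de)
  expect_lte(mean(de$fdr < 0.10), 0.10 + 2 * sqrt(0.1 * 0.9 / n))
  expect_lte(mean(de$pvalue < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("4-fold spikes at high means are detected with >= 80% power", {
  sp <- count_sim_spec(n_genes = 2000, ages = c(1, 5), reps_per_age = 3,
                       spike_fraction = 0.1, spike_fc = 4, dispersion = 0.05,
                       baseline_log2_mean = 11, baseline_log2_sd = 1,
                       seed = 52)
  cs <- simulate_counts(sp)
  de <- pairwise_de(cs, c(1, 5))
  sel <- cs$truth$spiked & cs$truth$base_mean >= 500
  expect_gt(sum(sel), 50)
  expect_gte(mean(de$pvalue[sel] < 0.05), 0.80)
})

test_that("pairwise_de validates age labels and replicate counts", {
  sp <- count_sim_spec(n_genes = 50, ages = c(1, 5), reps_per_age = 2,
                       seed = 53)
  cs <- simulate_counts(sp)
  expect_error(pairwise_de(cs, c(1, 25)), "missing")
  cs1 <- cs
  cs1$counts <- cs1$counts[, -1]
  cs1$samples <- cs1$samples[-1, ]
  expect_error(pairwise_de(cs1, c(1, 5)), "2 replicates")
})

test_that("BH-adjusted FDR is >= raw p and non-decreasing in p-rank", {
  sp <- count_sim_spec(n_genes = 500, ages = c(1, 5), reps_per_age = 3,
                       spike_fraction = 0.2, seed = 54)
  de <- pairwise_de(simulate_counts(sp), c(1, 5))
  expect_true(all(de$fdr >= de$pvalue))
  o <- order(de$pvalue)
  expect_true(all(diff(de$fdr[o]) >= -1e-15))
})

test_that("age-variable classification applies the strict >1.5-fold boundary", {
  mk <- function(l2fc, p, fdr) {
    d <- data.frame(gene = paste0("g", seq_along(l2fc)), base_mean = 100,
                    log2fc = l2fc, pvalue = p, fdr = fdr)
    attr(d, "pair") <- "d1_vs_d5"
    class(d) <- c("de_comparison", "data.frame")
    d
  }
  # gene 1: FC exactly 1.5 -> excluded; gene 2: FC 2.0 -> included;
  # gene 3: good FC but FDR too high; gene 4: down-regulated 1.6-fold
  cmp <- mk(c(log2(1.5), 1, 2, -log2(1.6)),
            p = c(0.01, 0.01, 0.01, 0.01),
            fdr = c(0.05, 0.05, 0.20, 0.05))
  av <- classify_age_variable(list(cmp))
  expect_identical(sort(av$variable), c("g2", "g4"))
  expect_identical(sort(av$constant), c("g1", "g3"))
})

test_that("variable and constant sets partition the expressed genes", {
  sp <- count_sim_spec(n_genes = 800, ages = c(1, 5, 25), reps_per_age = 3,
                       spike_fraction = 0.15, seed = 55)
  cs <- simulate_counts(sp)
  cmps <- list(pairwise_de(cs, c(1, 5)), pairwise_de(cs, c(5, 25)))
  av <- classify_age_variable(cmps)
  expect_length(intersect(av$variable, av$constant), 0)
  expect_setequal(c(av$variable, av$constant), av$expressed)
})

test_that("the printed partition arithmetic reproduces 64% constant genes", {
  # 16,243 expressed, 5,855 variable -> 10,388 constant = 64%
  expressed <- sprintf("g%05d", 1:16243)
  variable <- expressed[1:5855]
  n_constant <- length(setdiff(expressed, variable))
  expect_identical(n_constant, 10388L)
  expect_identical(round(100 * n_constant / length(expressed)), 64)
})

test_that("enrichment score follows (b/n)/(B/N) with the hypergeometric tail", {
  bg <- sprintf("g%05d", 1:16243)
  target <- bg[1:100]
  terms <- list(hit = c(bg[1:10], bg[200:389]),        # b = 10, B = 200
                prop = bg[1:16243])                     # b/n = B/N = 1
  res <- go_enrichment(target, terms, bg)
  hit <- res[res$term == "hit", ]
  expect_equal(hit$enrichment, (10 / 100) / (200 / 16243), tolerance = 1e-12)
  expect_equal(hit$enrichment, 8.12, tolerance = 1e-3)
  expect_equal(hit$p_value,
               phyper(9, 200, 16243 - 200, 100, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$enrichment[res$term == "prop"], 1, tolerance = 1e-12)
})

test_that("zero intersection gives enrichment 0 and p = 1", {
  bg <- paste0("g", 1:500)
  res <- go_enrichment(bg[1:20], list(t = bg[100:150]), bg)
  expect_equal(res$enrichment, 0)
  expect_equal(res$p_value, 1)
})

test_that("hypergeometric tail matches brute-force enumeration on small universes", {
  # oracle: direct sum of the hypergeometric pmf over j >= b
  brute_tail <- function(b, B, N, n) {
    j <- b:min(B, n)
    sum(choose(B, j) * choose(N - B, n - j)) / choose(N, n)
  }
  set.seed(56)
  bg <- paste0("g", 1:300)
  for (i in 1:10) {
    n <- sample(10:80, 1)
    B <- sample(10:120, 1)
    target <- sample(bg, n)
    term <- sample(bg, B)
    res <- go_enrichment(target, list(t = term), bg)
    expect_equal(res$p_value, brute_tail(res$b, B, 300, n),
                 tolerance = 1e-10)
  }
})

test_that("ortholog overlap reproduces the printed panel percentages", {
  # fly gene f_k maps to panel gene p_k one-to-one; set memberships built
  # from the printed integer counts
  mk_panel <- function(n_panel, n_cons_expr, n_av) {
    panel <- sprintf("p%03d", seq_len(n_panel))
    fly <- sprintf("f%03d", seq_len(n_panel))
    mapping <- data.frame(fly_gene = fly, foreign_gene = panel)
    list(mapping = mapping, panel = panel,
         expressed = fly[seq_len(n_cons_expr)],
         age_variable = fly[seq_len(n_av)])
  }
  # 294-gene panel, 108 age-variable -> 36.7%
  a <- mk_panel(294, 294, 108)
  ov_a <- ortholog_overlap(a$mapping, a$expressed, a$age_variable, a$panel)
  expect_identical(ov_a$age_variable, 108L)
  expect_equal(ov_a$pct_age_variable_of_panel, 36.7)
  # 154-gene panel, 105 conserved-and-expressed (68%), 33 age-variable (31%)
  b <- mk_panel(154, 105, 33)
  ov_b <- ortholog_overlap(b$mapping, b$expressed, b$age_variable, b$panel,
                           digits = 0)
  expect_identical(ov_b$conserved_expressed, 105L)
  expect_equal(ov_b$pct_conserved_expressed, 68)
  expect_equal(ov_b$pct_age_variable_of_conserved, 31)
  # 111-gene mouse panel, 74 conserved-and-expressed -> 67%
  c3 <- mk_panel(111, 74, 24)
  ov_c <- ortholog_overlap(c3$mapping, c3$expressed, c3$age_variable,
                           c3$panel, digits = 0)
  expect_equal(ov_c$pct_conserved_expressed, 67)
})

test_that("overlap percentages are stable under row permutation and empty sets are safe", {
  mapping <- data.frame(fly_gene = c("f1", "f2", "f3"),
                        foreign_gene = c("p1", "p2", "p3"))
  ov1 <- ortholog_overlap(mapping, c("f1", "f2"), "f1", c("p1", "p2", "p3"))
  set.seed(57)
  ov2 <- ortholog_overlap(mapping[sample(3), ], c("f2", "f1"), "f1",
                          c("p3", "p1", "p2"))
  expect_identical(unclass(ov1), unclass(ov2))
  ov0 <- ortholog_overlap(mapping, character(), character(), "p9")
  expect_identical(ov0$conserved_expressed, 0L)
  expect_equal(ov0$pct_conserved_expressed, 0)
  expect_warning(ortholog_overlap(rbind(mapping, mapping[1, ]),
                                  "f1", "f1", "p1"), "duplicate")
})

test_that("submission rounds apply their boundary rules (> 10,000 reads; >= 4-fold)", {
  genes <- paste0("g", 1:5)
  av <- structure(list(variable = genes, constant = character(),
                       expressed = genes, qualifying = NULL),
                  class = "age_variable_set")
  # round II: mean exactly 10,000 excluded (strict >)
  m <- matrix(c(10000L, 10001L, 9999L, 20000L, 5L), 5, 4)
  rownames(m) <- genes
  colnames(m) <- paste0("s", 1:4)
  counts <- list(counts = m,
                 samples = data.frame(sample_id = colnames(m),
                                      age_day = rep(c(1, 5), each = 2)))
  r2 <- prepare_submission_lists(av, counts = counts, round = "II")
  expect_setequal(r2, c("g2", "g4"))
  # round III: FC exactly 4 included (inclusive >=)
  cmp <- data.frame(gene = genes, base_mean = 1,
                    log2fc = c(2, log2(4), 1, -2.5, 0),
                    pvalue = 0.01, fdr = 0.01)
  attr(cmp, "pair") <- "d1_vs_d5"
  r3 <- prepare_submission_lists(av, comparisons = list(cmp), round = "III")
  expect_setequal(r3, c("g1", "g2", "g4"))
  # round I: union of GO groups, warning on an empty category
  expect_warning(
    r1 <- prepare_submission_lists(av,
                                   go_groups = list(trafficking = c("g1", "g9"),
                                                    dynein = character()),
                                   round = "I"),
    "empty GO category")
  expect_identical(r1, "g1")
})

test_that("TF candidate filter keeps expressed genes with NES >= 2.5 (inclusive)", {
  cand <- data.frame(gene = paste0("tf", 1:10),
                     NES = c(3.1, 2.5, 2.49, 4, 1, 2.8, 3.5, 2.6, 5, 2.5))
  expressed <- paste0("tf", c(1:6))
  out <- filter_tf_candidates(cand, expressed)
  # of the 6 expressed, tf3 (2.49) and tf5 (1.0) fall below threshold
  expect_setequal(out$gene, c("tf1", "tf2", "tf4", "tf6"))
  expect_true(all(out$NES >= 2.5))
  expect_error(filter_tf_candidates(data.frame(x = 1), expressed), "column")
})
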