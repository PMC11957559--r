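ratios_df <- function(ann, x_vals, a_vals) {
  nx <- sum(ann$genes$is_x)
  data.frame(gene_id = ann$genes$gene_id,
             log2_mf = c(x_vals, a_vals),
             excluded = FALSE)
}

test_that("log2 sex ratio handles equality, halving and zero means", {
  means <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      mean_M = c(10, 5, 0, 3),
                      mean_F = c(10, 10, 4, 0))
  r <- log2_sex_ratio(means)
  expect_equal(r$log2_mf[1:2], c(0, -1))
  expect_true(all(r$excluded[3:4]))
  expect_true(all(is.na(r$log2_mf[3:4])))
  # pseudo-count rescues zero-mean genes
  r2 <- log2_sex_ratio(means, pseudo = 1)
  expect_false(any(r2$excluded))
})

test_that("rank-sum p-values match exact permutation enumeration (n <= 8)", {
  set.seed(11)
  ann33 <- two_scaffold_ann(3, 3)
  for (i in 1:20) {
    x <- round(rnorm(3), 3)
    a <- round(rnorm(3), 3)
    res <- xa_ratio_test(ratios_df(ann33, x, a), ann33)
    expect_true(res$exact)
    expect_equal(res$p, rank_sum_perm_p(x, a), tolerance = 1e-12)
  }
  for (i in 1:20) {
    nx <- sample(2:8, 1); na <- sample(2:8, 1)
    ann <- two_scaffold_ann(nx, na)
    x <- round(rnorm(nx), 3); a <- round(rnorm(na), 3)
    res <- xa_ratio_test(ratios_df(ann, x, a), ann)
    expect_equal(res$p, rank_sum_perm_p(x, a), tolerance = 1e-12)
  }
})

test_that("signed-rank p-values match exact enumeration (n <= 8)", {
  set.seed(13)
  for (n in c(6, 7, 8)) {
    for (i in 1:10) {
      x <- round(rnorm(n, mean = -1.3, sd = 0.4), 3)
      res <- msci_test(x, reference = -1)
      if (res$exact)
        expect_equal(res$p, signed_rank_perm_p(x, -1), tolerance = 1e-12)
    }
  }
})

test_that("X-vs-autosome test detects a two-fold X reduction", {
  study <- run_dc_study(dc_sim_config("none", seed = 404))
  res <- xa_ratio_test(study$ratios, study$annotation)
  expect_lt(res$p, 1e-6)
  expect_lt(res$median_x, -0.8)
  # and within-sex: male X means are halved relative to autosomes
  wm <- within_sex_xa_test(study$means, study$annotation, "M")
  expect_lt(wm$p, 1e-3)
  expect_lt(wm$median_x, wm$median_auto)
})

test_that("class size preconditions are enforced", {
  ann <- two_scaffold_ann(1, 5)
  r <- ratios_df(ann, 0, rnorm(5))
  expect_error(xa_ratio_test(r, ann), ">= 2 genes")
  means <- data.frame(gene_id = ann$genes$gene_id,
                      mean_M = rexp(6), mean_F = rexp(6))
  expect_error(within_sex_xa_test(means, ann, "M"), ">= 2 genes")
})

test_that("MSCI test is degenerate at the reference and centered under the null", {
  d <- msci_test(rep(-1, 10))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  expect_equal(d$V, 0)

  set.seed(21)
  ps <- replicate(200, msci_test(rnorm(50, mean = -1, sd = 0.3))$p)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)

  expect_error(msci_test(rnorm(5)), ">= 6")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  # monotone non-decreasing on the sorted p-vector
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("sex-biased gene recovery on simulated 4-fold effects", {
  cfg <- sim_config(n_scaffolds = 2, scaffold_lengths = c(8e6, 8e6),
                    x_scaffold = 2, genes_per_scaffold = c(700, 60),
                    groups = data.frame(sex = c("M", "F"), tissue = "gonad",
                                        stage = "N1", n_replicates = 3),
                    dc_mode = "complete_upregulation",
                    sex_biased_fraction = 0.3, sex_bias_fold = 4,
                    tissue_specific_fraction = 0, dispersion = 0.05,
                    seed = 71)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  sb <- sex_biased_genes(sim$counts, sim$sheet, "gonad", "N1")
  est_frac <- sb$counts$n[sb$counts$category == "SB"] /
    sb$counts$n[sb$counts$category == "T"]
  expect_lt(abs(est_frac - 0.3), 0.07)
  # among truly biased genes that are called, the direction is right
  truth <- sim$truth$sex_bias[names(sb$labels)]
  hit <- sb$labels != "unbiased" & truth != "unbiased"
  expect_gt(mean(sb$labels[hit] == truth[hit]), 0.98)
})

test_that("sex-bias false positives stay controlled under the null", {
  fps <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config(n_scaffolds = 2, scaffold_lengths = c(8e6, 8e6),
                      x_scaffold = 2, genes_per_scaffold = c(500, 50),
                      groups = data.frame(sex = c("M", "F"),
                                          tissue = "gonad", stage = "N1",
                                          n_replicates = 3),
                      dc_mode = "complete_upregulation",
                      sex_biased_fraction = 0, tissue_specific_fraction = 0,
                      dispersion = 0.05, seed = 500 + i)
    ann <- simulate_annotation(cfg)
    sim <- simulate_counts(cfg, ann)
    sb <- sex_biased_genes(sim$counts, sim$sheet, "gonad", "N1")
    fps[i] <- mean(sb$labels != "unbiased")
  }
  expect_lte(mean(fps), 0.05)

  # a gene with identical counts everywhere is never called biased
  cfg <- tiny_config(seed = 9)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  flat <- sim$counts$counts
  flat["scaffold_1_g0001", ] <- 500
  sb <- sex_biased_genes(count_matrix(flat), sim$sheet, "brain", "adult")
  expect_equal(unname(sb$labels["scaffold_1_g0001"]), "unbiased")
})

test_that("replicate preconditions for sex-bias testing", {
  cfg <- sim_config(n_scaffolds = 2, scaffold_lengths = c(2e6, 2e6),
                    x_scaffold = 1, genes_per_scaffold = 30,
                    groups = data.frame(sex = c("M", "F"), tissue = "t",
                                        stage = "s",
                                        n_replicates = c(1, 3)),
                    seed = 2)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  expect_error(sex_biased_genes(sim$counts, sim$sheet, "t", "s"),
               ">= 2 replicates")
})

test_that("germline fraction inverts the mixture model", {
  expect_equal(estimate_germline_fraction(1, 0)$g, 0)
  expect_equal(estimate_germline_fraction(0.1, 0.1)$g, 1)
  expect_equal(estimate_germline_fraction(0.55, 0.1)$g, 0.5)
  expect_error(estimate_germline_fraction(0.5, 1), "residual")
  over <- estimate_germline_fraction(1.2, 0)
  expect_true(over$clamped)
  expect_equal(over$g, 0)
})

test_that("loess smoothing reproduces constants and lines, bounds noise", {
  x <- seq(0, 100, length.out = 40)
  cst <- smooth_expression_along_x(x, rep(3, 40))
  expect_equal(cst$smoothed, rep(3, 40), tolerance = 1e-8)
  lin <- smooth_expression_along_x(x, 2 * x + 1)
  expect_equal(lin$smoothed, 2 * sort(x) + 1, tolerance = 1e-6)
  set.seed(4)
  y <- rnorm(40)
  sm <- smooth_expression_along_x(x, y)
  expect_true(all(sm$smoothed >= min(y) - 1e-9 &
                    sm$smoothed <= max(y) + 1e-9))
  expect_error(smooth_expression_along_x(1:5, 1:5), ">= 10")
})
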