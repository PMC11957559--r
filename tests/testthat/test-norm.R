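cm_from <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  count_matrix(m)
}

test_that("low-expression filter keeps genes by CPM in enough libraries", {
  # filler genes pad every library to exactly 1e6, so counts == CPM
  counts <- rbind(gA = c(600, 600, 400, 400),
                  gB = c(400, 400, 400, 400),
                  gC = c(0, 0, 0, 0),
                  gD = c(5000, 5000, 5000, 5000))
  filler <- matrix(round((1e6 - colSums(counts)) / 2), nrow = 2, ncol = 4,
                   byrow = TRUE, dimnames = list(c("f1", "f2"), NULL))
  cm <- cm_from(rbind(counts, filler))
  stopifnot(all(cm$lib_sizes == 1e6))
  kept <- filter_low_expression(cm, min_cpm = 500, min_libraries = 2)
  expect_true("gA" %in% kept)    # 600 CPM in 2 of 4 libraries
  expect_false("gB" %in% kept)   # 400 CPM everywhere
  expect_false("gC" %in% kept)   # all zero
  expect_true("gD" %in% kept)
  expect_error(filter_low_expression(cm, samples = "s1"),
               "fewer than min_libraries")
})

test_that("TMM factors are 1 for identical or depth-scaled samples", {
  set.seed(7)
  base <- rpois(100, 200)
  cm <- cm_from(cbind(s1 = base, s2 = base, s3 = base))
  expect_equal(unname(tmm_factors(cm)), rep(1, 3), tolerance = 1e-12)
  cm2 <- cm_from(cbind(s1 = base, s2 = 2L * base))
  f <- tmm_factors(cm2)
  expect_equal(unname(f[1]), unname(f[2]), tolerance = 1e-9)
  expect_equal(prod(f), 1, tolerance = 1e-9)
})

test_that("TMM factors match a direct evaluation of the trimming formula", {
  set.seed(123)
  m <- matrix(rnbinom(50 * 2, mu = 100, size = 10), ncol = 2,
              dimnames = list(sprintf("g%02d", 1:50), c("s1", "s2")))
  m["g01", 1] <- 5000                      # one inflated gene
  cm <- cm_from(m)
  expect_equal(unname(tmm_factors(cm)), unname(tmm_oracle(m)),
               tolerance = 1e-10)

  # and on a larger case with library-size differences
  set.seed(99)
  m2 <- matrix(rnbinom(200 * 4, mu = 80, size = 5), ncol = 4,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  m2[, 3] <- m2[, 3] * 3L
  cm2 <- cm_from(m2)
  expect_equal(unname(tmm_factors(cm2)), unname(tmm_oracle(m2)),
               tolerance = 1e-10)
  expect_equal(exp(mean(log(tmm_factors(cm2)))), 1, tolerance = 1e-12)
})

test_that("CPM follows its definition and scale invariances", {
  cm <- cm_from(matrix(c(500, 999500, 100, 999900), ncol = 2,
                       dimnames = list(c("gA", "gB"), c("s1", "s2"))))
  expect_equal(cpm_matrix(cm)["gA", "s1"], 500)
  # factor 2 halves CPM
  expect_equal(cpm_matrix(cm, norm_factors = c(2, 1))["gA", "s1"], 250)
  # doubling counts and library leaves CPM unchanged
  cm2 <- cm_from(2 * cm$counts)
  expect_equal(cpm_matrix(cm2), cpm_matrix(cm), ignore_attr = TRUE)
  # with unit factors every column of the full matrix sums to 1e6
  expect_equal(unname(colSums(cpm_matrix(cm))), c(1e6, 1e6))
})

test_that("RPKM divides CPM by exon-union kilobases", {
  genes <- data.frame(gene_id = c("gA", "gB"), scaffold = "s",
                      strand = "+", start = c(1, 5001),
                      end = c(1000, 7000),
                      exon_union_length = c(1000, 2000))
  exons <- genes[, c("gene_id", "scaffold", "strand", "start", "end")]
  ann <- gene_annotation(genes, exons, c(s = 10000))
  cm <- cm_from(matrix(c(100, 999900, 100, 999900), ncol = 2,
                       dimnames = list(c("gA", "gB"), c("s1", "s2"))))
  rp <- rpkm_matrix(cm, ann)
  expect_equal(rp["gA", "s1"], 100)          # 100 cts / 1e6 lib / 1 kb
  expect_equal(rp["gB", "s1"], 999900 / 2)  # CPM 999900 over 2 kb
  cm0 <- cm_from(matrix(c(0, 1e6), ncol = 1,
                        dimnames = list(c("gA", "gB"), "s1")))
  expect_equal(rpkm_matrix(cm0, ann)["gA", "s1"], 0)
  expect_error(rpkm_matrix(cm, ann, genes = c("gA", "gZ")), "gZ")
})

test_that("RPKM is invariant to uniform depth rescaling of a sample", {
  cfg <- tiny_config(seed = 31)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  rp1 <- rpkm_matrix(sim$counts, ann)
  m2 <- sim$counts$counts
  m2[, 1] <- m2[, 1] * 5
  rp2 <- rpkm_matrix(count_matrix(m2), ann)
  expect_equal(rp1, rp2, tolerance = 1e-12)
})

test_that("sex means average replicates and demand both sexes", {
  expr <- matrix(c(10, 20, 7, 7), nrow = 1,
                 dimnames = list("gA", c("m1", "m2", "f1", "f2")))
  sheet <- sample_sheet(data.frame(
    sample_id = c("m1", "m2", "f1", "f2"),
    sex = c("M", "M", "F", "F"), tissue = "t", stage = "N1",
    replicate = c(1, 2, 1, 2)))
  mm <- mean_by_sex(expr, sheet)
  expect_equal(mm$mean_M, 15)
  expect_equal(mm$mean_F, 7)
  # permuting columns leaves the means unchanged
  mm2 <- mean_by_sex(expr[, c(3, 1, 4, 2), drop = FALSE], sheet)
  expect_equal(mm2$mean_M, 15)
  single <- mean_by_sex(expr[, c(1, 3), drop = FALSE], sheet)
  expect_equal(single$mean_M, 10)   # single replicate is itself
  expect_error(mean_by_sex(expr[, 1:2, drop = FALSE], sheet), "no F")
})

test_that("normalization equalizes CPM across simulated equal baselines", {
  cfg <- dc_sim_config("complete_upregulation", seed = 17)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  keep <- filter_low_expression(sim$counts)
  nf <- tmm_factors(sim$counts, keep)
  cp <- cpm_matrix(sim$counts, keep, norm_factors = nf)
  sample_means <- colMeans(cp)
  expect_lt(max(sample_means) / min(sample_means), 1.05)
})
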