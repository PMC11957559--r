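test_that("simulated annotation respects layout, bounds and determinism", {
  cfg <- sim_config(n_scaffolds = 2, scaffold_lengths = c(5e5, 4e5),
                    x_scaffold = 1, genes_per_scaffold = 10,
                    gene_length_range = c(900, 1100), seed = 11)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 20)
  expect_true(all(ann$genes$end <= ann$scaffold_lengths[ann$genes$scaffold]))
  expect_true(all(ann$genes$start >= 1))
  expect_true(all(ann$genes$exon_union_length >= 900 &
                    ann$genes$exon_union_length <= 1100))
  # genes on a scaffold do not overlap
  for (s in split(ann$genes, ann$genes$scaffold)) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
  # exon union lengths agree with the recorded exon intervals
  ul <- tapply(ann$exons$end - ann$exons$start + 1, ann$exons$gene_id, sum)
  expect_equal(as.numeric(ul[ann$genes$gene_id]),
               as.numeric(ann$genes$exon_union_length))

  ann2 <- simulate_annotation(cfg)
  expect_identical(ann, ann2)

  f1 <- tempfile(); f2 <- tempfile()
  write_gff3(ann, f1); write_gff3(simulate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("annotation simulation fails when genes cannot fit", {
  cfg <- sim_config(n_scaffolds = 1, scaffold_lengths = 10000,
                    x_scaffold = 1, genes_per_scaffold = 10,
                    gene_length_range = c(2000, 3000), seed = 1)
  expect_error(simulate_annotation(cfg), "exceeds scaffold length")
})

test_that("count means follow the copy-number x regulation model", {
  # realized M:F mean-count ratios on X and autosomes per regime
  ratio_by_class <- function(mode, g = 0.5, res = 0) {
    cfg <- dc_sim_config(mode, seed = 301, g = g, res = res,
                         n_reps = 10, dispersion = 0.05)
    ann <- simulate_annotation(cfg)
    sim <- simulate_counts(cfg, ann)
    sheet <- sim$sheet
    # divide out library-size variation before comparing sexes
    frac <- t(t(sim$counts$counts) / sim$counts$lib_sizes)
    m <- rowMeans(frac[, sheet$sample_id[sheet$sex == "M"]])
    f <- rowMeans(frac[, sheet$sample_id[sheet$sex == "F"]])
    isx <- stats::setNames(ann$genes$is_x, ann$genes$gene_id)
    xr <- sum(m[isx[names(m)]]) / sum(f[isx[names(f)]])
    # correct for the overall library composition shift the X causes
    ar <- sum(m[!isx[names(m)]]) / sum(f[!isx[names(f)]])
    c(x = xr / ar, auto = 1)
  }
  r_none <- ratio_by_class("none")
  expect_equal(unname(r_none["x"]), 0.5, tolerance = 0.10)
  r_comp <- ratio_by_class("complete_upregulation")
  expect_equal(unname(r_comp["x"]), 1, tolerance = 0.10)
  r_msci <- ratio_by_class("msci_mixture", g = 0.5, res = 0)
  expect_equal(unname(r_msci["x"]), 0.5, tolerance = 0.10)  # (0.5*2+0)/2
  r_fdr <- ratio_by_class("female_downregulation")
  expect_equal(unname(r_fdr["x"]), 1, tolerance = 0.10)     # 1 vs 2*0.5
})

test_that("count simulation is deterministic and labels every gene once", {
  cfg <- tiny_config(seed = 5, sex_biased_fraction = 0.2,
                     tissue_specific_fraction = 0.2)
  ann <- simulate_annotation(cfg)
  s1 <- simulate_counts(cfg, ann)
  s2 <- simulate_counts(cfg, ann)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  expect_setequal(names(s1$truth$sex_bias), ann$genes$gene_id)
  expect_setequal(names(s1$truth$tissue_label), ann$genes$gene_id)
  expect_true(all(s1$truth$sex_bias %in% c("MB", "FB", "unbiased")))
  expect_equal(sum(s1$truth$sex_bias != "unbiased"),
               round(0.2 * nrow(ann$genes)))
})

test_that("DNA coverage has Poisson means with a halved male X", {
  cfg <- sim_config(n_scaffolds = 3, scaffold_lengths = rep(2e7, 3),
                    x_scaffold = 2, genes_per_scaffold = 10, seed = 9)
  fem <- simulate_dna_coverage(cfg, "F", window = 1e5, depth = 50)
  w <- fem$windows
  for (s in unique(w$scaffold)) {
    d <- w$mean_depth[w$scaffold == s]
    expect_gt(length(d), 100)
    expect_lt(abs(mean(d) - 50), 3 * sqrt(50 / length(d)))
  }
  mal <- simulate_dna_coverage(cfg, "M", window = 1e5, depth = 50)
  mw <- mal$windows
  x <- mw$mean_depth[mw$scaffold == "scaffold_2"]
  a <- mw$mean_depth[mw$scaffold != "scaffold_2"]
  expect_lt(abs(mean(x) - 25), 3 * sqrt(25 / length(x)))
  expect_lt(abs(mean(a) - 50), 3 * sqrt(50 / length(a)))
})

test_that("coverage windows tile scaffolds exactly", {
  w <- make_windows(c(s = 1e6), 1e5)
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 9e5, by = 1e5))
  expect_equal(w$end, seq(1e5, 1e6, by = 1e5))
  expect_false(any(w$partial))
})

test_that("ChIP pair shares its tiling and encodes the X fold", {
  cfg <- sim_config(n_scaffolds = 3, scaffold_lengths = rep(9e6, 3),
                    x_scaffold = 1, genes_per_scaffold = 10,
                    chip_x_enrichment = 2, seed = 21)
  pair <- simulate_chip_pair(cfg, window = 30000, depth = 30)
  expect_identical(pair$chip$windows[, c("scaffold", "start", "end")],
                   pair$input$windows[, c("scaffold", "start", "end")])
  cx <- pair$chip$windows$mean_depth[pair$chip$windows$scaffold ==
                                       "scaffold_1"]
  ix <- pair$input$windows$mean_depth[pair$input$windows$scaffold ==
                                        "scaffold_1"]
  expect_equal(mean(cx) / mean(ix), 2, tolerance = 0.1)
  ca <- pair$chip$windows$mean_depth[pair$chip$windows$scaffold !=
                                       "scaffold_1"]
  ia <- pair$input$windows$mean_depth[pair$input$windows$scaffold !=
                                        "scaffold_1"]
  expect_equal(mean(ca) / mean(ia), 1, tolerance = 0.05)

  cfg1 <- sim_config(n_scaffolds = 3, scaffold_lengths = rep(9e6, 3),
                     x_scaffold = 1, genes_per_scaffold = 10,
                     chip_x_enrichment = 1, seed = 21)
  p1 <- simulate_chip_pair(cfg1, window = 30000, depth = 30)
  lr <- log2(mean(p1$chip$windows$mean_depth) /
               mean(p1$input$windows$mean_depth))
  expect_lt(abs(lr), 0.05)
})

test_that("config validation rejects invalid settings", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(germ_fraction = 1.2), "proportions")
  expect_error(sim_config(x_scaffold = 13), "x_scaffold")
  expect_error(sim_config(groups = data.frame()), "groups")
  expect_error(sim_config(chip_x_enrichment = 0), "chip_x_enrichment")
})
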