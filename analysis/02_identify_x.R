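#!/usr/bin/env Rscript
# Identify the X chromosome from male vs female DNA-seq coverage: in an
# X0/XX system males carry one X copy, so their coverage on the X is
# expected at half the female level (log2 ratio -1 per window).

source("analysis/00_study_design.R")

cfg <- study_design()
win <- make_windows(cfg$scaffold_lengths, DNA_WINDOW)
mapped <- read_library_sizes()

male <- normalize_track(read_bedgraph(
  file.path(INPUT_DIR, "dna_male.bedgraph"), win, mapped[["dna_male"]]))
female <- normalize_track(read_bedgraph(
  file.path(INPUT_DIR, "dna_female.bedgraph"), win, mapped[["dna_female"]]))

ratios <- coverage_log2_ratio(male, female)
report <- classify_scaffolds(ratios)

dir.create("results", showWarnings = FALSE)
write.table(format(report, digits = 4),
            "results/x_identification.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(format(ratios, digits = 4), "results/coverage_log2_mf.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

x_called <- report$scaffold[report$classification == "X-linked"]
cat("Scaffold classification (", nrow(ratios), "windows of",
    DNA_WINDOW / 1000, "kb):\n")
print(report[, c("scaffold", "n_windows", "median_log2_mf",
                 "classification")], row.names = FALSE)
cat("\nX-linked call:", x_called, "- median log2(M:F) =",
    round(report$median_log2_mf[report$scaffold == x_called], 3),
    "(hemizygous expectation -1; autosomes ~0)\n")
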