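#!/usr/bin/env Rscript
# Generate the synthetic study: gene annotation (GFF3), RNA-seq counts
# (TSV), sample sheet, male/female DNA coverage and ChIP/input tracks
# (bedGraph), plus the ground-truth sidecar. Everything downstream reads
# these files back from disk, exercising the same entry points a real
# dataset would use.

source("analysis/00_study_design.R")

cfg <- study_design()
files <- simulate_study_files(cfg, INPUT_DIR,
                              dna_window = DNA_WINDOW, dna_depth = 50,
                              chip_window = CHIP_WINDOW, chip_depth = 30)

ann <- read_gff3(files[["annotation"]])
sheet <- read_sample_sheet(files[["samples"]])
cm <- read_counts(files[["counts"]], sheet)

cat("Simulated study written to", INPUT_DIR, "\n")
cat("  genes:      ", nrow(ann$genes), "on", length(ann$scaffold_lengths),
    "scaffolds\n")
cat("  samples:    ", nrow(sheet), "(",
    length(unique(paste(sheet$tissue, sheet$stage))), "tissue x stage",
    "groups, 3 replicates per sex )\n")
cat("  library sizes:", format(round(range(cm$lib_sizes)), big.mark = ","),
    "\n")
cat("  true X:     ", jsonlite::read_json(files[["truth"]])$true_x_scaffold,
    "\n")
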