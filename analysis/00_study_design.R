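# Shared study design for the analysis scripts.
#
# One synthetic X0/XX study: 12 chromosomes (X = third largest), two
# tissues (brain as soma, reproductive tract as gonad) at three stages
# (N1, N4, adult), 3 replicates per sex. Somatic groups and N1 gonads are
# fully dosage-compensated by male X upregulation; N4 and adult gonads
# follow the germ/soma MSCI mixture (germ fraction 0.8 at N4 when meiosis
# dominates, 0.6 in adults where accessory somatic tissue dilutes the
# germline; residual X activity 10%).

library(xdose)

STUDY_SEED <- 1234L
INPUT_DIR <- "results/study_inputs"
DNA_WINDOW <- 1e5      # bp, male/female DNA coverage windows
CHIP_WINDOW <- 3e4     # bp, ChIP/input windows

study_design <- function(seed = STUDY_SEED) {
  groups <- rbind(
    expand.grid(sex = c("M", "F"), tissue = c("brain", "gut"),
                stage = c("N1", "N4", "adult"), n_replicates = 3,
                stringsAsFactors = FALSE),
    expand.grid(sex = c("M", "F"), tissue = "reproductive_tract",
                stage = c("N1", "N4", "adult"), n_replicates = 3,
                stringsAsFactors = FALSE))
  groups$dc_mode <- "complete_upregulation"
  groups$germ_fraction <- 0
  meiotic <- groups$tissue == "reproductive_tract" &
    groups$stage %in% c("N4", "adult")
  groups$dc_mode[meiotic] <- "msci_mixture"
  groups$germ_fraction[meiotic] <-
    ifelse(groups$stage[meiotic] == "N4", 0.8, 0.6)
  sim_config(n_scaffolds = 12, x_scaffold = 3,
             genes_per_scaffold = c(182, 182, 200, rep(182, 9)),
             groups = groups, dispersion = 0.05,
             dc_mode = "complete_upregulation",
             germ_fraction = 0.8, residual_x_activity = 0.1,
             sex_biased_fraction = 0.1, tissue_specific_fraction = 0.1,
             seed = seed)
}

read_library_sizes <- function() {
  libs <- read.delim(file.path(INPUT_DIR, "libraries.tsv"))
  setNames(libs$mapped_reads, libs$library)
}
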