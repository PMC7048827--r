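# Shared configuration for the analysis drivers.
#
# Every driver re-derives the synthetic ground truth from (SEED, default
# config), so the scripts can be run independently and all outputs are
# reproducible text tables. No binary intermediates are written.

library(semethdyn)

SEED <- 1L
RESULTS <- file.path("results")

truth_default <- function() {
  simulate_architecture(simulation_config(), seed = SEED)
}

write_tsv <- function(x, dir, file) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, file)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
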