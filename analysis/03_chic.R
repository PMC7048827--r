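#!/usr/bin/env Rscript
# Stage 3: capture Hi-C processing — filtering, distance-binned
# median-of-ratios normalisation, replicate correlation, per-subregion
# interaction frequency and the class contrast model.

source(file.path("analysis", "00_config.R"))

truth <- truth_default()
subregions <- utils::read.delim(
  file.path(RESULTS, "partition", "subregions_full.tsv"),
  stringsAsFactors = FALSE)

chic <- simulate_chic(truth, seed = SEED)
kept <- filter_interactions(chic$records)
message(sprintf("kept %d / %d interaction records after score/coverage filters",
                nrow(kept), nrow(chic$records)))

norm <- normalize_by_distance_bin(as.matrix(kept[, c("reads1", "reads2")]),
                                  kept$distance)
outdir <- file.path(RESULTS, "chic")
sf <- as.data.frame(norm$size_factors)
names(sf) <- c("reads1", "reads2")
sf$distance_bin <- rownames(norm$size_factors)
write_tsv(sf, outdir, "size_factors.tsv")

rho <- library_correlation(norm$normalized, 1L, 2L)
kept$norm_reads <- rowMeans(norm$normalized)
freq <- subregion_interaction_frequency(kept, subregions)
write_tsv(freq, outdir, "subregion_frequency.tsv")

fit <- interaction_class_model(freq)
write_tsv(fit$coefficients, outdir, "class_model.tsv")
write_tsv(data.frame(metric = "replicate_spearman", value = rho),
          outdir, "replicate_correlation.tsv")
print(fit$coefficients)
message(sprintf("replicate Spearman rho = %.4f", rho))
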