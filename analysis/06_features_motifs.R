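#!/usr/bin/env Rscript
# Stage 6: epigenetic features over subregions (simulated ChIP/input tracks,
# CpG density, DM-vs-PU logistic models) and PWM motif enrichment per
# subregion class on a simulated genome with a motif planted in PU
# subregions.

source(file.path("analysis", "00_config.R"))

truth <- truth_default()
subregions <- utils::read.delim(
  file.path(RESULTS, "partition", "subregions_full.tsv"),
  stringsAsFactors = FALSE)
pu_dm <- subregions[subregions$class %in% c("PU", "DM") &
                      (subregions$end - subregions$start) >= 200L, ]

set.seed(SEED)
chrom_len <- truth$chrom_len

## ---- simulated ChIP track with extra signal over PU subregions ----------
base_rate <- 0.5
chip <- rpois(chrom_len %/% 10L, base_rate)  # 10-bp bins
input <- rpois(chrom_len %/% 10L, base_rate)
# graded boost: strongest over PU, partial over DM, so the classes
# overlap and the logistic contrast is informative rather than separating
for (i in seq_len(nrow(pu_dm))) {
  bins <- (pu_dm$start[i] %/% 10L):(pu_dm$end[i] %/% 10L - 1L)
  boost <- if (pu_dm$class[i] == "PU") 0.6 else 0.3
  chip[bins + 1L] <- chip[bins + 1L] + rpois(length(bins), boost)
}
# expand to per-bp for the region quantifiers
chip_bp <- rep(chip, each = 10L)
input_bp <- rep(input, each = 10L)

enr <- vapply(seq_len(nrow(pu_dm)), function(i) {
  enrichment_score(chip_bp, input_bp,
                   data.frame(start = pu_dm$start[i], end = pu_dm$end[i]))
}, 0.0)

## ---- simulated genome sequence with CpG enrichment + motif in PU --------
genome_chars <- sample(c("A", "C", "G", "T"), chrom_len, TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3))
motif <- c("G", "A", "T", "A", "A", "G")
for (i in seq_len(nrow(pu_dm))) {
  s <- pu_dm$start[i]
  e <- pu_dm$end[i]
  # CpG-dense core in every PU/DM subregion
  cg_at <- seq(s + 5L, e - 5L, by = 25L)
  genome_chars[cg_at + 1L] <- "C"
  genome_chars[cg_at + 2L] <- "G"
  if (pu_dm$class[i] == "PU") {  # plant the motif only in PU
    for (off in seq(s + 20L, e - 20L, by = 150L)) {
      genome_chars[off + seq_along(motif)] <- motif
    }
  }
}
genome <- list(chrS = paste(genome_chars, collapse = ""))

dens <- vapply(seq_len(nrow(pu_dm)), function(i) {
  cpg_density(genome$chrS,
              data.frame(start = pu_dm$start[i], end = pu_dm$end[i]))
}, 0.0)

features <- data.frame(pu_dm[, c("se_id", "class", "start", "end")],
                       chip_enrichment = enr, cpg_density = dens)
outdir <- file.path(RESULTS, "features")
write_tsv(features, outdir, "subregion_features.tsv")

logit <- logistic_dm_vs_pu(features[, c("chip_enrichment", "cpg_density")],
                           features$class)
write_tsv(logit, outdir, "logistic_dm_vs_pu.tsv")
print(logit)

## ---- motif enrichment per class ------------------------------------------
m <- matrix(0.04, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
cons <- c(3L, 1L, 4L, 1L, 1L, 3L)  # GATAAG
for (j in 1:6) m[cons[j], j] <- 0.88
pwm_obj <- pwm("gataag", m)

tiles <- tile_regions(subregions[subregions$end - subregions$start >= 50L, ])
thr <- empirical_threshold(pwm_obj, genome, n_background = 20000L,
                           seed = SEED)
scanned <- scan_tiles(tiles, genome, pwm_obj, thr)
presence <- data.frame(motif = "gataag", class = scanned$class,
                       positive = scanned$positive)
enrich <- class_enrichment(presence)
write_tsv(enrich, file.path(RESULTS, "motifs"), "class_enrichment.tsv")
print(enrich)
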