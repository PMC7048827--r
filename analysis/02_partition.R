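#!/usr/bin/env Rscript
# Stage 2: HMM state calling and PU/DM/INT partition of every SE, from the
# coverage files written by stage 1, plus recovery statistics against the
# planted truth.

source(file.path("analysis", "00_config.R"))

simdir <- file.path(RESULTS, "sim")
outdir <- file.path(RESULTS, "partition")
res <- run_partition(file.path(simdir, "naive.cov"),
                     file.path(simdir, "primed.cov"),
                     file.path(simdir, "ses.bed"),
                     outdir)
run_report(outdir)

write_tsv(res$subregions, outdir, "subregions_full.tsv")

# base-pair agreement with the planted architecture
truth <- truth_default()
tot <- 0
agree <- 0
for (i in seq_len(nrow(truth$ses))) {
  se <- truth$ses[i, ]
  n <- se$end - se$start
  lab_truth <- rep("INT", n)
  lab_call <- rep("INT", n)
  kids <- truth$children[truth$children$se_id == se$name, ]
  for (j in seq_len(nrow(kids))) {
    lab_truth[(kids$start[j] - se$start + 1L):(kids$end[j] - se$start)] <-
      kids$class[j]
  }
  sub <- res$subregions[res$subregions$se_id == se$name &
                          res$subregions$class != "INT", ]
  for (j in seq_len(nrow(sub))) {
    lab_call[(sub$start[j] - se$start + 1L):(sub$end[j] - se$start)] <-
      sub$class[j]
  }
  tot <- tot + n
  agree <- agree + sum(lab_truth == lab_call)
}
recovery <- data.frame(
  metric = c("bp_agreement", "n_pu_called", "n_pu_planted",
             "n_dm_called", "n_dm_planted"),
  value = c(agree / tot,
            sum(res$subregions$class == "PU"),
            sum(truth$children$class == "PU"),
            sum(res$subregions$class == "DM"),
            sum(truth$children$class == "DM")))
write_tsv(recovery, outdir, "recovery.tsv")
print(recovery)
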