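#!/usr/bin/env Rscript
# Stage 4: predicted expression change (delta-X) per DM-containing SE from
# interaction intensity and methylation gain, compared with the simulated
# observed expression changes.

source(file.path("analysis", "00_config.R"))

truth <- truth_default()
subregions <- utils::read.delim(
  file.path(RESULTS, "partition", "subregions_full.tsv"),
  stringsAsFactors = FALSE)
freq <- utils::read.delim(
  file.path(RESULTS, "chic", "subregion_frequency.tsv"),
  stringsAsFactors = FALSE)
chic <- simulate_chic(truth, seed = SEED)

dm <- subregions[subregions$class == "DM", ]
dm_ses <- unique(dm$se_id)
rows <- lapply(dm_ses, function(id) {
  reads <- sum(freq$frequency[freq$se_id == id & freq$class == "DM"])
  r <- dm[dm$se_id == id, ]
  w_a <- sum(r$meth_a * r$n_cpgs_a) / sum(r$n_cpgs_a)
  w_b <- sum(r$meth_b * r$n_cpgs_b) / sum(r$n_cpgs_b)
  gene <- truth$genes$gene_id[truth$genes$se_id == id]
  data.frame(se_id = id, gene_id = gene,
             interaction_reads = reads,
             meth_pct_naive = 100 * w_a, meth_pct_primed = 100 * w_b,
             delta_x = predicted_expression_change(max(reads, 1) + 1,
                                                   100 * w_a, 100 * w_b),
             observed_log2fc = chic$gene_effects$true_log2fc[
               match(gene, chic$gene_effects$gene_id)],
             stringsAsFactors = FALSE)
})
deltax <- do.call(rbind, rows)

outdir <- file.path(RESULTS, "expression_link")
write_tsv(deltax, outdir, "deltax.tsv")
cmp <- predicted_vs_observed(deltax$delta_x, deltax$observed_log2fc)
write_tsv(data.frame(metric = c("pearson_r", "n_genes"),
                     value = c(cmp$r, cmp$n)),
          outdir, "predicted_vs_observed.tsv")
message(sprintf("delta-X vs observed log2FC: r = %.4f over %d genes",
                cmp$r, cmp$n))
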