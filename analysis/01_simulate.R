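#!/usr/bin/env Rscript
# Stage 1: simulate the two-condition bulk methylomes and the SE annotation.
# Writes bismark-style coverage tables, the SE BED, and the planted truth
# tables that later stages are benchmarked against.

source(file.path("analysis", "00_config.R"))

truth <- truth_default()
print(truth)

rec_a <- simulate_bulk_bsseq(truth, "A", seed = SEED)
rec_b <- simulate_bulk_bsseq(truth, "B", seed = SEED)

outdir <- file.path(RESULTS, "sim")
as_cov <- function(rec) {
  data.frame(chrom = rec$chrom, start1 = rec$pos + 1L, end1 = rec$pos + 1L,
             pct = round(100 * rec$meth / rec$total, 4),
             meth = rec$meth, unmeth = rec$total - rec$meth)
}
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
write.table(as_cov(rec_a), file.path(outdir, "naive.cov"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(as_cov(rec_b), file.path(outdir, "primed.cov"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(truth$ses[, c("chrom", "start", "end", "name")],
            file.path(outdir, "ses.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
message("wrote ", outdir, "/{naive.cov,primed.cov,ses.bed}")

write_tsv(truth$children, outdir, "planted_children.tsv")
write_tsv(truth$genes, outdir, "genes.tsv")
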