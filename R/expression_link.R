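#' Expressed genes by RPKM threshold
#'
#' @param table Expression data.frame with `gene_id` and sample columns
#'   (average RPKM).
#' @param sample Sample column name.
#' @param threshold Minimum RPKM (inclusive); default 1.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(table, sample, threshold = 1) {
  if (!sample %in% names(table)) {
    stop(sprintf("unknown sample '%s'", sample))
  }
  table$gene_id[table[[sample]] >= threshold]
}

#' Promoter windows around annotated TSSs
#'
#' A promoter is the `width` bp window centred on an annotated transcription
#' start site. Genes with several TSSs get one window per TSS. Windows
#' running off a chromosome edge are clipped and flagged.
#'
#' @param tss Data.frame with `gene_id`, `chrom`, `tss` (0-based position).
#' @param width Window width in bp (default 5000).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   clipping.
#' @return Data.frame `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
promoter_windows <- function(tss, width = 5000L, chrom_sizes = NULL) {
  half <- width %/% 2L
  start <- tss$tss - half
  end <- tss$tss + (width - half)
  clipped <- start < 0L
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[tss$chrom])
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
             start = as.integer(start), end = as.integer(end),
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Closest expressed gene to a super-enhancer
#'
#' Minimal edge-to-edge distance from the SE to the promoter window of an
#' expressed gene (0 when they overlap); ties broken by (distance, gene_id
#' lexicographic).
#'
#' @param se One-row interval data.frame (`chrom`, `start`, `end`).
#' @param promoters Promoter windows from [promoter_windows()].
#' @param expressed Character vector of expressed gene ids.
#' @return A list with `gene_id` and `distance`, or `NA` fields (with a
#'   warning) when no expressed promoter lies on the SE's chromosome.
#' @export
closest_expressed_gene <- function(se, promoters, expressed) {
  cand <- promoters[promoters$gene_id %in% expressed &
                      promoters$chrom == se$chrom, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning(sprintf("no expressed promoter on %s", se$chrom))
    return(list(gene_id = NA_character_, distance = NA_integer_))
  }
  d <- GenomicRanges::distance(
    intervals_to_granges(se)[rep(1L, nrow(cand))],
    intervals_to_granges(cand))
  best <- order(d, cand$gene_id)[1L]
  list(gene_id = cand$gene_id[best], distance = as.integer(d[best]))
}

#' Predicted expression change from interaction intensity and methylation
#'
#' The expected expression change of a promoter interacting with an SE
#' subregion whose methylation changes between conditions:
#' `log2(normalised interaction reads) x (%CpG condition A - %CpG condition
#' B)`. A subregion gaining methylation in condition B while strongly
#' interacting therefore predicts downregulation (negative value). Intended
#' for PU and DM subregions.
#'
#' @param norm_reads Normalised interaction read count(s), > 0.
#' @param meth_pct_a,meth_pct_b Percent CpG methylation in conditions A and
#'   B, in `[0, 100]`.
#' @return Numeric predicted change(s).
#' @export
predicted_expression_change <- function(norm_reads, meth_pct_a, meth_pct_b) {
  if (any(norm_reads <= 0)) stop("norm_reads must be positive")
  stopifnot(all(meth_pct_a >= 0 & meth_pct_a <= 100),
            all(meth_pct_b >= 0 & meth_pct_b <= 100))
  log2(norm_reads) * (meth_pct_a - meth_pct_b)
}

#' Pearson correlation of predicted vs observed expression changes
#'
#' @param predicted,observed Paired numeric vectors; pairs with a missing
#'   value in either are dropped.
#' @return A list with `r` (Pearson correlation; `NA` with `degenerate =
#'   TRUE` when either vector has zero variance) and `n`.
#' @export
predicted_vs_observed <- function(predicted, observed) {
  ok <- is.finite(predicted) & is.finite(observed)
  x <- predicted[ok]
  y <- observed[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = length(x), degenerate = TRUE))
  }
  list(r = stats::cor(x, y), n = length(x), degenerate = FALSE)
}
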