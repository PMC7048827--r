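#' Per-cell pooled methylation average over a subregion class
#'
#' For one cell, the mCpG/total-CpG read-level ratio pooled over all CpG
#' sites falling inside subregions of the requested class (PU, DM or INT).
#'
#' @param calls Per-cell CpG calls: data.frame `cell`, `chrom`, `pos`,
#'   `meth`, `total` (read-level call counts).
#' @param subregions Subregion data.frame (`chrom`, `start`, `end`, `class`).
#' @param class One of `"PU"`, `"DM"`, `"INT"`.
#' @return Named numeric vector of per-cell pooled ratios (`NA` for cells
#'   with no covered site in the class).
#' @export
class_average_per_cell <- function(calls, subregions, class) {
  sub <- subregions[subregions$class == class, , drop = FALSE]
  stopifnot(nrow(sub) > 0L)
  gr_calls <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  inside <- IRanges::overlapsAny(gr_calls, intervals_to_granges(sub))
  cells <- unique(calls$cell)
  meth <- tapply(calls$meth[inside], factor(calls$cell[inside], cells), sum)
  tot <- tapply(calls$total[inside], factor(calls$cell[inside], cells), sum)
  out <- as.numeric(meth) / as.numeric(tot)
  names(out) <- cells
  out
}

#' Per-cell subregion-level methylation matrix
#'
#' @param calls Per-cell CpG calls (see [class_average_per_cell()]).
#' @param subregions Subregion data.frame with `chrom`, `start`, `end`,
#'   `se_id`, `class`.
#' @return Numeric matrix cells x subregions of pooled per-subregion ratios
#'   (`NA` where uncovered), with a `class` attribute vector per column.
#' @export
cell_methylation_matrix <- function(calls, subregions) {
  ids <- sprintf("%s|%s|%d", subregions$se_id, subregions$class,
                 subregions$start)
  gr_calls <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_calls,
                                      intervals_to_granges(subregions))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  cells <- unique(calls$cell)
  cf <- factor(calls$cell[qh], cells)
  sf <- factor(ids[sh], ids)
  meth <- tapply(calls$meth[qh], list(cf, sf), sum)
  tot <- tapply(calls$total[qh], list(cf, sf), sum)
  mat <- meth / tot
  attr(mat, "class_labels") <- subregions$class
  mat
}

#' Cluster cells by DM methylation into naive-like and primed-like
#'
#' Complete-linkage hierarchical clustering on the squared differences
#' between the cells' total DM mCpG/total-CpG averages, cut into `k`
#' clusters. The cluster with the lower mean DM methylation is labelled
#' `"naive-like"`, the other `"primed-like"`. By default only serum-grown
#' cells are clustered and 2i cells retain their condition label; with
#' `serum_only = FALSE` all cells are clustered jointly and the cluster
#' containing 2i cells is interpreted as naive-like.
#'
#' @param dm_averages Named per-cell total DM methylation averages.
#' @param condition Named character vector (`"serum"` or `"2i"`) per cell;
#'   if `NULL` all cells are treated as serum.
#' @param k Number of clusters (default 2).
#' @param serum_only Cluster serum cells only (default `TRUE`).
#' @return A list with `labels` (named character vector: `"naive-like"`,
#'   `"primed-like"` or `"2i"`), `tree` (hclust object), `excluded` (cells
#'   without a DM average) and `degenerate` (all averages equal).
#' @export
cluster_cells <- function(dm_averages, condition = NULL, k = 2L,
                          serum_only = TRUE) {
  if (is.null(condition)) {
    condition <- stats::setNames(rep("serum", length(dm_averages)),
                                 names(dm_averages))
  }
  excluded <- names(dm_averages)[is.na(dm_averages)]
  if (length(excluded) > 0L) {
    warning(sprintf("%d cell(s) without DM average excluded", length(excluded)))
  }
  avail <- dm_averages[!is.na(dm_averages)]
  use <- if (serum_only) names(avail)[condition[names(avail)] == "serum"]
         else names(avail)
  if (length(use) < k) stop("fewer usable cells than clusters")
  x <- avail[use]
  d <- stats::as.dist(outer(x, x, function(a, b) (a - b)^2))
  tree <- stats::hclust(d, method = "complete")
  grp <- stats::cutree(tree, k = k)
  degenerate <- length(unique(x)) == 1L
  if (degenerate) warning("all DM averages equal; cluster split is arbitrary")
  means <- tapply(x, grp, mean)
  if (!serum_only && any(condition[use] == "2i")) {
    naive_grp <- as.integer(names(which.max(
      tapply(condition[use] == "2i", grp, mean))))
  } else {
    naive_grp <- as.integer(names(which.min(means)))
  }
  labels <- ifelse(grp == naive_grp, "naive-like", "primed-like")
  names(labels) <- use
  all_labels <- stats::setNames(rep(NA_character_, length(dm_averages)),
                                names(dm_averages))
  all_labels[names(labels)] <- labels
  all_labels[condition[names(all_labels)] == "2i" & serum_only] <- "2i"
  list(labels = all_labels, tree = tree, excluded = excluded,
       degenerate = degenerate)
}

#' Methylation variance of one cell across subregions of a class
#'
#' Sample variance (n - 1 denominator) of a cell's per-subregion methylation
#' ratios within one subregion class; `NA` when fewer than two subregions are
#' covered.
#'
#' @param cell_row Numeric vector of per-subregion ratios for one cell.
#' @param class_labels Subregion class per entry.
#' @param class Class to use (`"PU"`, `"DM"`, `"INT"`).
#' @return Non-negative variance, or `NA`.
#' @export
methylation_variance_per_cell <- function(cell_row, class_labels, class) {
  x <- cell_row[class_labels == class]
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::var(x)
}

#' Median-centre and unit-scale expression per gene
#'
#' Per gene (column): subtract the median across cells and divide by the
#' standard deviation across cells. Zero-variance genes are left centred and
#' flagged.
#'
#' @param counts Numeric matrix, cells x genes.
#' @return Normalised matrix with attribute `zero_variance` (logical per
#'   gene).
#' @export
normalize_expression <- function(counts) {
  stopifnot(nrow(counts) >= 2L)
  med <- apply(counts, 2L, stats::median)
  sdv <- apply(counts, 2L, stats::sd)
  zero <- sdv == 0
  centred <- sweep(counts, 2L, med)
  out <- sweep(centred, 2L, ifelse(zero, 1, sdv), "/")
  attr(out, "zero_variance") <- zero
  out
}

#' Per-cell signature score
#'
#' The mean of a cell's normalised read counts over the genes of a
#' signature; genes absent from the matrix are reported.
#'
#' @param normalized Normalised matrix (cells x genes) from
#'   [normalize_expression()].
#' @param genes Character vector of signature gene ids.
#' @return Named numeric per-cell scores, with attribute `missing_genes`.
#' @export
signature_score <- function(normalized, genes) {
  present <- intersect(genes, colnames(normalized))
  if (length(present) == 0L) stop("no signature gene present in the matrix")
  out <- rowMeans(normalized[, present, drop = FALSE])
  missing <- setdiff(genes, present)
  if (length(missing) > 0L) attr(out, "missing_genes") <- missing
  out
}

#' ROC curve and AUC of a score against binary labels
#'
#' Sweeps the top-ranking cutoff n from 0 to N: sensitivity is the proportion
#' of positives among all positives in the top n, 1-specificity the
#' proportion of negatives. Ties are handled by grouping tied scores
#' (equivalent to averaging over tied orderings), so the trapezoidal AUC
#' equals the Mann-Whitney rank statistic U / (n1 n0).
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical (or 0/1) positive-class labels.
#' @return Object of class `roc_curve`: list with `points` (data.frame
#'   `fpr`, `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores: the curve moves diagonally through a tie block
  grp_end <- which(c(s[-1L] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(l)[grp_end] / n1)
  fpr <- c(0, cumsum(!l)[grp_end] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = as.numeric(fpr),
                                     tpr = as.numeric(tpr)),
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Permutation p-value for an AUC
#'
#' Permutes the class labels `n_perm` times and reports
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + n_perm)`.
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_perm Number of permutations (default 1e5, matching a granularity
#'   of 1e-5).
#' @param seed Integer seed for reproducibility.
#' @return A list with `p`, `auc` (observed) and `n_perm`.
#' @export
auc_permutation_p <- function(scores, labels, n_perm = 1e5, seed = 1L) {
  stopifnot(n_perm >= 100)
  labels <- as.logical(labels)
  obs <- roc_auc(scores, labels)$auc
  # AUC via the rank form (fast inside the permutation loop)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  auc_of <- function(lab) {
    (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- 0L
  n <- length(labels)
  for (i in seq_len(n_perm)) {
    perm <- logical(n)
    perm[sample.int(n, n1)] <- TRUE
    if (auc_of(perm) >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + n_perm), auc = obs, n_perm = n_perm)
}
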