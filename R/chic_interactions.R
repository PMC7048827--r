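#' Merge consecutive restriction fragments into pseudo-fragments
#'
#' Groups of `k` consecutive restriction fragments per chromosome are merged
#' into one interval to increase the read count per called interaction; a
#' trailing remainder group of fewer than `k` fragments is kept as a smaller
#' pseudo-fragment and flagged.
#'
#' @param fragments Data.frame (`chrom`, `start`, `end`), ordered per
#'   chromosome.
#' @param k Fragments per pseudo-fragment (default 4).
#' @return Data.frame `chrom`, `start`, `end`, `n_fragments`, `remainder`.
#' @export
merge_pseudofragments <- function(fragments, k = 4L) {
  stopifnot(k >= 1L)
  out <- lapply(split(fragments, fragments$chrom), function(fr) {
    fr <- fr[order(fr$start), , drop = FALSE]
    grp <- (seq_len(nrow(fr)) - 1L) %/% k
    agg <- data.frame(
      chrom = fr$chrom[!duplicated(grp)],
      start = tapply(fr$start, grp, min),
      end = tapply(fr$end, grp, max),
      n_fragments = as.integer(table(grp)),
      stringsAsFactors = FALSE)
    agg$remainder <- agg$n_fragments < k
    agg
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter capture Hi-C interactions by score and coverage
#'
#' Keeps cis interaction records whose significance score is at least
#' `score_min` and whose geometric mean read count across replicates is at
#' least `cov_min`; trans records are dropped.
#'
#' @param records Interaction data.frame with a `score` column, replicate
#'   read columns named in `read_cols`, and optionally a logical `trans`
#'   column.
#' @param score_min Minimum interaction score (default 5).
#' @param cov_min Minimum geometric-mean read coverage (default 5 reads).
#' @param read_cols Names of the replicate read-count columns; default every
#'   column starting with `"reads"`.
#' @return The retained records.
#' @export
filter_interactions <- function(records, score_min = 5, cov_min = 5,
                                read_cols = grep("^reads", names(records),
                                                 value = TRUE)) {
  stopifnot(length(read_cols) >= 1L)
  reads <- as.matrix(records[, read_cols, drop = FALSE])
  geomean <- exp(rowMeans(log(pmax(reads, 0) + .Machine$double.xmin)))
  geomean[apply(reads == 0, 1L, any)] <- 0
  keep <- records$score >= score_min & geomean >= cov_min
  if (!is.null(records$trans)) keep <- keep & !records$trans
  records[keep, , drop = FALSE]
}

#' Distance-stratified median-of-ratios normalisation
#'
#' Normalises interaction read counts across libraries within distance
#' strata, because proximity-ligation counts near the capture bait are higher
#' and more variable than distal ones. Within each distance bin, a
#' median-of-ratios size factor is computed per library: the reference for
#' each record is its geometric mean across libraries (records with any zero
#' are excluded from factor estimation) and the factor is the median ratio of
#' count to reference.
#'
#' @param counts Numeric matrix, records x libraries.
#' @param distance Per-record bait-to-other-end distance (bp).
#' @param breaks Distance bin boundaries; default the four categories
#'   `[0, 25 kb)`, `[25, 100 kb)`, `[100, 300 kb)`, `[300 kb, Inf)`.
#' @return A list with `size_factors` (bins x libraries matrix),
#'   `normalized` (counts / factor) and `bin` (per-record bin index).
#' @export
normalize_by_distance_bin <- function(counts, distance,
                                      breaks = c(0, 25e3, 1e5, 3e5, Inf)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L, length(distance) == nrow(counts))
  bin <- findInterval(distance, breaks, rightmost.closed = FALSE)
  nbin <- length(breaks) - 1L
  sf <- matrix(1, nbin, ncol(counts),
               dimnames = list(NULL, colnames(counts)))
  normalized <- counts
  for (b in seq_len(nbin)) {
    rows <- which(bin == b)
    usable <- rows[apply(counts[rows, , drop = FALSE] > 0, 1L, all)]
    if (length(usable) == 0L) {
      if (length(rows) > 0L) {
        warning(sprintf("distance bin %d has no record without zeros; size factors set to 1", b))
      }
      next
    }
    logc <- log(counts[usable, , drop = FALSE])
    ref <- rowMeans(logc)  # log geometric mean
    sf[b, ] <- exp(apply(logc - ref, 2L, stats::median))
    normalized[rows, ] <- sweep(counts[rows, , drop = FALSE], 2L, sf[b, ], "/")
  }
  list(size_factors = sf, normalized = normalized, bin = bin)
}

#' Spearman correlation between two normalised libraries
#'
#' @param norm_counts Normalised count matrix (records x libraries).
#' @param lib_a,lib_b Library column names or indices.
#' @return Spearman rho (ties by average rank), or `NA` when fewer than 3
#'   records.
#' @export
library_correlation <- function(norm_counts, lib_a, lib_b) {
  x <- norm_counts[, lib_a]
  y <- norm_counts[, lib_b]
  if (length(x) < 3L) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Promoter-subregion interaction frequency at native fragment resolution
#'
#' For each significant promoter-SE pair, sums the normalised reads of
#' restriction fragments over the SE subregions they overlap. Subregions
#' narrower than `min_width` bp are discarded (too few overlapping fragments
#' for a robust estimate); a fragment spanning several subregions is assigned
#' to the subregion with the largest overlap.
#'
#' @param records Data.frame of fragment-resolution interactions with
#'   columns `bait` (promoter/gene id), `chrom`, `start`, `end` (other-end
#'   fragment, 0-based half-open), `norm_reads`, `distance` (bp).
#' @param subregions Subregion data.frame (`chrom`, `start`, `end`, `se_id`,
#'   `class`).
#' @param min_width Minimum subregion width in bp (default 500).
#' @return Data.frame `subregion`, `se_id`, `class`, `bait`, `frequency`,
#'   `n_baits` (capture baits interacting with the subregion), `distance`
#'   (mean fragment distance of the pair).
#' @export
subregion_interaction_frequency <- function(records, subregions,
                                            min_width = 500L) {
  sub <- subregions[subregions$end - subregions$start >= min_width, ,
                    drop = FALSE]
  if (nrow(sub) == 0L || nrow(records) == 0L) {
    return(data.frame(subregion = character(), se_id = character(),
                      class = character(), bait = character(),
                      frequency = numeric(), n_baits = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  sub$subregion <- sprintf("%s|%s|%d", sub$se_id, sub$class, sub$start)
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(records),
                                      intervals_to_granges(sub))
  if (length(hits) == 0L) {
    return(data.frame(subregion = character(), se_id = character(),
                      class = character(), bait = character(),
                      frequency = numeric(), n_baits = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ovl <- pmin(records$end[qh], sub$end[sh]) -
    pmax(records$start[qh], sub$start[sh])
  # max-overlap assignment: keep the best subregion per fragment record
  ord <- order(qh, -ovl)
  keep <- ord[!duplicated(qh[ord])]
  qh <- qh[keep]
  sh <- sh[keep]
  key <- paste(sub$subregion[sh], records$bait[qh], sep = "\r")
  freq <- tapply(records$norm_reads[qh], key, sum)
  dist <- tapply(records$distance[qh], key, mean)
  parts <- strsplit(names(freq), "\r", fixed = TRUE)
  out <- data.frame(
    subregion = vapply(parts, `[`, "", 1L),
    bait = vapply(parts, `[`, "", 2L),
    frequency = as.numeric(freq),
    distance = as.numeric(dist),
    stringsAsFactors = FALSE)
  m <- match(out$subregion, sub$subregion)
  out$se_id <- sub$se_id[m]
  out$class <- sub$class[m]
  nb <- tapply(out$bait, out$subregion, function(b) length(unique(b)))
  out$n_baits <- as.integer(nb[out$subregion])
  rownames(out) <- NULL
  out[, c("subregion", "se_id", "class", "bait", "frequency", "n_baits",
          "distance")]
}

#' Linear model for interaction frequency by subregion class
#'
#' Ordinary least squares of `log2(frequency + pseudocount)` on subregion
#' class with the two major confounders as covariates: the number of capture
#' baits per subregion and the log2 promoter-subregion distance. A covariate
#' that is constant across records carries no information and is dropped with
#' a warning (it would otherwise be collinear with the intercept); any other
#' rank deficiency is an error.
#'
#' @param table Output of [subregion_interaction_frequency()] (needs
#'   `frequency`, `class`, `n_baits`, `distance > 0`).
#' @param pseudocount Added to frequency before the log (default 1).
#' @param reference Reference class for the contrasts (default `"INT"`).
#' @return A list with `coefficients` (data.frame `term`, `estimate`, `se`,
#'   `t`, `p`) and the fitted `model`.
#' @export
interaction_class_model <- function(table, pseudocount = 1,
                                    reference = "INT") {
  stopifnot(all(table$distance > 0))
  table$class <- stats::relevel(factor(table$class), ref = reference)
  table$log2_frequency <- log2(table$frequency + pseudocount)
  table$log2_distance <- log2(table$distance)
  covariates <- c("n_baits", "log2_distance")
  constant <- vapply(covariates, function(v) {
    length(unique(table[[v]])) < 2L
  }, TRUE)
  if (any(constant)) {
    warning(sprintf("constant covariate(s) dropped (absorbed by intercept): %s",
                    paste(covariates[constant], collapse = ", ")))
  }
  rhs <- paste(c("class", covariates[!constant]), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("log2_frequency ~", rhs)),
                   data = table)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                                 se = sm[, 2L], t = sm[, 3L], p = sm[, 4L],
                                 row.names = NULL, stringsAsFactors = FALSE),
       model = fit)
}

# running mean with window k; edges averaged over the available bins
running_mean <- function(x, k = 7L) {
  n <- length(x)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - half):min(n, i + half)
    mean(x[w])
  }, 0.0)
}

#' Bin and smooth 4C-seq signal around a viewpoint
#'
#' Sums per-fragment normalised counts into fixed-width bins anchored at the
#' viewpoint (cis only, within `max_dist` up- and downstream) and smooths the
#' binned track with a running mean. Bins whose coverage falls below
#' `min_rpkm` RPKM are flagged for exclusion from differential comparison.
#'
#' @param fragments Data.frame with `mid` (fragment midpoint, bp) and
#'   `count` (normalised count) for cis fragments.
#' @param viewpoint Viewpoint position (bp).
#' @param bin Bin width in bp (default 5000).
#' @param k Running-mean window in bins (default 7).
#' @param max_dist Maximum distance from the viewpoint (default 1 Mb).
#' @param lib_size Library size used for the RPKM flag (default `sum(count)`).
#' @param min_rpkm RPKM threshold below which a bin is flagged (default
#'   1000).
#' @return Data.frame `bin_start`, `bin_end`, `count`, `smoothed`, `rpkm`,
#'   `low_coverage`.
#' @export
bin_and_smooth_4c <- function(fragments, viewpoint, bin = 5000L, k = 7L,
                              max_dist = 1e6, lib_size = sum(fragments$count),
                              min_rpkm = 1000) {
  sel <- abs(fragments$mid - viewpoint) <= max_dist
  fragments <- fragments[sel, , drop = FALSE]
  idx <- floor((fragments$mid - viewpoint) / bin)
  lo <- -ceiling(max_dist / bin)
  hi <- ceiling(max_dist / bin) - 1L
  all_idx <- lo:hi
  counts <- numeric(length(all_idx))
  tab <- tapply(fragments$count, idx, sum)
  counts[match(as.integer(names(tab)), all_idx)] <- tab
  sm <- running_mean(counts, k)
  rpkm <- counts / (bin / 1e3) / (max(lib_size, 1) / 1e6)
  data.frame(bin_start = viewpoint + all_idx * bin,
             bin_end = viewpoint + (all_idx + 1L) * bin,
             count = counts, smoothed = sm, rpkm = rpkm,
             low_coverage = rpkm < min_rpkm)
}
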