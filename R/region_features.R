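#' Meta-region coverage profile
#'
#' Splits each region into a fixed number of equal-width windows, averages
#' the base-wise signal within each window (proportionally for fractional
#' window boundaries when a region is shorter than `n_windows` bp), then
#' averages each window index across regions.
#'
#' @param regions Interval data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open. An optional `strand` column (`"-"` reverses the window order)
#'   is honoured.
#' @param signal Named list per chromosome of base-wise numeric signal
#'   vectors (position 1 = coordinate 0).
#' @param n_windows Number of windows (default 1000).
#' @return Numeric vector of length `n_windows`.
#' @export
profile_coverage <- function(regions, signal, n_windows = 1000L) {
  prof <- matrix(NA_real_, nrow(regions), n_windows)
  for (i in seq_len(nrow(regions))) {
    sig <- signal[[regions$chrom[i]]]
    a <- regions$start[i]
    b <- regions$end[i]
    stopifnot(!is.null(sig), b <= length(sig))
    x <- sig[(a + 1L):b]
    # cumulative integral of the stepwise signal; window mean from the
    # difference of interpolated cumulative values (handles fractional
    # boundaries exactly)
    cs <- c(0, cumsum(x))
    bounds <- seq(0, length(x), length.out = n_windows + 1L)
    ci <- stats::approx(seq_along(cs) - 1, cs, xout = bounds)$y
    w <- diff(ci) / diff(bounds)
    if (!is.null(regions$strand) && identical(regions$strand[i], "-")) {
      w <- rev(w)
    }
    prof[i, ] <- w
  }
  colMeans(prof)
}

#' ChIP enrichment score over a region
#'
#' Median over the region's positional bins of
#' `log2((chip RPKM + 1) / (input RPKM + 1))`.
#'
#' @param chip,input Base-wise RPKM signal vectors covering the chromosome.
#' @param region One-row interval data.frame (`start`, `end`), 0-based.
#' @param bin Bin width in bp used as the positional unit (default 10).
#' @return Median log2 fold change, or `NA` for an empty region.
#' @export
enrichment_score <- function(chip, input, region, bin = 10L) {
  idx <- (region$start + 1L):region$end
  if (length(idx) == 0L) return(NA_real_)
  stopifnot(max(idx) <= length(chip), max(idx) <= length(input))
  grp <- (idx - idx[1L]) %/% bin
  cmean <- tapply(chip[idx], grp, mean)
  imean <- tapply(input[idx], grp, mean)
  stats::median(log2((cmean + 1) / (imean + 1)))
}

#' Scale enrichment scores by their mean across subregions
#'
#' @param scores Numeric per-subregion scores for one feature.
#' @return `scores / mean(scores)` (output mean 1).
#' @export
scale_feature_across_subregions <- function(scores) {
  m <- mean(scores, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("mean enrichment score is zero")
  scores / m
}

#' Input-subtracted ATAC accessibility in RPKM
#'
#' Region read counts minus input (WCE) counts scaled to the ATAC library
#' depth, converted to reads per kilobase per million mapped reads. Negative
#' values after subtraction are retained and flagged.
#'
#' @param reads ATAC read count in the region.
#' @param input_reads Input (WCE) read count in the region.
#' @param region_width Region width in bp (> 0).
#' @param lib_size ATAC library size (mapped reads).
#' @param input_lib_size Input library size.
#' @return RPKM value with attribute `negative` (logical).
#' @export
atac_accessibility <- function(reads, input_reads, region_width, lib_size,
                               input_lib_size = lib_size) {
  stopifnot(region_width > 0, lib_size > 0, input_lib_size > 0)
  net <- reads - input_reads * lib_size / input_lib_size
  rpkm <- net / (region_width / 1e3) / (lib_size / 1e6)
  structure(rpkm, negative = rpkm < 0)
}

#' CpG dinucleotide density of a region
#'
#' @param sequence A character string or `Biostrings::DNAString` covering the
#'   chromosome (position 1 = coordinate 0).
#' @param region One-row interval data.frame (`start`, `end`), 0-based
#'   half-open.
#' @return Count of CG dinucleotides divided by region length in bp.
#'   Ambiguous bases never match.
#' @export
cpg_density <- function(sequence, region) {
  seq <- Biostrings::DNAString(as.character(sequence))
  width <- region$end - region$start
  stopifnot(width > 0)
  sub <- Biostrings::subseq(seq, start = region$start + 1L, end = region$end)
  Biostrings::countPattern("CG", sub) / width
}

#' Univariate logistic models for DM-vs-PU subregion class
#'
#' Fits one logistic regression per feature with subregion class as the
#' binary outcome (DM = 1, PU = 0). A positive coefficient means subregions
#' with higher feature values are more likely DM.
#'
#' @param features Data.frame/matrix of quantitative features (one column
#'   per feature).
#' @param labels Character vector in `{"DM","PU"}` (or logical DM indicator).
#' @return Data.frame `feature`, `estimate`, `se`, `statistic`, `p`.
#' @export
logistic_dm_vs_pu <- function(features, labels) {
  y <- if (is.logical(labels)) labels else labels == "DM"
  stopifnot(any(y), any(!y))
  features <- as.data.frame(features)
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    if (!fit$converged || max(abs(stats::coef(fit))) > 1e3) {
      stop(sprintf(
        "logistic fit for '%s' did not converge (possible perfect separation); consider penalised regression or pooling",
        f))
    }
    sm <- summary(fit)$coefficients
    data.frame(feature = f, estimate = sm["x", 1L], se = sm["x", 2L],
               statistic = sm["x", 3L], p = sm["x", 4L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear model for MED1 loss upon ESRRB depletion
#'
#' OLS of the log2 fold change of MED1 ChIP enrichment (knockout relative to
#' control) on ESRRB enrichment, subregion class (DM vs PU) and OCT4 binding
#' score (average log ChIP/control enrichment of overlapping peaks, 0 when no
#' peak overlaps). Negative coefficients indicate a greater MED1 decrease.
#'
#' @param table Data.frame with columns `med1_log2fc`, `esrrb`, `class`
#'   (`"DM"`/`"PU"`) and `oct4`.
#' @return A list with `coefficients` (data.frame `term`, `estimate`, `se`,
#'   `t`, `p`) and the fitted `model`.
#' @export
med1_loss_model <- function(table) {
  stopifnot(nrow(table) > 4L)
  table$class <- factor(table$class, levels = c("PU", "DM"))
  fit <- stats::lm(med1_log2fc ~ esrrb + class + oct4, data = table)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("collinear term(s): %s", paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                                 se = sm[, 2L], t = sm[, 3L], p = sm[, 4L],
                                 row.names = NULL, stringsAsFactors = FALSE),
       model = fit)
}
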