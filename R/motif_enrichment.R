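#' Position weight matrix
#'
#' @param id Motif identifier.
#' @param mat 4 x L matrix of per-position base probabilities, rows A, C, G,
#'   T; each column sums to 1.
#' @param background Background base frequencies (A, C, G, T).
#' @return Object of class `pwm`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 4L,
            all(abs(colSums(mat) - 1) < 1e-6),
            length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat, background = background), class = "pwm")
}

# log2-odds matrix with pseudocount; row 5 handles N/ambiguous bases
# (zero probability: an N position can never contribute a match)
pwm_logodds <- function(x, pseudocount = 0.01) {
  p <- sweep(x$mat + pseudocount, 2L, colSums(x$mat + pseudocount), "/")
  lo <- log2(p / x$background)
  rbind(lo, N = -Inf)
}

# DNA string -> integer code (A1 C2 G3 T4, anything else 5)
encode_dna <- function(seq) {
  code <- match(strsplit(toupper(as.character(seq)), "")[[1L]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# per-start log-odds score on the + strand for every position of `code`
pwm_position_scores <- function(code, lo) {
  L <- ncol(lo)
  npos <- length(code) - L + 1L
  if (npos < 1L) return(numeric(0))
  s <- numeric(npos)
  for (j in seq_len(L)) {
    s <- s + lo[, j][code[j:(j + npos - 1L)]]
  }
  s
}

# best score over both strands for every motif start position
pwm_scan_scores <- function(code, pwm_obj, pseudocount = 0.01) {
  lo <- pwm_logodds(pwm_obj, pseudocount)
  L <- ncol(lo) - 0L
  # reverse strand = scan with the reverse-complemented matrix
  lo_rc <- lo[c(4:1, 5L), rev(seq_len(ncol(lo))), drop = FALSE]
  pmax(pwm_position_scores(code, lo),
       pwm_position_scores(code, lo_rc))
}

#' Tile regions into fixed-width windows
#'
#' Partitions each region into `n = max(1, round(len / width))` tiles of
#' exactly `width` bp whose start points are equally spaced from the region
#' start to `end - width`. Regions shorter than `width` yield a single
#' clipped tile (the whole region), flagged.
#'
#' @param regions Interval data.frame (`chrom`, `start`, `end`) with optional
#'   `class` and `se_id` carried through.
#' @param width Tile width in bp; default 291 (the median ATAC-seq peak
#'   length).
#' @return Data.frame `chrom`, `start`, `end`, `tile_id`, `clipped`, plus
#'   carried columns.
#' @export
tile_regions <- function(regions, width = 291L) {
  stopifnot(width >= 1L)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    len <- regions$end[i] - regions$start[i]
    if (len < width) {
      starts <- regions$start[i]
      ends <- regions$end[i]
      clipped <- TRUE
    } else {
      n <- max(1L, round(len / width))
      starts <- round(seq(regions$start[i], regions$end[i] - width,
                          length.out = n))
      ends <- starts + width
      clipped <- FALSE
    }
    df <- data.frame(chrom = regions$chrom[i], start = as.integer(starts),
                     end = as.integer(ends), clipped = clipped,
                     stringsAsFactors = FALSE)
    for (col in intersect(c("class", "se_id"), names(regions))) {
      df[[col]] <- regions[[col]][i]
    }
    df
  })
  out <- do.call(rbind, out)
  out$tile_id <- sprintf("tile%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Empirical motif score threshold from background genome sampling
#'
#' Samples `n_background` random windows of `tile_width` bp from the genome
#' and returns the requested quantile (default 99%) of the per-window best
#' log-odds score over both strands, giving an empirical false discovery
#' rate of `1 - quantile` for presence calls.
#'
#' @param pwm_obj A [pwm()] object.
#' @param genome Named character vector/list of chromosome sequences.
#' @param n_background Number of background windows (default 50000).
#' @param tile_width Window width (default 291 bp).
#' @param quantile Quantile used as the cut-off (default 0.99).
#' @param seed Integer seed for the sampler.
#' @param pseudocount PWM pseudocount.
#' @return Numeric score threshold.
#' @export
empirical_threshold <- function(pwm_obj, genome, n_background = 50000L,
                                tile_width = 291L, quantile = 0.99,
                                seed = 1L, pseudocount = 0.01) {
  L <- ncol(pwm_obj$mat)
  lens <- vapply(genome, nchar, 0L)
  if (all(lens < tile_width)) stop("genome shorter than one background tile")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  usable <- names(lens)[lens >= tile_width]
  chrom <- sample(usable, n_background, replace = TRUE,
                  prob = lens[usable] - tile_width + 1)
  best <- numeric(n_background)
  for (chr in usable) {
    idx <- which(chrom == chr)
    if (length(idx) == 0L) next
    code <- encode_dna(genome[[chr]])
    scores <- pwm_scan_scores(code, pwm_obj, pseudocount)
    starts <- sample.int(lens[chr] - tile_width + 1L, length(idx),
                         replace = TRUE)
    nwin <- tile_width - L + 1L
    best[idx] <- vapply(starts, function(s) {
      max(scores[s:(s + nwin - 1L)])
    }, 0.0)
  }
  stats::quantile(best, quantile, names = FALSE)
}

#' Call motif presence per tile
#'
#' A tile is positive when its best log-odds score over both strands and all
#' offsets reaches the threshold. Ambiguous bases (N) never match.
#'
#' @param tiles Tile data.frame from [tile_regions()].
#' @param genome Named character vector/list of chromosome sequences.
#' @param pwm_obj A [pwm()] object.
#' @param threshold Score threshold from [empirical_threshold()].
#' @param pseudocount PWM pseudocount.
#' @return `tiles` with added columns `best_score` and `positive`.
#' @export
scan_tiles <- function(tiles, genome, pwm_obj, threshold,
                       pseudocount = 0.01) {
  L <- ncol(pwm_obj$mat)
  tiles$best_score <- -Inf
  for (chr in unique(tiles$chrom)) {
    idx <- which(tiles$chrom == chr)
    code <- encode_dna(genome[[chr]])
    scores <- pwm_scan_scores(code, pwm_obj, pseudocount)
    tiles$best_score[idx] <- vapply(idx, function(i) {
      lastpos <- tiles$end[i] - L + 1L
      if (lastpos <= tiles$start[i]) return(-Inf)
      max(scores[(tiles$start[i] + 1L):lastpos])
    }, 0.0)
  }
  tiles$positive <- is.finite(tiles$best_score) &
    tiles$best_score >= threshold
  tiles
}

#' Hypergeometric motif enrichment per subregion class
#'
#' For each motif and subregion class, tests whether motif-positive tiles are
#' over-represented in the class relative to the union of all classes
#' (upper-tail hypergeometric), with Benjamini-Hochberg adjustment across
#' motifs within each class.
#'
#' @param presence Data.frame with columns `motif`, `class` and logical
#'   `positive`; the classes partition the tile universe.
#' @return Data.frame `motif`, `class`, `hits_in_class`, `tiles_in_class`,
#'   `hits_in_union`, `tiles_in_union`, `p`, `p_adjusted`.
#' @export
class_enrichment <- function(presence) {
  stopifnot(all(c("motif", "class", "positive") %in% names(presence)))
  out <- list()
  for (m in unique(presence$motif)) {
    pm <- presence[presence$motif == m, , drop = FALSE]
    n_union <- nrow(pm)
    k_union <- sum(pm$positive)
    for (cl in unique(pm$class)) {
      sel <- pm$class == cl
      if (!any(sel)) {
        warning(sprintf("empty class '%s' skipped", cl))
        next
      }
      n_class <- sum(sel)
      k_class <- sum(pm$positive[sel])
      p <- stats::phyper(k_class - 1L, k_union, n_union - k_union, n_class,
                         lower.tail = FALSE)
      out[[paste(m, cl)]] <- data.frame(
        motif = m, class = cl, hits_in_class = k_class,
        tiles_in_class = n_class, hits_in_union = k_union,
        tiles_in_union = n_union, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$p_adjusted <- NA_real_
  for (cl in unique(out$class)) {
    sel <- out$class == cl
    out$p_adjusted[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out
}
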