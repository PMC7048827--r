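#' Filter CpG records by read coverage
#'
#' @param records CpG record data.frame.
#' @param min_cov Minimum total read count (inclusive); default 7 reads.
#' @return The records with `total >= min_cov`, order preserved.
#' @export
filter_by_coverage <- function(records, min_cov = 7L) {
  stopifnot(min_cov >= 1L)
  records[records$total >= min_cov, , drop = FALSE]
}

#' Chain CpGs into dense segments
#'
#' Splits the genome into segments of CpGs spaced by less than `max_gap` bp
#' (a new segment starts whenever the gap to the previous CpG reaches
#' `max_gap`, or the chromosome changes) and drops segments with fewer than
#' `min_cpgs` CpGs.
#'
#' @param records CpG records sorted by (chrom, pos).
#' @param max_gap Gap (bp) at or above which a new segment starts.
#' @param min_cpgs Minimum CpGs per retained segment.
#' @return A list with `records` (the retained CpGs, with a `segment_id`
#'   column) and `segments` (data.frame `segment_id`, `chrom`, `start`,
#'   `end`, `n_cpgs`; the interval spans the first to last member CpG, with
#'   `end = last pos + 2` to cover the dinucleotide).
#' @export
build_segments <- function(records, max_gap = 1000L, min_cpgs = 10L) {
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = cbind(records, segment_id = integer(0)),
                segments = data.frame(segment_id = integer(), chrom = character(),
                                      start = integer(), end = integer(),
                                      n_cpgs = integer(), stringsAsFactors = FALSE)))
  }
  newseg <- c(TRUE, records$chrom[-1L] != records$chrom[-n] |
                records$pos[-1L] - records$pos[-n] >= max_gap)
  seg <- cumsum(newseg)
  size <- tabulate(seg)
  keep <- size[seg] >= min_cpgs
  records <- records[keep, , drop = FALSE]
  seg <- seg[keep]
  if (nrow(records) == 0L) {
    return(list(records = cbind(records, segment_id = integer(0)),
                segments = data.frame(segment_id = integer(), chrom = character(),
                                      start = integer(), end = integer(),
                                      n_cpgs = integer(), stringsAsFactors = FALSE)))
  }
  seg <- match(seg, unique(seg))  # renumber 1..k
  records$segment_id <- seg
  first <- !duplicated(seg)
  last <- !duplicated(seg, fromLast = TRUE)
  segments <- data.frame(segment_id = seg[first],
                         chrom = records$chrom[first],
                         start = records$pos[first],
                         end = records$pos[last] + 2L,
                         n_cpgs = as.integer(tabulate(seg)),
                         stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records, segments = segments)
}

# maximal runs of >= min_run consecutive TRUE flags over ordered CpGs;
# a run breaks at FALSE flags, segment changes and gaps >= max_gap.
# Returns 0-based half-open spans from the first to last run CpG (+2).
flag_runs <- function(chrom, pos, flag, segment_id = NULL, min_run = 4L,
                      max_gap = 1000L) {
  n <- length(pos)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  if (is.null(segment_id)) segment_id <- rep(1L, n)
  brk <- c(TRUE, chrom[-1L] != chrom[-n] |
             segment_id[-1L] != segment_id[-n] |
             pos[-1L] - pos[-n] >= max_gap)
  grp <- cumsum(brk | !flag)  # new group at each break or non-flag CpG
  grp[!flag] <- NA_integer_
  ok <- which(!is.na(grp))
  if (length(ok) == 0L) return(empty)
  runs <- split(ok, grp[ok])
  runs <- runs[lengths(runs) >= min_run]
  if (length(runs) == 0L) return(empty)
  out <- data.frame(
    chrom = vapply(runs, function(i) chrom[i[1L]], ""),
    start = vapply(runs, function(i) pos[i[1L]], 0L),
    end = vapply(runs, function(i) pos[i[length(i)]] + 2L, 0L),
    n_cpgs = lengths(runs),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unmethylated runs within dense CpG segments
#'
#' Collects maximal runs of at least `min_run` consecutive CpGs called
#' unmethylated by the HMM, within one condition. Runs never cross segment
#' boundaries and break at gaps of `max_gap` or more.
#'
#' @param records Segmented, state-called CpG records (`chrom`, `pos`,
#'   `state`, `segment_id`).
#' @param min_run Minimum run length (CpGs).
#' @param max_gap Maximum within-run CpG spacing (exclusive), bp.
#' @return Data.frame of run intervals (`chrom`, `start`, `end`, `n_cpgs`).
#' @export
unmethylated_runs <- function(records, min_run = 4L, max_gap = 1000L) {
  stopifnot(all(c("state", "segment_id") %in% names(records)))
  flag_runs(records$chrom, records$pos, records$state == "U",
            records$segment_id, min_run, max_gap)
}

#' Persistently unmethylated (PU) intervals
#'
#' The bp-level intersection of the unmethylated runs of the two conditions
#' (e.g. naive ESC and primed EpiSC).
#'
#' @param runs_a,runs_b Run interval data.frames from [unmethylated_runs()].
#' @return Sorted, non-overlapping intervals.
#' @export
derive_pu <- function(runs_a, runs_b) {
  intersect_intervals(runs_a, runs_b)
}

#' Differentially methylated (DM) intervals
#'
#' Runs of at least `min_run` consecutive CpGs that are jointly unmethylated
#' in condition A (naive) and methylated in condition B (primed). Only CpGs
#' covered (post-filter) in both conditions enter the joint predicate. DM
#' intervals are trimmed of any overlap with PU (precedence PU > DM).
#'
#' @param joint Data.frame of shared CpGs with columns `chrom`, `pos`,
#'   `state_a`, `state_b` and optionally `segment_id`.
#' @param pu PU intervals used for trimming (may be empty).
#' @param min_run Minimum joint run length (CpGs).
#' @param max_gap Maximum within-run CpG spacing (exclusive), bp.
#' @return Sorted, non-overlapping intervals.
#' @export
derive_dm <- function(joint, pu = NULL, min_run = 4L, max_gap = 1000L) {
  runs <- flag_runs(joint$chrom, joint$pos,
                    joint$state_a == "U" & joint$state_b == "M",
                    joint$segment_id, min_run, max_gap)
  if (is.null(pu) || nrow(pu) == 0L || nrow(runs) == 0L) {
    return(runs[, c("chrom", "start", "end")])
  }
  setdiff_intervals(runs, pu)
}

#' Interstitial (INT) intervals
#'
#' The complement of the PU and DM intervals within a super-enhancer:
#' `SE - (PU union DM)`, split at PU/DM boundaries, zero-length pieces
#' dropped.
#'
#' @param se One-row data.frame (`chrom`, `start`, `end`) for the SE.
#' @param pu,dm Interval data.frames (may be empty).
#' @return Sorted, non-overlapping intervals covering the rest of the SE.
#' @export
derive_int <- function(se, pu, dm) {
  cols <- c("chrom", "start", "end")
  covered <- rbind(pu[, cols, drop = FALSE], dm[, cols, drop = FALSE])
  setdiff_intervals(se[, cols, drop = FALSE], covered)
}

#' Classify a super-enhancer by its subregion composition
#'
#' Class I SEs contain at least one PU subregion (optionally with DM
#' children); class II SEs contain DM subregions only. SEs with neither PU
#' nor DM children are `"unpartitioned"` and excluded from class statistics.
#'
#' @param subregions Data.frame of the SE's children with a `class` column
#'   in `{PU, DM, INT}`.
#' @return A list with `class` (`"I"`, `"II"` or `"unpartitioned"`),
#'   `n_pu`, `n_dm`.
#' @export
classify_se <- function(subregions) {
  n_pu <- sum(subregions$class == "PU")
  n_dm <- sum(subregions$class == "DM")
  cls <- if (n_pu >= 1L) "I" else if (n_dm >= 1L) "II" else "unpartitioned"
  list(class = cls, n_pu = n_pu, n_dm = n_dm)
}

#' Pooled methylation level over a region
#'
#' The read-level mCpG/CpG ratio: total methylated reads over total reads of
#' all CpGs inside the region.
#'
#' @param records CpG records.
#' @param region One-row data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @return A value in `[0, 1]`, or `NA` when no covered CpG lies inside.
#' @export
methylation_level <- function(records, region) {
  sel <- records$chrom == region$chrom &
    records$pos >= region$start & records$pos < region$end
  if (!any(sel)) return(NA_real_)
  sum(records$meth[sel]) / sum(records$total[sel])
}

#' Partition super-enhancers into PU, DM and INT subregions
#'
#' End-to-end driver over two conditions: coverage filtering, dense-segment
#' construction, per-chromosome HMM state calling, unmethylated-run and joint
#' DM-run detection, and per-SE partition into PU (unmethylated in both
#' conditions), DM (unmethylated in A, methylated in B) and INT (the
#' remainder), with SE class I/II calls.
#'
#' @param records_a,records_b Per-CpG records of condition A (naive) and B
#'   (primed).
#' @param ses SE intervals (`chrom`, `start`, `end`, `name`).
#' @param min_cov Coverage filter (reads).
#' @param max_gap Segment/run gap rule (bp, exclusive).
#' @param min_cpgs Minimum CpGs per segment.
#' @param min_run Minimum CpGs per unmethylated/DM run.
#' @param strict_pu If `TRUE`, PU intersections must still contain at least
#'   `min_run` CpGs covered in both conditions.
#' @return A list with `subregions` (data.frame `chrom`, `start`, `end`,
#'   `se_id`, `class`, `n_cpgs_a`, `n_cpgs_b`, `meth_a`, `meth_b`),
#'   `se_classes` (data.frame `se_id`, `class`, `n_pu`, `n_dm`), `states_a`,
#'   `states_b` (state-called records) and the thresholds used.
#' @export
partition_superenhancers <- function(records_a, records_b, ses,
                                     min_cov = 7L, max_gap = 1000L,
                                     min_cpgs = 10L, min_run = 4L,
                                     strict_pu = FALSE) {
  if (is.null(ses$name) || anyNA(ses$name)) {
    ses$name <- sprintf("SE%04d", seq_len(nrow(ses)))
  }
  prep <- function(records) {
    filt <- filter_by_coverage(records, min_cov)
    seg <- build_segments(filt, max_gap, min_cpgs)
    if (nrow(seg$records) == 0L) return(seg$records)
    call_states(seg$records)
  }
  st_a <- prep(records_a)
  st_b <- prep(records_b)

  runs_a <- unmethylated_runs(st_a, min_run, max_gap)
  runs_b <- unmethylated_runs(st_b, min_run, max_gap)

  # joint table over CpGs retained in both conditions
  key_a <- paste(st_a$chrom, st_a$pos)
  key_b <- paste(st_b$chrom, st_b$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  joint <- data.frame(chrom = st_a$chrom[ia], pos = st_a$pos[ia],
                      state_a = st_a$state[ia], state_b = st_b$state[ib],
                      segment_id = paste(st_a$segment_id[ia],
                                         st_b$segment_id[ib]),
                      stringsAsFactors = FALSE)
  joint <- joint[order(joint$chrom, joint$pos), , drop = FALSE]

  cols <- c("chrom", "start", "end")
  # genome-wide PU and DM intervals, computed once and clipped per SE
  pu_all <- derive_pu(runs_a, runs_b)
  if (strict_pu && nrow(pu_all) > 0L) {
    nshared <- vapply(seq_len(nrow(pu_all)), function(j) {
      sum(joint$chrom == pu_all$chrom[j] & joint$pos >= pu_all$start[j] &
            joint$pos < pu_all$end[j])
    }, 0L)
    pu_all <- pu_all[nshared >= min_run, , drop = FALSE]
  }
  dm_all <- derive_dm(joint, pu_all, min_run, max_gap)
  clip <- function(iv, se) {
    sel <- iv$chrom == se$chrom & iv$start < se$end & iv$end > se$start
    out <- iv[sel, cols, drop = FALSE]
    out$start <- pmax(out$start, se$start)
    out$end <- pmin(out$end, se$end)
    out
  }
  subregions <- list()
  se_classes <- list()
  for (i in seq_len(nrow(ses))) {
    se <- ses[i, , drop = FALSE]
    se_id <- se$name
    pu <- clip(pu_all, se)
    dm <- clip(dm_all, se)
    int <- derive_int(se, pu, dm)
    children <- rbind(
      if (nrow(pu)) cbind(pu, class = "PU") else NULL,
      if (nrow(dm)) cbind(dm, class = "DM") else NULL,
      if (nrow(int)) cbind(int, class = "INT") else NULL)
    if (is.null(children) || nrow(children) == 0L) next
    children$se_id <- se_id
    children$n_cpgs_a <- vapply(seq_len(nrow(children)), function(j) {
      sum(st_a$chrom == children$chrom[j] & st_a$pos >= children$start[j] &
            st_a$pos < children$end[j])
    }, 0L)
    children$n_cpgs_b <- vapply(seq_len(nrow(children)), function(j) {
      sum(st_b$chrom == children$chrom[j] & st_b$pos >= children$start[j] &
            st_b$pos < children$end[j])
    }, 0L)
    children$meth_a <- vapply(seq_len(nrow(children)), function(j) {
      methylation_level(st_a, children[j, ])
    }, 0.0)
    children$meth_b <- vapply(seq_len(nrow(children)), function(j) {
      methylation_level(st_b, children[j, ])
    }, 0.0)
    cl <- classify_se(children)
    subregions[[se_id]] <- children
    se_classes[[se_id]] <- data.frame(se_id = se_id, class = cl$class,
                                      n_pu = cl$n_pu, n_dm = cl$n_dm,
                                      stringsAsFactors = FALSE)
  }
  subregions <- if (length(subregions)) do.call(rbind, subregions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               class = character(), se_id = character(),
               stringsAsFactors = FALSE)
  se_classes <- if (length(se_classes)) do.call(rbind, se_classes) else
    data.frame(se_id = character(), class = character(), n_pu = integer(),
               n_dm = integer(), stringsAsFactors = FALSE)
  rownames(subregions) <- rownames(se_classes) <- NULL
  subregions <- subregions[order(subregions$chrom, subregions$start), ,
                           drop = FALSE]
  rownames(subregions) <- NULL
  list(subregions = subregions, se_classes = se_classes,
       states_a = st_a, states_b = st_b,
       thresholds = list(min_cov = min_cov, max_gap = max_gap,
                         min_cpgs = min_cpgs, min_run = min_run,
                         strict_pu = strict_pu))
}
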