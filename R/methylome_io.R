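#' Read a per-CpG methylation table
#'
#' Parses bulk bisulfite-sequencing CpG calls from either the bismark
#' coverage dialect (chrom, start 1-based, end, percent methylation,
#' methylated count, unmethylated count) or a bedGraph-with-counts dialect
#' (chrom, start 0-based, end, methylated count, total count). Positions are
#' returned on a single internal convention: the 0-based coordinate of the C
#' of the CpG on the + strand.
#'
#' @param path Path to a tab- or whitespace-delimited file. Lines starting
#'   with `#` are skipped.
#' @param dialect One of `"bismark_cov"` or `"bedgraph_counts"`.
#' @param collapse_strands If `TRUE`, records at adjacent positions `p` and
#'   `p + 1` (the two strands of one CpG) are summed into a single record at
#'   `p`. Inputs already strand-collapsed should keep the default `FALSE`.
#' @return A data.frame of CpG records with columns `chrom`, `pos` (0-based),
#'   `meth` and `total`, sorted by (chrom, pos).
#' @export
read_cpg_table <- function(path, dialect = c("bismark_cov", "bedgraph_counts"),
                           collapse_strands = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  ncols <- if (dialect == "bismark_cov") 6L else 5L
  bad <- which(lengths(fields) < ncols)
  if (length(bad) > 0L) {
    stop(sprintf("malformed CpG table line %d in '%s': expected %d columns",
                 lineno[bad[1L]], path, ncols))
  }
  mat <- do.call(rbind, fields)
  chrom <- mat[, 1L]
  if (dialect == "bismark_cov") {
    pos <- suppressWarnings(as.integer(mat[, 2L])) - 1L  # 1-based -> 0-based
    meth <- suppressWarnings(as.integer(mat[, 5L]))
    unmeth <- suppressWarnings(as.integer(mat[, 6L]))
    total <- meth + unmeth
  } else {
    pos <- suppressWarnings(as.integer(mat[, 2L]))
    meth <- suppressWarnings(as.integer(mat[, 4L]))
    total <- suppressWarnings(as.integer(mat[, 5L]))
  }
  bad <- which(is.na(pos) | is.na(meth) | is.na(total))
  if (length(bad) > 0L) {
    stop(sprintf("malformed CpG table line %d in '%s': non-numeric field",
                 lineno[bad[1L]], path))
  }
  bad <- which(meth > total | total < 1L | meth < 0L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid counts at line %d in '%s': need 0 <= meth <= total, total >= 1",
      lineno[bad[1L]], path))
  }
  rec <- data.frame(chrom = chrom, pos = pos, meth = meth, total = total,
                    stringsAsFactors = FALSE)
  if (collapse_strands) rec <- collapse_cpg_strands(rec)
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Collapse per-strand CpG records onto the + strand C
#'
#' Records at position `p + 1` whose predecessor on the same chromosome sits
#' at `p` are interpreted as the - strand call of the CpG at `p` and their
#' counts are summed into the `p` record.
#'
#' @param records CpG record data.frame (`chrom`, `pos`, `meth`, `total`).
#' @return Collapsed records, one per CpG.
#' @export
collapse_cpg_strands <- function(records) {
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  n <- nrow(records)
  if (n < 2L) return(records)
  # greedy left-to-right pairing: a record consumes its immediate successor
  # at pos + 1 on the same chromosome; each record pairs at most once, so
  # runs of adjacent records (e.g. CGCG) pair as (1,2), (3,4), ...
  consumed <- logical(n)
  i <- 1L
  while (i < n) {
    if (!consumed[i] &&
        records$chrom[i + 1L] == records$chrom[i] &&
        records$pos[i + 1L] == records$pos[i] + 1L) {
      records$meth[i] <- records$meth[i] + records$meth[i + 1L]
      records$total[i] <- records$total[i] + records$total[i + 1L]
      consumed[i + 1L] <- TRUE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out <- records[!consumed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read genomic intervals from a BED file
#'
#' @param path Path to a BED3+ file (0-based half-open). Column 4, if
#'   present, populates `name`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED line %d in '%s'", lineno[bad[1L]], path))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0L) {
    stop(sprintf("invalid interval at BED line %d in '%s': need start < end",
                 lineno[bad[1L]], path))
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' Write classified SE subregions as BED6
#'
#' The name field is `<parent SE id>|<PU|DM|INT>`; rows are ordered by
#' coordinate so output is deterministic.
#'
#' @param subregions Data.frame with `chrom`, `start`, `end`, `se_id`,
#'   `class`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subregions_bed <- function(subregions, path) {
  stopifnot(all(c("chrom", "start", "end", "se_id", "class") %in%
                  names(subregions)))
  sr <- subregions[order(subregions$chrom, subregions$start, subregions$end), ,
                   drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t.",
                   sr$chrom, as.integer(sr$start), as.integer(sr$end),
                   sr$se_id, sr$class)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression table
#'
#' @param path TSV with a header: `gene_id` then one column per sample
#'   (RPKM values). `#` comment lines are skipped.
#' @return Data.frame with `gene_id` and numeric sample columns.
#' @export
read_expression_table <- function(path) {
  tbl <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot("gene_id" %in% names(tbl))
  if (anyDuplicated(tbl$gene_id)) stop("duplicate gene_ids in expression table")
  num <- setdiff(names(tbl), "gene_id")
  for (s in num) {
    tbl[[s]] <- as.numeric(tbl[[s]])
    if (any(is.na(tbl[[s]])) || any(tbl[[s]] < 0)) {
      stop(sprintf("expression column '%s' has missing or negative values", s))
    }
  }
  tbl
}

# ---- interval algebra helpers (0-based half-open <-> GRanges) ----

#' Convert a 0-based half-open interval data.frame to GRanges
#' @param df Data.frame with `chrom`, `start`, `end`.
#' @return A `GRanges` object (1-based closed, as GRanges requires).
#' @export
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Convert GRanges back to a 0-based half-open interval data.frame
#' @param gr A `GRanges` object.
#' @return Data.frame with `chrom`, `start`, `end`.
#' @export
granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

# sort and merge overlapping/touching intervals, per chromosome
reduce_intervals <- function(a) {
  if (nrow(a) == 0L) return(empty_intervals())
  a <- a[order(a$chrom, a$start, a$end), , drop = FALSE]
  n <- nrow(a)
  grp <- cumsum(c(TRUE, a$chrom[-1L] != a$chrom[-n] |
                    a$start[-1L] > cummax_by(a$end, a$chrom)[-n]))
  data.frame(chrom = a$chrom[!duplicated(grp)],
             start = as.integer(tapply(a$start, grp, min)),
             end = as.integer(tapply(a$end, grp, max)),
             stringsAsFactors = FALSE)
}

# running max of x within consecutive chrom blocks (x sorted by chrom,start)
cummax_by <- function(x, chrom) {
  unlist(lapply(split(x, factor(chrom, unique(chrom))), cummax),
         use.names = FALSE)
}

# bp-level intersection of two 0-based interval sets; output sorted,
# non-overlapping
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_intervals())
  a <- reduce_intervals(a)
  b <- reduce_intervals(b)
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ac <- a[a$chrom == chr, ]
    bc <- b[b$chrom == chr, ]
    i <- j <- 1L
    while (i <= nrow(ac) && j <= nrow(bc)) {
      s <- max(ac$start[i], bc$start[j])
      e <- min(ac$end[i], bc$end[j])
      if (s < e) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = s, end = e, stringsAsFactors = FALSE)
      }
      if (ac$end[i] <= bc$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  if (length(out) == 0L) return(empty_intervals())
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# a minus b, bp-level
setdiff_intervals <- function(a, b) {
  if (nrow(a) == 0L) return(empty_intervals())
  a <- reduce_intervals(a)
  if (nrow(b) == 0L) return(a)
  b <- reduce_intervals(b)
  out <- list()
  for (chr in unique(a$chrom)) {
    ac <- a[a$chrom == chr, ]
    bc <- b[b$chrom == chr, ]
    for (i in seq_len(nrow(ac))) {
      s <- ac$start[i]
      e <- ac$end[i]
      hit <- bc[bc$start < e & bc$end > s, , drop = FALSE]
      cur <- s
      for (j in seq_len(nrow(hit))) {
        if (hit$start[j] > cur) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chr, start = cur, end = hit$start[j],
            stringsAsFactors = FALSE)
        }
        cur <- max(cur, hit$end[j])
      }
      if (cur < e) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = cur, end = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_intervals())
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}
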