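#' Run the SE partition stage end to end
#'
#' Reads (or accepts in-memory) two-condition per-CpG methylation tables and
#' an SE BED, runs coverage filtering, segmentation, per-chromosome HMM state
#' calling and the PU/DM/INT partition, and writes the subregion BED, the
#' per-SE class table, per-class summary counts and a run log recording the
#' thresholds used.
#'
#' @param records_a,records_b CpG record data.frames, or paths to bismark
#'   coverage files.
#' @param ses SE interval data.frame, or a BED path.
#' @param outdir Output directory (created if needed).
#' @param min_cov,max_gap,min_cpgs,min_run Partition thresholds; defaults are
#'   the pipeline's standard values (7 reads, 1 kb, 10 CpGs, 4 CpGs).
#' @return The [partition_superenhancers()] result, invisibly, with an
#'   `outdir` element added.
#' @export
run_partition <- function(records_a, records_b, ses, outdir,
                          min_cov = 7L, max_gap = 1000L, min_cpgs = 10L,
                          min_run = 4L) {
  if (is.character(records_a)) records_a <- read_cpg_table(records_a)
  if (is.character(records_b)) records_b <- read_cpg_table(records_b)
  if (is.character(ses)) ses <- read_bed(ses)
  stopifnot(nrow(records_a) > 0L, nrow(records_b) > 0L, nrow(ses) > 0L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- partition_superenhancers(records_a, records_b, ses,
                                  min_cov = min_cov, max_gap = max_gap,
                                  min_cpgs = min_cpgs, min_run = min_run)
  write_subregions_bed(res$subregions, file.path(outdir, "subregions.bed"))
  utils::write.table(res$se_classes, file.path(outdir, "se_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- as.data.frame(table(factor(res$subregions$class,
                                       c("PU", "DM", "INT"))),
                          stringsAsFactors = FALSE)
  names(counts) <- c("class", "n_subregions")
  utils::write.table(counts, file.path(outdir, "class_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(
    sprintf("semethdyn %s", as.character(utils::packageVersion("semethdyn"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("thresholds: min_cov=%d max_gap=%d min_cpgs=%d min_run=%d",
            min_cov, max_gap, min_cpgs, min_run),
    sprintf("n_ses=%d n_subregions=%d", nrow(ses), nrow(res$subregions)))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  res$outdir <- outdir
  invisible(res)
}

#' Summarise a completed partition run
#'
#' Collects the outputs of [run_partition()] into one machine-readable
#' summary (JSON): per-class subregion counts, per-class pooled methylation
#' levels per condition, and SE class tallies.
#'
#' @param outdir The partition run's output directory.
#' @param path Optional path for the JSON summary (default
#'   `<outdir>/summary.json`).
#' @return The summary list, invisibly.
#' @export
run_report <- function(outdir, path = file.path(outdir, "summary.json")) {
  bed <- file.path(outdir, "subregions.bed")
  cls <- file.path(outdir, "se_classes.tsv")
  missing <- c(bed, cls)[!file.exists(c(bed, cls))]
  if (length(missing) > 0L) {
    stop(sprintf("incomplete run: missing %s", paste(missing, collapse = ", ")))
  }
  sub <- read_bed(bed)
  parts <- strsplit(sub$name, "|", fixed = TRUE)
  sub$class <- vapply(parts, `[`, "", 2L)
  se_classes <- utils::read.delim(cls, stringsAsFactors = FALSE)
  count_of <- function(x, lv) {
    out <- as.list(as.integer(table(factor(x, lv))))
    names(out) <- lv
    out
  }
  summary <- list(
    schema = "semethdyn/partition-summary/1",
    n_subregions = count_of(sub$class, c("PU", "DM", "INT")),
    n_ses = count_of(se_classes$class, c("I", "II", "unpartitioned")))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
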