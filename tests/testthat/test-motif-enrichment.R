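# direct per-window PWM score oracle: enumerate offsets and both strands
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

score_window_brute <- function(window, pwm_obj, pseudocount = 0.01) {
  mat <- sweep(pwm_obj$mat + pseudocount, 2L,
               colSums(pwm_obj$mat + pseudocount), "/")
  lo <- log2(mat / pwm_obj$background)
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    L <- ncol(lo)
    if (length(ch) < L) return(-Inf)
    max(vapply(seq_len(length(ch) - L + 1L), function(i) {
      sum(vapply(seq_len(L), function(j) {
        b <- ch[i + j - 1L]
        if (b %in% rownames(lo)) lo[b, j] else -Inf
      }, 0.0))
    }, 0.0))
  }
  max(score_one(window), score_one(revcomp(window)))
}

gata_pwm <- function() {
  # near-consensus GATAAG
  m <- matrix(0.04, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c(3L, 1L, 4L, 1L, 1L, 3L)  # G A T A A G
  for (j in 1:6) m[cons[j], j] <- 0.88
  pwm("gata", m)
}

test_that("tiling uses round(len/width) equally spaced fixed-width windows", {
  r <- data.frame(chrom = "c1", start = 0L, end = 2910L)
  t10 <- tile_regions(r, 291L)
  expect_equal(nrow(t10), 10L)
  expect_equal(t10$end - t10$start, rep(291L, 10L))
  expect_equal(t10$start[1L], 0L)
  expect_equal(t10$end[10L], 2910L)
  expect_false(any(t10$clipped))

  # exactly one width: a single tile spanning the region
  t1 <- tile_regions(data.frame(chrom = "c1", start = 100L, end = 391L), 291L)
  expect_equal(nrow(t1), 1L)
  expect_equal(c(t1$start, t1$end), c(100L, 391L))

  # shorter than the width: single clipped tile
  ts <- tile_regions(data.frame(chrom = "c1", start = 0L, end = 100L), 291L)
  expect_true(ts$clipped)
  expect_equal(ts$end - ts$start, 100L)

  # rounding: 436 bp / 291 -> 1 tile; 437 bp -> 2 tiles
  expect_equal(nrow(tile_regions(data.frame(chrom = "c1", start = 0L,
                                            end = 436L), 291L)), 1L)
  expect_equal(nrow(tile_regions(data.frame(chrom = "c1", start = 0L,
                                            end = 437L), 291L)), 2L)

  # class/se_id columns carried through
  r2 <- data.frame(chrom = "c1", start = 0L, end = 600L,
                   class = "PU", se_id = "SE1")
  expect_equal(unique(tile_regions(r2, 291L)$class), "PU")
})

test_that("PWM scan scores match the offset-and-strand enumeration oracle", {
  p <- gata_pwm()
  set.seed(51)
  for (rep in 1:15) {
    window <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    got <- max(pwm_scan_scores(encode_dna(window), p))
    expect_equal(got, score_window_brute(window, p), tolerance = 1e-12)
  }

  # planted consensus scores strictly higher than scrambled background
  bg <- paste(rep("ACCT", 20), collapse = "")
  planted <- paste0(substr(bg, 1, 37), "GATAAG", substr(bg, 44, 80))
  expect_gt(max(pwm_scan_scores(encode_dna(planted), p)),
            max(pwm_scan_scores(encode_dna(bg), p)))

  # reverse complement of the consensus matches equally well
  rc <- paste0(substr(bg, 1, 37), "CTTATC", substr(bg, 44, 80))
  expect_equal(max(pwm_scan_scores(encode_dna(planted), p)),
               max(pwm_scan_scores(encode_dna(rc), p)), tolerance = 1e-12)

  # N positions can never contribute to a match
  expect_equal(max(pwm_scan_scores(encode_dna("NNNNNNNNNN"), p)), -Inf)
})

test_that("empirical thresholds are seeded quantiles with the stated FDR", {
  set.seed(52)
  genome <- list(chrS = paste(sample(c("A", "C", "G", "T"), 30000, TRUE),
                              collapse = ""))
  # a longer heterogeneous PWM gives a near-continuous score distribution,
  # so the 99% background quantile behaves like a 1% FDR cut-off
  m <- matrix(rexp(4 * 12), 4, 12)
  m <- sweep(m, 2L, colSums(m), "/")
  p <- pwm("rnd", m)
  thr1 <- empirical_threshold(p, genome, n_background = 2000L, seed = 3L)
  thr2 <- empirical_threshold(p, genome, n_background = 2000L, seed = 3L)
  expect_identical(thr1, thr2)

  # on fresh background tiles, ~1% are called positive at the threshold
  tiles <- tile_regions(data.frame(chrom = "chrS", start = 0L, end = 29100L),
                        291L)
  hit_rate <- mean(scan_tiles(tiles, genome, p, thr1)$positive)
  expect_lt(hit_rate, 0.05)

  # monotone in the quantile
  thr95 <- empirical_threshold(p, genome, n_background = 2000L,
                               quantile = 0.95, seed = 3L)
  expect_lte(thr95, thr1)
  expect_error(empirical_threshold(p, list(c1 = "ACGT")), "shorter")
})

test_that("tiles containing the planted motif are called positive", {
  set.seed(53)
  base <- sample(c("A", "C", "G", "T"), 6000, TRUE)
  base[2001:2006] <- c("G", "A", "T", "A", "A", "G")  # plant in tile 7
  genome <- list(chrS = paste(base, collapse = ""))
  p <- gata_pwm()
  thr <- empirical_threshold(p, genome, n_background = 1000L, seed = 4L)
  tiles <- tile_regions(data.frame(chrom = "chrS", start = 0L, end = 5820L),
                        291L)
  scanned <- scan_tiles(tiles, genome, p, thr)
  planted_tile <- which(tiles$start <= 2000L & tiles$end >= 2006L)
  expect_true(all(scanned$positive[planted_tile]))
  # the planted tile carries the genome-wide best score
  expect_equal(max(scanned$best_score),
               max(scanned$best_score[planted_tile]))
})

test_that("class enrichment is the upper-tail hypergeometric with BH per class", {
  presence <- data.frame(
    motif = "m1",
    class = c(rep("PU", 4), rep("INT", 6)),
    positive = c(rep(TRUE, 4), TRUE, rep(FALSE, 5)))
  res <- class_enrichment(presence)
  pu <- res[res$class == "PU", ]
  # population 10, 5 positives, class of 4 all positive: P = 5/210
  expect_equal(pu$p, 5 / 210, tolerance = 1e-12)
  expect_equal(pu$hits_in_class, 4L)
  expect_equal(pu$hits_in_union, 5L)

  # no enrichment signal when positives are proportional
  flat <- data.frame(motif = "m1",
                     class = rep(c("PU", "DM"), each = 10),
                     positive = rep(c(TRUE, rep(FALSE, 9)), 2))
  expect_true(all(class_enrichment(flat)$p > 0.5))

  # BH adjustment is applied per class across motifs
  set.seed(54)
  fake <- class_enrichment(data.frame(
    motif = rep(rep(c("a", "b", "c"), each = 20), 2),
    class = rep(c("PU", "INT"), each = 60),
    positive = runif(120) < rep(c(0.7, 0.4, 0.2, 0.1, 0.1, 0.1), each = 20)))
  for (cl in c("PU", "INT")) {
    sel <- fake$class == cl
    expect_equal(fake$p_adjusted[sel], p.adjust(fake$p[sel], method = "BH"),
                 tolerance = 1e-12)
  }
  # monotone: adjusted never smaller than raw
  expect_true(all(fake$p_adjusted >= fake$p - 1e-15))
})
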