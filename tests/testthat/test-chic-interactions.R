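test_that("pseudo-fragment merging groups k fragments with a flagged remainder", {
  fr <- data.frame(chrom = "chr1", start = 100L * (0:8), end = 100L * (1:9))
  m8 <- merge_pseudofragments(fr[1:8, ], k = 4L)
  expect_equal(nrow(m8), 2L)
  expect_equal(m8$start, c(0L, 400L))
  m9 <- merge_pseudofragments(fr, k = 4L)
  expect_equal(nrow(m9), 3L)
  expect_equal(m9$n_fragments, c(4L, 4L, 1L))
  expect_equal(m9$remainder, c(FALSE, FALSE, TRUE))
  expect_equal(merge_pseudofragments(fr, k = 1L)$start, fr$start)
})

test_that("interaction filter applies score and geometric-mean coverage rules", {
  rec <- data.frame(score = c(6, 6, 4.99, 6), reads1 = c(4, 1, 9, 9),
                    reads2 = c(9, 16, 9, 9), trans = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_interactions(rec)
  expect_equal(nrow(out), 1L)  # geomean(4,9)=6 kept; (1,16)=4 dropped;
                               # score 4.99 dropped; trans dropped
  expect_equal(out$reads1, 4)
  expect_equal(filter_interactions(out), out)  # idempotent
})

test_that("distance-binned median-of-ratios matches the independent oracle", {
  set.seed(12)
  counts <- matrix(rnbinom(150, mu = 50, size = 5) + 1, 50, 3)
  d <- rep(10e3, 50)  # one bin
  got <- normalize_by_distance_bin(counts, d)
  expect_equal(unname(got$size_factors[1L, ]),
               unname(median_of_ratios_oracle(counts)), tolerance = 1e-12)

  # identical libraries: all factors 1
  same <- cbind(counts[, 1L], counts[, 1L])
  expect_equal(unname(normalize_by_distance_bin(same, d)$size_factors[1L, ]),
               c(1, 1))

  # exact doubling: factor ratio 2, per distance bin
  d2 <- sample(c(10e3, 50e3, 200e3, 400e3), 50, TRUE)
  two <- cbind(counts[, 1L], 2 * counts[, 1L])
  sf <- normalize_by_distance_bin(two, d2)$size_factors
  expect_equal(unname(sf[, 2L] / sf[, 1L]), rep(2, 4))
})

test_that("median-of-ratios agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(14)
  counts <- matrix(rnbinom(200, mu = 80, size = 8) + 1, 50, 4)
  got <- normalize_by_distance_bin(counts, rep(1e3, 50))$size_factors[1L, ]
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("scaling one library changes only its factor and not normalised counts", {
  set.seed(15)
  counts <- matrix(rnbinom(120, mu = 40, size = 6) + 1, 40, 3)
  d <- sample(c(5e3, 60e3, 150e3, 5e5), 40, TRUE)
  base <- normalize_by_distance_bin(counts, d)
  scaled <- counts
  scaled[, 2L] <- scaled[, 2L] * 3
  got <- normalize_by_distance_bin(scaled, d)
  # with a geometric-mean reference, tripling one of three libraries
  # multiplies its factor by 3^(2/3), the others by 3^(-1/3): factor
  # ratios shift by exactly 3 and normalised counts by a common 3^(1/3)
  expect_equal(got$size_factors[, 2L] / got$size_factors[, 1L],
               3 * base$size_factors[, 2L] / base$size_factors[, 1L],
               tolerance = 1e-9)
  expect_equal(got$size_factors[, 3L] / got$size_factors[, 1L],
               base$size_factors[, 3L] / base$size_factors[, 1L],
               tolerance = 1e-9)
  expect_equal(got$normalized, 3^(1 / 3) * base$normalized, tolerance = 1e-9)
})

test_that("library correlation equals rank-then-Pearson", {
  set.seed(16)
  m <- cbind(a = rexp(200), b = rexp(200))
  m[, "b"] <- m[, "a"]^3  # monotone transform
  expect_equal(library_correlation(m, "a", "b"), 1)
  m2 <- cbind(a = 1:50, b = 50:1)
  expect_equal(library_correlation(m2, "a", "b"), -1)
  m3 <- cbind(a = rnorm(200), b = rnorm(200))
  expect_equal(library_correlation(m3, "a", "b"),
               cor(rank(m3[, "a"]), rank(m3[, "b"])), tolerance = 1e-12)
})

test_that("subregion interaction frequency applies width and max-overlap rules", {
  sub <- data.frame(chrom = "c1", start = c(0L, 1000L, 2000L),
                    end = c(499L, 1800L, 3000L), se_id = "SE1",
                    class = c("PU", "PU", "INT"), stringsAsFactors = FALSE)
  rec <- data.frame(bait = "g1", chrom = "c1",
                    start = c(1100L, 1700L), end = c(1500L, 2100L),
                    norm_reads = c(5, 7), distance = c(1e4, 1e4))
  out <- subregion_interaction_frequency(rec, sub, min_width = 500L)
  # width-499 subregion excluded; fragment 2 overlaps PU by 100 and INT by
  # 100 -- first-best kept deterministically, fragment 1 fully in PU
  expect_true(all(out$class %in% c("PU", "INT")))
  expect_equal(sum(out$frequency), 12)
  pu_row <- out[out$class == "PU", ]
  expect_gte(pu_row$frequency[1L], 5)

  rec2 <- data.frame(bait = "g1", chrom = "c1", start = 1000L, end = 1400L,
                     norm_reads = 3, distance = 5e3)
  out2 <- subregion_interaction_frequency(rec2, sub)
  expect_equal(out2$frequency, 3)
  expect_equal(out2$class, "PU")

  rec3 <- data.frame(bait = "g1", chrom = "c1", start = 1500L, end = 1900L,
                     norm_reads = 2, distance = 5e3)
  # overlaps PU by 300 bp and INT by 0 -> PU (within [1500,1800))
  expect_equal(subregion_interaction_frequency(rec3, sub)$class, "PU")
})

test_that("interaction class model recovers planted effects and controls type I", {
  set.seed(17)
  simulate_table <- function(n, pu_effect) {
    cl <- sample(c("PU", "DM", "INT"), n, TRUE)
    nb <- sample(1:5, n, TRUE)
    dist <- runif(n, 1e4, 1e6)
    log2f <- 10 + 0.3 * nb - 0.4 * log2(dist) +
      pu_effect * (cl == "PU") + rnorm(n, 0, 0.5)
    data.frame(frequency = pmax(2^log2f - 1, 0), class = cl, n_baits = nb,
               distance = dist, stringsAsFactors = FALSE)
  }
  fit <- interaction_class_model(simulate_table(500, 1))
  est <- fit$coefficients
  pu <- est[est$term == "classPU", ]
  expect_lt(abs(pu$estimate - 1), 3 * pu$se)
  expect_lt(pu$p, 0.01)

  pvals <- replicate(200, {
    f <- interaction_class_model(simulate_table(120, 0))
    f$coefficients$p[f$coefficients$term == "classPU"]
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)

  # orthogonal covariates: class estimate equals the group-mean difference
  tbl <- data.frame(frequency = 2^c(1, 2, 3, 4, 2, 3, 4, 5) - 1,
                    class = rep(c("PU", "INT"), each = 4),
                    n_baits = rep(c(1, 2, 1, 2), 2),
                    distance = rep(c(1e4, 1e4, 4e4, 4e4), 2))
  fit2 <- suppressWarnings(interaction_class_model(tbl))  # exact fit by design
  gm <- mean(log2(tbl$frequency[tbl$class == "PU"] + 1)) -
    mean(log2(tbl$frequency[tbl$class == "INT"] + 1))
  expect_equal(fit2$coefficients$estimate[fit2$coefficients$term == "classPU"],
               gm, tolerance = 1e-9)
})

test_that("4C binning and running-mean smoothing behave like a convolution", {
  fr <- data.frame(mid = seq(-5e5, 5e5, by = 2500) + 1e6, count = 10)
  out <- bin_and_smooth_4c(fr, viewpoint = 1e6, lib_size = 1e6)
  # bins whose whole 7-bin window sits inside the constant-count run
  const <- which(out$count == max(out$count))
  core <- const[const >= min(const) + 3L & const <= max(const) - 3L]
  expect_gt(length(core), 50L)
  expect_equal(out$smoothed[core], out$count[core])  # constant signal

  # impulse response: single nonzero bin spread over the 7-bin window
  fr2 <- data.frame(mid = 1e6 + 2500, count = 700)
  out2 <- bin_and_smooth_4c(fr2, viewpoint = 1e6, lib_size = 1e6)
  expect_equal(sum(out2$smoothed > 0), 7L)
  expect_equal(max(out2$smoothed), 100)

  # random track equals direct convolution away from the edges
  set.seed(18)
  x <- rpois(100, 20)
  sm <- semethdyn:::running_mean(x, 7L)
  direct <- stats::filter(x, rep(1 / 7, 7), sides = 2)
  expect_equal(sm[4:97], as.numeric(direct[4:97]), tolerance = 1e-12)

  # low-coverage flag at 1000 RPKM
  expect_true(all(out$low_coverage == (out$rpkm < 1000)))
})
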