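test_that("coverage filter is inclusive at the threshold", {
  rec <- make_records(rep(0.5, 3), totals = c(6L, 7L, 8L))
  expect_equal(filter_by_coverage(rec, 7L)$total, c(7L, 8L))
  expect_equal(filter_by_coverage(rec, 1L), rec)
  expect_equal(nrow(filter_by_coverage(rec, 9L)), 0L)
})

test_that("segments chain CpGs spaced under 1 kb and drop small segments", {
  rec <- data.frame(chrom = "chr1", pos = c(0L, 500L, 900L, 2500L),
                    meth = 0L, total = 10L)
  seg <- build_segments(rec, max_gap = 1000L, min_cpgs = 1L)
  expect_equal(seg$segments$n_cpgs, c(3L, 1L))  # 2500 - 900 >= 1000 splits
  expect_equal(seg$segments$end, c(902L, 2502L))

  rec2 <- data.frame(chrom = "chr1", pos = c(0L, 999L), meth = 0L, total = 10L)
  expect_equal(nrow(build_segments(rec2, min_cpgs = 1L)$segments), 1L)

  rec3 <- make_records(rep(0.5, 9))
  expect_equal(nrow(build_segments(rec3, min_cpgs = 10L)$segments), 0L)
})

test_that("raising the coverage floor never admits more CpGs", {
  set.seed(21)
  rec <- make_records(runif(200), totals = sample(1:20, 200, TRUE))
  n <- vapply(1:15, function(mc) {
    nrow(build_segments(filter_by_coverage(rec, mc), min_cpgs = 5L)$records)
  }, 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("unmethylated runs match a brute-force scan", {
  states <- c("U", "U", "U", "M", "U", "U", "U", "U")
  rec <- make_records(rep(0, 8))
  rec$state <- states
  rec$segment_id <- 1L
  runs <- unmethylated_runs(rec, min_run = 4L)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start, rec$pos[5L])
  expect_equal(runs$end, rec$pos[8L] + 2L)

  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:15, 1L)
    st <- sample(c("U", "M"), n, TRUE)
    r <- make_records(rep(0, n))
    r$state <- st
    r$segment_id <- 1L
    got <- unmethylated_runs(r, min_run = 4L)
    want <- runs_brute(st == "U", 4L)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$start[k], r$pos[want[[k]][1L]])
      expect_equal(got$end[k], r$pos[want[[k]][2L]] + 2L)
    }
  }
})

test_that("runs never cross segment boundaries or 1-kb gaps", {
  r <- data.frame(chrom = "chr1", pos = c(0L, 100L, 1100L, 1200L, 1300L, 1400L),
                  meth = 0L, total = 10L, state = "U",
                  segment_id = c(1L, 1L, 1L, 1L, 1L, 1L))
  runs <- unmethylated_runs(r, min_run = 4L, max_gap = 1000L)
  expect_equal(nrow(runs), 1L)  # gap of 1000 splits; only the last 4 qualify
  expect_equal(runs$start, 1100L)
  r$segment_id <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(nrow(unmethylated_runs(r, min_run = 4L)), 0L)
})

test_that("PU is the bp intersection of the two conditions' runs", {
  a <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  b <- data.frame(chrom = "chr1", start = 150L, end = 250L)
  expect_equal(derive_pu(a, b), data.frame(chrom = "chr1", start = 150L,
                                           end = 200L))
  expect_equal(nrow(derive_pu(a, data.frame(chrom = "chr1", start = 300L,
                                            end = 400L))), 0L)
  expect_equal(derive_pu(a, a), a)
})

test_that("DM requires joint U-in-A, M-in-B runs and yields to PU", {
  joint <- data.frame(chrom = "chr1", pos = 100L * (0:3),
                      state_a = "U", state_b = "M",
                      segment_id = 1L, stringsAsFactors = FALSE)
  dm <- derive_dm(joint, min_run = 4L)
  expect_equal(nrow(dm), 1L)
  joint2 <- joint
  joint2$state_b <- c("M", "M", "U", "M")
  expect_equal(nrow(derive_dm(joint2, min_run = 4L)), 0L)

  # joint-run brute-force oracle on random paired state strings
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:15, 1L)
    j <- data.frame(chrom = "chr1", pos = 50L * (seq_len(n) - 1L),
                    state_a = sample(c("U", "M"), n, TRUE),
                    state_b = sample(c("U", "M"), n, TRUE),
                    segment_id = 1L, stringsAsFactors = FALSE)
    got <- derive_dm(j, min_run = 4L)
    want <- runs_brute(j$state_a == "U" & j$state_b == "M", 4L)
    expect_equal(nrow(got), length(want))
  }

  # PU trimming: overlap removed from DM
  pu <- data.frame(chrom = "chr1", start = 0L, end = 150L)
  dm_trim <- derive_dm(joint, pu, min_run = 4L)
  expect_equal(dm_trim$start, 150L)
})

test_that("INT is the SE complement of PU and DM", {
  se <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  pu <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  dm <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  int <- derive_int(se, pu, dm)
  expect_equal(int$start, c(0L, 200L, 600L))
  expect_equal(int$end, c(100L, 500L, 1000L))
  expect_equal(derive_int(se, pu[0, ], dm[0, ]), se)
  expect_equal(nrow(derive_int(se, data.frame(chrom = "chr1", start = 0L,
                                              end = 1000L), dm[0, ])), 0L)
})

test_that("SE classes follow the PU/DM composition rule", {
  expect_equal(classify_se(data.frame(class = c("PU", "DM")))$class, "I")
  expect_equal(classify_se(data.frame(class = c("DM", "DM")))$class, "II")
  expect_equal(classify_se(data.frame(class = c("INT")))$class,
               "unpartitioned")
})

test_that("methylation level is the pooled read-level ratio", {
  rec <- make_records(c(0.8, 0.2), totals = c(10L, 10L))
  region <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  expect_equal(methylation_level(rec, region), 0.5)
  expect_true(is.na(methylation_level(rec, data.frame(chrom = "chr1",
                                                      start = 500L,
                                                      end = 600L))))
  expect_equal(methylation_level(make_records(c(1, 1)), region), 1.0)
})

test_that("each SE is exactly partitioned into disjoint PU/DM/INT", {
  truth <- small_truth(seed = 13L, n_ses = 8L)
  res <- partition_superenhancers(simulate_bulk_bsseq(truth, "A", 13L),
                                  simulate_bulk_bsseq(truth, "B", 13L),
                                  truth$ses)
  for (id in unique(res$subregions$se_id)) {
    s <- res$subregions[res$subregions$se_id == id, ]
    s <- s[order(s$start), ]
    se <- truth$ses[truth$ses$name == id, ]
    expect_true(all(s$start[-1L] >= s$end[-nrow(s)]))
    expect_equal(sum(s$end - s$start), se$end - se$start)
    expect_true(all(s$start >= se$start & s$end <= se$end))
  }
  # every PU/DM subregion contains at least 4 state-called CpGs
  pd <- res$subregions[res$subregions$class != "INT", ]
  expect_true(all(pmax(pd$n_cpgs_a, pd$n_cpgs_b) >= 4L))
})
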