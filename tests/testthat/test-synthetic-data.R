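test_that("architecture simulation is a seeded pure function", {
  t1 <- simulate_architecture(simulation_config(n_ses = 5L), seed = 99L)
  t2 <- simulate_architecture(simulation_config(n_ses = 5L), seed = 99L)
  expect_identical(t1$cpgs, t2$cpgs)
  expect_identical(t1$ses, t2$ses)
  t3 <- simulate_architecture(simulation_config(n_ses = 5L), seed = 100L)
  expect_false(identical(t1$cpgs, t3$cpgs))

  # global RNG state is untouched
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_architecture(simulation_config(n_ses = 3L), seed = 5L))
  expect_identical(.Random.seed, before)
})

test_that("planted children are disjoint, inside their SE, and class-consistent", {
  truth <- simulate_architecture(simulation_config(n_ses = 12L), seed = 7L)
  for (id in truth$ses$name) {
    se <- truth$ses[truth$ses$name == id, ]
    kids <- truth$children[truth$children$se_id == id, ]
    kids <- kids[order(kids$start), ]
    expect_true(all(kids$start >= se$start & kids$end <= se$end))
    if (nrow(kids) > 1L) {
      expect_true(all(kids$start[-1L] >= kids$end[-nrow(kids)]))
    }
    cls <- if (any(kids$class == "PU")) "I" else "II"
    expect_equal(truth$genes$se_class[truth$genes$se_id == id], cls)
  }
  # class II SEs carry only DM children
  ii <- truth$genes$se_id[truth$genes$se_class == "II"]
  expect_true(all(truth$children$class[truth$children$se_id %in% ii] == "DM"))
})

test_that("latent CpG states follow the planted class semantics", {
  truth <- simulate_architecture(simulation_config(n_ses = 10L), seed = 11L)
  cp <- truth$cpgs
  expect_false(is.unsorted(cp$pos, strictly = TRUE))
  expect_true(all(cp$state_a[cp$region == "PU"] == "U"))
  expect_true(all(cp$state_b[cp$region == "PU"] == "U"))
  expect_true(all(cp$state_a[cp$region == "DM"] == "U"))
  expect_true(all(cp$state_b[cp$region == "DM"] == "M"))
  expect_true(all(cp$state_a[cp$region == "INT"] == "M"))
  expect_true(all(cp$state_b[cp$region == "INT"] == "M"))
  # both states occur outside SEs so a genome-wide HMM is identifiable
  expect_true(any(cp$region == "Mbg"))

  # every planted child has >= 10 CpGs with sub-1kb spacing (survives the
  # segment filter by construction)
  for (cid in truth$children$child_id) {
    pos <- cp$pos[!is.na(cp$child_id) & cp$child_id == cid]
    expect_gte(length(pos), 10L)
    expect_true(all(diff(pos) < 1000L))
  }
})

test_that("bulk bisulfite draws respect coverage and state means", {
  truth <- small_truth(seed = 3L)
  rec <- simulate_bulk_bsseq(truth, "A", seed = 3L)
  expect_identical(rec, simulate_bulk_bsseq(truth, "A", seed = 3L))
  expect_true(all(rec$meth <= rec$total))
  expect_true(all(rec$total >= 1L))
  expect_lt(abs(mean(rec$total) - truth$config$coverage_mean /
                  (1 - dnbinom(0, mu = 10, size = 5))), 1.5)

  # pooled fractions near the emission means per latent state
  st <- truth$cpgs$state_a[match(rec$pos, truth$cpgs$pos)]
  fu <- sum(rec$meth[st == "U"]) / sum(rec$total[st == "U"])
  fm <- sum(rec$meth[st == "M"]) / sum(rec$total[st == "M"])
  expect_lt(abs(fu - 0.1), 0.02)
  expect_lt(abs(fm - 0.9), 0.02)

  # condition B flips DM CpGs to methylated
  recb <- simulate_bulk_bsseq(truth, "B", seed = 3L)
  stb <- truth$cpgs$region[match(recb$pos, truth$cpgs$pos)]
  fdm <- sum(recb$meth[stb == "DM"]) / sum(recb$total[stb == "DM"])
  expect_gt(fdm, 0.85)
  expect_false(identical(rec, recb))
})

test_that("single-cell mixture separates DM methylation by true label", {
  truth <- small_truth(seed = 5L, n_ses = 8L)
  sc <- simulate_single_cells(truth, seed = 5L)
  cfg <- truth$config
  expect_equal(nrow(sc$cells), cfg$n_2i + cfg$n_serum)
  expect_true(all(sc$calls$total == 1L))
  expect_true(all(sc$calls$meth %in% 0:1))
  expect_equal(nrow(sc$expression), nrow(sc$cells))

  children <- truth$children
  children$se_id <- children$se_id  # subregion table for pooling
  dm_avg <- class_average_per_cell(sc$calls, children, "DM")
  lab <- sc$cells$true_label[match(names(dm_avg), sc$cells$cell)]
  m_naive <- mean(dm_avg[lab == "naive-like"], na.rm = TRUE)
  m_primed <- mean(dm_avg[lab == "primed-like"], na.rm = TRUE)
  expect_lt(m_naive + 0.15, m_primed)
  expect_lt(mean(dm_avg[lab == "2i"], na.rm = TRUE), m_naive + 0.1)

  # class-II genes are upregulated in naive-like/2i cells
  ii <- truth$genes$gene_id[truth$genes$se_class == "II"]
  naive <- sc$cells$true_label %in% c("naive-like", "2i")
  if (length(ii) > 0L) {
    ratio <- mean(sc$expression[naive, ii]) / mean(sc$expression[!naive, ii])
    expect_gt(ratio, 2^(cfg$class2_log2fc - 0.5))
  }
  noise <- sc$genes$gene_id[sc$genes$type == "noise"]
  r0 <- mean(sc$expression[naive, noise]) / mean(sc$expression[!naive, noise])
  expect_lt(abs(log2(r0)), 0.5)
})

test_that("CHiC counts decay with distance and favour PU/DM fragments", {
  truth <- small_truth(seed = 9L, n_ses = 10L)
  chic <- simulate_chic(truth, seed = 9L)
  rec <- chic$records
  expect_identical(rec, simulate_chic(truth, seed = 9L)$records)
  expect_true(all(rec$reads1 >= 0 & rec$reads2 >= 0))
  expect_false(any(rec$trans))
  expect_equal(rec$end - rec$start,
               rep(truth$config$fragment_width, nrow(rec)))

  # planted boost: unmethylated subregions attract more contacts after
  # removing the distance trend
  fit <- lm(log2((rec$reads1 + rec$reads2) / 1.5 + 1) ~
              log2(rec$distance) + I(rec$class_truth != "INT"))
  boost_est <- coef(fit)[3L]
  expect_gt(boost_est, log2(3) - 0.5)

  # replicate depth ratio reflected in total counts
  expect_gt(sum(rec$reads1), 1.5 * sum(rec$reads2))

  # distance decay: counts fall with distance within the INT stratum
  int_rec <- rec[rec$class_truth == "INT", ]
  expect_lt(cor(log2(int_rec$distance),
                log2(int_rec$reads1 + 1)), -0.2)
})
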