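# Shared fixtures and independent brute-force oracles.

# CpG records at regular spacing from methylation fractions and coverages
make_records <- function(fracs, totals = rep(10L, length(fracs)),
                         spacing = 100L, chrom = "chr1", start = 0L) {
  data.frame(chrom = chrom,
             pos = start + spacing * (seq_along(fracs) - 1L),
             meth = as.integer(round(fracs * totals)),
             total = as.integer(totals), stringsAsFactors = FALSE)
}

# joint probability of one state path (1 = U, 2 = M) under binomial emissions
path_logprob <- function(path, params, records) {
  em <- vapply(1:2, function(s) {
    dbinom(records$meth, records$total, params$means[s], log = TRUE)
  }, numeric(nrow(records)))
  em <- matrix(em, nrow = nrow(records))
  lp <- log(params$initial[path[1L]]) + em[1L, path[1L]]
  for (t in seq_along(path)[-1L]) {
    lp <- lp + log(params$transition[path[t - 1L], path[t]]) + em[t, path[t]]
  }
  lp
}

# exhaustive-enumeration Viterbi oracle for short sequences
viterbi_brute <- function(params, records) {
  n <- nrow(records)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lp <- apply(paths, 1L, path_logprob, params = params, records = records)
  best <- lp[which.max(lp)]
  # ties: prefer lexicographically smaller path (more U earlier), matching
  # the tie-toward-U convention
  cand <- paths[abs(lp - best) < 1e-12, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand))
  list(path = c("U", "M")[cand[ord[1L], ]], loglik = best)
}

# brute-force scan for maximal runs of >= min_run consecutive TRUE values
runs_brute <- function(flag, min_run = 4L) {
  out <- list()
  i <- 1L
  n <- length(flag)
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# random valid two-state HMM parameters
random_params <- function() {
  st <- runif(2, 0.55, 0.99)
  tr <- matrix(c(st[1], 1 - st[1], 1 - st[2], st[2]), 2, 2, byrow = TRUE)
  means <- sort(runif(2, 0.02, 0.98))
  if (diff(means) < 0.05) means <- c(means[1], min(means[1] + 0.05, 0.99))
  init <- runif(1, 0.05, 0.95)
  hmm_params(c(init, 1 - init), tr, means)
}

# independent median-of-ratios size factors (single stratum)
median_of_ratios_oracle <- function(counts) {
  logc <- log(counts)
  usable <- is.finite(rowSums(logc))
  ref <- rowMeans(logc[usable, , drop = FALSE])
  apply(logc[usable, , drop = FALSE], 2L, function(col) {
    exp(median(col - ref))
  })
}

# brute-force complete-linkage agglomeration; returns merge heights
complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        h <- max(d[active[[i]], active[[j]]])
        if (h < best[1L]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1L])
    merged <- c(active[[best[2L]]], active[[best[3L]]])
    active <- active[-c(best[2L], best[3L])]
    active[[length(active) + 1L]] <- merged
  }
  heights
}

small_truth <- function(seed = 7L, n_ses = 6L) {
  simulate_architecture(simulation_config(n_ses = n_ses), seed = seed)
}
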