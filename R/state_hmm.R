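#' Two-state methylation HMM parameters
#'
#' Constructs and validates the parameter set of the two-state
#' (unmethylated/methylated) hidden Markov model over per-CpG methylation
#' counts. State 1 is U (unmethylated), state 2 is M (methylated);
#' identifiability is enforced by requiring `means[1] < means[2]`.
#'
#' @param initial Length-2 initial state probabilities (sums to 1).
#' @param transition 2x2 row-stochastic transition matrix.
#' @param means Length-2 expected methylation fraction per state, U < M.
#' @param dispersion Length-2 non-negative over-dispersion per state. 0 gives
#'   a pure binomial emission; > 0 a beta-binomial with that intra-class
#'   correlation parameterised as rho = dispersion / (1 + dispersion).
#' @param emission `"binomial"` (counts; default) or `"gaussian"`
#'   (on the methylation fraction, with per-state sd in `gaussian_sd`).
#' @param gaussian_sd Length-2 per-state sd for the gaussian emission mode.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(initial, transition, means, dispersion = c(0, 0),
                       emission = c("binomial", "gaussian"),
                       gaussian_sd = c(0.15, 0.15)) {
  emission <- match.arg(emission)
  initial <- as.numeric(initial)
  transition <- matrix(as.numeric(transition), 2L, 2L)
  means <- as.numeric(means)
  stopifnot(length(initial) == 2L, length(means) == 2L,
            length(dispersion) == 2L)
  if (abs(sum(initial) - 1) > 1e-9) stop("initial probabilities must sum to 1")
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  if (any(means < 0 | means > 1)) stop("emission means must lie in [0, 1]")
  if (means[1L] >= means[2L]) stop("require means[U] < means[M]")
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  structure(list(initial = initial, transition = transition, means = means,
                 dispersion = as.numeric(dispersion), emission = emission,
                 gaussian_sd = as.numeric(gaussian_sd)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Two-state methylation HMM parameters\n")
  cat(sprintf("  emission: %s; means U=%.4f M=%.4f\n",
              x$emission, x$means[1L], x$means[2L]))
  cat(sprintf("  self-transitions: U=%.4f M=%.4f; initial U=%.4f\n",
              x$transition[1L, 1L], x$transition[2L, 2L], x$initial[1L]))
  invisible(x)
}

# per-observation log emission densities, n x 2 matrix (col 1 = U, col 2 = M)
emission_loglik <- function(params, records) {
  n <- nrow(records)
  out <- matrix(NA_real_, n, 2L)
  for (s in 1:2) {
    mu <- params$means[s]
    if (params$emission == "gaussian") {
      out[, s] <- stats::dnorm(records$meth / records$total, mu,
                               params$gaussian_sd[s], log = TRUE)
    } else if (params$dispersion[s] > 0) {
      # beta-binomial: shape from mean and concentration 1/dispersion
      conc <- 1 / params$dispersion[s]
      a <- mu * conc
      b <- (1 - mu) * conc
      out[, s] <- lchoose(records$total, records$meth) +
        lbeta(records$meth + a, records$total - records$meth + b) -
        lbeta(a, b)
    } else {
      out[, s] <- stats::dbinom(records$meth, records$total, mu, log = TRUE)
    }
  }
  out
}

#' Seed HMM parameters from observed methylation fractions
#'
#' Emission means are seeded from the means of the lower and upper terciles
#' of the observed per-CpG methylation fractions; the transition matrix is
#' seeded with a high self-transition probability. Deterministic given the
#' input.
#'
#' @param records CpG record data.frame (`meth`, `total`).
#' @param self_transition Initial self-transition probability.
#' @param min_obs Minimum number of observations required.
#' @inheritParams hmm_params
#' @return An `hmm_params` object.
#' @export
initialize_params <- function(records, self_transition = 0.95, min_obs = 20L,
                              emission = c("binomial", "gaussian")) {
  emission <- match.arg(emission)
  if (nrow(records) < min_obs) {
    stop(sprintf("insufficient data: need >= %d CpGs, got %d",
                 min_obs, nrow(records)))
  }
  f <- records$meth / records$total
  q <- stats::quantile(f, c(1 / 3, 2 / 3), names = FALSE)
  mu_u <- mean(f[f <= q[1L]])
  mu_m <- mean(f[f >= q[2L]])
  # degenerate input (all fractions equal): repair by +/- epsilon
  if (!(mu_u < mu_m)) {
    warning("degenerate methylation fractions; seeding means by +/- 0.05")
    mid <- min(max(mean(f), 0.05), 0.95)
    mu_u <- mid - 0.05
    mu_m <- mid + 0.05
  }
  trans <- matrix(c(self_transition, 1 - self_transition,
                    1 - self_transition, self_transition),
                  2L, 2L, byrow = TRUE)
  hmm_params(initial = c(0.5, 0.5), transition = trans,
             means = c(mu_u, mu_m), emission = emission)
}

#' Viterbi decoding of per-CpG methylation states
#'
#' Computes the maximum a posteriori state path. Ties are broken toward the
#' unmethylated state (conservative for unmethylated-run calling).
#'
#' @param params An `hmm_params` object.
#' @param records Ordered CpG records of one chromosome.
#' @return A list with `states` (character vector in `{"U","M"}`) and
#'   `loglik` (joint log-likelihood of the decoded path).
#' @export
decode <- function(params, records) {
  n <- nrow(records)
  if (n == 0L) return(list(states = character(), loglik = 0))
  em <- emission_loglik(params, records)
  log_init <- log(params$initial)
  log_tr <- log(params$transition)
  # two-state recursion unrolled to scalar updates; ties break toward U
  a_uu <- log_tr[1L, 1L]; a_um <- log_tr[1L, 2L]
  a_mu <- log_tr[2L, 1L]; a_mm <- log_tr[2L, 2L]
  back_u <- integer(n)
  back_m <- integer(n)
  du <- log_init[1L] + em[1L, 1L]
  dm <- log_init[2L] + em[1L, 2L]
  em_u <- em[, 1L]
  em_m <- em[, 2L]
  if (n > 1L) {
    for (t in 2:n) {
      cu1 <- du + a_uu; cu2 <- dm + a_mu
      cm1 <- du + a_um; cm2 <- dm + a_mm
      if (cu1 >= cu2) { bu <- 1L; vu <- cu1 } else { bu <- 2L; vu <- cu2 }
      if (cm1 >= cm2) { bm <- 1L; vm <- cm1 } else { bm <- 2L; vm <- cm2 }
      back_u[t] <- bu; back_m[t] <- bm
      du <- vu + em_u[t]
      dm <- vm + em_m[t]
    }
  }
  path <- integer(n)
  path[n] <- if (du >= dm) 1L else 2L
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      path[t] <- if (path[t + 1L] == 1L) back_u[t + 1L] else back_m[t + 1L]
    }
  }
  list(states = c("U", "M")[path], loglik = max(du, dm))
}

#' Fit the two-state HMM by Viterbi-EM
#'
#' Alternates Viterbi decoding with hard-assignment re-estimation of the
#' initial, transition and emission parameters (segmental k-means). The joint
#' log-likelihood of the Viterbi path is non-decreasing across iterations;
#' training stops when the improvement falls below `tol` or after `max_iter`
#' iterations.
#'
#' @param records Ordered CpG records of one chromosome.
#' @param params0 Starting `hmm_params` (e.g. from [initialize_params()]).
#' @param max_iter Maximum number of EM iterations; 0 returns `params0`.
#' @param tol Convergence tolerance on the Viterbi log-likelihood.
#' @return A list with `params` (fitted `hmm_params`), `loglik` (trace of the
#'   per-iteration Viterbi log-likelihood), `iterations`, `converged`, and
#'   `empty_states` (states that received no assignments in some iteration
#'   and kept their previous emission parameters).
#' @export
fit_viterbi_em <- function(records, params0, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(params0, "hmm_params"))
  params <- params0
  trace <- numeric(0)
  prev_ll <- -Inf
  empty_states <- character(0)
  iter <- 0L
  converged <- FALSE
  eps <- 1e-6
  while (iter < max_iter) {
    iter <- iter + 1L
    dec <- decode(params, records)
    path <- match(dec$states, c("U", "M"))
    trace <- c(trace, dec$loglik)
    if (dec$loglik - prev_ll < tol && is.finite(prev_ll)) {
      converged <- TRUE
      break
    }
    prev_ll <- dec$loglik
    # M-step on hard assignments
    init <- c(path[1L] == 1L, path[1L] == 2L) * 1
    trans <- params$transition
    n <- length(path)
    if (n > 1L) {
      from <- path[-n]
      to <- path[-1L]
      for (s in 1:2) {
        cnt <- c(sum(from == s & to == 1L), sum(from == s & to == 2L))
        if (sum(cnt) > 0) trans[s, ] <- cnt / sum(cnt)
      }
    }
    means <- params$means
    gsd <- params$gaussian_sd
    for (s in 1:2) {
      sel <- path == s
      if (!any(sel)) {
        empty_states <- union(empty_states, c("U", "M")[s])
        next
      }
      if (params$emission == "gaussian") {
        f <- records$meth[sel] / records$total[sel]
        means[s] <- mean(f)
        if (sum(sel) > 1L) gsd[s] <- max(stats::sd(f), eps)
      } else {
        means[s] <- sum(records$meth[sel]) / sum(records$total[sel])
      }
      means[s] <- min(max(means[s], eps), 1 - eps)
    }
    # relabel so U keeps the lower mean
    if (means[1L] > means[2L]) {
      means <- rev(means)
      gsd <- rev(gsd)
      init <- rev(init)
      trans <- trans[2:1, 2:1]
    } else if (means[1L] == means[2L]) {
      means <- means + c(-eps, eps)
    }
    init <- pmin(pmax(init, eps), 1 - eps)
    init <- init / sum(init)
    params <- hmm_params(init, trans, means, params$dispersion,
                         params$emission, gsd)
  }
  list(params = params, loglik = trace, iterations = iter,
       converged = converged, empty_states = empty_states)
}

#' Fit and decode per chromosome
#'
#' Fits the HMM independently on each chromosome's retained CpGs and decodes
#' the whole chromosome with the fitted model.
#'
#' @param records CpG records (already coverage-filtered and restricted to
#'   retained segments), sorted by (chrom, pos).
#' @param ... Passed on to [initialize_params()] and [fit_viterbi_em()].
#' @param max_iter,tol See [fit_viterbi_em()].
#' @return `records` with an added character column `state` in `{"U","M"}`,
#'   plus attribute `fits`: a per-chromosome list of fit reports.
#' @export
call_states <- function(records, max_iter = 100L, tol = 1e-6, ...) {
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  records$state <- NA_character_
  fits <- list()
  for (chr in unique(records$chrom)) {
    sel <- records$chrom == chr
    chrrec <- records[sel, , drop = FALSE]
    p0 <- initialize_params(chrrec, ...)
    fit <- fit_viterbi_em(chrrec, p0, max_iter = max_iter, tol = tol)
    records$state[sel] <- decode(fit$params, chrrec)$states
    fits[[chr]] <- fit
  }
  attr(records, "fits") <- fits
  records
}

#' Signed methylation score on the -1..+1 scale
#'
#' Maps a CpG's methylation fraction and its HMM state call to a single
#' signed score: methylated CpGs score `+fraction` (in `[0, 1]`) and
#' unmethylated CpGs score `fraction - 1` (in `[-1, 0]`), so bar height shows
#' the extent of methylation (up) or demethylation (down).
#'
#' @param records CpG records with `meth` and `total` (`total >= 1`).
#' @param states Character vector in `{"U","M"}`, same length.
#' @return Numeric vector of scores in `[-1, 1]`.
#' @export
signed_score <- function(records, states) {
  stopifnot(nrow(records) == length(states),
            all(states %in% c("U", "M")), all(records$total >= 1L))
  f <- records$meth / records$total
  ifelse(states == "M", f, f - 1)
}
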