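#' Configuration for the synthetic data generator
#'
#' Bundles the parameters of a synthetic two-condition methylome with a
#' planted super-enhancer subregion architecture, matching the statistical
#' structure the analysis assumes: a latent two-state (U/M) methylation
#' architecture over SEs, negative-binomial bulk coverage, single cells drawn
#' from a naive-like/primed-like mixture whose DM methylation couples to
#' class-II gene expression, and capture Hi-C counts with distance decay and
#' stronger contacts at unmethylated subregions.
#'
#' @param n_ses Number of super-enhancers.
#' @param p_class1 Probability an SE is class I (has at least one PU child).
#' @param child_width Range (bp) of planted PU/DM child widths.
#' @param int_spacer Range (bp) of INT spacers between/around children.
#' @param se_gap Range (bp) of gaps between SEs.
#' @param cpg_gap_child,cpg_gap_int,cpg_gap_background CpG spacing ranges
#'   (bp) inside children, inside INT, and outside SEs.
#' @param emission_means Latent methylation fraction per state (U, M).
#' @param coverage_mean,coverage_size Negative-binomial bulk coverage.
#' @param self_transition True self-transition probability used for
#'   HMM-recovery simulations.
#' @param n_2i,n_serum Numbers of 2i and serum single cells.
#' @param naive_weight Mixture weight of naive-like cells among serum cells.
#' @param cell_dm_means Mean per-cell DM methylation for (naive-like,
#'   primed-like) cells.
#' @param cell_dm_sd Between-cell sd of the DM methylation mixture
#'   components.
#' @param cell_obs_rate Probability a CpG is observed in a given cell
#'   (1 - dropout).
#' @param expr_base_mean,expr_size Negative-binomial single-cell expression.
#' @param class2_log2fc Log2 upregulation of class-II SE genes in naive-like
#'   cells.
#' @param chic_gamma Distance-decay exponent of contact frequency.
#' @param chic_boost Named contact boosts for PU, DM, INT subregions
#'   (condition A).
#' @param chic_depths Relative depths of the two replicate libraries.
#' @param chic_size Negative-binomial size of CHiC counts.
#' @param fragment_width Restriction fragment width (bp).
#' @param gene_distance Range (bp) of promoter-to-SE distances.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_ses = 50L,
                              p_class1 = 0.6,
                              child_width = c(900L, 2000L),
                              int_spacer = c(400L, 900L),
                              se_gap = c(20000L, 60000L),
                              cpg_gap_child = c(20L, 90L),
                              cpg_gap_int = c(40L, 180L),
                              cpg_gap_background = c(200L, 1500L),
                              emission_means = c(0.1, 0.9),
                              coverage_mean = 10,
                              coverage_size = 5,
                              self_transition = 0.98,
                              n_2i = 16L,
                              n_serum = 64L,
                              naive_weight = 0.5,
                              cell_dm_means = c(0.15, 0.6),
                              cell_dm_sd = 0.1,
                              cell_obs_rate = 0.2,
                              expr_base_mean = 50,
                              expr_size = 4,
                              class2_log2fc = 2,
                              chic_gamma = 1,
                              chic_boost = c(PU = 3, DM = 3, INT = 1),
                              chic_depths = c(1, 0.5),
                              chic_size = 10,
                              fragment_width = 600L,
                              gene_distance = c(50000L, 400000L)) {
  cfg <- as.list(environment())
  stopifnot(cfg$emission_means[1L] < cfg$emission_means[2L],
            all(cfg$emission_means >= 0 & cfg$emission_means <= 1),
            cfg$naive_weight >= 0 && cfg$naive_weight <= 1,
            cfg$coverage_size > 0, cfg$chic_gamma >= 0,
            cfg$child_width[1L] > 4L * cfg$cpg_gap_child[2L])
  class(cfg) <- "sim_config"
  cfg
}

runif_int <- function(n, range) {
  as.integer(round(stats::runif(n, range[1L], range[2L])))
}

#' Simulate a super-enhancer subregion architecture with ground truth
#'
#' Places SEs along one synthetic chromosome; each class I SE receives at
#' least one planted PU child (and possibly DM children), each class II SE
#' only DM children; INT fills the remainder of every SE. CpG positions are
#' dense inside SEs (gaps well under 1 kb, at least 10 CpGs per child by
#' construction) and sparse outside, with occasional unmethylated background
#' islands so both latent states occur genome-wide. Latent states per
#' condition follow the planted classes: PU children are unmethylated in
#' both conditions, DM children unmethylated in A (naive) and methylated in
#' B (primed), INT and most background methylated in both.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the result is a pure function of
#'   (config, seed).
#' @return A list of class `synthetic_truth`: `ses`, `children`, `cpgs`
#'   (with latent `state_a`, `state_b`), `genes`, `chrom_len`, `config`,
#'   `seed`.
#' @export
simulate_architecture <- function(config = simulation_config(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ses <- list()
  children <- list()
  cpg_pos <- integer(0)
  cpg_region <- character(0)
  cpg_child <- character(0)

  place_cpgs <- function(start, end, gap_range) {
    pos <- integer(0)
    p <- start + runif_int(1L, c(2L, gap_range[2L]))
    while (p < end - 1L) {
      pos <- c(pos, p)
      p <- p + runif_int(1L, gap_range)
    }
    pos
  }

  cursor <- 10000L
  for (i in seq_len(config$n_ses)) {
    se_id <- sprintf("SE%03d", i)
    is_class1 <- stats::runif(1) < config$p_class1
    n_pu <- if (is_class1) sample(1:2, 1L) else 0L
    n_dm <- if (is_class1) sample(0:2, 1L) else sample(1:3, 1L)
    classes <- sample(c(rep("PU", n_pu), rep("DM", n_dm)))
    se_start <- cursor
    p <- se_start
    for (j in seq_along(classes)) {
      spacer <- runif_int(1L, config$int_spacer)
      child_start <- p + spacer
      repeat {
        w <- runif_int(1L, config$child_width)
        cp <- place_cpgs(child_start, child_start + w, config$cpg_gap_child)
        if (length(cp) >= 10L) break  # resample infeasible draws
      }
      child_end <- child_start + w
      # INT spacer CpGs before the child
      ip <- place_cpgs(p, child_start, config$cpg_gap_int)
      cpg_pos <- c(cpg_pos, ip, cp)
      cpg_region <- c(cpg_region, rep("INT", length(ip)),
                      rep(classes[j], length(cp)))
      cpg_child <- c(cpg_child, rep(NA_character_, length(ip)),
                     rep(sprintf("%s.%d", se_id, j), length(cp)))
      children[[sprintf("%s.%d", se_id, j)]] <- data.frame(
        se_id = se_id, child_id = sprintf("%s.%d", se_id, j),
        chrom = "chrS", start = child_start, end = child_end,
        class = classes[j], stringsAsFactors = FALSE)
      p <- child_end
    }
    se_end <- p + runif_int(1L, config$int_spacer)
    ip <- place_cpgs(p, se_end, config$cpg_gap_int)
    cpg_pos <- c(cpg_pos, ip)
    cpg_region <- c(cpg_region, rep("INT", length(ip)))
    cpg_child <- c(cpg_child, rep(NA_character_, length(ip)))
    ses[[se_id]] <- data.frame(
      name = se_id, chrom = "chrS", start = se_start, end = se_end,
      stringsAsFactors = FALSE)
    # background CpGs up to the next SE, with an occasional unmethylated
    # island (CpG-island-like) so the HMM sees both states outside SEs
    gap <- runif_int(1L, config$se_gap)
    bg <- place_cpgs(se_end + 500L, se_end + gap - 500L,
                     config$cpg_gap_background)
    state_bg <- rep("Mbg", length(bg))
    if (length(bg) > 0L && stats::runif(1) < 0.4) {
      isl_start <- se_end + runif_int(1L, c(2000L, max(3000L, gap - 3000L)))
      isl <- place_cpgs(isl_start, isl_start + 1200L, config$cpg_gap_child)
      bg <- c(bg, isl)
      state_bg <- c(state_bg, rep("Ubg", length(isl)))
      ord <- order(bg)
      bg <- bg[ord]
      state_bg <- state_bg[ord]
    }
    cpg_pos <- c(cpg_pos, bg)
    cpg_region <- c(cpg_region, state_bg)
    cpg_child <- c(cpg_child, rep(NA_character_, length(bg)))
    cursor <- se_end + gap
  }
  ses <- do.call(rbind, ses)
  children <- do.call(rbind, children)
  rownames(ses) <- rownames(children) <- NULL

  ord <- order(cpg_pos)
  cpg_pos <- cpg_pos[ord]
  cpg_region <- cpg_region[ord]
  cpg_child <- cpg_child[ord]
  dup <- duplicated(cpg_pos)
  cpg_pos <- cpg_pos[!dup]
  cpg_region <- cpg_region[!dup]
  cpg_child <- cpg_child[!dup]

  state_a <- ifelse(cpg_region %in% c("PU", "DM", "Ubg"), "U", "M")
  state_b <- ifelse(cpg_region %in% c("PU", "Ubg"), "U", "M")
  cpgs <- data.frame(chrom = "chrS", pos = cpg_pos, region = cpg_region,
                     child_id = cpg_child, state_a = state_a,
                     state_b = state_b, stringsAsFactors = FALSE)

  # one associated gene per SE; promoter TSS at a sampled distance
  side <- sample(c(-1L, 1L), config$n_ses, replace = TRUE)
  dist <- runif_int(config$n_ses, config$gene_distance)
  mid <- as.integer((ses$start + ses$end) / 2)
  genes <- data.frame(gene_id = sprintf("gene_%s", ses$name),
                      se_id = ses$name, chrom = "chrS",
                      tss = pmax(mid + side * dist, 1000L),
                      stringsAsFactors = FALSE)
  se_class <- vapply(ses$name, function(s) {
    cl <- children$class[children$se_id == s]
    if (any(cl == "PU")) "I" else "II"
  }, "")
  genes$se_class <- unname(se_class)

  structure(list(ses = ses, children = children, cpgs = cpgs, genes = genes,
                 chrom_len = cursor + 10000L, config = config, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic SE architecture: %d SEs (%d class I), %d children, %d CpGs on one %.1f-Mb chromosome\n",
    nrow(x$ses), sum(x$genes$se_class == "I"), nrow(x$children),
    nrow(x$cpgs), x$chrom_len / 1e6))
  invisible(x)
}

#' Simulate bulk bisulfite sequencing of one condition
#'
#' Coverage is negative-binomial; methylated read counts are binomial with
#' the state mean of the CpG's latent state in the requested condition.
#' CpGs drawing zero coverage are dropped (unobserved).
#'
#' @param truth A [simulate_architecture()] result.
#' @param condition `"A"` (naive) or `"B"` (primed).
#' @param seed Integer seed.
#' @return CpG records (`chrom`, `pos`, `meth`, `total`).
#' @export
simulate_bulk_bsseq <- function(truth, condition = c("A", "B"), seed = 1L) {
  condition <- match.arg(condition)
  cfg <- truth$config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + if (condition == "A") 0L else 10000L)
  n <- nrow(truth$cpgs)
  state <- if (condition == "A") truth$cpgs$state_a else truth$cpgs$state_b
  total <- stats::rnbinom(n, mu = cfg$coverage_mean, size = cfg$coverage_size)
  mu <- ifelse(state == "U", cfg$emission_means[1L], cfg$emission_means[2L])
  meth <- stats::rbinom(n, total, mu)
  keep <- total >= 1L
  data.frame(chrom = truth$cpgs$chrom[keep], pos = truth$cpgs$pos[keep],
             meth = meth[keep], total = total[keep],
             stringsAsFactors = FALSE)
}

# beta draws parameterised by mean and sd (clamped to a proper beta)
rbeta_ms <- function(n, mean, sd) {
  mean <- min(max(mean, 0.02), 0.98)
  v <- min(sd^2, 0.9 * mean * (1 - mean))
  conc <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate single-cell methylation calls and expression counts
#'
#' Serum cells are drawn from a naive-like/primed-like mixture; a cell's
#' per-DM-subregion methylation is Beta-distributed around its cluster mean,
#' while PU subregions stay lowly and INT subregions highly methylated in
#' every cell. 2i cells are hypomethylated throughout. CpG observation is
#' sparse (per-cell dropout) with single-read calls. Expression counts are
#' negative-binomial, with class-II SE genes upregulated in naive-like (and
#' 2i) cells and class-I genes shared; unrelated noise genes are included.
#'
#' @param truth A [simulate_architecture()] result.
#' @param seed Integer seed.
#' @param n_noise_genes Number of unrelated genes.
#' @return A list with `calls` (per-cell CpG calls), `expression` (cells x
#'   genes count matrix), `cells` (metadata with true labels) and `genes`.
#' @export
simulate_single_cells <- function(truth, seed = 1L, n_noise_genes = 20L) {
  cfg <- truth$config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 20000L)
  n_cells <- cfg$n_2i + cfg$n_serum
  cells <- data.frame(
    cell = sprintf("cell%03d", seq_len(n_cells)),
    condition = c(rep("2i", cfg$n_2i), rep("serum", cfg$n_serum)),
    stringsAsFactors = FALSE)
  serum_label <- ifelse(stats::runif(cfg$n_serum) < cfg$naive_weight,
                        "naive-like", "primed-like")
  cells$true_label <- c(rep("2i", cfg$n_2i), serum_label)

  in_se <- !is.na(truth$cpgs$child_id) | truth$cpgs$region == "INT"
  se_cpgs <- truth$cpgs[truth$cpgs$region %in% c("PU", "DM", "INT"), ,
                        drop = FALSE]
  calls <- list()
  for (i in seq_len(n_cells)) {
    lab <- cells$true_label[i]
    dm_mean <- switch(lab, "2i" = 0.08,
                      "naive-like" = cfg$cell_dm_means[1L],
                      "primed-like" = cfg$cell_dm_means[2L])
    obs <- which(stats::runif(nrow(se_cpgs)) < cfg$cell_obs_rate)
    if (length(obs) == 0L) next
    reg <- se_cpgs$region[obs]
    child <- se_cpgs$child_id[obs]
    # per-DM-child cell-level methylation around the cluster mean
    dm_children <- unique(child[reg == "DM"])
    child_mu <- stats::setNames(
      rbeta_ms(length(dm_children), dm_mean, cfg$cell_dm_sd), dm_children)
    mu <- ifelse(reg == "PU", 0.05,
                 ifelse(reg == "INT", if (lab == "2i") 0.6 else 0.8,
                        child_mu[child]))
    meth <- stats::rbinom(length(obs), 1L, mu)
    calls[[i]] <- data.frame(cell = cells$cell[i],
                             chrom = se_cpgs$chrom[obs],
                             pos = se_cpgs$pos[obs],
                             meth = meth, total = 1L,
                             stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  genes <- rbind(
    data.frame(gene_id = truth$genes$gene_id, type = truth$genes$se_class,
               stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("noise_%02d", seq_len(n_noise_genes)),
               type = "noise", stringsAsFactors = FALSE))
  naive_like <- cells$true_label %in% c("naive-like", "2i")
  expr <- matrix(0L, n_cells, nrow(genes),
                 dimnames = list(cells$cell, genes$gene_id))
  for (g in seq_len(nrow(genes))) {
    lfc <- if (genes$type[g] == "II") cfg$class2_log2fc else 0
    mu <- cfg$expr_base_mean * 2^(ifelse(naive_like, lfc, 0))
    expr[, g] <- stats::rnbinom(n_cells, mu = mu, size = cfg$expr_size)
  }
  list(calls = calls, expression = expr, cells = cells, genes = genes)
}

#' Simulate capture Hi-C interaction records
#'
#' For every SE-associated gene promoter (bait), restriction fragments along
#' its SE produce read counts with a power-law distance decay and a planted
#' contact boost at unmethylated (PU/DM) subregions relative to INT, under
#' condition A. Two replicate libraries with distinct depths are drawn from
#' negative binomials. The per-gene expected expression change implied by the
#' planted contacts and methylation gain is returned for recovery checks.
#'
#' @param truth A [simulate_architecture()] result.
#' @param seed Integer seed.
#' @param obs_log2fc_sd Noise sd of the simulated observed log2 fold
#'   changes.
#' @return A list with `records` (bait, other-end fragment interval, reads
#'   per replicate, score, distance, trans), `fragments`, and `gene_effects`
#'   (`gene_id`, `true_log2fc`, the simulated observed expression change).
#' @export
simulate_chic <- function(truth, seed = 1L, obs_log2fc_sd = 20) {
  cfg <- truth$config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 30000L)
  boosts <- cfg$chic_boost
  recs <- list()
  frags <- list()
  gene_fx <- numeric(nrow(truth$genes))
  for (i in seq_len(nrow(truth$ses))) {
    se <- truth$ses[i, ]
    gene <- truth$genes[truth$genes$se_id == se$name, ]
    kids <- truth$children[truth$children$se_id == se$name, , drop = FALSE]
    starts <- seq(se$start, se$end - cfg$fragment_width,
                  by = cfg$fragment_width)
    fr <- data.frame(chrom = se$chrom, start = as.integer(starts),
                     end = as.integer(starts + cfg$fragment_width),
                     se_id = se$name, stringsAsFactors = FALSE)
    # max-overlap class of each fragment (INT where no child overlaps)
    fr$class <- vapply(seq_len(nrow(fr)), function(j) {
      ovl <- pmin(fr$end[j], kids$end) - pmax(fr$start[j], kids$start)
      if (length(ovl) == 0L || max(ovl) <= 0L) return("INT")
      kids$class[which.max(ovl)]
    }, "")
    mid <- (fr$start + fr$end) / 2
    d <- abs(gene$tss - mid)
    mu <- 60 * boosts[fr$class] * (d / 5e4)^(-cfg$chic_gamma)
    r1 <- stats::rnbinom(nrow(fr), mu = mu * cfg$chic_depths[1L],
                         size = cfg$chic_size)
    r2 <- stats::rnbinom(nrow(fr), mu = mu * cfg$chic_depths[2L],
                         size = cfg$chic_size)
    score <- pmax(0, 4 + log2(mu + 1) / 2 + stats::rnorm(nrow(fr), 0, 0.5))
    recs[[se$name]] <- data.frame(
      bait = gene$gene_id, chrom = fr$chrom, start = fr$start, end = fr$end,
      reads1 = r1, reads2 = r2, score = score, distance = d,
      trans = FALSE, class_truth = fr$class, stringsAsFactors = FALSE)
    frags[[se$name]] <- fr
    # expected expression change implied by the planted contacts:
    # DM children lose (meanM - meanU) methylation between conditions
    dm <- fr$class == "DM"
    meth_gain_pct <- 100 * diff(cfg$emission_means)
    gene_fx[truth$genes$se_id == se$name] <-
      if (any(dm)) -log2(sum(mu[dm]) + 1) * meth_gain_pct else 0
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  gene_effects <- data.frame(
    gene_id = truth$genes$gene_id,
    true_log2fc = gene_fx + stats::rnorm(length(gene_fx), 0, obs_log2fc_sd),
    stringsAsFactors = FALSE)
  list(records = records, fragments = do.call(rbind, frags),
       gene_effects = gene_effects)
}
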