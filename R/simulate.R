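# Synthetic-data generator for two-population fine-mapping benchmarks.
#
# Scenario 1: sparse shared causal SNPs on top of a dense bivariate polygenic
# background, no confounding. Scenario 2: causal SNPs plus an unadjusted
# PC-like confounder that inflates LDSC intercepts above 1.

derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream * 7919) %% 2147483629)
}

#' Study configuration for the simulation scenarios
#'
#' Defaults reproduce the generative recipe at desk scale: a 200-SNP locus
#' (weak AR(1) LD in population 1, strong in population 2, so that causal SNPs
#' can be resolved by leveraging LD diversity), 5000 background SNPs for the
#' LD score regression step, per-SNP polygenic covariance
#' `0.005/500 * [[1, 0.8], [0.8, 1]]` (per-SNP heritability 1e-5, genetic
#' correlation 0.8), per-causal-SNP effect variance `0.25/500` (a 50-fold
#' per-SNP heritability enrichment over the polygenic background), and GWAS
#' sample sizes of 20,000 per population.
#'
#' @param p Number of locus SNPs.
#' @param block_size AR(1) LD block size at the locus.
#' @param rho Per-population AR(1) decay at the locus (|rho| < 1).
#' @param p_genome Number of background SNPs for the LDSC step (0 disables).
#' @param genome_block_size Background LD block size.
#' @param genome_rho Cycle of AR(1) decays across background blocks
#'   (population 2; population 1 uses `genome_rho * genome_rho_factor`).
#' @param genome_rho_factor Population-1 decay multiplier (< 1: weaker LD).
#' @param K_true Number of causal SNPs.
#' @param n Per-population GWAS sample sizes.
#' @param h2_polygenic Locus-scale polygenic heritability (over `p_ref` SNPs).
#' @param rg_polygenic Cross-population polygenic genetic correlation.
#' @param p_ref Reference SNP count converting locus heritability to the
#'   per-SNP scale (`omega = h2_polygenic / p_ref`).
#' @param sigma2_causal Per-causal-SNP effect variance per population.
#' @param confounder_var Per-population confounder variance (0 = absent).
#' @param drift_var Per-SNP ancestry-drift variance used by the
#'   individual-mode genotype generator (controls how strongly the leading
#'   genotype PC correlates with every SNP).
#' @param effect_dist Causal effect-size distribution: `"normal"` (default) or
#'   scaled t with `"t16"` / `"t4"` degrees of freedom (robustness checks).
#' @param n_reps Default replicate count for benchmark runs.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(p = 200, block_size = 20, rho = c(0.25, 0.95),
                            p_genome = 5000, genome_block_size = 25,
                            genome_rho = c(0, 0.4, 0.7, 0.9, 0.95),
                            genome_rho_factor = 0.6,
                            K_true = 3, n = c(20000, 20000),
                            h2_polygenic = 0.005, rg_polygenic = 0.8,
                            p_ref = 500, sigma2_causal = 0.25 / 500,
                            confounder_var = c(0, 0), drift_var = 2e-4,
                            effect_dist = c("normal", "t16", "t4"),
                            n_reps = 50) {
  effect_dist <- match.arg(effect_dist)
  stopifnot(p >= 1, all(abs(rho) < 1), all(n > 0), h2_polygenic >= 0,
            sigma2_causal >= 0, all(confounder_var >= 0),
            abs(rg_polygenic) <= 1)
  omega <- h2_polygenic / p_ref
  if (h2_polygenic + sigma2_causal * K_true + max(confounder_var) >= 1) {
    abort("heritability plus confounder variance must stay below 1",
          class = "xmapr_config_error")
  }
  structure(list(p = p, block_size = block_size, rho = rho,
                 p_genome = p_genome, genome_block_size = genome_block_size,
                 genome_rho = genome_rho, genome_rho_factor = genome_rho_factor,
                 K_true = K_true, n = n,
                 h2_polygenic = h2_polygenic, rg_polygenic = rg_polygenic,
                 p_ref = p_ref, omega = omega, sigma2_causal = sigma2_causal,
                 confounder_var = confounder_var, drift_var = drift_var,
                 effect_dist = effect_dist, n_reps = n_reps),
            class = "scenario_config")
}

#' Per-SNP polygenic covariance implied by a configuration
#'
#' @param cfg A `scenario_config`.
#' @return 2 x 2 matrix `omega * [[1, rg], [rg, 1]]`.
#' @export
omega_from_config <- function(cfg) {
  cfg$omega * matrix(c(1, cfg$rg_polygenic, cfg$rg_polygenic, 1), 2, 2)
}

ar1_block <- function(size, rho) {
  idx <- seq_len(size)
  rho^abs(outer(idx, idx, "-"))
}

#' Block-diagonal AR(1) LD matrices
#'
#' Builds a block-diagonal correlation matrix of AR(1) blocks
#' (`r_jl = rho^|j-l|` within a block), PSD by construction. A vector `rho`
#' yields one matrix per population over the same SNP ids.
#'
#' @param p SNP count.
#' @param block_size Block size (last block may be shorter).
#' @param rho AR(1) decay, scalar or one per population.
#' @param snp_id Optional SNP ids.
#' @return An `ld_matrix`, or a list of them when `rho` has length > 1.
#' @export
make_ld <- function(p, block_size = 20, rho = 0.9, snp_id = NULL) {
  stopifnot(all(abs(rho) < 1), p >= 1, block_size >= 1)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(p))
  build <- function(r) {
    R <- matrix(0, p, p)
    starts <- seq(1, p, by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1, p)
      R[s:e, s:e] <- ar1_block(e - s + 1, r)
    }
    ld_matrix(R, snp_id, repair = FALSE)
  }
  if (length(rho) == 1) build(rho) else lapply(rho, build)
}

#' Candidate causal SNPs under the leverage-of-diversity design
#'
#' Selects SNPs that are in strong LD (|r| > `high_r`) with at least
#' `min_high` other SNPs in population 2 but weakly correlated
#' (|r| > `low_r` with fewer than `max_low` SNPs) in population 1 -- loci
#' where combining populations is informative.
#'
#' @param lds List of two `ld_matrix` (population 1, population 2).
#' @param high_r,min_high Strong-LD rule for population 2.
#' @param low_r,max_low Weak-LD rule for population 1.
#' @return Integer vector of candidate SNP indices.
#' @export
candidate_causals <- function(lds, high_r = 0.9, min_high = 3,
                              low_r = 0.6, max_low = 2) {
  R1 <- abs(unclass(lds[[1]])); diag(R1) <- 0
  R2 <- abs(unclass(lds[[2]])); diag(R2) <- 0
  which(rowSums(R2 > high_r) >= min_high & rowSums(R1 > low_r) < max_low)
}

draw_effect <- function(n, var, dist) {
  if (var == 0 || n == 0) return(numeric(n))
  switch(dist,
         normal = rnorm(n, 0, sqrt(var)),
         t16 = stats::rt(n, 16) * sqrt(var * (16 - 2) / 16),
         t4 = stats::rt(n, 4) * sqrt(var * (4 - 2) / 4))
}

#' Draw the ground-truth genetic effects of one replicate
#'
#' Polygenic effects are bivariate normal with the per-SNP covariance implied
#' by the configuration; `K_true` causal SNPs are drawn from the
#' leverage-of-diversity candidates (or uniformly if none qualify) with
#' independent per-population effects of variance `sigma2_causal`.
#'
#' @param cfg A `scenario_config`.
#' @param lds Locus LD matrices (list of two), used for candidate selection.
#' @param seed Integer seed (replicate master seed).
#' @return A list of class `simulation_truth`: `causal_idx`, `beta`
#'   (K_true x 2), `phi` (p x 2), `confounder_var`.
#' @export
simulate_effects <- function(cfg, lds = NULL, seed = 1) {
  set.seed(derive_seed(seed, 1))
  Omega <- omega_from_config(cfg)
  Z <- matrix(rnorm(2 * cfg$p), cfg$p, 2)
  phi <- if (cfg$omega > 0) Z %*% chol(Omega) else Z * 0
  candidates <- if (!is.null(lds)) candidate_causals(lds) else integer(0)
  if (length(candidates) < cfg$K_true) candidates <- seq_len(cfg$p)
  if (cfg$K_true > length(candidates)) {
    abort("K_true exceeds the number of candidate causal SNPs",
          class = "xmapr_config_error")
  }
  causal_idx <- sort(sample(candidates, cfg$K_true))
  beta <- cbind(draw_effect(cfg$K_true, cfg$sigma2_causal, cfg$effect_dist),
                draw_effect(cfg$K_true, cfg$sigma2_causal, cfg$effect_dist))
  structure(list(causal_idx = causal_idx,
                 beta = matrix(beta, ncol = 2),
                 phi = phi, confounder_var = cfg$confounder_var),
            class = "simulation_truth")
}

sumstats_from_bz <- function(snp_id, bhat, n) {
  new_sumstats(tibble(snp_id = snp_id, allele_effect = "A", allele_other = "G",
                      bhat = bhat, se = 1 / sqrt(n), n = n))
}

#' Draw GWAS summary statistics for a locus
#'
#' Summary mode draws marginal effects directly from their sampling
#' distribution `bhat_t ~ N(R_t (b_t + phi_t), c_t S_t R_t S_t)` with
#' `s_tj = 1/sqrt(n_t)`; the confounder enters through the implied inflation
#' constant `c_t = 1 + n_t * confounder_var_t / M` (M = total SNPs the
#' confounder is spread over, `p_genome + p`), the drift-model form of
#' intercept inflation. Individual mode is provided by
#' [simulate_individual_replicate()], which builds genotypes and phenotypes
#' explicitly and runs per-SNP marginal regressions.
#'
#' @param truth A `simulation_truth`.
#' @param lds List of two locus `ld_matrix`.
#' @param cfg A `scenario_config`.
#' @param seed Replicate master seed.
#' @param chols Optional precomputed list of Cholesky factors of the LD
#'   matrices (upper triangular), to amortize across replicates.
#' @return List of two `xmap_sumstats`.
#' @export
simulate_sumstats <- function(truth, lds, cfg, seed = 1, chols = NULL) {
  p <- cfg$p
  b <- matrix(0, p, 2)
  if (length(truth$causal_idx) > 0) {
    b[truth$causal_idx, ] <- truth$beta
  }
  M_conf <- cfg$p_genome + cfg$p
  out <- vector("list", 2)
  for (t in 1:2) {
    set.seed(derive_seed(seed, 10 + t))
    R <- unclass(lds[[t]])
    ch <- if (!is.null(chols)) chols[[t]] else chol_psd(R)
    c_t <- 1 + cfg$n[t] * cfg$confounder_var[t] / M_conf
    mean_t <- R %*% (b[, t] + truth$phi[, t])
    eps <- sqrt(c_t / cfg$n[t]) * as.vector(crossprod(ch, rnorm(p)))
    out[[t]] <- sumstats_from_bz(snp_ids(lds[[t]]),
                                 as.vector(mean_t) + eps, cfg$n[t])
  }
  out
}

# Cholesky with a tiny ridge fallback for rank-deficient correlation matrices.
chol_psd <- function(R, ridge = 1e-8) {
  tryCatch(chol(R), error = function(e) chol(R + diag(ridge, nrow(R))))
}

genome_rhos <- function(cfg) {
  n_blocks <- ceiling(cfg$p_genome / cfg$genome_block_size)
  rep_len(cfg$genome_rho, n_blocks)
}

# Analytic per-SNP LD scores of the background genome (tiled AR(1) blocks).
genome_ld_scores <- function(cfg) {
  rhos2 <- genome_rhos(cfg)
  rhos1 <- rhos2 * cfg$genome_rho_factor
  gb <- cfg$genome_block_size
  ell1 <- ell2 <- ellx <- numeric(0)
  for (i in seq_along(rhos2)) {
    size <- min(gb, cfg$p_genome - (i - 1) * gb)
    B1 <- ar1_block(size, rhos1[i])
    B2 <- ar1_block(size, rhos2[i])
    ell1 <- c(ell1, rowSums(B1^2))
    ell2 <- c(ell2, rowSums(B2^2))
    ellx <- c(ellx, rowSums(B1 * B2))
  }
  ids <- paste0("bg", seq_len(cfg$p_genome))
  list(pop1 = tibble(snp_id = ids, ell = ell1, ell_cross = ellx),
       pop2 = tibble(snp_id = ids, ell = ell2, ell_cross = ellx))
}

#' Genome-wide summary statistics for the LD score regression step
#'
#' Draws per-SNP z-score pairs from their marginal moments under the polygenic
#' model: `Var(z_tj) = c_t + n_t * omega_t * ell_tj` and
#' `Cov(z_1j, z_2j) = sqrt(n_1 n_2) * omega_12 * ell_cross_j`, with analytic
#' LD scores from the background block structure. Inter-SNP correlation of the
#' z-scores is not emulated (it affects regression standard errors, which the
#' block jackknife absorbs, not the point estimates).
#'
#' @param cfg A `scenario_config`.
#' @param Omega Per-SNP polygenic covariance (defaults to the configured one).
#' @param c_vec Inflation constants (default from `confounder_var` as in
#'   [simulate_sumstats()]).
#' @param seed Replicate master seed.
#' @return List with `stats` (two `xmap_sumstats`) and `scores` (two LD score
#'   tibbles with `ell`, `ell_cross`).
#' @export
simulate_genome_stats <- function(cfg, Omega = omega_from_config(cfg),
                                  c_vec = NULL, seed = 1) {
  stopifnot(cfg$p_genome > 0)
  if (is.null(c_vec)) {
    c_vec <- 1 + cfg$n * cfg$confounder_var / (cfg$p_genome + cfg$p)
  }
  scores <- genome_ld_scores(cfg)
  set.seed(derive_seed(seed, 20))
  v1 <- c_vec[1] + cfg$n[1] * Omega[1, 1] * scores$pop1$ell
  v2 <- c_vec[2] + cfg$n[2] * Omega[2, 2] * scores$pop2$ell
  cv <- sqrt(cfg$n[1] * cfg$n[2]) * Omega[1, 2] * scores$pop1$ell_cross
  cv <- sign(cv) * pmin(abs(cv), 0.999 * sqrt(v1 * v2))
  p <- cfg$p_genome
  a <- sqrt(v1)
  bfac <- cv / a
  cfac <- sqrt(pmax(v2 - bfac^2, 1e-12))
  u1 <- rnorm(p); u2 <- rnorm(p)
  z1 <- a * u1
  z2 <- bfac * u1 + cfac * u2
  stats <- list(sumstats_from_bz(scores$pop1$snp_id, z1 / sqrt(cfg$n[1]), cfg$n[1]),
                sumstats_from_bz(scores$pop2$snp_id, z2 / sqrt(cfg$n[2]), cfg$n[2]))
  list(stats = stats, scores = list(scores$pop1, scores$pop2))
}

#' Simulate one complete scenario-1 replicate (summary mode)
#'
#' Locus LD per population, ground-truth effects, locus summary statistics,
#' and (when `p_genome > 0`) genome-wide statistics for the LDSC step.
#'
#' @param cfg A `scenario_config`.
#' @param seed Replicate master seed.
#' @param chols Optional precomputed LD Cholesky factors (see
#'   [simulate_sumstats()]).
#' @param lds Optional precomputed locus LD matrices.
#' @return List with `data` (an `xmap_data`), `truth`, `lds`, `genome`
#'   (or `NULL`), and `cfg`.
#' @export
simulate_locus <- function(cfg, seed = 1, lds = NULL, chols = NULL) {
  if (is.null(lds)) {
    lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  }
  truth <- simulate_effects(cfg, lds, seed)
  stats <- simulate_sumstats(truth, lds, cfg, seed, chols = chols)
  data <- xmap_data(stats, lds)
  genome <- if (cfg$p_genome > 0) simulate_genome_stats(cfg, seed = seed) else NULL
  list(data = data, truth = truth, lds = lds, genome = genome, cfg = cfg)
}

# --- individual mode -------------------------------------------------------

gen_block <- function(n, ch, delta_b, h, seed_b) {
  set.seed(seed_b)
  k <- ncol(ch)
  G <- matrix(rnorm(n * k), n, k) %*% ch
  if (!is.null(h)) {
    G <- (G + tcrossprod(h, delta_b)) / rep(sqrt(1 + delta_b^2), each = n)
  }
  G
}

# Leading principal component score of a centered genotype matrix via power
# iteration (sufficient when the ancestry axis dominates).
leading_pc <- function(G, iters = 40, seed = 1) {
  set.seed(seed)
  cm <- colMeans(G)
  v <- rnorm(ncol(G))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    u <- as.vector(G %*% v) - sum(cm * v)
    v <- as.vector(crossprod(G, u)) - cm * sum(u)
    v <- v / sqrt(sum(v^2))
  }
  score <- as.vector(G %*% v) - sum(cm * v)
  score - mean(score)
}

marginal_regression_block <- function(G, yc, n) {
  cm <- colMeans(G)
  cs2 <- colMeans(G^2) - cm^2
  sdx <- sqrt(pmax(cs2, 1e-12))
  covxy <- as.vector(crossprod(G, yc)) / n
  bhat <- covxy / sdx                      # effect per SD of genotype
  vary <- mean(yc^2)
  se <- sqrt(pmax(vary - bhat^2, 1e-12) / n)
  list(bhat = bhat, se = se)
}

#' Simulate one individual-mode replicate with an unadjusted confounder
#'
#' Builds standardized genotypes with an explicit two-subpopulation drift
#' structure for locus plus background SNPs, takes the leading principal
#' component of the background genotypes as the PC-like confounder, rescales
#' it to the configured variance, generates phenotypes
#' `y = PC + sum_k x_k beta_k + e` (scenario 2: no polygenic term), and runs
#' per-SNP marginal regressions without adjusting for the PC. The resulting
#' summary statistics carry intercept-type inflation, so LDSC intercepts
#' estimated from them exceed 1.
#'
#' @param cfg A `scenario_config` (use `confounder_var > 0`).
#' @param seed Replicate master seed.
#' @param include_polygenic Add the configured polygenic term to `y`
#'   (scenario 1 individual mode).
#' @param confounder `"axis"` (default) uses the ancestry axis of the
#'   simulated structure directly -- the population's leading principal
#'   component in expectation; `"sample_pc"` estimates the leading PC of the
#'   background genotypes by power iteration. At desk-scale SNP counts the
#'   sample PC is dominated by eigenvector sampling noise unless the drift
#'   variance is made unrealistically large, so the exact axis is the default.
#' @return List with `data` (locus `xmap_data`), `truth`, `genome`
#'   (genome-wide `stats` + `scores` for LDSC, locus SNPs excluded), `lds`.
#' @export
simulate_individual_replicate <- function(cfg, seed = 1,
                                          include_polygenic = FALSE,
                                          confounder = c("axis", "sample_pc")) {
  confounder <- match.arg(confounder)
  stopifnot(cfg$p_genome > 0)
  lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  truth <- simulate_effects(cfg, lds, seed)
  rhos2 <- genome_rhos(cfg)
  rhos1 <- rhos2 * cfg$genome_rho_factor
  gb <- cfg$genome_block_size
  scores <- genome_ld_scores(cfg)
  Omega <- omega_from_config(cfg)

  stats_locus <- vector("list", 2)
  stats_genome <- vector("list", 2)
  for (t in 1:2) {
    n_t <- cfg$n[t]
    # block plan: locus blocks first (their exact LD), then background blocks
    chols <- list()
    cols <- list()
    starts <- seq(1, cfg$p, by = cfg$block_size)
    for (st in starts) {
      e <- min(st + cfg$block_size - 1, cfg$p)
      chols[[length(chols) + 1]] <- chol_psd(unclass(lds[[t]])[st:e, st:e])
      cols[[length(cols) + 1]] <- st:e
    }
    n_locus_blocks <- length(chols)
    rhos <- if (t == 1) rhos1 else rhos2
    rem <- cfg$p_genome
    at <- cfg$p + 1
    for (i in seq_along(rhos)) {
      size <- min(gb, rem)
      chols[[length(chols) + 1]] <- chol(ar1_block(size, rhos[i]))
      cols[[length(cols) + 1]] <- at:(at + size - 1)
      at <- at + size
      rem <- rem - size
      if (rem <= 0) break
    }
    p_tot <- cfg$p + cfg$p_genome

    set.seed(derive_seed(seed, 60 + t))
    h <- NULL
    delta <- rep(0, p_tot)
    if (cfg$drift_var > 0) {
      h <- sample(c(-1, 1), n_t, replace = TRUE)
      delta <- rnorm(p_tot, 0, sqrt(cfg$drift_var))
    }
    block_seed <- function(b) derive_seed(seed, 1000 + t * 200 + b)

    # polygenic effects: locus SNPs from the truth draw, background SNPs
    # (same per-SNP covariance) drawn here
    phi_all <- matrix(0, p_tot, 2)
    if (include_polygenic) {
      phi_all[seq_len(cfg$p), ] <- truth$phi
      if (cfg$omega > 0) {
        set.seed(derive_seed(seed, 70))
        phi_all[(cfg$p + 1):p_tot, ] <-
          matrix(rnorm(2 * cfg$p_genome), cfg$p_genome, 2) %*% chol(Omega)
      }
    }

    # pass 1: accumulate the genetic signal in y block by block
    g_sig <- rep(0, n_t)
    for (b in seq_along(chols)) {
      cb <- cols[[b]]
      eff <- phi_all[cb, t]
      causal_here <- intersect(truth$causal_idx, cb)
      if (length(causal_here) > 0) {
        eff[match(causal_here, cb)] <- eff[match(causal_here, cb)] +
          truth$beta[match(causal_here, truth$causal_idx), t]
      }
      if (any(eff != 0)) {
        Gb <- gen_block(n_t, chols[[b]], delta[cb], h, block_seed(b))
        g_sig <- g_sig + as.vector(Gb %*% eff)
      }
    }

    conf <- rep(0, n_t)
    if (cfg$confounder_var[t] > 0) {
      if (is.null(h)) {
        abort("a confounder requires drift_var > 0 (ancestry structure)",
              class = "xmapr_config_error")
      }
      pc <- if (confounder == "sample_pc") {
        bg <- (n_locus_blocks + 1):length(chols)
        Gbg <- do.call(cbind, lapply(bg, function(b)
          gen_block(n_t, chols[[b]], delta[cols[[b]]], h, block_seed(b))))
        leading_pc(Gbg, seed = derive_seed(seed, 40 + t))
      } else {
        h - mean(h)
      }
      conf <- pc * sqrt(cfg$confounder_var[t] / stats::var(pc))
    }

    h2_used <- cfg$sigma2_causal * cfg$K_true +
      if (include_polygenic) cfg$h2_polygenic else 0
    resid_var <- 1 - h2_used - cfg$confounder_var[t]
    if (resid_var <= 0) {
      abort("heritability plus confounder variance >= 1",
            class = "xmapr_config_error")
    }
    set.seed(derive_seed(seed, 50 + t))
    y <- conf + g_sig + rnorm(n_t, 0, sqrt(resid_var))
    yc <- y - mean(y)

    # pass 2: per-SNP marginal regressions, regenerating each block
    bhat <- numeric(p_tot)
    se <- numeric(p_tot)
    for (b in seq_along(chols)) {
      cb <- cols[[b]]
      Gb <- gen_block(n_t, chols[[b]], delta[cb], h, block_seed(b))
      mr <- marginal_regression_block(Gb, yc, n_t)
      bhat[cb] <- mr$bhat
      se[cb] <- mr$se
    }
    locus_cols <- seq_len(cfg$p)
    bg_cols <- (cfg$p + 1):p_tot
    stats_locus[[t]] <- new_sumstats(tibble(
      snp_id = snp_ids(lds[[t]]), allele_effect = "A", allele_other = "G",
      bhat = bhat[locus_cols], se = se[locus_cols], n = n_t))
    stats_genome[[t]] <- new_sumstats(tibble(
      snp_id = scores$pop1$snp_id, allele_effect = "A", allele_other = "G",
      bhat = bhat[bg_cols], se = se[bg_cols], n = n_t))
  }
  list(data = xmap_data(stats_locus, lds), truth = truth,
       genome = list(stats = stats_genome,
                     scores = list(scores$pop1, scores$pop2)),
       lds = lds, cfg = cfg)
}

# --- evaluation metrics ----------------------------------------------------

#' Score fine-mapping output against the simulation truth
#'
#' Computes, per nominal FDR level, the empirical FDR
#' `1 - TP / selections` and power (recall of causal SNPs) of the global-FDR
#' selection; the partial AUC of the PIP-ranked ROC truncated at each FPR cap
#' (normalized by the cap); and credible-set size summaries when sets are
#' supplied.
#'
#' @param truth A `simulation_truth` (or integer vector of causal indices).
#' @param pip Length-p PIP vector (locus order).
#' @param fdr_levels Nominal global-FDR levels.
#' @param fpr_caps FPR truncation points for the partial AUC.
#' @param cs Optional credible-set tibble from [credible_sets()].
#' @return A tidy tibble with columns `metric`, `level`, `value`.
#' @export
evaluate_finemapping <- function(truth, pip, fdr_levels = c(0.05, 0.1, 0.2),
                                 fpr_caps = c(0.1, 0.2, 0.3), cs = NULL) {
  causal_idx <- if (inherits(truth, "simulation_truth")) truth$causal_idx else truth
  p <- length(pip)
  is_causal <- seq_len(p) %in% causal_idx
  rows <- list()
  for (xi in fdr_levels) {
    sel <- global_fdr_select(pip, xi = xi)$selected
    n_sel <- sum(sel)
    tp <- sum(sel & is_causal)
    fdr <- if (n_sel > 0) 1 - tp / n_sel else NA_real_
    pow <- if (length(causal_idx) > 0) tp / length(causal_idx) else NA_real_
    rows[[length(rows) + 1]] <- tibble(
      metric = c("fdr", "power", "n_selected"),
      level = xi, value = c(fdr, pow, n_sel))
  }
  for (cap in fpr_caps) {
    rows[[length(rows) + 1]] <- tibble(
      metric = "pauc", level = cap,
      value = partial_auc(pip, is_causal, cap))
  }
  if (!is.null(cs) && nrow(cs) > 0) {
    sizes <- cs %>% filter(.data$kept) %>% group_by(.data$component) %>%
      summarise(size = dplyr::n(), .groups = "drop")
    if (nrow(sizes) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        metric = c("cs_size_median", "cs_size_mean", "n_cs_kept"),
        level = NA_real_,
        value = c(stats::median(sizes$size), mean(sizes$size), nrow(sizes)))
    }
  }
  bind_rows(rows)
}

#' Partial area under the PIP-ranked ROC curve
#'
#' Trapezoid rule over the ROC of the PIP ranking (tied PIPs grouped),
#' truncated at `fpr_cap` with linear interpolation, normalized by the cap.
#'
#' @param score Ranking score (higher = more causal).
#' @param is_causal Logical truth vector.
#' @param fpr_cap FPR truncation in (0, 1].
#' @return Normalized partial AUC in [0, 1].
#' @export
partial_auc <- function(score, is_causal, fpr_cap = 0.1) {
  stopifnot(length(score) == length(is_causal), fpr_cap > 0, fpr_cap <= 1)
  n_pos <- sum(is_causal)
  n_neg <- sum(!is_causal)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) sum(is_causal & score >= s) / n_pos,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(s) sum(!is_causal & score >= s) / n_neg,
                     numeric(1)))
  area <- 0
  for (i in seq_len(length(thr))) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= fpr_cap) break
    if (x1 > fpr_cap) {
      frac <- (fpr_cap - x0) / (x1 - x0)
      y1 <- y0 + frac * (y1 - y0)
      x1 <- fpr_cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / fpr_cap
}
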