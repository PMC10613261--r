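test_that("AR(1) block LD matrices match their definition and stay PSD", {
  expect_equal(unclass(make_ld(5, 5, 0)), diag(5), ignore_attr = TRUE)
  R <- make_ld(6, 3, 0.9)
  expect_equal(R[1, 2], 0.9)
  expect_equal(R[1, 3], 0.81)
  expect_equal(R[1, 4], 0)  # across blocks
  for (rho in c(-0.7, 0.3, 0.95)) {
    ev <- eigen(unclass(make_ld(12, 4, rho)), symmetric = TRUE)$values
    expect_gt(min(ev), 0)
  }
  both <- make_ld(8, 4, c(0.2, 0.8))
  expect_length(both, 2)
  expect_equal(both[[1]][1, 2], 0.2)
  expect_equal(both[[2]][1, 2], 0.8)
})

test_that("candidate causal SNPs follow the leverage-of-diversity rule", {
  lds <- make_ld(40, 20, c(0.25, 0.95))
  cand <- candidate_causals(lds)
  expect_gt(length(cand), 0)
  R1 <- abs(unclass(lds[[1]])); diag(R1) <- 0
  R2 <- abs(unclass(lds[[2]])); diag(R2) <- 0
  for (j in cand) {
    expect_gte(sum(R2[j, ] > 0.9), 3)
    expect_lt(sum(R1[j, ] > 0.6), 2)
  }
})

test_that("effect draws match the configured covariances and are reproducible", {
  cfg <- scenario_config(p = 44728, p_genome = 0, K_true = 0)
  tr <- simulate_effects(cfg, seed = 31)
  expect_equal(nrow(tr$beta), 0)
  S <- cov(tr$phi)
  # per-SNP polygenic covariance [[1e-5, 8e-6], [8e-6, 1e-5]]; MC standard
  # error of a variance over 44728 draws is ~6.7e-8
  expect_lt(abs(S[1, 1] - 1e-5), 3e-7)
  expect_lt(abs(S[2, 2] - 1e-5), 3e-7)
  expect_lt(abs(S[1, 2] - 8e-6), 3e-7)

  cfg2 <- scenario_config(p = 100, p_genome = 0)
  t1 <- simulate_effects(cfg2, seed = 5)
  t2 <- simulate_effects(cfg2, seed = 5)
  expect_identical(t1, t2)
  expect_error(simulate_effects(scenario_config(p = 2, block_size = 2,
                                                p_genome = 0, K_true = 3),
                                seed = 1),
               class = "xmapr_config_error")
})

test_that("summary-mode draws have the model's first and second moments", {
  cfg <- scenario_config(p = 4, block_size = 4, rho = c(0.5, 0.5),
                         p_genome = 0, K_true = 1, n = c(5000, 5000),
                         h2_polygenic = 0)
  lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  truth <- simulate_effects(cfg, lds, seed = 2)
  draws <- sapply(1:4000, function(i) {
    simulate_sumstats(truth, lds, cfg, seed = i)[[1]]$bhat
  })
  b <- rep(0, 4); b[truth$causal_idx] <- truth$beta[, 1]
  mean_oracle <- as.vector(unclass(lds[[1]]) %*% b)
  cov_oracle <- unclass(lds[[1]]) / cfg$n[1]
  expect_lt(max(abs(rowMeans(draws) - mean_oracle)), 5 * sqrt(1 / 5000 / 4000))
  # MC standard error of a covariance entry is ~ V * sqrt(2/m) = 4.5e-6
  expect_lt(max(abs(cov(t(draws)) - cov_oracle)), 2e-5)
})

test_that("null summary statistics are calibrated z-scores", {
  cfg <- scenario_config(K_true = 0, h2_polygenic = 0, p_genome = 0)
  lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  truth <- simulate_effects(cfg, lds, seed = 3)
  # LD correlates z-scores within blocks, so moments are averaged over draws
  vs <- ms <- numeric(16)
  for (s in 1:16) {
    ss <- simulate_sumstats(truth, lds, cfg, seed = s)
    z <- c(ss[[1]]$z, ss[[2]]$z)
    ms[s] <- mean(z); vs[s] <- var(z)
  }
  # the strong-LD population contributes var ~ 13/200 to each per-replicate
  # mean, so the grand mean over 16 draws has SE ~ 0.034; bound at ~4 SE
  expect_lt(abs(mean(ms)), 0.15)
  expect_lt(abs(mean(vs) - 1), 0.2)
})

test_that("summary and individual modes agree in distribution on the locus", {
  cfg <- scenario_config(p = 40, block_size = 20, rho = c(0.25, 0.95),
                         p_genome = 60, K_true = 1, n = c(2000, 2000),
                         drift_var = 0)
  lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  n_reps <- 60
  chi2 <- matrix(0, n_reps, 2)  # mean locus chi-square per mode
  for (i in seq_len(n_reps)) {
    tr <- simulate_effects(cfg, lds, seed = 200 + i)
    ss <- simulate_sumstats(tr, lds, cfg, seed = 200 + i)
    ind <- simulate_individual_replicate(cfg, seed = 200 + i,
                                         include_polygenic = TRUE)
    chi2[i, 1] <- mean(c(ss[[1]]$z^2, ss[[2]]$z^2))
    chi2[i, 2] <- mean(c(ind$data$stats[[1]]$z^2, ind$data$stats[[2]]$z^2))
  }
  m <- colMeans(chi2)
  se <- apply(chi2, 2, sd) / sqrt(n_reps)
  expect_lt(abs(m[1] - m[2]), 3 * sqrt(sum(se^2)))
})

test_that("unadjusted confounding inflates estimated LDSC intercepts above one", {
  cfg <- scenario_config(K_true = 1, n = c(8000, 8000), p_genome = 1200,
                         confounder_var = c(0.05, 0.2), h2_polygenic = 0,
                         drift_var = 1e-3)
  cs <- sapply(1:3, function(s) {
    rep2 <- simulate_individual_replicate(cfg, seed = s)
    pp <- estimate_polygenic_params(rep2$genome$stats, rep2$genome$scores,
                                    clamp_c = FALSE)
    pp$c
  })
  expect_gt(mean(cs[1, ]), 1)       # confounder variance 0.05
  expect_gt(mean(cs[2, ]), 1.2)     # confounder variance 0.2: stronger
  expect_gt(mean(cs[2, ]), mean(cs[1, ]))
})

test_that("evaluation metrics match their definitions and a threshold-sweep oracle", {
  truth <- structure(list(causal_idx = c(2, 5)), class = "simulation_truth")
  # perfect selection: causal SNPs at pip 1, rest 0
  pip <- c(0, 1, 0, 0, 1, 0)
  m <- evaluate_finemapping(truth, pip, fdr_levels = 0.1, fpr_caps = 0.5)
  expect_equal(m$value[m$metric == "fdr"], 0)
  expect_equal(m$value[m$metric == "power"], 1)
  expect_equal(m$value[m$metric == "pauc"], 1)

  # 1 true among 2 selected -> empirical FDR 0.5
  m2 <- evaluate_finemapping(structure(list(causal_idx = 1),
                                       class = "simulation_truth"),
                             c(1, 1, 0, 0), fdr_levels = 0.3)
  expect_equal(m2$value[m2$metric == "fdr"], 0.5)

  # no causal SNPs: power undefined
  m3 <- evaluate_finemapping(integer(0), c(0.5, 0.1), fdr_levels = 0.5)
  expect_true(is.na(m3$value[m3$metric == "power"]))

  # pAUC vs exhaustive threshold sweep (with ties)
  set.seed(33)
  for (i in 1:10) {
    pip <- round(runif(40), 2)
    is_causal <- seq_along(pip) %in% sample(40, 5)
    for (cap in c(0.1, 0.25, 1)) {
      got <- partial_auc(pip, is_causal, cap)
      thr <- sort(unique(pip), decreasing = TRUE)
      pts <- cbind(0, 0)
      for (s in thr) {
        pts <- rbind(pts, c(sum(!is_causal & pip >= s) / sum(!is_causal),
                            sum(is_causal & pip >= s) / sum(is_causal)))
      }
      area <- 0
      for (r in 2:nrow(pts)) {
        x0 <- pts[r - 1, 1]; x1 <- pts[r, 1]
        y0 <- pts[r - 1, 2]; y1 <- pts[r, 2]
        if (x0 >= cap) break
        if (x1 > cap) {
          y1 <- y0 + (cap - x0) / (x1 - x0) * (y1 - y0)
          x1 <- cap
        }
        area <- area + (x1 - x0) * (y0 + y1) / 2
      }
      expect_equal(got, area / cap, tolerance = 1e-10)
    }
  }
})
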