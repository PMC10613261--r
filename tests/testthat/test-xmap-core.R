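test_that("single-SNP and symmetric-null E-steps behave as forced by the model", {
  # p = 1: softmax over one element
  d1 <- toy_data(matrix(0.01, 1, 2), matrix(0.01, 1, 2), diag(1), diag(1))
  mc <- make_consts(d1, polygenic_params(0, 0))
  st <- xmapr:::new_state(1, 2, 1)
  st <- xmapr:::estep_update_component(1, st, mc$consts, diag(1e-3, 2),
                                       matrix(0, 1, 2), mc$arr)
  expect_equal(st$pi[1, 1], 1)

  # all-zero evidence, equal se, identity LD: uniform posterior
  p <- 6
  d0 <- toy_data(matrix(0, p, 2), matrix(0.01, p, 2), diag(p), diag(p))
  mc0 <- make_consts(d0, polygenic_params(0, 0))
  st0 <- xmapr:::new_state(p, 2, 1)
  st0 <- xmapr:::estep_update_component(1, st0, mc0$consts, diag(1e-3, 2),
                                        matrix(0, p, 2), mc0$arr)
  expect_equal(st0$pi[1, ], rep(1 / p, p), tolerance = 1e-12)
})

test_that("K = 1 without polygenic effects reproduces the exact enumeration posterior", {
  set.seed(8)
  for (p in c(3, 6, 10)) {
    n <- 8000
    R1 <- random_corr(p); R2 <- random_corr(p)
    bhat <- matrix(rnorm(2 * p, 0, 0.02), p, 2)
    se <- matrix(1 / sqrt(n), p, 2)
    data <- toy_data(bhat, se, R1, R2, n = n)
    fit <- suppressWarnings(fit_xmap(data, K = 1,
                                     params = polygenic_params(0, 0),
                                     tol = 1e-10, max_iter = 500))
    arr <- xmapr:::data_arrays(data)
    oracle <- enumeration_k1(arr$bhat, arr$se, arr$R, fit$Sigma[[1]])
    expect_lt(max(abs(fit$pi[1, ] - oracle$post)), 1e-6)
    # ELBO equals the enumeration log evidence up to the dropped constant
    elbo <- utils::tail(fit$elbo_trace, 1)
    expect_equal(elbo, oracle$log_evidence - oracle$log_const,
                 tolerance = 1e-6)
  }
})

test_that("polygenic posterior matches closed forms and the dense inverse", {
  # disabled polygenic: nu = 0 exactly
  d <- toy_data(matrix(0.01, 3, 2), matrix(0.01, 3, 2), diag(3), diag(3))
  f <- suppressWarnings(fit_xmap(d, K = 1, params = polygenic_params(0, 0),
                                 max_iter = 5, tol = 1e-8))
  expect_equal(f$nu, matrix(0, 3, 2))

  # p = 1, R = [1], c = 1, diagonal Omega: scalar ridge per population
  n <- 10000
  om <- c(2e-4, 5e-4)
  d1 <- toy_data(matrix(c(0.03, -0.02), 1, 2), matrix(1 / sqrt(n), 1, 2),
                 diag(1), diag(1), n = n)
  pp <- polygenic_params(om[1], om[2], 0)
  mc <- make_consts(d1, pp)
  st <- xmapr:::update_polygenic(xmapr:::new_state(1, 2, 1), mc$consts,
                                 matrix(0, 1, 2))
  for (t in 1:2) {
    lam <- 1 / (n + 1 / om[t])
    expect_equal(st$nu[1, t], lam * n * mc$arr$bhat[1, t], tolerance = 1e-12)
  }

  # p = 5 random instance: nu matches a direct dense 10x10 inversion
  set.seed(9)
  p <- 5
  d5 <- toy_data(matrix(rnorm(2 * p, 0, 0.02), p, 2),
                 matrix(1 / sqrt(n) * exp(rnorm(2 * p, 0, 0.1)), p, 2),
                 random_corr(p), random_corr(p), n = n)
  pp5 <- polygenic_params(3e-5, 2e-5, 1e-5, c1 = 1.1, c2 = 1.3,
                          clamp_c = FALSE)
  mc5 <- make_consts(d5, pp5)
  Eb <- matrix(rnorm(2 * p, 0, 0.01), p, 2)
  st5 <- xmapr:::update_polygenic(xmapr:::new_state(p, 2, 1), mc5$consts, Eb)
  # oracle: build the 2p x 2p system explicitly and solve
  Oinv <- solve(pp5$Omega)
  Prec <- rbind(cbind(mc5$consts$M[[1]] + diag(Oinv[1, 1], p),
                      diag(Oinv[1, 2], p)),
                cbind(diag(Oinv[2, 1], p),
                      mc5$consts$M[[2]] + diag(Oinv[2, 2], p)))
  rhs <- c(mc5$consts$u[, 1] - mc5$consts$M[[1]] %*% Eb[, 1],
           mc5$consts$u[, 2] - mc5$consts$M[[2]] %*% Eb[, 2])
  nu_oracle <- solve(Prec, rhs)
  expect_lt(max(abs(c(st5$nu) - nu_oracle)), 1e-8)
  expect_equal(mc5$consts$solver$logdet_Lambda,
               -determinant(Prec, logarithm = TRUE)$modulus[1],
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("a zero-variance population drops out of the polygenic component exactly", {
  set.seed(19)
  p <- 4; n <- 10000
  d <- toy_data(matrix(rnorm(2 * p, 0, 0.02), p, 2),
                matrix(1 / sqrt(n), p, 2), random_corr(p), random_corr(p),
                n = n)
  pp <- polygenic_params(0, 3e-4, 0)
  mc <- make_consts(d, pp)
  st <- xmapr:::update_polygenic(xmapr:::new_state(p, 2, 1), mc$consts,
                                 matrix(0, p, 2))
  expect_equal(st$nu[, 1], rep(0, p))
  # population 2 matches its own single-population ridge
  M2 <- mc$consts$M[[2]]
  nu2_oracle <- solve(M2 + diag(1 / 3e-4, p), mc$consts$u[, 2])
  expect_lt(max(abs(st$nu[, 2] - nu2_oracle)), 1e-8)
})

test_that("M-step returns the posterior-weighted second moment", {
  # degenerate weights: all mass on one SNP
  st <- xmapr:::new_state(3, 2, 1)
  st$pi[1, ] <- c(1, 0, 0)
  m <- c(0.02, -0.01)
  V <- matrix(c(4e-4, 1e-4, 1e-4, 3e-4), 2, 2)
  st$mu[1, 1, ] <- m
  st$St[1, 1, , ] <- V
  expect_equal(xmapr:::mstep_sigma(st)[[1]], tcrossprod(m) + V)

  # zero means, identical conditional covariance: Sigma_k = V
  st2 <- xmapr:::new_state(4, 2, 1)
  for (j in 1:4) st2$St[1, j, , ] <- V
  expect_equal(xmapr:::mstep_sigma(st2)[[1]], V)

  # random state vs naive loop oracle
  set.seed(10)
  K <- 2; p <- 10
  st3 <- xmapr:::new_state(p, 2, K)
  for (k in 1:K) {
    w <- runif(p); st3$pi[k, ] <- w / sum(w)
    st3$mu[k, , ] <- matrix(rnorm(2 * p, 0, 0.02), p, 2)
    for (j in 1:p) {
      A <- matrix(rnorm(4, 0, 0.01), 2, 2)
      st3$St[k, j, , ] <- crossprod(A) + diag(1e-5, 2)
    }
  }
  out <- xmapr:::mstep_sigma(st3)
  for (k in 1:K) {
    oracle <- matrix(0, 2, 2)
    for (j in 1:p) {
      oracle <- oracle + st3$pi[k, j] *
        (tcrossprod(st3$mu[k, j, ]) + matrix(st3$St[k, j, , ], 2, 2))
    }
    expect_lt(max(abs(out[[k]] - oracle)), 1e-12)
    expect_gte(min(eigen(out[[k]], symmetric = TRUE)$values), 0)
  }
})

test_that("the ELBO is monotone over full VEM sweeps on random instances", {
  set.seed(12)
  worst <- 0
  for (i in 1:100) {
    p <- sample(5:15, 1)
    K <- sample(1:3, 1)
    n <- 5000
    data <- toy_data(matrix(rnorm(2 * p, 0, 0.03), p, 2),
                     matrix(1 / sqrt(n) * exp(rnorm(2 * p, 0, 0.1)), p, 2),
                     random_corr(p), random_corr(p), n = n)
    pp <- if (i %% 3 == 0) polygenic_params(0, 0) else
      polygenic_params(10^runif(1, -5.5, -3.5), 10^runif(1, -5.5, -3.5),
                       0, clamp_c = FALSE)
    fit <- suppressWarnings(fit_xmap(data, K = K, params = pp,
                                     tol = 1e-9, max_iter = 25))
    worst <- min(worst, min(diff(fit$elbo_trace)))
    expect_true(all(diff(fit$elbo_trace) > -1e-6))
    expect_equal(rowSums(fit$pi), rep(1, K), tolerance = 1e-8)
    expect_true(all(fit$pip$pip >= 0 & fit$pip$pip <= 1))
    for (S in fit$Sigma) {
      expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-15)
    }
  }
  expect_gt(worst, -1e-6)
})

test_that("the ELBO gradient in Sigma_k matches finite differences at an E-step fixed point", {
  set.seed(13)
  p <- 8; n <- 5000
  data <- toy_data(matrix(rnorm(2 * p, 0, 0.03), p, 2),
                   matrix(1 / sqrt(n), p, 2),
                   random_corr(p), random_corr(p), n = n)
  pp <- polygenic_params(0, 0)
  mc <- make_consts(data, pp)
  Sigma <- list(matrix(c(6e-4, 2e-4, 2e-4, 5e-4), 2, 2))
  state <- xmapr:::new_state(p, 2, 1)
  for (it in 1:60) state <- vem_sweep(state, mc$consts, Sigma, mc$arr)

  # analytic gradient: dL/dSigma = 0.5 * (Si %*% W %*% Si - Si), W the
  # pi-weighted second moment (the M-step statistic)
  W <- xmapr:::mstep_sigma(state)[[1]]
  Si <- solve(Sigma[[1]])
  grad <- 0.5 * (Si %*% W %*% Si - Si)
  eps <- 1e-8
  for (idx in list(c(1, 1), c(2, 2), c(1, 2))) {
    dS <- matrix(0, 2, 2)
    dS[idx[1], idx[2]] <- eps
    dS[idx[2], idx[1]] <- eps  # symmetric perturbation
    up <- xmapr:::compute_elbo(state, mc$consts, list(Sigma[[1]] + dS), pp)
    dn <- xmapr:::compute_elbo(state, mc$consts, list(Sigma[[1]] - dS), pp)
    fd <- (up - dn) / (2 * eps)
    an <- sum(grad * (dS / eps))
    expect_equal(fd, an, tolerance = 1e-4)
  }
})

test_that("permuting SNP order permutes the PIPs identically", {
  set.seed(14)
  p <- 20; n <- 10000
  R1 <- random_corr(p); R2 <- random_corr(p)
  bhat <- matrix(rnorm(2 * p, 0, 0.02), p, 2)
  bhat[7, ] <- c(0.06, 0.05)
  se <- matrix(1 / sqrt(n), p, 2)
  data <- toy_data(bhat, se, R1, R2, n = n)
  pp <- polygenic_params(1e-5, 1e-5, 5e-6)
  f1 <- suppressWarnings(fit_xmap(data, K = 2, params = pp, tol = 1e-8,
                                  max_iter = 80))
  perm <- sample(p)
  data_p <- toy_data(bhat[perm, ], se[perm, ], R1[perm, perm], R2[perm, perm],
                     n = n, snp_id = paste0("snp", perm))
  f2 <- suppressWarnings(fit_xmap(data_p, K = 2, params = pp, tol = 1e-8,
                                  max_iter = 80))
  expect_lt(max(abs(f2$pip$pip - f1$pip$pip[perm])), 1e-6)
})

test_that("null data give uniform posteriors and no surviving credible sets", {
  cfg <- scenario_config(p = 60, p_genome = 0, K_true = 0)
  lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  stats <- lapply(1:2, function(t) new_sumstats(tibble::tibble(
    snp_id = snp_ids(lds[[t]]), allele_effect = "A", allele_other = "G",
    bhat = 0, se = 1 / sqrt(2e4), n = 2e4)))
  data <- xmap_data(stats, lds)
  fit <- suppressWarnings(fit_xmap(data, K = 3, params = polygenic_params(0, 0),
                                   max_iter = 50))
  expect_equal(fit$pi, matrix(1 / 60, 3, 60), tolerance = 1e-9,
               ignore_attr = TRUE)
  cs <- credible_sets(fit)
  expect_false(any(cs$kept))
})

test_that("a strong single causal signal is ranked first under matched conditions", {
  cfg <- scenario_config(K_true = 1, h2_polygenic = 0)
  lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
  chols <- lapply(lds, function(R) xmapr:::chol_psd(unclass(R)))
  res <- t(vapply(1:40, function(s) {
    sim <- simulate_locus(cfg, seed = s, lds = lds, chols = chols)
    ci <- sim$truth$causal_idx
    f <- suppressWarnings(fit_xmap(sim$data, K = 5,
                                   params = polygenic_params(0, 0),
                                   tol = 1e-3, max_iter = 150))
    zz <- sim$data$stats[[1]]$z[ci]^2 + sim$data$stats[[2]]$z[ci]^2
    c(top = as.numeric(which.max(f$pip$pip) == ci),
      rank = rank(-f$pip$pip, ties.method = "min")[ci], zz = zz)
  }, numeric(3)))
  informative <- res[, "zz"] >= 20
  expect_gte(sum(informative), 5)
  expect_gte(mean(res[informative, "top"]), 0.8)
  expect_gte(mean(res[informative, "rank"] <= 3), 0.9)
})

test_that("fitted models expose tidy, glance and plotting interfaces", {
  cfg <- scenario_config(p = 40, p_genome = 0, K_true = 1)
  sim <- simulate_locus(cfg, seed = 4)
  fit <- suppressWarnings(fit_xmap(sim$data, K = 2,
                                   params = polygenic_params(1e-5, 1e-5, 8e-6),
                                   max_iter = 60))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  expect_true(all(c("snp_id", "pip", "local_fdr") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_elbo(fit), "ggplot")
})
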