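# Shared simulation batches, computed once per test run and reused by the
# acceptance tests (FDR calibration, credible-set resolution, parameter
# recovery, confounding correction).

.batch_cache <- new.env(parent = emptyenv())

memoize_batch <- function(name, fn) {
  if (!exists(name, envir = .batch_cache)) {
    assign(name, fn(), envir = .batch_cache)
  }
  get(name, envir = .batch_cache)
}

# scenario 1, defaults (K_true = 3), two-step pipeline with LDSC, K = 5
scenario1_batch <- function(n_reps = 50, base_seed = 0) {
  memoize_batch(paste0("s1_", n_reps, "_", base_seed), function() {
    cfg <- scenario_config()
    lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
    chols <- lapply(lds, function(R) xmapr:::chol_psd(unclass(R)))
    lapply(seq_len(n_reps), function(i) {
      s <- base_seed * 1000 + i
      sim <- simulate_locus(cfg, seed = s, lds = lds, chols = chols)
      pp <- estimate_polygenic_params(sim$genome$stats, sim$genome$scores)
      fit <- suppressWarnings(
        fit_xmap(sim$data, K = 5, params = pp, tol = 1e-3, max_iter = 150))
      list(truth = sim$truth, fit = fit,
           sel = select_snps(fit, xi = 0.1),
           cs = credible_sets(fit, alpha = 0.95, purity_threshold = 0.1))
    })
  })
}

# scenario 1 with a single causal SNP (parameter-recovery batch)
scenario1_k1_batch <- function(n_reps = 30, base_seed = 7) {
  memoize_batch(paste0("s1k1_", n_reps, "_", base_seed), function() {
    cfg <- scenario_config(K_true = 1)
    lds <- make_ld(cfg$p, cfg$block_size, cfg$rho)
    chols <- lapply(lds, function(R) xmapr:::chol_psd(unclass(R)))
    lapply(seq_len(n_reps), function(i) {
      s <- base_seed * 1000 + i
      sim <- simulate_locus(cfg, seed = s, lds = lds, chols = chols)
      pp <- estimate_polygenic_params(sim$genome$stats, sim$genome$scores)
      f5 <- suppressWarnings(
        fit_xmap(sim$data, K = 5, params = pp, tol = 1e-3, max_iter = 150))
      f10 <- suppressWarnings(
        fit_xmap(sim$data, K = 10, params = pp, tol = 1e-3, max_iter = 150))
      list(truth = sim$truth, f5 = f5, f10 = f10)
    })
  })
}

# scenario 2: individual mode with an unadjusted confounder; each replicate
# is fitted twice (LDSC-estimated intercepts vs intercepts forced to 1)
scenario2_batch <- function(n_reps = 10, base_seed = 3) {
  memoize_batch(paste0("s2_", n_reps, "_", base_seed), function() {
    cfg <- scenario_config(K_true = 1, n = c(20000, 20000), p_genome = 3000,
                           confounder_var = c(0.05, 0.2), h2_polygenic = 0)
    lapply(seq_len(n_reps), function(i) {
      s <- base_seed * 1000 + i
      rep2 <- simulate_individual_replicate(cfg, seed = s)
      raw <- estimate_polygenic_params(rep2$genome$stats, rep2$genome$scores,
                                       clamp_c = FALSE)
      mk <- function(c1, c2) polygenic_params(
        raw$Omega[1, 1], raw$Omega[2, 2], raw$Omega[1, 2], c1, c2)
      f_hat <- suppressWarnings(fit_xmap(rep2$data, K = 5,
                                         params = mk(raw$c[1], raw$c[2]),
                                         tol = 1e-3, max_iter = 150))
      f_one <- suppressWarnings(fit_xmap(rep2$data, K = 5, params = mk(1, 1),
                                         tol = 1e-3, max_iter = 150))
      list(truth = rep2$truth, c_raw = raw$c,
           sel_hat = select_snps(f_hat, xi = 0.1),
           sel_one = select_snps(f_one, xi = 0.1))
    })
  })
}

# aggregate empirical FDR over replicates (0/0 counts as no false discoveries)
aggregate_fdr <- function(batch, sel_field = "sel") {
  tp <- 0; n_sel <- 0
  for (r in batch) {
    sel <- which(r[[sel_field]]$selected)
    tp <- tp + sum(sel %in% r$truth$causal_idx)
    n_sel <- n_sel + length(sel)
  }
  list(fdr = if (n_sel > 0) 1 - tp / n_sel else 0, tp = tp, n_sel = n_sel)
}
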