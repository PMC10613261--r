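# Independent oracles used across tests. These deliberately avoid the
# package's own linear-algebra shortcuts: dense determinants/solves and
# explicit enumeration only.

# log density of N(0, V) at x
ldmvn0 <- function(x, V) {
  ch <- chol(V)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, x, transpose = TRUE)^2))
}

# Exact single-effect (K = 1, no polygenic) posterior over causal
# configurations by enumeration under the generative summary-statistic model
# bhat_t ~ N(R_t e_j beta_t, c_t S_t R_t S_t), (beta_1, beta_2) ~ N(0, Sigma).
# Requires a constant standard error per population (then the exact model and
# the working likelihood coincide for any R).
enumeration_k1 <- function(bhat, se, R, Sigma, c_vec = c(1, 1)) {
  p <- nrow(bhat)
  V <- lapply(1:2, function(t) c_vec[t] * R[[t]] * tcrossprod(se[, t]))
  bb <- c(bhat[, 1], bhat[, 2])
  logp <- vapply(seq_len(p), function(j) {
    c1 <- R[[1]][, j]; c2 <- R[[2]][, j]
    Vbig <- rbind(
      cbind(V[[1]] + Sigma[1, 1] * tcrossprod(c1),
            Sigma[1, 2] * tcrossprod(c1, c2)),
      cbind(Sigma[1, 2] * tcrossprod(c2, c1),
            V[[2]] + Sigma[2, 2] * tcrossprod(c2)))
    ldmvn0(bb, Vbig) + log(1 / p)
  }, numeric(1))
  m <- max(logp)
  list(post = exp(logp - m) / sum(exp(logp - m)),
       log_evidence = m + log(sum(exp(logp - m))),
       # constant dropped by the package ELBO: the null-model log density
       log_const = ldmvn0(bb[1:p], V[[1]]) + ldmvn0(bb[-(1:p)], V[[2]]))
}

# build a toy two-population dataset from raw numbers
toy_data <- function(bhat, se, R1, R2, n = 10000, snp_id = NULL) {
  p <- nrow(bhat)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(p))
  stats <- lapply(1:2, function(t) new_sumstats(tibble::tibble(
    snp_id = snp_id, allele_effect = "A", allele_other = "G",
    bhat = bhat[, t], se = se[, t], n = n)))
  xmap_data(stats, list(ld_matrix(R1, snp_id), ld_matrix(R2, snp_id)))
}

# random PSD correlation matrix
random_corr <- function(p, df = p + 2) {
  A <- matrix(rnorm(p * df), df, p)
  R <- stats::cov2cor(crossprod(A) / df)
  (R + t(R)) / 2
}

# run one full VEM sweep via package internals (for property tests)
vem_sweep <- function(state, consts, Sigma, arr, active = NULL) {
  K <- length(Sigma)
  if (is.null(active)) active <- rep(TRUE, K)
  Eb <- lapply(seq_len(K), function(k) xmapr:::component_mean(state, k))
  Ebt <- Reduce(`+`, Eb)
  for (k in which(active)) {
    state <- xmapr:::estep_update_component(k, state, consts, Sigma[[k]],
                                            Ebt - Eb[[k]] + state$nu, arr)
    Ebn <- xmapr:::component_mean(state, k)
    Ebt <- Ebt - Eb[[k]] + Ebn
    Eb[[k]] <- Ebn
  }
  state <- xmapr:::update_polygenic(state, consts, Ebt)
  state
}

make_consts <- function(data, params) {
  arr <- xmapr:::data_arrays(data)
  consts <- xmapr:::fit_constants(arr, params)
  consts$c <- params$c
  consts$solver <- xmapr:::make_polygenic_solver(arr, consts, params)
  list(arr = arr, consts = consts)
}
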