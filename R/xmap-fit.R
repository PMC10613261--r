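# Core variational EM for the cross-population sum-of-single-effects model
# with a dense polygenic component.
#
# Data model (summary level, T populations): for population t,
#   bhat_t ~ N( R_t (sum_k gamma_k beta_tk + phi_t), c_t S_t R_t S_t ),
# with gamma_k a single-causal-SNP indicator shared across populations,
# (beta_1k, beta_2k) ~ N(0, Sigma_k), per-SNP polygenic effects
# (phi_1j, phi_2j) ~ N(0, Omega). Omega and c are fixed (step 1, LDSC);
# the VEM updates only Sigma_1..Sigma_K.

# Extract aligned numeric arrays from an xmap_data object.
data_arrays <- function(data) {
  T_ <- data$n_pop
  p <- length(data$snp_id)
  bhat <- vapply(data$stats, function(s) s$bhat, numeric(p))
  se <- vapply(data$stats, function(s) s$se, numeric(p))
  n <- vapply(data$stats, function(s) stats::median(s$n), numeric(1))
  list(p = p, T = T_, bhat = matrix(bhat, p, T_), se = matrix(se, p, T_),
       n = n, R = lapply(data$ld, unclass))
}

# Per-fit constants: u[j,t] = bhat/(c s^2) (working-likelihood linear term),
# d[j,t] = r_jj/(c s^2) (its curvature diagonal), M_t = S^-1 R_t S^-1 / c_t.
fit_constants <- function(arr, params) {
  cc <- params$c
  u <- sweep(arr$bhat / arr$se^2, 2, cc, "/")
  d <- matrix(0, arr$p, arr$T)
  M <- vector("list", arr$T)
  for (t in seq_len(arr$T)) {
    d[, t] <- diag(arr$R[[t]]) / (cc[t] * arr$se[, t]^2)
    M[[t]] <- arr$R[[t]] / (cc[t] * tcrossprod(arr$se[, t]))
  }
  list(u = u, d = d, M = M)
}

inv_2x2 <- function(A, ridge = 1e-10) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    out <- solve(A + diag(ridge, nrow(A)))
  }
  out
}

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

new_state <- function(p, T_, K) {
  list(pi = matrix(1 / p, K, p),
       mu = array(0, c(K, p, T_)),
       St = array(0, c(K, p, T_, T_)),
       nu = matrix(0, p, T_),
       logdet_Lambda = 0)
}

# Expected single-effect vector for component k: E[gamma_k beta_tk] per SNP,
# the posterior mean pi~_kj * mu~_kj,t (p x T).
component_mean <- function(state, k) {
  state$pi[k, ] * matrix(state$mu[k, , ], ncol = dim(state$mu)[3])
}

#' Update one causal component's variational posterior
#'
#' Coordinate-ascent update of the categorical posterior `pi~_k`, conditional
#' effect means `mu~_kj` and covariances `Sigma~_kj` for component `k`, holding
#' the other components and the polygenic posterior fixed. The evidence for
#' SNP j is the LD-residualized marginal effect after removing the expected
#' effects of all components k' != k and the polygenic mean.
#'
#' @param k Component index.
#' @param state Variational state (see [fit_xmap()] internals).
#' @param consts Precomputed constants from the fit.
#' @param Sigma_k Current 2 x 2 (T x T) prior covariance of the component.
#' @param resid_theta p x T matrix of expected effects of the other components
#'   plus the polygenic mean.
#' @param arr Numeric data arrays.
#' @return The state with row k updated.
#' @keywords internal
estep_update_component <- function(k, state, consts, Sigma_k, resid_theta, arr) {
  T_ <- arr$T
  P <- inv_2x2(Sigma_k)
  w <- matrix(0, arr$p, T_)
  for (t in seq_len(T_)) {
    # residualized evidence under the working likelihood: u - M theta, with
    # M = S^-1 R S^-1 / c (symmetric; for constant per-population standard
    # errors this is the same as dividing the LD row by c * s_j^2)
    w[, t] <- consts$u[, t] - consts$M[[t]] %*% resid_theta[, t]
  }
  if (T_ == 2) {
    B11 <- consts$d[, 1] + P[1, 1]
    B22 <- consts$d[, 2] + P[2, 2]
    B12 <- P[1, 2]
    det <- B11 * B22 - B12^2
    S11 <- B22 / det; S22 <- B11 / det; S12 <- -B12 / det
    mu1 <- S11 * w[, 1] + S12 * w[, 2]
    mu2 <- S12 * w[, 1] + S22 * w[, 2]
    quad <- w[, 1] * mu1 + w[, 2] * mu2
    logits <- -0.5 * log(det) + 0.5 * quad
    state$pi[k, ] <- softmax(logits)
    state$mu[k, , 1] <- mu1; state$mu[k, , 2] <- mu2
    state$St[k, , 1, 1] <- S11; state$St[k, , 2, 2] <- S22
    state$St[k, , 1, 2] <- S12; state$St[k, , 2, 1] <- S12
  } else {
    logits <- numeric(arr$p)
    for (j in seq_len(arr$p)) {
      Sj <- inv_2x2(diag(consts$d[j, ], T_) + P)
      muj <- Sj %*% w[j, ]
      state$St[k, j, , ] <- Sj
      state$mu[k, j, ] <- muj
      logits[j] <- 0.5 * determinant(Sj, logarithm = TRUE)$modulus +
        0.5 * sum(w[j, ] * muj)
    }
    state$pi[k, ] <- softmax(logits)
  }
  state
}


#' Build the polygenic posterior solver
#'
#' The polygenic posterior covariance is
#' `Lambda~ = (blockdiag_t(S_t^-1 R_t S_t^-1 / c_t) + Omega^-1 kron I_p)^-1`.
#' For two populations the solver eigendecomposes each population block once
#' and factorizes the p x p Schur complement in the concatenated eigenbasis,
#' instead of forming the dense 2p x 2p inverse. `method = "dense"` builds the
#' dense inverse directly (used as an internal cross-check).
#'
#' @param arr,consts Fit arrays/constants.
#' @param params A `polygenic_params` object.
#' @param method `"eigen"` (structured, default) or `"dense"`.
#' @return A list with `solve(rhs)` (rhs and result are p x T matrices),
#'   `logdet_Lambda`, `active` flag, and for the dense method the full
#'   `Lambda`.
#' @keywords internal
make_polygenic_solver <- function(arr, consts, params, method = c("eigen", "dense")) {
  method <- match.arg(method)
  T_ <- arr$T
  p <- arr$p
  Omega <- params$Omega[seq_len(T_), seq_len(T_), drop = FALSE]
  if (all(Omega == 0)) {
    return(list(active = FALSE,
                solve = function(rhs) matrix(0, p, T_),
                logdet_Lambda = 0))
  }
  diag_zero <- diag(Omega) <= 1e-300
  if (any(diag_zero)) {
    # a zero diagonal means that population has no polygenic component; this
    # forces omega12 = 0 (PSD), so populations decouple and the zero-variance
    # one gets nu = 0 exactly
    if (any(Omega[diag_zero, !diag_zero] != 0)) {
      abort("Omega has a zero variance with nonzero covariance (not PSD)",
            class = "xmapr_config_error")
    }
    keep <- which(!diag_zero)
    sub_params <- params
    sub_params$Omega <- Omega[keep, keep, drop = FALSE]
    sub_arr <- arr; sub_arr$T <- length(keep)
    sub_arr$se <- arr$se[, keep, drop = FALSE]
    sub_arr$R <- arr$R[keep]
    sub_consts <- consts; sub_consts$M <- consts$M[keep]
    sub <- make_polygenic_solver(sub_arr, sub_consts, sub_params, method)
    solve_fn <- function(rhs) {
      out <- matrix(0, p, T_)
      out[, keep] <- sub$solve(rhs[, keep, drop = FALSE])
      out
    }
    return(list(active = sub$active, solve = solve_fn,
                logdet_Lambda = sub$logdet_Lambda, reduced_to = keep))
  }
  Oinv <- tryCatch(solve(Omega), error = function(e) NULL)
  if (is.null(Oinv)) {
    abort(paste0("polygenic covariance Omega is singular; supply a PSD Omega ",
                 "or disable the polygenic component (Omega = 0)"),
          class = "xmapr_config_error")
  }
  if (method == "dense" || T_ != 2) {
    Prec <- matrix(0, T_ * p, T_ * p)
    for (t in seq_len(T_)) {
      it <- (t - 1) * p + seq_len(p)
      Prec[it, it] <- consts$M[[t]]
      for (s in seq_len(T_)) {
        is <- (s - 1) * p + seq_len(p)
        Prec[it, is] <- Prec[it, is] + diag(Oinv[t, s], p)
      }
    }
    ch <- chol(Prec)
    Lambda <- chol2inv(ch)
    return(list(active = TRUE, Lambda = Lambda,
                solve = function(rhs) matrix(Lambda %*% as.vector(rhs), p, T_),
                logdet_Lambda = -2 * sum(log(diag(ch)))))
  }
  a <- Oinv[1, 1]; b <- Oinv[1, 2]; cc <- Oinv[2, 2]
  e1 <- eigen(consts$M[[1]], symmetric = TRUE)
  e2 <- eigen(consts$M[[2]], symmetric = TRUE)
  D1a <- pmax(e1$values, 0) + a
  G <- crossprod(e1$vectors, e2$vectors)
  Schur <- diag(pmax(e2$values, 0) + cc, nrow = p) - b^2 * crossprod(G, G / D1a)
  chS <- chol((Schur + t(Schur)) / 2)
  logdet_Lambda <- -(sum(log(D1a)) + 2 * sum(log(diag(chS))))
  solve_fn <- function(rhs) {
    r1 <- crossprod(e1$vectors, rhs[, 1])
    r2 <- crossprod(e2$vectors, rhs[, 2])
    x2 <- backsolve(chS, forwardsolve(t(chS), r2 - b * crossprod(G, r1 / D1a)))
    x1 <- (r1 - b * (G %*% x2)) / D1a
    cbind(e1$vectors %*% x1, e2$vectors %*% x2)
  }
  list(active = TRUE, solve = solve_fn, logdet_Lambda = logdet_Lambda)
}

#' Update the polygenic posterior mean
#'
#' `nu~ = Lambda~ (u - blockdiag(M_t) E[b])`, where `u` stacks
#' `S_t^-2 bhat_t / c_t` and `E[b]` is the total expected causal effect over
#' active components.
#'
#' @param state Variational state.
#' @param consts Fit constants (including the polygenic solver).
#' @param Eb_tot p x T total expected single effects.
#' @return The state with `nu` updated.
#' @keywords internal
update_polygenic <- function(state, consts, Eb_tot) {
  if (!consts$solver$active) {
    state$nu[] <- 0
    state$logdet_Lambda <- 0
    return(state)
  }
  rhs <- consts$u
  for (t in seq_len(ncol(rhs))) {
    rhs[, t] <- rhs[, t] - consts$M[[t]] %*% Eb_tot[, t]
  }
  state$nu <- consts$solver$solve(rhs)
  state$logdet_Lambda <- consts$solver$logdet_Lambda
  state
}

#' M-step update of the causal-effect covariances
#'
#' `Sigma_k = sum_j pi~_kj (mu~_kj mu~_kj^T + Sigma~_kj)`, the
#' posterior-weighted second moment, PSD by construction.
#'
#' @param state Variational state.
#' @param active Logical mask of active components.
#' @return List of T x T covariance matrices.
#' @keywords internal
mstep_sigma <- function(state, active = rep(TRUE, nrow(state$pi))) {
  K <- nrow(state$pi)
  T_ <- dim(state$mu)[3]
  lapply(seq_len(K), function(k) {
    if (!active[k]) return(matrix(0, T_, T_))
    pk <- state$pi[k, ]
    muk <- matrix(state$mu[k, , ], ncol = T_)
    S <- matrix(0, T_, T_)
    for (t in seq_len(T_)) {
      for (s in t:T_) {
        v <- sum(pk * (muk[, t] * muk[, s] + state$St[k, , t, s]))
        S[t, s] <- v; S[s, t] <- v
      }
    }
    S
  })
}

#' Evidence lower bound of the variational approximation
#'
#' Evaluated up to the additive constant that does not involve the
#' causal-effect covariances (the Gaussian normalization of the
#' summary-statistic likelihood). Used for convergence monitoring and to
#' verify the M-step; monotone non-decreasing over full VEM sweeps.
#'
#' @param state Variational state.
#' @param consts Fit constants.
#' @param Sigma List of component prior covariances.
#' @param params `polygenic_params`.
#' @param active Active-component mask.
#' @return A scalar.
#' @keywords internal
compute_elbo <- function(state, consts, Sigma, params, active = NULL) {
  K <- nrow(state$pi)
  p <- ncol(state$pi)
  T_ <- dim(state$mu)[3]
  if (is.null(active)) active <- rep(TRUE, K)
  Eb <- lapply(seq_len(K), function(k) {
    if (active[k]) component_mean(state, k) else matrix(0, p, T_)
  })
  Eb_tot <- Reduce(`+`, Eb)
  m <- Eb_tot + state$nu

  elbo <- sum(m * consts$u)
  for (t in seq_len(T_)) {
    elbo <- elbo - 0.5 * sum(m[, t] * (consts$M[[t]] %*% m[, t]))
  }
  for (k in which(active)) {
    pk <- state$pi[k, ]
    muk <- matrix(state$mu[k, , ], ncol = T_)
    iS <- inv_2x2(Sigma[[k]])
    ld_Sk <- determinant(Sigma[[k]], logarithm = TRUE)$modulus[1]
    for (t in seq_len(T_)) {
      elbo <- elbo -
        0.5 * sum(consts$d[, t] * pk * (muk[, t]^2 + state$St[k, , t, t])) +
        0.5 * sum(Eb[[k]][, t] * (consts$M[[t]] %*% Eb[[k]][, t]))
    }
    # E_q[log p(beta_k | gamma_k)] + entropy pieces per SNP
    tr_term <- numeric(p)
    logdet_St <- numeric(p)
    if (T_ == 2) {
      S11 <- state$St[k, , 1, 1]; S22 <- state$St[k, , 2, 2]
      S12 <- state$St[k, , 1, 2]
      tr_term <- iS[1, 1] * (S11 + muk[, 1]^2) + iS[2, 2] * (S22 + muk[, 2]^2) +
        2 * iS[1, 2] * (S12 + muk[, 1] * muk[, 2])
      logdet_St <- log(S11 * S22 - S12^2)
    } else {
      for (j in seq_len(p)) {
        Sj <- matrix(state$St[k, j, , ], T_, T_)
        tr_term[j] <- sum(iS * (Sj + tcrossprod(muk[j, ])))
        logdet_St[j] <- determinant(Sj, logarithm = TRUE)$modulus[1]
      }
    }
    elbo <- elbo - 0.5 * sum(pk * tr_term) +
      sum(pk * log(1 / p)) - sum(pk * log(pmax(pk, 1e-300))) +
      0.5 * sum(pk * (logdet_St - ld_Sk)) + 0.5 * T_
  }
  if (consts$solver$active) {
    Omega <- params$Omega[seq_len(T_), seq_len(T_), drop = FALSE]
    keep <- which(diag(Omega) > 1e-300)  # populations with a polygenic term
    Osub <- Omega[keep, keep, drop = FALSE]
    Oinv <- solve(Osub)
    for (t in seq_along(keep)) {
      for (s in seq_along(keep)) {
        elbo <- elbo - 0.5 * Oinv[t, s] *
          sum(state$nu[, keep[t]] * state$nu[, keep[s]])
      }
    }
    ld_O <- determinant(Osub, logarithm = TRUE)$modulus[1]
    # the Gaussian-entropy constant cancels Tr((M + Omega^-1 x I) Lambda~) = Tp
    elbo <- elbo - 0.5 * p * ld_O + 0.5 * state$logdet_Lambda
  }
  as.numeric(elbo)
}

#' Fit the cross-population fine-mapping model
#'
#' Runs the two-step design's second step: with the polygenic covariance Omega
#' and inflation constants c fixed (typically from [estimate_polygenic_params()]),
#' a variational EM algorithm alternates coordinate updates of the K
#' single-effect posteriors and the polygenic posterior with an M-step for the
#' causal-effect covariances, until the evidence lower bound stabilizes.
#'
#' @param data An `xmap_data` object from [harmonize()].
#' @param K Number of causal components (default 10; over-specifying K is safe
#'   because redundant components shrink toward zero variance).
#' @param params A `polygenic_params` object. `polygenic_params(0, 0)` disables
#'   the polygenic component.
#' @param tol Convergence threshold on the ELBO change (default 1e-4).
#' @param max_iter Maximum number of VEM sweeps (default 200).
#' @param sigma2_init Initial per-population causal-effect variance
#'   (default `1/p`). Initialization is deterministic: uniform `pi~`, zero
#'   means.
#' @param freeze_tol Components whose covariance trace falls below this are
#'   frozen as inactive (default 1e-12).
#' @param boundary_burnin Number of initial VEM sweeps before the
#'   interior-vs-boundary (Sigma_k = 0) ELBO comparison starts deactivating
#'   components (default 10).
#' @return An object of class `xmap_fit` with elements `pip` (tibble of
#'   `snp_id`, `pip`), `pi` (K x p posterior matrix), `Sigma` (list of fitted
#'   covariances), `elbo_trace`, `n_iter`, `converged`, `active`, plus the
#'   aligned data for downstream credible sets.
#' @examples
#' sim <- simulate_locus(scenario_config(p = 50, p_genome = 0, K_true = 1,
#'                                       n = c(5000, 5000)), seed = 1)
#' fit <- fit_xmap(sim$data, K = 2,
#'                 params = polygenic_params(1e-5, 1e-5, 8e-6))
#' head(tidy(fit))
#' @export
fit_xmap <- function(data, K = 10, params = polygenic_params(0, 0),
                     tol = 1e-4, max_iter = 200, sigma2_init = NULL,
                     freeze_tol = 1e-12, boundary_burnin = 10) {
  stopifnot(inherits(data, "xmap_data"), K >= 1)
  arr <- data_arrays(data)
  if (any(!is.finite(arr$bhat)) || any(!is.finite(arr$se))) {
    abort("non-finite values in harmonized summary statistics",
          class = "xmapr_input_error")
  }
  p <- arr$p; T_ <- arr$T
  consts <- fit_constants(arr, params)
  consts$c <- params$c
  consts$solver <- make_polygenic_solver(arr, consts, params)

  if (is.null(sigma2_init)) sigma2_init <- 1 / p
  Sigma <- replicate(K, diag(sigma2_init, T_), simplify = FALSE)
  state <- new_state(p, T_, K)
  active <- rep(TRUE, K)
  elbo_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    Eb <- lapply(seq_len(K), function(k) {
      if (active[k]) component_mean(state, k) else matrix(0, p, T_)
    })
    Eb_tot <- Reduce(`+`, Eb)
    for (k in seq_len(K)) {
      if (!active[k]) next
      resid_theta <- Eb_tot - Eb[[k]] + state$nu
      state <- estep_update_component(k, state, consts, Sigma[[k]],
                                      resid_theta, arr)
      Eb_new <- component_mean(state, k)
      Eb_tot <- Eb_tot - Eb[[k]] + Eb_new
      Eb[[k]] <- Eb_new
    }
    state <- update_polygenic(state, consts, Eb_tot)
    Sigma_new <- mstep_sigma(state, active)
    for (k in seq_len(K)) {
      if (active[k]) Sigma[[k]] <- Sigma_new[[k]]
      if (active[k] && sum(diag(Sigma[[k]])) < freeze_tol) {
        active[k] <- FALSE
        state$pi[k, ] <- 1 / p
        state$mu[k, , ] <- 0
        Sigma[[k]] <- matrix(0, T_, T_)
      }
    }
    # M-step over the closed parameter space: the interior stationary point
    # Sigma_k from above is compared against the boundary Sigma_k = 0 (the
    # component switched off; beta_k degenerate at zero, gamma_k posterior
    # equal to its uniform prior). Without this comparison the EM can camp a
    # redundant component on the best-scoring noise SNP even when the
    # evidence favors no k-th effect at all. The check starts after a burn-in
    # so components can localize and adapt Sigma_k before being judged.
    if (iter >= boundary_burnin && any(active)) {
      elbo_on <- compute_elbo(state, consts, Sigma, params, active)
      for (k in which(active)) {
        try_active <- active
        try_active[k] <- FALSE
        elbo_off <- compute_elbo(state, consts, Sigma, params, try_active)
        if (elbo_off > elbo_on) {
          active <- try_active
          state$pi[k, ] <- 1 / p
          state$mu[k, , ] <- 0
          Sigma[[k]] <- matrix(0, T_, T_)
          elbo_on <- elbo_off
        }
      }
    }
    elbo <- compute_elbo(state, consts, Sigma, params, active)
    elbo_trace <- c(elbo_trace, elbo)
    if (iter > 1 && abs(elbo - elbo_trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("VEM did not converge in %d iterations (last ELBO change %.3g)",
                 max_iter,
                 if (length(elbo_trace) > 1) diff(tail_n(elbo_trace, 2)) else NA))
  }
  pip <- compute_pip(state$pi, active)
  structure(
    list(snp_id = data$snp_id,
         pip = tibble(snp_id = data$snp_id, pip = pip),
         pi = state$pi, mu = state$mu, Sigma_tilde = state$St,
         nu = state$nu, Sigma = Sigma, active = active,
         elbo_trace = elbo_trace, n_iter = length(elbo_trace),
         converged = converged, K = K, params = params, data = data),
    class = "xmap_fit"
  )
}

tail_n <- function(x, n) x[seq.int(max(1, length(x) - n + 1), length(x))]

#' @export
print.xmap_fit <- function(x, ...) {
  cat(sprintf("<xmap_fit: %d SNPs, K = %d (%d active), %d iterations%s>\n",
              length(x$snp_id), x$K, sum(x$active), x$n_iter,
              if (x$converged) ", converged" else ", NOT converged"))
  top <- x$pip %>% arrange(dplyr::desc(.data$pip)) %>% head(5)
  print(top)
  invisible(x)
}
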