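#' Tidy a fitted fine-mapping model
#'
#' One row per SNP: PIP, local fdr, and the per-component posterior masses of
#' the active components.
#'
#' @param x An `xmap_fit`.
#' @param ... Unused.
#' @return A tibble with `snp_id`, `pip`, `local_fdr`, and `pi_k` columns.
#' @method tidy xmap_fit
#' @export
tidy.xmap_fit <- function(x, ...) {
  out <- tibble(snp_id = x$snp_id, pip = x$pip$pip,
                local_fdr = 1 - x$pip$pip)
  for (k in which(x$active)) {
    out[[paste0("pi_", k)]] <- x$pi[k, ]
  }
  out
}

#' One-row summary of a fitted fine-mapping model
#'
#' @param x An `xmap_fit`.
#' @param ... Unused.
#' @return A tibble with the component count, active components, iteration
#'   count, final ELBO, convergence flag, and the summed causal-effect
#'   variances per population.
#' @method glance xmap_fit
#' @export
glance.xmap_fit <- function(x, ...) {
  sig1 <- sum(vapply(x$Sigma[x$active], function(S) S[1, 1], numeric(1)))
  sig2 <- sum(vapply(x$Sigma[x$active], function(S) S[2, 2], numeric(1)))
  tibble(K = x$K, n_active = sum(x$active), n_snps = length(x$snp_id),
         n_iter = x$n_iter, elbo = tail_n(x$elbo_trace, 1),
         converged = x$converged,
         sigma2_total_1 = sig1, sigma2_total_2 = sig2,
         c1 = x$params$c[1], c2 = x$params$c[min(2, length(x$params$c))])
}

#' PIP plot of a fitted model
#'
#' SNP position (locus order) against posterior inclusion probability, with
#' members of kept level-`alpha` credible sets circled and colored by
#' component.
#'
#' @param object An `xmap_fit`.
#' @param alpha Credible-set level used for highlighting (default 0.95).
#' @param purity_threshold Purity filter for highlighted sets.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot xmap_fit
#' @export
autoplot.xmap_fit <- function(object, alpha = 0.95, purity_threshold = 0.1,
                              ...) {
  df <- tibble(index = seq_along(object$snp_id), snp_id = object$snp_id,
               pip = object$pip$pip)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$pip)) +
    ggplot2::geom_point(color = "grey35", size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "SNP (locus order)", y = "PIP") +
    ggplot2::theme_minimal()
  cs <- credible_sets(object, alpha = alpha,
                      purity_threshold = purity_threshold)
  if (nrow(cs) > 0) {
    kept <- cs %>% filter(.data$kept) %>%
      left_join(df, by = "snp_id")
    if (nrow(kept) > 0) {
      p <- p + ggplot2::geom_point(
        data = kept,
        ggplot2::aes(x = .data$index, y = .data$pip,
                     color = factor(.data$component)),
        shape = 1, size = 3, stroke = 1) +
        ggplot2::labs(color = "credible set")
    }
  }
  p
}

#' ELBO trace plot
#'
#' @param fit An `xmap_fit`.
#' @return A ggplot object showing the evidence lower bound per VEM sweep.
#' @export
plot_elbo <- function(fit) {
  df <- tibble(iteration = seq_along(fit$elbo_trace), elbo = fit$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "VEM sweep", y = "ELBO (up to constant)") +
    ggplot2::theme_minimal()
}
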