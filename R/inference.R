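#' Posterior inclusion probabilities from per-component posteriors
#'
#' `PIP_j = 1 - prod_k (1 - pi~_kj)` over the active components: the posterior
#' probability that SNP j drives at least one causal signal.
#'
#' @param pi_tilde K x p matrix of per-component categorical posteriors (rows
#'   sum to 1).
#' @param active Logical mask of components to include (frozen redundant
#'   components are excluded).
#' @return Length-p numeric vector in [0, 1].
#' @examples
#' compute_pip(rbind(c(0.5, 0.5), c(0.5, 0.5)))  # 0.75 0.75
#' @export
compute_pip <- function(pi_tilde, active = rep(TRUE, nrow(pi_tilde))) {
  pi_tilde <- rbind(pi_tilde)
  if (!any(active)) return(rep(0, ncol(pi_tilde)))
  pm <- pmin(pmax(pi_tilde[active, , drop = FALSE], 0), 1)
  1 - apply(1 - pm, 2, prod)
}

#' Select putative causal SNPs by controlling the global FDR
#'
#' The local false discovery rate of SNP j is `fdr_j = 1 - PIP_j`. SNPs are
#' sorted by local fdr (ascending, ties broken by original order) and the j-th
#' ordered SNP is selected while the running mean of the ordered local fdrs --
#' the global FDR at that cutoff -- stays below `xi`.
#'
#' @param pip A numeric PIP vector, or a data frame with columns `snp_id` and
#'   `pip` (e.g. the `pip` element of an `xmap_fit`).
#' @param xi Global FDR level in (0, 1) (default 0.1).
#' @return A tibble with columns `snp_id`, `pip`, `local_fdr`, `global_fdr`
#'   (cumulative mean at the SNP's rank), `selected`, in the original SNP
#'   order.
#' @export
global_fdr_select <- function(pip, xi = 0.1) {
  if (is.data.frame(pip)) {
    snp_id <- pip$snp_id
    pip <- pip$pip
  } else {
    snp_id <- if (!is.null(names(pip))) names(pip) else
      paste0("snp", seq_along(pip))
  }
  stopifnot(all(pip >= -1e-12 & pip <= 1 + 1e-12), xi >= 0, xi < 1)
  pip <- pmin(pmax(pip, 0), 1)
  local_fdr <- 1 - pip
  ord <- order(local_fdr)  # stable: ties keep original order
  cum_fdr <- cumsum(local_fdr[ord]) / seq_along(ord)
  sel_ranked <- cum_fdr < xi
  # selections form a prefix of the ranked list
  n_sel <- if (any(!sel_ranked)) which(!sel_ranked)[1] - 1 else length(ord)
  selected <- rep(FALSE, length(pip))
  global_fdr <- numeric(length(pip))
  global_fdr[ord] <- cum_fdr
  if (n_sel > 0) selected[ord[seq_len(n_sel)]] <- TRUE
  tibble(snp_id = snp_id, pip = pip, local_fdr = local_fdr,
         global_fdr = global_fdr, selected = selected)
}

#' Level-alpha credible set of one causal signal
#'
#' The smallest SNP set whose cumulative posterior mass under `pi~_k` reaches
#' `alpha`, built by adding SNPs in descending posterior order (ties broken by
#' original SNP order).
#'
#' @param pi_k Length-p posterior vector of one component (sums to 1).
#' @param alpha Coverage level in (0, 1) (default 0.95).
#' @param snp_id Optional SNP identifiers.
#' @param component Component index recorded in the output.
#' @return A list of class `credible_set` with `component`, `snps` (descending
#'   posterior order), `index`, `coverage` and `pi` (the per-SNP masses).
#' @export
credible_set <- function(pi_k, alpha = 0.95, snp_id = NULL, component = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_along(pi_k))
  ord <- order(pi_k, decreasing = TRUE)
  csum <- cumsum(pi_k[ord])
  size <- which(csum >= alpha - 1e-12)[1]
  if (is.na(size)) size <- length(pi_k)
  idx <- ord[seq_len(size)]
  structure(list(component = component, snps = snp_id[idx], index = idx,
                 coverage = csum[size], pi = pi_k[idx],
                 purity = NULL, kept = NA),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("<credible_set: component %d, %d SNP(s), coverage %.3f%s>\n",
              x$component, length(x$snps), x$coverage,
              if (!is.null(x$purity))
                paste0(", purity ", paste(format(x$purity, digits = 2),
                                          collapse = "/")) else ""))
  invisible(x)
}

#' Purity-filter a credible set against per-population LD
#'
#' Purity in one population is the minimum absolute pairwise correlation among
#' the set's SNPs (1 for singletons by convention). A set is discarded as
#' redundant only when its purity falls below `threshold` in every population.
#'
#' @param cs A `credible_set`.
#' @param lds List of `ld_matrix` objects, one per population.
#' @param threshold Minimum purity (default 0.1).
#' @return The credible set with `purity` (per population) and `kept` filled.
#' @export
purity_filter <- function(cs, lds, threshold = 0.1) {
  if (inherits(lds, "ld_matrix")) lds <- list(lds)
  purity <- vapply(lds, function(R) {
    idx <- match(cs$snps, snp_ids(R))
    if (anyNA(idx)) {
      abort("credible-set SNPs absent from LD matrix",
            class = "xmapr_input_error")
    }
    if (length(idx) == 1) return(1)
    sub <- abs(unclass(R)[idx, idx])
    min(sub[upper.tri(sub)])
  }, numeric(1))
  cs$purity <- purity
  cs$kept <- any(purity >= threshold)
  cs
}

#' Credible sets of a fitted model
#'
#' Builds a level-`alpha` credible set for every active component, attaches
#' per-population purity, flags duplicated sets, and marks sets failing the
#' purity rule in every population as discarded.
#'
#' @param fit An `xmap_fit`.
#' @param alpha Coverage level (default 0.95; 0.99 also conventional).
#' @param purity_threshold Minimum purity (default 0.1).
#' @return A tibble with one row per (component, SNP): `component`, `snp_id`,
#'   `pi`, `coverage`, per-population `purity_*`, `kept`, `duplicate`.
#' @export
credible_sets <- function(fit, alpha = 0.95, purity_threshold = 0.1) {
  stopifnot(inherits(fit, "xmap_fit"))
  lds <- fit$data$ld
  sets <- list()
  for (k in which(fit$active)) {
    cs <- credible_set(fit$pi[k, ], alpha = alpha, snp_id = fit$snp_id,
                       component = k)
    sets[[length(sets) + 1]] <- purity_filter(cs, lds, purity_threshold)
  }
  if (length(sets) == 0) {
    return(tibble(component = integer(), snp_id = character(), pi = numeric(),
                  coverage = numeric(), kept = logical(),
                  duplicate = logical()))
  }
  keys <- vapply(sets, function(cs) paste(sort(cs$snps), collapse = ","),
                 character(1))
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  rows <- purrr::imap(sets, function(cs, i) {
    out <- tibble(component = cs$component, snp_id = cs$snps, pi = cs$pi,
                  coverage = cs$coverage, kept = cs$kept, duplicate = dup[i])
    for (t in seq_along(cs$purity)) {
      out[[paste0("purity_", t)]] <- cs$purity[t]
    }
    out
  })
  bind_rows(rows)
}

#' Fitted-model SNP selection
#'
#' Convenience wrapper: global-FDR selection on the fit's PIPs.
#'
#' @param fit An `xmap_fit`.
#' @param xi Global FDR level (default 0.1).
#' @return See [global_fdr_select()].
#' @export
select_snps <- function(fit, xi = 0.1) {
  global_fdr_select(fit$pip, xi = xi)
}
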