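#' Compute LD scores from an LD matrix
#'
#' The LD score of SNP j is the sum of squared correlations with all SNPs in
#' the matrix, `ell_j = sum_l r_jl^2`. When a second population's matrix is
#' supplied (same SNP order), the cross-population score
#' `ell_cross_j = sum_l r1_jl * r2_jl` is added; it is the natural
#' trans-ancestry analogue used by the bivariate regression here.
#'
#' @param R An `ld_matrix`.
#' @param R_other Optional second-population `ld_matrix` in the same SNP order.
#' @return A tibble with columns `snp_id`, `ell` and (if `R_other` is given)
#'   `ell_cross`.
#' @export
compute_ld_scores <- function(R, R_other = NULL) {
  out <- tibble(snp_id = snp_ids(R), ell = unname(rowSums(unclass(R)^2)))
  if (!is.null(R_other)) {
    if (!identical(snp_ids(R), snp_ids(R_other))) {
      abort("LD matrices must share an identical SNP order",
            class = "xmapr_input_error")
    }
    out$ell_cross <- unname(rowSums(unclass(R) * unclass(R_other)))
  }
  out
}

ldsc_blocks <- function(p, n_blocks = 200) {
  n_blocks <- max(2, min(n_blocks, floor(p / 2)))
  sort(rep_len(seq_len(n_blocks), p))
}

# Weighted least squares of y on x (optionally without intercept) in closed
# form, with block-jackknife standard errors from per-block sufficient
# statistics (contiguous blocks, leave-one-block-out).
ldsc_wls <- function(x, y, w, intercept = TRUE, n_blocks = 200) {
  wls_coef <- function(W, Sx, Sy, Sxx, Sxy) {
    if (intercept) {
      b <- (W * Sxy - Sx * Sy) / (W * Sxx - Sx^2)
      c(a = (Sy - b * Sx) / W, b = b)
    } else {
      c(b = Sxy / Sxx)
    }
  }
  blocks <- ldsc_blocks(length(y), n_blocks)
  agg <- function(v) as.vector(rowsum(v, blocks))
  bW <- agg(w); bSx <- agg(w * x); bSy <- agg(w * y)
  bSxx <- agg(w * x^2); bSxy <- agg(w * x * y)
  co <- wls_coef(sum(bW), sum(bSx), sum(bSy), sum(bSxx), sum(bSxy))
  nb <- length(bW)
  jk <- vapply(seq_len(nb), function(i) {
    wls_coef(sum(bW[-i]), sum(bSx[-i]), sum(bSy[-i]),
             sum(bSxx[-i]), sum(bSxy[-i]))
  }, numeric(length(co)))
  jk <- matrix(jk, nrow = length(co))
  se <- sqrt((nb - 1) / nb * rowSums((jk - rowMeans(jk))^2))
  list(coef = co, se = se)
}

#' Univariate LD score regression
#'
#' Weighted least squares of the chi-square statistics `z^2` on LD scores:
#' `E[chi2_j] = c + n * omega * ell_j`, where the intercept `c` is the
#' confounding inflation constant and the slope divided by `n` is the per-SNP
#' heritability `omega`. Weights start at `1 / max(ell_j, 1)` and one
#' reweighting pass divides further by the squared fitted mean (standard LDSC
#' heteroskedasticity weighting). SNPs with `chi2 > max(80, 0.001 n)` are
#' excluded as outliers.
#'
#' @param z z-score vector.
#' @param scores Tibble from [compute_ld_scores()] (or any data frame with an
#'   `ell` column) matching `z` in order.
#' @param n GWAS sample size.
#' @param M Number of SNPs represented by the regression (defaults to
#'   `length(z)`); only used to report the implied total heritability.
#' @param n_blocks Number of contiguous jackknife blocks (default 200).
#' @return A list with `c` (intercept), `omega` (per-SNP heritability, floored
#'   at 0), `se_c`, `se_omega`, `h2` (= `omega * M`) and `n_used`.
#' @export
fit_univariate_ldsc <- function(z, scores, n, M = length(z), n_blocks = 200) {
  ell <- scores$ell
  if (length(z) != length(ell)) {
    abort("z and LD scores differ in length", class = "xmapr_input_error")
  }
  if (length(z) < 50) {
    warn("fewer than 50 SNPs for LD score regression; estimates will be unstable")
  }
  chi2 <- z^2
  keep <- is.finite(chi2) & chi2 <= max(80, 0.001 * n)
  chi2 <- chi2[keep]; ell_k <- ell[keep]
  if (stats::var(ell_k) < .Machine$double.eps) {
    warn("constant LD scores: slope unidentifiable, returning omega = 0")
    return(list(c = mean(chi2), omega = 0, se_c = stats::sd(chi2) / sqrt(length(chi2)),
                se_omega = NA_real_, h2 = 0, n_used = length(chi2)))
  }
  w <- 1 / pmax(ell_k, 1)
  f1 <- ldsc_wls(ell_k, chi2, w, intercept = TRUE, n_blocks = n_blocks)
  mu <- pmax(f1$coef[1] + f1$coef[2] * ell_k, 0.1)
  w2 <- w / mu^2
  f2 <- ldsc_wls(ell_k, chi2, w2, intercept = TRUE, n_blocks = n_blocks)
  omega <- max(f2$coef[2] / n, 0)
  list(c = unname(f2$coef[1]), omega = unname(omega),
       se_c = unname(f2$se[1]), se_omega = unname(f2$se[2] / n),
       h2 = unname(omega * M), n_used = length(chi2))
}

#' Bivariate LD score regression for the cross-population co-heritability
#'
#' Regresses the z-score products `z1_j * z2_j` on cross-population LD scores
#' with the intercept fixed at zero (the two GWAS have no overlapping samples),
#' slope `sqrt(n1 n2) * omega12`.
#'
#' @param z1,z2 z-score vectors, same SNP order.
#' @param scores Tibble with an `ell_cross` column (see [compute_ld_scores()]).
#' @param n1,n2 Per-population sample sizes.
#' @param omega1,omega2 Optional per-SNP heritabilities; when supplied,
#'   `omega12` is clamped so the 2 x 2 polygenic covariance stays PSD.
#' @param n_blocks Jackknife block count.
#' @return A list with `omega12` and `se_omega12`.
#' @export
fit_bivariate_ldsc <- function(z1, z2, scores, n1, n2,
                               omega1 = NULL, omega2 = NULL, n_blocks = 200) {
  if (!"ell_cross" %in% names(scores)) {
    abort("scores lack the ell_cross column needed for bivariate LDSC",
          class = "xmapr_config_error")
  }
  lx <- scores$ell_cross
  if (length(z1) != length(z2) || length(z1) != length(lx)) {
    abort("z1, z2 and ell_cross differ in length", class = "xmapr_input_error")
  }
  y <- z1 * z2
  keep <- is.finite(y) &
    z1^2 <= max(80, 0.001 * n1) & z2^2 <= max(80, 0.001 * n2)
  y <- y[keep]; lx_k <- lx[keep]
  ell_w <- if ("ell" %in% names(scores)) pmax(scores$ell[keep], 1) else
    pmax(abs(lx_k), 1)
  w <- 1 / ell_w
  f <- ldsc_wls(lx_k, y, w, intercept = FALSE, n_blocks = n_blocks)
  omega12 <- unname(f$coef[1]) / sqrt(n1 * n2)
  if (!is.null(omega1) && !is.null(omega2)) {
    cap <- sqrt(pmax(omega1, 0) * pmax(omega2, 0))
    omega12 <- sign(omega12) * min(abs(omega12), cap)
  }
  list(omega12 = omega12, se_omega12 = unname(f$se[1]) / sqrt(n1 * n2))
}

#' Bundle polygenic parameters for the fine-mapping step
#'
#' The 2 x 2 per-SNP polygenic covariance Omega and the per-population
#' inflation constants. `omega12` is clamped to keep Omega PSD and, by
#' default, intercept estimates below 1 are clamped to 1 (an intercept below
#' one would deflate standard errors, over-correcting; an intercept near one
#' means no confounding).
#'
#' @param omega1,omega2 Per-SNP polygenic variances (>= 0).
#' @param omega12 Per-SNP polygenic covariance.
#' @param c1,c2 Inflation constants.
#' @param clamp_c Clamp intercepts below 1 up to 1 (default `TRUE`).
#' @return A list of class `polygenic_params` with `Omega` (2 x 2) and `c`
#'   (length-2 vector).
#' @export
polygenic_params <- function(omega1, omega2, omega12 = 0, c1 = 1, c2 = 1,
                             clamp_c = TRUE) {
  omega1 <- max(omega1, 0); omega2 <- max(omega2, 0)
  # 0.999 of the PSD bound: a perfectly correlated (rank-1) Omega would make
  # the polygenic precision undefined
  cap <- 0.999 * sqrt(omega1 * omega2)
  omega12 <- sign(omega12) * min(abs(omega12), cap)
  cc <- c(c1, c2)
  if (any(cc <= 0)) {
    abort("inflation constants must be positive", class = "xmapr_config_error")
  }
  if (clamp_c) cc <- pmax(cc, 1)
  structure(list(Omega = matrix(c(omega1, omega12, omega12, omega2), 2, 2),
                 c = cc),
            class = "polygenic_params")
}

#' @export
print.polygenic_params <- function(x, ...) {
  cat("<polygenic_params>\nOmega:\n")
  print(x$Omega)
  cat("inflation constants:", format(x$c, digits = 4), "\n")
  invisible(x)
}

#' Estimate polygenic parameters from genome-wide summary statistics
#'
#' Step 1 of the two-step procedure: univariate LD score regression per
#' population for `omega_t` and the intercept `c_t`, then bivariate LD score
#' regression for `omega12`, with PSD clamping.
#'
#' @param stats List of two `xmap_sumstats` (genome-wide, same SNP order).
#' @param scores Either one score tibble shared by both populations or a list
#'   of two (columns `ell`, with `ell_cross` present on at least one).
#' @param clamp_c Clamp intercepts below 1 (default `TRUE`).
#' @param n_blocks Jackknife block count.
#' @return A `polygenic_params` object with an `estimates` attribute carrying
#'   the per-fit details (intercept/slope standard errors).
#' @export
estimate_polygenic_params <- function(stats, scores, clamp_c = TRUE,
                                      n_blocks = 200) {
  if (!is.list(scores) || is.data.frame(scores)) {
    scores <- list(scores, scores)
  }
  n1 <- stats::median(stats[[1]]$n)
  n2 <- stats::median(stats[[2]]$n)
  f1 <- fit_univariate_ldsc(stats[[1]]$z, scores[[1]], n1, n_blocks = n_blocks)
  f2 <- fit_univariate_ldsc(stats[[2]]$z, scores[[2]], n2, n_blocks = n_blocks)
  xs <- if ("ell_cross" %in% names(scores[[1]])) scores[[1]] else scores[[2]]
  fb <- fit_bivariate_ldsc(stats[[1]]$z, stats[[2]]$z, xs, n1, n2,
                           omega1 = f1$omega, omega2 = f2$omega,
                           n_blocks = n_blocks)
  out <- polygenic_params(f1$omega, f2$omega, fb$omega12,
                          c1 = f1$c, c2 = f2$c, clamp_c = clamp_c)
  attr(out, "estimates") <- list(pop1 = f1, pop2 = f2, cross = fb)
  out
}
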