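# High-level pipeline entry points backing the command-line interface.
# Each writes plain-text outputs under an output prefix plus a JSON manifest
# (options + input checksums) sufficient to re-run the step exactly.

write_manifest <- function(prefix, step, options, inputs = character(0)) {
  manifest <- list(step = step, options = options,
                   inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, paste0(prefix, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run LD score regression and write a polygenic-parameter file
#'
#' @param sumstats_paths Two genome-wide summary-statistic file paths.
#' @param score_paths One or two LD-score file paths (columns `SNP`, `L2` and
#'   optionally `L2_CROSS`).
#' @param prefix Output prefix; writes `<prefix>.params.json` and a manifest.
#' @param clamp_c Clamp intercepts below 1 up to 1.
#' @return The `polygenic_params`, invisibly.
#' @export
run_ldsc <- function(sumstats_paths, score_paths, prefix = "xmap_ldsc",
                     clamp_c = TRUE) {
  stats <- lapply(sumstats_paths, read_sumstats)
  scores <- lapply(score_paths, function(p) {
    if (!file.exists(p)) {
      abort(paste0("LD score file not found: ", p), class = "xmapr_input_error")
    }
    sc <- readr::read_table(p, show_col_types = FALSE, progress = FALSE)
    if (!all(c("SNP", "L2") %in% names(sc))) {
      abort(paste0("LD score file lacks SNP/L2 columns: ", p),
            class = "xmapr_input_error")
    }
    out <- tibble(snp_id = as.character(sc$SNP), ell = sc$L2)
    if ("L2_CROSS" %in% names(sc)) out$ell_cross <- sc$L2_CROSS
    out
  })
  if (length(scores) == 1) scores <- list(scores[[1]], scores[[1]])
  for (t in 1:2) {
    scores[[t]] <- scores[[t]][match(stats[[t]]$snp_id, scores[[t]]$snp_id), ]
    if (anyNA(scores[[t]]$ell)) {
      abort("LD scores missing for some summary-statistic SNPs",
            class = "xmapr_input_error")
    }
  }
  params <- estimate_polygenic_params(stats, scores, clamp_c = clamp_c)
  est <- attr(params, "estimates")
  out <- list(omega1 = params$Omega[1, 1], omega2 = params$Omega[2, 2],
              omega12 = params$Omega[1, 2],
              c1 = params$c[1], c2 = params$c[2],
              se = list(omega1 = est$pop1$se_omega, omega2 = est$pop2$se_omega,
                        omega12 = est$cross$se_omega12,
                        c1 = est$pop1$se_c, c2 = est$pop2$se_c))
  jsonlite::write_json(out, paste0(prefix, ".params.json"), auto_unbox = TRUE,
                       digits = NA)
  write_manifest(prefix, "ldsc",
                 list(sumstats = sumstats_paths, scores = score_paths,
                      clamp_c = clamp_c),
                 c(sumstats_paths, score_paths))
  invisible(params)
}

read_params_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path),
          class = "xmapr_input_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  polygenic_params(x$omega1, x$omega2, x$omega12, x$c1, x$c2, clamp_c = FALSE)
}

#' Run the fine-mapping pipeline on files and write result tables
#'
#' Reads per-population summary statistics and LD matrices, harmonizes them,
#' fits the model with fixed polygenic parameters, and writes the PIP table
#' (`<prefix>.pip.tsv`), credible sets (`<prefix>.cs.tsv`), fitted covariances
#' and ELBO trace (`<prefix>.fit.json`), the drop/flip audit log
#' (`<prefix>.audit.tsv`), and a run manifest.
#'
#' @param sumstats_paths Two summary-statistic file paths (locus SNPs).
#' @param ld_paths Two dense LD matrix file paths.
#' @param ld_snp_paths Two LD sidecar SNP-list file paths.
#' @param params_path Optional JSON parameter file from [run_ldsc()].
#' @param params Optional `polygenic_params` (overrides `params_path`).
#' @param K Number of causal components (default 10).
#' @param alpha Credible-set level (default 0.95).
#' @param xi Global FDR level for the selection column (default 0.1).
#' @param purity_threshold Credible-set purity threshold (default 0.1).
#' @param tol,max_iter VEM convergence controls.
#' @param disable_polygenic Force Omega = 0.
#' @param prefix Output prefix.
#' @return The `xmap_fit`, invisibly.
#' @export
run_fit <- function(sumstats_paths, ld_paths, ld_snp_paths,
                    params_path = NULL, params = NULL,
                    K = 10, alpha = 0.95, xi = 0.1, purity_threshold = 0.1,
                    tol = 1e-4, max_iter = 200, disable_polygenic = FALSE,
                    prefix = "xmap_fit") {
  stats <- lapply(sumstats_paths, read_sumstats)
  lds <- purrr::map2(ld_paths, ld_snp_paths, load_ld)
  data <- harmonize(stats, lds)
  if (is.null(params)) {
    params <- if (!is.null(params_path)) read_params_file(params_path) else
      polygenic_params(0, 0)
  }
  if (disable_polygenic) {
    params <- polygenic_params(0, 0, c1 = params$c[1], c2 = params$c[2],
                               clamp_c = FALSE)
  }
  fit <- fit_xmap(data, K = K, params = params, tol = tol,
                  max_iter = max_iter)
  sel <- select_snps(fit, xi = xi)
  pip_tab <- tidy(fit) %>%
    left_join(sel %>% select("snp_id", "global_fdr", "selected"),
              by = "snp_id")
  readr::write_tsv(pip_tab, paste0(prefix, ".pip.tsv"), progress = FALSE)
  cs <- credible_sets(fit, alpha = alpha, purity_threshold = purity_threshold)
  readr::write_tsv(cs, paste0(prefix, ".cs.tsv"), progress = FALSE)
  readr::write_tsv(data$log, paste0(prefix, ".audit.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(Sigma = lapply(fit$Sigma, function(S) as.vector(S)),
         active = fit$active, elbo_trace = fit$elbo_trace,
         n_iter = fit$n_iter, converged = fit$converged),
    paste0(prefix, ".fit.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(prefix, "fit",
                 list(sumstats = sumstats_paths, ld = ld_paths,
                      ld_snps = ld_snp_paths, params_path = params_path,
                      K = K, alpha = alpha, xi = xi,
                      purity_threshold = purity_threshold, tol = tol,
                      max_iter = max_iter,
                      disable_polygenic = disable_polygenic,
                      omega1 = params$Omega[1, 1], omega2 = params$Omega[2, 2],
                      omega12 = params$Omega[1, 2],
                      c1 = params$c[1], c2 = params$c[2]),
                 c(sumstats_paths, ld_paths, ld_snp_paths,
                   params_path %||% character(0)))
  inform(sprintf("fit: %d SNPs harmonized, %d dropped/flagged; %d credible set(s) kept",
                 length(data$snp_id), nrow(data$log),
                 if (nrow(cs)) length(unique(cs$component[cs$kept])) else 0L))
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one simulated replicate to disk in the pipeline's input formats
#'
#' @param cfg A `scenario_config`.
#' @param seed Replicate master seed.
#' @param prefix Output prefix; writes per-population summary statistics, LD
#'   matrices with sidecars, genome-wide statistics and LD-score files, and a
#'   truth table.
#' @return File-path list, invisibly.
#' @export
run_simulate <- function(cfg = scenario_config(), seed = 1,
                         prefix = "xmap_sim") {
  sim <- simulate_locus(cfg, seed = seed)
  paths <- list()
  for (t in 1:2) {
    paths[[paste0("sumstats", t)]] <- sprintf("%s.pop%d.sumstats.tsv", prefix, t)
    write_sumstats(sim$data$stats[[t]], paths[[paste0("sumstats", t)]])
    paths[[paste0("ld", t)]] <- sprintf("%s.pop%d.ld.txt", prefix, t)
    paths[[paste0("ld_snps", t)]] <- sprintf("%s.pop%d.snps.txt", prefix, t)
    write_ld(sim$lds[[t]], paths[[paste0("ld", t)]],
             paths[[paste0("ld_snps", t)]])
    if (!is.null(sim$genome)) {
      paths[[paste0("genome", t)]] <- sprintf("%s.pop%d.genome.tsv", prefix, t)
      write_sumstats(sim$genome$stats[[t]], paths[[paste0("genome", t)]])
      paths[[paste0("scores", t)]] <- sprintf("%s.pop%d.l2.tsv", prefix, t)
      sc <- sim$genome$scores[[t]]
      readr::write_tsv(tibble(SNP = sc$snp_id, L2 = sc$ell,
                              L2_CROSS = sc$ell_cross),
                       paths[[paste0("scores", t)]], progress = FALSE)
    }
  }
  truth_tab <- tibble(snp_id = sim$data$snp_id[sim$truth$causal_idx],
                      index = sim$truth$causal_idx,
                      beta1 = sim$truth$beta[, 1], beta2 = sim$truth$beta[, 2])
  paths$truth <- paste0(prefix, ".truth.tsv")
  readr::write_tsv(truth_tab, paths$truth, progress = FALSE)
  write_manifest(prefix, "simulate", c(unclass(cfg), list(seed = seed)))
  invisible(paths)
}

#' Score a PIP table against a truth table and write tidy metrics
#'
#' @param pip_path Path to a `<prefix>.pip.tsv` from [run_fit()].
#' @param truth_path Path to a `<prefix>.truth.tsv` from [run_simulate()].
#' @param prefix Output prefix for `<prefix>.metrics.tsv`.
#' @param fdr_levels,fpr_caps See [evaluate_finemapping()].
#' @return The metrics tibble, invisibly.
#' @export
run_evaluate <- function(pip_path, truth_path, prefix = "xmap_eval",
                         fdr_levels = c(0.05, 0.1, 0.2),
                         fpr_caps = c(0.1, 0.2, 0.3)) {
  for (f in c(pip_path, truth_path)) {
    if (!file.exists(f)) {
      abort(paste0("input file not found: ", f), class = "xmapr_input_error")
    }
  }
  pip_tab <- readr::read_tsv(pip_path, show_col_types = FALSE, progress = FALSE)
  truth_tab <- readr::read_tsv(truth_path, show_col_types = FALSE,
                               progress = FALSE)
  causal_idx <- match(truth_tab$snp_id, pip_tab$snp_id)
  metrics <- evaluate_finemapping(causal_idx[!is.na(causal_idx)],
                                  pip_tab$pip, fdr_levels, fpr_caps)
  readr::write_tsv(metrics, paste0(prefix, ".metrics.tsv"), progress = FALSE)
  write_manifest(prefix, "evaluate",
                 list(pip = pip_path, truth = truth_path),
                 c(pip_path, truth_path))
  invisible(metrics)
}
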