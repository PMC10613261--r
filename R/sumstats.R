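#' Construct a validated summary-statistics table
#'
#' A summary-statistics table holds per-SNP marginal regression results from a
#' single-population GWAS on the standardized-genotype scale: effect estimate
#' `bhat`, its standard error `se` (> 0), the GWAS sample size `n`, allele
#' codes, and the z-score `z = bhat / se`.
#'
#' @param df A data frame with columns `snp_id`, `allele_effect`,
#'   `allele_other`, `bhat`, `se`, `n` (and optionally `z`).
#' @return A tibble of class `xmap_sumstats` with a canonical column order and
#'   `z` filled in.
#' @export
new_sumstats <- function(df) {
  df <- as_tibble(df)
  required <- c("snp_id", "allele_effect", "allele_other", "bhat", "se", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("summary statistics lack required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "xmapr_config_error")
  }
  df$snp_id <- as.character(df$snp_id)
  df$allele_effect <- toupper(as.character(df$allele_effect))
  df$allele_other <- toupper(as.character(df$allele_other))
  keep <- is.finite(df$bhat) & is.finite(df$se) & df$se > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d row(s) with missing/non-finite bhat or se (or se <= 0)",
                   n_dropped))
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    abort("no usable summary-statistic rows after validation",
          class = "xmapr_input_error")
  }
  if (anyDuplicated(df$snp_id)) {
    dup <- unique(df$snp_id[duplicated(df$snp_id)])
    inform(sprintf("dropped %d duplicated SNP id(s)", length(dup)))
    df <- df[!df$snp_id %in% dup | !duplicated(df$snp_id), , drop = FALSE]
    df <- df[!duplicated(df$snp_id), , drop = FALSE]
  }
  if ("z" %in% names(df) && any(is.finite(df$z))) {
    bad <- is.finite(df$z) & abs(df$z - df$bhat / df$se) > 1e-6
    if (any(bad)) {
      abort(sprintf("%d row(s) have z inconsistent with bhat/se", sum(bad)),
            class = "xmapr_input_error")
    }
  }
  df$z <- df$bhat / df$se
  out <- df[, c(required, "z"), drop = FALSE]
  class(out) <- c("xmap_sumstats", class(out))
  out
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited file with a header and maps its columns
#' onto the canonical fields. With `BETA`/`SE` absent but `Z` and `N` present,
#' effects are reconstructed on the standardized scale as `bhat = z / sqrt(n)`,
#' `se = 1 / sqrt(n)` (the marginal-regression identity for standardized
#' genotypes and phenotype).
#'
#' @param path Path to the text file.
#' @param column_map Named character vector mapping canonical names
#'   (`snp_id`, `allele_effect`, `allele_other`, `bhat`, `se`, `n`, `z`) to the
#'   file's column names. Defaults to the conventional
#'   `SNP, A1, A2, BETA, SE, N, Z` header.
#' @return An `xmap_sumstats` tibble.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("SNP A1 A2 BETA SE N",
#'              "rs1 A G 0.01 0.005 1000",
#'              "rs2 C T -0.02 0.005 1000"), tf)
#' read_sumstats(tf)
#' @export
read_sumstats <- function(path,
                          column_map = c(snp_id = "SNP", allele_effect = "A1",
                                         allele_other = "A2", bhat = "BETA",
                                         se = "SE", n = "N", z = "Z")) {
  if (!file.exists(path)) {
    abort(paste0("summary-statistics file not found: ", path),
          class = "xmapr_input_error")
  }
  raw <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  present <- intersect(names(column_map), names(column_map)[column_map %in% names(raw)])
  ren <- column_map[present]
  df <- raw[, unname(ren), drop = FALSE]
  names(df) <- names(ren)

  have_beta <- all(c("bhat", "se") %in% names(df))
  have_z <- all(c("z", "n") %in% names(df))
  if (!have_beta && have_z) {
    df$bhat <- df$z / sqrt(df$n)
    df$se <- 1 / sqrt(df$n)
  }
  required <- c("snp_id", "allele_effect", "allele_other", "bhat", "se", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("file ", path, " lacks mapped column(s): ",
                 paste(column_map[missing_cols], collapse = ", ")),
          class = "xmapr_config_error")
  }
  new_sumstats(df)
}

#' Write summary statistics in the canonical text layout
#'
#' @param stats An `xmap_sumstats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- tibble(SNP = stats$snp_id, A1 = stats$allele_effect,
                A2 = stats$allele_other, BETA = stats$bhat, SE = stats$se,
                N = stats$n, Z = stats$z)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
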