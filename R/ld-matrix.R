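#' Construct an LD (SNP correlation) matrix
#'
#' Wraps a p x p correlation matrix with its SNP identifiers, after
#' symmetrization, positive-semidefinite repair and resetting the diagonal to
#' exactly 1. Reference-panel LD estimates are near-PSD at best; the repair
#' clips negative eigenvalues to zero, reconstructs, and rescales back to unit
#' diagonal so downstream regularized inverses exist.
#'
#' @param R A square numeric matrix of SNP correlations, entries in [-1, 1].
#' @param snp_id Character vector of SNP identifiers, one per row/column.
#' @param repair Logical; apply PSD repair (default `TRUE`).
#' @return A matrix of class `ld_matrix` with `snp_id` as dimnames.
#' @export
ld_matrix <- function(R, snp_id = rownames(R), repair = TRUE) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) {
    abort("LD matrix must be square", class = "xmapr_input_error")
  }
  p <- nrow(R)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(p))
  snp_id <- as.character(snp_id)
  if (length(snp_id) != p) {
    abort("SNP id list length does not match LD matrix dimension",
          class = "xmapr_input_error")
  }
  if (any(!is.finite(R))) {
    abort("LD matrix contains non-finite entries", class = "xmapr_input_error")
  }
  if (any(abs(R) > 1 + 1e-3)) {
    abort("LD matrix has |entry| > 1 + 1e-3; not a correlation matrix",
          class = "xmapr_input_error")
  }
  R <- (R + t(R)) / 2
  if (repair) R <- repair_psd(R)
  diag(R) <- 1
  dimnames(R) <- list(snp_id, snp_id)
  class(R) <- c("ld_matrix", "matrix", "array")
  R
}

#' Clip negative eigenvalues and rescale to unit diagonal
#'
#' @param R Symmetric matrix.
#' @return Nearest-in-spirit PSD correlation matrix: eigenvalues clipped at 0,
#'   reconstructed, and rescaled so the diagonal is 1.
#' @keywords internal
repair_psd <- function(R) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= 0) return(R)
  lam <- pmax(ev$values, 0)
  R2 <- ev$vectors %*% (lam * t(ev$vectors))
  d <- sqrt(pmax(diag(R2), .Machine$double.eps))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix: %d SNPs>\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

snp_ids <- function(R) rownames(R)

subset_ld <- function(R, ids) {
  idx <- match(ids, rownames(R))
  if (anyNA(idx)) {
    abort("requested SNPs absent from LD matrix", class = "xmapr_input_error")
  }
  out <- unclass(R)[idx, idx, drop = FALSE]
  class(out) <- c("ld_matrix", "matrix", "array")
  out
}

#' Load an LD matrix from a dense text file with a SNP sidecar
#'
#' @param path Whitespace-delimited dense matrix file (no header).
#' @param snp_path One-SNP-per-line sidecar text file giving row/column ids.
#' @return An `ld_matrix`.
#' @export
load_ld <- function(path, snp_path) {
  for (f in c(path, snp_path)) {
    if (!file.exists(f)) {
      abort(paste0("LD input file not found: ", f), class = "xmapr_input_error")
    }
  }
  R <- as.matrix(utils::read.table(path, header = FALSE))
  snp_id <- readLines(snp_path)
  snp_id <- snp_id[nzchar(trimws(snp_id))]
  if (nrow(R) != ncol(R)) {
    abort("LD matrix file is not square", class = "xmapr_input_error")
  }
  if (nrow(R) != length(snp_id)) {
    abort("LD matrix dimension does not match SNP sidecar length",
          class = "xmapr_input_error")
  }
  ld_matrix(R, snp_id)
}

#' Write an LD matrix and its SNP sidecar
#'
#' @param R An `ld_matrix`.
#' @param path Output path for the dense matrix.
#' @param snp_path Output path for the one-SNP-per-line sidecar.
#' @return `path`, invisibly.
#' @export
write_ld <- function(R, path, snp_path) {
  utils::write.table(unclass(R), path, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(R), snp_path)
  invisible(path)
}

#' Estimate an LD matrix from a genotype matrix
#'
#' Columns are standardized and pairwise Pearson correlations computed, then
#' symmetrized and PSD-repaired exactly as [load_ld()].
#'
#' @param G n x p numeric genotype matrix (individuals by SNPs).
#' @param snp_id Optional SNP ids (defaults to `colnames(G)`).
#' @return An `ld_matrix`.
#' @export
compute_ld_from_genotypes <- function(G, snp_id = colnames(G)) {
  G <- as.matrix(G)
  if (nrow(G) < 2) {
    abort("need at least 2 individuals to estimate LD",
          class = "xmapr_input_error")
  }
  R <- stats::cor(G)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(ncol(G)))
  ld_matrix(R, snp_id)
}
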