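COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize summary statistics and LD matrices across populations
#'
#' Restricts all populations to the shared SNP set, aligns effect alleles to
#' population 1 (flipping the sign of `bhat`/`z` where the allele pair is
#' swapped, on either strand), drops strand-ambiguous (A/T, C/G) SNPs by
#' default, and subsets every LD matrix to the common order. Population 1's SNP
#' order defines the canonical order, so the result is deterministic.
#'
#' @param stats A list of `xmap_sumstats`, one per population (>= 2 unless
#'   `allow_single = TRUE`).
#' @param lds A list of `ld_matrix` objects, one per population, each covering
#'   at least the SNPs of its summary statistics.
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default `TRUE`; without
#'   allele frequencies the strand of an A/T or C/G SNP cannot be resolved).
#' @param allow_single Permit a single population (diagnostic mode).
#' @return A list of class `xmap_data` with elements `snp_id`, `stats` (list of
#'   aligned tibbles), `ld` (list of aligned `ld_matrix`), `n_pop`, and `log`
#'   (a tibble auditing every dropped SNP and sign flip).
#' @export
harmonize <- function(stats, lds, drop_ambiguous = TRUE, allow_single = FALSE) {
  if (inherits(stats, "xmap_sumstats")) stats <- list(stats)
  if (inherits(lds, "ld_matrix")) lds <- list(lds)
  n_pop <- length(stats)
  if (length(lds) != n_pop) {
    abort("need one LD matrix per population", class = "xmapr_config_error")
  }
  if (n_pop < 2 && !allow_single) {
    abort("harmonize expects >= 2 populations (set allow_single = TRUE for one)",
          class = "xmapr_config_error")
  }
  for (t in seq_len(n_pop)) {
    missing <- setdiff(stats[[t]]$snp_id, snp_ids(lds[[t]]))
    if (length(missing) > 0) {
      abort(sprintf("population %d LD matrix lacks %d SNP(s) present in its summary statistics",
                    t, length(missing)),
            class = "xmapr_input_error")
    }
  }

  shared <- Reduce(intersect, lapply(stats, function(s) s$snp_id))
  # canonical order: population 1
  shared <- stats[[1]]$snp_id[stats[[1]]$snp_id %in% shared]
  if (length(shared) == 0) {
    abort("no SNPs shared across populations", class = "xmapr_input_error")
  }
  log_rows <- list()
  note_intersect <- setdiff(unique(unlist(lapply(stats, `[[`, "snp_id"))), shared)
  if (length(note_intersect) > 0) {
    log_rows[[length(log_rows) + 1]] <-
      tibble(snp_id = note_intersect, population = NA_integer_,
             action = "dropped", reason = "not shared across populations")
  }

  ref <- stats[[1]][match(shared, stats[[1]]$snp_id), , drop = FALSE]
  if (drop_ambiguous) {
    amb <- is_strand_ambiguous(ref$allele_effect, ref$allele_other)
    if (any(amb)) {
      log_rows[[length(log_rows) + 1]] <-
        tibble(snp_id = ref$snp_id[amb], population = NA_integer_,
               action = "dropped", reason = "strand-ambiguous allele pair")
      shared <- shared[!amb]
      ref <- ref[!amb, , drop = FALSE]
    }
  }
  if (length(shared) == 0) {
    abort("no SNPs left after strand-ambiguity filtering",
          class = "xmapr_input_error")
  }

  aligned <- vector("list", n_pop)
  aligned[[1]] <- ref
  keep <- rep(TRUE, length(shared))
  for (t in seq_len(n_pop)[-1]) {
    st <- stats[[t]][match(shared, stats[[t]]$snp_id), , drop = FALSE]
    a1 <- st$allele_effect; a2 <- st$allele_other
    r1 <- ref$allele_effect; r2 <- ref$allele_other
    same <- (a1 == r1 & a2 == r2) |
      (COMPLEMENT[a1] == r1 & COMPLEMENT[a2] == r2)
    swapped <- (a1 == r2 & a2 == r1) |
      (COMPLEMENT[a1] == r2 & COMPLEMENT[a2] == r1)
    swapped <- swapped & !same
    bad <- !(same | swapped)
    if (any(bad)) {
      warn(sprintf("population %d: dropping %d SNP(s) with irreconcilable allele pairs",
                   t, sum(bad)))
      log_rows[[length(log_rows) + 1]] <-
        tibble(snp_id = st$snp_id[bad], population = t,
               action = "dropped", reason = "irreconcilable allele pair")
      keep <- keep & !bad
    }
    if (any(swapped)) {
      log_rows[[length(log_rows) + 1]] <-
        tibble(snp_id = st$snp_id[swapped & keep], population = t,
               action = "flipped", reason = "effect/other alleles swapped")
      st$bhat[swapped] <- -st$bhat[swapped]
      st$z[swapped] <- -st$z[swapped]
      tmp <- st$allele_effect[swapped]
      st$allele_effect[swapped] <- st$allele_other[swapped]
      st$allele_other[swapped] <- tmp
    }
    aligned[[t]] <- st
  }
  shared <- shared[keep]
  if (length(shared) == 0) {
    abort("no SNPs left after allele reconciliation", class = "xmapr_input_error")
  }
  aligned <- lapply(aligned, function(s) {
    out <- s[match(shared, s$snp_id), , drop = FALSE]
    class(out) <- c("xmap_sumstats", "tbl_df", "tbl", "data.frame")
    out
  })
  ld_sub <- lapply(seq_len(n_pop), function(t) subset_ld(lds[[t]], shared))

  structure(
    list(snp_id = shared, stats = aligned, ld = ld_sub, n_pop = n_pop,
         log = if (length(log_rows)) bind_rows(log_rows) else
           tibble(snp_id = character(), population = integer(),
                  action = character(), reason = character())),
    class = "xmap_data"
  )
}

#' @export
print.xmap_data <- function(x, ...) {
  cat(sprintf("<xmap_data: %d SNPs x %d populations; %d audit record(s)>\n",
              length(x$snp_id), x$n_pop, nrow(x$log)))
  invisible(x)
}

#' Assemble an aligned dataset without file I/O
#'
#' Convenience wrapper used by the simulator and tests: takes in-memory
#' summary-statistics tibbles and LD matrices that are already on a common SNP
#' grid and runs the same harmonization path.
#'
#' @inheritParams harmonize
#' @return An `xmap_data` object.
#' @export
xmap_data <- function(stats, lds, drop_ambiguous = TRUE, allow_single = FALSE) {
  harmonize(stats, lds, drop_ambiguous = drop_ambiguous,
            allow_single = allow_single)
}
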