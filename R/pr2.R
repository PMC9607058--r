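#' Parity rule 2 (PR2) bias coordinates
#'
#' Within the fourfold-degenerate families (where any third-position base is
#' synonymous, so third positions are free of protein-level constraint),
#' tallies third-position bases and returns the PR2 plot coordinates:
#' AU-bias `A3 / (A3 + U3)` and GC-bias `G3 / (G3 + C3)`. The plot center
#' (0.5, 0.5), where complementary bases are used equally, indicates balance
#' between mutation pressure and selection; displacement marks asymmetric
#' forces. A coordinate whose denominator is zero is returned as `NA`.
#'
#' @param counts A codon-count tibble from [count_codons()] or
#'   [pool_codons()].
#' @param family_scope `"fourfold_only"` (default, Sueoka's construction) or
#'   `"all_codons"` to tally third positions of all 59 analyzable codons.
#' @return A tibble with one row per `id`: `au_bias`, `gc_bias`, `n_sites`,
#'   plus carried metadata.
#' @examples
#' counts <- count_codons(tibble::tibble(id = "x",
#'   sequence = "GCAGCTGCGGCC"))  # uniform Ala family
#' pr2(counts)  # both coordinates 0.5
#' @export
pr2 <- function(counts, family_scope = c("fourfold_only", "all_codons")) {
  family_scope <- match.arg(family_scope)
  code <- genetic_code()
  scope <- if (family_scope == "fourfold_only") {
    code$codon[code$degeneracy == 4]
  } else {
    code$codon
  }
  m <- .count_matrix(counts)[, scope, drop = FALSE]
  third <- m %*% t(.pos_matrix(3)[, scope, drop = FALSE])
  n_sites <- rowSums(third)
  if (any(n_sites == 0)) {
    warn(paste0("no third-position sites in scope for: ",
                paste(rownames(m)[n_sites == 0], collapse = ", ")))
  }
  au_den <- third[, "A"] + third[, "T"]
  gc_den <- third[, "G"] + third[, "C"]
  out <- tibble::tibble(
    id = rownames(m),
    au_bias = ifelse(au_den > 0, third[, "A"] / au_den, NA_real_),
    gc_bias = ifelse(gc_den > 0, third[, "G"] / gc_den, NA_real_),
    n_sites = as.integer(n_sites)
  )
  meta <- .counts_meta(counts)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}
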