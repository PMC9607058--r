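#' Relative synonymous codon usage (RSCU)
#'
#' For each sequence and each synonymous family, RSCU of a codon is its
#' observed count divided by the count expected if all `k` codons of the
#' family were used equally: `RSCU_i = g_i * k / sum(g)`. A value of 1 means
#' no bias; values below 0.6 and above 1.6 conventionally mark low- and
#' high-frequency codons. Within every observed family the 59 values satisfy
#' `sum(RSCU) = k` exactly.
#'
#' Families never observed in a sequence get `NA` rather than a fabricated
#' 0, so downstream consumers must state a policy: [rscu_pca()] imputes them
#' at the neutral value 1, while [sid()] drops them from the comparison.
#'
#' @param counts A codon-count tibble from [count_codons()] or
#'   [pool_codons()].
#' @return A long tibble with one row per `id` x codon: `id`, `codon`,
#'   `amino_acid`, `count`, `rscu`, plus carried metadata.
#' @examples
#' counts <- count_codons(tibble::tibble(id = "x", sequence = "GCAGCAGCAGCT"))
#' r <- rscu(counts)
#' r[r$amino_acid == "A", ]  # GCA: 3.0, GCT: 1.0 (k = 4, 4 codons observed)
#' @export
rscu <- function(counts) {
  stopifnot(all(c("id", "codon", "count") %in% names(counts)))
  code <- genetic_code()
  out <- counts |>
    dplyr::group_by(.data$id, .data$amino_acid) |>
    dplyr::mutate(.family_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      .k = code$degeneracy[match(.data$codon, code$codon)],
      rscu = ifelse(.data$.family_total > 0,
                    .data$count * .data$.k / .data$.family_total, NA_real_)
    ) |>
    dplyr::select(-".family_total", -".k")
  if (all(is.na(out$rscu))) abort("all synonymous families are empty")
  out
}

#' Classify codons by RSCU frequency class and family preference
#'
#' Adds the conventional frequency classes (`low` below 0.6, `high` above
#' 1.6, `unbiased_range` otherwise — boundary values fall in the unbiased
#' range) and flags each family's most used codon(s) as `preferred`, the
#' convention used to bold codons in published RSCU tables. Ties for the
#' family maximum are all flagged.
#'
#' @param rscu_tbl Output of [rscu()].
#' @return The input with `class` (factor) and `preferred` (logical) added.
#' @export
classify_codons <- function(rscu_tbl) {
  stopifnot("rscu" %in% names(rscu_tbl))
  rscu_tbl |>
    dplyr::mutate(class = factor(
      dplyr::case_when(
        is.na(.data$rscu) ~ NA_character_,
        .data$rscu < 0.6 ~ "low",
        .data$rscu > 1.6 ~ "high",
        TRUE ~ "unbiased_range"
      ),
      levels = c("low", "unbiased_range", "high")
    )) |>
    dplyr::group_by(.data$id, .data$amino_acid) |>
    dplyr::mutate(
      preferred = !is.na(.data$rscu) & .data$rscu == max(.data$rscu) &
        sum(.data$count) > 0
    ) |>
    dplyr::ungroup()
}

#' Third-position base composition of preferred codons
#'
#' Tallies, per sequence, the ending base of each family's preferred codon —
#' the summary behind statements like "13 of the 18 preferred codons are
#' A/C-ended". When a family's maximum is tied between t codons, each tied
#' codon contributes a share of 1/t so the total over observed families is
#' conserved (18 when all families are observed).
#'
#' @param rscu_tbl Output of [rscu()] (classification is applied internally
#'   if the `preferred` column is absent).
#' @return A tibble `id`, `base`, `n_families` (possibly fractional).
#' @export
ending_base_summary <- function(rscu_tbl) {
  if (!"preferred" %in% names(rscu_tbl)) rscu_tbl <- classify_codons(rscu_tbl)
  rscu_tbl |>
    dplyr::filter(.data$preferred) |>
    dplyr::group_by(.data$id, .data$amino_acid) |>
    dplyr::mutate(.share = 1 / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(base = chartr("T", "U", str_sub(.data$codon, 3, 3))) |>
    dplyr::group_by(.data$id, .data$base) |>
    dplyr::summarise(n_families = sum(.data$.share), .groups = "drop")
}

#' Reshape RSCU values into a codon-by-group table
#'
#' Produces the classic published layout: one row per codon (with its amino
#' acid), one column per sequence/region, values rounded to two decimals.
#'
#' @param rscu_tbl Output of [rscu()].
#' @param digits Decimal places for display (default 2); `NULL` keeps full
#'   precision.
#' @return A wide tibble `amino_acid`, `codon`, then one column per `id`.
#' @export
rscu_wide <- function(rscu_tbl, digits = 2) {
  vals <- rscu_tbl
  if (!is.null(digits)) vals$rscu <- round(vals$rscu, digits)
  vals |>
    dplyr::mutate(codon = factor(.data$codon, levels = codon_order())) |>
    tidyr::pivot_wider(
      id_cols = c("amino_acid", "codon"),
      names_from = "id", values_from = "rscu"
    ) |>
    dplyr::arrange(.data$codon) |>
    dplyr::mutate(codon = as.character(.data$codon))
}

# RSCU matrix (ids x 59) with NA for unobserved families
.rscu_matrix <- function(rscu_tbl) {
  wide <- tidyr::pivot_wider(
    rscu_tbl[, c("id", "codon", "rscu")],
    names_from = "codon", values_from = "rscu"
  )
  m <- as.matrix(wide[, codon_order(), drop = FALSE])
  rownames(m) <- wide$id
  m
}
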