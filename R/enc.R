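#' Homozygosity of one synonymous family
#'
#' Wright's bias-corrected probability that two codons sampled from a family
#' are the same type: with family total `n` and per-codon counts `n_i`,
#' `S = sum((n_i/n)^2)` and `F = (n*S - 1) / (n - 1)`. `F` is undefined for
#' `n < 2`, in which case `NA` is returned and the family is skipped from its
#' degeneracy-class mean in [enc()].
#'
#' @param family_counts Non-negative integer counts of one family's codons.
#' @return A single value in `(0, 1]`, 0 for perfectly even usage at `n = 2`,
#'   or `NA` when `n < 2`.
#' @examples
#' family_homozygosity(c(TTT = 2, TTC = 2))  # S = 0.5, F = 1/3
#' family_homozygosity(c(TTT = 4, TTC = 0))  # single codon used: F = 1
#' @export
family_homozygosity <- function(family_counts) {
  n <- sum(family_counts)
  if (n < 2) return(NA_real_)
  s <- sum((family_counts / n)^2)
  (n * s - 1) / (n - 1)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC summarizes how many codons a sequence effectively uses:
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean
#' [family_homozygosity()] over the families of degeneracy `k`. The value
#' runs from 20 (extreme bias, one codon per family) to 61 (all synonymous
#' codons used equally); estimates above 61, possible at small counts, are
#' clamped to 61 with the raw value kept in `enc_raw`. Sequences with
#' `ENC <= 35` are flagged as significantly biased.
#'
#' Families with fewer than 2 observations are skipped from their class mean.
#' When the single 3-fold family (Ile) is unusable, `F3` falls back to
#' `(F2 + F4)/2` (Wright's convention), so short genes missing Ile still get
#' an ENC; if a 2-, 4- or 6-fold class is entirely unusable the sequence
#' gets `NA` with the failing class named in `note`.
#'
#' Each row also carries `gc3s` (percent), the expected ENC under mutation
#' pressure alone at that GC3s ([expected_enc()]), and
#' `residual = enc - expected_enc`: points below the curve (negative
#' residual) are the classic signature of selection on codon usage.
#'
#' @param counts A codon-count tibble from [count_codons()] or
#'   [pool_codons()].
#' @return A tibble with one row per `id`: `enc`, `enc_raw`, `gc3s`,
#'   `expected_enc`, `residual`, `significant_bias`, `note`, plus carried
#'   metadata.
#' @examples
#' # one codon per family at count 4: maximal bias, ENC = 20
#' code <- genetic_code()
#' one <- dplyr::distinct(code, amino_acid, .keep_all = TRUE)
#' counts <- dplyr::mutate(code, id = "biased",
#'                         count = ifelse(codon %in% one$codon, 4L, 0L))
#' enc(counts)$enc
#' @export
enc <- function(counts) {
  stopifnot(all(c("id", "codon", "count") %in% names(counts)))
  code <- genetic_code()
  m <- .count_matrix(counts)
  comp <- composition(counts)

  per_seq <- lapply(rownames(m), function(sid) {
    row <- m[sid, ]
    fams <- split(row, code$amino_acid[match(names(row), code$codon)])
    f_vals <- vapply(fams, family_homozygosity, numeric(1))
    k_of <- vapply(fams, length, integer(1))
    f_bar <- vapply(c(2, 3, 4, 6), function(k) {
      v <- f_vals[k_of == k]
      v <- v[!is.na(v) & v > 0]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    names(f_bar) <- c("F2", "F3", "F4", "F6")
    note <- NA_character_
    if (is.na(f_bar["F3"]) && !is.na(f_bar["F2"]) && !is.na(f_bar["F4"])) {
      f_bar["F3"] <- (f_bar["F2"] + f_bar["F4"]) / 2
      note <- "F3 estimated as (F2 + F4)/2 (Ile family unusable)"
    }
    if (anyNA(f_bar)) {
      missing <- paste(names(f_bar)[is.na(f_bar)], collapse = ", ")
      return(tibble::tibble(
        id = sid, enc = NA_real_, enc_raw = NA_real_,
        note = paste0("no usable family in class ", missing)
      ))
    }
    raw <- 2 + 9 / f_bar["F2"] + 1 / f_bar["F3"] +
      5 / f_bar["F4"] + 3 / f_bar["F6"]
    tibble::tibble(id = sid, enc = min(raw, 61), enc_raw = unname(raw),
                   note = note)
  })

  out <- list_rbind(per_seq) |>
    dplyr::left_join(comp[, c("id", "GC3s")], by = "id") |>
    dplyr::rename(gc3s = "GC3s") |>
    dplyr::mutate(
      expected_enc = expected_enc(.data$gc3s / 100),
      residual = .data$enc - .data$expected_enc,
      significant_bias = !is.na(.data$enc) & .data$enc <= 35
    ) |>
    dplyr::select("id", "enc", "enc_raw", "gc3s", "expected_enc",
                  "residual", "significant_bias", "note")
  meta <- .counts_meta(counts)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}

#' Expected ENC under mutation pressure alone
#'
#' The standard ENC-plot reference curve: at synonymous third-position GC
#' content `s` (a fraction in `[0, 1]`), a sequence shaped only by
#' directional mutation pressure is expected to have
#' `ENC = 2 + s + 29 / (s^2 + (1 - s)^2)`. Observed points falling below
#' this curve indicate that natural selection also constrains codon choice.
#'
#' @param gc3s_fraction GC3s as a fraction in `[0, 1]` (vectorized).
#' @return Expected ENC value(s).
#' @examples
#' expected_enc(0.5)  # 60.5, the curve's maximum
#' expected_enc(0)    # 31
#' @export
expected_enc <- function(gc3s_fraction) {
  s <- gc3s_fraction
  if (any(!is.na(s) & (s < 0 | s > 1))) {
    abort("gc3s_fraction must lie in [0, 1]")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Sampled expected-ENC reference curve
#'
#' Convenience table of the [expected_enc()] curve for plotting, sampled at
#' fixed GC3s steps.
#'
#' @param step GC3s fraction step (default 0.01).
#' @return A tibble `gc3s` (percent), `expected_enc`.
#' @export
enc_reference_curve <- function(step = 0.01) {
  s <- seq(0, 1, by = step)
  tibble::tibble(gc3s = 100 * s, expected_enc = expected_enc(s))
}
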