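#' Nucleotide composition statistics per sequence
#'
#' Computes, for each sequence (or pooled tally), the base-composition
#' summaries conventionally reported in codon-usage studies: overall A/C/G/U
#' percentages with AU and GC totals; per-position GC percentages `GC1`,
#' `GC2`, `GC3` and their first-and-second-position mean `GC12`; and the
#' synonymous third-position base percentages `A3s/C3s/G3s/U3s` with
#' `GC3s = G3s + C3s`.
#'
#' All statistics use the 59 analyzable codons as denominator (the CodonW
#' convention: `ATG`, `TGG` and stops are removed before any composition is
#' measured). One consequence of using this single consistent denominator is
#' that `GC3` and `GC3s` coincide; both columns are kept because downstream
#' consumers conventionally expect both names. With `basis = "full_cds"` the
#' overall A/C/G/U/AU/GC percentages are instead taken over every base of the
#' raw sequence (requires a `sequence` column); positional and third-position
#' statistics always come from the analyzable codons.
#'
#' @param x A codon-count tibble from [count_codons()] or [pool_codons()], or
#'   (for `basis = "full_cds"`) a sequence tibble from [read_cds()].
#' @param basis `"analyzable_codons"` (default) or `"full_cds"`.
#' @return A tibble with one row per `id`: `n_codons`, `A`, `C`, `G`, `U`,
#'   `AU`, `GC`, `A3s`, `C3s`, `G3s`, `U3s`, `GC1`, `GC2`, `GC3`, `GC12`,
#'   `GC3s` (all percentages), plus carried metadata columns.
#' @examples
#' counts <- count_codons(tibble::tibble(id = "x", sequence = "GCAGCATTTTAA"))
#' composition(counts)
#' @export
composition <- function(x, basis = c("analyzable_codons", "full_cds")) {
  basis <- match.arg(basis)
  if (basis == "full_cds") {
    stopifnot("sequence" %in% names(x))
    counts <- count_codons(x)
  } else {
    stopifnot(all(c("codon", "count") %in% names(x)))
    counts <- x
  }
  m <- .count_matrix(counts)
  n <- rowSums(m)
  if (any(n == 0)) {
    abort(paste0(
      "no analyzable codons for: ",
      paste(rownames(m)[n == 0], collapse = ", ")
    ))
  }
  ids <- rownames(m)
  rownames(m) <- NULL
  n <- unname(n)

  # per-position base tallies: (seq x 59) %*% (59 x 4 indicator)
  pos <- lapply(1:3, function(p) m %*% t(.pos_matrix(p)))
  tot <- pos[[1]] + pos[[2]] + pos[[3]]

  pct <- 100 * tot / (3 * n)
  gc_pos <- vapply(pos, function(pm) 100 * (pm[, "G"] + pm[, "C"]) / n,
                   numeric(nrow(m)))
  if (is.null(dim(gc_pos))) gc_pos <- matrix(gc_pos, nrow = 1)
  third <- 100 * pos[[3]] / n

  out <- tibble::tibble(
    id = ids,
    n_codons = as.integer(n),
    A = pct[, "A"], C = pct[, "C"], G = pct[, "G"], U = pct[, "T"],
    AU = pct[, "A"] + pct[, "T"], GC = pct[, "G"] + pct[, "C"],
    A3s = third[, "A"], C3s = third[, "C"],
    G3s = third[, "G"], U3s = third[, "T"],
    GC1 = gc_pos[, 1], GC2 = gc_pos[, 2], GC3 = gc_pos[, 3],
    GC12 = (gc_pos[, 1] + gc_pos[, 2]) / 2,
    GC3s = third[, "G"] + third[, "C"]
  )
  out[-1] <- lapply(out[-1], unname)

  if (basis == "full_cds") {
    base_tab <- vapply(
      toupper(chartr("Uu", "Tt", x$sequence)),
      function(s) {
        b <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
        100 * as.numeric(b) / sum(b)
      },
      numeric(4)
    )
    ord <- match(out$id, x$id)
    out$A <- unname(base_tab[1, ord])
    out$C <- unname(base_tab[2, ord])
    out$G <- unname(base_tab[3, ord])
    out$U <- unname(base_tab[4, ord])
    out$AU <- out$A + out$U
    out$GC <- out$G + out$C
  }

  meta <- .counts_meta(counts)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}
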