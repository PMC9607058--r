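#' Build a host codon-usage reference
#'
#' Pools a host's coding-sequence codon counts and derives, per codon, its
#' within-family relative frequency (`freq`, the quantity RCDI divides by),
#' its RSCU value, and its Sharp–Li relative adaptiveness weight
#' `w = RSCU / max(RSCU in family)`, the quantity CAI averages. Families
#' that contain a zero count get a 0.5 pseudocount added to every codon of
#' that family (only then), so CAI and RCDI never take log of or divide by
#' zero; families with zero total are left undefined (`NA`) and dropped by
#' the scoring functions.
#'
#' @param x One of: a sequence tibble with `id`/`sequence` columns (counts
#'   are pooled across all records), a codon-count tibble from
#'   [count_codons()] (pooled likewise), or a 59/64-row usage table with
#'   `codon` and `count` columns (as from [read_codon_usage_table()]).
#' @param host_name Label for the host (used in adaptation reports).
#' @param pseudocount Pseudocount for families containing a zero
#'   (default 0.5).
#' @return An object of class `host_reference`: a tibble `codon`,
#'   `amino_acid`, `count`, `freq`, `rscu`, `w` with attributes `host_name`
#'   and `pseudocount`.
#' @examples
#' ref <- host_reference(
#'   tibble::tibble(codon = c("GCA", "GCT"), count = c(3, 1)),
#'   host_name = "toy"
#' )
#' ref[ref$amino_acid == "A", ]  # w(GCA) = 1, w(GCT) = 1/3, freq(GCA) = 0.75
#' @export
host_reference <- function(x, host_name = "host", pseudocount = 0.5) {
  stopifnot(is.data.frame(x), nrow(x) > 0)
  if ("sequence" %in% names(x)) {
    counts <- pool_codons(count_codons(x), id = host_name)
  } else if (all(c("codon", "count") %in% names(x))) {
    if (all(c("id", "amino_acid") %in% names(x))) {
      counts <- pool_codons(x, id = host_name)
    } else {
      tab <- x
      tab$codon <- toupper(chartr("Uu", "Tt", tab$codon))
      counts <- tibble::tibble(codon = codon_order()) |>
        dplyr::left_join(tab[, c("codon", "count")], by = "codon") |>
        dplyr::mutate(
          count = tidyr::replace_na(.data$count, 0),
          amino_acid = genetic_code()$amino_acid,
          id = host_name
        )
    }
  } else {
    abort("x must have a 'sequence' column or 'codon' and 'count' columns")
  }
  if (sum(counts$count) == 0) abort("host reference has no codon counts")

  ref <- counts |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::mutate(
      count = .data$count +
        ifelse(any(.data$count == 0) & sum(.data$count) > 0, pseudocount, 0),
      .total = sum(.data$count),
      freq = ifelse(.data$.total > 0, .data$count / .data$.total, NA_real_),
      rscu = ifelse(.data$.total > 0,
                    .data$count * dplyr::n() / .data$.total, NA_real_),
      w = ifelse(.data$.total > 0, .data$rscu / max(.data$rscu), NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "amino_acid", "count", "freq", "rscu", "w") |>
    dplyr::arrange(match(.data$codon, codon_order()))
  structure(ref, class = c("host_reference", class(ref)),
            host_name = host_name, pseudocount = pseudocount)
}

#' @export
print.host_reference <- function(x, ...) {
  cat("Host codon-usage reference:", attr(x, "host_name"), "\n")
  cat("  defined families:",
      dplyr::n_distinct(x$amino_acid[!is.na(x$w)]), "of 18;",
      "pseudocount", attr(x, "pseudocount"), "\n")
  NextMethod()
}

#' Read a 64-row codon usage table
#'
#' Reads the common exchange format for host codon usage: a tab-separated
#' file with columns `codon` and `count`, one row per codon (59 or 64 rows;
#' non-analyzable codons are ignored downstream). Values may be raw counts
#' or per-thousand frequencies — tables whose values sum to roughly 1000 are
#' detected as per-thousand and used as-is (all derived quantities are
#' ratios, so the scale cancels).
#'
#' @param path Path to the TSV file.
#' @return A tibble `codon`, `count`.
#' @export
read_codon_usage_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("codon", "count") %in% names(tab))) {
    abort("usage table must have 'codon' and 'count' columns")
  }
  tab$codon <- toupper(chartr("Uu", "Tt", tab$codon))
  if (abs(sum(tab$count) - 1000) < 50) {
    inform("usage table read as per-thousand frequencies")
  }
  tab[, c("codon", "count")]
}

.check_ref <- function(ref) {
  if (!inherits(ref, "host_reference")) {
    abort("ref must be a host_reference object (see host_reference())")
  }
}

#' Codon adaptation index (CAI)
#'
#' Sharp–Li CAI of each sequence against a host reference: the geometric
#' mean of the host relative-adaptiveness weight `w` over every scored codon
#' occurrence, `exp( sum(g_i * log(w_i)) / sum(g_i) )`. CAI runs from near 0
#' to 1; 1 means the sequence uses only the host's preferred codon of every
#' family. Codons whose family is undefined in the reference are dropped and
#' counted in `n_dropped`. CAI is invariant under duplication of a sequence
#' (it depends only on codon proportions).
#'
#' @param counts A codon-count tibble from [count_codons()] or
#'   [pool_codons()].
#' @param ref A [host_reference()] object.
#' @return A tibble with one row per `id`: `host_ref`, `cai`, `n_scored`,
#'   `n_dropped`, plus carried metadata.
#' @export
cai <- function(counts, ref) {
  .check_ref(ref)
  w <- setNames(ref$w, ref$codon)
  per_id <- counts |>
    dplyr::mutate(w = w[.data$codon]) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_scored = sum(.data$count[!is.na(.data$w)]),
      n_dropped = sum(.data$count[is.na(.data$w)]),
      cai = exp(sum(.data$count * log(.data$w), na.rm = TRUE) / n_scored),
      .groups = "drop"
    )
  if (any(per_id$n_scored == 0)) {
    abort(paste0("no scorable codons for: ",
                 paste(per_id$id[per_id$n_scored == 0], collapse = ", ")))
  }
  out <- per_id |>
    dplyr::mutate(host_ref = attr(ref, "host_name"), .after = "id") |>
    dplyr::select("id", "host_ref", "cai", "n_scored", "n_dropped")
  meta <- .counts_meta(counts)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}

#' Relative codon deoptimization index (RCDI)
#'
#' CAIcal-style RCDI of each sequence against a host reference: with
#' `CiFa` the codon's within-family relative frequency in the query, `CiFh`
#' the same in the host, `N_i` the codon's count and `N` the total scored
#' codons, `RCDI = sum( (CiFa / CiFh) * N_i / N )`. A query whose
#' within-family frequencies match the host exactly scores 1; any deviation
#' raises it (RCDI >= 1 for every query, by the Cauchy–Schwarz inequality
#' applied within each family), so larger values mean deoptimization
#' relative to the host. Families undefined in the reference are dropped
#' from both the sum and `N`.
#'
#' @inheritParams cai
#' @return A tibble with one row per `id`: `host_ref`, `rcdi`, `n_scored`, plus
#'   carried metadata.
#' @export
rcdi <- function(counts, ref) {
  .check_ref(ref)
  fh <- setNames(ref$freq, ref$codon)
  per_id <- counts |>
    dplyr::mutate(fh = fh[.data$codon]) |>
    dplyr::group_by(.data$id, .data$amino_acid) |>
    dplyr::mutate(fa = if (sum(.data$count) > 0) {
      .data$count / sum(.data$count)
    } else {
      NA_real_
    }) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_scored = sum(.data$count[!is.na(.data$fh)]),
      rcdi = sum(.data$count * .data$fa / .data$fh, na.rm = TRUE) / n_scored,
      .groups = "drop"
    )
  if (any(per_id$n_scored == 0)) {
    abort(paste0("no scorable codons for: ",
                 paste(per_id$id[per_id$n_scored == 0], collapse = ", ")))
  }
  out <- per_id |>
    dplyr::mutate(host_ref = attr(ref, "host_name")) |>
    dplyr::select("id", "host_ref", "rcdi", "n_scored")
  meta <- .counts_meta(counts)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}

#' Similarity index (SiD) between viral and host codon usage
#'
#' Compares RSCU vectors over the 59 analyzable codons by cosine similarity
#' `R(A, B) = sum(a*b) / sqrt(sum(a^2) * sum(b^2))` and reports the distance
#' `D = (1 - R) / 2`. Identical usage gives `D = 0`; usage with disjoint
#' codon support gives `D = 0.5`, the maximum attainable for non-negative
#' RSCU vectors (the index is conventionally quoted on a 0–1 scale). Higher
#' `D` means the host's codon usage has less in common with the virus's.
#' Codons undefined (`NA`) on either side are dropped from the inner
#' products; `R` is symmetric in its arguments.
#'
#' @param virus_rscu Output of [rscu()] (one or more sequences).
#' @param host Either a [host_reference()] object or an [rscu()] tibble for
#'   a single pooled host sequence.
#' @return A tibble with one row per `id`: `host_ref`, `sid_r`, `sid_d`,
#'   `n_codons_shared`, plus carried metadata.
#' @export
sid <- function(virus_rscu, host) {
  if (inherits(host, "host_reference")) {
    b <- setNames(host$rscu, host$codon)[codon_order()]
    host_name <- attr(host, "host_name")
  } else {
    stopifnot(is.data.frame(host), all(c("codon", "rscu") %in% names(host)))
    if ("id" %in% names(host) && dplyr::n_distinct(host$id) > 1) {
      abort("host rscu table must describe a single pooled source")
    }
    b <- setNames(host$rscu, host$codon)[codon_order()]
    host_name <- if ("id" %in% names(host)) host$id[1] else "host"
  }
  m <- .rscu_matrix(virus_rscu)
  per_id <- lapply(rownames(m), function(sid_) {
    a <- m[sid_, ]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) abort(paste0("no shared defined codons for '", sid_, "'"))
    aa <- a[keep]; bb <- b[keep]
    if (sum(aa^2) == 0 || sum(bb^2) == 0) {
      abort(paste0("all-zero RSCU vector in SiD comparison for '", sid_, "'"))
    }
    r <- sum(aa * bb) / sqrt(sum(aa^2) * sum(bb^2))
    tibble::tibble(id = sid_, host_ref = host_name, sid_r = r,
                   sid_d = (1 - r) / 2, n_codons_shared = sum(keep))
  })
  out <- list_rbind(per_id)
  meta <- .counts_meta(virus_rscu)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}

#' Score a cohort against a panel of host references
#'
#' Computes the full CAI / RCDI / SiD matrix of every sequence against every
#' host reference, the core of a virus–host adaptation scan. Group means are
#' obtained by passing the result to [summarize_by()].
#'
#' @param counts A codon-count tibble from [count_codons()].
#' @param refs A list of [host_reference()] objects (or a single one).
#' @return A tibble with one row per sequence x host: `id`, `host_ref`, `cai`,
#'   `rcdi`, `sid_r`, `sid_d`, `n_scored`, plus carried metadata.
#' @export
adaptation_scan <- function(counts, refs) {
  if (inherits(refs, "host_reference")) refs <- list(refs)
  stopifnot(length(refs) >= 1)
  v <- rscu(counts)
  per_ref <- lapply(refs, function(ref) {
    ca <- cai(counts, ref)[, c("id", "host_ref", "cai")]
    rc <- rcdi(counts, ref)[, c("id", "host_ref", "rcdi", "n_scored")]
    sd_ <- sid(v, ref)[, c("id", "host_ref", "sid_r", "sid_d")]
    dplyr::inner_join(dplyr::inner_join(ca, rc, by = c("id", "host_ref")),
                      sd_, by = c("id", "host_ref"))
  })
  out <- list_rbind(per_ref)[, c("id", "host_ref", "cai", "rcdi", "sid_r",
                                 "sid_d", "n_scored")]
  meta <- .counts_meta(counts)
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}
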