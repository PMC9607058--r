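#' Read coding sequences from FASTA, with optional metadata
#'
#' Loads a multi-record FASTA of complete in-frame coding sequences (DNA or
#' RNA alphabet) into a tibble, normalizing to the DNA alphabet (`U` to `T`,
#' uppercase). Records containing characters outside `A/C/G/T` (ambiguity
#' codes such as `N`) are excluded whole, with a message naming them: partial
#' masking would make per-sequence codon totals hard to interpret.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param metadata Optional path to a tab-separated table with a header and
#'   columns `id`, `host`, `region`, `group` (extra columns are kept); rows
#'   are joined to records by `id`. Alternatively a data frame of that shape.
#' @return A tibble with columns `id`, `sequence` and any joined metadata
#'   columns, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "AUGUUUGCATAA", ">s2", "ATGCCCTAA"), fa)
#' read_cds(fa)
#' @export
read_cds <- function(path, metadata = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort(paste0("empty FASTA file: ", path))
  seqs <- chartr("Uu", "Tt", as.character(recs))
  seqs <- toupper(seqs)
  ids <- sub("\\s.*$", "", names(recs))
  ok <- !grepl("[^ACGT]", seqs)
  if (any(!ok)) {
    inform(paste0(
      "excluded ", sum(!ok), " record(s) with non-ACGT characters: ",
      paste(ids[!ok], collapse = ", ")
    ))
  }
  out <- tibble::tibble(id = ids[ok], sequence = unname(seqs[ok]))
  if (!is.null(metadata)) {
    meta <- if (is.data.frame(metadata)) {
      tibble::as_tibble(metadata)
    } else {
      readr::read_tsv(metadata, show_col_types = FALSE)
    }
    if (!"id" %in% names(meta)) abort("metadata must have an 'id' column")
    out <- dplyr::left_join(out, meta, by = "id")
  }
  out
}

.count_one <- function(seq, id, frame_policy) {
  n <- nchar(seq)
  if (n %% 3 != 0) {
    if (frame_policy == "strict") {
      abort(paste0(
        "sequence '", id, "' has length ", n,
        " not divisible by 3 (use frame_policy = \"trim\" to drop the tail)"
      ))
    }
    seq <- substr(seq, 1, n - n %% 3)
    n <- nchar(seq)
  }
  if (n < 3) abort(paste0("sequence '", id, "' has no complete codon"))
  cods <- substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  is_stop <- cods %in% .stop_codons
  if (any(is_stop[-length(cods)])) {
    pos <- which(is_stop[-length(cods)])[1]
    abort(paste0(
      "internal stop codon ", cods[pos], " at codon ", pos, " of '", id,
      "': sequence is out of frame or pseudogenized"
    ))
  }
  # a single terminal stop is tolerated and dropped
  if (is_stop[length(cods)]) cods <- cods[-length(cods)]
  tab <- table(factor(cods, levels = codon_order()))
  as.integer(tab)
}

#' Tally in-frame codon usage for each coding sequence
#'
#' Splits each sequence into consecutive codons and counts them over the 59
#' analyzable codons ([genetic_code()]); `ATG`, `TGG` and stop codons are
#' excluded from the tally (and from `n_total`). A single terminal stop codon
#' is silently dropped; an internal stop is an error reporting its position,
#' since the inputs are expected to be complete ORFs. The tally is identical
#' whether the input is spelled with `T` or `U`.
#'
#' @param cds A tibble with columns `id` and `sequence` (as from [read_cds()]
#'   or [simulate_cohort()]); other columns (`host`, `region`, `group`, ...)
#'   are carried through.
#' @param frame_policy `"strict"` (default; length must be divisible by 3) or
#'   `"trim"` (drop trailing incomplete codon).
#' @return A long tibble with one row per sequence x analyzable codon:
#'   columns `id`, `codon`, `amino_acid`, `count`, plus carried metadata.
#' @examples
#' cds <- tibble::tibble(id = "x", sequence = "ATGTTTTAA")
#' counts <- count_codons(cds)
#' counts[counts$count > 0, ]  # one Phe codon; Met and the stop are excluded
#' @export
count_codons <- function(cds, frame_policy = c("strict", "trim")) {
  frame_policy <- match.arg(frame_policy)
  stopifnot(is.data.frame(cds), all(c("id", "sequence") %in% names(cds)))
  seqs <- toupper(chartr("Uu", "Tt", cds$sequence))
  code <- genetic_code()
  meta_cols <- setdiff(names(cds), c("sequence"))
  counts <- map2(seqs, cds$id, .count_one, frame_policy = frame_policy)
  out <- tibble::tibble(
    id = rep(cds$id, each = nrow(code)),
    codon = rep(code$codon, length(seqs)),
    amino_acid = rep(code$amino_acid, length(seqs)),
    count = unlist(counts)
  )
  meta <- cds[, meta_cols, drop = FALSE]
  if (ncol(meta) > 1) out <- dplyr::left_join(out, meta, by = "id")
  out
}

#' Pool codon tallies across sequences
#'
#' Sums codon counts elementwise, either over everything (one pooled tally
#' with `id = "pooled"`) or within groups of a metadata column, e.g. per
#' region or per host. Pooling is associative and commutative, and total
#' codon counts are additive.
#'
#' @param counts A codon-count tibble from [count_codons()].
#' @param by Optional column name(s) to pool within (e.g. `"region"`).
#' @param id Label used for the pooled `id` when `by` is `NULL`.
#' @return A codon-count tibble with one row per (group x) codon.
#' @export
pool_codons <- function(counts, by = NULL, id = "pooled") {
  stopifnot(is.data.frame(counts), nrow(counts) > 0)
  if (is.null(by)) {
    out <- counts |>
      dplyr::group_by(.data$codon, .data$amino_acid) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(id = id, .before = 1)
  } else {
    out <- counts |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$codon, .data$amino_acid) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(id = do.call(paste, c(dplyr::pick(dplyr::all_of(by)), sep = "/")), .before = 1)
  }
  dplyr::arrange(out, .data$id, match(.data$codon, codon_order()))
}

# wide count matrix, sequences x 59 codons in canonical order
.count_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(
    counts[, c("id", "codon", "count")],
    names_from = "codon", values_from = "count", values_fill = 0L
  )
  m <- as.matrix(wide[, codon_order(), drop = FALSE])
  rownames(m) <- wide$id
  m
}

# per-sequence metadata (one row per id) recovered from a long counts tibble
.counts_meta <- function(counts) {
  meta_cols <- setdiff(names(counts), c("codon", "amino_acid", "count"))
  dplyr::distinct(counts[, meta_cols, drop = FALSE], .data$id, .keep_all = TRUE)
}
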