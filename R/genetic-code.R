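# Canonical 59-codon table. Built once at load from the standard genetic code:
# Met (ATG), Trp (TGG) and the three stops are the "non-bias" codons -- they
# admit no synonymous choice, so every codon-usage statistic in the package
# excludes them. What remains is 18 amino acids in synonymous families of
# degeneracy 2 (x9), 3 (x1, Ile), 4 (x5) and 6 (x3).

.build_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  tab <- tibble::tibble(codon = names(gc), amino_acid = unname(gc))
  tab <- tab[!tab$amino_acid %in% c("*", "M", "W"), ]
  deg <- table(tab$amino_acid)
  tab$degeneracy <- as.integer(deg[tab$amino_acid])
  # family order: amino-acid symbol alphabetical; codons lexicographic within
  tab <- tab[order(tab$amino_acid, tab$codon), ]
  tab$third_base <- substr(tab$codon, 3, 3)
  tab
}

.codon_env <- new.env(parent = emptyenv())

.code_table <- function() {
  if (is.null(.codon_env$table)) {
    tab <- .build_genetic_code()
    .codon_env$table <- tab
    .codon_env$order <- tab$codon
    # per-position base indicator matrices (4 x 59) for composition stats
    bases <- c("A", "C", "G", "T")
    for (p in 1:3) {
      m <- sapply(tab$codon, function(cd) bases == substr(cd, p, p))
      rownames(m) <- bases
      .codon_env[[paste0("pos", p)]] <- m * 1
    }
  }
  .codon_env$table
}

#' The 59 analyzable codons of the standard genetic code
#'
#' Returns the fixed codon table used throughout the package: the 64 standard
#' codons minus the five non-bias codons (the three stop codons plus `ATG`
#' and `TGG`, the sole codons for Met and Trp). The remaining 59 codons encode
#' 18 amino acids in synonymous families of degeneracy 2, 3, 4 or 6. The row
#' order (amino acids alphabetically, codons lexicographically within each
#' family) is the canonical `codon_order` that all RSCU vectors, PCA loadings
#' and SiD inner products follow, so results are reproducible across runs.
#'
#' @param alphabet `"dna"` (default, codons spelled with `T`) or `"rna"`
#'   (spelled with `U`) for display. Internally everything is keyed on DNA.
#' @return A tibble with columns `codon`, `amino_acid` (1-letter symbol),
#'   `degeneracy` (family size, in `{2, 3, 4, 6}`) and `third_base`.
#' @examples
#' genetic_code()
#' table(genetic_code()$degeneracy)
#' @export
genetic_code <- function(alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  tab <- tibble::as_tibble(.code_table())
  if (alphabet == "rna") {
    tab$codon <- chartr("T", "U", tab$codon)
    tab$third_base <- chartr("T", "U", tab$third_base)
  }
  tab
}

#' @rdname genetic_code
#' @details `codon_order()` returns just the 59 codon strings in canonical
#'   order; `excluded_codons()` returns the five non-bias codons.
#' @export
codon_order <- function(alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  .code_table()
  out <- .codon_env$order
  if (alphabet == "rna") out <- chartr("T", "U", out)
  out
}

#' @rdname genetic_code
#' @export
excluded_codons <- function(alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  out <- c("TAA", "TAG", "TGA", "ATG", "TGG")
  if (alphabet == "rna") out <- chartr("T", "U", out)
  out
}

.stop_codons <- c("TAA", "TAG", "TGA")

# position-base indicator matrix, bases x 59
.pos_matrix <- function(p) {
  .code_table()
  .codon_env[[paste0("pos", p)]]
}
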