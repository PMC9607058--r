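# Fixture builders: codon-count tibbles constructed directly, bypassing
# sequence parsing, so statistics can be checked against hand arithmetic.

make_counts <- function(counts, id = "fixture") {
  code <- genetic_code()
  tibble::tibble(
    id = id,
    codon = code$codon,
    amino_acid = code$amino_acid,
    count = as.integer(ifelse(code$codon %in% names(counts),
                              counts[code$codon], 0))
  )
}

# equal count for every one of the 59 codons
uniform_counts <- function(per_codon = 6L, id = "uniform") {
  code <- genetic_code()
  tibble::tibble(id = id, codon = code$codon,
                 amino_acid = code$amino_acid,
                 count = as.integer(per_codon))
}

# exactly one codon used per family (the first in canonical order)
one_codon_per_family_counts <- function(count = 4L, id = "biased") {
  code <- genetic_code()
  first <- vapply(split(code$codon, code$amino_acid), `[`, "", 1)
  tibble::tibble(id = id, codon = code$codon,
                 amino_acid = code$amino_acid,
                 count = as.integer(ifelse(code$codon %in% first, count, 0)))
}

# random tally over all 59 codons (counts 0..max_count)
random_counts <- function(id = "rand", max_count = 20) {
  code <- genetic_code()
  tibble::tibble(id = id, codon = code$codon,
                 amino_acid = code$amino_acid,
                 count = sample(0:max_count, 59, replace = TRUE))
}

# independent brute-force ENC oracle: literal evaluation of Wright's
# formulas over a named count vector, no package code paths involved
oracle_enc <- function(counts) {
  code <- genetic_code()
  fams <- split(counts[code$codon], code$amino_acid)
  f_by_k <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (fam in fams) {
    n <- sum(fam)
    if (n < 2) next
    s <- sum((fam / n)^2)
    f <- (n * s - 1) / (n - 1)
    if (f <= 0) next
    k <- as.character(length(fam))
    f_by_k[[k]] <- c(f_by_k[[k]], f)
  }
  fb <- vapply(f_by_k, mean, numeric(1))
  2 + 9 / fb[["2"]] + 1 / fb[["3"]] + 5 / fb[["4"]] + 3 / fb[["6"]]
}
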