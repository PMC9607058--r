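test_that("read_cds normalizes the alphabet and joins metadata", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc", "AUGUUUGCAUAA", ">b", "ATGCCNTAA", ">c",
               "atgggttaa"), fa)
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\thost\tregion\tgroup",
               "a\tBrassica oleracea\tCP\tG1"), meta)
  expect_message(res <- read_cds(fa, meta), "non-ACGT")
  expect_equal(res$id, c("a", "c"))            # b excluded whole (N)
  expect_equal(res$sequence[1], "ATGTTTGCATAA") # U -> T, uppercased
  expect_equal(res$host[1], "Brassica oleracea")
  expect_true(is.na(res$host[2]))
  expect_error(read_cds(withr::local_tempfile(fileext = ".fa")), "not found")
})

test_that("codon tallies exclude non-bias codons and tolerate one terminal stop", {
  counts <- count_codons(tibble::tibble(id = "x", sequence = "ATGTTTTAA"))
  expect_equal(counts$count[counts$codon == "TTT"], 1L)
  expect_equal(sum(counts$count), 1L)  # Met and the terminal stop excluded

  counts2 <- count_codons(tibble::tibble(id = "y", sequence = "GCAGCAGCTTGG"))
  expect_equal(counts2$count[counts2$codon == "GCA"], 2L)
  expect_equal(counts2$count[counts2$codon == "GCT"], 1L)
  expect_equal(sum(counts2$count), 3L)  # Trp excluded
})

test_that("frame violations are hard errors with position reporting", {
  expect_error(
    count_codons(tibble::tibble(id = "z", sequence = "TTTTAAGGG")),
    "internal stop codon TAA at codon 2"
  )
  expect_error(
    count_codons(tibble::tibble(id = "w", sequence = "TTTT")),
    "not divisible by 3"
  )
  trimmed <- count_codons(tibble::tibble(id = "w", sequence = "TTTT"),
                          frame_policy = "trim")
  expect_equal(sum(trimmed$count), 1L)
})

test_that("tallies are invariant under U/T spelling and satisfy the length identity", {
  seq_t <- "ATGGCATTTTGGCATTAA"
  seq_u <- chartr("T", "U", seq_t)
  ct <- count_codons(tibble::tibble(id = "s", sequence = seq_t))
  cu <- count_codons(tibble::tibble(id = "s", sequence = seq_u))
  expect_equal(ct, cu)
  # sum(analyzable) + #ATG + #TGG + terminal stop = length / 3
  expect_equal(sum(ct$count) + 1 + 1 + 1, nchar(seq_t) / 3)
})

test_that("pooling is additive, commutative, associative, with identity on singletons", {
  set.seed(7)
  a <- random_counts("a")
  b <- random_counts("b")
  c3 <- random_counts("c")
  all3 <- dplyr::bind_rows(a, b, c3)
  pooled <- pool_codons(all3)
  expect_equal(sum(pooled$count), sum(a$count) + sum(b$count) + sum(c3$count))
  expect_equal(pooled$count,
               pool_codons(dplyr::bind_rows(c3, b, a))$count)
  ab_then_c <- pool_codons(dplyr::bind_rows(
    pool_codons(dplyr::bind_rows(a, b), id = "ab"), c3))
  expect_equal(ab_then_c$count, pooled$count)
  expect_equal(pool_codons(a)$count, a$count[order(match(a$codon, codon_order()))])
  # pooling by a metadata column
  all3$region <- c(rep("P1", 59), rep("CP", 59), rep("P1", 59))
  by_region <- pool_codons(all3, by = "region")
  expect_equal(sum(by_region$count[by_region$region == "P1"]),
               sum(a$count) + sum(c3$count))
})
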