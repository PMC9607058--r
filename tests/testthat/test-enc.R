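test_that("family homozygosity follows Wright's formulas", {
  expect_equal(family_homozygosity(c(TTT = 2, TTC = 2)), 1 / 3)  # S = 0.5
  expect_equal(family_homozygosity(c(TTT = 4, TTC = 0)), 1)
  expect_true(is.na(family_homozygosity(c(TTT = 1))))
  expect_true(is.na(family_homozygosity(c(TTT = 0, TTC = 0))))
})

test_that("ENC hits 20 for one codon per family and approaches 61 for even usage", {
  res <- enc(one_codon_per_family_counts(count = 4))
  expect_equal(res$enc, 20)
  expect_true(res$significant_bias)

  even <- enc(uniform_counts(per_codon = 1e6))
  expect_equal(even$enc, 61, tolerance = 1e-5)
  expect_false(even$significant_bias)

  # monotone convergence toward 61 under uniform usage as counts double
  encs <- vapply(c(2, 4, 8, 16), function(n) enc(uniform_counts(n))$enc,
                 numeric(1))
  expect_true(all(diff(encs) >= 0))
  expect_true(all(encs <= 61))
})

test_that("ENC agrees with an independent brute-force oracle on fixed tallies", {
  # skewed counts in every family so each homozygosity is strictly positive
  code <- genetic_code()
  patterns <- list(`2` = c(3L, 1L), `3` = c(2L, 1L, 1L),
                   `4` = c(3L, 1L, 1L, 1L), `6` = c(3L, 2L, 1L, 1L, 1L, 0L))
  counts <- code |>
    dplyr::group_by(amino_acid) |>
    dplyr::mutate(count = patterns[[as.character(dplyr::n())]]) |>
    dplyr::ungroup() |>
    dplyr::mutate(id = "mixed") |>
    dplyr::select(id, codon, amino_acid, count)
  got <- enc(counts)$enc_raw
  want <- oracle_enc(setNames(counts$count, counts$codon))
  expect_equal(got, unname(want), tolerance = 1e-12)
  # and on random tallies
  set.seed(5)
  for (rep in 1:5) {
    rc <- random_counts(max_count = 30)
    expect_equal(enc(rc)$enc_raw,
                 unname(oracle_enc(setNames(rc$count, rc$codon))),
                 tolerance = 1e-12)
  }
})

test_that("small uniform families with zero homozygosity leave their class unusable", {
  # uniform usage at minimal counts drives F to 0 in the 4- and 6-fold
  # classes; such families cannot contribute and the sequence gets a
  # flagged NA rather than an infinite ENC
  res <- enc(uniform_counts(1L))
  expect_true(is.na(res$enc))
  expect_match(res$note, "no usable family")
})

test_that("raw ENC above 61 is clamped with the raw value retained", {
  res <- enc(uniform_counts(per_codon = 2))
  expect_true(res$enc_raw > 61)
  expect_equal(res$enc, 61)
})

test_that("a missing Ile family falls back to (F2 + F4)/2; other classes do not", {
  counts <- one_codon_per_family_counts()
  no_ile <- dplyr::mutate(counts,
                          count = ifelse(amino_acid == "I", 0L, count))
  res <- enc(no_ile)
  expect_equal(res$enc, 20)  # F2 = F4 = 1, so the fallback F3 = 1 too
  expect_match(res$note, "F3 estimated")

  only_ile_missing_class <- dplyr::mutate(
    counts, count = ifelse(amino_acid %in% c("L", "R", "S"), 0L, count)
  )
  res2 <- enc(only_ile_missing_class)
  expect_true(is.na(res2$enc))
  expect_match(res2$note, "F6")
})

test_that("the expected-ENC curve evaluates exactly and obeys its reflection identity", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s), expected_enc(1 - s) + (2 * s - 1),
               tolerance = 1e-12)
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
})

test_that("ENC-plot residuals separate mutation-only from selection cohorts", {
  mut <- simulate_cohort(30, 600, regime = "mutation_only", theta_gc = 0.5,
                         seed = 101)
  res_mut <- enc(count_codons(mut))
  expect_lt(abs(mean(res_mut$residual)), 1.5)

  sel <- simulate_cohort(30, 600, regime = "selection", beta = 2, seed = 102)
  res_sel <- enc(count_codons(sel))
  expect_lt(mean(res_sel$residual), -5)

  # single fully biased sequence: residual = 20 - expected_enc(gc3s)
  one <- enc(one_codon_per_family_counts())
  expect_equal(one$residual, 20 - expected_enc(one$gc3s / 100))
})
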