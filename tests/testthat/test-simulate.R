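test_that("cohorts are deterministic for a fixed seed, down to the FASTA bytes", {
  c1 <- simulate_cohort(4, 120, seed = 99)
  c2 <- simulate_cohort(4, 120, seed = 99)
  expect_identical(c1$sequence, c2$sequence)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- simulate_cohort(4, 120, seed = 100)
  expect_false(identical(c1$sequence, c3$sequence))
})

test_that("generated CDS are valid ORFs that round-trip through FASTA", {
  cohort <- simulate_cohort(5, 200, regime = "mutation_only", seed = 3)
  expect_true(all(nchar(cohort$sequence) %% 3 == 0))
  counts <- count_codons(cohort)  # would error on any internal stop
  expect_true(all(counts$count >= 0))

  fa <- withr::local_tempfile(fileext = ".fa")
  meta <- withr::local_tempfile(fileext = ".tsv")
  cohort$host <- "hostX"
  write_cohort(cohort, fa, meta)
  back <- read_cds(fa, meta)
  expect_equal(back$sequence, cohort$sequence)
  expect_equal(back$host, cohort$host)
})

test_that("mutation-only composition tracks theta at every codon position", {
  for (theta in c(0.2, 0.5, 0.8)) {
    cohort <- simulate_cohort(10, 1500, regime = "mutation_only",
                              theta_gc = theta, seed = 41)
    comp <- composition(count_codons(cohort))
    expect_equal(mean(comp$GC3s), 100 * theta, tolerance = 0.05)
    expect_equal(mean(comp$GC12), 100 * theta, tolerance = 0.08)
  }
  # boundary: theta = 0 means no G/C anywhere
  cohort0 <- simulate_cohort(2, 200, theta_gc = 0, seed = 5)
  expect_equal(composition(count_codons(cohort0))$GC3s, c(0, 0))
})

test_that("host-mimic pooled codon frequencies match the host table", {
  set.seed(47)
  tab <- random_counts("h", max_count = 30) |>
    dplyr::mutate(count = count + 1L)
  ref <- host_reference(tab, host_name = "h")
  cohort <- simulate_cohort(10, 2000, regime = "host_mimic",
                            host_ref = ref, lambda = 1, seed = 53)
  pooled <- pool_codons(count_codons(cohort))
  # chi-square goodness of fit within each family
  fams <- split(seq_len(59), pooled$amino_acid)
  pvals <- vapply(fams, function(idx) {
    obs <- pooled$count[idx]
    expd <- ref$freq[match(pooled$codon[idx], ref$codon)]
    suppressWarnings(stats::chisq.test(obs, p = expd)$p.value)
  }, numeric(1))
  expect_gt(min(pvals), 0.001 / length(pvals))

  # truth record: expected RSCU = k * p
  truth <- cohort_truth(cohort)
  r <- rscu(pooled)
  expect_equal(r$rscu, truth$expected_rscu$expected_rscu[
    match(r$codon, truth$expected_rscu$codon)], tolerance = 0.1)
})

test_that("truth records carry the analytic expectations per regime", {
  mut <- simulate_cohort(2, 100, theta_gc = 0.3, seed = 7)
  expect_equal(cohort_truth(mut)$expected_gc3s, 30)
  expect_equal(cohort_truth(mut)$expected_slope, 1)
  sel <- simulate_cohort(2, 100, regime = "selection", seed = 7)
  expect_equal(cohort_truth(sel)$expected_slope, 0)
  expect_equal(cohort_truth(sel)$expected_pct_selection, 100)
})

test_that("multi-region cohorts emit one record per region with study-like sizes", {
  sizes <- tumv_region_sizes()
  cohort <- simulate_cohort(2, sizes, seed = 11)
  expect_equal(nrow(cohort), 2 * length(sizes))
  expect_setequal(unique(cohort$region), names(sizes))
  lens <- nchar(cohort$sequence) / 3 - 1  # minus terminal stop
  expect_equal(lens, rep(unname(sizes), 2))
  # short regions (6K1/6K2/PIPO) can miss families yet must not crash ENC
  short <- count_codons(cohort[cohort$region == "6K1", ])
  expect_true(all(!is.na(enc(short)$enc) | !is.na(enc(short)$note)))
})

test_that("infeasible profiles are rejected", {
  expect_error(simulate_cohort(1, 10, amino_acid_profile = c(A = 0), seed = 1),
               "profile")
  expect_error(simulate_cohort(1, 10, regime = "host_mimic", seed = 1),
               "host_ref")
})
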