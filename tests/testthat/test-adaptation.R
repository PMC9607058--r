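toy_ref <- function(pseudocount = 0) {
  # complete families so no pseudocount path is triggered by default
  counts <- dplyr::mutate(
    uniform_counts(2L, id = "host"),
    count = ifelse(codon == "GCA", 6L, count)
  )
  host_reference(counts, host_name = "toy", pseudocount = pseudocount)
}

test_that("host reference weights follow the Sharp-Li definition", {
  ref <- host_reference(
    tibble::tibble(codon = c("GCA", "GCT"), count = c(3, 1)),
    host_name = "h", pseudocount = 0
  )
  ala <- ref[ref$amino_acid == "A", ]
  expect_equal(ala$w[ala$codon == "GCA"], 1)
  expect_equal(ala$w[ala$codon == "GCT"], 1 / 3)
  expect_equal(ala$freq[ala$codon == "GCA"], 0.75)
  # observed families: within-family freq sums to 1, max w = 1
  defined <- ref[!is.na(ref$w), ]
  expect_equal(max(defined$w), 1)
  expect_equal(sum(defined$freq), 1)

  uniform_ref <- host_reference(uniform_counts(3L), host_name = "u")
  expect_equal(uniform_ref$w, rep(1, 59))
})

test_that("usage-table and FASTA inputs build identical references", {
  cds <- tibble::tibble(id = "h1", sequence = "ATGGCAGCAGCTTTTTAA")
  from_fasta <- host_reference(cds, host_name = "h")
  tab <- tibble::tibble(codon = c("GCA", "GCT", "TTT"), count = c(2, 1, 1))
  from_table <- host_reference(tab, host_name = "h")
  expect_equal(from_fasta$w, from_table$w)
  expect_equal(from_fasta$freq, from_table$freq)
})

test_that("families containing zeros get the pseudocount; zero-total families stay NA", {
  ref <- host_reference(
    tibble::tibble(codon = c("GCA", "GCT"), count = c(3, 1)),
    host_name = "h", pseudocount = 0.5
  )
  ala <- ref[ref$amino_acid == "A", ]
  expect_equal(ala$count[ala$codon == "GCC"], 0.5)
  expect_equal(ala$freq[ala$codon == "GCA"], 3.5 / 6)
  expect_true(all(is.na(ref$w[ref$amino_acid == "F"])))
})

test_that("CAI fixed points: all-preferred query scores 1; constant weight is returned", {
  ref <- toy_ref()  # GCA is the unique Ala maximum, all other families even
  all_gca <- make_counts(c(GCA = 10), id = "q")
  expect_equal(cai(all_gca, ref)$cai, 1)

  # all-GCT query against w(GCT) = 1/3: geometric mean of a constant
  ref13 <- host_reference(
    tibble::tibble(codon = c("GCA", "GCT", "GCC", "GCG"),
                   count = c(3, 1, 1, 1)),
    host_name = "h"
  )
  expect_equal(cai(make_counts(c(GCT = 7), id = "q"), ref13)$cai, 1 / 3)

  # duplication invariance
  q <- make_counts(c(GCA = 3, GCT = 2, TTT = 4), id = "q")
  q2 <- dplyr::mutate(q, count = count * 2L)
  expect_equal(cai(q, ref)$cai, cai(q2, ref)$cai)
  expect_error(cai(make_counts(c(), id = "q"), ref), "no scorable|no analyzable")
})

test_that("RCDI fixed points and lower bound", {
  ref <- toy_ref()
  # query proportional to the host usage -> RCDI exactly 1
  host_counts <- dplyr::mutate(tibble::as_tibble(toy_ref()),
                               id = "q", count = count * 3)
  expect_equal(rcdi(host_counts[, c("id", "codon", "amino_acid", "count")],
                    ref)$rcdi, 1)

  # one codon per family where the host splits 50/50 -> RCDI = 2
  ref5050 <- host_reference(
    tibble::tibble(codon = c("TTT", "TTC"), count = c(5, 5)),
    host_name = "h", pseudocount = 0
  )
  expect_equal(rcdi(make_counts(c(TTT = 8), id = "q"), ref5050)$rcdi, 2)

  # RCDI >= 1 for random small count tables against random references
  set.seed(17)
  for (rep in 1:50) {
    ref_r <- host_reference(random_counts(max_count = 9), host_name = "r")
    q <- random_counts(id = "q", max_count = 9)
    if (sum(q$count) == 0) next
    expect_gte(rcdi(q, ref_r)$rcdi, 1 - 1e-12)
  }
})

test_that("SiD fixed points, symmetry and bounds", {
  r1 <- rscu(make_counts(c(GCA = 3, GCT = 1, TTT = 2), id = "a"))
  expect_equal(sid(r1, dplyr::mutate(r1, id = "b"))$sid_d, 0)

  # disjoint support within shared defined families -> cosine 0, D = 0.5
  a <- rscu(make_counts(c(GCA = 4, TTT = 4), id = "a"))
  b <- dplyr::mutate(rscu(make_counts(c(GCC = 4, TTC = 4), id = "b")), id = "b")
  expect_equal(sid(a, b)$sid_r, 0)
  expect_equal(sid(a, b)$sid_d, 0.5)

  set.seed(19)
  for (rep in 1:20) {
    x <- rscu(random_counts("x"))
    y <- dplyr::mutate(rscu(random_counts("y")), id = "y")
    rxy <- sid(x, y)
    ryx <- sid(dplyr::mutate(y, id = "y2"),
               dplyr::mutate(x, id = "x2"))
    expect_equal(rxy$sid_r, ryx$sid_r, tolerance = 1e-12)
    expect_gte(rxy$sid_d, 0)
    expect_lte(rxy$sid_d, 1)
  }
})

test_that("a host reference scored against itself hits the RCDI and SiD fixed points", {
  ref <- toy_ref()
  self_counts <- dplyr::mutate(tibble::as_tibble(ref), id = "self")[,
    c("id", "codon", "amino_acid", "count")]
  expect_equal(rcdi(self_counts, ref)$rcdi, 1)
  expect_equal(sid(rscu(self_counts), ref)$sid_d, 0, tolerance = 1e-12)
  expect_lt(cai(self_counts, ref)$cai, 1)  # own usage is not one-codon-per-family
})

test_that("adaptation_scan ranks the generating host best on synthetic cohorts", {
  set.seed(23)
  gen_tab <- random_counts("gen", max_count = 30) |>
    dplyr::mutate(count = count + 1L)  # complete families
  other_tab <- dplyr::mutate(gen_tab, count = rev(count))
  gen_ref <- host_reference(gen_tab, host_name = "generating")
  other_ref <- host_reference(other_tab, host_name = "other")

  cohort <- simulate_cohort(8, 800, regime = "host_mimic",
                            host_ref = gen_ref, lambda = 1, seed = 31)
  scan <- adaptation_scan(count_codons(cohort), list(gen_ref, other_ref))
  by_host <- scan |>
    dplyr::group_by(host_ref) |>
    dplyr::summarise(cai = mean(cai), rcdi = mean(rcdi), sid_d = mean(sid_d))
  gen <- by_host[by_host$host_ref == "generating", ]
  oth <- by_host[by_host$host_ref == "other", ]
  expect_gt(gen$cai, oth$cai)
  expect_lt(gen$rcdi, oth$rcdi)
  expect_lt(gen$sid_d, oth$sid_d)
  expect_equal(gen$rcdi, 1, tolerance = 0.05)
  expect_equal(nrow(scan), 16)
})
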