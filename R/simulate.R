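# Synthetic coding-sequence cohorts with known generating structure. Three
# regimes cover the forces the analysis pipeline is meant to detect:
#   mutation_only - bases independent within a codon, position weights
#     calibrated so the analyzable-codon pool has GC content theta at all
#     three positions; the neutrality slope is 1 in expectation and points
#     sit on the ENC curve.
#   selection     - amino acids drawn from a fixed profile (so GC12 is
#     essentially constant), synonymous codon choice skewed toward one
#     preferred codon per family (strength beta) and toward a per-sequence
#     third-position GC level; GC3 varies while GC12 does not (slope ~ 0)
#     and ENC drops below the mutation-only curve.
#   host_mimic    - codons sampled from lambda * host within-family
#     frequencies + (1 - lambda) * uniform, for host-adaptation ground truth
#     (expected RSCU = k * p).

.derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1009L) * 1000003L + as.integer(index) * 7919L
}

# Mutation-only codon distribution. Bases are independent within a codon
# under a product measure over the 62 non-stop codons, but naive
# per-position GC weights equal to theta would NOT give measured GC
# contents of theta: conditioning on "not a stop" and excluding ATG/TGG
# from the tally both shift the per-position GC of the analyzable pool
# (the five removed codons are AT-rich at position 1 and unbalanced at 2
# and 3). The position weights are therefore calibrated by iterative
# proportional fitting so that the GC content of the analyzable 59-codon
# pool equals theta at every position -- which is what "the same
# mutational GC pressure acting at all three positions" means for the
# statistics this package measures, and what makes the expected
# neutrality slope exactly 1 and expected GC3s exactly 100 * theta.
.mutation_codon_probs <- function(theta) {
  code <- genetic_code()
  cods <- c(code$codon, "ATG", "TGG")
  pos_base <- lapply(1:3, function(k) substr(cods, k, k))
  pos_gc <- lapply(pos_base, function(b) b %in% c("G", "C"))
  analyzable <- cods %in% code$codon
  w_gc <- rep(theta, 3)
  for (it in 1:200) {
    p <- rep(1, length(cods))
    for (k in 1:3) {
      p <- p * ifelse(pos_gc[[k]], w_gc[k] / 2, (1 - w_gc[k]) / 2)
    }
    p <- p / sum(p)
    p59 <- p[analyzable] / sum(p[analyzable])
    m <- vapply(1:3, function(k) sum(p59 * pos_gc[[k]][analyzable]),
                numeric(1))
    if (theta == 0 || theta == 1 || max(abs(m - theta)) < 1e-12) break
    # odds update toward the target marginal at each position
    odds <- (w_gc / (1 - w_gc)) * (theta / (1 - theta)) / (m / (1 - m))
    w_gc <- odds / (1 + odds)
  }
  setNames(p, cods)
}

.sample_mutation_only <- function(n_codons, theta) {
  p <- .mutation_codon_probs(theta)
  sample(names(p), n_codons, replace = TRUE, prob = p)
}

# Selection-regime codon probabilities. Within each family, codons are
# grouped into blocks sharing their first two bases (six-fold families span
# two blocks; all others are a single block). The block is chosen with a
# probability that depends only on the preference weights exp(beta * pref),
# and the per-sequence third-position GC level gc3 reweights codons only
# WITHIN a block. First/second-position composition is therefore
# statistically independent of gc3 -- GC12 stays flat while GC3 varies,
# which is what "selection acting on synonymous third positions only" means
# for the neutrality plot.
.selection_codon_prob <- function(code, preferred, beta, gc3) {
  w_pref <- ifelse(code$codon %in% preferred, exp(beta), 1)
  w_gc3 <- ifelse(code$third_base %in% c("G", "C"), gc3, 1 - gc3)
  block <- paste(code$amino_acid, substr(code$codon, 1, 2))
  block_w <- tapply(w_pref, block, sum)          # theta-independent
  within_w <- w_pref * w_gc3
  within_tot <- tapply(within_w, block, sum)
  one_per_block <- !duplicated(block)
  fam_tot <- tapply(as.vector(block_w[block[one_per_block]]),
                    code$amino_acid[one_per_block], sum)
  # p(codon) = p(block | family) * p(codon | block)
  p <- as.vector(block_w[block]) / as.vector(fam_tot[code$amino_acid]) *
    within_w / as.vector(within_tot[block])
  setNames(p, code$codon)
}

.sample_by_family <- function(n_codons, aa_profile, codon_prob) {
  code <- genetic_code()
  aas <- sample(names(aa_profile), n_codons, replace = TRUE,
                prob = aa_profile)
  cod <- character(n_codons)
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    fam <- code$codon[code$amino_acid == aa]
    pr <- codon_prob[fam]
    cod[idx] <- sample(fam, length(idx), replace = TRUE, prob = pr)
  }
  cod
}

#' Generate a synthetic coding-sequence cohort with known structure
#'
#' Emits complete in-frame CDS records (with a terminal `TAA` stop) under one
#' of three generating regimes, providing ground truth for every statistic
#' in the package. Generation is deterministic for a fixed `seed`; each
#' sequence uses a substream derived from `(seed, index)`, so cohorts are
#' reproducible record-by-record.
#'
#' Regimes:
#' * `"mutation_only"`: bases independent within each codon under a
#'   product measure over the non-stop codons, with per-position GC weights
#'   calibrated so the analyzable-codon pool has GC content exactly
#'   `theta_gc` at every position (G/C and A/T split evenly). Expected GC3s
#'   is `100 * theta_gc` and the expected neutrality slope across sequences
#'   with varying `theta_gc` is 1.
#' * `"selection"`: amino acids from `amino_acid_profile` (default uniform
#'   over the 18 analyzable amino acids, which maximizes family coverage in
#'   short genes); within each family, codon weights multiply a preference
#'   factor `exp(beta)` for the family's preferred codon by a third-position
#'   factor favoring GC with per-sequence probability drawn uniformly from
#'   `gc3_range`. GC12 stays near-constant while GC3 varies (neutrality
#'   slope about 0) and ENC falls below the mutation-only expectation.
#' * `"host_mimic"`: codons drawn from `lambda * host_freq + (1 - lambda) *
#'   uniform` within each family, where `host_freq` comes from a
#'   [host_reference()]; amino acids from `amino_acid_profile`.
#'
#' @param n_sequences Number of sequences.
#' @param n_codons Codons per sequence (before the terminal stop). Either a
#'   single number or a named vector of region sizes (one record per
#'   sequence x region); [tumv_region_sizes()] gives sizes emulating a
#'   potyvirus genome.
#' @param regime `"mutation_only"`, `"selection"` or `"host_mimic"`.
#' @param theta_gc GC probability per base for `mutation_only`. A single
#'   value, or a length-2 range from which each sequence's value is drawn
#'   uniformly (the design used for neutrality-plot cohorts).
#' @param beta Preference strength for `selection` (log-weight of each
#'   family's preferred codon; 0 = no preference). Default 1.
#' @param preferred Named character vector mapping amino acid to its
#'   preferred codon for `selection`; default: the first codon of each
#'   family in [codon_order()].
#' @param gc3_range Range of the per-sequence third-position GC level for
#'   `selection` (default `c(0.3, 0.7)`).
#' @param host_ref A [host_reference()] for `host_mimic`.
#' @param lambda Mixing weight toward the host frequencies (default 1).
#' @param amino_acid_profile Named numeric vector of amino-acid frequencies
#'   (defaults to uniform over the 18 analyzable amino acids).
#' @param seed Integer seed governing the whole cohort.
#' @param host,group Optional metadata labels stamped on every record.
#' @return A tibble `id`, `sequence`, `host`, `region`, `group` ready for
#'   [count_codons()], with attribute `"truth"` (see [cohort_truth()])
#'   recording the generating parameters and the analytic expectations they
#'   imply.
#' @examples
#' cohort <- simulate_cohort(5, 300, regime = "mutation_only",
#'                           theta_gc = 0.5, seed = 1)
#' composition(count_codons(cohort))$GC3s  # near 50
#' @export
simulate_cohort <- function(n_sequences, n_codons = 3000,
                            regime = c("mutation_only", "selection",
                                       "host_mimic"),
                            theta_gc = 0.5, beta = 1, preferred = NULL,
                            gc3_range = c(0.3, 0.7), host_ref = NULL,
                            lambda = 1, amino_acid_profile = NULL,
                            seed = 1, host = NA_character_,
                            group = NA_character_) {
  regime <- match.arg(regime)
  stopifnot(n_sequences >= 1, all(n_codons >= 1))
  if (length(n_codons) > 1 && is.null(names(n_codons))) {
    abort("a multi-element n_codons must be a named region-size vector")
  }
  regions <- if (is.null(names(n_codons))) {
    c(polyprotein = unname(n_codons))
  } else {
    n_codons
  }

  code <- genetic_code()
  if (is.null(amino_acid_profile)) {
    aas <- unique(code$amino_acid)
    amino_acid_profile <- setNames(rep(1 / length(aas), length(aas)), aas)
  }
  if (any(amino_acid_profile < 0) || sum(amino_acid_profile) <= 0) {
    abort("amino_acid_profile must be non-negative with positive sum")
  }
  amino_acid_profile <- amino_acid_profile / sum(amino_acid_profile)
  if (all(amino_acid_profile == 0)) abort("infeasible amino-acid profile")

  if (regime == "selection") {
    if (is.null(preferred)) {
      preferred <- vapply(split(code$codon, code$amino_acid), `[`, "", 1)
    }
    stopifnot(length(theta_gc) %in% 1:2, length(gc3_range) == 2)
  }
  if (regime == "host_mimic") {
    if (is.null(host_ref)) abort("host_mimic regime needs host_ref")
    .check_ref(host_ref)
    stopifnot(lambda >= 0, lambda <= 1)
    hfreq <- setNames(host_ref$freq, host_ref$codon)
  }
  if (regime == "mutation_only") {
    stopifnot(length(theta_gc) %in% 1:2,
              all(theta_gc >= 0), all(theta_gc <= 1))
  }

  rows <- list()
  truth_theta <- numeric(0)
  i_row <- 0
  for (i in seq_len(n_sequences)) {
    set.seed(.derive_seed(seed, i))
    theta_i <- if (length(theta_gc) == 2) {
      runif(1, theta_gc[1], theta_gc[2])
    } else {
      theta_gc
    }
    gc3_i <- runif(1, gc3_range[1], gc3_range[2])
    truth_theta <- c(truth_theta, theta_i)
    for (rg in names(regions)) {
      nc <- regions[[rg]]
      cod <- switch(regime,
        mutation_only = .sample_mutation_only(nc, theta_i),
        selection = .sample_by_family(
          nc, amino_acid_profile,
          .selection_codon_prob(code, preferred, beta, gc3_i)
        ),
        host_mimic = {
          k <- code$degeneracy
          p <- lambda * hfreq[code$codon] + (1 - lambda) / k
          p[is.na(p)] <- 1 / k[is.na(p)]
          .sample_by_family(nc, amino_acid_profile,
                            setNames(p, code$codon))
        }
      )
      i_row <- i_row + 1
      rows[[i_row]] <- tibble::tibble(
        id = sprintf("seq%03d_%s", i, rg),
        sequence = paste0(paste(cod, collapse = ""), "TAA"),
        host = host, region = rg, group = group
      )
    }
  }
  out <- list_rbind(rows)

  truth <- list(
    regime = regime, seed = seed, n_sequences = n_sequences,
    regions = regions,
    theta_gc = if (regime == "mutation_only") truth_theta else NULL,
    expected_gc3s = if (regime == "mutation_only" && length(theta_gc) == 1) {
      100 * theta_gc
    } else {
      NULL
    },
    expected_slope = switch(regime, mutation_only = 1, selection = 0, NULL),
    expected_pct_selection = switch(regime, mutation_only = 0,
                                    selection = 100, NULL),
    expected_rscu = if (regime == "host_mimic") {
      k <- code$degeneracy
      p <- lambda * hfreq[code$codon] + (1 - lambda) / k
      p[is.na(p)] <- 1 / k[is.na(p)]
      tibble::tibble(codon = code$codon, expected_rscu = unname(k * p))
    } else {
      NULL
    },
    beta = if (regime == "selection") beta else NULL,
    lambda = if (regime == "host_mimic") lambda else NULL,
    host_name = if (regime == "host_mimic") attr(host_ref, "host_name") else NULL
  )
  attr(out, "truth") <- truth
  out
}

#' Ground-truth record of a synthetic cohort
#'
#' Returns the generating parameters of a [simulate_cohort()] result
#' together with the analytic expectations they imply (expected GC3s under
#' mutation only; expected neutrality slope per regime; expected RSCU
#' `k * p` under host mimicry), for consumption by test harnesses.
#'
#' @param cohort A tibble produced by [simulate_cohort()].
#' @return A named list.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) abort("cohort carries no truth record")
  truth
}

#' Region sizes emulating a potyvirus genome
#'
#' Approximate codon counts of the turnip mosaic virus polyprotein and its
#' mature protein regions plus PIPO, for generating study-shaped cohorts:
#' the polyprotein is about 3100 codons and the shortest regions (6K1, 6K2,
#' PIPO) are around 50–60 codons, which is what makes undefined RSCU
#' families and the ENC fallback paths worth exercising.
#'
#' @return A named integer vector of codons per region.
#' @export
tumv_region_sizes <- function() {
  c(P1 = 362L, `HC-Pro` = 458L, P3 = 355L, `6K1` = 52L, CI = 644L,
    `6K2` = 53L, VPg = 192L, NIa = 242L, NIb = 518L, CP = 288L,
    PIPO = 60L, polyprotein = 3100L)
}

#' Write a cohort as FASTA plus metadata TSV
#'
#' Serializes a sequence tibble to a standard multi-record FASTA file and a
#' tab-separated metadata table (`id`, `host`, `region`, `group`) that
#' [read_cds()] can round-trip.
#'
#' @param cohort A tibble with `id` and `sequence` columns.
#' @param fasta_path,metadata_path Output file paths (metadata optional).
#' @return `fasta_path`, invisibly.
#' @export
write_cohort <- function(cohort, fasta_path, metadata_path = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(cohort)))
  writeLines(
    paste0(">", cohort$id, "\n", cohort$sequence),
    fasta_path
  )
  if (!is.null(metadata_path)) {
    meta <- cohort[, intersect(c("id", "host", "region", "group"),
                               names(cohort)), drop = FALSE]
    readr::write_tsv(meta, metadata_path)
  }
  invisible(fasta_path)
}
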