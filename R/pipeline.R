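#' Run the full codon-usage analysis end-to-end
#'
#' Chains every stage of the package over one cohort: codon tallying,
#' nucleotide composition, RSCU with codon classification, ENC with the
#' ENC-plot table, PR2 coordinates, the neutrality regression, PCA of RSCU
#' space, and (when host references are supplied) the CAI/RCDI/SiD
#' adaptation scan. Stages can be toggled off independently; the result is
#' a plain list of tibbles (plus the fit/PCA objects) so each piece chains
#' into further dplyr/ggplot2 work.
#'
#' @param cds A sequence tibble from [read_cds()] or [simulate_cohort()].
#' @param host_refs Optional list of [host_reference()] objects for the
#'   adaptation stage.
#' @param stages Character vector of stages to run; default all of
#'   `"composition"`, `"rscu"`, `"enc"`, `"pr2"`, `"neutrality"`, `"pca"`,
#'   `"adaptation"`.
#' @param n_axes PCA axes to keep (default 4).
#' @param pr2_scope Passed to [pr2()].
#' @param frame_policy Passed to [count_codons()].
#' @return An object of class `codon_analysis`: a list with `counts` and
#'   one element per executed stage.
#' @examples
#' cohort <- simulate_cohort(6, 200, seed = 42)
#' res <- run_codon_analysis(cohort)
#' res$enc
#' @export
run_codon_analysis <- function(cds, host_refs = NULL,
                               stages = c("composition", "rscu", "enc",
                                          "pr2", "neutrality", "pca",
                                          "adaptation"),
                               n_axes = 4,
                               pr2_scope = "fourfold_only",
                               frame_policy = "strict") {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list(counts = count_codons(cds, frame_policy = frame_policy))
  if ("composition" %in% stages) {
    out$composition <- composition(out$counts)
  }
  if (any(c("rscu", "pca") %in% stages)) {
    out$rscu <- classify_codons(rscu(out$counts))
  }
  if ("enc" %in% stages) out$enc <- enc(out$counts)
  if ("pr2" %in% stages) out$pr2 <- pr2(out$counts, family_scope = pr2_scope)
  if ("neutrality" %in% stages) {
    comp <- out$composition %||% composition(out$counts)
    out$neutrality <- if (nrow(comp) >= 3 && var(comp$GC3) > 0) {
      neutrality_fit(comp)
    } else {
      NULL
    }
  }
  if ("pca" %in% stages && dplyr::n_distinct(out$counts$id) >= 2) {
    ids <- dplyr::n_distinct(out$counts$id)
    out$pca <- rscu_pca(out$rscu, n_axes = min(n_axes, ids - 1))
  }
  if ("adaptation" %in% stages && !is.null(host_refs)) {
    out$adaptation <- adaptation_scan(out$counts, host_refs)
  }
  structure(out, class = "codon_analysis")
}

#' @export
print.codon_analysis <- function(x, ...) {
  cat("Codon usage analysis of", dplyr::n_distinct(x$counts$id),
      "sequences\n")
  cat("  stages:", paste(setdiff(names(x), "counts"), collapse = ", "), "\n")
  if (!is.null(x$enc)) {
    cat(sprintf("  ENC: mean %.2f, %d/%d flagged as significantly biased\n",
                mean(x$enc$enc, na.rm = TRUE),
                sum(x$enc$significant_bias), nrow(x$enc)))
  }
  if (!is.null(x$neutrality)) {
    cat(sprintf("  neutrality slope %.3f (mutation %.1f%%, selection %.1f%%)\n",
                x$neutrality$slope, x$neutrality$pct_mutation,
                x$neutrality$pct_selection))
  }
  invisible(x)
}

#' Grouped mean and standard deviation of stage outputs
#'
#' Summarizes every numeric column of a stage table as mean and sample
#' standard deviation per group — the form in which cohort-level codon-usage
#' results are conventionally reported (e.g. per region or per host). Groups
#' with a single row get `NA` sd.
#'
#' @param data A stage tibble (composition, ENC, PR2, adaptation, ...).
#' @param ... Grouping columns (tidy-select), e.g. `region`, `host`.
#' @return A tibble with one row per group: `n`, then `<col>_mean` and
#'   `<col>_sd` for every numeric column.
#' @export
summarize_by <- function(data, ...) {
  grouped <- dplyr::group_by(data, ...)
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, names(attr(grouped, "groups")))
  dplyr::summarise(
    grouped,
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(num_cols),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~sd(.x, na.rm = TRUE))),
    .groups = "drop"
  )
}
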