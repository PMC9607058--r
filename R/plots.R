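#' ENC plot: observed ENC against GC3s with the expected curve
#'
#' The classic diagnostic scatter: each sequence's ENC against its GC3s,
#' with the mutation-only expectation ([expected_enc()]) as a dotted
#' reference curve. Points on the curve are consistent with mutation
#' pressure alone; points below it indicate additional selective
#' constraint on codon choice.
#'
#' @param enc_tbl Output of [enc()].
#' @param colour_by Optional metadata column to colour points.
#' @return A ggplot object.
#' @export
plot_enc <- function(enc_tbl, colour_by = NULL) {
  stopifnot(all(c("enc", "gc3s") %in% names(enc_tbl)))
  curve <- enc_reference_curve()
  p <- ggplot(enc_tbl, aes(x = .data$gc3s, y = .data$enc))
  if (!is.null(colour_by)) {
    p <- p + geom_point(aes(colour = .data[[colour_by]]), alpha = 0.7)
  } else {
    p <- p + geom_point(alpha = 0.7)
  }
  p +
    geom_line(data = curve, aes(x = .data$gc3s, y = .data$expected_enc),
              linetype = "dotted") +
    geom_hline(yintercept = 35, linetype = "dashed", colour = "grey50") +
    coord_cartesian(ylim = c(20, 61)) +
    labs(x = "GC3s (%)", y = "ENC") +
    theme_bw()
}

#' PR2 bias plot
#'
#' AU-bias against GC-bias at fourfold third positions, with the (0.5, 0.5)
#' center marked: the point of equal use of complementary bases, where
#' mutation pressure and selection are balanced.
#'
#' @param pr2_tbl Output of [pr2()].
#' @param colour_by Optional metadata column to colour points.
#' @return A ggplot object.
#' @export
plot_pr2 <- function(pr2_tbl, colour_by = NULL) {
  stopifnot(all(c("au_bias", "gc_bias") %in% names(pr2_tbl)))
  p <- ggplot(pr2_tbl, aes(x = .data$gc_bias, y = .data$au_bias))
  if (!is.null(colour_by)) {
    p <- p + geom_point(aes(colour = .data[[colour_by]]), alpha = 0.7)
  } else {
    p <- p + geom_point(alpha = 0.7)
  }
  p +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    geom_vline(xintercept = 0.5, linetype = "dotted") +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "GC bias  G3/(G3+C3)", y = "AU bias  A3/(A3+U3)") +
    theme_bw()
}

#' RSCU profile bar plot
#'
#' RSCU per codon (canonical order, grouped by amino acid) for one or a few
#' sequences, with the 0.6 / 1.6 low- and high-frequency thresholds marked.
#'
#' @param rscu_tbl Output of [rscu()].
#' @param alphabet Display codons with `"dna"` (T) or `"rna"` (U) spelling.
#' @return A ggplot object.
#' @export
plot_rscu <- function(rscu_tbl, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  d <- rscu_tbl
  lab <- if (alphabet == "rna") chartr("T", "U", codon_order()) else codon_order()
  d$codon <- factor(
    if (alphabet == "rna") chartr("T", "U", d$codon) else d$codon,
    levels = lab
  )
  ggplot(d, aes(x = .data$codon, y = .data$rscu, fill = .data$amino_acid)) +
    geom_col() +
    geom_hline(yintercept = c(0.6, 1.6), linetype = "dotted") +
    ggplot2::facet_wrap(~id, ncol = 1) +
    labs(x = NULL, y = "RSCU") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6),
                   legend.position = "none")
}
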