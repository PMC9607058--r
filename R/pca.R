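#' Principal component analysis of RSCU space
#'
#' Represents each sequence as its 59-dimensional RSCU vector (in the
#' canonical [codon_order()]) and performs covariance PCA: the matrix is
#' mean-centered but not rescaled, since RSCU values are already
#' dimensionless and family-normalized. Undefined RSCU entries (families a
#' short gene never uses) are imputed at the neutral value 1 before
#' centering; the number of imputed cells per sequence is reported. Each
#' axis is oriented so that its largest-magnitude loading is positive,
#' making score signs reproducible.
#'
#' @param rscu_tbl Output of [rscu()] for at least two sequences.
#' @param n_axes Number of axes to keep (default 4; at most
#'   `min(59, n_sequences - 1)`).
#' @return An object of class `rscu_pca`: `scores` (tibble, one row per
#'   sequence), `loadings` (tibble, one row per codon), `explained_variance_pct`,
#'   `n_imputed` per sequence, and `degenerate` (TRUE when total variance is
#'   0, in which case explained percentages are `NA`). Methods: [tidy()],
#'   [glance()], `print()`, [autoplot()].
#' @export
rscu_pca <- function(rscu_tbl, n_axes = 4) {
  m <- .rscu_matrix(rscu_tbl)
  if (nrow(m) < 2) abort("PCA needs at least 2 sequences")
  max_axes <- min(ncol(m), nrow(m) - 1)
  if (n_axes > max_axes) {
    abort(paste0("n_axes must be <= ", max_axes, " for this input"))
  }
  n_imputed <- rowSums(is.na(m))
  m[is.na(m)] <- 1

  total_var <- sum(apply(m, 2, var))
  if (total_var == 0) {
    return(structure(
      list(
        scores = tibble::tibble(id = rownames(m)),
        loadings = tibble::tibble(codon = colnames(m)),
        explained_variance_pct = rep(NA_real_, n_axes),
        n_imputed = setNames(as.integer(n_imputed), rownames(m)),
        degenerate = TRUE
      ),
      class = "rscu_pca"
    ))
  }

  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_axes, ncol(pc$rotation)))
  rot <- pc$rotation[, keep, drop = FALSE]
  scr <- pc$x[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry positive on every axis
  for (j in seq_along(keep)) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) {
      rot[, j] <- -rot[, j]
      scr[, j] <- -scr[, j]
    }
  }
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)

  meta <- .counts_meta(rscu_tbl)
  scores <- dplyr::bind_cols(
    tibble::tibble(id = rownames(m)),
    tibble::as_tibble(scr)
  )
  if (ncol(meta) > 1) scores <- dplyr::left_join(scores, meta, by = "id")

  structure(
    list(
      scores = scores,
      loadings = dplyr::bind_cols(tibble::tibble(codon = colnames(m)),
                                  tibble::as_tibble(rot)),
      explained_variance_pct = expl[keep],
      explained_variance_pct_all = expl,
      n_imputed = setNames(as.integer(n_imputed), rownames(m)),
      degenerate = FALSE
    ),
    class = "rscu_pca"
  )
}

#' @export
print.rscu_pca <- function(x, ...) {
  if (x$degenerate) {
    cat("RSCU PCA: degenerate (zero total variance across sequences)\n")
    return(invisible(x))
  }
  cat("RSCU PCA over", nrow(x$scores), "sequences x 59 codons\n")
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", "), "\n")
  if (any(x$n_imputed > 0)) {
    cat("  imputed RSCU cells (value 1):", sum(x$n_imputed), "\n")
  }
  invisible(x)
}

#' @rdname rscu_pca
#' @param x,object An `rscu_pca` object.
#' @param ... Unused.
#' @export
tidy.rscu_pca <- function(x, ...) x$scores

#' @rdname rscu_pca
#' @export
glance.rscu_pca <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$explained_variance_pct),
    explained_variance_pct = x$explained_variance_pct,
    cumulative_pct = cumsum(x$explained_variance_pct)
  )
}

#' @rdname rscu_pca
#' @param colour_by Optional metadata column in the scores to colour points.
#' @export
autoplot.rscu_pca <- function(object, colour_by = NULL, ...) {
  if (object$degenerate) abort("cannot plot a degenerate PCA result")
  p <- ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour_by)) {
    p <- p + geom_point(aes(colour = .data[[colour_by]]), alpha = 0.7)
  } else {
    p <- p + geom_point(alpha = 0.7)
  }
  p + labs(
    x = sprintf("Axis 1 (%.1f%%)", object$explained_variance_pct[1]),
    y = sprintf("Axis 2 (%.1f%%)", object$explained_variance_pct[2])
  ) + theme_bw()
}
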