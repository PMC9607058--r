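#' Neutrality plot regression of GC12 on GC3
#'
#' Across a cohort of sequences, regresses GC content at the first and
#' second codon positions (GC12, which mutation and selection both shape)
#' on GC content at the third position (GC3, shaped mostly by mutation).
#' Under mutation pressure alone the points fall on the identity line and
#' the slope is near 1; selection on codon usage flattens the slope toward
#' 0. The slope is therefore read as the fraction of codon-usage pressure
#' attributable to mutation: `pct_mutation = 100 * slope` and
#' `pct_selection = 100 * (1 - slope)` (e.g. slope 0.106 partitions as
#' 10.6% mutation, 89.4% selection).
#'
#' @param data A data frame with GC12 and GC3 columns — typically the output
#'   of [composition()].
#' @param gc12,gc3 Column names (default `"GC12"`, `"GC3"`), in percent.
#' @return An object of class `neutrality_fit` with components `slope`,
#'   `intercept`, `r` (Pearson correlation), `p_value`, `n_points`,
#'   `pct_mutation`, `pct_selection`, the underlying `lm` fit and the point
#'   data. Methods: [tidy()], [glance()], `print()`, [autoplot()].
#' @examples
#' pts <- tibble::tibble(GC3 = c(30, 40, 50), GC12 = c(30, 40, 50))
#' neutrality_fit(pts)  # points on the identity line: slope 1
#' @export
neutrality_fit <- function(data, gc12 = "GC12", gc3 = "GC3") {
  stopifnot(is.data.frame(data), all(c(gc12, gc3) %in% names(data)))
  pts <- tibble::tibble(gc12 = data[[gc12]], gc3 = data[[gc3]])
  pts <- pts[stats::complete.cases(pts), ]
  if (nrow(pts) < 3) abort("neutrality regression needs at least 3 points")
  if (var(pts$gc3) == 0) abort("degenerate abscissa: all GC3 values equal")
  fit <- lm(gc12 ~ gc3, data = pts)
  # perfect fits and zero-variance ordinates are legitimate here (exact
  # identity-line or flat inputs); the stats warnings would only be noise
  ct <- suppressWarnings(cor.test(pts$gc3, pts$gc12, method = "pearson"))
  slope <- unname(coef(fit)[2])
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r = unname(ct$estimate),
      p_value = ct$p.value,
      n_points = nrow(pts),
      pct_mutation = 100 * slope,
      pct_selection = 100 * (1 - slope),
      slope_se = suppressWarnings(summary(fit))$coefficients[2, 2],
      model = fit,
      points = pts
    ),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Neutrality plot regression (GC12 ~ GC3), n =", x$n_points, "\n")
  cat(sprintf("  slope     %.4f (se %.4f)   intercept %.3f\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  Pearson r %.4f   p = %.3g\n", x$r, x$p_value))
  cat(sprintf("  mutation pressure %.1f%%   natural selection %.1f%%\n",
              x$pct_mutation, x$pct_selection))
  invisible(x)
}

#' @rdname neutrality_fit
#' @param x A `neutrality_fit` object.
#' @param ... Unused.
#' @export
tidy.neutrality_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(suppressWarnings(summary(x$model))$coefficients[1, 2],
                  x$slope_se)
  )
}

#' @rdname neutrality_fit
#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r = x$r,
    p.value = x$p_value, n = x$n_points,
    pct_mutation = x$pct_mutation, pct_selection = x$pct_selection
  )
}

#' @rdname neutrality_fit
#' @param object A `neutrality_fit` object.
#' @export
autoplot.neutrality_fit <- function(object, ...) {
  ggplot(object$points, aes(x = .data$gc3, y = .data$gc12)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    labs(x = "GC3 (%)", y = "GC12 (%)",
         title = sprintf("Neutrality plot: slope %.3f (mutation %.1f%%)",
                         object$slope, object$pct_mutation)) +
    theme_bw()
}
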