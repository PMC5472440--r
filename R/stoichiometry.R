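#' Binding stoichiometry from a saturation titration
#'
#' Under saturating ligand (nucleosome) concentrations a titration rises
#' linearly while binding sites remain free and flattens once they are
#' occupied. Straight lines are fitted to the unsaturated and saturated
#' segments and the stoichiometry extrapolated from their intersection:
#' \deqn{[P]_{break} = \frac{Y_1 - Y_2}{S_2 - S_1}, \qquad
#'       ratio = \frac{[P]_{break}}{[N]}}
#' where \eqn{Y_1, S_1} are the intercept and slope of the unsaturated line,
#' \eqn{Y_2, S_2} those of the saturated line and \eqn{[N]} the fixed ligand
#' concentration. The segment split is chosen by minimising the total residual
#' sum of squares over all admissible splits (lowest-\eqn{k} points vs
#' highest points).
#'
#' @param titr A [titration()] with `ligand_conc` set; replicates are pooled.
#' @param min_points Minimum points per segment (at least 2).
#' @param parallel_tol Relative slope-difference tolerance below which the two
#'   lines are declared parallel and the fit fails.
#' @return An object of class `"stoich_fit"`: `Y1`, `S1`, `Y2`, `S2`,
#'   `breakpoint_conc`, `ratio` (= breakpoint / ligand concentration),
#'   segment sizes and the unit. A warning is raised if the breakpoint falls
#'   outside 0.1-10 times the titrated range.
#' @examples
#' P <- seq(100, 2000, by = 100)
#' resp <- pmin(P, 1000)  # breakpoint at 1000
#' fit_stoichiometry(titration(P, resp, ligand_conc = 500, unit = "nM"))
#' @export
fit_stoichiometry <- function(titr, min_points = 2L, parallel_tol = 1e-8) {
  stopifnot(inherits(titr, "titration"))
  lig <- attr(titr, "ligand_conc")
  if (is.na(lig) || lig <= 0)
    stop("stoichiometry requires a positive fixed 'ligand_conc'")
  df <- stats::aggregate(response ~ conc, data = as.data.frame(titr), FUN = mean)
  df <- df[order(df$conc), ]
  n <- nrow(df)
  if (n < 2L * min_points + 1L)
    stop("too few distinct concentrations for a two-segment fit")
  best <- NULL
  for (k in seq(min_points, n - min_points)) {
    lo <- df[seq_len(k), ]
    hi <- df[seq(k + 1L, n), ]
    f1 <- stats::lm(response ~ conc, data = lo)
    f2 <- stats::lm(response ~ conc, data = hi)
    rss <- sum(residuals(f1)^2) + sum(residuals(f2)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, k = k, f1 = f1, f2 = f2)
  }
  Y1 <- unname(coef(best$f1)[1]); S1 <- unname(coef(best$f1)[2])
  Y2 <- unname(coef(best$f2)[1]); S2 <- unname(coef(best$f2)[2])
  scale <- max(abs(c(S1, S2)), .Machine$double.eps)
  if (abs(S1 - S2) <= parallel_tol * scale)
    stop("unsaturated and saturated segments are parallel: ",
         "no intersection, stoichiometry undefined")
  bp <- (Y1 - Y2) / (S2 - S1)
  if (bp < 0.1 * min(df$conc) || bp > 10 * max(df$conc))
    warning(sprintf("breakpoint %.4g %s lies outside 0.1-10x the titrated range",
                    bp, conc_unit(titr)))
  out <- list(Y1 = Y1, S1 = S1, Y2 = Y2, S2 = S2,
              breakpoint_conc = bp, ratio = bp / lig,
              ligand_conc = lig, split = best$k, n = n,
              rss = best$rss, unit = conc_unit(titr), data = titr)
  class(out) <- "stoich_fit"
  out
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("Two-line saturation stoichiometry fit\n")
  cat(sprintf("  unsaturated: Y1 = %.4g, S1 = %.4g per %s (%d points)\n",
              x$Y1, x$S1, x$unit, x$split))
  cat(sprintf("  saturated:   Y2 = %.4g, S2 = %.4g per %s (%d points)\n",
              x$Y2, x$S2, x$unit, x$n - x$split))
  cat(sprintf("  breakpoint = %.4g %s; [N] = %.4g %s\n",
              x$breakpoint_conc, x$unit, x$ligand_conc, x$unit))
  cat(sprintf("  stoichiometry (breakpoint / [N]) = %.3f\n", x$ratio))
  invisible(x)
}

#' @export
coef.stoich_fit <- function(object, ...) {
  c(Y1 = object$Y1, S1 = object$S1, Y2 = object$Y2, S2 = object$S2,
    breakpoint_conc = object$breakpoint_conc, ratio = object$ratio)
}

#' @export
predict.stoich_fit <- function(object, newdata = NULL, ...) {
  P <- if (is.null(newdata)) object$data$conc
       else if (is.numeric(newdata)) newdata else newdata$conc
  ifelse(P <= object$breakpoint_conc,
         object$Y1 + object$S1 * P, object$Y2 + object$S2 * P)
}

#' @export
plot.stoich_fit <- function(x, ...) {
  titr <- x$data
  graphics::plot(titr$conc, titr$response,
                 xlab = paste0("[titrant] (", x$unit, ")"),
                 ylab = "response", ...)
  graphics::abline(x$Y1, x$S1, lty = 2)
  graphics::abline(x$Y2, x$S2, lty = 2)
  graphics::abline(v = x$breakpoint_conc, col = "grey")
  invisible(x)
}
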