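#' Hill model response
#'
#' Cooperative (Hill) saturation curve
#' \deqn{F(P) = F_{min} + (F_{max}-F_{min}) \frac{P^h}{K_{1/2}^h + P^h}}
#' used for equilibrium binding (fraction bound / FNorm vs titrant) and, with
#' `F_min = 0`, for the allosteric sigmoidal rate model \eqn{V = V_{max}
#' P^h/(K_{1/2}^h + P^h)}.
#'
#' @param P Titrant concentration(s), `>= 0`.
#' @param K_half Half-saturation concentration, `> 0` (same unit as `P`).
#' @param h Hill coefficient, `> 0`.
#' @param F_min,F_max Baseline and plateau response.
#' @return Response values, monotone nondecreasing in `P` (for `F_max >= F_min`).
#' @examples
#' hill_response(1, K_half = 1, h = 1.8)  # 0.5 at half-saturation
#' @export
hill_response <- function(P, K_half, h, F_min = 0, F_max = 1) {
  if (!is.numeric(K_half) || K_half <= 0) stop("'K_half' must be > 0")
  if (!is.numeric(h) || h <= 0) stop("'h' must be > 0")
  if (any(P < 0)) stop("'P' must be >= 0")
  # (P/K)^h / (1 + (P/K)^h) avoids overflow for large h or P
  x <- (P / K_half)^h
  F_min + (F_max - F_min) * x / (1 + x)
}

multistart_nlsLM <- function(formula, data, starts, lower, upper) {
  best <- NULL
  controls <- list(minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                              ptol = 1e-10),
                   minpack.lm::nls.lm.control(maxiter = 500))
  for (st in starts) {
    fit <- NULL
    for (ctrl in controls) {     # exact fits can defeat the tight tolerances
      fit <- tryCatch(
        minpack.lm::nlsLM(formula, data = data, start = st,
                          lower = lower, upper = upper, control = ctrl),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best) - 1e-12))
      best <- fit
  }
  best
}

new_hill_fit <- function(fit, titr, free_fmin, subclass = NULL) {
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  F_min <- if (free_fmin) est[["F_min"]] else 0
  resp <- titr$response
  rss <- deviance(fit)
  tss <- sum((resp - mean(resp))^2)
  out <- list(
    K_half = est[["K_half"]], h = est[["h"]],
    F_min = F_min, F_max = est[["F_max"]],
    se = c(K_half = unname(ifelse("K_half" %in% names(se), se[["K_half"]], NA)),
           h = unname(ifelse("h" %in% names(se), se[["h"]], NA)),
           F_min = if (free_fmin) unname(se[["F_min"]]) else NA_real_,
           F_max = unname(ifelse("F_max" %in% names(se), se[["F_max"]], NA))),
    unit = conc_unit(titr),
    n = nrow(titr),
    rss = rss,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    data = titr,
    convergence = TRUE)
  class(out) <- c(subclass, "hill_fit")
  out
}

#' Fit the cooperative binding (Hill) model to a titration
#'
#' Unweighted nonlinear least squares with multi-start Levenberg-Marquardt
#' initialisation: `K_half` is seeded at the concentration where the response
#' crosses its midpoint and `h` at 1 (plus a coarse grid of alternatives), the
#' convention used when fitting thermophoresis and gel-shift binding curves.
#'
#' @param titr A [titration()] with at least 6 distinct concentrations
#'   spanning the transition.
#' @param free_fmin Fit the baseline `F_min` (default) or pin it at 0 (the
#'   rate-titration convention).
#' @param noise_floor Minimum response range, as a fraction of the largest
#'   absolute response, below which the titration is declared flat and the fit
#'   refused (the behaviour of an inactive, non-binding sample).
#' @return An object of class `"hill_fit"` with elements `K_half`, `h`,
#'   `F_min`, `F_max`, standard errors `se`, `rss`, `r_squared` and the unit,
#'   supporting `print`, `summary`, `coef`, `predict`, `plot` and `residuals`.
#' @seealso [hill_linearize()] for the confirmatory Hill plot.
#' @examples
#' P <- 2^(0:7)
#' fit <- fit_hill(titration(P, hill_response(P, 10, 1.8), unit = "nM"))
#' coef(fit)
#' @export
fit_hill <- function(titr, free_fmin = TRUE, noise_floor = 0.02) {
  stopifnot(inherits(titr, "titration"))
  if (length(unique(titr$conc)) < 6L)
    stop("need >= 6 distinct concentrations to fit the Hill model")
  resp <- titr$response
  rng <- diff(range(resp))
  if (rng < noise_floor * max(abs(resp), .Machine$double.eps))
    stop("response range is below the noise floor: flat titration ",
         "(no detectable binding or activity); Hill fit refused")
  # midpoint-crossing concentration seeds K_half
  mid <- min(resp) + rng / 2
  ord <- order(titr$conc)
  above <- which(resp[ord] >= mid)
  K0 <- titr$conc[ord][if (length(above)) above[1] else ceiling(nrow(titr) / 2)]
  starts <- list()
  for (h0 in c(1, 0.5, 2, 4))
    for (K in unique(c(K0, stats::median(titr$conc))))
      starts[[length(starts) + 1L]] <-
        if (free_fmin) list(K_half = K, h = h0, F_min = min(resp), F_max = max(resp))
        else list(K_half = K, h = h0, F_max = max(resp))
  lo_K <- min(titr$conc) / 1e3
  hi_K <- max(titr$conc) * 1e3
  if (free_fmin) {
    form <- response ~ F_min + (F_max - F_min) * (conc / K_half)^h /
      (1 + (conc / K_half)^h)
    lower <- c(K_half = lo_K, h = 1e-3, F_min = -Inf, F_max = -Inf)
    upper <- c(K_half = hi_K, h = 50, F_min = Inf, F_max = Inf)
  } else {
    form <- response ~ F_max * (conc / K_half)^h / (1 + (conc / K_half)^h)
    lower <- c(K_half = lo_K, h = 1e-3, F_max = -Inf)
    upper <- c(K_half = hi_K, h = 50, F_max = Inf)
  }
  fit <- multistart_nlsLM(form, as.data.frame(titr), starts, lower, upper)
  if (is.null(fit))
    stop("Hill fit did not converge from any starting point")
  new_hill_fit(fit, titr, free_fmin)
}

#' Hill-plot linearisation
#'
#' Confirms a fitted Hill coefficient by regressing
#' \eqn{\log(\theta/(1-\theta))} on \eqn{\log P}, where the fractional
#' saturation \eqn{\theta} is computed from the fitted amplitudes. Points at
#' the extremes of the range, where the log-odds transform blows up the noise,
#' are excluded: only points with `theta_min <= theta <= theta_max` (default
#' retention band 10-90 %) are kept.
#'
#' @param titr The [titration()] that was fitted.
#' @param fit The corresponding [fit_hill()] (or [fit_rate_titration()])
#'   result, used for `F_min`/`F_max`.
#' @param theta_min,theta_max Retention band for fractional saturation.
#' @return A list of class `"hill_plot"` with `slope` (the confirmatory Hill
#'   coefficient), `intercept`, `se_slope`, the retained `log_P` and
#'   `log_odds`, and the number of excluded points.
#' @export
hill_linearize <- function(titr, fit, theta_min = 0.1, theta_max = 0.9) {
  stopifnot(inherits(titr, "titration"), inherits(fit, "hill_fit"))
  theta <- (titr$response - fit$F_min) / (fit$F_max - fit$F_min)
  keep <- is.finite(theta) & theta >= theta_min & theta <= theta_max
  if (sum(keep) < 3L)
    stop("fewer than 3 points retained inside the ", theta_min * 100, "-",
         theta_max * 100, "% saturation band; Hill plot not possible")
  lx <- log(titr$conc[keep])
  ly <- log(theta[keep] / (1 - theta[keep]))
  reg <- stats::lm(ly ~ lx)
  out <- list(slope = unname(coef(reg)[2]), intercept = unname(coef(reg)[1]),
              se_slope = summary(reg)$coefficients[2, 2],
              log_P = lx, log_odds = ly, n_excluded = sum(!keep))
  class(out) <- "hill_plot"
  out
}

#' @export
print.hill_plot <- function(x, ...) {
  cat(sprintf("Hill plot: slope (h) = %.3f +/- %.3f, %d point(s) excluded\n",
              x$slope, x$se_slope, x$n_excluded))
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Cooperative (Hill) binding fit\n")
  cat(sprintf("  K_1/2 = %.4g %s (se %.3g)\n", x$K_half, x$unit, x$se[["K_half"]]))
  cat(sprintf("  h     = %.3f (se %.3g)\n", x$h, x$se[["h"]]))
  cat(sprintf("  F_min = %.4g, F_max = %.4g\n", x$F_min, x$F_max))
  cat(sprintf("  n = %d, R^2 = %.4f\n", x$n, x$r_squared))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  RSS = %.4g\n", object$rss))
  invisible(object)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(K_half = object$K_half, h = object$h,
    F_min = object$F_min, F_max = object$F_max)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  P <- if (is.null(newdata)) object$data$conc
       else if (is.numeric(newdata)) newdata else newdata$conc
  hill_response(P, object$K_half, object$h, object$F_min, object$F_max)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  titr <- x$data
  graphics::plot(titr$conc, titr$response, log = "x",
                 xlab = paste0("[titrant] (", x$unit, ")"),
                 ylab = "response", ...)
  P <- exp(seq(log(min(titr$conc)), log(max(titr$conc)), length.out = 200))
  graphics::lines(P, predict(x, P))
  invisible(x)
}
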