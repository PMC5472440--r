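#' Construct an assay trace
#'
#' A time series from a one-pot sliding/ATPase assay: either the FRET sliding
#' signal of dual-labelled nucleosomes or the NADH absorbance proxy of the
#' coupled ATPase system, in fluorescence units (FU).
#'
#' @param time Time in seconds, strictly increasing, `time[1] >= 0`,
#'   at least 10 samples.
#' @param signal Signal in FU, same length as `time`.
#' @param kind `"sliding_fret"` or `"atpase_nadh"`.
#' @param meta Optional named list (substrate name, protein and nucleosome
#'   concentrations, ...).
#' @param scale_to Optional full-scale value: raw sliding traces are rescaled
#'   so their initial value equals `scale_to` (the assay convention is a
#'   100,000 FU full scale); the applied factor is stored as attribute
#'   `scale_factor`.
#' @return A data frame of class `"assay_trace"`.
#' @export
assay_trace <- function(time, signal, kind = c("sliding_fret", "atpase_nadh"),
                        meta = list(), scale_to = NULL) {
  kind <- match.arg(kind)
  if (length(time) != length(signal)) stop("'time' and 'signal' lengths differ")
  if (length(time) < 10L) stop("an assay trace needs at least 10 samples")
  if (time[1] < 0 || any(diff(time) <= 0))
    stop("'time' must be nonnegative and strictly increasing")
  scale_factor <- 1
  if (!is.null(scale_to)) {
    if (signal[1] == 0) stop("cannot rescale a trace whose initial value is 0")
    scale_factor <- scale_to / signal[1]
    signal <- signal * scale_factor
  }
  out <- data.frame(time = time, signal = signal)
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta
  attr(out, "scale_factor") <- scale_factor
  class(out) <- c("assay_trace", "data.frame")
  out
}

#' @export
print.assay_trace <- function(x, ...) {
  cat(sprintf("Assay trace (%s): %d samples over %.4g-%.4g s\n",
              attr(x, "kind"), nrow(x), x$time[1], x$time[nrow(x)]))
  invisible(x)
}

#' Write an assay trace as a two-column delimited table
#'
#' Metadata (kind, scale factor, any `meta` entries) go in leading `#` header
#' lines; columns are `time_s` and `signal_FU`.
#' @param x An [assay_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "assay_trace"))
  meta <- attr(x, "meta")
  hdr <- c(sprintf("# kind: %s", attr(x, "kind")),
           sprintf("# scale_factor: %.15g", attr(x, "scale_factor")))
  if (length(meta))
    hdr <- c(hdr, sprintf("# meta.%s: %s", names(meta),
                          vapply(meta, format, "", digits = 15)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = x$time, signal_FU = x$signal), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an assay trace written by [write_trace()]
#' @param path Input path.
#' @return An [assay_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  df <- utils::read.csv(text = lines[!is_meta], stringsAsFactors = FALSE)
  if (!all(c("time_s", "signal_FU") %in% names(df)))
    stop("trace table must have columns 'time_s' and 'signal_FU'")
  if (!is.numeric(df$time_s) || !is.numeric(df$signal_FU))
    stop("non-numeric cells in trace table (decimal commas are not accepted)")
  m <- meta[grep("^meta\\.", names(meta))]
  names(m) <- sub("^meta\\.", "", names(m))
  out <- assay_trace(df$time_s, df$signal_FU,
                     kind = if (is.null(meta$kind)) "sliding_fret" else meta$kind,
                     meta = m)
  if (!is.null(meta$scale_factor)) attr(out, "scale_factor") <- meta$scale_factor
  out
}

#' ADP standard for the NADH-coupled ATPase assay
#'
#' The slope of a simultaneously measured ADP standard curve converts the
#' NADH signal into absolute ADP (= ATP hydrolysed).
#'
#' @param slope Signal change per micromolar ADP (FU/µM); nonzero, usually
#'   negative (NADH is consumed).
#' @param nadh_conc Assay NADH concentration in µM (design constant, 200 or
#'   400).
#' @return An object of class `"adp_standard"`.
#' @export
adp_standard <- function(slope, nadh_conc = 200) {
  if (!is.numeric(slope) || slope == 0) stop("standard 'slope' must be nonzero")
  if (nadh_conc <= 0) stop("'nadh_conc' must be positive")
  structure(list(slope = slope, nadh_conc = nadh_conc), class = "adp_standard")
}

#' Initial rate of an assay trace
#'
#' Slope of a linear regression over an early window of the trace. The default
#' window is the first 10 % of the time to half-completion of the total signal
#' change (minimum 4 samples), mirroring the manual early-slope convention for
#' initial velocities.
#'
#' @param trace An [assay_trace()].
#' @param window Either `NULL` (default window), a numeric length-2 time
#'   interval in seconds, or a single fraction in (0, 1] of the trace span.
#' @return A list of class `"initial_rate"`: `rate` (magnitude, signal
#'   units/s), `direction` (+1 rising, -1 falling, 0 flat), `se`, `window`,
#'   `n`.
#' @export
initial_rate <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "assay_trace"))
  t <- trace$time; s <- trace$signal
  if (is.null(window)) {
    total <- s[length(s)] - s[1]
    if (total == 0) {
      w <- range(t)
    } else {
      half_idx <- which(abs(s - s[1]) >= abs(total) / 2)[1]
      t_half <- if (is.na(half_idx)) t[length(t)] else t[half_idx]
      w <- c(t[1], t[1] + 0.10 * (t_half - t[1]))
    }
  } else if (length(window) == 1L) {
    if (window <= 0 || window > 1) stop("fractional window must be in (0, 1]")
    w <- c(t[1], t[1] + window * (t[length(t)] - t[1]))
  } else {
    w <- sort(window[1:2])
  }
  if (w[1] < t[1] - 1e-9 || w[2] > t[length(t)] + 1e-9)
    stop("window lies outside the trace")
  keep <- t >= w[1] - 1e-9 & t <= w[2] + 1e-9
  if (sum(keep) < 4L) {           # widen to the first 4 samples at minimum
    keep <- seq_along(t) <= max(4L, sum(keep))
    w[2] <- max(t[keep])
  }
  if (sum(keep) < 4L) stop("initial-rate window must contain >= 4 samples")
  reg <- stats::lm(s[keep] ~ t[keep])
  slope <- unname(coef(reg)[2])
  # exact traces make summary.lm warn about a perfect fit; the se is then 0
  se <- suppressWarnings(summary(reg)$coefficients[2, 2])
  structure(list(rate = abs(slope), direction = sign(slope), se = se,
                 window = w, n = sum(keep)),
            class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("Initial rate: %.4g FU/s (%s, se %.3g, %d points in [%.3g, %.3g] s)\n",
              x$rate, c("falling", "flat", "rising")[x$direction + 2],
              x$se, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Convert an NADH trace into an absolute ATPase rate
#'
#' In the coupled assay each hydrolysed ATP regenerates through pyruvate
#' kinase / lactate dehydrogenase and oxidises one NADH, so
#' `rate = |signal slope| / |standard slope|` gives µM ATP/s; dividing by the
#' enzyme concentration gives a per-enzyme turnover in 1/s.
#'
#' @param trace An `"atpase_nadh"` [assay_trace()], or an [initial_rate()]
#'   already extracted from one.
#' @param standard An [adp_standard()].
#' @param enzyme_conc Optional enzyme concentration in µM for the per-enzyme
#'   rate.
#' @param window Passed to [initial_rate()] when `trace` is a trace.
#' @return A list with `atp_rate` (µM ATP/s) and, when `enzyme_conc` is
#'   given, `per_enzyme_rate` (1/s).
#' @export
nadh_to_atp <- function(trace, standard, enzyme_conc = NULL, window = NULL) {
  stopifnot(inherits(standard, "adp_standard"))
  r <- if (inherits(trace, "initial_rate")) trace else initial_rate(trace, window)
  atp_rate <- r$rate / abs(standard$slope)
  out <- list(atp_rate = atp_rate,
              se = r$se / abs(standard$slope))
  if (!is.null(enzyme_conc)) {
    if (enzyme_conc <= 0) stop("'enzyme_conc' must be positive")
    out$per_enzyme_rate <- atp_rate / enzyme_conc
  }
  out
}

#' Fit the allosteric sigmoidal model to a rate titration
#'
#' Initial velocities vs protein concentration are fitted to
#' \eqn{V = V_{max} [P]^h / (K_{1/2}^h + [P]^h)} (the Hill model with the
#' baseline pinned at 0). The sigmoidal fit is compared against a straight
#' line \eqn{V = a + b[P]} by small-sample-corrected AIC: unstimulated ATPase
#' depends linearly on protein concentration and is reported as such rather
#' than forced through a sigmoid. Flat titrations (range below the noise
#' floor) give an explicit zero-activity result, the behaviour of an
#' ATPase-dead complex.
#'
#' @param rates A [titration()] of initial rates vs protein concentration.
#' @param noise_floor As in [fit_hill()].
#' @return For a sigmoidal winner, an object of classes
#'   `c("sigmoidal_fit", "hill_fit")` whose `V_max` element aliases `F_max`,
#'   with `model = "sigmoidal"` and the AICc of both candidates; for a linear
#'   winner a `"linear_rate_fit"` with intercept/slope; for a flat titration a
#'   `"zero_activity_fit"`.
#' @examples
#' P <- c(12.5, 25, 50, 100, 200, 400, 800)
#' V <- hill_response(P, 100, 1.9, 0, 50)
#' fit_rate_titration(titration(P, V, ligand_conc = 100, unit = "nM"))
#' @export
fit_rate_titration <- function(rates, noise_floor = 0.02) {
  stopifnot(inherits(rates, "titration"))
  resp <- rates$response
  rng <- diff(range(resp))
  if (rng < noise_floor * max(abs(resp), .Machine$double.eps) ||
      max(abs(resp)) == 0) {
    out <- list(V_max = 0, K_half = NA_real_, h = NA_real_,
                mean_rate = mean(resp), unit = conc_unit(rates),
                data = rates, model = "zero_activity")
    class(out) <- "zero_activity_fit"
    return(out)
  }
  hf <- fit_hill(rates, free_fmin = FALSE, noise_floor = noise_floor)
  lf <- stats::lm(response ~ conc, data = as.data.frame(rates))
  n <- nrow(rates)
  aicc <- function(rss, k) n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  aicc_sig <- aicc(hf$rss, 4)                      # 3 params + sigma
  aicc_lin <- aicc(sum(residuals(lf)^2), 3)        # 2 params + sigma
  # a half-saturation beyond the titrated range means no saturation was
  # observed: the "sigmoid" is a disguised straight line
  unresolved <- hf$K_half > max(rates$conc)
  if (aicc_lin < aicc_sig || unresolved) {
    out <- list(intercept = unname(coef(lf)[1]), slope = unname(coef(lf)[2]),
                se = summary(lf)$coefficients[, 2],
                rss = sum(residuals(lf)^2), aicc = c(linear = aicc_lin,
                                                     sigmoidal = aicc_sig),
                unit = conc_unit(rates), data = rates, model = "linear")
    class(out) <- "linear_rate_fit"
    return(out)
  }
  hf$V_max <- hf$F_max
  hf$model <- "sigmoidal"
  hf$aicc <- c(linear = aicc_lin, sigmoidal = aicc_sig)
  class(hf) <- c("sigmoidal_fit", class(hf))
  hf
}

#' @export
print.sigmoidal_fit <- function(x, ...) {
  cat("Allosteric sigmoidal rate fit\n")
  cat(sprintf("  V_max = %.4g /s (se %.3g)\n", x$V_max, x$se[["F_max"]]))
  cat(sprintf("  K_1/2 = %.4g %s (se %.3g)\n", x$K_half, x$unit, x$se[["K_half"]]))
  cat(sprintf("  h     = %.3f (se %.3g)\n", x$h, x$se[["h"]]))
  cat(sprintf("  n = %d, R^2 = %.4f\n", x$n, x$r_squared))
  invisible(x)
}

#' @export
print.linear_rate_fit <- function(x, ...) {
  cat("Linear rate dependence (sigmoidal model rejected by AICc)\n")
  cat(sprintf("  rate = %.4g + %.4g x [P] (%s)\n", x$intercept, x$slope, x$unit))
  invisible(x)
}

#' @export
print.zero_activity_fit <- function(x, ...) {
  cat("Zero-activity titration: response range below the noise floor\n")
  cat(sprintf("  mean rate = %.4g\n", x$mean_rate))
  invisible(x)
}

#' ATPase-to-sliding coupling efficiency
#'
#' ATP molecules hydrolysed per base pair of productive sliding. A perfectly
#' coupled motor spends one ATP per base pair; the measured ratio of around 8
#' for wild-type dimers quantifies the futile (uncoupled) hydrolysis.
#'
#' @param atp_consumed ATP consumed (count per nucleosome, or µM).
#' @param bp_slid Base pairs slid (same per-nucleosome or bulk basis).
#' @return A list of class `"coupling_report"` with `atp`, `bp` and
#'   `efficiency` (ATP per bp); when `bp_slid` is 0 the efficiency is the
#'   sentinel string `"fully uncoupled"`, not a number.
#' @examples
#' coupling_efficiency(400, 50)  # efficiency 8
#' @export
coupling_efficiency <- function(atp_consumed, bp_slid) {
  if (atp_consumed < 0 || bp_slid < 0) stop("inputs must be nonnegative")
  eff <- if (bp_slid == 0) "fully uncoupled" else atp_consumed / bp_slid
  structure(list(atp = atp_consumed, bp = bp_slid, efficiency = eff),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  if (is.character(x$efficiency))
    cat(sprintf("Coupling: %s (%.4g ATP, 0 bp slid)\n", x$efficiency, x$atp))
  else
    cat(sprintf("Coupling: %.3g ATP per bp (%.4g ATP / %.4g bp)\n",
                x$efficiency, x$atp, x$bp))
  invisible(x)
}

trace_from_input <- function(x, labelled_end = "left") {
  if (inherits(x, "assay_trace")) return(x)
  if (inherits(x, "sliding_ensemble")) return(fret_proxy(x, labelled_end))
  stop("expected an 'assay_trace' or 'sliding_ensemble'")
}

#' Fraction of the total signal change reached at a time point
#'
#' `(signal(0) - signal(t)) / (signal(0) - plateau)`, clamped to [0, 1].
#' The plateau is the mean over the final `plateau_frac` of the trace and must
#' be flat: if the signal still changes there by more than `plateau_tol` of
#' the total amplitude, no plateau is detectable and an error is raised.
#'
#' @param x An [assay_trace()] or a `sliding_ensemble` (reduced through
#'   [fret_proxy()]).
#' @param t Time in seconds; must lie within the trace.
#' @param plateau_frac Final fraction of the trace used as the plateau.
#' @param plateau_tol Flatness tolerance (fraction of total amplitude).
#' @return Completion fraction in [0, 1].
#' @export
completion_fraction <- function(x, t, plateau_frac = 0.2, plateau_tol = 0.05) {
  trace <- trace_from_input(x)
  tt <- trace$time; s <- trace$signal
  if (t < tt[1] || t > tt[length(tt)]) stop("'t' lies outside the trace")
  tail_idx <- tt >= tt[length(tt)] - plateau_frac * (tt[length(tt)] - tt[1])
  plateau <- mean(s[tail_idx])
  amp <- s[1] - plateau
  if (abs(amp) < .Machine$double.eps)
    stop("no plateau detectable: trace shows no net signal change")
  drift <- diff(range(s[tail_idx]))
  if (drift > plateau_tol * abs(amp))
    stop("no plateau detectable: trace still changing at its end")
  s_t <- stats::approx(tt, s, xout = t)$y
  min(1, max(0, (s[1] - s_t) / amp))
}
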