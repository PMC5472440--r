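#' Simulate nucleosome sliding by a dimeric remodeller
#'
#' Continuous-time stochastic simulation of dyad position for an ensemble of
#' independent nucleosomes, each engaged by one remodeller dimer that senses
#' the DNA flanking both sides of the octamer.
#'
#' The model: with flanks \eqn{(l_L, l_R)} (which always sum to
#' `dna_length - 147`), a 1 bp step toward side \eqn{i} (shrinking flank
#' \eqn{i}) has propensity \eqn{k_{step0}\,\sigma(l_i) + k_{leak}/2}, where
#' \eqn{\sigma} is a logistic sensing function with midpoint `s_sense` and
#' width `sense_width`. The net drift \eqn{k_{step0}(\sigma(l_{long}) -
#' \sigma(l_{short}))} therefore grows the shorter flank, vanishes at equal
#' flanks, and a fully flanked nucleosome (both \eqn{\sigma} high) undergoes
#' undirected stepping. Preferred positions every `well_period` bp (in
#' register with the start) slow well escape by \eqn{e^{-well\_depth}};
#' stepping onto a well when both flanks satisfy
#' \eqn{\sigma \ge arrest\_sigma} arrests the molecule with probability
#' `p_arrest` (the "slow stop" by progressive uncoupling). ATP hydrolysis
#' proceeds at `k_atp` per active motor irrespective of stepping; coupled and
#' leak steps debit the same ledger, so `atp_count >= steps` always. A dimer
#' with one working motor slides only in its productive orientation, drawn
#' with probability 1/2 at binding unless fixed in the [dimer_spec()].
#'
#' @param substrate An `aNb` string or [parse_substrate()] result.
#' @param dimer A [dimer_spec()]; default wild-type homodimer.
#' @param params A [sim_params()]; default the wild-type preset. Pass
#'   `sim_params("WTdCTD")` etc. for variants.
#' @param t_end Simulated time in seconds.
#' @param n_molecules Ensemble size.
#' @param seed Optional integer seed (recorded in the result).
#' @param n_out Number of output time points (including 0 and `t_end`).
#' @return Object of class `"sliding_ensemble"`: `time` (length `n_out`),
#'   matrices `disp` (dyad displacement in bp from the start, molecules in
#'   rows) and `atp` (cumulative ATP per molecule), `steps`, `arrested`,
#'   `arrest_time`, `productive`, `final_left_flank`, plus the substrate,
#'   dimer, params and seed.
#' @examples
#' ens <- simulate_sliding("0N100", t_end = 200, n_molecules = 20, seed = 1)
#' summary(ens)
#' @export
simulate_sliding <- function(substrate, dimer = dimer_spec("WT", "WT"),
                             params = sim_params("WT"), t_end = 300,
                             n_molecules = 100, seed = NULL, n_out = 201) {
  sub <- parse_substrate(substrate)
  stopifnot(inherits(dimer, "dimer_spec"), inherits(params, "sim_params"))
  if (n_molecules < 1) stop("'n_molecules' must be >= 1")
  if (t_end <= 0) stop("'t_end' must be > 0")
  if (sub$dna_length < sub$footprint)
    stop("substrate shorter than the nucleosome footprint")
  if (!is.null(seed)) set.seed(seed)
  total <- sub$left_flank + sub$right_flank
  out_times <- seq(0, t_end, length.out = max(n_out, 2L))
  res <- .sim_core(as.integer(n_molecules), out_times,
                   as.integer(sub$left_flank), as.integer(total),
                   params$k_step0, params$s_sense, params$sense_width,
                   dimer$n_active_motors * params$k_atp,
                   params$p_arrest, params$arrest_sigma,
                   as.integer(params$well_period), params$well_depth,
                   params$k_leak, dimer$p_productive)
  structure(list(time = out_times, disp = res$disp, atp = res$atp,
                 steps = res$steps, arrested = res$arrested,
                 arrest_time = res$arrest_time, productive = res$productive,
                 final_left_flank = res$final_l,
                 substrate = sub, dimer = dimer, params = params,
                 seed = seed),
            class = "sliding_ensemble")
}

#' @export
print.sliding_ensemble <- function(x, ...) {
  n <- nrow(x$disp)
  cat(sprintf("Sliding ensemble: %d molecules on %s, %s:%s dimer, preset %s, %g s\n",
              n, x$substrate$name, x$dimer$protomer_a, x$dimer$protomer_b,
              x$params$preset, max(x$time)))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' @export
summary.sliding_ensemble <- function(object, ...) {
  print(object)
  fin <- object$disp[, ncol(object$disp)]
  cat(sprintf("  final displacement: mean %.2f bp, mean |d| %.2f bp\n",
              mean(fin), mean(abs(fin))))
  cat(sprintf("  arrested: %.1f%%; mean ATP %.1f; mean steps %.1f\n",
              100 * mean(object$arrested),
              mean(object$atp[, ncol(object$atp)]), mean(object$steps)))
  invisible(object)
}

#' @export
plot.sliding_ensemble <- function(x, n_show = 20, ...) {
  n <- min(n_show, nrow(x$disp))
  graphics::matplot(x$time, t(x$disp[seq_len(n), , drop = FALSE]),
                    type = "l", lty = 1, col = grDevices::grey(0.5, 0.4),
                    xlab = "time (s)", ylab = "dyad displacement (bp)", ...)
  graphics::lines(x$time, colMeans(x$disp), lwd = 2)
  invisible(x)
}

#' Mean ATP consumed per molecule up to a time
#'
#' @param ensemble A `sliding_ensemble`.
#' @param t Time (s); defaults to the end of the run.
#' @return Mean cumulative ATP per molecule at `t` (linear interpolation on
#'   the output grid).
#' @export
atp_consumed <- function(ensemble, t = max(ensemble$time)) {
  stopifnot(inherits(ensemble, "sliding_ensemble"))
  stats::approx(ensemble$time, colMeans(ensemble$atp), xout = t)$y
}

#' Mean absolute dyad displacement at a time
#'
#' @param ensemble A `sliding_ensemble`.
#' @param t Time (s); defaults to the end of the run.
#' @return Mean of |displacement| over molecules, in bp.
#' @export
mean_abs_displacement <- function(ensemble, t = max(ensemble$time)) {
  stopifnot(inherits(ensemble, "sliding_ensemble"))
  stats::approx(ensemble$time,
                colMeans(abs(ensemble$disp)), xout = t)$y
}

#' Reduce an ensemble's end points to a gel-band ladder
#'
#' Final dyad positions are binned to the nearest preferred position (the
#' well grid, `well_period` bp in register with the start position); wells
#' holding at least `occupancy_threshold` of the molecules are reported as
#' bands, positioned as bp offsets from the DNA centre (0 = centred,
#' positive = toward the originally longer right flank).
#'
#' @param ensemble A `sliding_ensemble`.
#' @param occupancy_threshold Minimum occupancy fraction for a band.
#' @return Object of class `"band_pattern"`: data frame `bands` (columns
#'   `offset_bp`, `occupancy`) plus the sub-threshold mass.
#' @export
band_pattern <- function(ensemble, occupancy_threshold = 0.05) {
  stopifnot(inherits(ensemble, "sliding_ensemble"))
  l <- ensemble$final_left_flank
  if (!length(l)) stop("empty ensemble")
  a0 <- ensemble$substrate$left_flank
  per <- ensemble$params$well_period
  total <- a0 + ensemble$substrate$right_flank
  lw <- a0 + per * round((l - a0) / per)        # snap to the well grid
  offset <- lw - total / 2                       # bp from DNA centre
  tab <- table(offset)
  occ <- as.numeric(tab) / length(l)
  keep <- occ >= occupancy_threshold
  bands <- data.frame(offset_bp = as.numeric(names(tab))[keep],
                      occupancy = occ[keep])
  bands <- bands[order(bands$offset_bp), ]
  rownames(bands) <- NULL
  structure(list(bands = bands, below_threshold = 1 - sum(bands$occupancy),
                 threshold = occupancy_threshold, well_period = per),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("Band pattern: %d band(s) (occupancy >= %.2g)\n",
              nrow(x$bands), x$threshold))
  print(x$bands)
  invisible(x)
}

#' FRET read-out proxy for a simulated ensemble
#'
#' Maps dyad trajectories to the normalised donor-acceptor signal of an
#' end-labelled sliding assay: each molecule contributes
#' \eqn{\exp(-d / decay)} where \eqn{d} is the distance (bp) from the
#' labelled DNA end to the octamer edge, so the mean signal is monotone in
#' that distance; the trace is normalised to an initial value of 1.
#'
#' @param ensemble A `sliding_ensemble`.
#' @param labelled_end `"left"` or `"right"`.
#' @param decay FRET distance constant in bp.
#' @return An [assay_trace()] of kind `"sliding_fret"`.
#' @export
fret_proxy <- function(ensemble, labelled_end = c("left", "right"),
                       decay = 10) {
  stopifnot(inherits(ensemble, "sliding_ensemble"))
  labelled_end <- match.arg(labelled_end)
  if (!nrow(ensemble$disp)) stop("empty ensemble")
  a0 <- ensemble$substrate$left_flank
  total <- a0 + ensemble$substrate$right_flank
  l <- ensemble$disp + a0                      # left flank over time
  d <- if (labelled_end == "left") l else total - l
  sig <- colMeans(exp(-d / decay))
  assay_trace(ensemble$time, sig / sig[1], kind = "sliding_fret",
              meta = list(substrate = ensemble$substrate$name,
                          labelled_end = labelled_end, decay = decay))
}

#' Operational flank-sensing limit of a parameter set
#'
#' Simulates centrally positioned `xNx` substrates over a grid of symmetric
#' flank lengths and returns the largest `x` at which the ensemble shows no
#' net sliding (mean absolute dyad displacement below `threshold`). Wild-type
#' parameters keep centred nucleosomes parked up to 50 bp flanks; once both
#' flanks exceed the sensing range the dimer can no longer tell where the
#' ends are and the nucleosomes mobilise.
#'
#' @param params A [sim_params()] or preset name.
#' @param flank_grid Symmetric flank lengths to probe (bp).
#' @param dimer Dimer used for the probe; defaults to an active homodimer.
#' @param n_molecules,t_end Ensemble size and simulated time per flank length.
#' @param threshold Displacement threshold in bp.
#' @param seed Optional seed.
#' @return Largest grid value with mean |displacement| < `threshold`
#'   (or `NA` if none), with the per-flank means as attribute `profile`.
#' @export
sensing_range <- function(params = sim_params("WT"),
                          flank_grid = seq(20, 80, by = 10),
                          dimer = dimer_spec("WT", "WT"),
                          n_molecules = 300, t_end = 3600,
                          threshold = 2, seed = NULL) {
  if (is.character(params)) params <- sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  prof <- vapply(flank_grid, function(x) {
    ens <- simulate_sliding(sprintf("%dN%d", x, x), dimer = dimer,
                            params = params, t_end = t_end,
                            n_molecules = n_molecules, n_out = 2L)
    mean(abs(ens$disp[, 2L]))
  }, numeric(1))
  parked <- flank_grid[prof < threshold]
  out <- if (length(parked)) max(parked) else NA_integer_
  attr(out, "profile") <- data.frame(flank = flank_grid, mean_abs_disp = prof)
  out
}
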