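# Independent oracles used to freeze expected values. Each is a direct,
# brute-force computation kept separate from the implementation it checks.

# Direct arithmetic evaluation of the saturation curve (no shared code path:
# written out exactly as the algebra reads).
oracle_hill <- function(P, K, h, Fmin = 0, Fmax = 1) {
  Fmin + (Fmax - Fmin) * P^h / (K^h + P^h)
}

# Closed-form simple linear regression (slope/intercept from covariances).
oracle_lm <- function(x, y) {
  sx <- x - mean(x); sy <- y - mean(y)
  slope <- sum(sx * sy) / sum(sx^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Pairwise line intersection by hand algebra.
oracle_intersection <- function(Y1, S1, Y2, S2) (Y2 - Y1) / (S1 - S2)

# Brute-force gel-band oracle: histogram final positions on the well grid and
# threshold occupancies.
oracle_bands <- function(final_l, a0, total, period, threshold) {
  lw <- a0 + period * round((final_l - a0) / period)
  off <- lw - total / 2
  tab <- table(off)
  occ <- as.numeric(tab) / length(final_l)
  data.frame(offset_bp = as.numeric(names(tab))[occ >= threshold],
             occupancy = occ[occ >= threshold])
}

# Enumeration of ordered protomer pairs, collapsed to unordered dimer types.
oracle_dimer_probs <- function(fractions) {
  sp <- names(fractions)
  out <- list()
  for (a in sp) for (b in sp) {
    key <- paste(sort(c(a, b)), collapse = ":")
    out[[key]] <- (out[[key]] %||% 0) + fractions[[a]] * fractions[[b]]
  }
  unlist(out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hand-built ensemble for read-out tests.
fake_ensemble <- function(disp, time = seq(0, 10, length.out = ncol(disp)),
                          substrate = "0N100", params = sim_params("WT")) {
  sub <- parse_substrate(substrate)
  structure(list(time = time, disp = disp,
                 atp = matrix(0, nrow(disp), ncol(disp)),
                 steps = rep(0L, nrow(disp)),
                 arrested = rep(FALSE, nrow(disp)),
                 arrest_time = rep(NA_real_, nrow(disp)),
                 productive = rep(TRUE, nrow(disp)),
                 final_left_flank = sub$left_flank + disp[, ncol(disp)],
                 substrate = sub, dimer = dimer_spec("WT", "WT"),
                 params = params, seed = NULL),
            class = "sliding_ensemble")
}
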