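#' Protomer species mixture
#'
#' Fractions of complex species in a reaction (e.g. an equimolar wild-type /
#' ATPase-dead mixture). Species must be known to the preset registry
#' (`WT`, `EA`, `WTdCTD`, `EAdCTD`).
#'
#' @param fractions Named numeric vector of species fractions, nonnegative,
#'   summing to 1 (within `tol`).
#' @param tol Tolerance on the fraction sum.
#' @return Object of class `"species_mix"`.
#' @examples
#' species_mix(c(WT = 0.5, EA = 0.5))
#' @export
species_mix <- function(fractions, tol = 1e-8) {
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    stop("'fractions' must be a named vector of species fractions")
  attrs <- species_attributes()
  unknown <- setdiff(names(fractions), rownames(attrs))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > tol)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  structure(list(fractions = fractions,
                 attributes = attrs[names(fractions), , drop = FALSE]),
            class = "species_mix")
}

#' @export
print.species_mix <- function(x, ...) {
  cat("Species mixture:",
      paste(sprintf("%s = %.3g", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  invisible(x)
}

dimer_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = ":")
}

#' Random-pairing (Punnett) dimer distribution
#'
#' Protomers pair at random, so unordered dimer probabilities follow
#' Hardy-Weinberg combinatorics: \eqn{p(i,i) = f_i^2} and
#' \eqn{p(i,j) = 2 f_i f_j} for \eqn{i \ne j}. An equimolar two-species mix
#' gives the 1:2:1 homodimer:heterodimer:homodimer square.
#'
#' @param mix A [species_mix()] or a named fraction vector.
#' @return Object of class `"dimer_distribution"`: data frame with
#'   `protomer_a`, `protomer_b`, `dimer` (sorted `a:b` key) and `prob`.
#' @examples
#' dimer_distribution(c(WT = 0.5, EA = 0.5))  # 0.25 / 0.5 / 0.25
#' @export
dimer_distribution <- function(mix) {
  if (!inherits(mix, "species_mix")) mix <- species_mix(mix)
  sp <- names(mix$fractions)
  f <- mix$fractions
  rows <- list()
  for (i in seq_along(sp)) for (j in i:length(sp)) {
    p <- if (i == j) f[i]^2 else 2 * f[i] * f[j]
    rows[[length(rows) + 1L]] <-
      data.frame(protomer_a = sp[i], protomer_b = sp[j],
                 dimer = dimer_key(sp[i], sp[j]), prob = unname(p))
  }
  d <- do.call(rbind, rows)
  d <- d[d$prob > 0, ]
  rownames(d) <- NULL
  structure(list(table = d, mix = mix), class = "dimer_distribution")
}

#' @export
print.dimer_distribution <- function(x, ...) {
  cat("Random-pairing dimer distribution:\n")
  print(x$table[, c("dimer", "prob")])
  invisible(x)
}

#' Per-dimer relative activity rules
#'
#' Builds the default relative sliding and ATPase activities (wild-type
#' homodimer = 1) for every dimer type in a distribution, from the protomer
#' attributes:
#'
#' * Motors — sliding needs at least one working motor: both active gives 1,
#'   a single active motor gives 0.5, none gives 0. With
#'   `heterodimer_mode = "orientation"` (default) the 0.5 encodes one
#'   productive orientation out of two equally likely ones (half the
#'   single-motor dimers slide at the full rate, half not at all); with
#'   `"uniform"` every single-motor dimer slides at half rate. The ensemble
#'   expectation is identical; the mode is recorded for trajectory-level use.
#'   ATPase scales with the number of active motors (0.5 per motor).
#' * CTDs — losing both C-terminal domains multiplies sliding by
#'   `ctd_sliding_factor` (default 0.2, the 5-fold drop) and ATPase by
#'   `ctd_atpase_factor` (default 2); a dimer with a single CTD takes the
#'   geometric mean of the intact and doubly truncated factors (a qualitative
#'   interpolation — the mixed-CTD dimers are not calibration targets).
#'
#' @param dist A [dimer_distribution()] (or mix convertible to one).
#' @param heterodimer_mode `"orientation"` or `"uniform"`.
#' @param ctd_sliding_factor,ctd_atpase_factor CTD-loss multipliers.
#' @return Object of class `"activity_rules"`: data frame with `dimer`,
#'   `sliding`, `atpase`.
#' @export
activity_rules <- function(dist,
                           heterodimer_mode = c("orientation", "uniform"),
                           ctd_sliding_factor = 0.2,
                           ctd_atpase_factor = 2) {
  heterodimer_mode <- match.arg(heterodimer_mode)
  if (!inherits(dist, "dimer_distribution")) dist <- dimer_distribution(dist)
  attrs <- species_attributes()
  tab <- dist$table
  sliding <- atpase <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    a <- tab$protomer_a[k]; b <- tab$protomer_b[k]
    motors <- attrs[a, "motor_active"] + attrs[b, "motor_active"]
    ctds <- attrs[a, "ctd_present"] + attrs[b, "ctd_present"]
    motor_sliding <- c(0, 0.5, 1)[motors + 1]
    ctd_sliding <- c(ctd_sliding_factor, sqrt(ctd_sliding_factor), 1)[ctds + 1]
    ctd_atpase <- c(ctd_atpase_factor, sqrt(ctd_atpase_factor), 1)[ctds + 1]
    sliding[k] <- motor_sliding * ctd_sliding
    atpase[k] <- (motors / 2) * ctd_atpase
  }
  structure(list(table = data.frame(dimer = tab$dimer, sliding = sliding,
                                    atpase = atpase),
                 heterodimer_mode = heterodimer_mode,
                 ctd_sliding_factor = ctd_sliding_factor,
                 ctd_atpase_factor = ctd_atpase_factor),
            class = "activity_rules")
}

#' @export
print.activity_rules <- function(x, ...) {
  cat(sprintf("Per-dimer activity rules (heterodimer mode: %s)\n",
              x$heterodimer_mode))
  print(x$table)
  invisible(x)
}

#' Predicted ensemble activity of a dimer mixture
#'
#' Expectation of per-dimer relative activities under the random-pairing
#' distribution; linear in the dimer probabilities. For an equimolar
#' wild-type / ATPase-dead mix the inactive homodimers (25 %) contribute
#' nothing, the wild-type homodimers (25 %) a quarter of the pure rate, and
#' the heterodimers (50 %) the remaining quarter, giving 50 % overall.
#'
#' @param dist A [dimer_distribution()] (or mix).
#' @param rules An [activity_rules()]; defaults to the rules derived from
#'   `dist`. Must cover every dimer type occurring in `dist`.
#' @return List of class `"activity_prediction"` with `sliding` and `atpase`
#'   relative rates (pure wild-type homodimer = 1).
#' @examples
#' predict_activity(dimer_distribution(c(WT = 0.5, EA = 0.5)))$sliding  # 0.5
#' @export
predict_activity <- function(dist, rules = activity_rules(dist)) {
  if (!inherits(dist, "dimer_distribution")) dist <- dimer_distribution(dist)
  stopifnot(inherits(rules, "activity_rules"))
  tab <- dist$table
  idx <- match(tab$dimer, rules$table$dimer)
  if (anyNA(idx))
    stop("missing activity rule for dimer type(s): ",
         paste(tab$dimer[is.na(idx)], collapse = ", "))
  structure(list(sliding = sum(tab$prob * rules$table$sliding[idx]),
                 atpase = sum(tab$prob * rules$table$atpase[idx]),
                 dist = dist, rules = rules),
            class = "activity_prediction")
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat(sprintf("Predicted ensemble activity (relative to pure WT): sliding %.3g, ATPase %.3g\n",
              x$sliding, x$atpase))
  invisible(x)
}

#' Predicted rate titration for a dimer mixture
#'
#' Composes dimer occupancy (the wild-type allosteric sigmoidal titration
#' preset) with the mixture's predicted relative activity to emit an
#' initial-rate titration ready for [fit_rate_titration()]: the plateau is
#' scaled by [predict_activity()], the half-saturation and cooperativity are
#' those of the occupancy preset (binding of the mutant complexes is
#' indistinguishable from wild type, so occupancy is mixture-independent).
#'
#' @param mix A [species_mix()] or named fraction vector.
#' @param assay `"sliding"` or `"atpase"`.
#' @param rules Optional [activity_rules()].
#' @param conc Protein concentration grid (nM).
#' @param reference Activity preset name used for the pure-WT curve.
#' @param ligand_conc Nucleosome concentration (nM).
#' @return A [titration()] of predicted rates with the prediction recorded in
#'   its `truth` attribute.
#' @export
mixture_titration <- function(mix, assay = c("sliding", "atpase"),
                              rules = NULL,
                              conc = c(12.5, 25, 50, 100, 200, 400, 800),
                              reference = "WT", ligand_conc = 100) {
  assay <- match.arg(assay)
  if (!inherits(mix, "species_mix")) mix <- species_mix(mix)
  dist <- dimer_distribution(mix)
  if (is.null(rules)) rules <- activity_rules(dist)
  pred <- predict_activity(dist, rules)
  ref <- activity_preset(reference, assay)
  rel <- if (assay == "sliding") pred$sliding else pred$atpase
  V <- rel * hill_response(conc, ref$K_half, ref$h, 0, ref$V_max)
  out <- titration(conc, V, ligand_conc = ligand_conc, unit = ref$unit)
  attr(out, "truth") <- list(relative_activity = rel, V_max = rel * ref$V_max,
                             K_half = ref$K_half, h = ref$h)
  out
}
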