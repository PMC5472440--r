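# Synthetic-assay generators. Every generator draws from a known model with
# recorded ground truth (the `truth` attribute), multiplicative Gaussian
# signal noise (default 2 %) and a fixed seed option, so each analysis stage
# has an automated recovery test without any external data.

apply_noise <- function(y, noise, floor_sd = 0) {
  if (noise < 0 || floor_sd < 0) stop("noise levels must be >= 0")
  y * (1 + stats::rnorm(length(y), 0, noise)) +
    if (floor_sd > 0) stats::rnorm(length(y), 0, floor_sd) else 0
}

#' Default two-fold dilution concentration grid
#'
#' Standard serial-dilution design: `n` points descending by factor 2 from
#' `top`, returned in increasing order.
#'
#' @param top Highest concentration.
#' @param n Number of points.
#' @return Increasing numeric vector.
#' @export
dilution_series <- function(top, n = 16) {
  sort(top / 2^(seq_len(n) - 1))
}

#' Generate a synthetic equilibrium-binding titration
#'
#' Hill-model responses (thermophoresis-style fraction bound) at a fixed
#' ligand concentration with multiplicative Gaussian noise. Defaults follow
#' the isolated-CTD vs 50 bp duplex design: 16-point two-fold dilution,
#' 2 % noise.
#'
#' @param preset A [binding_preset()] name, or `NULL` when passing the model
#'   explicitly.
#' @param K_half,h,F_min,F_max Model parameters (override the preset).
#' @param conc Concentration grid; default a 16-point two-fold series with
#'   top `20 * K_half`.
#' @param ligand_conc Fixed ligand concentration.
#' @param unit Concentration unit.
#' @param replicates Number of replicates.
#' @param noise Multiplicative Gaussian noise fraction.
#' @param seed Optional seed.
#' @return A [titration()] with the generating parameters in the `truth`
#'   attribute.
#' @examples
#' titr <- gen_binding_titration("CTD_DNA", replicates = 2, seed = 1)
#' @export
gen_binding_titration <- function(preset = "CTD_DNA", K_half = NULL, h = NULL,
                                  F_min = NULL, F_max = NULL, conc = NULL,
                                  ligand_conc = NULL, unit = NULL,
                                  replicates = 1, noise = 0.02, seed = NULL) {
  p <- if (is.null(preset)) list() else binding_preset(preset)
  K_half <- if (is.null(K_half)) p$K_half else K_half
  h <- if (is.null(h)) p$h else h
  F_min <- if (is.null(F_min)) if (is.null(p$F_min)) 0 else p$F_min else F_min
  F_max <- if (is.null(F_max)) if (is.null(p$F_max)) 1 else p$F_max else F_max
  unit <- if (is.null(unit)) if (is.null(p$unit)) "nM" else p$unit else unit
  ligand_conc <- if (is.null(ligand_conc)) {
    if (is.null(p$ligand_conc)) NA_real_ else p$ligand_conc
  } else ligand_conc
  if (is.null(conc)) conc <- dilution_series(20 * K_half)
  if (!is.null(seed)) set.seed(seed)
  conc_all <- rep(conc, replicates)
  rep_id <- rep(seq_len(replicates), each = length(conc))
  y <- hill_response(conc_all, K_half, h, F_min, F_max)
  y <- apply_noise(y, noise)
  out <- titration(conc_all, y, ligand_conc = ligand_conc, unit = unit,
                   replicate = rep_id)
  attr(out, "truth") <- list(K_half = K_half, h = h, F_min = F_min,
                             F_max = F_max, noise = noise)
  out
}

#' Generate a synthetic saturation (stoichiometry) titration
#'
#' Two-segment response: linear rise with slope `S1` up to the breakpoint at
#' `ratio * ligand_conc` (all binding sites filled), then slope `S2`.
#' Defaults follow the saturation design with 500 nM nucleosomes and a
#' stoichiometry of two complexes per nucleosome.
#'
#' @param ratio True binding stoichiometry (complexes per ligand).
#' @param ligand_conc Fixed ligand concentration.
#' @param S1,S2,Y1 Segment slopes and unsaturated intercept.
#' @param conc Concentration grid; default 16 points spanning 0.2-5x the
#'   breakpoint.
#' @param unit Concentration unit.
#' @param replicates,noise,seed As in [gen_binding_titration()].
#' @return A [titration()] with ground truth attached.
#' @export
gen_stoichiometry_titration <- function(ratio = 2, ligand_conc = 500,
                                        S1 = 1, S2 = 0.02, Y1 = 0,
                                        conc = NULL, unit = "nM",
                                        replicates = 3, noise = 0.02,
                                        seed = NULL) {
  bp <- ratio * ligand_conc
  if (is.null(conc)) conc <- seq(0.2 * bp, 5 * bp, length.out = 16)
  if (!is.null(seed)) set.seed(seed)
  Y2 <- Y1 + (S1 - S2) * bp                      # continuity at the breakpoint
  conc_all <- rep(conc, replicates)
  rep_id <- rep(seq_len(replicates), each = length(conc))
  y <- ifelse(conc_all <= bp, Y1 + S1 * conc_all, Y2 + S2 * conc_all)
  y <- apply_noise(y, noise)
  out <- titration(conc_all, y, ligand_conc = ligand_conc, unit = unit,
                   replicate = rep_id)
  attr(out, "truth") <- list(ratio = ratio, breakpoint = bp, S1 = S1, S2 = S2,
                             Y1 = Y1, Y2 = Y2, noise = noise)
  out
}

#' Generate a synthetic initial-rate titration
#'
#' Initial velocities vs protein concentration from a dimer-activity preset
#' (allosteric sigmoidal for nucleosome-stimulated sliding and ATPase,
#' straight line through the origin for unstimulated ATPase), with
#' multiplicative noise. The default design: 12.5-800 nM protein in two-fold
#' steps, 100 nM nucleosome, 3 replicates, 2 % noise.
#'
#' @param assay `"sliding"`, `"atpase"` or `"basal_atpase"` (no nucleosome).
#' @param preset Activity preset name (`"WT"` or `"dCTD"`).
#' @param mix Optional [species_mix()]: rates are scaled by the Punnett
#'   prediction via [mixture_titration()] semantics.
#' @param conc Protein concentration grid (nM).
#' @param ligand_conc Nucleosome concentration (nM; `NA` for basal).
#' @param replicates,noise,seed As in [gen_binding_titration()].
#' @return A [titration()] with ground truth attached.
#' @examples
#' rt <- gen_rate_titration("sliding", "WT", seed = 3)
#' @export
gen_rate_titration <- function(assay = c("sliding", "atpase", "basal_atpase"),
                               preset = "WT", mix = NULL,
                               conc = c(12.5, 25, 50, 100, 200, 400, 800),
                               ligand_conc = 100, replicates = 3,
                               noise = 0.02, seed = NULL) {
  assay <- match.arg(assay)
  if (!is.null(seed)) set.seed(seed)
  conc_all <- rep(conc, replicates)
  rep_id <- rep(seq_len(replicates), each = length(conc))
  if (assay == "basal_atpase") {
    slope <- nucleoslide_presets()$activity[[preset]]$basal_atpase_slope
    v <- slope * conc_all
    truth <- list(model = "linear", slope = slope, noise = noise)
    ligand_conc <- NA_real_
    unit <- "nM"
  } else {
    p <- activity_preset(preset, assay)
    rel <- 1
    if (!is.null(mix)) {
      pred <- predict_activity(dimer_distribution(mix))
      rel <- if (assay == "sliding") pred$sliding else pred$atpase
    }
    v <- rel * hill_response(conc_all, p$K_half, p$h, 0, p$V_max)
    truth <- list(model = "sigmoidal", V_max = rel * p$V_max,
                  K_half = p$K_half, h = p$h, relative_activity = rel,
                  noise = noise)
    unit <- p$unit
  }
  v <- apply_noise(v, noise)
  out <- titration(conc_all, v, ligand_conc = ligand_conc, unit = unit,
                   replicate = rep_id)
  attr(out, "truth") <- truth
  out
}

#' Generate paired synthetic sliding / ATPase kinetic traces
#'
#' Emulates the one-pot assay (dual-labelled nucleosomes plus the
#' NADH-coupled ATP regeneration system): a sliding FRET trace and an NADH
#' absorbance trace whose slope encodes the ATPase rate through a synthetic
#' ADP standard.
#'
#' With `source = "analytic"` the sliding signal is an exponential decay with
#' the requested time constant and the NADH signal falls linearly at
#' `atp_rate * standard slope`; with `source = "simulator"` both traces are
#' reduced from a [simulate_sliding()] ensemble (FRET via [fret_proxy()],
#' NADH from the bulk ATP ledger at the given nucleosome concentration).
#'
#' @param source `"analytic"` or `"simulator"`.
#' @param preset Simulator preset (also selects the dead-motor `EA` flat
#'   trace for the analytic source).
#' @param substrate Substrate name for the simulator source.
#' @param t_end,n_time Trace span (s) and number of samples.
#' @param tau_slide Analytic sliding time constant (s).
#' @param atp_rate Analytic bulk ATPase rate (µM ATP/s).
#' @param nucleosome_conc Nucleosome concentration (µM) for the simulator
#'   bulk conversion.
#' @param standard_slope ADP standard slope (FU/µM, negative: NADH falls).
#' @param nadh_conc NADH concentration (µM).
#' @param n_molecules Simulator ensemble size.
#' @param noise,seed As in [gen_binding_titration()].
#' @return List of class `"kinetic_traces"`: `sliding` and `atpase`
#'   [assay_trace()]s, the [adp_standard()], and `truth`.
#' @export
gen_kinetic_traces <- function(source = c("analytic", "simulator"),
                               preset = "WT", substrate = "0N100",
                               t_end = 300, n_time = 151, tau_slide = 30,
                               atp_rate = 0.44, nucleosome_conc = 0.1,
                               standard_slope = -300, nadh_conc = 200,
                               n_molecules = 200, noise = 0.02, seed = NULL) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  std <- adp_standard(standard_slope, nadh_conc)
  tt <- seq(0, t_end, length.out = n_time)
  nadh0 <- nadh_conc * abs(standard_slope)
  if (source == "analytic") {
    is_dead <- preset %in% c("EA", "EAdCTD")
    s_slide <- if (is_dead) rep(1, n_time) else exp(-tt / tau_slide)
    atp_uM <- if (is_dead) rep(0, n_time) else atp_rate * tt
    truth <- list(source = source, tau_slide = if (is_dead) Inf else tau_slide,
                  atp_rate = if (is_dead) 0 else atp_rate)
  } else {
    sp <- sim_params(preset)
    dm <- dimer_spec(preset, preset)
    ens <- simulate_sliding(substrate, dimer = dm, params = sp, t_end = t_end,
                            n_molecules = n_molecules, n_out = n_time)
    fr <- fret_proxy(ens)
    s_slide <- fr$signal
    atp_uM <- colMeans(ens$atp) * nucleosome_conc  # bulk µM at 1 dimer/nucleosome
    t50 <- tt[which(abs(s_slide - s_slide[1]) >=
                      0.5 * abs(s_slide[length(s_slide)] - s_slide[1]))[1]]
    truth <- list(source = source, ensemble = ens,
                  t_half = t50,
                  atp_rate = dm$n_active_motors * sp$k_atp * nucleosome_conc)
  }
  slide_fu <- apply_noise(1e5 * s_slide, noise)
  nadh_fu <- apply_noise(nadh0 - abs(standard_slope) * atp_uM, noise)
  out <- list(
    sliding = assay_trace(tt, slide_fu, "sliding_fret",
                          meta = list(substrate = substrate, preset = preset)),
    atpase = assay_trace(tt, nadh_fu, "atpase_nadh",
                         meta = list(substrate = substrate, preset = preset,
                                     nucleosome_conc_uM = nucleosome_conc)),
    standard = std, truth = truth)
  class(out) <- "kinetic_traces"
  out
}

#' @export
print.kinetic_traces <- function(x, ...) {
  cat("Paired synthetic kinetic traces (sliding FRET + NADH ATPase)\n")
  print(x$sliding); print(x$atpase)
  invisible(x)
}

#' Generate a synthetic gel mobility shift (EMSA) titration
#'
#' Bound fraction from the Hill model mapped to free and shifted band
#' intensities. Noise perturbs the bound fraction, so total signal per lane
#' is conserved by construction (as for a fixed amount of labelled probe).
#'
#' @param preset Binding preset; default the CTD-DNA design (50 nM duplex,
#'   apparent K around 1 µM).
#' @param conc Protein concentration grid.
#' @param total_signal Per-lane total intensity.
#' @param noise,seed As in [gen_binding_titration()].
#' @return Data frame of class `"emsa_table"` with columns `conc`, `free`,
#'   `shifted`; ground truth attached.
#' @export
gen_emsa <- function(preset = "CTD_DNA", conc = NULL, total_signal = 1000,
                     noise = 0.02, seed = NULL) {
  p <- binding_preset(preset)
  if (is.null(conc)) conc <- dilution_series(20 * p$K_half, 12)
  if (!is.null(seed)) set.seed(seed)
  theta <- hill_response(conc, p$K_half, p$h)
  theta <- pmin(1, pmax(0, apply_noise(theta, noise)))
  out <- data.frame(conc = conc, free = (1 - theta) * total_signal,
                    shifted = theta * total_signal)
  attr(out, "truth") <- list(K_half = p$K_half, h = p$h, unit = p$unit,
                             total_signal = total_signal)
  attr(out, "unit") <- p$unit
  class(out) <- c("emsa_table", "data.frame")
  out
}
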