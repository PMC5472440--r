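# Preset registry: a versioned YAML file shipped with the package holds the
# simulator rate laws, species attributes, binding and activity presets.

presets_env <- new.env(parent = emptyenv())

#' Load the packaged parameter presets
#'
#' @param path Optional alternative presets file (YAML).
#' @return The full presets list (`simulator`, `species`, `binding`,
#'   `activity`, `stoichiometry`).
#' @export
nucleoslide_presets <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(presets_env$presets)) {
      f <- system.file("extdata", "presets.yaml", package = "nucleoslide",
                       mustWork = TRUE)
      presets_env$presets <- yaml::read_yaml(f)
    }
    return(presets_env$presets)
  }
  yaml::read_yaml(path)
}

species_attributes <- function() {
  sp <- nucleoslide_presets()$species
  out <- do.call(rbind, lapply(sp, function(s)
    c(motor_active = isTRUE(s$motor_active), ctd_present = isTRUE(s$ctd_present))))
  rownames(out) <- names(sp)
  out
}

#' Simulator rate-law parameters
#'
#' Returns the mechanistic parameters of the sliding simulator, starting from
#' a named preset (`"WT"`, `"EA"`, `"WTdCTD"`, `"EAdCTD"`) with optional
#' overrides.
#'
#' Parameters: `k_step0` (bp/s, maximal coupled stepping rate), `s_sense`
#' (bp, flank-sensing midpoint), `sense_width` (bp, logistic softness),
#' `k_atp` (1/s, ATP turnover per active nucleosome-bound motor), `p_arrest`
#' (per-well-crossing arrest probability once both flanks are sensed),
#' `arrest_sigma` (sensing level required of both flanks for arrest),
#' `well_period` (bp), `well_depth` (dimensionless landscape bias) and
#' `k_leak` (1/s, undirected flank-independent stepping).
#'
#' @param preset Preset name.
#' @param ... Named overrides of individual parameters.
#' @return Object of class `"sim_params"`.
#' @examples
#' sim_params("WT", k_atp = 2.0)
#' @export
sim_params <- function(preset = "WT", ...) {
  presets <- nucleoslide_presets()$simulator
  if (!preset %in% names(presets))
    stop("unknown simulator preset '", preset, "'; known: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[preset]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown simulator parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  rates <- c("k_step0", "k_atp", "k_leak")
  if (any(unlist(p[rates]) < 0)) stop("rates must be >= 0")
  if (p$p_arrest < 0 || p$p_arrest > 1) stop("'p_arrest' must be in [0, 1]")
  if (p$well_period < 1) stop("'well_period' must be >= 1")
  if (p$sense_width <= 0) stop("'sense_width' must be > 0")
  p$preset <- preset
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulator parameters (preset %s):\n", x$preset))
  cat(sprintf("  k_step0 %.3g bp/s, sensing %g +/- %g bp, k_atp %.3g /s/motor\n",
              x$k_step0, x$s_sense, x$sense_width, x$k_atp))
  cat(sprintf("  wells every %g bp (depth %.3g), p_arrest %.3g (sigma >= %.3g), k_leak %.3g /s\n",
              x$well_period, x$well_depth, x$p_arrest, x$arrest_sigma, x$k_leak))
  invisible(x)
}

#' Cooperative-binding preset
#'
#' @param name `"CTD_DNA"` (isolated CTD vs 50 bp duplex, K_1/2 1.0 µM,
#'   h 1.8), `"WT_nucleosome"` or `"dCTD_nucleosome"`.
#' @return List with `K_half`, `h`, `F_min`, `F_max`, `unit`, `ligand_conc`.
#' @export
binding_preset <- function(name = "CTD_DNA") {
  presets <- nucleoslide_presets()$binding
  if (!name %in% names(presets))
    stop("unknown binding preset '", name, "'")
  presets[[name]]
}

#' Dimer-activity (rate-titration) preset
#'
#' @param name `"WT"` or `"dCTD"`.
#' @param assay `"sliding"` or `"atpase"`.
#' @return List with `V_max`, `K_half`, `h`, `unit`.
#' @export
activity_preset <- function(name = "WT", assay = c("sliding", "atpase")) {
  assay <- match.arg(assay)
  presets <- nucleoslide_presets()$activity
  if (!name %in% names(presets))
    stop("unknown activity preset '", name, "'")
  presets[[name]][[assay]]
}
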