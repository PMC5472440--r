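NUC_FOOTPRINT <- 147L

#' Parse an aNb nucleosome substrate name
#'
#' Substrates are named by their flanking DNA: `"aNb"` means `a` bp of free
#' DNA to the left of the 147 bp octamer footprint and `b` bp to the right
#' (`"0N100"` is end-positioned with a 100 bp overhang, `"50N50"` is centred).
#'
#' @param name An `aNb` string, or an existing `nucleosome_substrate`.
#' @return An object of class `"nucleosome_substrate"`: `left_flank`,
#'   `right_flank`, `footprint` (147), `dna_length` and the canonical `name`.
#' @examples
#' parse_substrate("0N100")$dna_length  # 247
#' @export
parse_substrate <- function(name) {
  if (inherits(name, "nucleosome_substrate")) return(name)
  if (!is.character(name) || length(name) != 1L ||
      !grepl("^[0-9]+N[0-9]+$", name))
    stop("substrate name must match digits-N-digits, e.g. '0N100'")
  parts <- as.integer(strsplit(name, "N", fixed = TRUE)[[1]])
  structure(list(left_flank = parts[1], right_flank = parts[2],
                 footprint = NUC_FOOTPRINT,
                 dna_length = parts[1] + NUC_FOOTPRINT + parts[2],
                 name = paste0(parts[1], "N", parts[2])),
            class = "nucleosome_substrate")
}

#' @export
print.nucleosome_substrate <- function(x, ...) {
  cat(sprintf("Nucleosome substrate %s: %d bp DNA (%d | [%d] | %d)\n",
              x$name, x$dna_length, x$left_flank, x$footprint, x$right_flank))
  invisible(x)
}

#' Specify a remodeller dimer
#'
#' Two protomer species from `{WT, EA, WTdCTD, EAdCTD}` (EA = Walker-motif
#' point mutant with a dead motor; dCTD = C-terminal domain truncation).
#' A dimer with exactly one working motor is productive for sliding in only
#' one of its two binding orientations; unless an orientation is fixed, each
#' molecule draws its orientation with equal probability at binding.
#'
#' @param protomer_a,protomer_b Species labels.
#' @param orientation `NULL` (random, the default), `"a_leads"` or
#'   `"b_leads"`. Only meaningful when the protomers differ in capability.
#' @return Object of class `"dimer_spec"` with derived per-protomer
#'   `motor_active` and `ctd_present` flags, the number of active motors and
#'   the probability that a bound dimer is sliding-productive.
#' @examples
#' dimer_spec("WT", "EA")$p_productive  # 0.5
#' @export
dimer_spec <- function(protomer_a = "WT", protomer_b = protomer_a,
                       orientation = NULL) {
  attrs <- species_attributes()
  for (sp in c(protomer_a, protomer_b))
    if (!sp %in% rownames(attrs))
      stop("unknown protomer species '", sp, "'; known: ",
           paste(rownames(attrs), collapse = ", "))
  motor <- c(a = attrs[protomer_a, "motor_active"],
             b = attrs[protomer_b, "motor_active"])
  ctd <- c(a = attrs[protomer_a, "ctd_present"],
           b = attrs[protomer_b, "ctd_present"])
  n_active <- sum(motor)
  if (!is.null(orientation)) {
    orientation <- match.arg(orientation, c("a_leads", "b_leads"))
    if (protomer_a == protomer_b)
      stop("orientation is defined only when the protomers differ in capability")
  }
  # one working motor: productive when that motor leads; both: always;
  # none: never
  p_productive <- if (n_active == 2L) 1
    else if (n_active == 0L) 0
    else if (is.null(orientation)) 0.5
    else as.numeric((orientation == "a_leads") == unname(motor["a"]))
  structure(list(protomer_a = protomer_a, protomer_b = protomer_b,
                 orientation = orientation, motor_active = motor,
                 ctd_present = ctd, n_active_motors = n_active,
                 p_productive = p_productive),
            class = "dimer_spec")
}

#' @export
print.dimer_spec <- function(x, ...) {
  cat(sprintf("Remodeller dimer %s:%s — %d active motor(s), %d CTD(s), P(productive) = %.2g\n",
              x$protomer_a, x$protomer_b, x$n_active_motors,
              sum(x$ctd_present), x$p_productive))
  invisible(x)
}
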