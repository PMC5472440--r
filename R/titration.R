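#' Construct a titration object
#'
#' A titration is the unit of binding and rate analysis: an ordered series of
#' titrant (protein) concentrations with a measured response (fraction bound,
#' thermophoresis FNorm, or an initial rate) at a fixed ligand concentration.
#'
#' @param conc Numeric vector of titrant concentrations, strictly positive and,
#'   within each replicate, strictly increasing.
#' @param response Numeric response of the same length as `conc`.
#' @param ligand_conc Fixed ligand (nucleosome or DNA) concentration, in the
#'   same unit as `conc`. May be `NA` when irrelevant.
#' @param unit Concentration unit label carried through fits (e.g. `"nM"`,
#'   `"uM"`). All fits are performed and reported in this unit.
#' @param replicate Optional replicate labels (recycled if length 1).
#'
#' @return A data frame of class `"titration"` with columns `conc`, `response`,
#'   `replicate` and attributes `unit` and `ligand_conc`.
#' @examples
#' titr <- titration(c(1, 2, 4, 8, 16, 32), hill_response(c(1, 2, 4, 8, 16, 32), 4, 2),
#'                   ligand_conc = 0.5, unit = "uM")
#' @export
titration <- function(conc, response, ligand_conc = NA_real_, unit = "nM",
                      replicate = 1L) {
  if (!is.numeric(conc) || !is.numeric(response))
    stop("'conc' and 'response' must be numeric")
  if (length(conc) != length(response))
    stop("'conc' and 'response' must have the same length")
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be finite and strictly positive")
  if (any(!is.finite(response)))
    stop("responses must be finite")
  replicate <- rep_len(replicate, length(conc))
  for (r in unique(replicate)) {
    cc <- conc[replicate == r]
    if (any(diff(cc) <= 0))
      stop("concentrations must be strictly increasing within replicate '", r, "'")
  }
  if (!is.na(ligand_conc) && ligand_conc <= 0)
    stop("'ligand_conc' must be positive")
  out <- data.frame(conc = conc, response = response, replicate = replicate)
  attr(out, "unit") <- unit
  attr(out, "ligand_conc") <- ligand_conc
  class(out) <- c("titration", "data.frame")
  out
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("Titration: %d points, %d replicate(s), [titrant] %.4g-%.4g %s\n",
              nrow(x), length(unique(x$replicate)),
              min(x$conc), max(x$conc), attr(x, "unit")))
  lig <- attr(x, "ligand_conc")
  if (!is.na(lig))
    cat(sprintf("Fixed ligand concentration: %.4g %s\n", lig, attr(x, "unit")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

conc_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "conc" else u
}

#' Write a titration to a delimited text file
#'
#' Tables are comma-delimited UTF-8 with a single header row; the unit is
#' encoded in the concentration column name (e.g. `conc_nM`) and the fixed
#' ligand concentration and any generator ground truth are stored in leading
#' `#`-comment metadata lines, so a file round-trips through
#' [read_titration()] unchanged.
#'
#' @param x A [titration()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(x, path) {
  stopifnot(inherits(x, "titration"))
  meta <- c(sprintf("# ligand_conc: %.15g", attr(x, "ligand_conc")),
            sprintf("# unit: %s", attr(x, "unit")))
  truth <- attr(x, "truth")
  if (!is.null(truth))
    meta <- c(meta, sprintf("# truth.%s: %.15g", names(truth), unlist(truth)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  df <- data.frame(conc = x$conc, response = x$response, replicate = x$replicate)
  names(df)[1] <- paste0("conc_", attr(x, "unit"))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]*:", "", body))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  meta
}

#' Read a titration written by [write_titration()]
#'
#' Validates the header (a `conc_<unit>` column, `response`, optional
#' `replicate`), column types and within-replicate concentration ordering.
#' Non-numeric cells (including locale decimal commas) are a parse error,
#' never a silent misread.
#'
#' @param path Input file path.
#' @return A [titration()] object; generator ground truth, if present in the
#'   file, is restored as the `truth` attribute.
#' @export
read_titration <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta]
  if (length(body) < 2L) stop("no data rows in '", path, "'")
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  conc_col <- grep("^conc(_|$)", names(df), value = TRUE)
  if (length(conc_col) != 1L || !("response" %in% names(df)))
    stop("titration table must have columns 'conc_<unit>' and 'response'; got: ",
         paste(names(df), collapse = ", "))
  extra <- setdiff(names(df), c(conc_col, "response", "replicate"))
  if (length(extra))
    stop("unknown column(s) in titration table: ", paste(extra, collapse = ", "))
  for (cl in c(conc_col, "response"))
    if (!is.numeric(df[[cl]]))
      stop("column '", cl, "' contains non-numeric cells ",
           "(decimal commas are not accepted)")
  unit <- sub("^conc_?", "", conc_col)
  if (unit == "") unit <- if (is.null(meta$unit)) "nM" else meta$unit
  lig <- if (is.null(meta$ligand_conc)) NA_real_ else meta$ligand_conc
  out <- titration(df[[conc_col]], df$response, ligand_conc = lig, unit = unit,
                   replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
  truth_keys <- grep("^truth\\.", names(meta), value = TRUE)
  if (length(truth_keys)) {
    truth <- meta[truth_keys]
    names(truth) <- sub("^truth\\.", "", truth_keys)
    attr(out, "truth") <- truth
  }
  out
}
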