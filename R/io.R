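#' @title Tabular and JSON interchange
#' @description CSV is the single tabular interchange format: a series file
#'   has columns `conc`, optionally `conc_unit`, and replicate columns
#'   `rep1..repN`. Structured results round-trip through JSON with stable key
#'   order, recording the package version and any seed.
#' @name cli_io
NULL

#' Read a replicate anisotropy series from CSV
#'
#' Replicate columns are detected by the `rep` prefix. Concentrations are
#' converted to molar from `unit` (or a per-row `conc_unit` column, which
#' takes precedence), then rows are sorted by concentration, so shuffled
#' files parse to the same series.
#'
#' @param path CSV path.
#' @param unit Declared concentration unit (`"nM"`, `"uM"`, `"mM"`, `"M"`);
#'   ignored when the file carries a `conc_unit` column.
#' @param type `"titration"` or `"competition"`.
#' @param probe_total,protein_total Assay totals (molar); `protein_total` is
#'   required for competition series.
#' @param calibration An [fp_calibration()] (competition series only).
#' @return A [titration_series()] or [competition_series()].
#' @export
read_series_csv <- function(path, unit = "M",
                            type = c("titration", "competition"),
                            probe_total = 5e-8, protein_total = NULL,
                            calibration = fp_calibration()) {
  type <- match.arg(type)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"conc" %in% names(d))
    stop("missing required column 'conc' in ", path, call. = FALSE)
  repcols <- grep("^rep[0-9]+$", names(d), value = TRUE)
  if (!length(repcols))
    stop("no replicate columns (rep1..repN) in ", path, call. = FALSE)
  for (cc in c("conc", repcols)) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    if (anyNA(v) & !all(is.na(d[[cc]]) == is.na(v)))
      stop("non-numeric cells in column ", cc, call. = FALSE)
    d[[cc]] <- v
  }
  if (anyNA(d$conc)) stop("non-numeric or missing concentrations", call. = FALSE)
  u <- if ("conc_unit" %in% names(d)) d$conc_unit else unit
  conc <- conc_to_molar(d$conc, u)
  if (anyDuplicated(conc))
    stop("duplicate concentrations in ", path, call. = FALSE)
  o <- order(conc)
  reps <- lapply(o, function(i) {
    v <- as.numeric(d[i, repcols])
    v[!is.na(v)]
  })
  if (type == "titration") {
    titration_series(probe_total, conc[o], reps)
  } else {
    if (is.null(protein_total))
      stop("competition series needs protein_total", call. = FALSE)
    competition_series(probe_total, protein_total, conc[o], reps, calibration)
  }
}

#' Write a series to CSV
#'
#' @param series A titration or competition series.
#' @param path Output path.
#' @param unit Concentration unit to write (default `"M"`).
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, unit = "M") {
  k <- max(lengths(series$r))
  m <- t(vapply(series$r, function(v) c(v, rep(NA_real_, k - length(v))),
                numeric(k)))
  d <- data.frame(conc = series$conc / .unit_factors[[unit]], conc_unit = unit)
  colnames(m) <- paste0("rep", seq_len(k))
  utils::write.csv(cbind(d, m), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an anisotropy calibration from a JSON sidecar
#'
#' @param path JSON file with keys `r_free`, `r_bound`, `q_ratio`.
#' @return An [fp_calibration()].
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp_calibration(j$r_free, j$r_bound, j$q_ratio)
}

.serialize_result <- function(x) {
  if (inherits(x, c("pip_binding_fit", "pip_ic50_fit", "pip_competition_fit"))) {
    x <- unclass(x)
    x$data <- NULL; x$series <- NULL
  } else if (inherits(x, "pip_ki")) {
    x <- unclass(x)
  }
  rapply(x, function(v) {
    if (is.numeric(v)) {
      v[!is.finite(v)] <- NA
      if (!is.null(names(v))) return(as.list(v))   # keep names as JSON keys
    }
    v
  }, how = "replace")
}

#' Write a fit or analysis result to JSON
#'
#' Keys are written in stable order; the file records the package version and
#' (when supplied) the seed and configuration so a result file is
#' self-describing. Non-finite standard errors serialize as null.
#'
#' @param result A fit object or plain list.
#' @param path Output path.
#' @param seed,config Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, seed = NULL, config = NULL) {
  payload <- list(
    package = "pipbind",
    version = as.character(utils::packageVersion("pipbind")),
    seed = seed,
    config = config,
    result = .serialize_result(result))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON result file
#'
#' @param path JSON path written by [write_result_json()].
#' @return The parsed list.
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
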