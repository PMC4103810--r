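#' @title Replicate anisotropy series
#' @description Containers for direct-titration and competition FP data.
#'   A series stores, for each concentration on a strictly increasing grid,
#'   the surviving replicate anisotropies, together with the assay constants
#'   needed to model it. All concentrations are held internally in molar units;
#'   file readers convert from a declared unit (nM/uM/mM/M).
#' @name fp_series
NULL

.unit_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
                   pM = 1e-12)

#' Convert concentrations to molar
#'
#' @param x Numeric concentrations.
#' @param unit One of `"M"`, `"mM"`, `"uM"` (or `"µM"`), `"nM"`, `"pM"`.
#' @return Concentrations in molar.
#' @export
conc_to_molar <- function(x, unit) {
  f <- .unit_factors[match(unit, names(.unit_factors))]
  if (anyNA(f)) stop("unknown concentration unit: ", paste(unique(unit[is.na(f)]), collapse = ", "),
                     call. = FALSE)
  x * f
}

.validate_points <- function(conc, reps, what) {
  stopifnot(is.numeric(conc), length(conc) == length(reps))
  if (any(conc < 0)) stop(what, " concentrations must be >= 0", call. = FALSE)
  if (anyNA(conc) || any(!is.finite(conc))) stop("non-finite concentrations", call. = FALSE)
  if (is.unsorted(conc, strictly = TRUE))
    stop(what, " concentrations must be strictly increasing (duplicates found?)",
         call. = FALSE)
  for (r in reps) {
    if (length(r) < 1L || any(!is.finite(r)))
      stop("every point needs >= 1 finite replicate anisotropy", call. = FALSE)
  }
}

.as_rep_list <- function(r, n_points) {
  if (is.matrix(r)) r <- lapply(seq_len(nrow(r)), function(i) r[i, ][!is.na(r[i, ])])
  else if (is.numeric(r)) r <- as.list(r)
  stopifnot(is.list(r), length(r) == n_points)
  lapply(r, as.numeric)
}

#' Direct-titration series (probe vs. increasing protein)
#'
#' @param probe_total Total labeled-probe concentration (molar).
#' @param conc Strictly increasing protein monomer totals (molar).
#' @param r Replicate anisotropies: a matrix with one row per concentration
#'   (NA-padded rows allowed) or a list of numeric vectors.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(probe_total, conc, r) {
  stopifnot(probe_total >= 0)
  reps <- .as_rep_list(r, length(conc))
  .validate_points(conc, reps, "protein")
  structure(list(probe_total = probe_total, conc = as.numeric(conc), r = reps),
            class = "titration_series")
}

#' Competition series (probe + protein vs. increasing competitor)
#'
#' @param probe_total Total labeled-probe concentration (molar).
#' @param protein_total Total protein monomer concentration (molar, > 0).
#' @param conc Strictly increasing competitor totals (molar).
#' @param r Replicate anisotropies as in [titration_series()].
#' @param calibration An [fp_calibration()] used to convert anisotropy to
#'   fraction bound.
#' @return An object of class `"competition_series"`.
#' @export
competition_series <- function(probe_total, protein_total, conc, r,
                               calibration = fp_calibration()) {
  stopifnot(probe_total >= 0)
  if (protein_total <= 0) stop("protein_total must be > 0", call. = FALSE)
  reps <- .as_rep_list(r, length(conc))
  .validate_points(conc, reps, "competitor")
  structure(list(probe_total = probe_total, protein_total = protein_total,
                 conc = as.numeric(conc), r = reps,
                 calibration = as_fp_calibration(calibration)),
            class = "competition_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series: %d points, probe %.3g M, %s replicates/point\n",
              length(x$conc), x$probe_total,
              paste(range(lengths(x$r)), collapse = "-")))
  invisible(x)
}

#' @export
print.competition_series <- function(x, ...) {
  cat(sprintf("Competition series: %d points, probe %.3g M, protein %.3g M\n",
              length(x$conc), x$probe_total, x$protein_total))
  invisible(x)
}

#' Flatten a series to replicate-level long format
#'
#' @param series A titration or competition series.
#' @return A data.frame with columns `conc` and `r`, one row per replicate.
#' @export
series_long <- function(series) {
  data.frame(conc = rep(series$conc, lengths(series$r)),
             r = unlist(series$r, use.names = FALSE))
}

#' Apply Grubbs outlier screening to every concentration point
#'
#' Runs [grubbs_filter()] independently on the replicates of each point and
#' drops the flagged values. Points with fewer than 3 replicates are passed
#' through untouched (the test is undefined there).
#'
#' @param series A titration or competition series.
#' @param alpha Significance level for the Grubbs test.
#' @return The series with flagged replicates removed, plus an attribute
#'   `"qc"`: a data.frame of `conc`, `n_before`, `n_flagged`.
#' @export
qc_series <- function(series, alpha = 0.05) {
  n_before <- lengths(series$r)
  n_flag <- integer(length(series$r))
  for (i in seq_along(series$r)) {
    if (length(series$r[[i]]) >= 3L) {
      res <- grubbs_filter(series$r[[i]], alpha = alpha)
      series$r[[i]] <- res$kept
      n_flag[i] <- length(res$flagged)
    }
  }
  attr(series, "qc") <- data.frame(conc = series$conc, n_before = n_before,
                                   n_flagged = n_flag)
  series
}
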