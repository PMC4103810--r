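#' Anisotropy calibration for a fluorescence-polarization probe
#'
#' Bundles the three photophysical constants needed to convert an observed
#' anisotropy into the fraction of labeled probe bound: the anisotropy of the
#' free probe (`r_free`), the anisotropy of the fully bound probe (`r_bound`),
#' and the bound/free quantum-yield ratio `Q = q_b / q_f`. A `Q` below 1
#' indicates the probe's fluorescence is quenched on binding, which biases the
#' naive linear interpolation and is corrected by [anisotropy_to_fraction_bound()].
#'
#' @param r_free Anisotropy of the unbound probe (dimensionless).
#' @param r_bound Anisotropy of the fully bound probe; must exceed `r_free`.
#' @param q_ratio Quantum-yield ratio of the bound over the free probe
#'   (dimensionless, > 0). Defaults mirror a FITC-labeled PIP-Box peptide
#'   binding PCNA (r_f 0.0470, r_b 0.1587, Q 0.70).
#' @return An object of class `"fp_calibration"`.
#' @examples
#' cal <- fp_calibration()
#' anisotropy_to_fraction_bound(0.10, cal)
#' @export
fp_calibration <- function(r_free = 0.0470, r_bound = 0.1587, q_ratio = 0.70) {
  stopifnot(is.numeric(r_free), is.numeric(r_bound), is.numeric(q_ratio),
            length(r_free) == 1L, length(r_bound) == 1L, length(q_ratio) == 1L,
            is.finite(r_free), is.finite(r_bound), is.finite(q_ratio))
  if (r_bound <= r_free)
    stop("degenerate calibration: r_bound must exceed r_free", call. = FALSE)
  if (q_ratio <= 0)
    stop("q_ratio must be > 0", call. = FALSE)
  structure(list(r_free = r_free, r_bound = r_bound, q_ratio = q_ratio),
            class = "fp_calibration")
}

#' @export
print.fp_calibration <- function(x, ...) {
  cat(sprintf("FP calibration: r_free = %.4f, r_bound = %.4f, Q = %.3f\n",
              x$r_free, x$r_bound, x$q_ratio))
  invisible(x)
}

as_fp_calibration <- function(cal) {
  if (inherits(cal, "fp_calibration")) return(cal)
  if (is.list(cal) && all(c("r_free", "r_bound", "q_ratio") %in% names(cal)))
    return(fp_calibration(cal$r_free, cal$r_bound, cal$q_ratio))
  stop("not an fp_calibration (need r_free, r_bound, q_ratio)", call. = FALSE)
}

#' Convert observed anisotropy to fraction of probe bound
#'
#' Applies the quantum-yield-corrected conversion
#' \deqn{f_b = \frac{r - r_f}{(r - r_f) + Q (r_b - r)}}
#' which accounts for the change in fluorescence intensity between the free and
#' bound states. Noisy anisotropies slightly outside the calibration window map
#' to values slightly outside \[0, 1\]; they are deliberately not clamped so
#' that downstream least-squares fits remain unbiased.
#'
#' @param r Observed anisotropy (vectorized).
#' @param cal An [fp_calibration()].
#' @return Fraction bound, same length as `r`.
#' @seealso [fraction_bound_to_anisotropy()] for the exact inverse.
#' @export
anisotropy_to_fraction_bound <- function(r, cal) {
  cal <- as_fp_calibration(cal)
  (r - cal$r_free) / ((r - cal$r_free) + cal$q_ratio * (cal$r_bound - r))
}

#' Convert fraction bound to the anisotropy that would be observed
#'
#' Exact inverse of [anisotropy_to_fraction_bound()]; used by the synthetic
#' data generators to place noise on the anisotropy scale.
#'
#' @param f_b Fraction of probe bound (vectorized).
#' @param cal An [fp_calibration()].
#' @return Anisotropy values.
#' @export
fraction_bound_to_anisotropy <- function(f_b, cal) {
  cal <- as_fp_calibration(cal)
  q <- cal$q_ratio
  (cal$r_free * (1 - f_b) + q * f_b * cal$r_bound) / ((1 - f_b) + q * f_b)
}

#' Control panel for assay-quality assessment
#'
#' Holds replicate anisotropy readings for the positive control (probe plus
#' saturating protein) and the negative control (probe only), as used for the
#' Z'-factor separation statistic.
#'
#' @param positive_values,negative_values Numeric vectors of replicate
#'   anisotropies, each of length >= 2.
#' @return An object of class `"control_panel"`.
#' @export
control_panel <- function(positive_values, negative_values) {
  if (length(positive_values) < 2L || length(negative_values) < 2L)
    stop("each control arm needs at least 2 replicates", call. = FALSE)
  stopifnot(all(is.finite(positive_values)), all(is.finite(negative_values)))
  structure(list(positive_values = as.numeric(positive_values),
                 negative_values = as.numeric(negative_values)),
            class = "control_panel")
}

#' Z'-factor of an assay control panel
#'
#' Separation statistic
#' \deqn{Z' = 1 - \frac{3(\sigma_+ + \sigma_-)}{|\mu_+ - \mu_-|}}
#' computed with sample standard deviations. Values above ~0.5 indicate a
#' screening-quality assay window.
#'
#' @param panel A [control_panel()].
#' @return The Z' statistic (scalar; at most 1, unbounded below).
#' @export
z_prime <- function(panel) {
  stopifnot(inherits(panel, "control_panel"))
  mu_p <- mean(panel$positive_values); mu_n <- mean(panel$negative_values)
  if (mu_p == mu_n)
    stop("undefined separation: control means are equal", call. = FALSE)
  1 - 3 * (stats::sd(panel$positive_values) + stats::sd(panel$negative_values)) /
    abs(mu_p - mu_n)
}

#' Two-sided Grubbs critical value
#'
#' Critical value for the two-sided Grubbs outlier statistic at significance
#' `alpha` and sample size `n`, from the Student-t quantile at `alpha/(2n)` on
#' `n - 2` degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return Critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  t2 <- stats::qt(1 - alpha / (2 * n), df = n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Screen replicate measurements for a single outlier (Grubbs' test)
#'
#' Two-sided Grubbs test: G = max|x_i - mean(x)| / sd(x) is compared against
#' [grubbs_critical()]. At most one value — the most extreme — is flagged per
#' pass; with the small replicate counts typical of plate assays (N = 4),
#' iterative removal is unstable, so a single pass is the default.
#'
#' @param values Numeric vector of replicate measurements (length >= 3).
#' @param alpha Significance level (default 0.05).
#' @param passes Maximum number of removal passes (default 1).
#' @return A list with `kept` (surviving values), `flagged` (integer indices
#'   into the original vector, possibly empty), `G` (the statistic from the
#'   first pass) and `critical` (its critical value).
#' @export
grubbs_filter <- function(values, alpha = 0.05, passes = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L)
    stop("Grubbs' test requires at least 3 replicates", call. = FALSE)
  stopifnot(all(is.finite(values)))
  flagged <- integer(0)
  keep <- seq_len(n)
  G1 <- NA_real_; crit1 <- NA_real_
  for (pass in seq_len(passes)) {
    x <- values[keep]
    if (length(x) < 3L) break
    s <- stats::sd(x)
    if (s == 0) {                       # all equal: nothing can be an outlier
      if (pass == 1L) { G1 <- 0; crit1 <- grubbs_critical(length(x), alpha) }
      break
    }
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    crit <- grubbs_critical(length(x), alpha)
    if (pass == 1L) { G1 <- G; crit1 <- crit }
    if (G > crit) {
      worst <- keep[which.max(dev)]
      flagged <- c(flagged, worst)
      keep <- setdiff(keep, worst)
    } else break
  }
  list(kept = values[keep], flagged = flagged, G = G1, critical = crit1)
}
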