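#' @title Nonlinear least-squares estimation for FP binding data
#' @description Fits are performed on replicate-level data (uniform weights)
#'   after Grubbs screening, with positive parameters (dissociation constants,
#'   IC50) estimated in log space via Levenberg-Marquardt. Standard errors are
#'   delta-method transforms of the log-space covariance.
#' @name fp_fitting
NULL

.lm_fit <- function(resid_fn, start, lower = NULL, upper = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  if (is.null(lower)) lower <- rep(-Inf, length(start))
  if (is.null(upper)) upper <- rep(Inf, length(start))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = lower, upper = upper, control = ctrl)
  p <- length(start); n <- length(fit$fvec)
  dof <- max(n - p, 1L)
  sigma2 <- sum(fit$fvec^2) / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, p) else sqrt(pmax(diag(covm), 0))
  names(se) <- names(start)
  list(par = fit$par, se = se, rss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4, info = fit$info,
       message = fit$message, n = n)
}

#' Fit a direct titration to the Hill binding model
#'
#' Least-squares fit of anisotropy against total protein concentration,
#' \deqn{r = r_f + (r_b - r_f) \frac{P^n}{K_d^n + P^n},}
#' on replicate-level data after per-point Grubbs screening. The dissociation
#' constant `K_d` and Hill slope `n` are estimated in log space together with
#' the two anisotropy asymptotes.
#'
#' @param series A [titration_series()].
#' @param alpha Grubbs significance level for replicate QC (default 0.05).
#' @param start Optional named list overriding starting values
#'   (`K_d`, `hill_n`, `r_free`, `r_bound`).
#' @return An object of class `"pip_binding_fit"` with elements `K_d`,
#'   `hill_n`, `r_free`, `r_bound`, `se` (named vector), `converged`,
#'   `flag_reason`, `rss`, `data` (the replicate-level data used) and `series`.
#' @export
fit_direct <- function(series, alpha = 0.05, start = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$conc) < 5L)
    stop("need >= 5 concentration points spanning the transition", call. = FALSE)
  series <- qc_series(series, alpha = alpha)
  d <- series_long(series)
  span <- diff(range(d$r))
  flag_reason <- NULL
  if (span <= 0 || stats::sd(d$r) < 1e-12) {
    fit <- list(par = c(log_kd = NA_real_, log_n = NA_real_,
                        r_free = NA_real_, r_bound = NA_real_),
                se = c(log_kd = NA_real_, log_n = NA_real_,
                       r_free = NA_real_, r_bound = NA_real_),
                rss = NA_real_, converged = FALSE, n = nrow(d))
    flag_reason <- "degenerate data: anisotropies carry no signal"
  } else {
    pmeans <- tapply(d$r, d$conc, mean)
    conc <- as.numeric(names(pmeans))
    mid <- min(pmeans) + 0.5 * diff(range(pmeans))
    kd0 <- conc[which.min(abs(pmeans - mid))]
    if (kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
    s <- list(K_d = kd0, hill_n = 1, r_free = min(pmeans), r_bound = max(pmeans))
    if (!is.null(start)) s[names(start)] <- start
    resid_fn <- function(p) {
      fb <- hill_fraction_bound(d$conc, exp(p[["log_kd"]]), exp(p[["log_n"]]))
      p[["r_free"]] + (p[["r_bound"]] - p[["r_free"]]) * fb - d$r
    }
    fit <- .lm_fit(resid_fn,
                   start = c(log_kd = log(s$K_d), log_n = log(s$hill_n),
                             r_free = s$r_free, r_bound = s$r_bound))
  }
  kd <- exp(fit$par[["log_kd"]]); nhill <- exp(fit$par[["log_n"]])
  conc_pos <- series$conc[series$conc > 0]
  in_range <- is.finite(kd) && length(conc_pos) &&
    kd >= min(conc_pos) / 10 && kd <= max(conc_pos) * 10
  converged <- isTRUE(fit$converged) && is.finite(kd) && in_range &&
    is.finite(fit$par[["r_bound"]]) && fit$par[["r_bound"]] > fit$par[["r_free"]]
  if (is.null(flag_reason) && !converged)
    flag_reason <- if (!in_range) "K_d outside tested concentration range"
                   else "optimizer did not converge"
  se <- c(K_d = unname(kd * fit$se[["log_kd"]]),
          hill_n = unname(nhill * fit$se[["log_n"]]),
          r_free = unname(fit$se[["r_free"]]), r_bound = unname(fit$se[["r_bound"]]))
  structure(list(K_d = unname(kd), hill_n = unname(nhill),
                 r_free = unname(fit$par[["r_free"]]),
                 r_bound = unname(fit$par[["r_bound"]]),
                 se = se, converged = converged, flag_reason = flag_reason,
                 rss = fit$rss, n_obs = fit$n, data = d, series = series),
            class = "pip_binding_fit")
}

#' Fit a competition series to the four-parameter logistic (IC50 model)
#'
#' Converts replicate anisotropies to fraction bound via the series
#' calibration, then fits
#' \deqn{f_b = bottom + \frac{top - bottom}{1 + (I/IC_{50})^{-n}}}
#' with a signed Hill slope: displacement curves report negative `n` (the
#' fraction bound falls with competitor). `fb_at_max` is the mean converted
#' fraction bound at the highest tested competitor concentration and feeds
#' [select_competition_model()].
#'
#' @param series A [competition_series()].
#' @param alpha Grubbs significance level for replicate QC.
#' @return An object of class `"pip_ic50_fit"` with `IC50`, `hill_n`, `top`,
#'   `bottom`, `fb_at_max`, `se`, `converged`, `flag_reason`, `rss`, `data`.
#' @export
fit_ic50 <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "competition_series"))
  if (length(series$conc) < 6L)
    stop("need >= 6 competitor concentrations", call. = FALSE)
  series <- qc_series(series, alpha = alpha)
  d <- series_long(series)
  d$fb <- anisotropy_to_fraction_bound(d$r, series$calibration)
  d <- d[d$conc > 0, , drop = FALSE]   # logistic undefined at I = 0
  fb_at_max <- mean(d$fb[d$conc == max(d$conc)])
  pmeans <- tapply(d$fb, d$conc, mean)
  conc <- as.numeric(names(pmeans))
  top0 <- max(pmeans); bot0 <- min(pmeans)
  mid <- bot0 + 0.5 * (top0 - bot0)
  ic0 <- conc[which.min(abs(pmeans - mid))]
  resid_fn <- function(p) {
    z <- exp(-p[["n"]] * (log(d$conc) - p[["log_ic50"]]))
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) / (1 + z) - d$fb
  }
  fit <- .lm_fit(resid_fn,
                 start = c(log_ic50 = log(ic0), n = -1, top = top0, bottom = bot0))
  ic50 <- exp(fit$par[["log_ic50"]])
  wrong_dir <- stats::cor(log(d$conc), d$fb, method = "spearman") > 0 ||
    fit$par[["n"]] > 0
  in_range <- is.finite(ic50) && ic50 >= min(conc) / 10 && ic50 <= max(conc) * 10
  converged <- isTRUE(fit$converged) && !wrong_dir && in_range &&
    fit$par[["top"]] > fit$par[["bottom"]]
  flag_reason <- if (converged) NULL
    else if (wrong_dir) "wrong direction: fraction bound rises with competitor"
    else if (!in_range) "IC50 outside tested concentration range"
    else "optimizer did not converge"
  se <- c(IC50 = unname(ic50 * fit$se[["log_ic50"]]), hill_n = unname(fit$se[["n"]]),
          top = unname(fit$se[["top"]]), bottom = unname(fit$se[["bottom"]]))
  structure(list(IC50 = unname(ic50), hill_n = unname(fit$par[["n"]]),
                 top = unname(fit$par[["top"]]), bottom = unname(fit$par[["bottom"]]),
                 fb_at_max = fb_at_max, se = se, converged = converged,
                 flag_reason = flag_reason, rss = fit$rss, n_obs = fit$n,
                 data = d, series = series),
            class = "pip_ic50_fit")
}

#' Apparent dissociation constant of an uncorrected anisotropy Hill fit
#'
#' Fitting raw anisotropy with the Hill model (as [fit_direct()] does) while
#' the signal is quantum-yield quenched (Q != 1) shifts the curve midpoint:
#' the occupancy isotherm with constant `K_d` composed with the exact
#' anisotropy conversion is again a Hill curve with the same slope but
#' midpoint \eqn{K_d Q^{-1/n}}. This helper returns that apparent constant,
#' the quantity [fit_direct()] estimates on data generated (or measured) with
#' quenching.
#'
#' @param K_d Occupancy-space dissociation constant (molar).
#' @param hill_n Hill slope.
#' @param q_ratio Quantum-yield ratio Q.
#' @return The anisotropy-space apparent K_d (molar).
#' @export
apparent_kd <- function(K_d, hill_n = 1, q_ratio = 0.70) {
  stopifnot(K_d > 0, q_ratio > 0)
  K_d * q_ratio^(-1 / hill_n)
}

#' Classic Cheng-Prusoff inhibition constant
#'
#' \deqn{K_i = \frac{IC_{50}}{1 + [L]/K_d}} with `[L]` the total probe
#' concentration and `K_d` the probe's dissociation constant.
#'
#' @param I50 Fitted IC50 (molar).
#' @param L_probe_total Total labeled probe (molar).
#' @param K_d Probe dissociation constant (molar).
#' @return An object of class `"pip_ki"`.
#' @export
ki_classic <- function(I50, L_probe_total, K_d) {
  stopifnot(I50 > 0, L_probe_total >= 0, K_d > 0)
  ki <- I50 / (1 + L_probe_total / K_d)
  structure(list(K_i = ki, method = "classic",
                 inputs = list(I50 = I50, L = L_probe_total, K_d = K_d)),
            class = "pip_ki")
}

#' Modified Cheng-Prusoff inhibition constant for FP assays
#'
#' \deqn{K_i = \frac{[I]_{50}}{[L]_{50}/K_d + [P]_0/K_d + 1}}
#' where \eqn{[L]_{50} = L_{ST}(1 - f_{b0}/2)} is the free probe at 50%
#' inhibition and \eqn{[P]_0 = R_T - f_{b0} L_{ST}} the free protein at 0%
#' inhibition, given the zero-competitor probe occupancy `fb0`. This form
#' corrects the classic equation for probe and protein depletion under FP
#' assay conditions (following the Nikolovska-Coleska treatment).
#'
#' @param I50 Fitted IC50 (molar).
#' @param fb0 Fraction of probe bound at zero competitor (0 < fb0 < 1).
#' @param L_ST Total labeled probe (molar).
#' @param R_T Total protein monomer (molar).
#' @param K_d Probe dissociation constant (molar).
#' @return An object of class `"pip_ki"` whose `inputs` record the derived
#'   `L50` and `P0`.
#' @export
ki_modified <- function(I50, fb0, L_ST, R_T, K_d) {
  stopifnot(I50 > 0, fb0 > 0, fb0 < 1, L_ST >= 0, R_T >= 0, K_d > 0)
  L50 <- L_ST * (1 - fb0 / 2)
  P0 <- R_T - fb0 * L_ST
  ki <- I50 / (L50 / K_d + P0 / K_d + 1)
  structure(list(K_i = ki, method = "modified",
                 inputs = list(I50 = I50, fb0 = fb0, L_ST = L_ST, R_T = R_T,
                               K_d = K_d, L50 = L50, P0 = P0)),
            class = "pip_ki")
}

.competition_fb_model <- function(model, conc, R_T, L_ST, K_d1, K_d2, K_d3 = NULL) {
  if (model == "incomplete")
    return(.incomplete_fb_vec(conc, R_T, L_ST, K_d1, K_d2, K_d3))
  vapply(conc, function(LT) {
    st <- solve_competition_complete(R_T, L_ST, LT, K_d1, K_d2)
    fraction_bound(st, L_ST)
  }, numeric(1))
}

# vectorized four-state fraction bound over a competitor grid: bisection on
# free protein with the closed-form inner quadratic, all points in lockstep
.incomplete_fb_vec <- function(L_T, R_T, L_ST, K_d1, K_d2, K_d3) {
  if (R_T <= 0 || L_ST <= 0) return(rep(0, length(L_T)))
  k23 <- K_d2 * K_d3
  inner <- function(R) {
    a <- R / k23; c1 <- 1 + R / K_d1; c2 <- 1 + R / K_d2
    b <- c1 * c2 + a * (L_ST - L_T)
    disc <- sqrt(b * b + 4 * a * c2 * L_T * c1)
    I <- ifelse(b >= 0, 2 * L_T * c1 / (b + disc),
                (disc - b) / (2 * pmax(a, 1e-300) * c2))
    I[L_T <= 0] <- 0
    list(I = I, L = L_ST / (c1 + a * I))
  }
  resid <- function(R) {
    inn <- inner(R)
    R * (1 + inn$L / K_d1 + inn$I / K_d2 + inn$I * inn$L / k23) - R_T
  }
  lo <- rep(0, length(L_T)); hi <- rep(R_T, length(L_T))
  for (it in 1:120) {
    mid <- (lo + hi) / 2
    neg <- resid(mid) <= 0
    lo <- ifelse(neg, mid, lo)
    hi <- ifelse(neg, hi, mid)
  }
  R <- (lo + hi) / 2
  inn <- inner(R)
  (R * inn$L / K_d1 + R * inn$I * inn$L / k23) / L_ST
}

#' Fit a competition series to the exact complete-displacement model
#'
#' Estimates the competitor dissociation constant `K_d2` by least squares on
#' fraction-bound data, evaluating the model through the exact cubic solver
#' [solve_competition_complete()] with the probe constant `K_d1` held fixed
#' (taken from a prior direct fit).
#'
#' @param series A [competition_series()].
#' @param K_d1 Probe dissociation constant (molar), fixed.
#' @param alpha Grubbs significance level for replicate QC.
#' @return An object of class `"pip_competition_fit"` (`model = "complete"`).
#' @export
fit_competition_complete <- function(series, K_d1, alpha = 0.05) {
  stopifnot(inherits(series, "competition_series"), K_d1 > 0)
  series <- qc_series(series, alpha = alpha)
  d <- series_long(series)
  d$fb <- anisotropy_to_fraction_bound(d$r, series$calibration)
  R_T <- series$protein_total; L_ST <- series$probe_total
  conc_pos <- series$conc[series$conc > 0]
  resid_fn <- function(p)
    .competition_fb_model("complete", d$conc, R_T, L_ST, K_d1,
                          exp(p[["log_kd2"]])) - d$fb
  fit <- .lm_fit(resid_fn, start = c(log_kd2 = log(stats::median(conc_pos))),
                 lower = log(1e-13), upper = log(1))
  kd2 <- exp(fit$par[["log_kd2"]])
  converged <- isTRUE(fit$converged) && is.finite(kd2)
  # systematic residual at high competitor reveals an unmodeled plateau
  hi <- d$conc >= sort(unique(d$conc), decreasing = TRUE)[min(2, length(unique(d$conc)))]
  res <- resid_fn(fit$par)
  plateau_residual <- -mean(res[hi])    # observed minus model at high L_T
  structure(list(model = "complete", K_d2 = unname(kd2), K_d3 = NULL,
                 K_d1 = K_d1,
                 se = c(K_d2 = unname(kd2 * fit$se[["log_kd2"]])),
                 rss = fit$rss, converged = converged,
                 plateau_residual = plateau_residual,
                 n_obs = fit$n, data = d, series = series),
            class = "pip_competition_fit")
}

#' Fit a competition series to the incomplete (four-state) model
#'
#' Joint least squares over (`K_d2`, `K_d3`) with model evaluation through
#' [solve_competition_incomplete()], `K_d1` fixed. Three Levenberg-Marquardt
#' starts (a base start plus seeded jitter) guard against local minima in the
#' two-parameter landscape. Warns when the fraction-bound plateau is not
#' sampled by the data (then `K_d3` is weakly identified), and when the
#' observed plateau is ~0 (then `K_d3` is unbounded above).
#'
#' @param series A [competition_series()].
#' @param K_d1 Probe dissociation constant (molar), fixed.
#' @param alpha Grubbs significance level.
#' @param n_starts Number of optimizer starts (default 3).
#' @param seed Seed for the start jitter (default 1).
#' @return An object of class `"pip_competition_fit"` (`model = "incomplete"`)
#'   with both `K_d2` and `K_d3`.
#' @export
fit_competition_incomplete <- function(series, K_d1, alpha = 0.05,
                                       n_starts = 3L, seed = 1L) {
  stopifnot(inherits(series, "competition_series"), K_d1 > 0)
  series <- qc_series(series, alpha = alpha)
  d <- series_long(series)
  d$fb <- anisotropy_to_fraction_bound(d$r, series$calibration)
  R_T <- series$protein_total; L_ST <- series$probe_total
  pmeans <- tapply(d$fb, d$conc, mean)
  conc <- as.numeric(names(pmeans))
  fb_max_conc <- pmeans[[which.max(conc)]]
  if (fb_max_conc < 0.02)
    warning("fraction bound ~0 at the highest competitor concentration; ",
            "K_d3 is unbounded above (complete model may suffice)", call. = FALSE)
  # plateau sampled iff the last two points have stopped moving
  if (length(conc) >= 3) {
    last2 <- pmeans[order(conc)][c(length(conc) - 1, length(conc))]
    rng <- diff(range(pmeans))
    if (rng > 0 && abs(diff(last2)) > 0.1 * rng)
      warning("plateau not sampled at high competitor; K_d3 weakly identifiable",
              call. = FALSE)
  }
  resid_fn <- function(p)
    .competition_fb_model("incomplete", d$conc, R_T, L_ST, K_d1,
                          exp(p[["log_kd2"]]), exp(p[["log_kd3"]])) - d$fb
  kd30 <- if (fb_max_conc > 0.01 && fb_max_conc < 1)
    R_T * (1 - fb_max_conc) / fb_max_conc else 100 * K_d1
  base <- c(log_kd2 = log(stats::median(conc[conc > 0])), log_kd3 = log(kd30))
  jit <- with_preserved_seed(seed, {
    matrix(stats::rnorm(2 * n_starts, 0, 0.7), ncol = 2)
  })
  jit[1, ] <- 0
  best <- NULL
  for (k in seq_len(n_starts)) {
    st <- base + jit[k, ]
    cand <- tryCatch(.lm_fit(resid_fn, start = st, lower = rep(log(1e-13), 2),
                             upper = rep(log(10), 2)),
                     error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
  }
  if (is.null(best))
    stop("non-convergence: all optimizer starts failed", call. = FALSE)
  kd2 <- exp(best$par[["log_kd2"]]); kd3 <- exp(best$par[["log_kd3"]])
  structure(list(model = "incomplete", K_d2 = unname(kd2), K_d3 = unname(kd3),
                 K_d1 = K_d1,
                 se = c(K_d2 = unname(kd2 * best$se[["log_kd2"]]),
                        K_d3 = unname(kd3 * best$se[["log_kd3"]])),
                 rss = best$rss, converged = isTRUE(best$converged),
                 n_obs = best$n, data = d, series = series),
            class = "pip_competition_fit")
}

#' Choose between complete and incomplete competition models
#'
#' A competitor that fully displaces the probe leaves the fraction bound at
#' ~0 at the highest tested concentration and is described by the complete
#' model; a residual plateau indicates a ternary complex and calls for the
#' incomplete (four-state) model. The decision rule is
#' `fb_at_max > threshold` (strict inequality).
#'
#' @param fit A converged [fit_ic50()] result.
#' @param threshold Plateau threshold on the fraction bound (default 0.05).
#' @return `"complete"` or `"incomplete"`.
#' @export
select_competition_model <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "pip_ic50_fit"))
  if (!isTRUE(fit$converged))
    stop("model selection requires a converged IC50 fit", call. = FALSE)
  if (fit$fb_at_max > threshold) "incomplete" else "complete"
}
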