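#' @title Exact competitive-binding equilibria
#' @description Closed-form and iterative solvers for the binding models that
#'   underlie FP titration and competition curves: the one-site direct model
#'   (quadratic mass balance), the complete-competition three-species model
#'   (cubic in free protein), and the incomplete-competition four-state model
#'   in which the competitor-bound protein retains a (weaker) probe site with
#'   dissociation constant Kd3, producing a ternary complex and a nonzero
#'   fraction-bound plateau at saturating competitor.
#'
#'   Species naming: R = free protein monomer, L* = free labeled probe,
#'   I = free competitor, RL* = protein-probe, RI = protein-competitor,
#'   RIL* = ternary complex. All concentrations molar. Totals below 1e-15 M
#'   are treated as zero.
#' @name equilibria
NULL

.CONC_EPS <- 1e-15

.species_state <- function(R = 0, L = 0, I = 0, RL = 0, RI = 0, RIL = 0) {
  structure(list(free_protein = R, free_probe = L, free_competitor = I,
                 binary_probe_complex = RL, binary_competitor_complex = RI,
                 ternary_complex = RIL),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  v <- unlist(x)
  cat("Equilibrium species (M):\n")
  print(signif(v, 6))
  invisible(x)
}

#' Fraction of probe bound in an equilibrium state
#'
#' Both the binary protein-probe complex and the ternary complex count as
#' "bound" signal (the ternary complex is assumed to carry the same anisotropy
#' and quantum yield as the binary complex).
#'
#' @param state A species state from one of the solvers.
#' @param probe_total Total probe concentration (molar).
#' @return Fraction bound in \[0, 1\]; 0 when `probe_total` is 0.
#' @export
fraction_bound <- function(state, probe_total) {
  if (probe_total <= .CONC_EPS) return(0)
  (state$binary_probe_complex + state$ternary_complex) / probe_total
}

#' One-site direct binding: exact quadratic solution
#'
#' Solves R + L* = RL* with dissociation constant `K_d1` under total
#' concentrations `R_T` and `L_ST`. The bound complex is the smaller root of
#' \eqn{x^2 - (R_T + L_{ST} + K_{d1}) x + R_T L_{ST} = 0}, which always lies
#' in \[0, min(R_T, L_ST)\].
#'
#' @param R_T Total protein monomer (molar).
#' @param L_ST Total labeled probe (molar).
#' @param K_d1 Probe dissociation constant (molar, > 0).
#' @return A species state.
#' @export
solve_direct <- function(R_T, L_ST, K_d1) {
  stopifnot(R_T >= 0, L_ST >= 0, K_d1 > 0)
  if (R_T <= .CONC_EPS) R_T <- 0
  if (L_ST <= .CONC_EPS) L_ST <- 0
  b <- R_T + L_ST + K_d1
  # numerically stable smaller root: 2c / (b + sqrt(b^2 - 4c))
  disc <- b * b - 4 * R_T * L_ST
  RL <- if (R_T * L_ST == 0) 0 else 2 * R_T * L_ST / (b + sqrt(max(disc, 0)))
  RL <- min(RL, R_T, L_ST)
  .species_state(R = R_T - RL, L = L_ST - RL, RL = RL)
}

#' Hill binding isotherm
#'
#' Depletion-free fractional occupancy \eqn{f_b = P^n / (K_d^n + P^n)} used to
#' fit direct titrations of anisotropy against total protein concentration.
#'
#' @param P Protein concentration (molar, vectorized, >= 0).
#' @param K_d Midpoint dissociation constant (molar, > 0).
#' @param n Hill slope.
#' @return Fraction bound.
#' @export
hill_fraction_bound <- function(P, K_d, n = 1) {
  stopifnot(K_d > 0)
  if (n < 0 && any(P == 0))
    stop("P = 0 with negative Hill slope is undefined", call. = FALSE)
  pn <- (P / K_d)^n
  pn / (1 + pn)
}

# Cubic coefficients for the complete-competition model, free protein [R]:
# [R]^3 + d [R]^2 + e [R] + f = 0
.complete_cubic_coefs <- function(R_T, L_ST, L_T, K_d1, K_d2) {
  d <- K_d1 + K_d2 + L_ST + L_T - R_T
  e <- K_d1 * K_d2 + K_d2 * (L_ST - R_T) + K_d1 * (L_T - R_T)
  f <- -K_d1 * K_d2 * R_T
  c(d = d, e = e, f = f)
}

# Physical root of x^3 + d x^2 + e x + f in (0, R_T], trigonometric method
# with bisection fallback when the discriminant is numerically marginal.
.solve_cubic_physical <- function(d, e, f, R_T) {
  g <- function(x) ((x + d) * x + e) * x + f
  # magnitude of the terms entering g(x): measures attainable precision
  gscale <- function(x) abs(x)^3 + abs(d) * x^2 + abs(e) * abs(x) + abs(f)
  # depressed cubic t^3 + p t + q, x = t - d/3
  p <- e - d * d / 3
  q <- 2 * d^3 / 27 - d * e / 3 + f
  x <- NA_real_
  disc <- -(4 * p^3 + 27 * q^2)
  if (is.finite(disc) && disc > 0 && p < 0) {
    m <- 2 * sqrt(-p / 3)
    arg <- 3 * q / (p * m)
    arg <- min(1, max(-1, arg))
    theta <- acos(arg) / 3
    roots <- m * cos(theta - 2 * pi * (0:2) / 3) - d / 3
    cand <- roots[roots > 0 & roots <= R_T * (1 + 1e-9)]
    if (length(cand)) x <- min(cand)   # unique in exact arithmetic
  }
  if (is.finite(x)) {
    # Newton polish: the trig form loses the smallest root to cancellation
    # when the roots are widely separated
    for (i in 1:8) {
      gp <- (3 * x + 2 * d) * x + e
      if (gp == 0) break
      step <- g(x) / gp
      xn <- min(max(x - step, 0), R_T)
      if (!is.finite(xn) || xn == x) break
      x <- xn
      if (abs(step) <= 1e-14 * max(abs(x), 1e-300)) break
    }
  }
  marginal <- !is.finite(x) || abs(g(x)) > 1e-10 * max(gscale(x), 1e-300)
  if (marginal) {
    lo <- 0; hi <- R_T
    if (g(lo) > 0 || g(hi) < 0)
      stop("numerical failure: no physical root in [0, R_T]", call. = FALSE)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) <= 0) lo <- mid else hi <- mid
      if (hi - lo <= 1e-15 * max(hi, 1e-300)) break
    }
    x <- (lo + hi) / 2
  }
  min(max(x, 0), R_T)
}

#' Complete competition: exact cubic solution
#'
#' Solves the three-species system R + L* = RL* (Kd1), R + I = RI (Kd2) under
#' totals (R_T, L_ST, L_T). Free protein \[R\] is the physical root of the
#' cubic \eqn{[R]^3 + d[R]^2 + e[R] + f = 0} with
#' d = Kd1 + Kd2 + L_ST + L_T - R_T,
#' e = Kd1 Kd2 + Kd2 (L_ST - R_T) + Kd1 (L_T - R_T),
#' f = -Kd1 Kd2 R_T; the probe fraction bound is then \[R\]/(\[R\] + Kd1).
#' The trigonometric closed form is used for speed during curve fitting, with
#' a guaranteed bounded bisection fallback.
#'
#' @param R_T,L_ST,L_T Totals of protein, probe and competitor (molar).
#' @param K_d1 Probe dissociation constant (molar).
#' @param K_d2 Competitor dissociation constant (molar).
#' @return A species state with `ternary_complex = 0`.
#' @export
solve_competition_complete <- function(R_T, L_ST, L_T, K_d1, K_d2) {
  stopifnot(R_T >= 0, L_ST >= 0, L_T >= 0, K_d1 > 0, K_d2 > 0)
  if (R_T <= .CONC_EPS) return(.species_state(L = L_ST, I = L_T))
  if (L_T <= .CONC_EPS) {
    st <- solve_direct(R_T, L_ST, K_d1)
    return(st)
  }
  co <- .complete_cubic_coefs(R_T, L_ST, L_T, K_d1, K_d2)
  R <- .solve_cubic_physical(co["d"], co["e"], co["f"], R_T)
  L <- L_ST * K_d1 / (K_d1 + R)
  I <- L_T * K_d2 / (K_d2 + R)
  .species_state(R = R, L = L, I = I, RL = R * L / K_d1, RI = R * I / K_d2)
}

# Given free protein R, the inner (I, L*) balances of the four-state model
# reduce to a quadratic in free competitor I:
#   a c2 I^2 + [c1 c2 + a (L_ST - L_T)] I - L_T c1 = 0
# with a = R/(Kd2 Kd3), c1 = 1 + R/Kd1, c2 = 1 + R/Kd2. The positive root is
# taken in a cancellation-free form.
.incomplete_inner <- function(R, L_ST, L_T, K_d1, K_d2, K_d3) {
  k23 <- K_d2 * K_d3
  a <- R / k23
  c1 <- 1 + R / K_d1
  c2 <- 1 + R / K_d2
  if (L_T <= 0) return(list(I = 0, L = L_ST / c1))
  b <- c1 * c2 + a * (L_ST - L_T)
  disc <- sqrt(b * b + 4 * a * c2 * L_T * c1)
  I <- if (b >= 0) 2 * L_T * c1 / (b + disc) else (disc - b) / (2 * a * c2)
  list(I = I, L = L_ST / (c1 + a * I))
}

#' Incomplete competition: four-state model solver
#'
#' Solves R + L* = RL* (Kd1), R + I = RI (Kd2), RI + L* = RIL* (Kd3) by nested
#' bounded bisection on the free-protein and free-competitor balances. Because
#' the competitor-bound protein retains a probe site, the observed probe
#' fraction bound ((RL* + RIL*)/L_ST) plateaus at the occupancy of a direct
#' titration with affinity Kd3 instead of falling to zero at saturating
#' competitor.
#'
#' @param R_T,L_ST,L_T Totals (molar).
#' @param K_d1 Probe dissociation constant for free protein (molar).
#' @param K_d2 Competitor dissociation constant (molar).
#' @param K_d3 Probe dissociation constant for competitor-bound protein (molar).
#' @return A species state; mass balances hold to relative 1e-9.
#' @export
solve_competition_incomplete <- function(R_T, L_ST, L_T, K_d1, K_d2, K_d3) {
  stopifnot(R_T >= 0, L_ST >= 0, L_T >= 0, K_d1 > 0, K_d2 > 0, K_d3 > 0)
  if (R_T <= .CONC_EPS) return(.species_state(L = L_ST, I = L_T))
  k23 <- K_d2 * K_d3
  resid <- function(R) {
    inn <- .incomplete_inner(R, L_ST, L_T, K_d1, K_d2, K_d3)
    R * (1 + inn$L / K_d1 + inn$I / K_d2 + inn$I * inn$L / k23) - R_T
  }
  lo <- 0; hi <- R_T
  for (i in 1:120) {
    mid <- (lo + hi) / 2
    if (resid(mid) <= 0) lo <- mid else hi <- mid
  }
  R <- (lo + hi) / 2
  inn <- .incomplete_inner(R, L_ST, L_T, K_d1, K_d2, K_d3)
  I <- inn$I; L <- inn$L
  st <- .species_state(R = R, L = L, I = I,
                       RL = R * L / K_d1, RI = R * I / K_d2,
                       RIL = R * I * L / k23)
  # convergence check on all three balances
  tot <- c(R_T, L_ST, L_T)
  got <- c(R + st$binary_probe_complex + st$binary_competitor_complex + st$ternary_complex,
           L + st$binary_probe_complex + st$ternary_complex,
           I + st$binary_competitor_complex + st$ternary_complex)
  relerr <- abs(got - tot) / pmax(tot, .CONC_EPS)
  if (any(tot > .CONC_EPS & relerr > 1e-8))
    stop(sprintf("four-state solver did not converge (max rel. balance error %.2e)",
                 max(relerr)), call. = FALSE)
  st
}

#' Brute-force equilibrium oracle (bisection on free protein)
#'
#' Independent verifier for the closed-form solvers: solves the free-protein
#' mass balance of the direct or complete-competition model by plain bisection
#' on \[0, R_T\] to relative 1e-12 and reconstructs all species. Intended for
#' cross-checks and tests, not for curve fitting.
#'
#' @inheritParams solve_competition_complete
#' @param L_T Competitor total; 0 gives the direct model.
#' @param K_d2 Competitor dissociation constant; ignored when `L_T = 0`.
#' @return A species state.
#' @export
oracle_solve <- function(R_T, L_ST, L_T = 0, K_d1, K_d2 = Inf) {
  stopifnot(R_T >= 0, L_ST >= 0, L_T >= 0, K_d1 > 0)
  if (R_T <= .CONC_EPS) return(.species_state(L = L_ST, I = L_T))
  resid <- function(R) {
    L <- L_ST * K_d1 / (K_d1 + R)
    I <- if (L_T > 0 && is.finite(K_d2)) L_T * K_d2 / (K_d2 + R) else L_T
    R + R * L / K_d1 + (if (is.finite(K_d2)) R * I / K_d2 else 0) - R_T
  }
  lo <- 0; hi <- R_T
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo <= 1e-13 * max(hi, 1e-300)) break
  }
  R <- (lo + hi) / 2
  L <- L_ST * K_d1 / (K_d1 + R)
  I <- if (L_T > 0 && is.finite(K_d2)) L_T * K_d2 / (K_d2 + R) else L_T
  RI <- if (is.finite(K_d2)) R * I / K_d2 else 0
  .species_state(R = R, L = L, I = I, RL = R * L / K_d1, RI = RI)
}
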