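# S3 methods for the fit classes

#' @export
print.pip_binding_fit <- function(x, ...) {
  cat("Direct binding fit (Hill model)\n")
  cat(sprintf("  K_d    = %.4g M (SE %.2g)\n", x$K_d, x$se[["K_d"]]))
  cat(sprintf("  Hill n = %.3g (SE %.2g)\n", x$hill_n, x$se[["hill_n"]]))
  cat(sprintf("  r_free = %.4f, r_bound = %.4f\n", x$r_free, x$r_bound))
  if (!isTRUE(x$converged))
    cat("  ** flagged:", x$flag_reason %||% "not converged", "\n")
  invisible(x)
}

#' @export
print.pip_ic50_fit <- function(x, ...) {
  cat("Competition fit (four-parameter logistic)\n")
  cat(sprintf("  IC50      = %.4g M (SE %.2g)\n", x$IC50, x$se[["IC50"]]))
  cat(sprintf("  Hill n    = %.3g (SE %.2g)\n", x$hill_n, x$se[["hill_n"]]))
  cat(sprintf("  top       = %.3f, bottom = %.3f\n", x$top, x$bottom))
  cat(sprintf("  fb at max = %.3f\n", x$fb_at_max))
  if (!isTRUE(x$converged))
    cat("  ** flagged:", x$flag_reason %||% "not converged", "\n")
  invisible(x)
}

#' @export
print.pip_competition_fit <- function(x, ...) {
  cat(sprintf("Exact competition fit (%s model), K_d1 fixed at %.4g M\n",
              x$model, x$K_d1))
  cat(sprintf("  K_d2 = %.4g M (SE %.2g)\n", x$K_d2, x$se[["K_d2"]]))
  if (!is.null(x$K_d3))
    cat(sprintf("  K_d3 = %.4g M (SE %.2g)\n", x$K_d3, x$se[["K_d3"]]))
  cat(sprintf("  residual sum of squares = %.4g\n", x$rss))
  if (!isTRUE(x$converged)) cat("  ** flagged: not converged\n")
  invisible(x)
}

#' @export
print.pip_ki <- function(x, ...) {
  cat(sprintf("K_i = %.4g M (%s Cheng-Prusoff)\n", x$K_i, x$method))
  invisible(x)
}

#' @export
coef.pip_binding_fit <- function(object, ...) {
  c(K_d = object$K_d, hill_n = object$hill_n,
    r_free = object$r_free, r_bound = object$r_bound)
}

#' @export
coef.pip_ic50_fit <- function(object, ...) {
  c(IC50 = object$IC50, hill_n = object$hill_n,
    top = object$top, bottom = object$bottom)
}

#' @export
coef.pip_competition_fit <- function(object, ...) {
  out <- c(K_d2 = object$K_d2)
  if (!is.null(object$K_d3)) out <- c(out, K_d3 = object$K_d3)
  out
}

#' @export
predict.pip_binding_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.list(newdata)) newdata$conc else newdata
  object$r_free + (object$r_bound - object$r_free) *
    hill_fraction_bound(conc, object$K_d, object$hill_n)
}

#' @export
predict.pip_ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.list(newdata)) newdata$conc else newdata
  z <- exp(-object$hill_n * (log(conc) - log(object$IC50)))
  object$bottom + (object$top - object$bottom) / (1 + z)
}

#' @export
predict.pip_competition_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.list(newdata)) newdata$conc else newdata
  .competition_fb_model(object$model, conc, object$series$protein_total,
                        object$series$probe_total, object$K_d1, object$K_d2,
                        object$K_d3)
}

#' @export
residuals.pip_binding_fit <- function(object, ...) {
  object$data$r - predict(object)
}

#' @export
residuals.pip_ic50_fit <- function(object, ...) {
  object$data$fb - predict(object)
}

#' @export
residuals.pip_competition_fit <- function(object, ...) {
  object$data$fb - predict(object)
}

#' @export
summary.pip_binding_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  RSS = %.4g over %d replicate observations\n",
              object$rss, object$n_obs))
  invisible(object)
}

#' @export
summary.pip_ic50_fit <- summary.pip_binding_fit

#' @export
plot.pip_binding_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc, d$r, log = "x", xlab = "protein (M)",
                 ylab = "anisotropy", ...)
  cs <- exp(seq(log(min(d$conc[d$conc > 0])), log(max(d$conc)), length.out = 100))
  graphics::lines(cs, predict(x, cs))
  invisible(x)
}

#' @export
plot.pip_ic50_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc, d$fb, log = "x", xlab = "competitor (M)",
                 ylab = "fraction bound", ...)
  cs <- exp(seq(log(min(d$conc)), log(max(d$conc)), length.out = 100))
  graphics::lines(cs, predict(x, cs))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
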