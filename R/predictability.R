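#' Adjusted repeatability from a location-scale posterior
#'
#' Per posterior draw, the among-individual variance is the squared mean-model
#' random-intercept SD and the residual variance is the squared exponential of
#' the dispersion-model intercept (the dispersion submodel works on the log
#' residual-SD scale, so the intercept is exponentiated and then squared);
#' repeatability is `R = V_individual / (V_individual + V_residual)`.  All
#' statistics are computed per draw and then summarized (posterior mean and
#' 95% HPD interval), the practice the reference analysis implies; the
#' plug-in value at the posterior means differs by the Jensen gap.
#'
#' @param posterior A `dhmm_posterior`, or a list/data frame with numeric
#'   elements `sd_intercept` and `gamma0` (posterior draws; scalars give the
#'   plug-in value).
#' @param prob Credible mass (default 0.95).
#' @return Object of class `repeatability_estimate`: `mean`, `hpd`
#'   (NA-filled when fewer than 100 draws), and per-draw `r`,
#'   `v_individual`, `v_residual`.
#' @export
repeatability <- function(posterior, prob = 0.95) {
  src <- if (inherits(posterior, "dhmm_posterior")) posterior$draws else
    posterior
  if (!all(c("sd_intercept", "gamma0") %in% names(src))) {
    stop("posterior must provide 'sd_intercept' and 'gamma0' draws")
  }
  v_ind <- src$sd_intercept^2
  v_res <- exp(src$gamma0)^2
  r <- v_ind / (v_ind + v_res)
  hpd <- if (length(r) >= 100L) hpd_interval(r, prob) else c(NA_real_,
                                                             NA_real_)
  structure(list(mean = mean(r), hpd = hpd, r = r,
                 v_individual = v_ind, v_residual = v_res, prob = prob),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f [%s]\n", x$mean,
              if (anyNA(x$hpd)) "HPD needs >= 100 draws" else
                sprintf("%.0f%% HPD %.3f to %.3f", 100 * x$prob,
                        x$hpd[1], x$hpd[2])))
  invisible(x)
}

#' Coefficient of predictability CV_P
#'
#' `CV_P = sqrt(exp(omega^2) - 1)`: the coefficient of variation of the
#' individual residual SDs implied by a lognormal dispersion random effect
#' whose log-scale SD is `omega`.  Applied to a scalar or vector it evaluates
#' the closed form; applied to a fitted posterior it evaluates per draw,
#' summarizes by posterior mean and HPD interval, and extracts each
#' individual's posterior rIIV (residual SD on the response scale for the
#' population-typical covariate profile, `exp(gamma0 + w_i)`); low rIIV means
#' high predictability.
#'
#' @param x Non-negative numeric (the dispersion random-intercept SD), or a
#'   `dhmm_posterior`.
#' @param ... Passed to methods.
#' @return Numeric of the same length as `x`, or (for a posterior) an object
#'   of class `predictability_estimate` with `mean`, `hpd`, per-draw `cv_p`
#'   and the draws-by-individual `riiv` matrix.
#' @export
cv_p <- function(x, ...) UseMethod("cv_p")

#' @rdname cv_p
#' @export
cv_p.default <- function(x, ...) {
  if (!is.numeric(x)) stop("x must be numeric or a dhmm_posterior")
  if (anyNA(x) || any(x < 0)) {
    stop("omega must be non-negative (it is the SD of the dispersion ",
         "random intercept)")
  }
  sqrt(exp(x^2) - 1)
}

#' @rdname cv_p
#' @param prob Credible mass (default 0.95).
#' @export
cv_p.dhmm_posterior <- function(x, prob = 0.95, ...) {
  if (!"omega" %in% names(x$draws)) stop("posterior lacks 'omega' draws")
  omega <- x$draws$omega
  cv <- cv_p.default(omega)
  riiv <- exp(x$draws$gamma0 + x$re[, , "w"])
  colnames(riiv) <- dimnames(x$re)[[2]]
  structure(list(mean = mean(cv),
                 hpd = if (length(cv) >= 100L) hpd_interval(cv, prob) else
                   c(NA_real_, NA_real_),
                 cv_p = cv, riiv = riiv, prob = prob),
            class = "predictability_estimate")
}

#' @export
print.predictability_estimate <- function(x, ...) {
  cat(sprintf("CV_P = %.3f", x$mean))
  if (!anyNA(x$hpd)) cat(sprintf(" [%.0f%% HPD %.3f to %.3f]",
                                 100 * x$prob, x$hpd[1], x$hpd[2]))
  cat("\n")
  invisible(x)
}

#' Correlation between behavioural type and predictability
#'
#' Summarizes the posterior of the correlation between the mean-model random
#' intercept (behavioural type) and the dispersion-model random intercept
#' (log rIIV).  Because low rIIV means high predictability, a negative
#' correlation says that individuals with higher trait means are the more
#' predictable ones.
#'
#' @param posterior A `dhmm_posterior`.
#' @param prob Credible mass (default 0.95).
#' @return Tibble with one row: `mean`, `hpd_low`, `hpd_high`, `significant`
#'   (HPD excludes zero).
#' @export
type_predictability_correlation <- function(posterior, prob = 0.95) {
  stopifnot(inherits(posterior, "dhmm_posterior"))
  if (!"r_intercept_omega" %in% names(posterior$draws)) {
    stop("posterior lacks 'r_intercept_omega' draws")
  }
  r <- posterior$draws$r_intercept_omega
  h <- hpd_interval(r, prob)
  tibble::tibble(mean = mean(r), hpd_low = h[1], hpd_high = h[2],
                 significant = h[1] > 0 | h[2] < 0)
}
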