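#' weibullrelease: Weibull modelling of cumulative drug-release kinetics
#'
#' Tools for analysing in-vitro cumulative drug-release profiles with the
#' non-normalized Weibull distribution. Units are fixed package-wide: time
#' in hours, release in percent of loaded drug (0-100 scale, never a
#' fraction).
#'
#' @keywords internal
"_PACKAGE"

# ---- domain error helpers ----------------------------------------------

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wr_domain_error", "error")))
}

#' Weibull release parameters
#'
#' Bundle of the three parameters of the non-normalized Weibull cumulative
#' release model \eqn{M(t) = M_\infty (1 - e^{-(t/\tau_K)^\beta})}.
#'
#' @param m_inf Maximum (saturation) released drug amount, percent of the
#'   loaded drug. Must be >= 0.
#' @param tau_k Characteristic release time \eqn{\tau_K}, hours; 63.2\% of
#'   `m_inf` is released at `t = tau_k`. Must be > 0.
#' @param beta Dimensionless shape (stretching) exponent \eqn{\beta}. Must
#'   be > 0. Values <= 0.75 indicate Fickian diffusion, 0.75-1 combined
#'   diffusion plus swelling, > 1 a complex sigmoidal release.
#'
#' @return An object of class `"weibull_params"`: a named list with
#'   elements `m_inf`, `tau_k`, `beta`.
#' @examples
#' p <- weibull_params(m_inf = 27.8, tau_k = 10.51, beta = 0.71)
#' weibull_cdf(40, p)
#' @export
weibull_params <- function(m_inf, tau_k, beta) {
  for (nm in c("m_inf", "tau_k", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_domain("'%s' must be a single finite number", nm)
  }
  if (m_inf < 0) stop_domain("'m_inf' must be >= 0 (got %g)", m_inf)
  if (tau_k <= 0) stop_domain("'tau_k' must be > 0 (got %g)", tau_k)
  if (beta <= 0) stop_domain("'beta' must be > 0 (got %g)", beta)
  structure(list(m_inf = as.numeric(m_inf), tau_k = as.numeric(tau_k),
                 beta = as.numeric(beta)),
            class = "weibull_params")
}

as_weibull_params <- function(p) {
  if (inherits(p, "weibull_params")) return(p)
  if (is.numeric(p) && length(p) == 3L)
    return(weibull_params(p[[1L]], p[[2L]], p[[3L]]))
  if (is.list(p) && all(c("m_inf", "tau_k", "beta") %in% names(p)))
    return(weibull_params(p$m_inf, p$tau_k, p$beta))
  stop_domain("cannot interpret 'p' as Weibull parameters")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull release parameters: M_inf = %g %%, tau_K = %g h, beta = %g\n",
              x$m_inf, x$tau_k, x$beta))
  invisible(x)
}

check_times <- function(t) {
  if (!is.numeric(t) || anyNA(t))
    stop_domain("'t' must be numeric with no missing values")
  if (any(t < 0))
    stop_domain("negative time is outside the model domain (min t = %g h)",
                min(t))
  as.numeric(t)
}

#' Weibull cumulative release
#'
#' The non-normalized Weibull CDF
#' \eqn{M(t) = M_\infty(1 - e^{-(t/\tau_K)^\beta})}: cumulative percent of
#' the loaded drug released by time `t`.
#'
#' @param t Time(s), hours, >= 0. Vectorized.
#' @param p A [weibull_params()] object (or a length-3 numeric
#'   `c(m_inf, tau_k, beta)`).
#' @return Cumulative release, percent; values lie in `[0, m_inf)` and are
#'   monotone non-decreasing in `t`.
#' @seealso [weibull_pdf()], [weibull_inverse()], [kohlrausch()]
#' @examples
#' p <- weibull_params(15.1, 27.90, 2.67)
#' weibull_cdf(c(20, 40, 80), p)
#' @export
weibull_cdf <- function(t, p) {
  t <- check_times(t)
  p <- as_weibull_params(p)
  p$m_inf * (1 - exp(-(t / p$tau_k)^p$beta))
}

#' Weibull release speed (non-normalized PDF)
#'
#' Derivative of [weibull_cdf()]:
#' \eqn{f(t) = M_\infty (\beta/\tau_K)(t/\tau_K)^{\beta-1} e^{-(t/\tau_K)^\beta}},
#' in percent per hour.
#'
#' For `beta < 1` the density diverges as `t -> 0`; evaluating it at
#' exactly `t = 0` in that regime raises an error of class
#' `"wr_diverges_error"` rather than returning `Inf`, so that tabulation
#' code fails loudly.
#'
#' @inheritParams weibull_cdf
#' @return Release speed, percent/hour, non-negative.
#' @export
weibull_pdf <- function(t, p) {
  t <- check_times(t)
  p <- as_weibull_params(p)
  if (p$beta < 1 && any(t == 0))
    stop(errorCondition(
      sprintf("release speed diverges at t = 0 for beta = %g < 1", p$beta),
      class = c("wr_diverges_error", "wr_domain_error", "error")))
  u <- t / p$tau_k
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- p$m_inf * (p$beta / p$tau_k) * u[pos]^(p$beta - 1) *
    exp(-u[pos]^p$beta)
  if (any(!pos)) out[!pos] <- if (p$beta == 1) p$m_inf / p$tau_k else 0
  out
}

#' Invert the Weibull cumulative release
#'
#' Closed-form inverse of [weibull_cdf()]: the time at which cumulative
#' release first reaches `m` percent,
#' \eqn{t = \tau_K(-\ln(1 - m/M_\infty))^{1/\beta}}.
#'
#' @param m Cumulative release, percent; `0 <= m < m_inf`. Vectorized.
#' @inheritParams weibull_cdf
#' @return Time, hours.
#' @export
weibull_inverse <- function(m, p) {
  p <- as_weibull_params(p)
  if (!is.numeric(m) || anyNA(m))
    stop_domain("'m' must be numeric with no missing values")
  if (any(m < 0)) stop_domain("negative release target")
  if (any(m >= p$m_inf))
    stop_domain("release target unreachable: %g %% >= saturation M_inf = %g %%",
                max(m), p$m_inf)
  p$tau_k * (-log(1 - m / p$m_inf))^(1 / p$beta)
}

#' Small-time power-law limit of the Weibull model
#'
#' First-order Taylor expansion of [weibull_cdf()] for small
#' \eqn{(t/\tau_K)^\beta}: \eqn{M(t) \approx M_\infty (t/\tau_K)^\beta}.
#' This is the Korsmeyer-Peppas power-law form, and coincides with the
#' Higuchi square-root law when `beta = 1/2`.
#'
#' @inheritParams weibull_cdf
#' @return Approximate cumulative release, percent.
#' @export
powerlaw_limit <- function(t, p) {
  t <- check_times(t)
  p <- as_weibull_params(p)
  p$m_inf * (t / p$tau_k)^p$beta
}

#' Kohlrausch stretched-exponential survival function
#'
#' The fraction of drug still retained at time `t`,
#' \eqn{e^{-(t/\tau_K)^\beta}}; the complement of the normalized Weibull
#' CDF and the classical relaxation function of disordered media.
#'
#' @param t Time(s), hours, >= 0.
#' @param tau_k Characteristic time, hours, > 0.
#' @param beta Shape exponent, > 0.
#' @return Dimensionless surviving fraction in `(0, 1]`.
#' @export
kohlrausch <- function(t, tau_k, beta) {
  t <- check_times(t)
  if (tau_k <= 0) stop_domain("'tau_k' must be > 0")
  if (beta <= 0) stop_domain("'beta' must be > 0")
  exp(-(t / tau_k)^beta)
}

#' Mean release (relaxation) time
#'
#' The mean of the Weibull waiting-time distribution,
#' \eqn{\langle\tau\rangle = (\tau_K/\beta)\,\Gamma(1/\beta)
#'   = \tau_K\,\Gamma(1 + 1/\beta)}.
#' Both equivalent closed forms are evaluated and asserted equal to 1e-12
#' relative, guarding against Gamma-argument mistakes.
#'
#' @inheritParams weibull_cdf
#' @return Mean release time, hours.
#' @examples
#' mean_release_time(weibull_params(15.1, 27.90, 2.67))  # 24.8 h
#' @export
mean_release_time <- function(p) {
  p <- as_weibull_params(p)
  a <- (p$tau_k / p$beta) * gamma(1 / p$beta)
  b <- p$tau_k * gamma(1 + 1 / p$beta)
  stopifnot(abs(a - b) <= 1e-12 * abs(b))
  b
}

#' Standard deviation of the release time
#'
#' \eqn{\sigma = \sqrt{(\tau_K^2/\beta)\,[\,2\Gamma(2/\beta)
#'   - (1/\beta)\Gamma(1/\beta)^2\,]}}, identically the standard Weibull
#' standard deviation
#' \eqn{\tau_K\sqrt{\Gamma(1+2/\beta) - \Gamma(1+1/\beta)^2}}.
#'
#' @inheritParams weibull_cdf
#' @return Standard deviation of the release time, hours.
#' @export
std_release_time <- function(p) {
  p <- as_weibull_params(p)
  v <- (p$tau_k^2 / p$beta) *
    (2 * gamma(2 / p$beta) - (1 / p$beta) * gamma(1 / p$beta)^2)
  v2 <- p$tau_k^2 * (gamma(1 + 2 / p$beta) - gamma(1 + 1 / p$beta)^2)
  stopifnot(abs(v - v2) <= 1e-10 * abs(v2))
  sqrt(v)
}

#' Derived time statistics of a Weibull release model
#'
#' @inheritParams weibull_cdf
#' @return A list with `mean_time` and `std_time` (hours) and `mode_time`
#'   (hours; `NA` when `beta <= 1`, where the release-speed density has no
#'   interior maximum).
#' @export
derived_stats <- function(p) {
  p <- as_weibull_params(p)
  mode_t <- if (p$beta > 1)
    p$tau_k * ((p$beta - 1) / p$beta)^(1 / p$beta) else NA_real_
  list(mean_time = mean_release_time(p),
       std_time = std_release_time(p),
       mode_time = mode_t)
}

# ---- classical mechanistic comparison models ---------------------------

.mech_model_sizes <- c(zero_order = 1L, first_order = 2L, higuchi = 1L,
                       power_law = 2L, weibull = 3L)

#' Mechanistic release-model coefficients
#'
#' Container for the classical comparison models. Coefficient conventions:
#' * `zero_order`: `k0` (\%/h), release `k0 * t`;
#' * `first_order`: `m_inf` (\%) and rate `k` (1/h), release
#'   `m_inf * (1 - exp(-k t))`;
#' * `higuchi`: `k_h` (\%/sqrt(h)), release `k_h * sqrt(t)`;
#' * `power_law`: prefactor `k` (\%/h^n) and exponent `n`, release
#'   `k * t^n` (Korsmeyer-Peppas);
#' * `weibull`: `m_inf`, `tau_k`, `beta` as in [weibull_params()].
#'
#' @param model_id One of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"power_law"`, `"weibull"`.
#' @param coefficients Numeric vector; its length must match the model
#'   (1, 2, 1, 2, 3 respectively) and rate constants must be positive.
#' @return An object of class `"mech_model"`.
#' @export
mech_model <- function(model_id, coefficients) {
  model_id <- match.arg(model_id, names(.mech_model_sizes))
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != .mech_model_sizes[[model_id]])
    stop_domain("model '%s' needs %d coefficient(s), got %d", model_id,
                .mech_model_sizes[[model_id]], length(coefficients))
  if (anyNA(coefficients))
    stop_domain("coefficients must not contain NA")
  rate <- switch(model_id,
                 zero_order = coefficients[1L],
                 first_order = coefficients[2L],
                 higuchi = coefficients[1L],
                 power_law = coefficients[1L],
                 weibull = coefficients[2L])
  if (rate <= 0)
    stop_domain("rate constant of model '%s' must be > 0", model_id)
  structure(list(model_id = model_id, coefficients = coefficients),
            class = "mech_model")
}

#' Evaluate a mechanistic release model
#'
#' @param c A [mech_model()] object.
#' @param t Time(s), hours, >= 0.
#' @return Cumulative release, percent.
#' @export
model_value <- function(c, t) {
  if (!inherits(c, "mech_model")) stop_domain("'c' must be a mech_model")
  t <- check_times(t)
  co <- c$coefficients
  switch(c$model_id,
         zero_order = co[1L] * t,
         first_order = co[1L] * (1 - exp(-co[2L] * t)),
         higuchi = co[1L] * sqrt(t),
         power_law = co[1L] * t^co[2L],
         weibull = weibull_cdf(t, weibull_params(co[1L], co[2L], co[3L])),
         stop_domain("unknown model id '%s'", c$model_id))
}

#' Printed parameter sets of the three release conditions
#'
#' The fitted Weibull parameter presets used throughout the package:
#' a non-irradiated silver-polymethacrylate system and the laser-irradiated
#' colloid and electrospun-nanofiber carriers of the drug sorafenib
#' tosylate.
#'
#' @return A named list of [weibull_params()]: `non_irradiated`
#'   (0.012, 17.60, 1.01), `colloids` (15.1, 27.90, 2.67) and `nanofibers`
#'   (27.8, 10.51, 0.71).
#' @export
release_presets <- function() {
  list(non_irradiated = weibull_params(0.012, 17.60, 1.01),
       colloids = weibull_params(15.1, 27.90, 2.67),
       nanofibers = weibull_params(27.8, 10.51, 0.71))
}
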