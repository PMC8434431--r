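# Seeded synthetic release-profile generator: known ground truth plus
# controlled additive Gaussian noise, so fitting and interpretation are
# testable without external data.

# run expr with a local RNG state seeded by `seed`, restoring the caller's
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed))
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  else
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Sampling schedule for a simulated release experiment
#'
#' @param kind `"paperlike"` (dense early sampling, sparse late, spanning
#'   roughly 0.25-80 h as in a typical withdrawal assay), `"uniform"`, or
#'   `"log_spaced"`.
#' @param n_points Number of sampling times, >= 3.
#' @param t_max Last sampling time, hours; default 80.
#' @param t_min First sampling time for the log-spaced kinds; default
#'   0.25 h.
#' @return An object of class `"sampling_schedule"`.
#' @export
sampling_schedule <- function(kind = c("paperlike", "uniform",
                                       "log_spaced"),
                              n_points = 20L, t_max = 80, t_min = 0.25) {
  kind <- match.arg(kind)
  if (!is.numeric(n_points) || n_points < 3L)
    stop_domain("'n_points' must be >= 3")
  if (t_max <= 0) stop_domain("'t_max' must be > 0")
  if (t_min <= 0 || t_min >= t_max)
    stop_domain("'t_min' must satisfy 0 < t_min < t_max")
  structure(list(kind = kind, n_points = as.integer(n_points),
                 t_max = t_max, t_min = t_min),
            class = "sampling_schedule")
}

#' Materialize a sampling schedule into times
#'
#' `uniform` gives equally spaced times ending at `t_max`; `log_spaced`
#' and `paperlike` give geometrically spaced times from `t_min` to
#' `t_max`, which concentrates points at early times where the release
#' curve changes fastest.
#'
#' @param s A [sampling_schedule()].
#' @return Strictly increasing times, hours.
#' @export
generate_schedule <- function(s) {
  stopifnot(inherits(s, "sampling_schedule"))
  switch(s$kind,
         uniform = seq(s$t_max / s$n_points, s$t_max,
                       length.out = s$n_points),
         log_spaced = ,
         paperlike = exp(seq(log(s$t_min), log(s$t_max),
                             length.out = s$n_points)))
}

#' Additive-Gaussian noise model
#'
#' @param sd Noise standard deviation on cumulative release, percent,
#'   >= 0.
#' @param seed Integer RNG seed; mandatory, recorded in the profile
#'   provenance.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sd, seed) {
  if (!is.numeric(sd) || sd < 0) stop_domain("'sd' must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_domain("'seed' is mandatory and must be a single integer")
  structure(list(kind = "additive_gaussian", sd = sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a noisy cumulative release profile
#'
#' Evaluates the Weibull cumulative release at the scheduled times and
#' adds independent Gaussian noise, clipping at 0 from below (assay
#' readings cannot be negative). No monotonicity is enforced on the noisy
#' values: real withdrawal-assay data show small inversions and fitters
#' must tolerate them. The ground-truth parameters, noise level and seed
#' are stored in the profile's `provenance` field, and the simulation is
#' fully deterministic given the seed.
#'
#' @param p A [weibull_params()] ground truth.
#' @param s A [sampling_schedule()].
#' @param noise A [noise_model()].
#' @param label Profile label.
#' @return A [release_profile()] with `m_inf_hint = p$m_inf` and a
#'   `provenance` list.
#' @export
generate_profile <- function(p, s, noise, label = "synthetic") {
  p <- as_weibull_params(p)
  stopifnot(inherits(s, "sampling_schedule"),
            inherits(noise, "noise_model"))
  times <- generate_schedule(s)
  clean <- weibull_cdf(times, p)
  eps <- if (noise$sd > 0)
    with_seed(noise$seed, stats::rnorm(length(times), 0, noise$sd))
  else numeric(length(times))
  prof <- release_profile(times, pmax(0, clean + eps), label = label,
                          m_inf_hint = p$m_inf)
  prof$provenance <- list(m_inf = p$m_inf, tau_k = p$tau_k,
                          beta = p$beta, noise_sd = noise$sd,
                          seed = noise$seed, schedule_kind = s$kind)
  prof
}

#' Parameter-recovery experiment
#'
#' Repeats simulate-then-fit `reps` times and aggregates estimator bias
#' and root-mean-square error for `tau_k` and `beta`. Per-replicate seeds
#' are derived deterministically from the base seed of the noise model
#' (`seed + i`, kept below 2^31). Non-convergent replicates are excluded
#' and counted.
#'
#' @param p_true Ground-truth [weibull_params()].
#' @param reps Number of replicates, >= 10.
#' @param noise A [noise_model()]; its seed is the base seed.
#' @param s A [sampling_schedule()].
#' @return A list with `bias` and `rmse` (each named `c(tau_k, beta)`),
#'   `n_converged`, `n_failed`, `estimates` (data frame of per-replicate
#'   estimates).
#' @export
recovery_experiment <- function(p_true, reps, noise, s) {
  p_true <- as_weibull_params(p_true)
  if (reps < 10L) stop_domain("'reps' must be >= 10")
  est <- matrix(NA_real_, nrow = reps, ncol = 2L,
                dimnames = list(NULL, c("tau_k", "beta")))
  for (i in seq_len(reps)) {
    ni <- noise_model(noise$sd, (noise$seed + i) %% .Machine$integer.max)
    prof <- generate_profile(p_true, s, ni)
    fit <- fit_weibull_cdf(prof, m_inf = p_true$m_inf)
    if (fit$converged)
      est[i, ] <- c(fit$params$tau_k, fit$params$beta)
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop_domain("no replicate converged")
  truth <- c(tau_k = p_true$tau_k, beta = p_true$beta)
  err <- sweep(est[ok, , drop = FALSE], 2L, truth)
  list(bias = colMeans(err),
       rmse = sqrt(colMeans(err^2)),
       n_converged = sum(ok), n_failed = sum(!ok),
       estimates = as.data.frame(est[ok, , drop = FALSE]))
}
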