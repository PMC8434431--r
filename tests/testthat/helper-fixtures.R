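# Shared fixtures: the three printed parameter sets and noiseless-profile
# builders used across the suite.

presets <- release_presets()
p_nonirr <- presets$non_irradiated  # (0.012, 17.60, 1.01)
p_colloids <- presets$colloids      # (15.1, 27.90, 2.67)
p_nanofibers <- presets$nanofibers  # (27.8, 10.51, 0.71)

noiseless_profile <- function(p, times, label = "noiseless") {
  release_profile(times, weibull_cdf(times, p), label = label,
                  m_inf_hint = p$m_inf)
}

# deterministic "random" valid parameter sets for property-style loops
random_params <- function(n, seed = 99L) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(replicate(n, weibull_params(
    m_inf = runif(1, 5, 100),
    tau_k = runif(1, 0.5, 50),
    beta = runif(1, 0.3, 3.5)), simplify = FALSE))
}
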