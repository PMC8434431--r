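# Transport-mechanism classification from fitted shape exponents.

new_mechanism_label <- function(category, basis, value, note = "") {
  structure(list(category = category, basis = basis,
                 value = value, note = note),
            class = "mechanism_label")
}

#' @export
print.mechanism_label <- function(x, ...) {
  cat(sprintf("Mechanism: %s (%s = %g)%s\n", x$category, x$basis, x$value,
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

#' Classify the release mechanism from the Weibull shape exponent
#'
#' Band rules: `beta <= 0.75` indicates Fickian diffusion (in either
#' fractal or Euclidean spaces); `0.75 < beta < 1` a combined mechanism of
#' Fickian diffusion and swelling-controlled transport; `beta > 1` a
#' complex sigmoidal release whose rate rises to an inflection point
#' before decaying. `beta = 1` exactly is the first-order (exponential)
#' kinetics boundary and is labelled `first_order_like`. Whenever
#' `|beta - 1| <= first_order_band` the note carries a first-order-like
#' annotation, since shape exponents indistinguishable from 1 describe
#' concentration-gradient-driven release.
#'
#' @param beta Shape exponent, > 0.
#' @param first_order_band Half-width of the annotation band around
#'   `beta = 1`; default 0.1.
#' @return A `"mechanism_label"` with fields `category`, `basis`
#'   (`"beta"`), `value`, `note`.
#' @examples
#' classify_beta(0.71)  # fickian_diffusion
#' classify_beta(2.67)  # complex_sigmoidal
#' @export
classify_beta <- function(beta, first_order_band = 0.1) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0)
    stop_domain("'beta' must be a single positive number")
  category <-
    if (beta <= 0.75) "fickian_diffusion"
    else if (beta < 1) "combined_fickian_swelling"
    else if (beta == 1) "first_order_like"
    else "complex_sigmoidal"
  note <- if (abs(beta - 1) <= first_order_band && beta != 1)
    "first-order-like (beta within band around 1: release governed by the concentration gradient)"
  else if (beta == 1)
    "exact first-order (exponential) kinetics"
  else ""
  new_mechanism_label(category, "beta", beta, note)
}

#' Classify the release mechanism from the early power-law slope
#'
#' Interprets the Korsmeyer-Peppas exponent `n` estimated from the initial
#' log-log slope of a release curve: `n <= lower` suggests a
#' diffusion-controlled process (the Higuchi regime sits at `n = 0.5`);
#' `lower < n <= upper` is compatible with near-constant-rate (zero-order
#' like) kinetics; `n > upper` signals complex collective processes
#' (polymer degradation, swelling, erosion acting together). Band edges
#' are configurable; the defaults are 0.6 and 1.2.
#'
#' @param n Power-law exponent, > 0.
#' @param bands Length-2 numeric `c(lower, upper)` band edges.
#' @return A `"mechanism_label"` with `basis = "powerlaw_n"`.
#' @examples
#' classify_powerlaw_slope(0.48)  # diffusion_controlled
#' classify_powerlaw_slope(0.88)  # zero_order_like
#' classify_powerlaw_slope(2.57)  # complex_collective
#' @export
classify_powerlaw_slope <- function(n, bands = c(0.6, 1.2)) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop_domain("'n' must be a single positive number")
  if (length(bands) != 2L || bands[1L] >= bands[2L])
    stop_domain("'bands' must be c(lower, upper) with lower < upper")
  category <-
    if (n <= bands[1L]) "diffusion_controlled"
    else if (n <= bands[2L]) "zero_order_like"
    else "complex_collective"
  note <- switch(category,
    diffusion_controlled = "initial release consistent with a diffusion process",
    zero_order_like = "initial release at near-constant rate",
    complex_collective = "several internal collective processes (swelling, degradation) likely at work")
  new_mechanism_label(category, "powerlaw_n", n, note)
}
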