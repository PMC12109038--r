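#' Upper end of the useful prediction-error range
#'
#' Three times the weight switch-over scale
#' `sqrt(2 * (prior_var + lik_var) * log(1 / eps))` (the prediction error
#' at which the posterior weights cross, see [mixture_weights()]). The
#' information-gain peaks sit near the switch-over, so `[0, delta_upper()]`
#' always brackets them with a wide margin; it is the default grid and
#' optimisation bound throughout.
#'
#' @inheritParams augmented_evidence
#' @return A positive scalar.
#' @export
delta_upper <- function(prior_var, lik_var, eps = 1e-3) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  check_eps(eps)
  3 * sqrt(2 * (prior_var + lik_var) * log(1 / eps))
}

# default curve grid: linear coverage plus log-spaced refinement near zero
default_delta_grid <- function(prior_var, lik_var, eps, n = 400L) {
  hi <- delta_upper(prior_var, lik_var, eps)
  n_lin <- ceiling(n / 2)
  n_log <- n - n_lin
  sort(unique(c(
    seq(0, hi, length.out = n_lin),
    exp(seq(log(hi * 1e-3), log(hi), length.out = n_log))
  )))
}

#' Tabulate the information-gain curves
#'
#' Evaluates surprise, recognition gain (KLD), Bayesian surprise (BS) and
#' total information gain (IG = KLD + BS) of the noise-augmented model
#' along a prediction-error grid. This is the Wundt-curve table: each gain
#' is an inverted-U function of prediction error (and of surprise, see
#' [gain_vs_surprise()]).
#'
#' @inheritParams augmented_evidence
#' @param deltas Optional sorted non-negative grid of prediction errors.
#'   Defaults to `n` points (log-spaced plus linear) on
#'   `[0, delta_upper()]`.
#' @param n Number of grid points when `deltas` is `NULL`.
#' @return A tibble of class `gain_curve` with columns `delta`, `surprise`,
#'   `kld`, `bs`, `ig` (all gains in nats) and the model parameters as
#'   attributes.
#' @examples
#' \donttest{
#' curve <- gain_curve(prior_var = 10, lik_var = 1, n = 50)
#' dplyr::slice_max(curve, ig, n = 1)
#' }
#' @export
gain_curve <- function(prior_var, lik_var, eps = 1e-3, deltas = NULL,
                       n = 400L) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  check_eps(eps)
  if (is.null(deltas)) {
    deltas <- default_delta_grid(prior_var, lik_var, eps, n)
  }
  check_nonnegative(deltas, "deltas")
  if (is.unsorted(deltas)) {
    abort("`deltas` must be sorted in increasing order.",
          class = "epigain_parameter_error")
  }
  kld <- withCallingHandlers(
    kld_mixture(deltas, prior_var, lik_var, eps),
    epigain_numerical_error = function(e) {
      abort(paste0("gain_curve failed while evaluating KLD: ",
                   conditionMessage(e)),
            class = "epigain_numerical_error")
    }
  )
  bs <- bs_mixture(deltas, prior_var, lik_var, eps)
  out <- tibble(
    delta = deltas,
    surprise = mixture_surprise(deltas, prior_var, lik_var, eps),
    kld = kld,
    bs = bs,
    ig = kld + bs
  )
  structure(out,
            class = c("gain_curve", class(out)),
            prior_var = prior_var, lik_var = lik_var, eps = eps)
}

#' Reparameterise a gain curve by surprise
#'
#' Returns the same tabulated gains as functions of surprise instead of
#' prediction error (the Wundt-curve axis). Surprise is strictly monotone
#' in prediction error under the noise-augmented model, so this is a pure
#' reparameterisation: no value is recomputed and the peaks are unchanged.
#'
#' @param curve A [gain_curve()].
#' @return A tibble with columns `surprise`, `kld`, `bs`, `ig` (and
#'   `delta` retained last for reference).
#' @export
gain_vs_surprise <- function(curve) {
  stopifnot(inherits(curve, "gain_curve"))
  if (is.unsorted(curve$surprise)) {
    abort("surprise is not monotone along the grid; the curve is corrupt.",
          class = "epigain_internal_error")
  }
  dplyr::select(as_tibble(curve), "surprise", "kld", "bs", "ig", "delta")
}
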