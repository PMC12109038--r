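#' Simulate an alternating-curiosity inquiry cycle
#'
#' Deterministic simulation of the idealised inquiry dynamic: diversive
#' curiosity (novelty seeking) jumps the prediction error to the Bayesian
#' surprise optimum `delta_bs`, specific curiosity (evidence seeking)
#' jumps it to the recognition-gain optimum `delta_kld`, and the two
#' phases strictly alternate. The settled trace oscillates between the two
#' optima, so its surprise amplitude equals `d_s = s_bs - s_kld` and its
#' prediction-error amplitude equals `d_delta` — the standing surprise
#' fluctuation around the optimal arousal level, which always brackets the
#' total-gain optimum `s_ig`.
#'
#' The trace is a pure function of the parameters; there is no randomness.
#'
#' @inheritParams augmented_evidence
#' @param n_steps Number of curiosity-driven steps (>= 2).
#' @param start_delta Prediction error of the starting state (step 0).
#' @param start_phase `"auto"` (default), `"diversive"` or `"specific"`.
#'   `"auto"` starts diversive when the starting surprise lies below the
#'   recognition-gain optimum `s_kld` (climbing the Wundt curve from the
#'   boredom side) and specific otherwise (descending from confusion).
#' @param optima Optionally a precomputed [find_optima()] result for the
#'   same parameters, to avoid re-optimising.
#' @return A tibble of class `inquiry_cycle` with one row for the start
#'   state (step 0, phase `"start"`) and one per step: columns `step`,
#'   `phase`, `delta`, `surprise`, `kld`, `bs`, `ig`. The generating
#'   optimum summary is attached as attribute `"optima"`.
#' @examples
#' \donttest{
#' simulate_cycle(prior_var = 10, lik_var = 1, n_steps = 6)
#' }
#' @export
simulate_cycle <- function(prior_var, lik_var, eps = 1e-3, n_steps = 6L,
                           start_delta = 0,
                           start_phase = c("auto", "diversive", "specific"),
                           optima = NULL) {
  start_phase <- match.arg(start_phase)
  if (!is.numeric(n_steps) || n_steps < 2L) {
    abort("`n_steps` must be at least 2.", class = "epigain_parameter_error")
  }
  check_nonnegative(start_delta, "start_delta")
  if (is.null(optima)) {
    optima <- find_optima(prior_var, lik_var, eps)
  }
  stopifnot(inherits(optima, "gain_optima"))
  g <- glance(optima)

  if (start_phase == "auto") {
    s0 <- mixture_surprise(start_delta, prior_var, lik_var, eps)
    start_phase <- if (s0 < g$s_kld) "diversive" else "specific"
  }
  phases <- rep(c(start_phase,
                  setdiff(c("diversive", "specific"), start_phase)),
                length.out = n_steps)
  deltas <- ifelse(phases == "diversive", g$delta_bs, g$delta_kld)

  all_deltas <- c(start_delta, deltas)
  kld <- kld_mixture(all_deltas, prior_var, lik_var, eps)
  bs <- bs_mixture(all_deltas, prior_var, lik_var, eps)
  out <- tibble(
    step = 0:n_steps,
    phase = c("start", phases),
    delta = all_deltas,
    surprise = mixture_surprise(all_deltas, prior_var, lik_var, eps),
    kld = kld,
    bs = bs,
    ig = kld + bs
  )
  structure(out, class = c("inquiry_cycle", class(out)),
            optima = g, prior_var = prior_var, lik_var = lik_var, eps = eps)
}
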