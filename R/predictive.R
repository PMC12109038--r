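#' Predictive recognition gain (pKLD)
#'
#' The recognition gain expected under the Gaussian predictive marginal of
#' observations, `q(o) = N(prior_mean, prior_var + lik_var)`. Because the
#' pure-Gaussian recognition gain is `a_kld * delta^2 + b_kld` and
#' `E[delta^2] = prior_var + lik_var` under the predictive marginal, the
#' expectation has the closed form
#' `a_kld * (prior_var + lik_var) + b_kld` (normalised-density
#' convention). It vanishes as `prior_var -> 0`: with nothing left to
#' learn about the state there is no recognition gain to expect.
#'
#' @inheritParams posterior_params
#' @return Expected recognition gain in nats, >= 0.
#' @examples
#' predictive_kld(1, 1) # 1/2 + (1/2 - log(2)/2)
#' @export
predictive_kld <- function(prior_var, lik_var) {
  co <- gain_coefficients(prior_var, lik_var)
  co$a_kld * (prior_var + lik_var) + co$b_kld
}

#' Predictive Bayesian surprise = state-observation mutual information
#'
#' The Bayesian surprise expected under the predictive marginal equals the
#' mutual information between hidden state and observation of the Gaussian
#' channel: `I(s; o) = log((prior_var + lik_var) / lik_var) / 2`. It is
#' invariant to the prior mean and vanishes as `prior_var -> 0`.
#'
#' @inheritParams posterior_params
#' @return Mutual information in nats, >= 0.
#' @examples
#' mutual_information(10, 1) # log(11)/2
#' @export
mutual_information <- function(prior_var, lik_var) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  0.5 * log((prior_var + lik_var) / lik_var)
}

#' Ambiguity (expected conditional observation entropy)
#'
#' The observation entropy expected to remain after state recognition and
#' learning: for the Gaussian likelihood the conditional entropy
#' `H(o | s) = log(2 * pi * e * lik_var) / 2` is constant in `s`, so the
#' ambiguity equals it. Normalised-density convention; can be negative for
#' very precise observations (differential entropy).
#'
#' @inheritParams posterior_params
#' @return Ambiguity in nats.
#' @examples
#' ambiguity(1) # log(2 * pi * exp(1)) / 2
#' @export
ambiguity <- function(lik_var) {
  check_positive(lik_var, "lik_var")
  0.5 * log(2 * pi * exp(1) * lik_var)
}

#' Risk of a policy's predictive marginal
#'
#' KL divergence of the predictive observation marginal
#' `N(prior_mean, prior_var + lik_var)` from a desired observation
#' distribution (the preference). Zero iff the predictive marginal equals
#' the preference.
#'
#' @inheritParams posterior_params
#' @param preference A [gaussian_belief()] giving the preferred
#'   observation distribution.
#' @return Risk in nats, >= 0.
#' @examples
#' risk(10, 1, preference = gaussian_belief(0, 11)) # 0
#' @export
risk <- function(prior_var, lik_var, preference, prior_mean = 0) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  if (missing(preference) || is.null(preference)) {
    abort("`preference` is required to compute risk.",
          class = "epigain_parameter_error")
  }
  stopifnot(inherits(preference, "gaussian_belief"))
  kl_gaussians(gaussian_belief(prior_mean, prior_var + lik_var), preference)
}

#' Expected free energy = risk + ambiguity
#'
#' The expected free energy of a policy, decomposed as the sum of
#' [risk()] and [ambiguity()]. When the predictive marginal matches the
#' preference the risk vanishes and the expected free energy reduces to
#' the ambiguity; maximising the predictive information gains
#' ([predictive_kld()] + [mutual_information()]) at fixed predictive
#' entropy is then equivalent to minimising ambiguity, since the
#' predictive entropy satisfies `H(o) = pBS + ambiguity`.
#'
#' @inheritParams risk
#' @return Expected free energy in nats.
#' @export
expected_free_energy <- function(prior_var, lik_var, preference,
                                 prior_mean = 0) {
  risk(prior_var, lik_var, preference, prior_mean) + ambiguity(lik_var)
}

#' Predictive free-energy report
#'
#' All predictive quantities of a Gaussian policy model in one row:
#' expected recognition gain (`pkld`), mutual information (`pbs`),
#' `ambiguity`, and — when a preference is supplied — `risk` and expected
#' free energy (`efe`).
#'
#' @inheritParams posterior_params
#' @param pref_mean,pref_var Optional preference parameters; both must be
#'   given together.
#' @return A one-row tibble with columns `pkld`, `pbs`, `ambiguity`,
#'   `risk`, `efe` (`NA` for the last two without a preference).
#' @examples
#' predictive_report(10, 1, pref_mean = 0, pref_var = 11)
#' @export
predictive_report <- function(prior_var, lik_var, prior_mean = 0,
                              pref_mean = NULL, pref_var = NULL) {
  has_pref <- !is.null(pref_mean) || !is.null(pref_var)
  if (has_pref && (is.null(pref_mean) || is.null(pref_var))) {
    abort("supply both `pref_mean` and `pref_var`, or neither.",
          class = "epigain_parameter_error")
  }
  rk <- efe <- NA_real_
  if (has_pref) {
    pref <- gaussian_belief(pref_mean, pref_var)
    rk <- risk(prior_var, lik_var, pref, prior_mean)
    efe <- rk + ambiguity(lik_var)
  }
  tibble(
    pkld = predictive_kld(prior_var, lik_var),
    pbs = mutual_information(prior_var, lik_var),
    ambiguity = ambiguity(lik_var),
    risk = rk,
    efe = efe
  )
}
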