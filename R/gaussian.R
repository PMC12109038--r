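#' One-dimensional Gaussian belief
#'
#' A lightweight container for a univariate Gaussian state density
#' `N(mean, var)`. The same object plays the roles of prior, posterior and
#' observation preference throughout the package.
#'
#' @param mean Mean, in state units.
#' @param var Variance, in state units squared; must be strictly positive.
#'
#' @return An object of class `gaussian_belief`: a named list with elements
#'   `mean` and `var`.
#' @examples
#' gaussian_belief(0, 10)
#' @export
gaussian_belief <- function(mean, var) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    abort("`mean` must be a single finite number.",
          class = "epigain_parameter_error")
  }
  check_positive(var, "var")
  structure(list(mean = mean, var = var), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> N(mean = %g, var = %g)\n", x$mean, x$var))
  invisible(x)
}

#' Conjugate Gaussian posterior parameters
#'
#' Updates a Gaussian prior `N(prior_mean, prior_var)` with a single
#' observation under a Gaussian likelihood of variance `lik_var`, returning
#' the exact conjugate posterior
#' `N((prior_var * obs + lik_var * prior_mean) / (prior_var + lik_var),
#'    prior_var * lik_var / (prior_var + lik_var))`.
#' The posterior variance is always smaller than both `prior_var` and
#' `lik_var`.
#'
#' @param obs Observed value (likelihood peak location).
#' @param prior_var Prior variance \eqn{\sigma_p^2 > 0} (prediction
#'   uncertainty).
#' @param lik_var Likelihood variance \eqn{\sigma_l^2 > 0} (observation
#'   uncertainty).
#' @param prior_mean Prior mean \eqn{\eta}; defaults to 0.
#'
#' @return A [gaussian_belief()] holding the posterior mean and variance.
#' @examples
#' posterior_params(11, prior_var = 10, lik_var = 1) # N(10, 10/11)
#' @export
posterior_params <- function(obs, prior_var, lik_var, prior_mean = 0) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  total <- prior_var + lik_var
  gaussian_belief(
    mean = (prior_var * obs + lik_var * prior_mean) / total,
    var  = prior_var * lik_var / total
  )
}

#' Gaussian model evidence kernel
#'
#' The model evidence of the Gaussian generative model as a function of
#' prediction error, in the kernel-height-one convention:
#' `e(delta) = exp(-delta^2 / (2 * (prior_var + lik_var)))`.
#' It equals 1 at `delta = 0` and decays to 0 as the prediction error grows,
#' so the corresponding surprise [gaussian_surprise()] starts at zero.
#'
#' @param delta Prediction error \eqn{\delta \ge 0}, the distance between
#'   the prior mean and the likelihood peak. Vectorised.
#' @inheritParams posterior_params
#'
#' @return Evidence values in `(0, 1]`.
#' @examples
#' evidence_kernel(0, 10, 1)          # 1
#' evidence_kernel(sqrt(22), 10, 1)   # exp(-1)
#' @export
evidence_kernel <- function(delta, prior_var, lik_var) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  check_nonnegative(delta, "delta")
  exp(-delta^2 / (2 * (prior_var + lik_var)))
}

#' Gaussian surprise (negative log evidence)
#'
#' Shannon surprise of the pure-Gaussian model,
#' `-log(e(delta)) = delta^2 / (2 * (prior_var + lik_var))`:
#' a quadratic function of prediction error, zero iff `delta = 0`, unbounded
#' as `delta` grows. In nats.
#'
#' @inheritParams evidence_kernel
#' @return Surprise values, >= 0.
#' @examples
#' gaussian_surprise(sqrt(22), 10, 1) # 1
#' @export
gaussian_surprise <- function(delta, prior_var, lik_var) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  check_nonnegative(delta, "delta")
  delta^2 / (2 * (prior_var + lik_var))
}

#' KL divergence between two univariate Gaussians
#'
#' `kl_gaussians(p, q)` returns `D_KL(p || q)` in nats:
#' `log(sd_q / sd_p) + (var_p + (mean_p - mean_q)^2) / (2 var_q) - 1/2`.
#' KL divergence is asymmetric: swap the arguments for the reverse
#' direction.
#'
#' @param p,q [gaussian_belief()] objects.
#' @return A single non-negative number; zero iff `p` and `q` coincide.
#' @examples
#' kl_gaussians(gaussian_belief(0, 1), gaussian_belief(1, 1)) # 0.5
#' @export
kl_gaussians <- function(p, q) {
  stopifnot(inherits(p, "gaussian_belief"), inherits(q, "gaussian_belief"))
  0.5 * log(q$var / p$var) +
    (p$var + (p$mean - q$mean)^2) / (2 * q$var) - 0.5
}

#' Perceived uncertainty (expected inverse accuracy)
#'
#' The expected negative log-likelihood under the exact Gaussian posterior,
#' `U = -E[log p(o | s)]` with the *normalised* Gaussian likelihood density.
#' Together with Bayesian surprise it reconstructs the normalised negative
#' log evidence: `-log p(o) = BS + U`, where
#' `-log p(o) = log(2 pi (prior_var + lik_var)) / 2 + gaussian_surprise()`.
#'
#' `U` depends on the observation only through the prediction error, so it
#' is parameterised by `delta` directly.
#'
#' @inheritParams evidence_kernel
#' @return Perceived uncertainty in nats (finite for all finite `delta`).
#' @examples
#' d <- 3
#' lhs <- 0.5 * log(2 * pi * 11) + gaussian_surprise(d, 10, 1)
#' lhs - bs_closed(d, 10, 1) - perceived_uncertainty(d, 10, 1) # ~0
#' @export
perceived_uncertainty <- function(delta, prior_var, lik_var) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  check_nonnegative(delta, "delta")
  total <- prior_var + lik_var
  post_var <- prior_var * lik_var / total
  # E[(o - s)^2] under the posterior: (o - post_mean)^2 + post_var,
  # with o - post_mean = -lik_var * delta / total
  esq <- post_var + (lik_var * delta / total)^2
  0.5 * log(2 * pi * lik_var) + esq / (2 * lik_var)
}
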