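#' Quadratic coefficients of the pure-Gaussian information gains
#'
#' Without a noise floor both information gains are quadratics of the
#' prediction error:
#' `KLD_N(delta) = a_kld * delta^2 + b_kld` and
#' `BS_N(delta) = a_bs * delta^2 + b_bs`, with
#' \deqn{a_{KLD} = \frac{\sigma_p^2}{2\sigma_l^2(\sigma_p^2+\sigma_l^2)},
#'   \quad
#'   b_{KLD} = \frac{1}{2}\ln\frac{\sigma_l^2}{\sigma_p^2+\sigma_l^2}
#'     + \frac{\sigma_p^2}{2\sigma_l^2},}
#' \deqn{a_{BS} = \frac{\sigma_p^2}{2(\sigma_p^2+\sigma_l^2)^2},
#'   \quad
#'   b_{BS} = \frac{1}{2}\ln\frac{\sigma_p^2+\sigma_l^2}{\sigma_l^2}
#'     - \frac{\sigma_p^2}{2(\sigma_p^2+\sigma_l^2)}.}
#' Both slope coefficients are strictly positive for any positive
#' variances, so prediction error always increases both gains — the
#' divergence that motivates the uniform-noise correction in
#' [kld_mixture()] / [bs_mixture()].
#'
#' @inheritParams posterior_params
#' @return A one-row tibble with columns `a_kld`, `b_kld`, `a_bs`, `b_bs`
#'   (nats and nats per squared state unit).
#' @examples
#' gain_coefficients(1, 1) # a_kld = 1/4, a_bs = 1/8
#' @export
gain_coefficients <- function(prior_var, lik_var) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  total <- prior_var + lik_var
  tibble(
    a_kld = prior_var / (2 * lik_var * total),
    b_kld = 0.5 * log(lik_var / total) + prior_var / (2 * lik_var),
    a_bs  = prior_var / (2 * total^2),
    b_bs  = 0.5 * log(total / lik_var) - prior_var / (2 * total)
  )
}

#' Closed-form recognition gain of the pure-Gaussian model
#'
#' `KLD_N = D_KL(prior || posterior)` as an explicit quadratic of the
#' prediction error (see [gain_coefficients()]). Strictly increasing in
#' `delta` on `delta >= 0`; used as the `eps -> 0` oracle for the numerical
#' mixture gain [kld_mixture()].
#'
#' @inheritParams evidence_kernel
#' @return Recognition gain in nats, >= 0. Vectorised over `delta`.
#' @examples
#' kld_closed(2, 1, 1) # 1 + (1/2 - log(2)/2)
#' @export
kld_closed <- function(delta, prior_var, lik_var) {
  check_nonnegative(delta, "delta")
  co <- gain_coefficients(prior_var, lik_var)
  co$a_kld * delta^2 + co$b_kld
}

#' Closed-form Bayesian surprise of the pure-Gaussian model
#'
#' `BS_N = D_KL(posterior || prior)` as a quadratic of the prediction error
#' (see [gain_coefficients()]). The reverse KL direction of
#' [kld_closed()]; the two differ whenever the variances differ.
#'
#' @inheritParams evidence_kernel
#' @return Bayesian surprise in nats, >= 0. Vectorised over `delta`.
#' @examples
#' bs_closed(0, 1, 1) # log(2)/2 - 1/4
#' @export
bs_closed <- function(delta, prior_var, lik_var) {
  check_nonnegative(delta, "delta")
  co <- gain_coefficients(prior_var, lik_var)
  co$a_bs * delta^2 + co$b_bs
}
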