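#' Gaussian likelihood with a uniform noise floor
#'
#' Describes the noise-augmented likelihood
#' `p_eps(o | s) = alpha * (p(o | s) + eps)` with `alpha = 1 / (1 + eps)`:
#' a Gaussian kernel of variance `lik_var` plus a constant floor `eps`
#' modelling spontaneous neural firing far from the likelihood mode. The
#' floor is what turns both information gains into inverted-U functions of
#' prediction error.
#'
#' @param lik_var Likelihood variance \eqn{\sigma_l^2 > 0}.
#' @param eps Uniform floor probability \eqn{\epsilon \in (0, 1)};
#'   default `1e-3`.
#'
#' @return An object of class `noisy_likelihood`: list with `lik_var`,
#'   `eps` and the normaliser `alpha = 1 / (1 + eps)` (so
#'   `alpha * (1 + eps) == 1`).
#' @examples
#' noisy_likelihood(1)
#' @export
noisy_likelihood <- function(lik_var, eps = 1e-3) {
  check_positive(lik_var, "lik_var")
  check_eps(eps)
  structure(list(lik_var = lik_var, eps = eps, alpha = 1 / (1 + eps)),
            class = "noisy_likelihood")
}

#' @export
print.noisy_likelihood <- function(x, ...) {
  cat(sprintf("<noisy_likelihood> lik_var = %g, eps = %g, alpha = %.10g\n",
              x$lik_var, x$eps, x$alpha))
  invisible(x)
}

#' Evidence under the noise-augmented likelihood
#'
#' `p_eps(o) = alpha * (e(delta) + eps)` where `e(delta)` is the Gaussian
#' evidence kernel [evidence_kernel()]. Equals 1 at `delta = 0` (the
#' normaliser cancels at the peak) and decreases towards the floor
#' `alpha * eps > 0` as the prediction error grows — the evidence never
#' vanishes, so surprise saturates instead of diverging.
#'
#' @inheritParams evidence_kernel
#' @param eps Uniform floor probability in `(0, 1)`; default `1e-3`.
#' @return Evidence values in `(alpha * eps, 1]`. Vectorised over `delta`.
#' @examples
#' augmented_evidence(0, 10, 1)           # 1
#' augmented_evidence(1e3, 10, 1, 1e-3)   # ~ 1e-3/1.001
#' @export
augmented_evidence <- function(delta, prior_var, lik_var, eps = 1e-3) {
  check_eps(eps)
  (evidence_kernel(delta, prior_var, lik_var) + eps) / (1 + eps)
}

#' Surprise under the noise-augmented likelihood
#'
#' Negative log of [augmented_evidence()]: zero at `delta = 0`, strictly
#' increasing in `delta`, and saturating at `log((1 + eps) / eps)` as the
#' prediction error grows. This bounded surprise is the arousal-potential
#' axis of the Wundt-curve gain functions.
#'
#' @inheritParams augmented_evidence
#' @return Surprise in nats, in `[0, log((1 + eps) / eps))`.
#' @examples
#' mixture_surprise(c(0, 5, 50), 10, 1)
#' @export
mixture_surprise <- function(delta, prior_var, lik_var, eps = 1e-3) {
  -log(augmented_evidence(delta, prior_var, lik_var, eps))
}

#' Posterior mixture weights
#'
#' Under the noise-augmented likelihood the posterior is a two-component
#' mixture of the conjugate Gaussian posterior and the prior, with weights
#' `w_post = e(delta) / (e(delta) + eps)` and
#' `w_pri = eps / (e(delta) + eps)`.
#' At small prediction error the Gaussian posterior dominates; the weights
#' cross at `e(delta) = eps`, i.e.
#' `delta = sqrt(2 * (prior_var + lik_var) * log(1 / eps))`, beyond which
#' the posterior collapses back onto the prior and the information gains
#' decay to zero.
#'
#' @inheritParams augmented_evidence
#' @return A tibble with columns `delta`, `w_post`, `w_pri`
#'   (`w_post + w_pri == 1` exactly).
#' @examples
#' mixture_weights(c(0, 5, 10, 20), 10, 1)
#' @export
mixture_weights <- function(delta, prior_var, lik_var, eps = 1e-3) {
  check_eps(eps)
  e <- evidence_kernel(delta, prior_var, lik_var)
  w_post <- e / (e + eps)
  tibble(delta = delta, w_post = w_post, w_pri = 1 - w_post)
}

#' Two-component mixture posterior
#'
#' Constructs the full posterior under the noise-augmented likelihood for a
#' single prediction error: `w_post * N_post + w_pri * N_pri`, where
#' `N_post` is the conjugate Gaussian posterior and `N_pri` the prior.
#'
#' @inheritParams augmented_evidence
#' @param prior_mean Prior mean; defaults to 0. The observation is placed
#'   at `prior_mean - delta`.
#' @return An object of class `mixture_posterior`: list with `w_post`,
#'   `w_pri`, `post` and `pri` ([gaussian_belief()] components), plus the
#'   generating parameters.
#' @examples
#' mp <- mixture_posterior(5, 10, 1)
#' mixture_pdf(0, mp)
#' @export
mixture_posterior <- function(delta, prior_var, lik_var, eps = 1e-3,
                              prior_mean = 0) {
  check_nonnegative(delta, "delta")
  stopifnot(length(delta) == 1L)
  w <- mixture_weights(delta, prior_var, lik_var, eps)
  obs <- prior_mean - delta
  structure(
    list(
      w_post = w$w_post,
      w_pri  = w$w_pri,
      post   = posterior_params(obs, prior_var, lik_var, prior_mean),
      pri    = gaussian_belief(prior_mean, prior_var),
      delta  = delta, eps = eps
    ),
    class = "mixture_posterior"
  )
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat(sprintf(
    "<mixture_posterior> delta = %g, eps = %g\n  w_post = %.6g * N(%.6g, %.6g)\n  w_pri  = %.6g * N(%.6g, %.6g)\n",
    x$delta, x$eps, x$w_post, x$post$mean, x$post$var,
    x$w_pri, x$pri$mean, x$pri$var))
  invisible(x)
}

#' Mixture posterior density
#'
#' Evaluates `w_post * N_post(s) + w_pri * N_pri(s)`; integrates to 1 over
#' the real line.
#'
#' @param s State values (vectorised).
#' @param mp A [mixture_posterior()].
#' @param log Return the log density?
#' @return Density (or log density) values.
#' @export
mixture_pdf <- function(s, mp, log = FALSE) {
  stopifnot(inherits(mp, "mixture_posterior"))
  lp <- log_sum_exp2(
    base::log(mp$w_post) + dnorm(s, mp$post$mean, sqrt(mp$post$var), log = TRUE),
    base::log(mp$w_pri)  + dnorm(s, mp$pri$mean,  sqrt(mp$pri$var),  log = TRUE)
  )
  if (log) lp else exp(lp)
}

#' Numerical KL divergence between two densities
#'
#' Computes `D_KL(p || q) = integral of p * log(p / q)` by adaptive
#' quadrature on a finite domain covering effectively all of `p`'s mass.
#' Used for the mixture-posterior divergences, which have no closed form.
#' Tiny negative results from round-off (within `-1e-9`) are clamped to 0.
#'
#' @param log_p,log_q Vectorised functions returning log densities.
#' @param lower,upper Integration domain; must cover the support of `p` to
#'   negligible tail mass.
#' @param rel_tol,abs_tol Quadrature tolerances.
#' @return The divergence in nats, >= 0.
#' @examples
#' kl_numeric(function(s) dnorm(s, log = TRUE),
#'            function(s) dnorm(s, 1, 1, log = TRUE), -12, 13) # 0.5
#' @export
kl_numeric <- function(log_p, log_q, lower, upper,
                       rel_tol = 1e-9, abs_tol = 1e-12) {
  integrand <- function(s) {
    lp <- log_p(s)
    out <- numeric(length(s))
    live <- lp > -700         # exp underflows below ~ -745; integrand ~ 0 there
    if (any(live)) {
      out[live] <- exp(lp[live]) * (lp[live] - log_q(s[live]))
    }
    out
  }
  res <- tryCatch(
    integrate(integrand, lower, upper,
              rel.tol = rel_tol, abs.tol = abs_tol, subdivisions = 500L),
    error = function(e) {
      abort(paste0("KL quadrature failed on [", signif(lower, 6), ", ",
                   signif(upper, 6), "]: ", conditionMessage(e)),
            class = "epigain_numerical_error")
    }
  )
  val <- res$value
  if (val < 0) {
    if (val < -1e-9) {
      abort(sprintf("KL quadrature returned %.3e (< -1e-9); integrand or domain is wrong.", val),
            class = "epigain_numerical_error")
    }
    val <- 0
  }
  val
}

# integration window covering prior and Gaussian-posterior components
mixture_domain <- function(mp) {
  sds <- sqrt(c(mp$post$var, mp$pri$var))
  w <- 12 * max(sds)
  c(min(mp$post$mean, mp$pri$mean) - w,
    max(mp$post$mean, mp$pri$mean) + w)
}

#' Recognition gain under the noise-augmented likelihood
#'
#' `KLD(delta) = D_KL(prior || mixture posterior)`, evaluated by numerical
#' quadrature ([kl_numeric()]). Unlike the pure-Gaussian [kld_closed()],
#' this gain rises with prediction error only while the Gaussian posterior
#' dominates the mixture, peaks near the weight switch-over, and decays to
#' zero as the posterior collapses onto the prior — the Wundt-curve shape.
#'
#' @inheritParams augmented_evidence
#' @return Gain in nats, >= 0. Vectorised over `delta`.
#' @examples
#' kld_mixture(c(0, 5, 10, 30), 10, 1)
#' @export
kld_mixture <- function(delta, prior_var, lik_var, eps = 1e-3) {
  check_nonnegative(delta, "delta")
  vapply(delta, function(d) {
    mp <- mixture_posterior(d, prior_var, lik_var, eps)
    dom <- mixture_domain(mp)
    tryCatch(
      kl_numeric(
        function(s) dnorm(s, mp$pri$mean, sqrt(mp$pri$var), log = TRUE),
        function(s) mixture_pdf(s, mp, log = TRUE),
        dom[1], dom[2]
      ),
      epigain_numerical_error = function(e) {
        abort(paste0("KLD at delta = ", signif(d, 8), ": ",
                     conditionMessage(e)),
              class = "epigain_numerical_error")
      }
    )
  }, numeric(1))
}

#' Bayesian surprise under the noise-augmented likelihood
#'
#' `BS(delta) = D_KL(mixture posterior || prior)`: the reverse direction of
#' [kld_mixture()], with the same inverted-U dependence on prediction
#' error but a peak at a larger prediction error (and surprise).
#'
#' @inheritParams augmented_evidence
#' @return Gain in nats, >= 0. Vectorised over `delta`.
#' @examples
#' bs_mixture(c(0, 5, 10, 30), 10, 1)
#' @export
bs_mixture <- function(delta, prior_var, lik_var, eps = 1e-3) {
  check_nonnegative(delta, "delta")
  vapply(delta, function(d) {
    mp <- mixture_posterior(d, prior_var, lik_var, eps)
    dom <- mixture_domain(mp)
    tryCatch(
      kl_numeric(
        function(s) mixture_pdf(s, mp, log = TRUE),
        function(s) dnorm(s, mp$pri$mean, sqrt(mp$pri$var), log = TRUE),
        dom[1], dom[2]
      ),
      epigain_numerical_error = function(e) {
        abort(paste0("BS at delta = ", signif(d, 8), ": ",
                     conditionMessage(e)),
              class = "epigain_numerical_error")
      }
    )
  }, numeric(1))
}
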