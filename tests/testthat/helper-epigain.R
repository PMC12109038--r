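# shared fixtures and test-side oracles

# reference parameterisation used throughout (wide prior, precise likelihood)
fig_params <- list(prior_var = 10, lik_var = 1, eps = 1e-3)

# count interior maxima of a sampled curve, merging peaks whose separating
# dip is within `tol` (quadrature noise would otherwise split the single
# analytic peak, or the flat near-zero tail would sprout spurious ones)
count_peaks <- function(x, tol = 1e-8) {
  n <- length(x)
  cand <- which(vapply(2:(n - 1), function(i) {
    x[i] >= x[i - 1] && x[i] >= x[i + 1] &&
      (x[i] > x[i - 1] || x[i] > x[i + 1])
  }, logical(1))) + 1L
  if (length(cand) <= 1L) return(length(cand))
  repeat {
    merged <- FALSE
    for (k in seq_len(length(cand) - 1L)) {
      dip <- min(x[cand[k]:cand[k + 1L]])
      if (min(x[cand[k]], x[cand[k + 1L]]) - dip <= tol) {
        drop <- if (x[cand[k]] < x[cand[k + 1L]]) k else k + 1L
        cand <- cand[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  length(cand)
}

# independent quadrature oracle for D_KL(N1 || N2), bypassing kl_numeric
kl_gauss_quad <- function(m1, v1, m2, v2) {
  f <- function(s) {
    dnorm(s, m1, sqrt(v1)) *
      (dnorm(s, m1, sqrt(v1), log = TRUE) - dnorm(s, m2, sqrt(v2), log = TRUE))
  }
  w <- 10 * sqrt(max(v1, v2))
  stats::integrate(f, min(m1, m2) - w, max(m1, m2) + w,
                   rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# normalised negative log evidence of the pure-Gaussian model
norm_neg_log_evidence <- function(delta, prior_var, lik_var) {
  total <- prior_var + lik_var
  0.5 * log(2 * pi * total) + delta^2 / (2 * total)
}
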