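test_that("conjugate posterior parameters match the closed form", {
  # wide prior, precise observation pulls the mean almost to the data
  post <- posterior_params(11, prior_var = 10, lik_var = 1)
  expect_equal(post$mean, 10)
  expect_equal(post$var, 10 / 11)

  # equal variances: midpoint mean, halved variance
  post <- posterior_params(4, prior_var = 3, lik_var = 3, prior_mean = 2)
  expect_equal(post$mean, 3)
  expect_equal(post$var, 1.5)

  # zero prediction error leaves the mean fixed
  post <- posterior_params(2, prior_var = 5, lik_var = 7, prior_mean = 2)
  expect_equal(post$mean, 2)

  # posterior variance always sharper than both sources
  for (pv in c(0.5, 3, 40)) {
    for (lv in c(0.5, 3, 40)) {
      expect_lt(posterior_params(1, pv, lv)$var, min(pv, lv))
    }
  }

  expect_error(posterior_params(1, -1, 1), class = "epigain_parameter_error")
  expect_error(posterior_params(1, 1, 0), class = "epigain_parameter_error")
})

test_that("posterior agrees with normalising the prior-times-likelihood", {
  # numeric normalisation oracle for p(s | o)
  pv <- 10; lv <- 1; o <- 11
  post <- posterior_params(o, pv, lv)
  joint <- function(s) dnorm(s, 0, sqrt(pv)) * dnorm(o, s, sqrt(lv))
  z <- integrate(joint, -50, 50, rel.tol = 1e-12)$value
  m <- integrate(function(s) s * joint(s) / z, -50, 50, rel.tol = 1e-12)$value
  v <- integrate(function(s) (s - m)^2 * joint(s) / z, -50, 50,
                 rel.tol = 1e-12)$value
  expect_equal(post$mean, m, tolerance = 1e-8)
  expect_equal(post$var, v, tolerance = 1e-8)
})

test_that("evidence kernel peaks at one and decays with prediction error", {
  expect_identical(evidence_kernel(0, 10, 1), 1)
  expect_equal(evidence_kernel(sqrt(22), 10, 1), exp(-1))
  ds <- seq(0, 40, length.out = 100)
  expect_true(all(diff(evidence_kernel(ds, 10, 1)) < 0))
  expect_equal(evidence_kernel(1e4, 10, 1), 0)
})

test_that("Gaussian surprise is the quadratic negative log evidence", {
  expect_identical(gaussian_surprise(0, 10, 1), 0)
  expect_equal(gaussian_surprise(sqrt(22), 10, 1), 1)
  # quadratic scaling: doubling delta quadruples the surprise
  expect_equal(gaussian_surprise(6, 3, 2), 4 * gaussian_surprise(3, 3, 2))
  expect_equal(gaussian_surprise(2.5, 10, 1),
               -log(evidence_kernel(2.5, 10, 1)))
})

test_that("Gaussian-Gaussian KL divergence is exact and asymmetric", {
  p <- gaussian_belief(0, 1)
  expect_equal(kl_gaussians(p, p), 0)
  expect_equal(kl_gaussians(p, gaussian_belief(1, 1)), 0.5)
  q <- gaussian_belief(2, 5)
  expect_false(isTRUE(all.equal(kl_gaussians(p, q), kl_gaussians(q, p))))
  # quadrature oracle on a few asymmetric cases
  for (case in list(c(0, 1, 2, 5), c(-1, 4, 1, 0.5), c(3, 10, 3, 2))) {
    expect_equal(
      kl_gaussians(gaussian_belief(case[1], case[2]),
                   gaussian_belief(case[3], case[4])),
      kl_gauss_quad(case[1], case[2], case[3], case[4]),
      tolerance = 1e-8
    )
  }
})

test_that("surprise decomposes into Bayesian surprise plus uncertainty", {
  # -ln p(o) = BS + U with normalised densities, across random draws
  set.seed(11)
  for (i in 1:50) {
    pv <- exp(runif(1, log(0.1), log(50)))
    lv <- exp(runif(1, log(0.1), log(50)))
    d <- runif(1, 0, 3 * sqrt(pv + lv))
    lhs <- norm_neg_log_evidence(d, pv, lv)
    rhs <- bs_closed(d, pv, lv) + perceived_uncertainty(d, pv, lv)
    expect_lt(abs(lhs - rhs), 1e-10)
  }
})

test_that("perceived uncertainty is finite and tracks likelihood entropy", {
  expect_true(all(is.finite(perceived_uncertainty(c(0, 1, 100), 10, 1))))
  # for wide likelihoods U is dominated by the likelihood entropy term
  lvs <- c(1e2, 1e4, 1e6)
  gap <- perceived_uncertainty(1, 10, lvs) - 0.5 * log(2 * pi * lvs)
  expect_true(all(gap > 0 & gap < 1))
})
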