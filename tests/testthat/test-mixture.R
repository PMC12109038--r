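test_that("augmented evidence is floored, normalised at the peak", {
  expect_equal(augmented_evidence(0, 10, 1, 1e-3), 1)
  # saturation at alpha * eps for huge prediction errors
  expect_equal(augmented_evidence(1e3, 10, 1, 1e-3), 1e-3 / 1.001)
  # floor never below the pure-Gaussian evidence (up to alpha)
  ds <- seq(0, 30, length.out = 50)
  expect_true(all(augmented_evidence(ds, 10, 1) >=
                    evidence_kernel(ds, 10, 1) / (1 + 1e-3)))
  nl <- noisy_likelihood(1, 1e-3)
  expect_equal(nl$alpha * (1 + nl$eps), 1)
})

test_that("mixture surprise rises monotonically and saturates", {
  expect_equal(mixture_surprise(0, 10, 1), 0)
  ds <- seq(0, 50, length.out = 300)
  s <- mixture_surprise(ds, 10, 1)
  expect_true(all(diff(s) >= 0))
  sat <- log((1 + 1e-3) / 1e-3)
  expect_true(all(s <= sat))
  expect_lt(mixture_surprise(15, 10, 1), sat)
  expect_equal(mixture_surprise(1e4, 10, 1), sat, tolerance = 1e-12)
})

test_that("mixture weights sum to one and switch over at e(delta) = eps", {
  w0 <- mixture_weights(0, 10, 1, 1e-3)
  expect_equal(w0$w_post, 1 / 1.001)

  # exact algebraic complement
  ds <- seq(0, 40, length.out = 60)
  w <- mixture_weights(ds, 10, 1)
  expect_identical(w$w_post + w$w_pri, rep(1, length(ds)))
  expect_true(all(diff(w$w_post) <= 0))
  expect_true(all(diff(w$w_pri) >= 0))
  # strictly monotone where the weights are not saturated
  expect_gt(w$w_pri[20], w$w_pri[1])

  # equal weights exactly where the kernel evidence meets the floor
  for (eps in c(1e-2, 1e-3, 1e-5)) {
    d_star <- sqrt(2 * 11 * log(1 / eps))
    w <- mixture_weights(d_star, 10, 1, eps)
    expect_equal(w$w_post, 0.5, tolerance = 1e-12)
    expect_equal(w$w_pri, 0.5, tolerance = 1e-12)
  }

  # far tail: prior takes over completely
  expect_equal(mixture_weights(1e4, 10, 1)$w_pri, 1)
})

test_that("mixture posterior density is a proper two-component mixture", {
  mp <- mixture_posterior(5, 10, 1)
  s <- seq(-15, 15, length.out = 7)
  manual <- mp$w_post * dnorm(s, mp$post$mean, sqrt(mp$post$var)) +
    mp$w_pri * dnorm(s, mp$pri$mean, sqrt(mp$pri$var))
  expect_equal(mixture_pdf(s, mp), manual, tolerance = 1e-12)

  # degenerate weights recover the pure components
  mp_post <- mixture_posterior(0, 10, 1, eps = 1e-12)
  expect_equal(mixture_pdf(1.3, mp_post),
               dnorm(1.3, mp_post$post$mean, sqrt(mp_post$post$var)),
               tolerance = 1e-9)
  mp_pri <- mixture_posterior(200, 10, 1, eps = 1e-3)
  expect_equal(mixture_pdf(1.3, mp_pri), dnorm(1.3, 0, sqrt(10)),
               tolerance = 1e-9)

  # normalisation oracle across parameter draws
  set.seed(31)
  for (i in 1:10) {
    pv <- exp(runif(1, -1, 4)); lv <- exp(runif(1, -1, 4))
    d <- runif(1, 0, 2.5 * sqrt(2 * (pv + lv) * log(1e3)))
    mp <- mixture_posterior(d, pv, lv)
    mass <- integrate(function(s) mixture_pdf(s, mp),
                      -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(mass - 1), 1e-8)
  }
})

test_that("numerical KL reproduces closed forms and degenerate zeros", {
  lp <- function(s) dnorm(s, log = TRUE)
  expect_equal(kl_numeric(lp, lp, -12, 12), 0, tolerance = 1e-9)
  expect_equal(
    kl_numeric(lp, function(s) dnorm(s, 1, 1, log = TRUE), -12, 13),
    0.5, tolerance = 1e-9
  )
  # mixture that degenerates to the prior diverges from it by nothing
  mp <- mixture_posterior(500, 10, 1)
  expect_equal(
    kl_numeric(function(s) dnorm(s, 0, sqrt(10), log = TRUE),
               function(s) mixture_pdf(s, mp, log = TRUE), -40, 40),
    0, tolerance = 1e-9
  )
})

test_that("mixture gains collapse to the closed forms as the floor vanishes", {
  # floor-negligible regime: posterior keeps mass over the prior support
  for (pv in c(0.5, 1, 2)) {
    for (lv in c(5, 25, 50)) {
      ds <- seq(0, 3 * sqrt(pv + lv), length.out = 5)
      expect_equal(kld_mixture(ds, pv, lv, eps = 1e-12),
                   kld_closed(ds, pv, lv), tolerance = 1e-6)
      expect_equal(bs_mixture(ds, pv, lv, eps = 1e-12),
                   bs_closed(ds, pv, lv), tolerance = 1e-6)
    }
  }
})

test_that("information gains vanish deep in the noise-dominated tail", {
  expect_lt(kld_mixture(50, 10, 1), 1e-6)
  expect_lt(bs_mixture(50, 10, 1), 1e-6)
  # small-delta regime: gains still grow with prediction error
  expect_gt(kld_mixture(1, 10, 1), kld_mixture(0, 10, 1))
  expect_gt(bs_mixture(1, 10, 1), bs_mixture(0, 10, 1))
  # the two divergences differ at a generic prediction error
  expect_false(isTRUE(all.equal(kld_mixture(5, 10, 1), bs_mixture(5, 10, 1))))
})

test_that("each mixture gain has a single interior peak", {
  set.seed(41)
  for (i in 1:2) {
    pv <- exp(runif(1, 0, 3.5)); lv <- exp(runif(1, 0, 3.5))
    ds <- seq(0, delta_upper(pv, lv), length.out = 300)
    kld <- kld_mixture(ds, pv, lv)
    bs <- bs_mixture(ds, pv, lv)
    expect_equal(count_peaks(kld), 1L)
    expect_equal(count_peaks(bs), 1L)
    expect_equal(count_peaks(kld + bs), 1L)
  }
})
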