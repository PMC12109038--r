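#' Locate the optimal prediction errors and surprises
#'
#' Maximises each of KLD, BS and IG = KLD + BS over the prediction error by
#' bounded scalar optimisation (golden-section search with parabolic
#' interpolation, via [stats::optimize()]), bracketed by a coarse pre-scan
#' that guards against the optimiser's unimodality assumption. Reports the
#' optimal prediction errors `delta_kld <= delta_ig <= delta_bs`, the
#' corresponding optimal surprises `s_kld`, `s_ig`, `s_bs` (via
#' [mixture_surprise()]), the gain maxima, and the fluctuation magnitudes
#' `d_delta = delta_bs - delta_kld` and `d_s = s_bs - s_kld` (always
#' positive: maximising novelty needs more surprise than maximising
#' evidence).
#'
#' If a maximum lies at an optimisation bound the result is flagged
#' `non_interior` and a warning is raised.
#'
#' @inheritParams augmented_evidence
#' @param bounds Optional `c(lower, upper)` search interval for the
#'   prediction error; defaults to `c(0, delta_upper(...))`, which always
#'   brackets the peaks.
#' @param n_scan Number of pre-scan points used to bracket each peak.
#' @param tol Optimiser tolerance on the prediction error.
#' @return An object of class `gain_optima`; see [tidy()] (one row per
#'   gain) and [glance()] (one-row summary with all ten optimum fields plus
#'   `d_delta` and `d_s`).
#' @examples
#' \donttest{
#' opt <- find_optima(prior_var = 10, lik_var = 1)
#' glance(opt)
#' }
#' @export
find_optima <- function(prior_var, lik_var, eps = 1e-3, bounds = NULL,
                        n_scan = 101L, tol = 1e-6) {
  check_positive(prior_var, "prior_var")
  check_positive(lik_var, "lik_var")
  check_eps(eps)
  if (is.null(bounds)) {
    bounds <- c(0, delta_upper(prior_var, lik_var, eps))
  }
  stopifnot(length(bounds) == 2L, bounds[1] >= 0, bounds[2] > bounds[1])

  grid <- seq(bounds[1], bounds[2], length.out = n_scan)
  kld <- kld_mixture(grid, prior_var, lik_var, eps)
  bs <- bs_mixture(grid, prior_var, lik_var, eps)
  scans <- list(kld = kld, bs = bs, ig = kld + bs)
  objectives <- list(
    kld = function(d) kld_mixture(d, prior_var, lik_var, eps),
    bs  = function(d) bs_mixture(d, prior_var, lik_var, eps),
    ig  = function(d) kld_mixture(d, prior_var, lik_var, eps) +
                      bs_mixture(d, prior_var, lik_var, eps)
  )

  rows <- purrr::map(names(scans), function(g) {
    vals <- scans[[g]]
    # flat-maximum tie-break: smallest delta within 1e-9 of the scan best
    i <- min(which(vals >= max(vals) - 1e-9))
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, n_scan)]
    opt <- optimize(objectives[[g]], c(lo, hi), maximum = TRUE, tol = tol)
    d_opt <- opt$maximum
    v_opt <- opt$objective
    # keep the scan point if refinement somehow lost ground
    if (vals[i] > v_opt) {
      d_opt <- grid[i]
      v_opt <- vals[i]
    }
    non_interior <- i == 1L || i == n_scan ||
      d_opt <= bounds[1] + tol || d_opt >= bounds[2] - tol
    if (non_interior) {
      warn(sprintf("non-interior optimum for %s at delta = %g", g, d_opt),
           class = "epigain_non_interior_optimum")
    }
    tibble(gain = g, delta_opt = d_opt,
           surprise_opt = mixture_surprise(d_opt, prior_var, lik_var, eps),
           gain_max = v_opt, non_interior = non_interior)
  })

  structure(
    list(summary = dplyr::bind_rows(rows),
         prior_var = prior_var, lik_var = lik_var, eps = eps,
         bounds = bounds, tol = tol),
    class = "gain_optima"
  )
}

#' @export
print.gain_optima <- function(x, ...) {
  cat(sprintf("<gain_optima> prior_var = %g, lik_var = %g, eps = %g\n",
              x$prior_var, x$lik_var, x$eps))
  print(x$summary)
  g <- glance(x)
  cat(sprintf("d_delta = %.6g, d_s = %.6g\n", g$d_delta, g$d_s))
  invisible(x)
}

#' Tidy the per-gain optima
#'
#' @param x A `gain_optima` object from [find_optima()].
#' @param ... Unused.
#' @return A tibble with one row per gain (`kld`, `bs`, `ig`) and columns
#'   `gain`, `delta_opt`, `surprise_opt`, `gain_max`, `non_interior`.
#' @export
tidy.gain_optima <- function(x, ...) {
  x$summary
}

#' One-row summary of the gain optima
#'
#' @param x A `gain_optima` object from [find_optima()].
#' @param ... Unused.
#' @return A one-row tibble: `delta_kld`, `delta_bs`, `delta_ig`, `s_kld`,
#'   `s_bs`, `s_ig`, `max_kld`, `max_bs`, `max_ig`, `d_delta`, `d_s`,
#'   `non_interior`.
#' @export
glance.gain_optima <- function(x, ...) {
  s <- x$summary
  v <- function(g, col) s[[col]][s$gain == g]
  tibble(
    delta_kld = v("kld", "delta_opt"),
    delta_bs  = v("bs", "delta_opt"),
    delta_ig  = v("ig", "delta_opt"),
    s_kld = v("kld", "surprise_opt"),
    s_bs  = v("bs", "surprise_opt"),
    s_ig  = v("ig", "surprise_opt"),
    max_kld = v("kld", "gain_max"),
    max_bs  = v("bs", "gain_max"),
    max_ig  = v("ig", "gain_max"),
    d_delta = v("bs", "delta_opt") - v("kld", "delta_opt"),
    d_s = v("bs", "surprise_opt") - v("kld", "surprise_opt"),
    non_interior = any(s$non_interior)
  )
}
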