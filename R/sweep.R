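#' Build a variance sweep grid
#'
#' All combinations of likelihood variance (observation uncertainty) and
#' prior variance (prediction uncertainty), one row per cell. The default
#' ranges are `[1, 50]` for both axes; the default step of 1 gives a
#' 50 x 50 desk-scale grid, while `step = 0.1` reproduces the full-density
#' sweep (about 240k cells — expect a long run).
#'
#' @param lik_vars,prior_vars Explicit axis values; override the ranges.
#' @param lik_range,prior_range Length-2 ranges used with `step`.
#' @param step Grid spacing used with the ranges.
#' @return A tibble with columns `lik_var` and `prior_var`.
#' @examples
#' sweep_cells(lik_vars = c(1, 10, 50), prior_vars = c(1, 10, 50))
#' @export
sweep_cells <- function(lik_vars = NULL, prior_vars = NULL,
                        lik_range = c(1, 50), prior_range = c(1, 50),
                        step = 1) {
  check_positive(step, "step")
  if (is.null(lik_vars)) lik_vars <- seq(lik_range[1], lik_range[2], by = step)
  if (is.null(prior_vars)) {
    prior_vars <- seq(prior_range[1], prior_range[2], by = step)
  }
  check_positive(lik_vars, "lik_vars")
  check_positive(prior_vars, "prior_vars")
  tidyr::crossing(lik_var = lik_vars, prior_var = prior_vars)
}

#' Sweep the gain optima over a variance grid
#'
#' Runs [find_optima()] for every `(lik_var, prior_var)` cell of a grid,
#' collecting the optimal prediction errors, optimal surprises, gain
#' maxima and the fluctuation magnitudes `d_delta` and `d_s`. The sweep is
#' deterministic: identical inputs give identical output, which also makes
#' the optional checkpoint resume exact.
#'
#' @param cells A tibble with columns `lik_var` and `prior_var`
#'   (see [sweep_cells()]). Data-frame-first so grids pipe in directly.
#' @param eps Uniform floor probability; default `1e-3`.
#' @param checkpoint Optional path to a CSV checkpoint. Completed cells are
#'   appended periodically; on restart, cells already present are reused.
#' @param progress Emit a progress message every `progress` cells
#'   (`FALSE` to stay quiet). Defaults to reporting on grids above
#'   10^4 cells, which also raise a size warning.
#' @param ... Passed to [find_optima()] (e.g. `n_scan`, `tol`).
#' @return A tibble of class `gain_sweep`: one row per cell with columns
#'   `lik_var`, `prior_var`, `delta_kld`, `delta_bs`, `delta_ig`, `s_kld`,
#'   `s_bs`, `s_ig`, `max_kld`, `max_bs`, `max_ig`, `d_delta`, `d_s`,
#'   `non_interior`. Non-interior-optimum warnings are collected and
#'   reported once at the end.
#' @examples
#' \donttest{
#' sweep_cells(lik_vars = c(1, 10), prior_vars = c(1, 10)) |>
#'   run_sweep()
#' }
#' @export
run_sweep <- function(cells = sweep_cells(), eps = 1e-3, checkpoint = NULL,
                      progress = NULL, ...) {
  stopifnot(is.data.frame(cells),
            all(c("lik_var", "prior_var") %in% names(cells)))
  check_eps(eps)
  n_cells <- nrow(cells)
  if (n_cells > 1e4) {
    warn(sprintf("sweep grid has %d cells; this will take a while.", n_cells))
    if (is.null(progress)) progress <- 1000L
  }
  if (is.null(progress)) progress <- FALSE

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tibble::as_tibble(utils::read.csv(checkpoint))
  }

  key <- function(l, p) paste(format(l, digits = 15), format(p, digits = 15))
  done_keys <- if (is.null(done)) character() else key(done$lik_var, done$prior_var)

  n_warn <- 0L
  rows <- vector("list", n_cells)
  fresh <- 0L
  for (i in seq_len(n_cells)) {
    l <- cells$lik_var[i]
    p <- cells$prior_var[i]
    k <- key(l, p)
    hit <- match(k, done_keys)
    if (!is.na(hit)) {
      rows[[i]] <- done[hit, ]
    } else {
      g <- withCallingHandlers(
        glance(find_optima(prior_var = p, lik_var = l, eps = eps, ...)),
        epigain_non_interior_optimum = function(w) {
          n_warn <<- n_warn + 1L
          invokeRestart("muffleWarning")
        }
      )
      rows[[i]] <- dplyr::bind_cols(tibble(lik_var = l, prior_var = p), g)
      fresh <- fresh + 1L
      if (!is.null(checkpoint) && fresh %% 25L == 0L) {
        write_gain_csv(dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))]),
                       checkpoint)
      }
    }
    if (!isFALSE(progress) && i %% progress == 0L) {
      message(sprintf("sweep: %d / %d cells", i, n_cells))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(checkpoint)) write_gain_csv(out, checkpoint)
  if (n_warn > 0L) {
    warn(sprintf("%d of %d cells reported a non-interior optimum.",
                 n_warn, n_cells))
  }
  structure(out, class = c("gain_sweep", class(out)), eps = eps)
}

#' One-row summary of a variance sweep
#'
#' @param x A `gain_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A one-row tibble: cell count, whether the ordering
#'   `delta_kld <= delta_ig <= delta_bs` and `d_s > 0` hold in every cell,
#'   the minimum `d_s`, the largest `max_ig`, and the number of
#'   non-interior cells.
#' @export
glance.gain_sweep <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    ordering_ok = all(x$delta_kld <= x$delta_ig & x$delta_ig <= x$delta_bs),
    all_d_s_positive = all(x$d_s > 0),
    min_d_s = min(x$d_s),
    max_max_ig = max(x$max_ig),
    n_non_interior = sum(x$non_interior)
  )
}

# is x monotone in the given direction, ignoring inversions below tol?
monotone_ok <- function(x, direction, tol = 1e-6) {
  d <- diff(x)
  if (direction == "increasing") all(d > -tol) else all(d < tol)
}

trend_series_check <- function(grid, value, axis, direction, tol) {
  other <- setdiff(c("lik_var", "prior_var"), axis)
  series <- split(grid, grid[[other]])
  ok <- vapply(series, function(s) {
    s <- s[order(s[[axis]]), ]
    if (nrow(s) < 3L) return(NA)
    monotone_ok(s[[value]], direction, tol)
  }, logical(1))
  c(n_series = length(ok), n_consistent = sum(ok, na.rm = TRUE),
    applicable = sum(!is.na(ok)))
}

#' Check the qualitative uncertainty trends on a sweep
#'
#' Audits a sweep grid against the model's qualitative predictions about
#' how the optima respond to observation uncertainty (`lik_var`) and
#' prediction uncertainty (`prior_var`):
#'
#' * maximum gains decrease as `lik_var` increases;
#' * all optimal prediction errors increase in both variances;
#' * `s_kld` decreases while `s_bs` increases in `prior_var`;
#' * all optimal surprises increase in `lik_var`;
#' * the fluctuation `d_s` decreases in `lik_var` and increases in
#'   `prior_var`;
#' * corner ordering: `max_ig` at (smallest `lik_var`, largest `prior_var`)
#'   exceeds `max_ig` at (largest `lik_var`, smallest `prior_var`).
#'
#' Each monotonicity check runs per row/column of the grid; inversions
#' smaller than `tol` (quadrature noise scale) are ignored. Trends along an
#' axis with fewer than 3 values are reported as not applicable rather
#' than failed.
#'
#' @param grid A `gain_sweep` from [run_sweep()].
#' @param tol Absolute tolerance below which an inversion is treated as
#'   numerical noise.
#' @return A tibble of class `trend_report`: one row per check with
#'   columns `trend`, `quantity`, `axis`, `direction`, `n_series`,
#'   `n_consistent`, `pass` (`NA` when not applicable).
#' @export
trend_report <- function(grid, tol = 1e-6) {
  stopifnot(inherits(grid, "gain_sweep") || is.data.frame(grid))
  checks <- tibble::tribble(
    ~trend,            ~quantity,    ~axis,       ~direction,
    "max_gain_vs_lik",  "max_kld",   "lik_var",   "decreasing",
    "max_gain_vs_lik",  "max_bs",    "lik_var",   "decreasing",
    "max_gain_vs_lik",  "max_ig",    "lik_var",   "decreasing",
    "opt_delta_vs_lik", "delta_kld", "lik_var",   "increasing",
    "opt_delta_vs_lik", "delta_bs",  "lik_var",   "increasing",
    "opt_delta_vs_lik", "delta_ig",  "lik_var",   "increasing",
    "opt_delta_vs_prior", "delta_kld", "prior_var", "increasing",
    "opt_delta_vs_prior", "delta_bs",  "prior_var", "increasing",
    "opt_delta_vs_prior", "delta_ig",  "prior_var", "increasing",
    "surprise_vs_prior", "s_kld",    "prior_var", "decreasing",
    "surprise_vs_prior", "s_bs",     "prior_var", "increasing",
    "surprise_vs_lik",  "s_kld",     "lik_var",   "increasing",
    "surprise_vs_lik",  "s_bs",      "lik_var",   "increasing",
    "surprise_vs_lik",  "s_ig",      "lik_var",   "increasing",
    "d_s_vs_lik",       "d_s",       "lik_var",   "decreasing",
    "d_s_vs_prior",     "d_s",       "prior_var", "increasing"
  )
  res <- purrr::pmap(checks, function(trend, quantity, axis, direction) {
    st <- trend_series_check(grid, quantity, axis, direction, tol)
    tibble(trend = trend, quantity = quantity, axis = axis,
           direction = direction,
           n_series = unname(st["n_series"]),
           n_consistent = unname(st["n_consistent"]),
           pass = if (st["applicable"] == 0) NA else
             st["n_consistent"] == st["applicable"])
  })
  out <- dplyr::bind_rows(res)

  # corner ordering on max_ig
  corner <- NA
  if (length(unique(grid$lik_var)) >= 2 &&
      length(unique(grid$prior_var)) >= 2) {
    lo_l <- min(grid$lik_var); hi_l <- max(grid$lik_var)
    lo_p <- min(grid$prior_var); hi_p <- max(grid$prior_var)
    a <- grid$max_ig[grid$lik_var == lo_l & grid$prior_var == hi_p]
    b <- grid$max_ig[grid$lik_var == hi_l & grid$prior_var == lo_p]
    if (length(a) == 1L && length(b) == 1L) corner <- a > b
  }
  out <- dplyr::bind_rows(out, tibble(
    trend = "corner_max_ig", quantity = "max_ig", axis = "both",
    direction = "small lik_var & large prior_var > large lik_var & small prior_var",
    n_series = 1, n_consistent = as.numeric(isTRUE(corner)), pass = corner
  ))
  structure(out, class = c("trend_report", class(out)))
}

#' @export
print.trend_report <- function(x, ...) {
  NextMethod()
  ap <- x$pass[!is.na(x$pass)]
  cat(sprintf("%d of %d applicable trend checks pass.\n", sum(ap), length(ap)))
  invisible(x)
}
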