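# internal helpers: argument checks and numerics

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be a finite positive number."),
          class = "epigain_parameter_error")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(paste0("`", name, "` must be finite and >= 0."),
          class = "epigain_parameter_error")
  }
  invisible(x)
}

check_eps <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) ||
      eps <= 0 || eps >= 1) {
    abort("`eps` must be a single number in (0, 1).",
          class = "epigain_parameter_error")
  }
  invisible(eps)
}

# elementwise log(exp(a) + exp(b)) without overflow
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # if both are -Inf, m - m is NaN; the sum is -Inf
  out[is.infinite(m) & m < 0] <- -Inf
  out
}
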