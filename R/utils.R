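# Internal helpers shared across modules.

# Half-up rounding for percent metrics (base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Ordinary least-squares slope (and intercept/residuals) of y on x.
ols_fit <- function(x, y) {
  xm <- mean(x)
  ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  list(slope = slope, intercept = intercept,
       residuals = y - (intercept + slope * x))
}

# Run code with a temporary RNG state seeded at `seed`.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), code)
}

stop_invalid <- function(msg) {
  rlang::abort(msg, class = "mfecg_invalid_argument")
}

stop_format <- function(msg) {
  rlang::abort(msg, class = "mfecg_format_error")
}
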