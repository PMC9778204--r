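# Seeded generators for validation signals.
#
# Each generator is a pure function of its parameters and seed: the same
# call returns a bit-identical signal.  The fixtures cover the reference
# cases whose complexity or multifractality is known in closed form
# (white noise, 1/f noise, binomial cascades, fractional Brownian
# motion) plus a two-class ECG-like cohort whose large-scale entropy
# ordering (normal-sinus-rhythm-like above heart-failure-like) is the
# controlled property.

new_signal <- function(values, fs, kind, params, seed) {
  structure(
    list(values = as.numeric(values), fs = fs, kind = kind,
         params = params, seed = seed),
    class = "mf_signal"
  )
}

#' @export
print.mf_signal <- function(x, ...) {
  cat("<mf_signal>", x$kind, "| n =", length(x$values),
      "| fs =", x$fs, "Hz\n")
  invisible(x)
}

#' Extract the sample vector from a signal-like object
#'
#' Accepts plain numeric vectors, synthetic signals, ECG records and
#' segments, returning the underlying numeric samples.
#'
#' @param x A numeric vector or an object with a `$values` or `$samples`
#'   field.
#' @return Numeric vector of samples.
#' @export
signal_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x)) {
    if (!is.null(x$values)) return(as.numeric(x$values))
    if (!is.null(x$samples)) return(as.numeric(x$samples))
  }
  stop_invalid("cannot extract sample values from this object")
}

#' Uniform white noise
#'
#' Zero-centered i.i.d. samples drawn uniformly on \[-0.5, 0.5\]. The flat
#' spectrum makes this the maximal-irregularity reference for multiscale
#' entropy: coarse-graining averages independent samples, so entropy
#' falls monotonically with scale.
#'
#' @param n Number of samples (`n >= 1`).
#' @param seed Integer RNG seed.
#' @return An `mf_signal` of kind `"white"`.
#' @export
white_noise <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  v <- with_rng(seed, stats::runif(n, -0.5, 0.5))
  new_signal(v, fs = 1, kind = "white", params = list(n = n), seed = seed)
}

#' 1/f (pink) noise
#'
#' Starts from uniformly distributed white noise, imposes a `1/f` power
#' distribution on its spectrum (amplitude scaled by `1/sqrt(f)`, DC bin
#' zeroed, Nyquist-symmetric so the inverse transform is real), and
#' returns the inverse FFT. The result has a log-log periodogram slope
#' near -1 and a nearly scale-independent sample-entropy profile, the
#' classic benchmark for long-range-correlated physiological signals.
#'
#' @param n Number of samples (`n >= 16`).
#' @param seed Integer RNG seed.
#' @return An `mf_signal` of kind `"pink"`.
#' @export
one_over_f_noise <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 16) stop_invalid("n must be >= 16")
  n <- as.integer(n)
  w <- with_rng(seed, stats::runif(n, -0.5, 0.5))
  xf <- stats::fft(w)
  k <- seq_len(n) - 1
  fbin <- pmin(k, n - k)          # symmetric frequency index
  amp <- ifelse(fbin > 0, 1 / sqrt(fbin), 0)
  v <- Re(stats::fft(xf * amp, inverse = TRUE)) / n
  new_signal(v, fs = 1, kind = "pink", params = list(n = n), seed = seed)
}

#' Binomial multiplicative cascade (primitive)
#'
#' Builds the deterministic binomial measure on `2^levels` dyadic cells
#' with left/right weights `p` and `1 - p` (weight order shuffled
#' independently per node when a seed is given) and returns its
#' cumulative sum. The scaling exponents are known in closed form,
#' `tau(q) = -log2(p^q + (1-p)^q)`, making this the canonical fixture
#' for multifractal estimators: wavelet-leader analysis of the primitive
#' must recover `zeta(q) = 1 + tau(q)`.
#'
#' @param levels Cascade depth `J >= 4`; the signal has `2^J` samples.
#' @param p Left multiplier in (0, 1).
#' @param seed Integer RNG seed for per-node weight shuffling, or `NULL`
#'   for the fully deterministic cascade.
#' @return An `mf_signal` of kind `"cascade"`; `params` carries `p`,
#'   `levels`, and closed-form exponent functions `tau(q)`, `zeta(q)`,
#'   `alpha(q)`.
#' @export
binomial_cascade <- function(levels, p, seed = NULL) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop_invalid("p must be in (0, 1)")
  if (!is.numeric(levels) || levels < 4) stop_invalid("levels must be >= 4")
  J <- as.integer(levels)
  build <- function() {
    mu <- 1
    for (j in seq_len(J)) {
      w <- matrix(rep(c(p, 1 - p), each = length(mu)), ncol = 2)
      if (!is.null(seed)) {
        flip <- stats::runif(length(mu)) < 0.5
        w[flip, ] <- w[flip, 2:1]
      }
      mu <- as.vector(t(cbind(mu * w[, 1], mu * w[, 2])))
    }
    mu
  }
  mu <- if (is.null(seed)) build() else with_rng(seed, build())
  q_sum <- function(q) p^q + (1 - p)^q
  params <- list(
    p = p, levels = J,
    tau = function(q) -log2(q_sum(q)),
    zeta = function(q) 1 - log2(q_sum(q)),
    alpha = function(q) {
      -(p^q * log(p) + (1 - p)^q * log(1 - p)) / (q_sum(q) * log(2))
    }
  )
  new_signal(cumsum(mu), fs = 1, kind = "cascade", params = params,
             seed = if (is.null(seed)) NA_integer_ else seed)
}

# Autocovariance of fractional Gaussian noise with unit variance.
fgn_acov <- function(k, H) {
  (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H)) / 2
}

#' Fractional Brownian motion
#'
#' Exact synthesis of a fractional Brownian motion path with Hurst
#' exponent `H` by circulant embedding of the fractional-Gaussian-noise
#' covariance (Cholesky fallback for the rare small-`n` cases where the
#' embedding is not nonnegative definite). fBm is the monofractal
#' reference: its scaling function is linear, `zeta(q) = q H`, so the
#' singularity spectrum collapses to the point `(H, 1)`.
#'
#' @param n Number of samples.
#' @param H Hurst exponent in (0, 1).
#' @param seed Integer RNG seed.
#' @return An `mf_signal` of kind `"fbm"` containing the path (cumulative
#'   sum of unit-variance fGn increments).
#' @export
fbm <- function(n, H, seed = 1L) {
  if (!is.numeric(H) || H <= 0 || H >= 1) stop_invalid("H must be in (0, 1)")
  if (!is.numeric(n) || n < 2) stop_invalid("n must be >= 2")
  n <- as.integer(n)
  acov <- fgn_acov(0:(n - 1), H)
  circ <- c(acov, acov[(n - 1):2])
  lam <- Re(stats::fft(circ))
  incr <- if (min(lam) > -1e-10) {
    lam <- pmax(lam, 0)
    m <- length(circ)
    z <- with_rng(seed, complex(real = stats::rnorm(m),
                                imaginary = stats::rnorm(m)))
    w <- stats::fft(sqrt(lam / m) * z)
    Re(w)[seq_len(n)]
  } else {
    S <- outer(0:(n - 1), 0:(n - 1), function(i, j) fgn_acov(i - j, H))
    L <- chol(S)
    as.vector(t(L) %*% with_rng(seed, stats::rnorm(n)))
  }
  new_signal(cumsum(incr), fs = 1, kind = "fbm",
             params = list(n = n, H = H), seed = seed)
}

# PQRST beat template: five displaced Gaussians, amplitudes in mV,
# centers/widths in seconds relative to the R peak.
ecg_beat_template <- function(t) {
  centers <- c(P = -0.20, Q = -0.05, R = 0.00, S = 0.045, T = 0.28)
  amps    <- c(P = 0.15, Q = -0.10, R = 1.00, S = -0.20, T = 0.35)
  widths  <- c(P = 0.040, Q = 0.012, R = 0.018, S = 0.014, T = 0.070)
  out <- numeric(length(t))
  for (i in seq_along(centers)) {
    out <- out + amps[i] * exp(-0.5 * ((t - centers[i]) / widths[i])^2)
  }
  out
}

#' Two-class synthetic ECG-like signal
#'
#' Generates a PQRST-like waveform (five displaced Gaussians repeated at
#' roughly 70 beats/min) whose class difference lives entirely in the
#' stochastic part. The `"ecg_nsr_like"` class adds beat-to-beat RR
#' jitter and 1/f noise -- complex structure across scales -- while the
#' `"ecg_chf_like"` class adds a low-amplitude, strongly smoothed (hence
#' more regular) noise with nearly fixed RR intervals. On cohorts of
#' segments the mean first-moment multiscale entropy over scales 10--20
#' is therefore higher for the NSR-like class, reproducing the ordering
#' observed between healthy and congestive-heart-failure ECG.
#'
#' @param kind `"ecg_nsr_like"` or `"ecg_chf_like"`.
#' @param fs Sampling rate in Hz.
#' @param duration Segment duration in seconds; `fs * duration >= 256`.
#' @param seed Integer RNG seed.
#' @return An `mf_signal` with `fs` set and `kind` as requested.
#' @export
synthetic_ecg <- function(kind = c("ecg_nsr_like", "ecg_chf_like"),
                          fs = 128, duration = 64, seed = 1L) {
  kind <- match.arg(kind)
  n <- round(fs * duration)
  if (n < 256) stop_invalid("fs * duration must be at least 256 samples")
  v <- with_rng(seed, {
    rr_base <- 0.85
    n_beats <- ceiling(duration / rr_base) + 2L
    jitter_sd <- if (kind == "ecg_nsr_like") 0.05 else 0.005
    rr <- rr_base * (1 + stats::rnorm(n_beats, 0, jitter_sd))
    rr <- pmax(rr, 0.4)
    beat_times <- cumsum(c(stats::runif(1, 0, rr_base), rr))
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    for (bt in beat_times[beat_times < duration + 0.5]) {
      idx <- which(tt >= bt - 0.45 & tt <= bt + 0.55)
      x[idx] <- x[idx] + ecg_beat_template(tt[idx] - bt)
    }
    if (kind == "ecg_nsr_like") {
      pn <- one_over_f_noise(n, seed = seed + 1000L)$values
      pn <- pn / stats::sd(pn)
      x + 0.10 * pn
    } else {
      wn <- stats::rnorm(n)
      k <- max(3L, round(0.35 * fs))   # ~0.35 s moving average
      sm <- stats::filter(wn, rep(1 / k, k), method = "convolution",
                          sides = 2, circular = TRUE)
      sm <- as.numeric(sm) / stats::sd(sm)
      x + 0.03 * sm
    }
  })
  new_signal(v, fs = fs, kind = kind,
             params = list(fs = fs, duration = duration), seed = seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.mf_signal <- function(object, max_seconds = 10, ...) {
  tt <- (seq_along(object$values) - 1) / object$fs
  keep <- tt <= max_seconds
  df <- tibble::tibble(time = tt[keep], value = object$values[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = paste0(object$kind, " (fs = ", object$fs, " Hz)"))
}

#' Write a signal to the package CSV dialect
#'
#' The CSV dialect is a first header line `fs=<Hz>` followed by one
#' sample per row.
#'
#' @param x Signal-like object (see [signal_values()]); `fs` is taken
#'   from the object or from the `fs` argument.
#' @param path Output file path.
#' @param fs Sampling rate override in Hz.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, fs = NULL) {
  v <- signal_values(x)
  if (is.null(fs)) fs <- if (is.list(x) && !is.null(x$fs)) x$fs else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("fs=", format(fs, scientific = FALSE)), con)
  writeLines(format(v, scientific = FALSE, trim = TRUE, digits = 15), con)
  invisible(path)
}
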