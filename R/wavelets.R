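# Wavelet filter banks and transforms.
#
# Two transforms are needed: a decimated pyramid (detail coefficients for
# multifractal analysis, 'db3' by default) and an undecimated (MODWT)
# multiresolution analysis with exact additive reconstruction for
# denoising ('bior2.6' by default).  Filter coefficients are the standard
# published Daubechies / Cohen-Daubechies-Feauveau values.

wt_filter_table <- list(
  db1 = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    orthogonal = TRUE, n_vanish = 1L, regularity = 1
  ),
  db2 = list(
    dec_lo = c(-0.12940952255092145, 0.22414386804185735,
               0.836516303737469, 0.48296291314469025),
    dec_hi = c(-0.48296291314469025, 0.836516303737469,
               -0.22414386804185735, -0.12940952255092145),
    orthogonal = TRUE, n_vanish = 2L, regularity = 2
  ),
  db3 = list(
    dec_lo = c(0.03522629188570953, -0.08544127388202666,
               -0.13501102001025458, 0.45987750211849154,
               0.8068915093110925, 0.33267055295008263),
    dec_hi = c(-0.33267055295008263, 0.8068915093110925,
               -0.45987750211849154, -0.13501102001025458,
               0.08544127388202666, 0.03522629188570953),
    orthogonal = TRUE, n_vanish = 3L, regularity = 3
  ),
  bior2.6 = list(
    dec_lo = c(0, -0.006905339660024878, 0.013810679320049757,
               0.04695630968816917, -0.1077232986963881,
               -0.16987135563661201, 0.4474660099696121,
               0.966747552403483, 0.4474660099696121,
               -0.16987135563661201, -0.1077232986963881,
               0.04695630968816917, 0.013810679320049757,
               -0.006905339660024878),
    dec_hi = c(0, 0, 0, 0, 0, 0.3535533905932738, -0.7071067811865476,
               0.3535533905932738, 0, 0, 0, 0, 0, 0),
    rec_lo = c(0, 0, 0, 0, 0, 0.3535533905932738, 0.7071067811865476,
               0.3535533905932738, 0, 0, 0, 0, 0, 0),
    rec_hi = c(0, 0.006905339660024878, 0.013810679320049757,
               -0.04695630968816917, -0.1077232986963881,
               0.16987135563661201, 0.4474660099696121,
               -0.966747552403483, 0.4474660099696121,
               0.16987135563661201, -0.1077232986963881,
               -0.04695630968816917, 0.013810679320049757,
               0.006905339660024878),
    # symmetry centres (0-based) of the linear-phase filters
    centers = c(dec_lo = 7, dec_hi = 6, rec_lo = 6, rec_hi = 7),
    orthogonal = FALSE, n_vanish = 2L, regularity = 2
  )
)

#' Wavelet filter bank
#'
#' Returns the analysis/synthesis filter coefficients and metadata for a
#' named wavelet. Orthogonal Daubechies filters (`db1`--`db3`) and the
#' biorthogonal spline wavelet `bior2.6` are provided.
#'
#' @param wavelet Filter name, one of `"db1"`, `"db2"`, `"db3"`, `"bior2.6"`.
#' @return A list with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric filter taps), `orthogonal`, `n_vanish` (vanishing moments of
#'   the analysis wavelet) and `regularity`.
#' @export
wt_filters <- function(wavelet = "db3") {
  f <- wt_filter_table[[wavelet]]
  if (is.null(f)) stop_invalid(paste0("unknown wavelet '", wavelet, "'"))
  if (f$orthogonal) {
    f$rec_lo <- rev(f$dec_lo)
    f$rec_hi <- rev(f$dec_hi)
  }
  f$name <- wavelet
  f
}

# One analysis level of the decimated pyramid with half-point symmetric
# extension: out[i] = sum_k h[k] * a_ext[2 i - k + 1].
dwt_step <- function(a, h_lo, h_hi) {
  n <- length(a)
  if (n %% 2L == 1L) {
    a <- c(a, a[n])
    n <- n + 1L
  }
  L <- length(h_lo)
  xp <- c(rev(a[seq_len(L - 1L)]), a, rev(a)[seq_len(L - 1L)])
  lo_full <- stats::filter(xp, h_lo, method = "convolution", sides = 1)
  hi_full <- stats::filter(xp, h_hi, method = "convolution", sides = 1)
  idx <- (L - 1L) + seq(2L, n, by = 2L)
  list(approx = as.numeric(lo_full[idx]), detail = as.numeric(hi_full[idx]))
}

#' L1-normalized wavelet detail coefficients
#'
#' Computes the decimated discrete wavelet transform of a signal and
#' stores the detail coefficient magnitudes with an L1 normalization,
#' i.e. `2^(-j/2)` times the usual L2-normalized coefficients at octave
#' `j`. The L1 normalization makes coefficient magnitudes of a function
#' with local Hoelder exponent `h` scale as `2^(j h)`, which is the form
#' multifractal regression estimators need.
#'
#' @param x Numeric signal (or an object with a `$values` field such as
#'   the synthetic-signal and segment records of this package).
#' @param wavelet Analysis wavelet name; default `"db3"` (3 vanishing
#'   moments).
#' @param j2 Coarsest octave to compute; defaults to
#'   [max_scale_index()] of the signal length.
#' @return An object of class `wt_coeffs`: a list with `d` (list of
#'   per-octave magnitude vectors, finest first), `nj` (coefficient
#'   counts), `wavelet`, `n_vanish`, `regularity`, `n` (signal length).
#' @export
dwt_l1 <- function(x, wavelet = "db3", j2 = NULL) {
  x <- signal_values(x)
  f <- wt_filters(wavelet)
  if (is.null(j2)) j2 <- max_scale_index(length(x), f$n_vanish)
  L <- length(f$dec_lo)
  if (length(x) < 2^j2) {
    stop_invalid("signal too short for the requested number of octaves")
  }
  d <- vector("list", j2)
  a <- x
  for (j in seq_len(j2)) {
    if (length(a) < L) {
      stop_invalid("signal too short for the requested number of octaves")
    }
    st <- dwt_step(a, f$dec_lo, f$dec_hi)
    d[[j]] <- abs(st$detail) * 2^(-j / 2)
    a <- st$approx
  }
  structure(
    list(d = d, nj = vapply(d, length, integer(1)), wavelet = wavelet,
         n_vanish = f$n_vanish, regularity = f$regularity, n = length(x)),
    class = "wt_coeffs"
  )
}

#' @export
print.wt_coeffs <- function(x, ...) {
  cat("<wt_coeffs> wavelet", x$wavelet, "| octaves 1..", length(x$d),
      "| nj:", paste(x$nj, collapse = " "), "\n")
  invisible(x)
}

# Frequency response of an a-trous-upsampled filter, zero-phase for
# linear-phase filters (phase referenced to the stored symmetry centre).
wt_transfer <- function(h, center, upsample, n) {
  om <- 2 * pi * (seq_len(n) - 1) / n
  l <- seq_along(h) - 1
  E <- exp(-1i * outer(om * upsample, l - center))
  as.vector(E %*% h)
}

# Analysis/synthesis frequency responses at one MODWT level.  For the
# symmetric biorthogonal filters the stored integer symmetry centres
# give zero-phase (Hermitian) responses; for orthogonal filters the
# analysis response is taken causal and the synthesis response is its
# conjugate (time-reversal), which realizes perfect reconstruction.
modwt_transfers <- function(f, up, n) {
  if (f$orthogonal) {
    Gd <- wt_transfer(f$dec_lo / sqrt(2), 0, up, n)
    Hd <- wt_transfer(f$dec_hi / sqrt(2), 0, up, n)
    list(Gd = Gd, Hd = Hd, Gr = Conj(Gd), Hr = Conj(Hd))
  } else {
    cs <- f$centers
    list(Gd = wt_transfer(f$dec_lo / sqrt(2), cs[["dec_lo"]], up, n),
         Hd = wt_transfer(f$dec_hi / sqrt(2), cs[["dec_hi"]], up, n),
         Gr = wt_transfer(f$rec_lo / sqrt(2), cs[["rec_lo"]], up, n),
         Hr = wt_transfer(f$rec_hi / sqrt(2), cs[["rec_hi"]], up, n))
  }
}

# Undecimated (MODWT) analysis of x to J levels, circular boundary,
# computed per level in the frequency domain.
# Returns W (list of detail coefficient series) and V (level-J smooth).
modwt <- function(x, wavelet = "bior2.6", J = 8L) {
  f <- wt_filters(wavelet)
  n <- length(x)
  xhat <- stats::fft(x)
  W <- vector("list", J)
  vhat <- xhat
  for (j in seq_len(J)) {
    tr <- modwt_transfers(f, 2^(j - 1), n)
    W[[j]] <- Re(stats::fft(tr$Hd * vhat, inverse = TRUE)) / n
    vhat <- tr$Gd * vhat
  }
  V <- Re(stats::fft(vhat, inverse = TRUE)) / n
  list(W = W, V = V, wavelet = wavelet, J = J, n = n)
}

# Inverse of modwt(); accepts modified coefficient series.
imodwt <- function(m) {
  f <- wt_filters(m$wavelet)
  n <- m$n
  vhat <- stats::fft(m$V)
  for (j in rev(seq_len(m$J))) {
    tr <- modwt_transfers(f, 2^(j - 1), n)
    vhat <- tr$Gr * vhat + tr$Hr * stats::fft(m$W[[j]])
  }
  Re(stats::fft(vhat, inverse = TRUE)) / n
}
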