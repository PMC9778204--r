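# Independent brute-force oracles used across the test files.
# Each oracle is a literal, loop-based transcription of the definitions,
# sharing no code with the package implementations.

# Sample entropy: per-origin template probabilities averaged over
# Ns-m+1 origins (order m) and Ns-m origins (order m+1), self-matches
# excluded, Chebyshev distance strictly below r.
sampen_oracle <- function(y, m, r) {
  ns <- length(y)
  nm <- ns - m + 1
  nm1 <- ns - m
  count_at <- function(i, len, n_orig) {
    cnt <- 0
    for (j in seq_len(n_orig)) {
      if (j != i && max(abs(y[i:(i + len - 1)] - y[j:(j + len - 1)])) < r) {
        cnt <- cnt + 1
      }
    }
    cnt
  }
  a_m <- mean(vapply(seq_len(nm), function(i) count_at(i, m, nm) / nm,
                     numeric(1)))
  a_m1 <- mean(vapply(seq_len(nm1), function(i) count_at(i, m + 1, nm1) / nm1,
                      numeric(1)))
  if (a_m == 0 || a_m1 == 0) return(NA_real_)
  -log(a_m1 / a_m)
}

# Wavelet leaders by exhaustive enumeration: for each octave/position,
# scan every coefficient at every octave j' <= j and keep those whose
# dyadic interval [ (k'-1) 2^j', k' 2^j' ) lies inside the 3-cell
# neighborhood [ (k-2) 2^j, (k+1) 2^j ).
leaders_oracle <- function(d) {
  j2 <- length(d)
  out <- vector("list", j2)
  for (j in seq_len(j2)) {
    nj <- length(d[[j]])
    out[[j]] <- vapply(seq_len(nj), function(k) {
      lo <- (k - 2) * 2^j
      hi <- (k + 1) * 2^j
      best <- -Inf
      for (jp in seq_len(j)) {
        for (kp in seq_along(d[[jp]])) {
          a <- (kp - 1) * 2^jp
          b <- kp * 2^jp
          if (a >= lo && b <= hi) best <- max(best, d[[jp]][kp])
        }
      }
      best
    }, numeric(1))
  }
  out
}

# Fabricated coefficient container for leader/structure tests.
fake_coeffs <- function(d, n = sum(lengths(d)) * 2) {
  structure(
    list(d = d, nj = vapply(d, length, integer(1)), wavelet = "db3",
         n_vanish = 3L, regularity = 3, n = n),
    class = "wt_coeffs"
  )
}

fake_leaders <- function(L) {
  structure(
    list(L = L, nj = vapply(L, length, integer(1)), wavelet = "db3",
         n = sum(lengths(L)) * 2),
    class = "wt_leaders"
  )
}

# One analysis level by naive convolution/decimation under the package's
# stated contract: out[i] = sum_k h[k] * a_ext[2 i - k + 1] with
# half-point symmetric extension, downsampling at even positions.
dwt_step_oracle <- function(a, h) {
  n <- length(a)
  if (n %% 2 == 1) {
    a <- c(a, a[n])
    n <- n + 1
  }
  L <- length(h)
  ext <- function(p) {
    if (p >= 1 && p <= n) return(a[p])
    if (p < 1) return(a[1 - p])       # half-point reflection
    a[2 * n - p + 1]
  }
  out <- numeric(n %/% 2)
  for (i in seq_len(n %/% 2)) {
    s <- 0
    for (k in seq_len(L)) s <- s + h[k] * ext(2 * i - k + 1)
    out[i] <- s
  }
  out
}

# Full detail pyramid via the naive per-level oracle.
dwt_l1_oracle <- function(x, wavelet = "db3", j2) {
  f <- wt_filters(wavelet)
  d <- vector("list", j2)
  a <- x
  for (j in seq_len(j2)) {
    d[[j]] <- abs(dwt_step_oracle(a, f$dec_hi)) * 2^(-j / 2)
    a <- dwt_step_oracle(a, f$dec_lo)
  }
  d
}

# Denoised synthetic two-class cohorts for pipeline tests.
make_ecg_cohort <- function(kind, n, seed0, fs = 128, duration = 64) {
  lapply(seq_len(n), function(i) {
    denoise(synthetic_ecg(kind, fs = fs, duration = duration,
                          seed = seed0 + i))
  })
}

# Well-separated two-class feature table (no signal processing) for
# fast classifier tests.
make_blob_features <- function(n_per_class = 40, sep = 4, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    segment_id = paste0("s", seq_len(2 * n_per_class)),
    label = rep(c("NSR", "CHF"), each = n_per_class),
    f1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep)),
    f2 = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep)),
    f3 = rnorm(2 * n_per_class),
    ok = TRUE
  )
}
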