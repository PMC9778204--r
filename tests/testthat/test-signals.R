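# Synthetic signal generators: determinism, closed-form statistics,
# preconditions.

test_that("generators are pure functions of (params, seed)", {
  expect_identical(white_noise(8, seed = 4)$values,
                   white_noise(8, seed = 4)$values)
  expect_identical(one_over_f_noise(64, seed = 9)$values,
                   one_over_f_noise(64, seed = 9)$values)
  expect_identical(fbm(256, 0.7, seed = 2)$values,
                   fbm(256, 0.7, seed = 2)$values)
  expect_identical(binomial_cascade(8, 0.6, seed = 3)$values,
                   binomial_cascade(8, 0.6, seed = 3)$values)
  expect_identical(synthetic_ecg("ecg_nsr_like", seed = 5)$values,
                   synthetic_ecg("ecg_nsr_like", seed = 5)$values)
  expect_false(identical(white_noise(8, seed = 4)$values,
                         white_noise(8, seed = 5)$values))
})

test_that("white noise is zero-centered and uncorrelated", {
  w <- white_noise(100000, seed = 2)
  expect_length(w$values, 100000)
  expect_lt(abs(mean(w$values)), 0.01)
  r1 <- cor(w$values[-1], w$values[-length(w$values)])
  expect_lt(abs(r1), 0.02)
  expect_error(white_noise(0), class = "mfecg_invalid_argument")
})

test_that("1/f noise has periodogram slope near -1 over the central decade", {
  p <- one_over_f_noise(65536, seed = 3)
  v <- p$values
  expect_true(is.finite(var(v)) && var(v) > 0)
  pg <- abs(stats::fft(v))[2:32769]^2
  fr <- (1:32768) / 65536
  sel <- fr > 0.001 & fr < 0.1
  slope <- unname(coef(lm(log(pg[sel]) ~ log(fr[sel])))[2])
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
  expect_error(one_over_f_noise(8), class = "mfecg_invalid_argument")
})

test_that("binomial cascade conserves mass and carries exact exponents", {
  cas <- binomial_cascade(10, 0.5)
  incr <- diff(c(0, cas$values))
  expect_equal(max(incr), min(incr))          # p = 1/2: uniform measure
  expect_equal(cas$values[length(cas$values)], 1, tolerance = 1e-12)
  cas2 <- binomial_cascade(10, 0.37, seed = 1)
  expect_equal(cas2$values[length(cas2$values)], 1, tolerance = 1e-12)
  cas3 <- binomial_cascade(14, 0.6)
  expect_equal(cas3$params$tau(1), 0, tolerance = 1e-14)
  expect_equal(cas3$params$zeta(0), 0, tolerance = 1e-14)
  expect_error(binomial_cascade(10, 1.2), class = "mfecg_invalid_argument")
  expect_error(binomial_cascade(2, 0.6), class = "mfecg_invalid_argument")
})

test_that("fBm increments match the closed-form autocovariance", {
  n <- 65536
  f5 <- fbm(n, 0.5, seed = 7)
  i5 <- diff(c(0, f5$values))
  expect_lt(abs(cor(i5[-1], i5[-n])), 0.02)   # H = 1/2: ordinary BM
  expect_equal(var(i5), 1, tolerance = 3 / sqrt(n) * 3)
  f7 <- fbm(n, 0.7, seed = 7)
  i7 <- diff(c(0, f7$values))
  expect_lt(abs(cor(i7[-1], i7[-n]) - (2^(2 * 0.7 - 1) - 1)), 0.03)
  expect_error(fbm(100, 1.1), class = "mfecg_invalid_argument")
})

test_that("synthetic ECG respects the length contract", {
  s <- synthetic_ecg("ecg_nsr_like", fs = 128, duration = 64, seed = 1)
  expect_length(s$values, 8192)
  s250 <- synthetic_ecg("ecg_chf_like", fs = 250, duration = 64, seed = 1)
  expect_length(s250$values, 16000)
  expect_error(synthetic_ecg("ecg_nsr_like", fs = 128, duration = 1),
               class = "mfecg_invalid_argument")
})

test_that("NSR-like cohorts have higher large-scale entropy than CHF-like", {
  msen1 <- function(kind, seeds) {
    vapply(seeds, function(i) {
      seg <- denoise(synthetic_ecg(kind, seed = i))
      as.numeric(mse_feature(seg, moment = 1))
    }, numeric(1))
  }
  nsr <- msen1("ecg_nsr_like", 1:30)
  chf <- msen1("ecg_chf_like", 101:130)
  expect_gt(mean(nsr), mean(chf))
})

test_that("signal CSV roundtrips through the reader", {
  s <- one_over_f_noise(512, seed = 1)
  s$fs <- 128
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, path)
  rec <- read_ecg(path, "csv")
  expect_equal(rec$fs, 128)
  expect_equal(rec$samples, s$values, tolerance = 1e-12)
})
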