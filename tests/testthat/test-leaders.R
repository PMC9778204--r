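# Wavelet-leader multifractal machinery.

test_that("the coarsest-octave rule follows the filter-length bound", {
  expect_equal(max_scale_index(8192, 3), 10L)
  expect_equal(max_scale_index(256, 3), 5L)
  expect_equal(max_scale_index(14, 3), 1L)
  expect_error(max_scale_index(7, 3), class = "mfecg_invalid_argument")
})

test_that("detail coefficients annihilate low-order polynomials", {
  co <- dwt_l1(rep(4.2, 1024), "db3", j2 = 5)
  expect_true(all(vapply(co$d, max, numeric(1)) < 1e-12))
  tq <- (seq_len(2048) / 2048)
  x <- 2 * tq^2 - 0.7 * tq + 0.1
  co2 <- dwt_l1(x, "db3", j2 = 6)
  for (j in 1:6) {
    d <- co2$d[[j]]
    interior <- d[7:(length(d) - 6)]
    expect_lt(max(interior), 1e-8)
  }
})

test_that("the pyramid matches a naive convolution-decimation oracle", {
  set.seed(4)
  x <- numeric(256)
  x[97] <- 1                       # Kronecker impulse
  co <- dwt_l1(x, "db3", j2 = 4)
  oracle <- dwt_l1_oracle(x, "db3", 4)
  for (j in 1:4) expect_equal(co$d[[j]], oracle[[j]], tolerance = 1e-13)
  y <- rnorm(512)
  co2 <- dwt_l1(y, "db3", j2 = 5)
  oracle2 <- dwt_l1_oracle(y, "db3", 5)
  for (j in 1:5) expect_equal(co2$d[[j]], oracle2[[j]], tolerance = 1e-12)
})

test_that("leaders equal the exhaustive-enumeration oracle and dominate", {
  # hand-checked micro-examples
  L1 <- compute_leaders(fake_coeffs(list(c(1, 3, 2, 5))))
  expect_equal(L1$L[[1]], c(3, 3, 5, 5))
  L2 <- compute_leaders(fake_coeffs(list(c(1, 3, 2, 5), c(4, 1))))
  expect_equal(L2$L[[2]][1], 5)    # sup over own cell, neighbors, children
  set.seed(8)
  for (rep in 1:5) {
    d <- list(runif(16), runif(8), runif(4), runif(2))
    ld <- compute_leaders(fake_coeffs(d))
    expect_equal(ld$L, leaders_oracle(d))
    for (j in 1:4) expect_true(all(ld$L[[j]] >= d[[j]]))
  }
})

test_that("structure functions reduce to direct summation", {
  ld <- fake_leaders(list(rep(2, 4)))
  S <- structure_functions(ld, c(0, 2))
  expect_equal(S$S[S$q == 2], 4)
  expect_equal(S$S[S$q == 0], 1)
  set.seed(9)
  L <- list(runif(32, 0.1, 2), runif(16, 0.1, 2), runif(8, 0.1, 2))
  S2 <- structure_functions(fake_leaders(L), c(-1, 0.5, 3))
  for (j in 1:3) {
    for (q in c(-1, 0.5, 3)) {
      expect_equal(S2$S[S2$j == j & S2$q == q], mean(L[[j]]^q),
                   tolerance = 1e-14)
    }
  }
})

test_that("scaling function recovers exact log-linear leaders", {
  H <- 0.6
  L <- lapply(1:5, function(j) rep(2^(j * H), 2^(8 - j)))
  S <- structure_functions(fake_leaders(L), seq(-2, 2, 0.5))
  z <- scaling_function(S, 1, 5)
  expect_equal(z$zeta, H * z$q, tolerance = 1e-10)
  expect_equal(z$zeta[z$q == 0], 0, tolerance = 1e-12)
  expect_error(scaling_function(S, 1, 2), class = "mfecg_invalid_argument")
})

test_that("Legendre transform handles linear and quadratic scaling exactly", {
  q <- seq(-3, 3, 0.25)
  lin <- legendre_spectrum(tibble::tibble(q = q, zeta = 0.7 * q))
  expect_equal(lin$alpha, rep(0.7, length(q)), tolerance = 1e-12)
  expect_equal(lin$f_alpha, rep(1, length(q)), tolerance = 1e-12)
  H <- 0.8; cc <- 0.05
  quad <- legendre_spectrum(tibble::tibble(q = q, zeta = H * q - cc * q^2 / 2))
  interior <- seq(2, length(q) - 1)
  expect_equal(quad$alpha[interior], H - cc * q[interior], tolerance = 1e-12)
  expect_equal(quad$f_alpha[interior],
               1 - (H - quad$alpha[interior])^2 / (2 * cc), tolerance = 1e-12)
  expect_error(legendre_spectrum(tibble::tibble(q = c(0, 1, 3),
                                                zeta = c(0, 1, 2))),
               class = "mfecg_invalid_argument")
})

test_that("direct estimator is exact for uniform leaders", {
  H <- 0.45
  L <- lapply(1:5, function(j) rep(2^(j * H), 2^(9 - j)))
  d <- direct_spectrum(fake_leaders(L), seq(-2, 2, 0.5), 1, 5)
  expect_equal(d$alpha, rep(H, nrow(d)), tolerance = 1e-10)
  expect_equal(d$f_alpha, rep(1, nrow(d)), tolerance = 1e-10)
})

test_that("spectrum features read off the singularity indices", {
  q <- seq(-5, 5, 0.25)
  leg <- legendre_spectrum(tibble::tibble(q = q, zeta = 0.7 * q))
  ft <- spectrum_features(leg, 5)
  expect_equal(ft$alpha0, 0.7, tolerance = 1e-12)
  expect_equal(ft$delta_alpha, 0, tolerance = 1e-12)
  expect_error(spectrum_features(leg[leg$q != 0, ], 5),
               class = "mfecg_invalid_argument")
})

test_that("Hoelder bounds recover exact exponents and flag degeneracy", {
  H <- 0.7
  co <- fake_coeffs(lapply(1:5, function(j) rep(2^(j * H), 2^(8 - j))))
  hb <- hoelder_bounds(co, 1, 5)
  expect_equal(hb$h_min, H, tolerance = 1e-12)
  expect_equal(hb$h_max, H, tolerance = 1e-12)
  zero <- fake_coeffs(lapply(1:4, function(j) rep(0, 2^(6 - j))))
  w <- testthat::capture_warnings(hbz <- hoelder_bounds(zero, 1, 4))
  expect_gte(length(w), 1)
  expect_true(is.na(hbz$h_min))
})

test_that("wavelet adequacy is a strict inequality check", {
  expect_true(check_wavelet_adequacy(0.3, 2.5, 3, 3)$pass)
  expect_false(check_wavelet_adequacy(0.3, 3.2, 3, 3)$pass)
  expect_false(check_wavelet_adequacy(0.3, 3, 3, 3)$pass)   # boundary
})

test_that("cascade scaling-function recovery does not degrade with depth", {
  qs <- seq(-2, 5, by = 0.5)
  err_for <- function(J) {
    cas <- binomial_cascade(J, 0.6)
    j2 <- max_scale_index(2^J, 1)
    ld <- compute_leaders(dwt_l1(cas, "db1", j2 = j2))
    S <- suppressWarnings(structure_functions(ld, qs))
    z <- scaling_function(S, 3, j2)
    max(abs(z$zeta[match(qs, z$q)] - cas$params$zeta(qs)))
  }
  e10 <- err_for(10)
  e14 <- err_for(14)
  expect_lt(e14, e10 + 0.01)
  expect_lt(e14, 0.05)
})

test_that("estimated scaling functions are concave up to fit noise", {
  cas <- binomial_cascade(12, 0.65, seed = 2)
  sp <- suppressWarnings(mf_spectrum(cas, wavelet = "db1", j1 = 3))
  z <- sp$spectrum$zeta
  expect_true(all(diff(diff(z)) <= 0.02))
  # alpha(q) non-increasing in q
  expect_true(all(diff(sp$spectrum$alpha_direct) <= 1e-3))
})

test_that("the full spectrum wrapper assembles consistent components", {
  fb <- fbm(4096, 0.6, seed = 3)
  sp <- suppressWarnings(mf_spectrum(fb))
  expect_s3_class(sp, "mf_spectrum")
  expect_equal(sp$spectrum$zeta[sp$spectrum$q == 0], 0, tolerance = 1e-10)
  expect_true(sp$features$delta_alpha >= 0)
  expect_true(all(sp$spectrum$f_direct <= 1 + 0.05))
  g <- glance(sp)
  expect_true(all(c("alpha0", "h_min", "adequate") %in% names(g)))
  expect_s3_class(tidy(sp), "tbl_df")
})
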