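# Wavelet-leader multifractal analysis.
#
# From L1-normalized detail coefficients we form leaders (local suprema
# over finer scales within a 3-cell neighborhood), structure functions,
# the scaling function zeta(q) by log-log regression, and two estimates
# of the singularity spectrum: the Legendre transform of zeta(q) and a
# direct weighted-moment (canonical-measure) estimator.

#' Coarsest usable octave for a given signal length
#'
#' `j2 = floor(log2(N / (2 * Nv + 1)))` where `Nv` is the number of
#' vanishing moments of the analysis wavelet; at coarser octaves fewer
#' coefficients remain than the wavelet filter needs.
#'
#' @param n Signal length.
#' @param n_vanish Vanishing moments of the analysis wavelet (3 for
#'   `db3`).
#' @return Integer octave index `j2 >= 1`.
#' @export
max_scale_index <- function(n, n_vanish = 3) {
  if (n <= 2 * n_vanish + 1) stop_invalid("signal too short")
  as.integer(floor(log2(n / (2 * n_vanish + 1))))
}

#' Wavelet leaders
#'
#' The leader at octave `j`, position `k` is the supremum of the
#' L1-normalized coefficient magnitudes over all octaves `j' <= j` whose
#' dyadic support lies inside the union of the cell `(j, k)` and its two
#' neighbors; out-of-range neighbors at array edges are omitted.
#'
#' @param coeffs A `wt_coeffs` object from [dwt_l1()].
#' @return An object of class `wt_leaders`: list with `L` (per-octave
#'   leader vectors), `nj`, and the originating coefficient metadata.
#' @export
compute_leaders <- function(coeffs) {
  stopifnot(inherits(coeffs, "wt_coeffs"))
  d <- coeffs$d
  j2 <- length(d)
  # M[[j]][k]: sup of |d| over octaves <= j within the dyadic cell (j, k)
  M <- vector("list", j2)
  M[[1]] <- d[[1]]
  if (j2 > 1) {
    for (j in 2:j2) {
      nj <- length(d[[j]])
      prev <- M[[j - 1]]
      child1 <- prev[pmin(2 * seq_len(nj) - 1, length(prev))]
      child2 <- prev[pmin(2 * seq_len(nj), length(prev))]
      m <- pmax(d[[j]], child1, child2)
      # fold any unparented trailing finer cells into the last parent
      extra <- length(prev) - 2 * nj
      if (extra > 0) {
        m[nj] <- max(m[nj], prev[(2 * nj + 1):length(prev)])
      }
      M[[j]] <- m
    }
  }
  L <- vector("list", j2)
  for (j in seq_len(j2)) {
    m <- M[[j]]
    nj <- length(m)
    left <- c(-Inf, m[-nj])
    right <- c(m[-1], -Inf)
    L[[j]] <- pmax(left, m, right)
  }
  structure(
    list(L = L, nj = vapply(L, length, integer(1)),
         wavelet = coeffs$wavelet, n = coeffs$n),
    class = "wt_leaders"
  )
}

#' Structure functions of wavelet leaders
#'
#' `S(j, q) = mean(L(j, k)^q)` over the `nj` leaders at octave `j`.
#' Exactly-zero leaders (flat signal regions) are excluded at `q < 0`
#' and floored at `1e-300` otherwise; affected counts are recorded in
#' the `n_zero` attribute.
#'
#' @param leaders A `wt_leaders` object.
#' @param q_grid Numeric vector of moment orders.
#' @return A tibble with columns `j`, `q`, `S`, `nj`.
#' @export
structure_functions <- function(leaders, q_grid) {
  stopifnot(inherits(leaders, "wt_leaders"))
  n_zero <- 0L
  rows <- purrr::map_dfr(seq_along(leaders$L), function(j) {
    l <- leaders$L[[j]]
    nz <- sum(l == 0)
    n_zero <<- n_zero + nz
    purrr::map_dfr(q_grid, function(q) {
      lq <- if (q < 0) l[l > 0] else pmax(l, 1e-300)
      if (length(lq) == 0) {
        return(tibble::tibble(j = j, q = q, S = NA_real_, nj = 0L))
      }
      tibble::tibble(j = j, q = q, S = mean(lq^q), nj = length(lq))
    })
  })
  if (n_zero > 0) {
    rlang::warn(paste0(n_zero, " zero leader(s) floored/excluded"))
  }
  attr(rows, "n_zero") <- n_zero
  rows
}

#' Scaling function by log-log regression
#'
#' `zeta(q)` is the ordinary-least-squares slope of `log2 S(j, q)`
#' against octave `j` over `j1..j2`; fit residual norms are recorded.
#'
#' @param S Structure-function tibble from [structure_functions()].
#' @param j1,j2 Octave fit range (at least 3 octaves).
#' @return A tibble with columns `q`, `zeta`, `resid_rms`.
#' @export
scaling_function <- function(S, j1 = 1, j2 = max(S$j)) {
  jj <- j1:j2
  if (length(jj) < 3) stop_invalid("need at least 3 octaves in the fit range")
  S %>%
    dplyr::filter(.data$j %in% jj, !is.na(.data$S)) %>%
    dplyr::group_by(.data$q) %>%
    dplyr::summarise(
      zeta = ols_fit(.data$j, log2(.data$S))$slope,
      resid_rms = sqrt(mean(ols_fit(.data$j, log2(.data$S))$residuals^2)),
      .groups = "drop"
    )
}

#' Singularity spectrum by Legendre transform
#'
#' `alpha(q) = d zeta / d q` by central finite differences (one-sided at
#' the grid endpoints) and `f(alpha) = q * alpha - zeta + 1`.
#'
#' @param zeta Tibble with columns `q` and `zeta` on a uniform grid.
#' @return A tibble with columns `q`, `zeta`, `alpha`, `f_alpha`.
#' @export
legendre_spectrum <- function(zeta) {
  zeta <- dplyr::arrange(zeta, .data$q)
  q <- zeta$q
  dq <- diff(q)
  if (length(q) < 3 || max(abs(dq - dq[1])) > 1e-8 * max(abs(dq))) {
    stop_invalid("q grid must be uniform with at least 3 points")
  }
  z <- zeta$zeta
  n <- length(q)
  alpha <- numeric(n)
  alpha[1] <- (z[2] - z[1]) / dq[1]
  alpha[n] <- (z[n] - z[n - 1]) / dq[1]
  if (n > 2) alpha[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dq[1])
  tibble::tibble(q = q, zeta = z, alpha = alpha,
                 f_alpha = q * alpha - z + 1)
}

#' Singularity spectrum by the direct (weighted-moment) method
#'
#' For each `q` the leaders at octave `j` are turned into canonical
#' weights `P(j,k) = L(j,k)^q / sum_k L(j,k)^q`; then
#' `alpha(q)` is the regression slope over octaves of
#' `sum_k P log2 L`, and `f(alpha(q))` is one plus the slope of
#' `sum_k P log2 P + log2 nj` (the entropy offset makes the uniform-
#' weight case, with `f = 1`, give slope zero).
#'
#' @param leaders A `wt_leaders` object.
#' @param q_grid Numeric vector of moment orders.
#' @param j1,j2 Octave fit range (at least 3 octaves).
#' @return A tibble with columns `q`, `alpha`, `f_alpha`.
#' @export
direct_spectrum <- function(leaders, q_grid, j1 = 1,
                            j2 = length(leaders$L)) {
  stopifnot(inherits(leaders, "wt_leaders"))
  jj <- j1:j2
  if (length(jj) < 3) stop_invalid("need at least 3 octaves in the fit range")
  purrr::map_dfr(q_grid, function(q) {
    U <- numeric(length(jj))
    V <- numeric(length(jj))
    for (i in seq_along(jj)) {
      l <- leaders$L[[jj[i]]]
      l <- if (q < 0) l[l > 0] else pmax(l, 1e-300)
      lq <- l^q
      P <- lq / sum(lq)
      U[i] <- sum(P * log2(l))
      pos <- P > 0
      V[i] <- sum(P[pos] * log2(P[pos])) + log2(length(l))
    }
    tibble::tibble(q = q,
                   alpha = ols_fit(jj, U)$slope,
                   f_alpha = 1 + ols_fit(jj, V)$slope)
  })
}

#' Summary features of a singularity spectrum
#'
#' `alpha_min = alpha(+qmax)` (strongest singularities, large
#' fluctuations), `alpha0 = alpha(0)` (spectrum apex), `alpha_max =
#' alpha(-qmax)` (weakest singularities), and the spectrum width
#' `delta_alpha = alpha_max - alpha_min`.
#'
#' @param spec Tibble with columns `q` and `alpha` (from
#'   [legendre_spectrum()] or [direct_spectrum()]).
#' @param qmax Extreme moment order present in the grid.
#' @return A one-row tibble with `alpha_min`, `alpha0`, `alpha_max`,
#'   `delta_alpha`.
#' @export
spectrum_features <- function(spec, qmax = max(spec$q)) {
  pick <- function(qv) {
    i <- which(abs(spec$q - qv) < 1e-9)
    if (length(i) != 1) {
      stop_invalid(paste0("q grid must contain ", qv))
    }
    spec$alpha[i]
  }
  a_min <- pick(qmax)
  a_max <- pick(-qmax)
  tibble::tibble(alpha_min = a_min, alpha0 = pick(0), alpha_max = a_max,
                 delta_alpha = a_max - a_min)
}

#' Uniform Hoelder exponent bounds
#'
#' `h_min` is the regression slope over octaves of `log2 max_k d(j, k)`
#' (governs the strongest singularity present); `h_max` is the slope of
#' `log2 min_k d(j, k)` with exactly-zero coefficients excluded.
#'
#' @param coeffs A `wt_coeffs` object.
#' @param j1,j2 Octave fit range (at least 3 octaves).
#' @return A one-row tibble with `h_min` and `h_max` (either may be
#'   `NA` with a warning when a scale is degenerate).
#' @export
hoelder_bounds <- function(coeffs, j1 = 1, j2 = length(coeffs$d)) {
  stopifnot(inherits(coeffs, "wt_coeffs"))
  jj <- j1:j2
  if (length(jj) < 3) stop_invalid("need at least 3 octaves in the fit range")
  mx <- numeric(0); mn <- numeric(0); jv <- integer(0)
  for (j in jj) {
    d <- coeffs$d[[j]]
    d <- d[d > 0]
    if (length(d) == 0) {
      rlang::warn(paste0("octave ", j, ": all-zero coefficients excluded"))
      next
    }
    mx <- c(mx, max(d)); mn <- c(mn, min(d)); jv <- c(jv, j)
  }
  if (length(jv) < 3) {
    rlang::warn("fewer than 3 usable octaves; Hoelder bounds undefined")
    return(tibble::tibble(h_min = NA_real_, h_max = NA_real_))
  }
  tibble::tibble(h_min = ols_fit(jv, log2(mx))$slope,
                 h_max = ols_fit(jv, log2(mn))$slope)
}

#' Wavelet adequacy check
#'
#' A sufficient condition for the analyzing wavelet to resolve the
#' regularity present in the data is `h_max < min(regularity,
#' n_vanish)` (strict inequality), together with a valid `h_min`
#' estimate.
#'
#' @param h_min,h_max Uniform Hoelder bound estimates.
#' @param n_vanish Vanishing moments of the wavelet.
#' @param regularity Regularity index of the wavelet.
#' @return A one-row tibble with the inputs, the bound, and logical
#'   `pass`.
#' @export
check_wavelet_adequacy <- function(h_min, h_max, n_vanish = 3,
                                   regularity = n_vanish) {
  bound <- min(regularity, n_vanish)
  pass <- is.finite(h_max) && is.finite(h_min) && h_max < bound
  tibble::tibble(h_min = h_min, h_max = h_max, bound = bound, pass = pass)
}

#' Full wavelet-leader multifractal analysis
#'
#' Convenience wrapper: detail coefficients, leaders, structure
#' functions, scaling function, both spectrum estimators, summary
#' features and the adequacy check, with the package defaults
#' (`db3`, symmetric q grid `-qmax..qmax` step `dq`, octaves
#' `j1..max_scale_index(N)`).
#'
#' @param x Numeric signal or signal-like object.
#' @param wavelet Analysis wavelet (default `"db3"`).
#' @param qmax,dq Extent and step of the symmetric moment grid
#'   (defaults 5 and 0.25).
#' @param j1 Finest octave of the regression range (default 1).
#' @param j2 Coarsest octave; defaults to [max_scale_index()].
#' @param method Spectrum used for the summary features: `"direct"`
#'   (weighted-moment estimator, the default) or `"legendre"`.
#' @return An object of class `mf_spectrum`: list with tibbles
#'   `spectrum` (q, zeta, alpha, f_alpha per method), `features`,
#'   `hoelder`, `adequacy`, plus `leaders` metadata.
#' @export
mf_spectrum <- function(x, wavelet = "db3", qmax = 5, dq = 0.25, j1 = 1,
                        j2 = NULL, method = c("direct", "legendre")) {
  method <- match.arg(method)
  x <- signal_values(x)
  f <- wt_filters(wavelet)
  if (is.null(j2)) j2 <- max_scale_index(length(x), f$n_vanish)
  q_grid <- seq(-qmax, qmax, by = dq)
  coeffs <- dwt_l1(x, wavelet, j2)
  leaders <- compute_leaders(coeffs)
  S <- suppressWarnings(structure_functions(leaders, q_grid))
  zeta <- scaling_function(S, j1, j2)
  leg <- legendre_spectrum(zeta[, c("q", "zeta")])
  dir <- direct_spectrum(leaders, q_grid, j1, j2)
  spec <- dplyr::left_join(
    leg %>% dplyr::rename(alpha_legendre = "alpha",
                          f_legendre = "f_alpha"),
    dir %>% dplyr::rename(alpha_direct = "alpha", f_direct = "f_alpha"),
    by = "q"
  )
  chosen <- if (method == "direct") dir else leg[, c("q", "alpha", "f_alpha")]
  features <- spectrum_features(chosen, qmax)
  hb <- suppressWarnings(hoelder_bounds(coeffs, j1, j2))
  adequacy <- check_wavelet_adequacy(hb$h_min, hb$h_max, f$n_vanish,
                                     f$regularity)
  structure(
    list(spectrum = spec, features = features, hoelder = hb,
         adequacy = adequacy, method = method, wavelet = wavelet,
         q_grid = q_grid, j1 = j1, j2 = j2, n = length(x)),
    class = "mf_spectrum"
  )
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat("<mf_spectrum>", x$wavelet, "| octaves", x$j1, "..", x$j2,
      "| method", x$method, "\n")
  print(x$features)
  invisible(x)
}

#' @rdname mf_spectrum
#' @param x An `mf_spectrum` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mf_spectrum <- function(x, ...) x$spectrum

#' @rdname mf_spectrum
#' @exportS3Method generics::glance
glance.mf_spectrum <- function(x, ...) {
  dplyr::bind_cols(x$features, x$hoelder,
                   tibble::tibble(adequate = x$adequacy$pass,
                                  j1 = x$j1, j2 = x$j2, n = x$n))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mf_spectrum <- function(object, ...) {
  cols <- if (object$method == "direct") {
    c(alpha = "alpha_direct", f = "f_direct")
  } else {
    c(alpha = "alpha_legendre", f = "f_legendre")
  }
  df <- tibble::tibble(alpha = object$spectrum[[cols["alpha"]]],
                       f = object$spectrum[[cols["f"]]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$f)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(alpha), y = expression(f(alpha)),
                  title = "Singularity spectrum")
}
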