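# Deterministic stage-structured model: eggs, larvae, pupae, adult
# females, with quadratic density-dependent larval mortality and a
# residual immature mortality forcing mu_c(t).

#' Carrying capacity of the normalized system
#'
#' Chooses the larval carrying capacity so that the per-capita
#' density-dependent mortality rate at the average larval density,
#' `mean_L^2 / kappa`, is ten times the average density-independent
#' larval mortality `mean_mu_L`; i.e. density dependence dominates
#' larval deaths by an order of magnitude.
#'
#' @param mean_L Time-average larval count of the normalized system.
#' @param mean_mu_L Time-average temperature-driven larval mortality
#'   rate (per day).
#' @return `mean_L^2 / (10 * mean_mu_L)`.
#' @export
derive_kappa <- function(mean_L, mean_mu_L) {
  if (!is.finite(mean_L) || mean_L <= 0) stop("mean_L must be positive")
  if (!is.finite(mean_mu_L) || mean_mu_L <= 0) stop("mean_mu_L must be positive")
  mean_L^2 / (10 * mean_mu_L)
}

#' Location-specific carrying capacity
#'
#' Scales the normalized-system carrying capacity by the squared initial
#' adult abundance of a location, so that each location's dynamics are
#' the normalized dynamics scaled by its initial abundance.
#'
#' @param kappa_norm Carrying capacity of the normalized system
#'   (initial abundance 1).
#' @param n0 Initial adult abundance at the location (>= 0; a location
#'   with 0 carries no population).
#' @return `kappa_norm * n0^2`, vectorized over `n0`.
#' @export
scale_kappa <- function(kappa_norm, n0) {
  stopifnot(is.finite(kappa_norm), kappa_norm > 0)
  if (any(n0 < 0)) stop("n0 must be >= 0")
  kappa_norm * n0^2
}

# Right-hand side of the stage-structured system under constant forcing.
# parms: a, d_E, d_L, d_P, mu_E, mu_L, mu_P, mu_N, mu_c, kappa, n_E.
ode_rhs <- function(t, y, p) {
  E <- y[1]; L <- y[2]; P <- y[3]; N <- y[4]
  dd <- if (is.finite(p$kappa)) L^2 / p$kappa else 0
  list(c(
    p$n_E * p$a * N / 2 - (p$d_E + p$mu_E) * E,
    p$d_E * E - (p$d_L + p$mu_L + p$mu_c + dd) * L,
    p$d_L * L - (p$d_P + p$mu_P + p$mu_c) * P,
    p$d_P * P - p$mu_N * N
  ))
}

# One-day advance with constant forcing using the Radau method.
# Restarting at each day boundary keeps step discontinuities in the
# daily forcing off the solver's interior steps.
radau_day <- function(y, rhs, parms, atol, rtol, day) {
  out <- tryCatch(
    deSolve::radau(y = y, times = c(0, 1), func = rhs, parms = parms,
                   atol = atol, rtol = rtol),
    warning = function(w) stop("solver failed on day ", day, ": ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("solver failed on day ", day, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  unname(out[nrow(out), -1])
}

# Clamp solver noise: values in (-1e-9, 0) are set to 0; anything more
# negative is a genuine failure.
clamp_noise <- function(y, day) {
  neg <- y < 0
  if (any(y < -1e-9)) {
    stop("state went negative beyond solver noise on day ", day,
         " (min ", format(min(y)), ")", call. = FALSE)
  }
  y[neg] <- 0
  y
}

#' Forward integration of the stage-structured model
#'
#' Integrates the egg/larva/pupa/adult system under daily
#' piecewise-constant forcing: the temperature-driven rates and the
#' residual mortality `mu_c` are held constant over each day and the
#' integration is restarted at every day boundary with deSolve's Radau
#' method (absolute and relative tolerance 1e-6 by default).
#'
#' @param state0 Numeric vector `c(E, L, P, N)` at day 0, all >= 0.
#' @param rates A [build_rate_series()] result covering the span.
#' @param mu_c Daily residual larval/pupal mortality series (per day,
#'   >= 0), same length as `rates` has rows.
#' @param kappa Carrying capacity (may be `Inf` to disable density
#'   dependence).
#' @param t_span Optional `c(first, last)` day index pair (0-based,
#'   relative to the first row of `rates`); defaults to the full span.
#' @param n_E Eggs laid per gonotrophic cycle.
#' @param atol,rtol Solver tolerances.
#' @return Data frame with columns `day`, `E`, `L`, `P`, `N`, one row
#'   per day from the start to the end of the span.
#' @export
integrate_forward <- function(state0, rates, mu_c, kappa, t_span = NULL,
                              n_E = 63, atol = 1e-6, rtol = 1e-6) {
  stopifnot(length(state0) == 4, all(is.finite(state0)), all(state0 >= 0))
  n <- nrow(rates)
  if (length(mu_c) != n) stop("mu_c must have one entry per rate-series day")
  if (any(!is.finite(mu_c)) || any(mu_c < 0)) {
    stop("mu_c must be finite and >= 0 elementwise")
  }
  if (is.null(t_span)) t_span <- c(0, n - 1)
  i0 <- t_span[1]; i1 <- t_span[2]
  if (i0 < 0 || i1 > n - 1 || i1 < i0) stop("t_span outside the rate series")

  days <- i0:i1
  traj <- matrix(NA_real_, nrow = length(days), ncol = 4,
                 dimnames = list(NULL, c("E", "L", "P", "N")))
  y <- as.numeric(state0)
  traj[1, ] <- y
  if (length(days) > 1) {
    for (k in seq_len(length(days) - 1)) {
      i <- days[k] + 1L # row of `rates` giving the forcing on [day, day+1)
      p <- list(a = rates$a[i], d_E = rates$d_E[i], d_L = rates$d_L[i],
                d_P = rates$d_P[i], mu_E = rates$mu_E[i], mu_L = rates$mu_L[i],
                mu_P = rates$mu_P[i], mu_N = rates$mu_N[i],
                mu_c = mu_c[i], kappa = kappa, n_E = n_E)
      y <- clamp_noise(radau_day(y, ode_rhs, p, atol, rtol, days[k]), days[k])
      traj[k + 1, ] <- y
    }
  }
  out <- data.frame(day = days, traj)
  class(out) <- c("ode_trajectory", "data.frame")
  out
}
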