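# Shared fixtures, built in code at load time.

# A constant rate series for analytic comparisons.
constant_rates <- function(n, a = 0.26, d_E = 0.27, d_L = 0.23, d_P = 0.35,
                           mu_E = 0.011, mu_L = 0.01, mu_P = 0.01,
                           mu_N = 0.091) {
  out <- data.frame(day = 0:(n - 1), a = a, d_E = d_E, d_L = d_L, d_P = d_P,
                    mu_E = mu_E, mu_L = mu_L, mu_P = mu_P, mu_N = mu_N)
  class(out) <- c("rate_series", "data.frame")
  out
}

# Closed-form positive equilibrium of the stage-structured system under
# constant rates and constant mu_c (independent derivation: solve the
# four balance equations, which reduce to a single quadratic in N).
analytic_equilibrium <- function(r, mu_c, kappa, n_E = 63) {
  e1 <- n_E * r$a[1] / 2 / (r$d_E[1] + r$mu_E[1])          # E = e1 N
  p1 <- r$mu_N[1] / r$d_P[1]                               # P = p1 N
  l1 <- (r$d_P[1] + r$mu_P[1] + mu_c) * p1 / r$d_L[1]      # L = l1 N
  c1 <- r$d_L[1] + r$mu_L[1] + mu_c
  # d_E e1 N = (c1 + (l1 N)^2 / kappa) l1 N
  N2 <- kappa * (r$d_E[1] * e1 - c1 * l1) / l1^3
  if (N2 <= 0) stop("no positive equilibrium for these rates")
  N <- sqrt(N2)
  c(E = e1 * N, L = l1 * N, P = p1 * N, N = N)
}

# A small calibrated synthetic scenario shared by several test files.
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synth_spec(n_buildings = 250, n_days = 330, seed = 402)
      temps <- generate_temperature(spec)
      city <- generate_city(spec)
      target <- generate_target_abundance(city, spec)
      calib <- calibrate(target$series$N_city, temps)
      cache <<- list(spec = spec, temps = temps, city = city,
                     target = target, calib = calib)
    }
    cache
  }
})

# The full default-scale scenario (2,000 buildings, ~1e5 adults,
# 1,095 days), shared by the acceptance checks that require it.
paper_scale_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synth_spec()
      temps <- generate_temperature(spec)
      city <- generate_city(spec)
      target <- generate_target_abundance(city, spec)
      calib <- calibrate(target$series$N_city, temps)
      cache <<- list(spec = spec, temps = temps, city = city,
                     target = target, calib = calib)
    }
    cache
  }
})

# A dense city: all pairwise distances below the movement radius.
dense_city <- function(n = 30, side = 60) {
  structure(list(
    buildings = data.frame(id = seq_len(n),
                           x = runif(n, 0, side), y = runif(n, 0, side),
                           zone = rep_len(1:3, n)),
    extent = side
  ), class = "city")
}

# Minimal constant forcing for direct ABM experiments.
constant_forcing <- function(n_days, rates = constant_rates(n_days),
                             mu_c = 0, kappa_norm = 1e12,
                             imm0 = c(E = 0, L = 0, P = 0), n_E = 63) {
  list(rates = rates, mu_c = rep(mu_c, n_days), kappa_norm = kappa_norm,
       n_E = n_E, E = imm0[["E"]], L = imm0[["L"]], P = imm0[["P"]])
}
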