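# Synthetic-city generator: building map with contiguous zones, a
# seasonal equatorial temperature series, and a separable (rank-1)
# space-by-time target abundance surface standing in for a statistical
# abundance reconstruction.

#' Specification of a synthetic city
#'
#' Collects every knob of the synthetic fixtures. Defaults emulate a
#' desk-scale analogue of an equatorial Amazonian city: about 2,000
#' buildings averaging 50 adult females each (1e5 adults city-wide),
#' 35 administrative zones, air temperature near 26 C with a mild
#' seasonal cycle, and a rank-1 abundance surface with two spatial
#' hotspots (southwest and northeast).
#'
#' @param n_buildings Number of buildings.
#' @param extent Side of the square spatial extent, metres.
#' @param n_zones Number of contiguous zones.
#' @param n_days Length of the daily series.
#' @param seed Integer seed fixing every draw.
#' @param t_annual_mean Annual mean air temperature, C.
#' @param t_seasonal_amp Seasonal (annual sinusoid) amplitude, C.
#' @param t_offset_max,t_offset_min Mean diurnal offsets of the daily
#'   max above / min below the mean, C.
#' @param t_diurnal_sd Day-to-day jitter of the diurnal offsets, C.
#' @param t_noise_sd Innovation s.d. of the AR(1) noise on the daily
#'   mean, C.
#' @param t_noise_rho AR(1) autocorrelation of that noise.
#' @param mean_adults Mean initial adult females per building.
#' @param abundance_amp Amplitude of the annual cycle of the city-wide
#'   series (fraction of its mean).
#' @param abundance_amp2 Amplitude of a semi-annual harmonic.
#' @param weights_sdlog Log-scale s.d. of the lognormal spatial weights.
#' @param weights_corr_len Spatial correlation length of the log-weight
#'   field, metres. The abundance surface being emulated is smooth at
#'   the zone scale; spatially white weights would misrepresent it.
#' @param hotspots Matrix (or list of `c(x, y)`) of hotspot centres in
#'   fractions of the extent.
#' @param hotspot_width Gaussian s.d. of hotspot boosts, fraction of the
#'   extent.
#' @param hotspot_boost Peak multiplicative boost at a hotspot centre.
#' @param equal_baseline If `TRUE`, every building's weight is set to
#'   the maximum weight (equal-baseline counterfactual scenario).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_buildings = 2000, extent = 2000, n_zones = 35,
                       n_days = 1095, seed = 20260101,
                       t_annual_mean = 26.4, t_seasonal_amp = 1.2,
                       t_offset_max = 5.3, t_offset_min = 4.2,
                       t_diurnal_sd = 0.3, t_noise_sd = 0.3,
                       t_noise_rho = 0.8,
                       mean_adults = 50, abundance_amp = 0.4,
                       abundance_amp2 = 0.1, weights_sdlog = 0.6,
                       weights_corr_len = 2000,
                       hotspots = rbind(c(0.2, 0.2), c(0.8, 0.8)),
                       hotspot_width = 0.30, hotspot_boost = 2,
                       equal_baseline = FALSE) {
  spec <- as.list(environment())
  stopifnot(n_buildings >= 1, extent > 0, n_zones >= 1, n_days >= 3,
            mean_adults > 0, abundance_amp >= 0, abundance_amp + abundance_amp2 < 1,
            t_offset_max > 0, t_offset_min > 0)
  if (n_zones > n_buildings) stop("n_zones must not exceed n_buildings")
  structure(spec, class = "synth_spec")
}

#' Generate a synthetic building map
#'
#' Places buildings uniformly at random in the square extent and assigns
#' contiguous zones by nearest zone-seed (seeds on a jittered regular
#' grid). Any zone left empty steals the building nearest its seed, so
#' every zone is non-empty whenever `n_zones <= n_buildings`.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `city` with element `buildings` (data frame
#'   `id`, `x`, `y`, `zone`) and `extent`.
#' @export
generate_city <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_buildings
  x <- runif(n, 0, spec$extent)
  y <- runif(n, 0, spec$extent)

  nc <- ceiling(sqrt(spec$n_zones))
  nr <- ceiling(spec$n_zones / nc)
  cell <- expand.grid(cx = seq_len(nc), cy = seq_len(nr))[seq_len(spec$n_zones), ]
  sx <- (cell$cx - 0.5) / nc * spec$extent + runif(spec$n_zones, -0.1, 0.1) * spec$extent / nc
  sy <- (cell$cy - 0.5) / nr * spec$extent + runif(spec$n_zones, -0.1, 0.1) * spec$extent / nr
  d2 <- outer(x, sx, "-")^2 + outer(y, sy, "-")^2
  zone <- max.col(-d2)
  for (z in seq_len(spec$n_zones)) {
    if (!any(zone == z)) {
      free <- which(tabulate(zone, spec$n_zones)[zone] > 1)
      zone[free[which.min(d2[free, z])]] <- z
    }
  }
  structure(list(
    buildings = data.frame(id = seq_len(n), x = x, y = y, zone = zone),
    extent = spec$extent
  ), class = "city")
}

#' Generate a synthetic daily temperature series
#'
#' Daily mean = annual mean + seasonal sinusoid + AR(1) noise; the daily
#' max and min are the mean plus/minus positive diurnal offsets with
#' half-normal jitter, so min <= mean <= max holds by construction.
#'
#' @param spec A [synth_spec()].
#' @param cfg A [thermal_config()] used to derive water temperatures.
#' @return A [temperature_series()].
#' @export
generate_temperature <- function(spec, cfg = thermal_config()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1L)
  day <- 0:(spec$n_days - 1)
  season <- spec$t_seasonal_amp * sin(2 * pi * day / 365.25)
  eps <- numeric(spec$n_days)
  innov <- rnorm(spec$n_days, 0, spec$t_noise_sd)
  for (t in seq_len(spec$n_days)) {
    eps[t] <- if (t == 1) innov[1] else spec$t_noise_rho * eps[t - 1] + innov[t]
  }
  t_mean <- spec$t_annual_mean + season + eps
  t_max <- t_mean + spec$t_offset_max + abs(rnorm(spec$n_days, 0, spec$t_diurnal_sd))
  t_min <- t_mean - spec$t_offset_min - abs(rnorm(spec$n_days, 0, spec$t_diurnal_sd))
  df <- data.frame(day = day,
                   date = as.Date("2000-01-01") + day,
                   t_mean = t_mean, t_min = t_min, t_max = t_max)
  temperature_series(df, cfg)
}

#' Generate a separable target abundance surface
#'
#' Builds `N(x, t) = w(x) S(t)`: lognormal per-building weights boosted
#' near the configured hotspot centres and rescaled so their mean equals
#' `mean_adults`, and a strictly positive seasonal city-wide signal
#' normalized to `S(0) = 1`. The surface is rank 1 by construction
#' (space and time enter separately, never jointly).
#'
#' @param city A [generate_city()] result.
#' @param spec The same [synth_spec()].
#' @return A list of class `target_abundance` with `weights`
#'   (per-building initial adults), `S` (city-wide seasonal factor,
#'   `S[1] = 1`), `series` (data frame `day`, `N_city`), and `n_days`.
#' @export
generate_target_abundance <- function(city, spec) {
  stopifnot(inherits(city, "city"), inherits(spec, "synth_spec"))
  set.seed(spec$seed + 2L)
  b <- city$buildings
  w <- exp(spec$weights_sdlog * gaussian_field(b$x, b$y, spec$extent,
                                               spec$weights_corr_len))
  hs <- spec$hotspots
  if (is.list(hs)) hs <- do.call(rbind, hs)
  sig <- spec$hotspot_width * spec$extent
  for (k in seq_len(nrow(hs))) {
    d2 <- (b$x - hs[k, 1] * spec$extent)^2 + (b$y - hs[k, 2] * spec$extent)^2
    w <- w * (1 + spec$hotspot_boost * exp(-d2 / (2 * sig^2)))
  }
  w <- w / mean(w) * spec$mean_adults
  if (spec$equal_baseline) w[] <- max(w)

  day <- 0:(spec$n_days - 1)
  S <- 1 + spec$abundance_amp * sin(2 * pi * day / 365.25) +
    spec$abundance_amp2 * sin(4 * pi * day / 365.25 + 0.7)
  S <- S / S[1]
  stopifnot(all(S > 0))
  structure(list(
    weights = w,
    S = S,
    series = data.frame(day = day, N_city = sum(w) * S),
    n_days = spec$n_days
  ), class = "target_abundance")
}

# Smooth unit-variance Gaussian field at the given coordinates: iid
# standard-normal values on a coarse grid with spacing ~ corr_len,
# bilinearly interpolated. Marginal variance is restandardized so the
# interpolated field has unit variance at every point.
gaussian_field <- function(x, y, extent, corr_len) {
  ng <- max(2L, ceiling(extent / corr_len) + 1L)
  z <- matrix(rnorm(ng * ng), ng, ng)
  gx <- pmin(pmax(x / extent, 0), 1) * (ng - 1) + 1
  gy <- pmin(pmax(y / extent, 0), 1) * (ng - 1) + 1
  ix <- pmin(floor(gx), ng - 1); fx <- gx - ix
  iy <- pmin(floor(gy), ng - 1); fy <- gy - iy
  v <- z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    z[cbind(ix + 1, iy)] * fx * (1 - fy) +
    z[cbind(ix, iy + 1)] * (1 - fx) * fy +
    z[cbind(ix + 1, iy + 1)] * fx * fy
  sdv <- sqrt((1 - fx)^2 * (1 - fy)^2 + fx^2 * (1 - fy)^2 +
                (1 - fx)^2 * fy^2 + fx^2 * fy^2)
  v / sdv
}

#' Full building-by-day abundance matrix
#'
#' Materializes the separable surface `w(x) S(t)` as an explicit matrix
#' (buildings in rows, days in columns). Exactly rank 1.
#'
#' @param target A [generate_target_abundance()] result.
#' @return Numeric matrix `n_buildings x n_days`.
#' @export
abundance_matrix <- function(target) {
  stopifnot(inherits(target, "target_abundance"))
  outer(target$weights, target$S)
}
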