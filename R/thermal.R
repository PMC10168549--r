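# Temperature-dependent vital rates: development, gonotrophic cycle,
# stage mortalities, and the air-to-water temperature conversion.

#' Load a thermal-rate configuration
#'
#' Reads a hierarchical YAML configuration describing the temperature
#' responses of all eight vital rates, the eggs-per-gonotrophic-cycle
#' constant, the container sun-exposure fraction and the air-to-water
#' temperature regressions. With no argument, the default configuration
#' shipped with the package is loaded.
#'
#' @param path Path to a YAML file, or `NULL` for the shipped default.
#' @return A validated list of class `thermal_config`.
#' @export
thermal_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thermal_default.yaml", package = "aedesfuse")
  }
  cfg <- yaml::read_yaml(path)
  validate_thermal_config(cfg)
}

#' @rdname thermal_config
#' @param cfg A candidate configuration list.
#' @export
validate_thermal_config <- function(cfg) {
  stopifnot(is.list(cfg))
  need <- c("n_eggs_per_cycle", "sun_exposure", "development",
            "gonotrophic", "mortality", "water")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("thermal config is missing blocks: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(cfg$n_eggs_per_cycle) || cfg$n_eggs_per_cycle <= 0) {
    stop("n_eggs_per_cycle must be a positive number")
  }
  if (cfg$sun_exposure < 0 || cfg$sun_exposure > 1) {
    stop("sun_exposure must lie in [0, 1]")
  }
  for (stage in c("egg", "larva", "pupa")) {
    check_enthalpy_params(cfg$development[[stage]], paste0("development$", stage))
  }
  check_enthalpy_params(cfg$gonotrophic, "gonotrophic")
  for (stage in c("egg", "larva", "pupa", "adult")) {
    check_mortality_params(cfg$mortality[[stage]], paste0("mortality$", stage))
  }
  for (comp in c("mean", "min", "max")) {
    w <- cfg$water[[comp]]
    if (is.null(w) || !all(c("intercept", "slope", "sun") %in% names(w))) {
      stop("water$", comp, " must have intercept, slope and sun coefficients")
    }
    if (w$slope < 0) stop("water$", comp, " slope must be nonnegative")
  }
  structure(cfg, class = "thermal_config")
}

check_enthalpy_params <- function(p, label) {
  need <- c("rho25", "deltaH_A", "deltaH_H", "T_half")
  if (is.null(p) || !all(need %in% names(p))) {
    stop(label, " must supply ", paste(need, collapse = ", "))
  }
  if (!is.finite(p$rho25) || p$rho25 < 0) stop(label, "$rho25 must be >= 0")
  if (p$deltaH_H != 0 && p$T_half <= 0) stop(label, "$T_half must be positive")
  invisible(p)
}

check_mortality_params <- function(p, label) {
  need <- c("base", "thr_hi", "coef_hi", "scale_hi", "thr_lo", "coef_lo", "scale_lo")
  if (is.null(p) || !all(need %in% names(p))) {
    stop(label, " must supply ", paste(need, collapse = ", "))
  }
  if (p$base < 0) stop(label, "$base must be >= 0")
  if (p$coef_hi < 0 || p$coef_lo < 0) stop(label, " response coefficients must be >= 0")
  if (p$scale_hi <= 0 || p$scale_lo <= 0) stop(label, " response scales must be > 0")
  if (p$thr_lo > p$thr_hi) stop(label, ": thr_lo must not exceed thr_hi")
  invisible(p)
}

# Gas constant of the enthalpy model, cal / (mol K).
.R_CAL <- 1.987

#' Enthalpy-model development rate
#'
#' Sharpe & DeMichele (Schoolfield) temperature response used for the
#' egg, larval and pupal development rates and the gonotrophic-cycle
#' rate: `rho25 * (T/298) * exp(dHA/R (1/298 - 1/T))` divided by the
#' high-temperature inhibition term `1 + exp(dHH/R (1/T_half - 1/T))`,
#' with `T` in Kelvin. A `deltaH_H` of exactly 0 disables inhibition.
#'
#' @param t_water Temperature in degrees C (water temperature for the
#'   immature stages, air temperature for the gonotrophic cycle).
#' @param params A list with `rho25`, `deltaH_A`, `deltaH_H`, `T_half`.
#' @return Development rate per day, vectorized over `t_water`.
#' @export
development_rate <- function(t_water, params) {
  check_enthalpy_params(params, "params")
  if (any(!is.finite(t_water))) stop("non-finite temperature")
  TK <- t_water + 273.15
  num <- params$rho25 * (TK / 298) *
    exp(params$deltaH_A / .R_CAL * (1 / 298 - 1 / TK))
  if (params$deltaH_H == 0) {
    denom <- 1
  } else {
    denom <- 1 + exp(params$deltaH_H / .R_CAL * (1 / params$T_half - 1 / TK))
  }
  num / denom
}

#' Threshold-exponential stage mortality rate
#'
#' Baseline per-day mortality plus a continuous exponential response
#' above a high-temperature threshold (and, symmetrically, below a
#' low-temperature threshold, inert in equatorial climates where the
#' daily minimum never reaches it). For daily forcing the relevant
#' argument is the day's maximum temperature.
#'
#' @param t_max_relevant Daily maximum temperature, degrees C (water for
#'   immature stages, air for adults).
#' @param params A list with `base`, `thr_hi`, `coef_hi`, `scale_hi`,
#'   `thr_lo`, `coef_lo`, `scale_lo`.
#' @return Mortality rate per day, vectorized over the temperature.
#' @export
mortality_rate <- function(t_max_relevant, params) {
  check_mortality_params(params, "params")
  if (any(!is.finite(t_max_relevant))) stop("non-finite temperature")
  t <- t_max_relevant
  hi <- ifelse(t > params$thr_hi,
               params$coef_hi * (exp((t - params$thr_hi) / params$scale_hi) - 1), 0)
  lo <- ifelse(t < params$thr_lo,
               params$coef_lo * (exp((params$thr_lo - t) / params$scale_lo) - 1), 0)
  params$base + hi + lo
}

#' Air-to-water temperature conversion
#'
#' Maps the daily air-temperature triple (min, mean, max) to the
#' container-water triple through per-component linear regressions with
#' a sun-exposure term. The returned triple is forced to satisfy
#' min <= mean <= max.
#'
#' @param t_min,t_mean,t_max Air temperatures in degrees C (vectors of
#'   equal length).
#' @param cfg A [thermal_config()].
#' @return A data frame with columns `tw_min`, `tw_mean`, `tw_max`.
#' @export
water_temperature <- function(t_min, t_mean, t_max, cfg = thermal_config()) {
  if (any(!is.finite(c(t_min, t_mean, t_max)))) {
    stop("non-finite air temperature")
  }
  if (any(t_min > t_mean + 1e-9) || any(t_mean > t_max + 1e-9)) {
    stop("air temperatures must satisfy min <= mean <= max on every day")
  }
  s <- cfg$sun_exposure
  lin <- function(w, t) w$intercept + w$slope * t + w$sun * s
  tw_mean <- lin(cfg$water$mean, t_mean)
  tw_min <- pmin(lin(cfg$water$min, t_min), tw_mean)
  tw_max <- pmax(lin(cfg$water$max, t_max), tw_mean)
  data.frame(tw_min = tw_min, tw_mean = tw_mean, tw_max = tw_max)
}

#' Construct a daily temperature series
#'
#' Validates a daily air-temperature table and derives the water triple.
#' Days must be contiguous and each day must satisfy min <= mean <= max.
#'
#' @param df Data frame with columns `day` (0-based integer index),
#'   `date` (Date or ISO-8601 string), `t_mean`, `t_min`, `t_max`.
#' @param cfg A [thermal_config()] used for the water conversion.
#' @return The input with water columns `tw_min`, `tw_mean`, `tw_max`
#'   appended; class `temperature_series`.
#' @export
temperature_series <- function(df, cfg = thermal_config()) {
  need <- c("day", "date", "t_mean", "t_min", "t_max")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("temperature table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) < 1) stop("empty temperature table")
  if (!all(df$day == seq(df$day[1], length.out = nrow(df)))) {
    stop("temperature series has a gap: day index must be contiguous")
  }
  if (any(!is.finite(df$t_mean)) || any(!is.finite(df$t_min)) || any(!is.finite(df$t_max))) {
    stop("non-finite air temperature")
  }
  if (any(df$t_min > df$t_mean + 1e-9) || any(df$t_mean > df$t_max + 1e-9)) {
    stop("air temperatures must satisfy min <= mean <= max on every day")
  }
  df$date <- as.Date(df$date)
  tw <- water_temperature(df$t_min, df$t_mean, df$t_max, cfg)
  out <- cbind(df[need], tw)
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Daily vital-rate series from a temperature series
#'
#' Evaluates all eight vital rates day by day: development rates
#' (`d_E`, `d_L`, `d_P`) at the mean water temperature, the gonotrophic
#' rate `a` at the mean air temperature, immature mortalities
#' (`mu_E`, `mu_L`, `mu_P`) at the maximum water temperature, and the
#' adult mortality `mu_N` at the maximum air temperature.
#'
#' @param temps A [temperature_series()].
#' @param cfg A [thermal_config()].
#' @return Data frame of class `rate_series` with columns `day`, `a`,
#'   `d_E`, `d_L`, `d_P`, `mu_E`, `mu_L`, `mu_P`, `mu_N`.
#' @export
build_rate_series <- function(temps, cfg = thermal_config()) {
  if (!inherits(temps, "temperature_series")) {
    temps <- temperature_series(temps, cfg)
  }
  out <- data.frame(
    day = temps$day,
    a = development_rate(temps$t_mean, cfg$gonotrophic),
    d_E = development_rate(temps$tw_mean, cfg$development$egg),
    d_L = development_rate(temps$tw_mean, cfg$development$larva),
    d_P = development_rate(temps$tw_mean, cfg$development$pupa),
    mu_E = mortality_rate(temps$tw_max, cfg$mortality$egg),
    mu_L = mortality_rate(temps$tw_max, cfg$mortality$larva),
    mu_P = mortality_rate(temps$tw_max, cfg$mortality$pupa),
    mu_N = mortality_rate(temps$t_max, cfg$mortality$adult)
  )
  stopifnot(all(is.finite(as.matrix(out))), all(out[-1] >= 0))
  class(out) <- c("rate_series", "data.frame")
  out
}
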