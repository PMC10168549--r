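# CSV input/output for all standard artifacts. Numeric columns are
# written with 17 significant digits so that read(write(x)) returns the
# exact doubles that were written.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(what, " file is malformed: missing column(s) ",
         paste(missing, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "))
  }
  invisible(df)
}

#' Read and write the standard CSV artifacts
#'
#' Readers validate the schema and rebuild the in-memory classes;
#' writers emit plain CSV with full-precision numerics, so a write/read
#' round trip reproduces the object exactly.
#'
#' @param path File path.
#' @param city,temps,target,calib,schedule,census Objects to write.
#' @param cfg A [thermal_config()] for re-deriving water temperatures
#'   on read.
#' @name aedesfuse_io
NULL

#' @rdname aedesfuse_io
#' @export
write_buildings_csv <- function(city, path) {
  write_table(city$buildings[c("id", "x", "y", "zone")], path)
}

#' @rdname aedesfuse_io
#' @export
read_buildings_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("id", "x", "y", "zone"), "buildings")
  if (anyDuplicated(df$id)) stop("buildings file has duplicate ids")
  structure(list(buildings = df, extent = max(df$x, df$y)), class = "city")
}

#' @rdname aedesfuse_io
#' @export
write_temperature_csv <- function(temps, path, water = FALSE) {
  cols <- c("date", "t_mean", "t_min", "t_max")
  if (water) cols <- c(cols, "tw_mean", "tw_min", "tw_max")
  write_table(as.data.frame(temps)[cols], path)
}

#' @rdname aedesfuse_io
#' @export
read_temperature_csv <- function(path, cfg = thermal_config()) {
  df <- utils::read.csv(path)
  check_columns(df, c("date", "t_mean", "t_min", "t_max"), "temperature")
  df$day <- seq_len(nrow(df)) - 1L
  temperature_series(df, cfg)
}

#' @rdname aedesfuse_io
#' @export
write_abundance_csv <- function(target, path) {
  weights_path <- sub("(\\.csv)?$", "_weights.csv", path)
  write_table(target$series, path)
  write_table(data.frame(building = seq_along(target$weights),
                         weight = target$weights), weights_path)
  invisible(c(path, weights_path))
}

#' @rdname aedesfuse_io
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("day", "N_city"), "abundance")
  weights_path <- sub("(\\.csv)?$", "_weights.csv", path)
  w <- NULL
  if (file.exists(weights_path)) {
    wdf <- utils::read.csv(weights_path)
    check_columns(wdf, c("building", "weight"), "abundance weights")
    w <- wdf$weight
  }
  structure(list(weights = w,
                 S = df$N_city / df$N_city[1],
                 series = df,
                 n_days = nrow(df)), class = "target_abundance")
}

#' @rdname aedesfuse_io
#' @export
write_calibration_csv <- function(calib, path) {
  sidecar <- sub("(\\.csv)?$", ".json", path)
  df <- data.frame(
    day = seq_along(calib$mu_c) - 1L,
    mu_c = calib$mu_c,
    E = calib$E, L = calib$L, P = calib$P,
    N_reconstructed = calib$N_reconstructed,
    clamped_P = calib$clamp_flags$P,
    clamped_L = calib$clamp_flags$L,
    clamped_mu_c = calib$clamp_flags$mu_c
  )
  write_table(df, path)
  jsonlite::write_json(
    list(kappa_norm = calib$kappa_norm, rmsd_self = calib$rmsd_self,
         n_E = calib$n_E, scale = calib$scale,
         burnin_days = calib$burnin_days),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' @rdname aedesfuse_io
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("day", "mu_c", "E", "L", "P", "N_reconstructed",
                      "clamped_P", "clamped_L", "clamped_mu_c"),
                "calibration")
  sidecar <- sub("(\\.csv)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(list(
    mu_c = df$mu_c, kappa_norm = meta$kappa_norm,
    E = df$E, L = df$L, P = df$P,
    N_reconstructed = df$N_reconstructed,
    N_forward = NULL,
    clamp_flags = data.frame(P = df$clamped_P, L = df$clamped_L,
                             mu_c = df$clamped_mu_c),
    burnin_days = meta$burnin_days,
    rmsd_self = meta$rmsd_self,
    rates = NULL,
    n_E = meta$n_E,
    scale = meta$scale
  ), class = "calibration_result")
}

#' @rdname aedesfuse_io
#' @export
write_schedule_csv <- function(schedule, path) {
  write_table(as.data.frame(schedule), path)
}

#' @rdname aedesfuse_io
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("day", "building", "id", "round", "treated"), "schedule")
  class(df) <- c("spray_schedule", "data.frame")
  df
}

#' @rdname aedesfuse_io
#' @export
write_census_csv <- function(census, path) {
  long <- data.frame(
    day = rep(seq_len(nrow(census)) - 1L, ncol(census)),
    age = rep(as.integer(colnames(census)), each = nrow(census)),
    count = as.vector(census)
  )
  write_table(long[long$count > 0, ], path)
}

#' @rdname aedesfuse_io
#' @export
read_census_csv <- function(path, n_days = NULL, max_age = NULL) {
  df <- utils::read.csv(path)
  check_columns(df, c("day", "age", "count"), "census")
  if (is.null(n_days)) n_days <- max(df$day) + 1L
  if (is.null(max_age)) max_age <- max(df$age)
  m <- matrix(0L, nrow = n_days, ncol = max_age + 1,
              dimnames = list(NULL, 0:max_age))
  m[cbind(df$day + 1L, df$age + 1L)] <- df$count
  m
}

#' @rdname aedesfuse_io
#' @export
write_trajectory_csv <- function(traj, path) {
  write_table(as.data.frame(traj)[c("day", "E", "L", "P", "N")], path)
}
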