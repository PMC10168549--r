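# Spatially explicit stochastic simulation: deterministic per-building
# immature stages, individual adult females with stochastic emergence,
# death and movement, forced by the calibrated residual mortality.

#' Convert a daily rate to a daily probability
#'
#' `prob = 1 - exp(-rate)`; the survival complement composes correctly
#' across days (two days at rates a and b give the same survival as one
#' day at a + b).
#'
#' @param rate Non-negative daily rate(s).
#' @return Probability in `[0, 1)`.
#' @export
rate_to_prob <- function(rate) {
  if (any(rate < 0)) stop("rate must be >= 0")
  1 - exp(-rate)
}

#' Neighbor index within the movement radius
#'
#' For each building, all other buildings strictly within the given
#' Euclidean radius. Implemented with a grid-bucket sweep so large
#' cities do not require an all-pairs distance matrix. The relation is
#' symmetric and excludes the building itself.
#'
#' @param city A `city` (list with `buildings` data frame `id, x, y`).
#' @param radius Movement radius in metres.
#' @param wrap `NULL` for plane geometry, or the side of a periodic
#'   (torus) domain. Synthetic cities are generated as periodic domains
#'   so that a desk-scale city emulates the bulk of a much larger one
#'   instead of being dominated by its own edges.
#' @return A list of class `neighbor_index` with flat compressed
#'   storage: `nbr` (building row indices), `ptr` (0-based offsets,
#'   length `n + 1`), `count` (neighbors per building), and the
#'   `radius`.
#' @export
build_neighbor_index <- function(city, radius = 100, wrap = NULL) {
  b <- city$buildings
  n <- nrow(b)
  if (!is.null(wrap)) {
    stopifnot(wrap > 2 * radius)
    nbrs <- vector("list", n)
    wdist2 <- function(d, span) {
      d <- abs(d)
      pmin(d, span - d)^2
    }
    for (lo in seq(1, n, by = 512)) {
      hi <- min(lo + 511, n)
      d2 <- outer(b$x[lo:hi], b$x, function(p, q) wdist2(p - q, wrap)) +
        outer(b$y[lo:hi], b$y, function(p, q) wdist2(p - q, wrap))
      for (i in lo:hi) {
        hit <- which(d2[i - lo + 1, ] < radius^2)
        nbrs[[i]] <- hit[hit != i]
      }
    }
    count <- lengths(nbrs)
    return(structure(list(nbr = unlist(nbrs, use.names = FALSE),
                          ptr = c(0L, cumsum(count)), count = count,
                          radius = radius), class = "neighbor_index"))
  }
  cx <- floor(b$x / radius)
  cy <- floor(b$y / radius)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  nbrs <- vector("list", n)
  for (cell in cells) {
    kx <- cx[cell[1]]; ky <- cy[cell[1]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k2 <- paste(kx + dx, ky + dy)
      if (!is.null(cells[[k2]])) cand <- c(cand, cells[[k2]])
    }
    if (length(cand) == 0) next
    d2 <- outer(b$x[cell], b$x[cand], "-")^2 + outer(b$y[cell], b$y[cand], "-")^2
    within <- d2 < radius^2
    for (i in seq_along(cell)) {
      hit <- cand[within[i, ]]
      nbrs[[cell[i]]] <- hit[hit != cell[i]]
    }
  }
  count <- lengths(nbrs)
  structure(list(
    nbr = unlist(nbrs, use.names = FALSE),
    ptr = c(0L, cumsum(count)),
    count = count,
    radius = radius
  ), class = "neighbor_index")
}

# Advance the per-building immature subsystem one day with fixed adult
# counts, by classical RK4 with enough substeps for the stiffest
# per-capita loss rate present that day.
advance_immatures <- function(E, L, P, A, r, mu_c, kappa, n_E) {
  dd_rate <- function(L) ifelse(kappa > 0, L * L / kappa, 0)
  rhs <- function(E, L, P) {
    dd <- dd_rate(L)
    list(dE = n_E * r$a * A / 2 - (r$d_E + r$mu_E) * E,
         dL = r$d_E * E - (r$d_L + r$mu_L + mu_c + dd) * L,
         dP = r$d_L * L - (r$d_P + r$mu_P + mu_c) * P)
  }
  lmax <- max(r$d_E + r$mu_E, r$d_P + r$mu_P + mu_c,
              r$d_L + r$mu_L + mu_c + max(dd_rate(L), 0))
  n_sub <- max(4L, ceiling(1.5 * lmax))
  h <- 1 / n_sub
  for (s in seq_len(n_sub)) {
    k1 <- rhs(E, L, P)
    k2 <- rhs(E + h / 2 * k1$dE, L + h / 2 * k1$dL, P + h / 2 * k1$dP)
    k3 <- rhs(E + h / 2 * k2$dE, L + h / 2 * k2$dL, P + h / 2 * k2$dP)
    k4 <- rhs(E + h * k3$dE, L + h * k3$dL, P + h * k3$dP)
    E <- E + h / 6 * (k1$dE + 2 * k2$dE + 2 * k3$dE + k4$dE)
    L <- L + h / 6 * (k1$dL + 2 * k2$dL + 2 * k3$dL + k4$dL)
    P <- P + h / 6 * (k1$dP + 2 * k2$dP + 2 * k3$dP + k4$dP)
  }
  list(E = pmax(E, 0), L = pmax(L, 0), P = pmax(P, 0))
}

#' Initialize the agent-based model state
#'
#' Sets each building's immature stages to the normalized calibrated
#' values scaled by its initial adult abundance, its carrying capacity
#' to [scale_kappa()] of that abundance, and places initial adults by
#' stochastic rounding of the (generally non-integer) abundance, all at
#' age 0.
#'
#' @param city A `city`.
#' @param forcing A `calibration_result` (or a list with `kappa_norm`
#'   and normalized initial immatures `E`, `L`, `P`).
#' @param N0 Per-building initial adult abundance (length =
#'   number of buildings).
#' @return A list of class `abm_state`: `E`, `L`, `P`, `kappa`
#'   (per-building), `adult_b`, `adult_age` (one entry per adult),
#'   `day`.
#' @export
abm_init <- function(city, forcing, N0) {
  n_b <- nrow(city$buildings)
  stopifnot(length(N0) == n_b, all(N0 >= 0))
  imm0 <- c(forcing$E[1], forcing$L[1], forcing$P[1])
  base <- floor(N0)
  counts <- as.integer(base + (runif(n_b) < (N0 - base)))
  structure(list(
    E = N0 * imm0[1],
    L = N0 * imm0[2],
    P = N0 * imm0[3],
    kappa = forcing$kappa_norm * N0^2,
    adult_b = rep(seq_len(n_b), counts),
    adult_age = integer(sum(counts)),
    day = 0L
  ), class = "abm_state")
}

#' Advance the agent-based model by one day
#'
#' Event order within the day: (1) advance the deterministic immature
#' stages (egg input from each building's current integer adult count);
#' (2) draw emergents per building as Poisson with rate `d_P P` and add
#' them as age-0 adults (the deterministic P is not decremented by the
#' draw); (3) each adult dies with probability
#' `1 - exp(-(mu_N + spray increment))`; same-day emergents are exposed
#' for half a day (probability `1 - exp(-rate/2)`), since emergence
#' occurs mid-day on average -- full-day exposure of emergents would
#' bias the adult inflow low relative to the continuous-time model;
#' (4) each survivor moves with the daily movement probability to a
#' uniformly chosen neighboring building (staying put if it has none);
#' (5) survivors that existed before today age by one day, emergents
#' stay age 0.
#'
#' @param state An `abm_state`.
#' @param rates_day One row of a [build_rate_series()] data frame.
#' @param mu_c_day Residual immature mortality for the day.
#' @param spray_inc Per-building added adult mortality (per day; scalar
#'   0 when no campaign is active).
#' @param cfg List with `nbr` (a [build_neighbor_index()]), `n_E`, and
#'   `move_prob`.
#' @return The advanced `abm_state`, with a `diag` list (`n_emerged`,
#'   `n_died`, `n_moved`, `adult_days`) attached.
#' @export
step_day <- function(state, rates_day, mu_c_day, spray_inc, cfg) {
  if (any(!is.finite(c(mu_c_day, unlist(rates_day[-1]))))) {
    stop("missing or non-finite forcing for day ", state$day)
  }
  n_b <- length(state$E)
  A <- tabulate(state$adult_b, nbins = n_b)

  imm <- advance_immatures(state$E, state$L, state$P, A, rates_day,
                           mu_c_day, state$kappa, cfg$n_E)

  n_em <- rpois(n_b, rates_day$d_P * imm$P)
  new_b <- rep(seq_len(n_b), n_em)
  adult_b <- c(state$adult_b, new_b)
  is_old <- c(rep(TRUE, length(state$adult_b)), rep(FALSE, length(new_b)))
  adult_age <- c(state$adult_age, integer(length(new_b)))

  rate_die <- rates_day$mu_N + spray_inc
  if (length(rate_die) == 1) rate_die <- rep(rate_die, n_b)
  p_die_full <- rate_to_prob(rate_die)
  p_die_half <- rate_to_prob(rate_die / 2)
  n_tot <- length(adult_b)
  die <- if (n_tot) {
    p <- ifelse(is_old, p_die_full[adult_b], p_die_half[adult_b])
    runif(n_tot) < p
  } else {
    logical(0)
  }
  adult_b <- adult_b[!die]
  adult_age <- adult_age[!die]
  is_old <- is_old[!die]

  n_s <- length(adult_b)
  n_moved <- 0L
  if (n_s) {
    wants <- runif(n_s) < cfg$move_prob
    can <- cfg$nbr$count[adult_b] > 0L
    mv <- which(wants & can)
    n_moved <- length(mv)
    if (n_moved) {
      bb <- adult_b[mv]
      k <- cfg$nbr$count[bb]
      pick <- cfg$nbr$ptr[bb] + 1L + as.integer(floor(runif(n_moved) * k))
      adult_b[mv] <- cfg$nbr$nbr[pick]
    }
    adult_age[is_old] <- adult_age[is_old] + 1L
  }

  state$E <- imm$E; state$L <- imm$L; state$P <- imm$P
  state$adult_b <- adult_b
  state$adult_age <- adult_age
  state$day <- state$day + 1L
  state$diag <- list(n_emerged = sum(n_em), n_died = sum(die),
                     n_moved = n_moved, adult_days = n_s)
  state
}

#' Run the agent-based model
#'
#' Simulates the city forward under the calibrated forcing, optionally
#' with a spraying campaign. All randomness flows from the single
#' `seed`; a campaign's schedule is drawn from a deterministically
#' derived sub-seed so that the main event stream is identical across
#' runs that share `seed` (a zero-increment campaign reproduces the
#' baseline run bit for bit).
#'
#' @param city A `city`.
#' @param forcing A `calibration_result`, or any list with `rates`,
#'   `mu_c`, `kappa_norm`, `n_E` and normalized initial immatures `E`,
#'   `L`, `P`.
#' @param N0 Per-building initial adult abundance.
#' @param seed Integer seed.
#' @param campaign Optional [campaign_spec()].
#' @param n_days Number of simulated days (default: length of the
#'   forcing).
#' @param move_prob Daily movement probability.
#' @param radius Movement radius, metres.
#' @param max_age Age census cap (older adults accumulate in the last
#'   bin).
#' @param record_buildings If `TRUE`, keep the full day-by-building
#'   adult count matrix.
#' @param nbr Optional precomputed [build_neighbor_index()].
#' @return A list of class `abm_run`: `city_series` (data frame `day`,
#'   `N_total`, `n_emerged`, `n_died`, `n_moved`, `adult_days`),
#'   `age_census` (matrix day x age 0..`max_age`), optionally
#'   `building_counts`, and `schedule` when a campaign ran.
#' @export
run_abm <- function(city, forcing, N0, seed, campaign = NULL, n_days = NULL,
                    move_prob = 0.3, radius = 100, max_age = 150,
                    record_buildings = FALSE, nbr = NULL) {
  rates <- forcing$rates
  mu_c <- forcing$mu_c
  if (is.null(n_days)) n_days <- length(mu_c)
  stopifnot(n_days >= 1, n_days <= nrow(rates), length(mu_c) == nrow(rates))
  n_b <- nrow(city$buildings)
  if (is.null(nbr)) nbr <- build_neighbor_index(city, radius)
  cfg <- list(nbr = nbr, n_E = forcing$n_E, move_prob = move_prob)

  schedule <- NULL
  treated_by_day <- NULL
  if (!is.null(campaign)) {
    set.seed((seed + 131071L) %% .Machine$integer.max)
    schedule <- schedule_campaign(city, campaign)
    tr <- schedule[schedule$treated, c("day", "building")]
    treated_by_day <- split(tr$building, tr$day)
  }

  set.seed(seed)
  state <- abm_init(city, forcing, N0)

  city_series <- data.frame(day = 0:(n_days - 1), N_total = NA_real_,
                            n_emerged = 0L, n_died = 0L, n_moved = 0L,
                            adult_days = 0L)
  age_census <- matrix(0L, nrow = n_days, ncol = max_age + 1,
                       dimnames = list(NULL, 0:max_age))
  building_counts <- if (record_buildings) {
    matrix(0L, nrow = n_days, ncol = n_b)
  }
  last_treat <- rep(NA_real_, n_b)

  census <- function(d) {
    city_series$N_total[d + 1] <<- length(state$adult_b)
    ages <- pmin(state$adult_age, max_age)
    age_census[d + 1, ] <<- tabulate(ages + 1L, nbins = max_age + 1)
    if (record_buildings) {
      building_counts[d + 1, ] <<- tabulate(state$adult_b, nbins = n_b)
    }
  }
  census(0)

  for (d in seq_len(n_days - 1)) {
    spray_inc <- 0
    if (!is.null(campaign)) {
      hit <- treated_by_day[[as.character(d)]]
      if (!is.null(hit)) last_treat[hit] <- d
      spray_inc <- spray_increment(last_treat, d, campaign)
    }
    state <- step_day(state, rates[d, ], mu_c[d], spray_inc, cfg)
    census(d)
    dg <- state$diag
    city_series[d + 1, c("n_emerged", "n_died", "n_moved", "adult_days")] <-
      c(dg$n_emerged, dg$n_died, dg$n_moved, dg$adult_days)
  }

  structure(list(
    city_series = city_series,
    age_census = age_census,
    building_counts = building_counts,
    schedule = schedule,
    seed = seed,
    n_days = n_days
  ), class = "abm_run")
}
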