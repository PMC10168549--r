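# Analysis summaries: zone heatmap matrices, adult age-distribution
# statistics (moments and bimodality coefficient), and rebound metrics
# of sprayed versus baseline trajectories.

#' Zone-by-day abundance matrix
#'
#' Aggregates per-building daily adult counts to zones, sampled every
#' `every_n_days` days. With `normalize = TRUE` each sampled column is
#' divided by that day's city-wide total, so columns sum to one.
#'
#' @param building_counts Matrix of daily per-building adult counts
#'   (days in rows, buildings in columns), e.g. from [run_abm()] with
#'   `record_buildings = TRUE`.
#' @param city The matching `city`.
#' @param every_n_days Sampling stride in days.
#' @param normalize Normalize each sampled column to sum to one.
#' @return Matrix of class `zone_matrix` (zones in rows, sampled days
#'   in columns). Normalized columns on days with zero city total are
#'   set to `NA` with a warning.
#' @export
zone_matrix <- function(building_counts, city, every_n_days = 100,
                        normalize = TRUE) {
  zones <- sort(unique(city$buildings$zone))
  days <- seq(1, nrow(building_counts), by = every_n_days)
  m <- matrix(0, nrow = length(zones), ncol = length(days),
              dimnames = list(zone = zones, day = days - 1))
  for (j in seq_along(days)) {
    tot <- tapply(building_counts[days[j], ], city$buildings$zone, sum)
    m[names(tot), j] <- tot
  }
  if (normalize) {
    cs <- colSums(m)
    bad <- cs == 0
    if (any(bad)) {
      warning("zero city-wide abundance on sampled day(s) ",
              paste(colnames(m)[bad], collapse = ", "),
              "; normalized column undefined")
    }
    m <- sweep(m, 2, ifelse(bad, NA, cs), "/")
  }
  class(m) <- c("zone_matrix", class(m))
  m
}

# Moments of an integer-age histogram; kurtosis is Pearson (non-excess)
# so the bimodality coefficient lands in [0, 1].
histogram_moments <- function(counts, ages = seq_along(counts) - 1) {
  n <- sum(counts)
  if (n == 0) return(list(n = 0, mean = NA_real_, var = NA_real_,
                          skewness = NA_real_, kurtosis = NA_real_,
                          bimodality = NA_real_))
  m <- sum(counts * ages) / n
  ctr <- ages - m
  m2 <- sum(counts * ctr^2) / n
  if (sum(counts > 0) < 2 || m2 == 0) {
    return(list(n = n, mean = m, var = m2, skewness = NA_real_,
                kurtosis = NA_real_, bimodality = NA_real_))
  }
  m3 <- sum(counts * ctr^3) / n
  m4 <- sum(counts * ctr^4) / n
  g <- m3 / m2^1.5
  k <- m4 / m2^2
  list(n = n, mean = m, var = m2, skewness = g, kurtosis = k,
       bimodality = (g^2 + 1) / k)
}

#' Age-distribution statistics from an adult age census
#'
#' Computes, for each day of an age census, the population moments of
#' the integer-age histogram -- mean, variance, skewness and Pearson
#' (non-excess) kurtosis -- and the bimodality coefficient
#' `b = (skewness^2 + 1) / kurtosis`, which lies in `[0, 1]` (it is
#' 1/3 for a mesokurtic symmetric distribution, 5/9 for an exponential
#' one, and approaches 1 for a symmetric two-point distribution). Days
#' with fewer than two distinct ages yield `NA` moments.
#'
#' @param age_census Matrix of daily age histograms (days in rows, ages
#'   0, 1, ... in columns), e.g. from [run_abm()], or a single
#'   histogram vector.
#' @return Data frame of class `age_stats` with one row per day:
#'   `day`, `n`, `mean`, `var`, `skewness`, `kurtosis`, `bimodality`.
#' @export
age_stats <- function(age_census) {
  if (is.null(dim(age_census))) age_census <- matrix(age_census, nrow = 1)
  if (sum(age_census) == 0) stop("empty age census")
  rows <- lapply(seq_len(nrow(age_census)), function(d) {
    as.data.frame(histogram_moments(age_census[d, ]))
  })
  out <- cbind(day = seq_len(nrow(age_census)) - 1, do.call(rbind, rows))
  class(out) <- c("age_stats", "data.frame")
  out
}

#' Rebound metrics of a sprayed trajectory against its baseline
#'
#' Finds the post-campaign-start minimum of the sprayed series, the
#' percent reduction at that minimum relative to the same-day baseline,
#' and the times from campaign start until the sprayed/baseline ratio
#' returns to within 10% and within 1% of baseline. Threshold crossings
#' must be sustained (default 7 consecutive days) to discount
#' single-day stochastic flickers. Months use 30.44 days.
#'
#' @param sprayed,baseline Equal-length daily city-wide abundance
#'   series.
#' @param campaign_start Day index (0-based) at which the campaign
#'   begins.
#' @param sustain_days Consecutive days a threshold crossing must hold.
#' @return List of class `rebound_metrics`: `min_abundance`, `min_day`,
#'   `reduction_pct`, `days_to_10pct`, `days_to_1pct`,
#'   `months_to_10pct`, `months_to_1pct` (days are counted from
#'   campaign start; `NA` when the series never sustains the
#'   threshold).
#' @export
rebound_metrics <- function(sprayed, baseline, campaign_start,
                            sustain_days = 7) {
  n <- length(sprayed)
  stopifnot(length(baseline) == n, campaign_start >= 0, campaign_start < n)
  idx <- (campaign_start + 1):n # 1-based positions from campaign start
  if (any(baseline[idx] == 0)) {
    stop("baseline abundance is zero on a comparison day; ",
         "reduction and ratios undefined")
  }
  k <- idx[which.min(sprayed[idx])]
  min_abundance <- sprayed[k]
  reduction_pct <- 100 * (1 - min_abundance / baseline[k])

  ratio <- sprayed[idx] / baseline[idx]
  sustained_day <- function(thr) {
    ok <- ratio >= thr
    run <- 0L
    for (i in seq_along(ok)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run >= sustain_days) return(i - sustain_days) # 0-based, crossing day
    }
    NA_integer_
  }
  d10 <- sustained_day(0.90)
  d01 <- sustained_day(0.99)
  structure(list(
    min_abundance = min_abundance,
    min_day = k - 1,
    reduction_pct = reduction_pct,
    days_to_10pct = d10,
    days_to_1pct = d01,
    months_to_10pct = d10 / 30.44,
    months_to_1pct = d01 / 30.44
  ), class = "rebound_metrics")
}
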