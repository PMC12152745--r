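# Nightly aggregation and season-level episodicity statistics: CV of nightly
# traffic, bootstrap confidence intervals, percent-of-nights, core-season
# spans and peak (50%-passage) dates.

#' Aggregate integrated scans into nightly summaries
#'
#' Time-integrates the migration traffic rate over each night with
#' midpoint-to-midpoint weights clipped to `[sunset, sunrise]`:
#' `mt_night = sum(MTR_i * dt_i)` (birds km-1) and the time-weighted
#' `mean_mtr`. A night is gap-flagged when any stretch without a usable MTR
#' (including the sunset and sunrise edges) exceeds `max_gap_h`.
#'
#' @param scans Data frame of integrated scans (`datetime`, `mtr`, plus any
#'   carried columns) with a `night` column of `Date` keys.
#' @param station A [station_config()] (for sunset/sunrise bounds).
#' @param max_gap_h Maximum tolerated gap in usable MTR, hours.
#' @return Data frame: `night`, `mean_mtr`, `mt_night`, `n_scans`,
#'   `gap_flag`.
#' @export
nightly_summaries <- function(scans, station, max_gap_h = 1) {
  stopifnot(nrow(scans) > 0, "night" %in% names(scans))
  nights <- sort(unique(scans$night))
  out <- lapply(nights, function(nt) {
    s <- scans[scans$night == nt, , drop = FALSE]
    s <- s[order(s$datetime), , drop = FALSE]
    nb <- night_bounds(nt, station)
    tn <- as.numeric(s$datetime)
    lo <- as.numeric(nb$sunset)
    hi <- as.numeric(nb$sunrise)
    mids <- if (nrow(s) > 1) (tn[-1] + tn[-nrow(s)]) / 2 else numeric(0)
    edges <- pmin(pmax(c(lo, mids, hi), lo), hi)
    dt_h <- diff(edges) / 3600
    ok <- is.finite(s$mtr)
    mt <- if (any(ok)) sum(s$mtr[ok] * dt_h[ok]) else NA_real_
    mean_mtr <- if (any(ok)) mt / sum(dt_h[ok]) else NA_real_
    gap <- if (!any(ok)) {
      (hi - lo) / 3600
    } else {
      tok <- tn[ok]
      max(diff(c(lo, tok, hi))) / 3600
    }
    data.frame(night = nt, mean_mtr = mean_mtr, mt_night = mt,
               n_scans = nrow(s), gap_flag = gap > max_gap_h)
  })
  do.call(rbind, out)
}

#' Coefficient of variation of nightly traffic rate
#'
#' Sample (n-1) standard deviation of the nightly mean MTR divided by its
#' mean; the paper-scale contrast between steady (low CV) and episodic
#' (high CV) migration seasons.
#'
#' @param mean_mtr Nightly mean migration traffic rates.
#' @return Unitless CV.
#' @export
season_cv <- function(mean_mtr) {
  x <- mean_mtr[is.finite(mean_mtr)]
  if (length(x) < 2) stop("need >= 2 nights with traffic", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("mean nightly traffic is zero", call. = FALSE)
  stats::sd(x) / m
}

#' Bootstrap a nightly statistic
#'
#' Percentile bootstrap over nights, resampled with replacement:
#' 10 000 replicates and a 95% interval by default. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param x Nightly values (e.g. mean MTR).
#' @param statistic `"mean"` or `"cv"`.
#' @param n_rep Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List `estimate`, `lo`, `hi`.
#' @export
bootstrap_stat <- function(x, statistic = c("mean", "cv"), n_rep = 10000,
                           level = 0.95, seed = 1) {
  statistic <- match.arg(statistic)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need >= 2 nights", call. = FALSE)
  fn <- if (statistic == "mean") mean else function(z) stats::sd(z) / mean(z)
  est <- fn(x)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_rep, replace = TRUE),
                  nrow = n_rep)
    apply(idx, 1, function(i) fn(x[i]))
  })
  a <- (1 - level) / 2
  qs <- stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(estimate = est, lo = qs[1], hi = qs[2])
}

#' Percent of nights capturing a fraction of seasonal passage
#'
#' Sorts nights by traffic, descending, and finds the smallest set whose
#' summed traffic reaches `fraction` of the season total; returns that set's
#' size as a percent of the nights with data. Few-percent values mean
#' episodic migration; values near `100 * fraction` mean a steady season.
#'
#' @param mt_night Nightly migration traffic (birds km-1).
#' @param fraction Target fraction of total seasonal passage (0-1).
#' @return Percent of nights, in `(0, 100]`.
#' @export
pct_nights <- function(mt_night, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  x <- mt_night[is.finite(mt_night)]
  total <- sum(x)
  if (total <= 0) stop("all-zero seasonal traffic", call. = FALSE)
  cum <- cumsum(sort(x, decreasing = TRUE))
  k <- which(cum >= fraction * total - 1e-9 * total)[1]
  100 * k / length(x)
}

#' Core-season span in days
#'
#' Days between the chronological cumulative-passage crossings of `lo` and
#' `hi` fractions of the season total (e.g. 20-80% or 10-90%).
#'
#' @param night `Date` vector.
#' @param mt_night Nightly migration traffic aligned with `night`.
#' @param lo,hi Fractions of total passage, `lo < hi`.
#' @return Span in days (0 when one night holds the whole core).
#' @export
core_span <- function(night, mt_night, lo, hi) {
  stopifnot(lo < hi, lo > 0, hi <= 1)
  ok <- is.finite(mt_night)
  night <- as.Date(night[ok])
  x <- mt_night[ok][order(night)]
  night <- sort(night)
  total <- sum(x)
  if (total <= 0) stop("all-zero seasonal traffic", call. = FALSE)
  cum <- cumsum(x)
  d_lo <- night[which(cum >= lo * total - 1e-9 * total)[1]]
  d_hi <- night[which(cum >= hi * total - 1e-9 * total)[1]]
  as.numeric(d_hi - d_lo)
}

#' Peak (median passage) date
#'
#' First night by which the chronological cumulative migration traffic
#' reaches half the season total.
#'
#' @inheritParams core_span
#' @return `Date`.
#' @export
peak_date <- function(night, mt_night) {
  ok <- is.finite(mt_night)
  night <- as.Date(night[ok])
  x <- mt_night[ok][order(night)]
  night <- sort(night)
  total <- sum(x)
  if (total <= 0) stop("all-zero seasonal traffic", call. = FALSE)
  night[which(cumsum(x) >= 0.5 * total - 1e-9 * total)[1]]
}

#' Cumulative seasonal passage curve
#'
#' @inheritParams core_span
#' @return Data frame `night`, `cum_fraction`; non-decreasing, ending at 1.
#' @export
cumulative_curve <- function(night, mt_night) {
  ok <- is.finite(mt_night)
  night <- as.Date(night[ok])
  x <- mt_night[ok][order(night)]
  night <- sort(night)
  total <- sum(x)
  if (total <= 0) stop("all-zero seasonal traffic", call. = FALSE)
  data.frame(night = night, cum_fraction = cumsum(x) / total)
}

#' Full season phenology report
#'
#' Convenience wrapper assembling the season-level episodicity statistics
#' from nightly summaries.
#'
#' @param nightly Output of [nightly_summaries()].
#' @param n_rep Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List with `total_mt`, `cv`, `cv_ci`, `mean_mtr`, `mean_ci`,
#'   `pct_nights` (50/75/90), `core_spans` (20-80, 10-90), `peak_date`,
#'   `n_nights`.
#' @export
season_phenology <- function(nightly, n_rep = 10000, seed = 1) {
  mtr <- nightly$mean_mtr
  bt_mean <- bootstrap_stat(mtr, "mean", n_rep = n_rep, seed = seed)
  bt_cv <- bootstrap_stat(mtr, "cv", n_rep = n_rep, seed = seed + 1)
  list(
    n_nights = sum(is.finite(nightly$mt_night)),
    total_mt = sum(nightly$mt_night, na.rm = TRUE),
    mean_mtr = bt_mean$estimate,
    mean_ci = c(bt_mean$lo, bt_mean$hi),
    cv = season_cv(mtr),
    cv_ci = c(bt_cv$lo, bt_cv$hi),
    pct_nights = list(p50 = pct_nights(nightly$mt_night, 0.50),
                      p75 = pct_nights(nightly$mt_night, 0.75),
                      p90 = pct_nights(nightly$mt_night, 0.90)),
    core_spans = list(span_20_80 = core_span(nightly$night, nightly$mt_night,
                                             0.2, 0.8),
                      span_10_90 = core_span(nightly$night, nightly$mt_night,
                                             0.1, 0.9)),
    peak_date = format(peak_date(nightly$night, nightly$mt_night))
  )
}
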