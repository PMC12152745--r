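# Seasonal windows, diel exclusion, seasonal direction filtering, nightly
# thinning to the reference scan, and completeness rules.

#' Migratory season windows
#'
#' Boreal spring and fall passage windows; defaults are February 20 - June 1
#' and August 1 - November 25, both boundaries inclusive. Overridable for
#' other flyways.
#'
#' @param spring,fall Character vectors `c("mm-dd", "mm-dd")` of window start
#'   and end.
#' @return A `season_windows` list.
#' @export
season_windows <- function(spring = c("02-20", "06-01"),
                           fall = c("08-01", "11-25")) {
  w <- list(spring = spring, fall = fall)
  ref <- function(md) as.Date(paste0("2001-", md))  # non-leap reference year
  for (s in names(w)) stopifnot(ref(w[[s]][1]) <= ref(w[[s]][2]))
  if (ref(w$spring[2]) >= ref(w$fall[1])) {
    stop("season windows overlap", call. = FALSE)
  }
  structure(w, class = "season_windows")
}

#' Season of a date
#'
#' @param date `Date` vector (night keys).
#' @param windows A [season_windows()].
#' @return Character vector: `"spring"`, `"fall"` or `"none"`.
#' @export
season_of <- function(date, windows = season_windows()) {
  date <- as.Date(date)
  md <- format(date, "%m-%d")
  out <- rep("none", length(date))
  out[md >= windows$spring[1] & md <= windows$spring[2]] <- "spring"
  out[md >= windows$fall[1] & md <= windows$fall[2]] <- "fall"
  out
}

#' Remove bins moving against the seasonal migration direction
#'
#' Cleans partitioned bins whose track is inconsistent with the season's
#' broad-front movement: spring (northbound migration) removes tracks
#' strictly inside (90, 270) degrees; fall (southbound migration) removes
#' tracks strictly below 90 or strictly above 270 degrees. The boundaries 90
#' and 270 are retained in both seasons. Bins with missing track pass
#' through, flagged.
#'
#' @param data Data frame with a `track` column (compass degrees).
#' @param season `"spring"` or `"fall"`.
#' @return `data` with the offending rows removed and a logical
#'   `track_missing` column added.
#' @export
direction_filter <- function(data, season) {
  season <- match.arg(season, c("spring", "fall"))
  tr <- data$track %% 360
  drop <- if (season == "spring") {
    tr > 90 & tr < 270
  } else {
    tr < 90 | tr > 270
  }
  drop[is.na(tr)] <- FALSE
  out <- data[!drop, , drop = FALSE]
  out$track_missing <- is.na(out$track)
  rownames(out) <- NULL
  out
}

#' Thin a night to its reference scan
#'
#' Selects the single scan closest to a fixed offset after sunset (3 h by
#' default, near the typical nightly density peak and safely past dusk bat
#' emergence); ties resolve to the earlier scan.
#'
#' @param scans Data frame with a `datetime` column (one night's scans).
#' @param sunset POSIXct sunset instant of that night.
#' @param offset_h Offset after sunset, hours.
#' @return The selected row of `scans`.
#' @export
thin_to_reference <- function(scans, sunset, offset_h = 3) {
  if (!nrow(scans)) stop("empty night", call. = FALSE)
  target <- sunset + offset_h * 3600
  dist <- abs(as.numeric(scans$datetime) - as.numeric(target))
  cand <- which(dist == min(dist))
  pick <- cand[which.min(as.numeric(scans$datetime[cand]))]
  scans[pick, , drop = FALSE]
}

#' Season completeness report
#'
#' Data-sufficiency rules for reporting season-level statistics: mean/CV of
#' nightly traffic need more than two weeks of continuous data; seasonal
#' migration-traffic totals need at least a 75%-complete time series, with
#' more than 3000 radar volumes qualifying as near-complete.
#'
#' @param nights_with_data `Date` vector of nights having at least one usable
#'   scan.
#' @param season_start,season_end `Date` bounds of the season window
#'   (inclusive).
#' @param n_volumes Total radar volumes acquired over the season.
#' @return List: `fraction_nights_with_data`, `longest_continuous_run_days`,
#'   `n_volumes`, and pass/fail flags `pass_cv_rule` (> 14 consecutive days),
#'   `pass_mt_rule` (fraction >= 0.75), `near_complete` (> 3000 volumes).
#' @export
completeness <- function(nights_with_data, season_start, season_end,
                         n_volumes = NA_integer_) {
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  all_nights <- seq(season_start, season_end, by = "day")
  have <- all_nights %in% as.Date(nights_with_data)
  runs <- rle(have)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  frac <- mean(have)
  list(fraction_nights_with_data = frac,
       longest_continuous_run_days = as.integer(longest),
       n_volumes = n_volumes,
       pass_cv_rule = longest > 14,
       pass_mt_rule = frac >= 0.75,
       near_complete = is.finite(n_volumes) && n_volumes > 3000)
}
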