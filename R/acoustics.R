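# Nightly flight-call rates from recording logs and pairing with radar
# nights.

#' Read a nightly flight-call log
#'
#' @param path CSV with columns `night` (local date), `taxon`, `calls`,
#'   `hours` (recording hours after removing outages; constant within a
#'   night).
#' @return Data frame with parsed `night` as `Date`.
#' @export
read_call_log <- function(path) {
  if (!file.exists(path)) stop("cannot read call log: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("night", "taxon", "calls", "hours")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("call log lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$calls < 0) || any(df$hours < 0)) {
    stop("negative calls or hours", call. = FALSE)
  }
  df$night <- as.Date(df$night)
  df
}

#' Nightly call rate
#'
#' Calls per recording hour for each night, total or per taxon. Counts and
#' hours are summed across a night's recordings before dividing, so the rate
#' is invariant to how a night was split into files.
#'
#' @param log Data frame as from [read_call_log()].
#' @param taxon `"all"` for the total rate, otherwise a taxon name.
#' @return Data frame `night`, `hours`, `calls`, `call_rate` (calls h-1).
#' @export
call_rate <- function(log, taxon = "all") {
  if (taxon != "all") log <- log[log$taxon == taxon, , drop = FALSE]
  if (!nrow(log)) stop("no recordings for taxon '", taxon, "'", call. = FALSE)
  nights <- sort(unique(log$night))
  # hours are per-recording-night effort, identical across taxa rows
  hours <- vapply(nights, function(nt) {
    h <- unique(log$hours[log$night == nt])
    if (length(h) != 1) h <- max(h)
    h
  }, numeric(1))
  calls <- vapply(nights, function(nt) sum(log$calls[log$night == nt]),
                  numeric(1))
  if (any(hours <= 0)) stop("night with zero recording hours", call. = FALSE)
  data.frame(night = nights, hours = hours, calls = calls,
             call_rate = calls / hours)
}

#' Fourth-root transform of a call rate
#'
#' Variance-stabilizing transform used before modelling call rates.
#'
#' @param rate Non-negative call rate(s).
#' @return `rate^(1/4)`.
#' @export
transform_rate <- function(rate) {
  if (any(rate < 0, na.rm = TRUE)) stop("negative call rate", call. = FALSE)
  rate^0.25
}

#' Pair acoustic and radar nights
#'
#' Inner join on the night key, keeping only nights when both the recorder
#' and the radar were operating; reports the pair count.
#'
#' @param rates Output of [call_rate()].
#' @param radar_nights Data frame with `night` plus radar quantities (e.g.
#'   `vid` from the reference scan, and covariates).
#' @return Data frame of paired nights with `call_rate`,
#'   `call_rate_4rt` and all radar columns.
#' @export
pair_with_radar <- function(rates, radar_nights) {
  out <- merge(rates, radar_nights, by = "night")
  if (!nrow(out)) {
    warning("no concurrent acoustic and radar nights", call. = FALSE)
  }
  out$call_rate_4rt <- transform_rate(out$call_rate)
  message(nrow(out), " paired night(s)")
  out[order(out$night), , drop = FALSE]
}

#' Correlate call rate with radar bird density
#'
#' Pearson correlation (and its square) between the nightly call rate and the
#' radar's vertically integrated bird density. By default the fourth-root
#' transformed rate is used, matching the modelling transform; `transformed =
#' FALSE` gives the raw-rate variant, and both are worth reporting.
#'
#' @param paired Output of [pair_with_radar()].
#' @param transformed Use the fourth-root rate (default) or the raw rate.
#' @return List `r`, `r2`, `n`.
#' @export
correlate_calls <- function(paired, transformed = TRUE) {
  x <- if (transformed) paired$call_rate_4rt else paired$call_rate
  y <- paired$vid
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need >= 3 paired nights", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("constant series", call. = FALSE)
  }
  r <- stats::cor(x[ok], y[ok])
  list(r = r, r2 = r^2, n = sum(ok))
}
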