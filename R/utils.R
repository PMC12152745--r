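# Internal helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Compass bearing of a velocity vector
#'
#' Converts eastward/northward components to a compass bearing with 0 = north,
#' 90 = east, in `[0, 360)`.
#'
#' @param u Eastward component (m s-1).
#' @param v Northward component (m s-1).
#' @return Bearing in degrees. `NA` where both components are zero or missing.
#' @keywords internal
bearing_from_uv <- function(u, v) {
  out <- (atan2(u, v) * RAD2DEG) %% 360
  out[out > 360 - 1e-9] <- 0  # fold the wrap-around seam onto 0
  out[!is.finite(u) | !is.finite(v) | (u == 0 & v == 0)] <- NA_real_
  out
}

# Unit vector (u, v) pointing along a compass bearing.
uv_from_bearing <- function(bearing_deg) {
  th <- bearing_deg * DEG2RAD
  cbind(u = sin(th), v = cos(th))
}

# Shortest signed angular difference a - b in (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Parse ISO-8601 UTC timestamps strictly; error on failure.
parse_utc <- function(x, what = "datetime") {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    todo <- which(is.na(out) & !is.na(x))
    if (!length(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row(s) %s: '%s'", what,
                 paste(utils::head(bad, 3), collapse = ", "), x[bad[1]]),
         call. = FALSE)
  }
  out
}

fmt_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
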