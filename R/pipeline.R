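# Pipeline assembly: configuration, the simulate / run / report entry points
# and their file outputs. These functions are what the thin command-line
# wrapper in inst/cli/aeromig.R dispatches to.

#' Pipeline configuration
#'
#' @param station A [station_config()].
#' @param out_dir Output directory (created if absent).
#' @param preset Scenario preset name for [cmd_simulate()].
#' @param seed Integer seed recorded in every output.
#' @param vpts,atmosphere,calls Input file paths for [cmd_run()]; defaults
#'   point at [cmd_simulate()]'s outputs under `out_dir`.
#' @param windows A [season_windows()].
#' @param partition A [partition_params()].
#' @param n_rep Bootstrap replicates for season statistics.
#' @param max_gap_h Intra-night gap tolerance, hours.
#' @param airspeed Airspeed for flow assistance, m s-1.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(station, out_dir, preset = "tropical", seed = 1,
                            vpts = file.path(out_dir, "vpts.csv"),
                            atmosphere = file.path(out_dir, "atmosphere.csv"),
                            calls = file.path(out_dir, "calls.csv"),
                            windows = season_windows(),
                            partition = partition_params(),
                            n_rep = 10000, max_gap_h = 1, airspeed = 8) {
  stopifnot(inherits(station, "station_config"))
  structure(list(station = station, out_dir = out_dir, preset = preset,
                 seed = as.integer(seed), vpts = vpts,
                 atmosphere = atmosphere, calls = calls, windows = windows,
                 partition = partition, n_rep = n_rep,
                 max_gap_h = max_gap_h, airspeed = airspeed),
            class = "pipeline_config")
}

# Stable short hash of the configuration, embedded in outputs.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %%
            .Machine$integer.max)
}

#' Simulate a scenario to disk
#'
#' Generates the scenario named by `config$preset` with `config$seed` and
#' writes `vpts.csv`, `atmosphere.csv`, `calls.csv`, `manifest_nights.csv`,
#' `manifest_bins.csv` and `manifest.json` under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return File paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  params <- scenario_preset(config$preset, seed = config$seed)
  grid <- gen_atmosphere(params, config$station)
  truth <- gen_truth_nights(params)
  prof <- gen_profiles(truth, grid, params, config$station)
  calls <- gen_calls(prof, params, config$station)
  paths <- list(vpts = config$vpts, atmosphere = config$atmosphere,
                calls = config$calls,
                manifest_nights = file.path(config$out_dir,
                                            "manifest_nights.csv"),
                manifest_bins = file.path(config$out_dir,
                                          "manifest_bins.csv"),
                manifest = file.path(config$out_dir, "manifest.json"))
  write_vpts(prof$series, paths$vpts)
  write_atmosphere(grid, paths$atmosphere)
  utils::write.csv(calls, paths$calls, row.names = FALSE)
  utils::write.csv(data.frame(night = format(truth$night),
                              mt_true = truth$mt_true),
                   paths$manifest_nights, row.names = FALSE)
  mb <- prof$manifest$bins
  mb$datetime <- fmt_utc(mb$datetime)
  utils::write.csv(mb, paths$manifest_bins, row.names = FALSE)
  man <- list(preset = config$preset, seed = config$seed,
              config_hash = config_hash(config),
              total_passage = params$total_passage,
              peak_day = format(params$peak_day),
              night_sigma = params$night_sigma,
              n_nights = nrow(truth))
  jsonlite::write_json(man, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the analysis pipeline
#'
#' Executes pair, partition, screen, thin, integrate and phenology stages on
#' the configured inputs (plus acoustic pairing when a call log is present)
#' and writes `nightly.csv`, `season.json` and `covariates.csv` under
#' `config$out_dir`. All randomness (bootstrap) derives from `config$seed`,
#' so repeated runs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The season report list, invisibly.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  st <- config$station
  series <- read_vpts(config$vpts, st)
  grid <- read_atmosphere(config$atmosphere)
  paired <- pair_weather(series, grid)
  part <- partition_series(series, paired, config$partition)

  d <- part$data
  night_ok <- is_night(d$datetime, st$lat, st$lon)
  if (!all(night_ok)) {
    d <- d[night_ok, , drop = FALSE]
  }
  d$night <- assign_night(d$datetime, st)
  d$season <- season_of(d$night, config$windows)
  d <- d[d$season != "none", , drop = FALSE]
  if (!nrow(d)) stop("data error: no nocturnal in-season bins", call. = FALSE)

  seasons <- list()
  nightly_all <- list()
  cov_all <- list()
  for (sn in unique(paste(format(d$night, "%Y"), d$season))) {
    sel <- paste(format(d$night, "%Y"), d$season) == sn
    ds <- direction_filter(d[sel, , drop = FALSE], unique(d$season[sel]))
    sub <- part
    sub$data <- ds
    scans <- integrate_profile(sub, use = "bird")
    scans$night <- assign_night(scans$datetime, st)
    nightly <- nightly_summaries(scans, st, max_gap_h = config$max_gap_h)
    yr <- sub("(\\d+) .*", "\\1", sn)
    ssn <- sub(".* ", "", sn)
    w <- if (ssn == "spring") config$windows$spring else config$windows$fall
    comp <- completeness(nightly$night[is.finite(nightly$mt_night)],
                         as.Date(paste0(yr, "-", w[1])),
                         as.Date(paste0(yr, "-", w[2])),
                         n_volumes = length(unique(ds$datetime)))
    pheno <- season_phenology(nightly, n_rep = config$n_rep,
                              seed = config$seed)
    # reference-scan covariate rows (one per night)
    pdir <- preferred_direction(ds$track, ds$eta_bird)
    cov <- lapply(split(scans, scans$night), function(s) {
      nb <- night_bounds(s$night[1], st)
      ref <- thin_to_reference(s, nb$sunset)
      bins <- ds[ds$datetime == ref$datetime, , drop = FALSE]
      wxb <- paired[paired$datetime == ref$datetime, , drop = FALSE]
      wxb <- wxb[match(bins$height, wxb$height), , drop = FALSE]
      tb <- tailwind_eq_airspeed(wxb$u_wind, wxb$v_wind, pdir,
                                 config$airspeed)
      wgt <- bins$eta_bird
      wmean <- function(z) {
        ok <- is.finite(z) & is.finite(wgt)
        if (!any(ok) || sum(wgt[ok]) == 0) NA_real_
        else sum(z[ok] * wgt[ok]) / sum(wgt[ok])
      }
      gt <- ground_level_value(wxb, "temp", st)
      data.frame(night = s$night[1], vid = ref$vid,
                 mean_height = ref$mean_height,
                 tailwind = wmean(tb),
                 temp_ground = gt$temp[1],
                 shum = wmean(wxb$shum), omega = wmean(wxb$omega),
                 tke = wmean(wxb$tke))
    })
    cov <- do.call(rbind, cov)
    screened <- collinearity_screen(
      cov[c("tailwind", "temp_ground", "shum", "omega", "tke")],
      priority = c("shum", "tailwind", "omega", "temp_ground", "tke"))
    seasons[[sn]] <- c(list(season = sn, preferred_direction = pdir,
                            completeness = comp,
                            covariates_retained = screened), pheno)
    nightly$season <- sn
    cov$season <- sn
    nightly_all[[sn]] <- nightly
    cov_all[[sn]] <- cov
  }
  nightly <- do.call(rbind, nightly_all)
  cov <- do.call(rbind, cov_all)

  report <- list(config_hash = config_hash(config), seed = config$seed,
                 station = st$id, seasons = seasons)
  if (!is.null(config$calls) && file.exists(config$calls)) {
    rates <- call_rate(read_call_log(config$calls))
    paired_n <- suppressMessages(
      pair_with_radar(rates, cov[setdiff(names(cov), "season")]))
    if (nrow(paired_n) >= 3 && stats::sd(paired_n$vid) > 0) {
      report$acoustics <- list(
        n_paired = nrow(paired_n),
        pearson_r_4rt = correlate_calls(paired_n, transformed = TRUE)$r,
        pearson_r_raw = correlate_calls(paired_n, transformed = FALSE)$r)
    }
    pc <- paired_n
    pc$night <- format(pc$night)
    utils::write.csv(pc, file.path(config$out_dir, "paired_calls.csv"),
                     row.names = FALSE)
  }
  out_nightly <- nightly
  out_nightly$night <- format(out_nightly$night)
  utils::write.csv(out_nightly, file.path(config$out_dir, "nightly.csv"),
                   row.names = FALSE)
  out_cov <- cov
  out_cov$night <- format(out_cov$night)
  utils::write.csv(out_cov, file.path(config$out_dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "season.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Render a human-readable season report
#'
#' Markdown summary of the season statistics written by [cmd_run()]:
#' cumulative-passage staircase, CV table and percent-of-nights table.
#' Regeneration is idempotent.
#'
#' @param out_dir Directory holding `season.json` and `nightly.csv`.
#' @return Path of the written `report.md`, invisibly.
#' @export
cmd_report <- function(out_dir) {
  sj <- file.path(out_dir, "season.json")
  nc <- file.path(out_dir, "nightly.csv")
  if (!file.exists(sj) || !file.exists(nc)) {
    stop("missing analysis outputs in ", out_dir, call. = FALSE)
  }
  rep <- jsonlite::read_json(sj, simplifyVector = TRUE)
  nightly <- utils::read.csv(nc, stringsAsFactors = FALSE)
  lines <- c(sprintf("# Migration season report - station %s", rep$station),
             sprintf("seed %d, config %s", rep$seed, rep$config_hash), "")
  for (sn in names(rep$seasons)) {
    s <- rep$seasons[[sn]]
    lines <- c(lines, sprintf("## %s", sn), "")
    if (!isTRUE(s$completeness$pass_mt_rule) &&
        !isTRUE(s$completeness$pass_cv_rule)) {
      lines <- c(lines, "insufficient data (completeness rules not met)", "")
      next
    }
    lines <- c(lines,
      sprintf("- nights with data: %d", s$n_nights),
      sprintf("- total migration traffic: %.0f birds/km", s$total_mt),
      sprintf("- mean nightly MTR: %.1f [%.1f, %.1f] birds/km/h",
              s$mean_mtr, s$mean_ci[1], s$mean_ci[2]),
      sprintf("- CV of nightly MTR: %.2f [%.2f, %.2f]",
              s$cv, s$cv_ci[1], s$cv_ci[2]),
      sprintf("- %% of nights for 50/75/90%% of passage: %.1f / %.1f / %.1f",
              s$pct_nights[["p50"]], s$pct_nights[["p75"]],
              s$pct_nights[["p90"]]),
      sprintf("- core spans 20-80%% / 10-90%%: %.0f / %.0f days",
              s$core_spans[["span_20_80"]], s$core_spans[["span_10_90"]]),
      sprintf("- peak (50%%-passage) date: %s", s$peak_date),
      sprintf("- preferred direction: %.0f deg", s$preferred_direction), "")
    ns <- nightly[nightly$season == sn & is.finite(nightly$mt_night), ]
    cum <- cumsum(ns$mt_night) / sum(ns$mt_night)
    step <- seq(0.1, 1, by = 0.1)
    idx <- vapply(step, function(q) which(cum >= q - 1e-12)[1], integer(1))
    lines <- c(lines, "cumulative passage (fraction: date):",
               paste(sprintf("  %.0f%%: %s", 100 * step, ns$night[idx]),
                     collapse = "\n"), "")
  }
  if (!is.null(rep$acoustics)) {
    lines <- c(lines, "## Acoustics",
               sprintf("- paired nights: %d", rep$acoustics$n_paired),
               sprintf("- Pearson r (fourth-root rate vs VID): %.3f",
                       rep$acoustics$pearson_r_4rt),
               sprintf("- Pearson r (raw rate vs VID): %.3f",
                       rep$acoustics$pearson_r_raw), "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
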