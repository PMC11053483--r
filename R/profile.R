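# End-to-end pipeline orchestration and the personalized gait profile.

#' Packaged population reference values
#'
#' Subject-mean gait parameters (mean and standard deviation over a healthy
#' adult cohort) used as the default reference for z-score gait profiles.
#' Note the cohort skews towards a slower walking pattern (larger step
#' lengths and longer step times) than larger population datasets; profiles
#' built against it should be read with that caveat.
#'
#' @return data.frame of class `reference_population`: `parameter`, `group`
#'   (temporal / spatial / indicator), `mean`, `sd`.
#' @export
reference_population <- function() {
  df <- data.frame(
    parameter = c("walking_speed", "cadence", "step_time", "stride_time",
                  "stance_time", "swing_time", "single_support",
                  "double_support", "step_length", "step_width",
                  "step_angle", "stride_length"),
    group = c("indicator", "indicator", "temporal", "temporal", "temporal",
              "temporal", "temporal", "temporal", "spatial", "spatial",
              "spatial", "spatial"),
    mean = c(1.184, 104.1, 0.581, 1.258, 0.747, 0.415, 0.415, 0.167,
             0.678, 0.086, 4.123, 1.415),
    sd = c(0.140, 8.566, 0.046, 0.172, 0.066, 0.033, 0.033, 0.026,
           0.062, 0.023, 1.287, 0.214),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("reference_population", "data.frame"))
}

#' Read a reference population from JSON
#'
#' Expects `{"parameter": {"mean": m, "sd": s}, ...}`; sds must be positive.
#'
#' @param path JSON file path.
#' @return a `reference_population` data.frame (group tags inferred from the
#'   packaged defaults where the parameter names match, `indicator`
#'   otherwise).
#' @export
read_reference <- function(path) {
  raw <- jsonlite::read_json(path)
  def <- reference_population()
  df <- data.frame(
    parameter = names(raw),
    group = ifelse(names(raw) %in% def$parameter,
                   def$group[match(names(raw), def$parameter)], "indicator"),
    mean = vapply(raw, function(e) as.numeric(e$mean), 0),
    sd = vapply(raw, function(e) as.numeric(e$sd), 0),
    stringsAsFactors = FALSE
  )
  if (any(df$sd <= 0)) stop("reference sds must be positive", call. = FALSE)
  structure(df, class = c("reference_population", "data.frame"))
}

#' Run the full gait-analysis pipeline
#'
#' Executes preprocess -> footstep detection -> temporal parameters ->
#' spatial parameters (when the layout has at least three sensors) ->
#' gait-health indicators on one trace. Records sampled faster than 2 kHz
#' are lowpass-decimated to ~1 kHz for the temporal path while the full-rate
#' record feeds the spatial path. Stage failures after detection are caught
#' and reported in `warnings` with the stage name; partial results are still
#' returned.
#'
#' @param record a [vibration_record()] or a path readable by
#'   [read_record()].
#' @param layout a [sensor_layout()] or a path readable by [read_layout()].
#' @param config named list overriding defaults: `lowpass_temporal_hz` (500),
#'   `lowpass_spatial_hz` (2500), `detect_band_hz` (c(5, 50)),
#'   `min_consecutive` (3), `height_k` (3), `prominence_k` (3), `spacing_s`
#'   (c(0.25, 2.5)), `quiet_interval` (NULL = before the first footstep),
#'   `stance_fraction_hint` (0.64), `grid_m` (0.05), `v_clamp` (c(30, 300)),
#'   `step_prior` (c(0.65, 0.1)), `attenuation_rate` (0.5, for normalized
#'   energy), `noise_segment` (a [vibration_record()] for Wiener denoising).
#' @param calibration optional data.frame (`x`, `y`, `t_strike`) of
#'   ground-truth footsteps for velocity calibration.
#' @param velocity optional [velocity_profile()] (skips calibration).
#' @param bands optional cached [floor_bands()] for this floor.
#' @param contact_model optional [train_contact_classifier()] model.
#' @return list of class `gait_results`: `events`, `bands`, `temporal`,
#'   `spatial`, `indicators`, `warnings`.
#' @export
run_pipeline <- function(record, layout, config = list(),
                         calibration = NULL, velocity = NULL, bands = NULL,
                         contact_model = NULL) {
  if (is.character(record)) record <- read_record(record)
  if (is.character(layout)) layout <- read_layout(layout)
  check_layout_record(record, layout)
  cfg <- modifyList(list(
    lowpass_temporal_hz = 500, lowpass_spatial_hz = 2500,
    detect_band_hz = c(5, 50), min_consecutive = 3, height_k = 3,
    prominence_k = 3, spacing_s = c(0.25, 2.5), quiet_interval = NULL,
    stance_fraction_hint = 0.64, grid_m = 0.05, v_clamp = c(30, 300),
    step_prior = c(0.65, 0.1), attenuation_rate = 0.5,
    noise_segment = NULL
  ), config)
  warnings <- character(0)
  note <- function(stage, msg)
    warnings <<- c(warnings, sprintf("[%s] %s", stage, msg))

  # --- preprocess -----------------------------------------------------------
  fs <- record$sample_rate
  spatial_rec <- record
  if (!is.null(cfg$noise_segment))
    spatial_rec <- wiener_denoise(spatial_rec, cfg$noise_segment)
  temporal_rec <- spatial_rec
  if (cfg$lowpass_temporal_hz < fs / 2)
    temporal_rec <- lowpass(temporal_rec, cfg$lowpass_temporal_hz)
  dec <- max(1L, floor(fs / 1000))
  if (dec > 1L) temporal_rec <- decimate_record(temporal_rec, dec)

  # --- detection ------------------------------------------------------------
  qi <- cfg$quiet_interval %||% c(rec_times(temporal_rec)[1],
                                  rec_times(temporal_rec)[1] + 2.8)
  noise <- estimate_noise_stats(temporal_rec, qi, band = cfg$detect_band_hz)
  events <- detect_footsteps(temporal_rec, noise, layout,
                             band = cfg$detect_band_hz,
                             min_consecutive = cfg$min_consecutive,
                             height_k = cfg$height_k,
                             prominence_k = cfg$prominence_k,
                             spacing_s = cfg$spacing_s)
  out <- list(events = events, bands = bands, temporal = NULL,
              spatial = NULL, indicators = NULL, warnings = warnings)
  class(out) <- "gait_results"
  if (nrow(events) < 3) {
    note("detect", "fewer than 3 footsteps detected; stopping")
    out$warnings <- warnings
    return(out)
  }

  # --- temporal -------------------------------------------------------------
  tempo <- tryCatch(
    estimate_temporal(temporal_rec, events, bands = bands,
                      quiet_interval = cfg$quiet_interval,
                      stance_fraction_hint = cfg$stance_fraction_hint),
    error = function(e) {
      note("temporal", conditionMessage(e))
      NULL
    })
  out$temporal <- tempo
  out$bands <- if (!is.null(tempo)) tempo$bands else bands

  # --- spatial --------------------------------------------------------------
  if (nrow(layout) < 3) {
    note("spatial", "skipped: fewer than 3 sensors")
  } else if (!is.null(tempo) && sum(!is.na(tempo$cycles$t_strike)) >= 3) {
    profile <- velocity
    if (is.null(profile) && !is.null(calibration)) {
      profile <- tryCatch(
        calibrate_from_truth(calibration, spatial_rec, layout,
                             quiet_interval = cfg$quiet_interval,
                             clamp = cfg$v_clamp),
        error = function(e) {
          note("spatial", paste("calibration failed:", conditionMessage(e)))
          NULL
        })
    }
    out$spatial <- tryCatch(
      estimate_spatial(spatial_rec, layout, tempo$cycles$t_strike,
                       profile = profile,
                       quiet_interval = cfg$quiet_interval,
                       step_prior = cfg$step_prior, grid_m = cfg$grid_m),
      error = function(e) {
        note("spatial", conditionMessage(e))
        NULL
      })
  }

  # --- indicators -----------------------------------------------------------
  out$indicators <- tryCatch(
    compute_indicators(temporal_rec, events, tempo, out$spatial, layout,
                       cfg, contact_model),
    error = function(e) {
      note("indicators", conditionMessage(e))
      NULL
    })
  out$warnings <- warnings
  out
}

# Assemble the indicator block from stage outputs.
compute_indicators <- function(record, events, tempo, spatial, layout, cfg,
                               contact_model = NULL) {
  cad <- cadence_from_window(events)
  ind <- list(cadence = cad$cadence, step_frequency = cad$step_frequency,
              cadence_partial_window = cad$partial_window)

  params <- if (!is.null(tempo)) tempo$params else NULL
  si <- list(); bs <- list()
  by_side <- function(v, side) {
    ok <- !is.na(v)
    if (!any(ok & side == "A") || !any(ok & side == "B")) return(NULL)
    c(A = mean(v[ok & side == "A"]), B = mean(v[ok & side == "B"]))
  }
  if (!is.null(params)) {
    st <- by_side(params$stance_time, params$side)
    if (!is.null(st)) si$stance_time <- unname(
      symmetry_index(st["A"], st["B"], "stance_time")$si)
    bt <- params$step_time[!is.na(params$step_time)]
    if (length(bt) >= 2) bs$step_time <- balance_score(bt, "step_time")$bs
  }
  sp <- if (!is.null(spatial)) spatial$params else NULL
  if (!is.null(sp)) {
    sl <- by_side(sp$step_length, rep(c("A", "B"), length.out = nrow(sp)))
    if (!is.null(sl)) si$step_length <- unname(
      symmetry_index(sl["A"], sl["B"], "step_length")$si)
    wv <- sp$step_width[!is.na(sp$step_width)]
    if (length(wv) >= 2) bs$step_width <- balance_score(wv, "step_width")$bs
  }

  # kinetic proxy: per-footstep normalized energy at the event's best channel
  if (!is.null(spatial) && nrow(spatial$locations) >= 2 &&
      !is.null(params)) {
    en <- vapply(seq_len(nrow(spatial$locations)), function(j) {
      i <- spatial$locations$step[j]
      if (i > nrow(events)) return(NA_real_)
      ch <- events$peak_channel[i]
      t0 <- events$peak_time[i] - 0.3
      t1 <- events$peak_time[i] + 0.5
      tm <- rec_times(record)
      idx <- which(tm >= t0 & tm <= t1)
      d <- layout_distances(layout, spatial$locations$x[j],
                            spatial$locations$y[j])[ch]
      normalized_energy(record$samples[idx, ch], d,
                        2 * cfg$attenuation_rate)
    }, 0)
    side <- events$side[spatial$locations$step]
    ee <- by_side(en, side)
    if (!is.null(ee)) si$energy <- unname(
      symmetry_index(ee["A"], ee["B"], "energy")$si)
    if (sum(!is.na(en)) >= 2) bs$energy <- balance_score(en, "energy")$bs
  }

  # walking speed: step length over step time, matched by footstep index
  if (!is.null(sp) && !is.null(params)) {
    idx <- sp$step[!is.na(sp$step_length)]
    idx <- idx[idx < nrow(events)]
    if (length(idx)) {
      v <- walking_speed(sp$step_length[match(idx, sp$step)],
                         events$peak_time[idx], events$peak_time[idx + 1])
      ind$walking_speed_mean <- mean(v, na.rm = TRUE)
    }
  }

  if (!is.null(contact_model) && !is.null(tempo)) {
    n <- nrow(events)
    feats <- t(vapply(seq_len(n), function(i) {
      win <- c(events$peak_time[i] - 0.3, events$peak_time[i] + 0.6)
      contact_features(tempo$spectrum, win)
    }, numeric(length(contact_features(tempo$spectrum,
                                       c(tempo$spectrum$time[1],
                                         tempo$spectrum$time[1] + 1))))))
    ind$contact <- predict_contact(contact_model, feats)
  }
  ind$si <- si
  ind$bs <- bs
  ind
}

#' Build a personalized gait profile
#'
#' Summarizes a trace into per-parameter means and z-scores against a
#' reference population: `z = (value - ref_mean) / ref_sd`. The two
#' double-support measures are averaged into one `double_support` parameter
#' for profiling. Parameters absent from the trace are omitted; estimated
#' parameters missing from the reference are listed in the `unreferenced`
#' attribute and excluded.
#'
#' @param results a `gait_results` list from [run_pipeline()].
#' @param reference a `reference_population` (default the packaged one).
#' @return data.frame of class `gait_profile`: `parameter`, `group`,
#'   `value`, `ref_mean`, `ref_sd`, `z`.
#' @export
build_profile <- function(results, reference = reference_population()) {
  vals <- list()
  tp <- if (!is.null(results$temporal)) results$temporal$params else NULL
  if (!is.null(tp)) {
    m <- function(v) if (all(is.na(v))) NULL else mean(v, na.rm = TRUE)
    vals$step_time <- m(tp$step_time)
    vals$stride_time <- m(tp$stride_time)
    vals$stance_time <- m(tp$stance_time)
    vals$swing_time <- m(tp$swing_time)
    vals$single_support <- m(tp$single_support)
    ds <- c(tp$double_support1, tp$double_support2)
    vals$double_support <- if (all(is.na(ds))) NULL else mean(ds, na.rm = TRUE)
  }
  sp <- if (!is.null(results$spatial)) results$spatial$params else NULL
  if (!is.null(sp)) {
    m <- function(v) if (all(is.na(v))) NULL else mean(v, na.rm = TRUE)
    vals$step_length <- m(sp$step_length)
    vals$step_width <- m(sp$step_width)
    vals$step_angle <- m(sp$step_angle)
    vals$stride_length <- m(sp$stride_length)
  }
  ind <- results$indicators
  if (!is.null(ind)) {
    vals$cadence <- ind$cadence
    if (!is.null(ind$walking_speed_mean))
      vals$walking_speed <- ind$walking_speed_mean
  }
  vals <- vals[!vapply(vals, is.null, TRUE)]
  unref <- setdiff(names(vals), reference$parameter)
  vals <- vals[setdiff(names(vals), unref)]
  i <- match(names(vals), reference$parameter)
  out <- data.frame(
    parameter = names(vals), group = reference$group[i],
    value = unlist(vals), ref_mean = reference$mean[i],
    ref_sd = reference$sd[i], stringsAsFactors = FALSE
  )
  out$z <- (out$value - out$ref_mean) / out$ref_sd
  rownames(out) <- NULL
  attr(out, "unreferenced") <- unref
  structure(out, class = c("gait_profile", "data.frame"))
}

#' Radar plot of a gait profile
#'
#' z-score rings around the population mean (the zero circle), with the
#' temporal (green), spatial (red) and indicator (blue) parameter groups
#' colour-coded.
#'
#' @param profile a `gait_profile` from [build_profile()].
#' @param z_limit radial axis limit in z units.
#' @return a ggplot object.
#' @export
plot_gait_profile <- function(profile, z_limit = 3) {
  df <- as.data.frame(profile)
  df$z_clip <- pmin(pmax(df$z, -z_limit), z_limit)
  df$parameter <- factor(df$parameter,
                         levels = df$parameter[order(df$group)])
  df <- df[order(df$parameter), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = parameter, y = z_clip)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50",
                        linetype = "dashed") +
    ggplot2::geom_polygon(ggplot2::aes(group = 1), fill = NA,
                          colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = group), size = 3) +
    ggplot2::scale_colour_manual(values = c(temporal = "forestgreen",
                                            spatial = "firebrick",
                                            indicator = "steelblue")) +
    ggplot2::coord_polar() +
    ggplot2::ylim(-z_limit, z_limit) +
    ggplot2::labs(y = "z-score vs reference", x = NULL,
                  title = "Personalized gait profile") +
    ggplot2::theme_minimal()
  p
}

#' Write pipeline results to a directory
#'
#' Persists every stage's output as CSV/JSON: `events.csv`, `temporal.csv`,
#' `locations.csv`, `spatial.csv`, `indicators.json`, `bands.json`,
#' `warnings.txt`.
#'
#' @param results a `gait_results` list.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$events))
    write_events(results$events, file.path(dir, "events.csv"))
  if (!is.null(results$temporal) && !is.null(results$temporal$params))
    write.csv(results$temporal$params, file.path(dir, "temporal.csv"),
              row.names = FALSE)
  if (!is.null(results$bands))
    jsonlite::write_json(list(strike_band = results$bands$strike_band,
                              off_band = results$bands$off_band),
                         file.path(dir, "bands.json"), digits = NA)
  if (!is.null(results$spatial)) {
    write.csv(results$spatial$locations, file.path(dir, "locations.csv"),
              row.names = FALSE)
    if (!is.null(results$spatial$params))
      write.csv(results$spatial$params, file.path(dir, "spatial.csv"),
                row.names = FALSE)
  }
  if (!is.null(results$indicators)) {
    ind <- results$indicators
    ind$contact <- NULL
    jsonlite::write_json(ind, file.path(dir, "indicators.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(results$indicators$contact))
      write.csv(results$indicators$contact, file.path(dir, "contact.csv"),
                row.names = FALSE)
  }
  writeLines(results$warnings %||% character(0),
             file.path(dir, "warnings.txt"))
  invisible(dir)
}
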