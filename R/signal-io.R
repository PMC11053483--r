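# Base containers: multichannel vibration records and sensor layouts.

#' Multichannel vibration record
#'
#' A sampled multichannel floor-vibration signal. Channels are stored as the
#' columns of a numeric matrix whose column names are the sensor ids; sample
#' index 1 corresponds to `start_time`, and all event times produced by the
#' pipeline are reported in seconds from the record start.
#'
#' @param samples numeric matrix, one column per sensor (column names are the
#'   sensor ids; unnamed columns get ids `S1, S2, ...`).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds (default 0).
#' @return an object of class `vibration_record` with fields `samples`,
#'   `sample_rate`, `start_time`.
#' @examples
#' rec <- vibration_record(cbind(S1 = sin(1:100), S2 = cos(1:100)), 100)
#' rec_times(rec)[1:3]
#' @export
vibration_record <- function(samples, sample_rate, start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop_field("samples", "must be numeric")
  if (!all(is.finite(samples))) stop_field("samples", "must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop_field("sample_rate", "must be a single positive number")
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("S", seq_len(ncol(samples)))
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "vibration_record"
  )
}

#' @export
print.vibration_record <- function(x, ...) {
  cat(sprintf(
    "<vibration_record> %d channels (%s), %d samples @ %g Hz, %.3f s\n",
    ncol(x$samples), paste(colnames(x$samples), collapse = ", "),
    nrow(x$samples), x$sample_rate, nrow(x$samples) / x$sample_rate
  ))
  invisible(x)
}

#' Sample times of a record
#' @param record a [vibration_record()].
#' @return numeric vector of times in seconds.
#' @export
rec_times <- function(record) {
  record$start_time + (seq_len(nrow(record$samples)) - 1) / record$sample_rate
}

#' Sensor ids of a record
#' @param record a [vibration_record()].
#' @export
rec_sensors <- function(record) colnames(record$samples)

# Extract one channel as a numeric vector, by sensor id.
rec_channel <- function(record, sensor) {
  if (!sensor %in% colnames(record$samples))
    stop(sprintf("unknown sensor id '%s'", sensor), call. = FALSE)
  record$samples[, sensor]
}

#' Sensor layout
#'
#' Planar sensor coordinates in metres. x is the longitudinal walkway axis and
#' y the lateral axis; the first sensor conventionally sits near x = 0.
#'
#' @param sensor character vector of unique sensor ids.
#' @param x,y numeric coordinates in metres.
#' @return an object of class `sensor_layout` (a data.frame with columns
#'   `sensor`, `x`, `y`).
#' @examples
#' sensor_layout(c("S1", "S2"), x = c(0, 2), y = c(0, 0))
#' @export
sensor_layout <- function(sensor, x, y) {
  sensor <- as.character(sensor)
  if (anyDuplicated(sensor)) stop_field("sensor", "ids must be unique")
  if (length(x) != length(sensor) || length(y) != length(sensor))
    stop_field("x/y", "must match the number of sensor ids")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_field("x/y", "coordinates must be finite numbers")
  structure(
    data.frame(sensor = sensor, x = as.numeric(x), y = as.numeric(y),
               stringsAsFactors = FALSE),
    class = c("sensor_layout", "data.frame")
  )
}

# Euclidean distances from every sensor to a point (px, py); named vector.
layout_distances <- function(layout, px, py) {
  setNames(sqrt((layout$x - px)^2 + (layout$y - py)^2), layout$sensor)
}

#' Read a sensor layout from JSON
#'
#' The file maps sensor ids to `[x, y]` coordinate pairs in metres, e.g.
#' `{"S1": [0, 0], "S2": [2, 0]}`.
#'
#' @param path path to a JSON file.
#' @return a [sensor_layout()].
#' @export
read_layout <- function(path) {
  raw <- jsonlite::read_json(path)
  if (length(raw) == 0) stop("layout file contains no sensors", call. = FALSE)
  ids <- names(raw)
  if (is.null(ids) || anyDuplicated(ids))
    stop("layout ids must be unique and named", call. = FALSE)
  xy <- lapply(raw, function(p) {
    p <- unlist(p)
    if (length(p) != 2 || !is.numeric(p))
      stop("each layout entry must be a numeric [x, y] pair", call. = FALSE)
    p
  })
  m <- do.call(rbind, xy)
  sensor_layout(ids, m[, 1], m[, 2])
}

#' Write a sensor layout to JSON
#' @param layout a [sensor_layout()].
#' @param path output path.
#' @export
write_layout <- function(layout, path) {
  obj <- lapply(seq_len(nrow(layout)), function(i) c(layout$x[i], layout$y[i]))
  names(obj) <- layout$sensor
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read a vibration record
#'
#' Two formats are supported. `"csv"` is delimited text with a header row
#' `time_s,S1,S2,...`: the sample rate is recovered from the time column.
#' `"bin"` is the package's float32 binary format (a JSON header line followed
#' by little-endian float32 samples in channel-interleaved order), written by
#' [write_record()].
#'
#' @param path input path.
#' @param format `"csv"` or `"bin"`; default guesses from the file extension.
#' @return a [vibration_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "bin")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bin$", path)) "bin" else "csv"
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  if (format == "csv") read_record_csv(path) else read_record_bin(path)
}

read_record_csv <- function(path) {
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop(sprintf("unreadable record '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  if (nrow(df) == 0) stop("record file has no samples", call. = FALSE)
  if (!"time_s" %in% names(df))
    stop("record file is missing the 'time_s' column (sample-rate metadata)",
         call. = FALSE)
  chans <- setdiff(names(df), "time_s")
  if (length(chans) == 0) stop("record file has no channels", call. = FALSE)
  for (ch in chans) {
    if (anyNA(df[[ch]]))
      stop(sprintf("channel '%s' is shorter than the others (ragged columns)",
                   ch), call. = FALSE)
    if (!is.numeric(df[[ch]]))
      stop(sprintf("channel '%s' is not numeric", ch), call. = FALSE)
  }
  tm <- df$time_s
  if (nrow(df) < 2) stop("record needs at least two samples", call. = FALSE)
  fs <- 1 / median(diff(tm))
  vibration_record(as.matrix(df[chans]), sample_rate = fs, start_time = tm[1])
}

read_record_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0) stop("record file has no samples", call. = FALSE)
  meta <- jsonlite::fromJSON(header)
  n <- meta$n_samples
  ids <- meta$sensors
  vals <- readBin(con, "numeric", n = n * length(ids), size = 4,
                  endian = "little")
  if (length(vals) < n * length(ids))
    stop("record file is truncated", call. = FALSE)
  m <- matrix(vals, nrow = n, ncol = length(ids), byrow = TRUE)
  colnames(m) <- ids
  vibration_record(m, sample_rate = as.numeric(meta$sample_rate),
                   start_time = as.numeric(meta$start_time %||% 0))
}

#' Write a vibration record
#'
#' @param record a [vibration_record()].
#' @param path output path.
#' @param format `"csv"` (text, header `time_s,S1,...`) or `"bin"` (float32
#'   binary with a JSON header line). Text round-trips samples to better than
#'   1e-6 relative error; binary is bit-exact at float32 precision.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "bin")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bin$", path)) "bin" else "csv"
  if (format == "csv") {
    df <- data.frame(time_s = rec_times(record), check.names = FALSE)
    df <- cbind(df, as.data.frame(record$samples, check.names = FALSE))
    # 9 significant digits keeps the text round-trip under 1e-6 relative error
    write.csv(format(df, digits = 9, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- jsonlite::toJSON(list(
      sample_rate = record$sample_rate, start_time = record$start_time,
      n_samples = nrow(record$samples), sensors = rec_sensors(record)
    ), auto_unbox = TRUE, digits = NA)
    writeLines(as.character(hdr), con)
    writeBin(as.numeric(t(record$samples)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Check that a record and a layout describe the same sensors
#'
#' @param record a [vibration_record()].
#' @param layout a [sensor_layout()].
#' @return invisibly `TRUE`; errors listing the missing ids otherwise.
#' @export
check_layout_record <- function(record, layout) {
  missing <- setdiff(rec_sensors(record), layout$sensor)
  if (length(missing))
    stop(sprintf("sensors missing from layout: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
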