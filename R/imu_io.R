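#' Multi-sensor IMU recordings
#'
#' A recording holds synchronized tri-axial accelerometer and gyroscope
#' streams from up to four limb-worn sensors, all sharing one sampling rate
#' and sample count. Accelerometer values are in m/s^2 with gravity included;
#' gyroscope values are in rad/s. Sensor order is always canonical
#' (left_arm, right_arm, left_leg, right_leg, filtered to the present
#' subset) so that concatenated channel indices are reproducible.
#'
#' @name imu_io
NULL

#' Canonical sensor placements
#' @export
CH_PLACEMENTS <- c("left_arm", "right_arm", "left_leg", "right_leg")

canonical_sensors <- function(sensors) {
  bad <- setdiff(sensors, CH_PLACEMENTS)
  if (length(bad)) {
    stop(sprintf("unknown sensor placement(s): %s", paste(bad, collapse = ", ")))
  }
  CH_PLACEMENTS[CH_PLACEMENTS %in% sensors]
}

#' Construct a recording
#'
#' @param data named list, one entry per sensor placement, each a list with
#'   elements `acc` (n x 3 matrix, m/s^2, gravity included) and `gyro`
#'   (n x 3 matrix, rad/s). `gyro` may be omitted (accelerometer-only
#'   recording), but then for every sensor; such recordings support only the
#'   accelerometer input modalities.
#' @param rate_hz sampling rate in Hz (nominally 52).
#' @param id recording identifier string.
#' @param start_time recording start, seconds (annotations share this clock).
#' @return an object of class `ch_recording`.
#' @export
recording <- function(data, rate_hz = 52, id = "rec", start_time = 0) {
  if (!length(data) || is.null(names(data))) {
    stop("`data` must be a non-empty named list of sensors")
  }
  sensors <- canonical_sensors(names(data))
  if (length(sensors) != length(data)) stop("duplicate sensor placements")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be a positive number")
  }
  ns <- NULL
  has_gyro <- !is.null(data[[sensors[1]]]$gyro)
  out <- list()
  for (s in sensors) {
    d <- data[[s]]
    if (is.null(d$gyro) == has_gyro) {
      stop("gyroscope channels must be present for all sensors or none")
    }
    acc <- as.matrix(d$acc)
    if (ncol(acc) != 3L) stop(sprintf("sensor '%s': acc must have 3 columns", s))
    if (is.null(ns)) ns <- nrow(acc)
    if (nrow(acc) != ns) stop("inconsistent channel lengths across sensors")
    storage.mode(acc) <- "double"
    colnames(acc) <- c("ax", "ay", "az")
    gyro <- NULL
    if (has_gyro) {
      gyro <- as.matrix(d$gyro)
      if (ncol(gyro) != 3L) {
        stop(sprintf("sensor '%s': gyro must have 3 columns", s))
      }
      if (nrow(gyro) != ns) {
        stop(sprintf("sensor '%s': acc and gyro lengths differ", s))
      }
      storage.mode(gyro) <- "double"
      colnames(gyro) <- c("gx", "gy", "gz")
    }
    out[[s]] <- list(acc = acc, gyro = gyro)
  }
  if (ns == 0L) stop("empty recording")
  structure(list(id = as.character(id), rate_hz = as.numeric(rate_hz),
                 start_time = as.numeric(start_time), sensors = sensors,
                 n_samples = ns, has_gyro = has_gyro, data = out),
            class = "ch_recording")
}

#' @export
print.ch_recording <- function(x, ...) {
  cat(sprintf("<ch_recording> id=%s  %d sensors (%s)\n", x$id,
              length(x$sensors), paste(x$sensors, collapse = ", ")))
  cat(sprintf("  %d samples/channel at %g Hz (%.1f min), %d channels total\n",
              x$n_samples, x$rate_hz, x$n_samples / x$rate_hz / 60,
              6L * length(x$sensors)))
  invisible(x)
}

#' Number of scalar channels in a recording (6 per sensor)
#' @param rec a `ch_recording`.
#' @export
n_channels <- function(rec) 6L * length(rec$sensors)

#' Select a subset of sensors
#'
#' Returns a recording containing exactly the requested placements, with
#' untouched samples and unchanged rate; canonical ordering is preserved
#' regardless of the order of `placements`.
#'
#' @param rec a `ch_recording`.
#' @param placements non-empty character vector of placements to keep.
#' @export
select_sensors <- function(rec, placements) {
  stopifnot(inherits(rec, "ch_recording"))
  if (!length(placements)) stop("sensor subset must be non-empty")
  placements <- canonical_sensors(unique(placements))
  missing <- setdiff(placements, rec$sensors)
  if (length(missing)) {
    stop(sprintf("sensor(s) not present in recording: %s",
                 paste(missing, collapse = ", ")))
  }
  recording(rec$data[placements], rate_hz = rec$rate_hz, id = rec$id,
            start_time = rec$start_time)
}

#' Simulate a reduced sampling rate
#'
#' Emulates recording at 26 or 13 Hz while keeping the 52 Hz sample grid
#' (so downstream framing and classifier architecture are unchanged): the
#' signal is low-pass filtered with a zero-phase 8th-order anti-alias filter
#' at 0.8 x (target/2) Hz, decimated by the integer factor, then upsampled
#' by zero insertion and low-pass filtered again with gain compensation.
#' Frequency content above the simulated Nyquist is suppressed; a target of
#' 52 Hz returns the input unchanged.
#'
#' @param rec a `ch_recording` at 52 Hz.
#' @param target_hz one of 52, 26, 13.
#' @export
simulate_rate <- function(rec, target_hz) {
  stopifnot(inherits(rec, "ch_recording"))
  if (!target_hz %in% c(52, 26, 13)) {
    stop("`target_hz` must be one of 52, 26, 13")
  }
  if (rec$rate_hz != 52) stop("rate simulation expects a 52 Hz recording")
  if (target_hz == 52) return(rec)
  factor <- as.integer(52 / target_hz)
  spec <- filter_spec("low_pass", 8, 0.8 * target_hz / 2)
  sos <- spec_to_sos(spec, rec$rate_hz)
  n <- rec$n_samples
  process <- function(x) {
    x <- sos_filtfilt(sos, x)
    dec <- x[seq(1L, n, by = factor)]
    nd <- length(dec)
    ## pad by odd reflection at the decimated level so the zero-insertion
    ## comb pattern continues coherently past both edges
    pd <- min(nd - 1L, ceiling(sos_padlen(sos, n) / factor) + 2L)
    dec_p <- c(2 * dec[1] - dec[(pd + 1):2], dec,
               2 * dec[nd] - dec[(nd - 1):(nd - pd)])
    up <- numeric(length(dec_p) * factor)
    up[seq(1L, length(up), by = factor)] <- dec_p
    y <- factor * sos_filtfilt(sos, up)
    y[pd * factor + seq_len(n)]
  }
  data <- lapply(rec$data, function(d) {
    list(acc = apply(d$acc, 2, process),
         gyro = if (!is.null(d$gyro)) apply(d$gyro, 2, process))
  })
  recording(data, rate_hz = rec$rate_hz, id = rec$id,
            start_time = rec$start_time)
}

## ---------------------------------------------------------------------------
## File formats
##
## Delimited text: header line "# rate_hz=<num> id=<str> sensors=<a,b,...>"
## followed by rows "t,sensor,ax,ay,az,gx,gy,gz" (t in seconds).
##
## Binary container: single file, little-endian --
##   bytes 1-8   : magic "CARRYSNS"
##   int32       : header length H
##   H bytes     : JSON header {id, rate_hz, start_time, sensors, n_samples}
##   per sensor in header order: n x 3 doubles acc (column-major),
##                               n x 3 doubles gyro (column-major)
## ---------------------------------------------------------------------------

BIN_MAGIC <- charToRaw("CARRYSNS")

detect_format <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = 8L)
  if (length(head) == 8L && identical(head, BIN_MAGIC)) "binary" else "delimited"
}

#' Load a recording from disk
#'
#' @param path file path.
#' @param format `"auto"` (default; sniffs the binary magic), `"delimited"`
#'   or `"binary"`. See the package vignette for the format definitions.
#' @return a `ch_recording` with canonical sensor order.
#' @export
load_recording <- function(path, format = c("auto", "delimited", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") format <- detect_format(path)
  if (format == "binary") load_recording_binary(path)
  else load_recording_delimited(path)
}

load_recording_delimited <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#")) {
    stop("malformed header: first line must start with '#'")
  }
  hdr <- lines[1]
  get_field <- function(name) {
    m <- regmatches(hdr, regexpr(sprintf("%s=[^ ]+", name), hdr))
    if (!length(m)) stop(sprintf("malformed header: missing field '%s'", name))
    sub(sprintf("%s=", name), "", m)
  }
  rate_hz <- suppressWarnings(as.numeric(get_field("rate_hz")))
  if (is.na(rate_hz) || rate_hz <= 0) {
    stop("malformed header: rate_hz must be a positive number")
  }
  id <- get_field("id")
  sensors <- strsplit(get_field("sensors"), ",")[[1]]
  sensors <- canonical_sensors(sensors)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stop("empty recording")
  df <- utils::read.csv(text = body, header = FALSE,
                        col.names = c("t", "sensor", "ax", "ay", "az",
                                      "gx", "gy", "gz"),
                        stringsAsFactors = FALSE)
  data <- list()
  ns <- NULL
  for (s in sensors) {
    rows <- df[df$sensor == s, , drop = FALSE]
    if (!nrow(rows)) stop(sprintf("sensor '%s' declared but has no samples", s))
    rows <- rows[order(rows$t), , drop = FALSE]
    dt <- diff(rows$t)
    if (any(dt > 2 / rate_hz + 1e-9)) {
      at <- rows$t[which(dt > 2 / rate_hz + 1e-9)[1]]
      stop(sprintf("timestamp gap > 2 sample periods in sensor '%s' at %.3f s",
                   s, at))
    }
    if (is.null(ns)) ns <- nrow(rows)
    if (nrow(rows) != ns) {
      stop(sprintf("inconsistent channel lengths: sensor '%s' has %d samples, expected %d",
                   s, nrow(rows), ns))
    }
    data[[s]] <- list(acc = as.matrix(rows[, c("ax", "ay", "az")]),
                      gyro = as.matrix(rows[, c("gx", "gy", "gz")]))
  }
  start_time <- min(df$t)
  recording(data, rate_hz = rate_hz, id = id, start_time = start_time)
}

load_recording_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, BIN_MAGIC)) stop("malformed header: bad magic bytes")
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(hlen) || is.na(hlen) || hlen <= 0) {
    stop("malformed header: bad header length")
  }
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  if (is.null(hdr$rate_hz) || hdr$rate_hz <= 0) {
    stop("malformed header: rate_hz must be positive")
  }
  n <- as.integer(hdr$n_samples)
  if (is.na(n) || n <= 0) stop("empty recording")
  data <- list()
  for (s in hdr$sensors) {
    acc <- matrix(readBin(con, "double", n = 3L * n, size = 8L,
                          endian = "little"), n, 3L)
    gyro <- matrix(readBin(con, "double", n = 3L * n, size = 8L,
                           endian = "little"), n, 3L)
    if (nrow(acc) != n) stop("inconsistent channel lengths: truncated file")
    data[[s]] <- list(acc = acc, gyro = gyro)
  }
  start_time <- if (is.null(hdr$start_time)) 0 else hdr$start_time
  recording(data, rate_hz = hdr$rate_hz, id = hdr$id, start_time = start_time)
}

#' Write a recording to disk
#'
#' The binary container round-trips samples bit-exactly; the delimited text
#' format round-trips to the declared decimal precision.
#'
#' @param rec a `ch_recording`.
#' @param path output file path.
#' @param format `"delimited"` or `"binary"`.
#' @param digits significant decimal digits for the delimited format.
#' @export
write_recording <- function(rec, path, format = c("delimited", "binary"),
                            digits = 6) {
  stopifnot(inherits(rec, "ch_recording"))
  format <- match.arg(format)
  if (!rec$has_gyro) {
    stop("cannot serialize a recording without gyroscope channels")
  }
  if (format == "binary") {
    con <- file(path, "wb"); on.exit(close(con))
    hdr <- jsonlite::toJSON(list(id = rec$id, rate_hz = rec$rate_hz,
                                 start_time = rec$start_time,
                                 sensors = rec$sensors,
                                 n_samples = rec$n_samples),
                            auto_unbox = TRUE)
    hraw <- charToRaw(as.character(hdr))
    writeBin(BIN_MAGIC, con)
    writeBin(length(hraw), con, size = 4L, endian = "little")
    writeBin(hraw, con)
    for (s in rec$sensors) {
      writeBin(as.vector(rec$data[[s]]$acc), con, size = 8L, endian = "little")
      writeBin(as.vector(rec$data[[s]]$gyro), con, size = 8L, endian = "little")
    }
  } else {
    t <- rec$start_time + (seq_len(rec$n_samples) - 1L) / rec$rate_hz
    hdr <- sprintf("# rate_hz=%g id=%s sensors=%s", rec$rate_hz, rec$id,
                   paste(rec$sensors, collapse = ","))
    fmt <- sprintf("%%.%df", digits)
    blocks <- vapply(rec$sensors, function(s) {
      m <- cbind(rec$data[[s]]$acc, rec$data[[s]]$gyro)
      vals <- apply(m, 1, function(r) paste(sprintf(fmt, r), collapse = ","))
      paste(sprintf("%.6f", t), s, vals, sep = ",", collapse = "\n")
    }, character(1))
    writeLines(c(hdr, blocks), path)
  }
  invisible(path)
}
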