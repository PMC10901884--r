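#' Preprocessing: gravity split, input assembly and framing
#'
#' The classifier consumes fixed-length overlapping frames of the assembled
#' input channels. Accelerometer signals can be decomposed into a slow
#' (gravity/orientation, f < 0.5 Hz) and a fast (movement, f > 0.5 Hz)
#' component with an 8th-order Butterworth high-pass: the high-pass output is
#' the movement component and the gravity component is obtained by
#' subtraction, so the two always sum back to the input exactly.
#'
#' @name preprocess
NULL

#' Framing configuration
#'
#' Defaults follow the 2.3 s / 50% overlap analysis grid: 120-sample frames
#' with a 60-sample hop at 52 Hz.
#'
#' @param frame_len_samples frame length in samples.
#' @param hop_samples hop between frame starts in samples.
#' @param rate_hz sampling rate the frame grid refers to.
#' @return an object of class `ch_framing`.
#' @export
framing_config <- function(frame_len_samples = 120L, hop_samples = 60L,
                           rate_hz = 52) {
  frame_len_samples <- as.integer(frame_len_samples)
  hop_samples <- as.integer(hop_samples)
  if (frame_len_samples < 1L || hop_samples < 1L ||
      hop_samples > frame_len_samples) {
    stop("need 0 < hop_samples <= frame_len_samples")
  }
  structure(list(frame_len_samples = frame_len_samples,
                 hop_samples = hop_samples, rate_hz = as.numeric(rate_hz),
                 frame_len_s = frame_len_samples / rate_hz,
                 overlap = 1 - hop_samples / frame_len_samples),
            class = "ch_framing")
}

#' Number of frames obtainable from a signal
#' @param n_samples samples per channel.
#' @param cfg a [framing_config()].
#' @export
n_frames_for <- function(n_samples, cfg) {
  if (n_samples < cfg$frame_len_samples) return(0L)
  as.integer((n_samples - cfg$frame_len_samples) %/% cfg$hop_samples + 1L)
}

#' Frame start/end times
#'
#' Frames are half-open intervals `[start, start + frame_len_s)` in seconds
#' from the recording start, indexed from frame 1 at t = 0.
#'
#' @inheritParams n_frames_for
#' @return two-column matrix (start_s, end_s), one row per frame.
#' @export
frame_times <- function(n_samples, cfg) {
  nf <- n_frames_for(n_samples, cfg)
  start <- (seq_len(nf) - 1L) * cfg$hop_samples / cfg$rate_hz
  cbind(start_s = start, end_s = start + cfg$frame_len_s)
}

#' Split a signal into gravity and movement components
#'
#' @param x numeric vector (one accelerometer channel).
#' @param rate_hz sampling rate in Hz.
#' @param cutoff_hz high-pass cutoff (default 0.5 Hz).
#' @param order filter order (default 8).
#' @return list with elements `low` (gravity/orientation) and `high`
#'   (movement); `low + high` equals `x` exactly by construction.
#' @export
split_gravity <- function(x, rate_hz, cutoff_hz = 0.5, order = 8L) {
  minlen <- 3L * order
  if (length(x) <= minlen) {
    stop(sprintf("signal too short for gravity split: need > %d samples", minlen))
  }
  if (rate_hz <= 1) stop("`rate_hz` must exceed 1 Hz")
  high <- zero_phase_filter(x, filter_spec("high_pass", order, cutoff_hz),
                            rate_hz)
  list(low = x - high, high = high)
}

#' Assemble classifier input channels from a recording
#'
#' Builds the channel matrix fed to the neural classifier, with a layout
#' descriptor that routes channel blocks to the encoder heads:
#' \describe{
#'   \item{acc_gyro}{raw accelerometer to the accelerometer head, gyroscope
#'     to the gyroscope head (6 channels/sensor).}
#'   \item{acc_preprocessed}{low-pass (f < 0.5 Hz) accelerometer to the
#'     accelerometer head; the high-pass accelerometer replaces the
#'     gyroscope input (6 channels/sensor, no gyroscope used).}
#'   \item{acc_raw}{raw accelerometer only; the gyroscope head is inactive
#'     (3 channels/sensor).}
#' }
#'
#' @param rec a `ch_recording`.
#' @param modality one of `"acc_gyro"`, `"acc_preprocessed"`, `"acc_raw"`.
#' @param gravity_cutoff_hz,gravity_order gravity-split filter parameters.
#' @return list of class `ch_input`: `series` (channels x samples matrix),
#'   `layout` (data.frame with sensor, head, axis per channel), `modality`,
#'   `heads` (active head names), `sensors`, `rate_hz`.
#' @export
assemble_input <- function(rec,
                           modality = c("acc_gyro", "acc_preprocessed",
                                        "acc_raw"),
                           gravity_cutoff_hz = 0.5, gravity_order = 8L) {
  stopifnot(inherits(rec, "ch_recording"))
  modality <- match.arg(modality)
  if (modality == "acc_gyro" && !isTRUE(rec$has_gyro)) {
    stop("modality 'acc_gyro' requires gyroscope channels, which this recording lacks")
  }
  per_sensor <- if (modality == "acc_raw") 3L else 6L
  series <- matrix(0, nrow = per_sensor * length(rec$sensors),
                   ncol = rec$n_samples)
  layout <- data.frame(sensor = character(0), head = character(0),
                       axis = character(0))
  row <- 0L
  for (s in rec$sensors) {
    acc <- t(rec$data[[s]]$acc)
    if (modality == "acc_gyro") {
      block <- rbind(acc, t(rec$data[[s]]$gyro))
      heads <- rep(c("acc", "gyro"), each = 3L)
      axes <- c("ax", "ay", "az", "gx", "gy", "gz")
    } else if (modality == "acc_preprocessed") {
      sg <- apply(rec$data[[s]]$acc, 2, function(ch) {
        g <- split_gravity(ch, rec$rate_hz, gravity_cutoff_hz, gravity_order)
        cbind(g$low, g$high)
      })
      ## sg: (2n) x 3 with low stacked on high per column
      n <- rec$n_samples
      low <- t(sg[seq_len(n), , drop = FALSE])
      high <- t(sg[n + seq_len(n), , drop = FALSE])
      block <- rbind(low, high)
      heads <- rep(c("acc", "gyro"), each = 3L)
      axes <- c("ax_low", "ay_low", "az_low", "ax_high", "ay_high", "az_high")
    } else {
      block <- acc
      heads <- rep("acc", 3L)
      axes <- c("ax", "ay", "az")
    }
    series[row + seq_len(per_sensor), ] <- block
    layout <- rbind(layout, data.frame(sensor = s, head = heads, axis = axes))
    row <- row + per_sensor
  }
  structure(list(series = series, layout = layout, modality = modality,
                 heads = if (modality == "acc_raw") "acc" else c("acc", "gyro"),
                 sensors = rec$sensors, rate_hz = rec$rate_hz),
            class = "ch_input")
}

#' Segment an assembled input into overlapping frames
#'
#' @param input a `ch_input` from [assemble_input()], or a channels x samples
#'   numeric matrix.
#' @param cfg a [framing_config()].
#' @return object of class `ch_frames`: `frames` (C x L x F array),
#'   `frame_times` (F x 2 matrix), plus the layout/modality carried over.
#'   Trailing samples that do not fill a frame are dropped.
#' @export
make_frames <- function(input, cfg = framing_config()) {
  series <- if (inherits(input, "ch_input")) input$series else as.matrix(input)
  n <- ncol(series)
  L <- cfg$frame_len_samples
  nf <- n_frames_for(n, cfg)
  if (nf < 1L) {
    stop(sprintf("series too short to frame: %d samples < frame length %d",
                 n, L))
  }
  C <- nrow(series)
  idx <- outer(seq_len(L), (seq_len(nf) - 1L) * cfg$hop_samples, "+")
  frames <- array(series[, as.vector(idx)], dim = c(C, L, nf))
  structure(list(frames = frames, frame_times = frame_times(n, cfg),
                 layout = if (inherits(input, "ch_input")) input$layout,
                 modality = if (inherits(input, "ch_input")) input$modality,
                 sensors = if (inherits(input, "ch_input")) input$sensors,
                 heads = if (inherits(input, "ch_input")) input$heads,
                 cfg = cfg),
            class = "ch_frames")
}

#' @export
print.ch_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ch_frames> %d frames x %d channels x %d samples (%s)\n",
              d[3], d[1], d[2],
              if (is.null(x$modality)) "raw matrix" else x$modality))
  invisible(x)
}

#' Number of frames in a `ch_frames`
#' @param frames a `ch_frames`.
#' @export
n_frames <- function(frames) dim(frames$frames)[3]
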