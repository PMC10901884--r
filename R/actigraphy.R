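#' Actigraphy baseline detector
#'
#' The classical single-sensor movement-quantification baseline: the
#' tri-axial accelerometer magnitude \eqn{a_{mag} = \sqrt{a_x^2 + a_y^2 +
#' a_z^2}} is band-pass filtered to 1-6 Hz (4th-order Butterworth), and a
#' moving integral -- the sum of absolute filtered magnitude values within
#' each analysis frame -- serves as an activity count. Carrying is detected
#' by thresholding the count; the threshold is swept over the empirical
#' count distribution and scored with kappa/accuracy against reference
#' labels.
#'
#' @name actigraphy
NULL

#' Euclidean magnitude of a tri-axial signal
#'
#' @param acc n x 3 matrix (columns = axes).
#' @return numeric vector of pointwise Euclidean norms.
#' @export
magnitude <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("`acc` must have exactly 3 channels (columns)")
  sqrt(rowSums(acc^2))
}

#' Per-frame actigraphy activity counts
#'
#' @param rec a `ch_recording`, or an n x 3 accelerometer matrix.
#' @param sensor sensor placement used for the single-sensor count (default
#'   `"left_arm"`, matching common wrist-worn actigraphy practice); ignored
#'   when `rec` is a bare matrix.
#' @param cfg a [framing_config()] defining the analysis frames; window
#'   variants (e.g. 1.15 s to 10 s) are supported through it.
#' @param band_hz band-pass range in Hz.
#' @param order Butterworth order of the band-pass.
#' @param rate_hz sampling rate; taken from the recording when available.
#' @return object of class `ch_actigraphy`: `counts` (one non-negative
#'   value per frame), `frame_times`, `sensor`, `cfg`.
#' @export
actigraphy_counts <- function(rec, sensor = "left_arm",
                              cfg = framing_config(), band_hz = c(1, 6),
                              order = 4L, rate_hz = NULL) {
  if (inherits(rec, "ch_recording")) {
    if (!sensor %in% rec$sensors) {
      stop(sprintf("sensor '%s' not present in recording", sensor))
    }
    acc <- rec$data[[sensor]]$acc
    rate_hz <- rec$rate_hz
  } else {
    acc <- as.matrix(rec)
    if (is.null(rate_hz)) stop("`rate_hz` required for a bare matrix input")
  }
  if (rate_hz <= 2 * max(band_hz)) {
    stop(sprintf("sampling rate %g Hz too low for a %g-%g Hz band-pass",
                 rate_hz, band_hz[1], band_hz[2]))
  }
  amag <- magnitude(acc)
  flt <- zero_phase_filter(amag, filter_spec("band_pass", order, band_hz),
                           rate_hz)
  av <- abs(flt)
  nf <- n_frames_for(length(av), cfg)
  if (nf < 1L) stop("signal shorter than one frame")
  idx <- outer(seq_len(cfg$frame_len_samples),
               (seq_len(nf) - 1L) * cfg$hop_samples, "+")
  counts <- colSums(matrix(av[as.vector(idx)], cfg$frame_len_samples, nf))
  structure(list(counts = counts, frame_times = frame_times(length(av), cfg),
                 sensor = if (inherits(rec, "ch_recording")) sensor else NA,
                 cfg = cfg),
            class = "ch_actigraphy")
}

#' Threshold sweep of the actigraphy detector
#'
#' For each threshold, frames with count above the threshold are predicted
#' as carrying; kappa and accuracy are computed on the frames valid in the
#' reference. The default grid uses quantile-spaced points of the empirical
#' count distribution so the sweep covers all attainable operating points.
#'
#' @param feature a `ch_actigraphy` or numeric count vector.
#' @param ref binary reference labels: `ch_frame_labels` (binary scheme) or
#'   an integer vector (1 = non-carry, 2 = carry, NA = masked).
#' @param thresholds numeric grid; default 200 quantile-spaced points.
#' @return object of class `ch_sweep`: data.frame `curve` (threshold,
#'   kappa, accuracy), `best` (row maximizing kappa), `degenerate` flag set
#'   when the feature has no spread.
#' @export
threshold_sweep <- function(feature, ref, thresholds = NULL) {
  counts <- if (inherits(feature, "ch_actigraphy")) feature$counts
            else as.numeric(feature)
  if (inherits(ref, "ch_frame_labels")) {
    if (ref$scheme$n_classes != 2L) {
      stop("threshold sweep needs a binary reference scheme")
    }
    y <- ref$class_idx
  } else {
    y <- as.integer(ref)
  }
  if (length(y) != length(counts)) {
    stop("feature and reference lengths differ")
  }
  ok <- !is.na(y)
  counts_v <- counts[ok]; y_v <- y[ok]
  if (length(unique(y_v)) < 2L) {
    stop("reference contains a single class; sweep is undefined")
  }
  degenerate <- length(unique(counts_v)) < 2L
  if (is.null(thresholds)) {
    thresholds <- unique(stats::quantile(counts_v,
                                         probs = seq(0, 1, length.out = 200),
                                         names = FALSE, type = 7))
  }
  curve <- data.frame(threshold = thresholds, kappa = NA_real_,
                      accuracy = NA_real_)
  for (i in seq_along(thresholds)) {
    pred <- 1L + (counts_v > thresholds[i])
    cm <- matrix(tabulate(y_v + 2L * (pred - 1L), nbins = 4L), 2, 2)
    k <- suppressWarnings(kappa_multiclass(cm))
    curve$kappa[i] <- if (is.na(k)) 0 else k
    curve$accuracy[i] <- accuracy(cm)
  }
  best <- curve[which.max(curve$kappa), , drop = FALSE]
  structure(list(curve = curve, best = best, degenerate = degenerate),
            class = "ch_sweep")
}

#' @export
print.ch_sweep <- function(x, ...) {
  cat(sprintf("<ch_sweep> %d thresholds; best kappa %.3f (acc %.1f%%) at %.3g%s\n",
              nrow(x$curve), x$best$kappa, x$best$accuracy, x$best$threshold,
              if (x$degenerate) " [degenerate feature]" else ""))
  invisible(x)
}
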