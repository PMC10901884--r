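#' Butterworth filtering in second-order-section form
#'
#' Filter design and zero-phase application used throughout the package
#' (gravity/movement split, anti-alias filtering for sampling-rate simulation,
#' and the actigraphy band-pass). Filters are designed from the analog
#' Butterworth prototype poles and realized as a cascade of biquads
#' (second-order sections), which stays numerically well-conditioned at the
#' very low normalized cutoffs this package needs (e.g. 0.5 Hz at 52 Hz),
#' where a single 8th-order transfer function polynomial is fragile.
#'
#' @name filters
#' @keywords internal
NULL

#' Filter specification
#'
#' @param kind one of `"low_pass"`, `"high_pass"`, `"band_pass"`.
#' @param order filter order (of the analog prototype; a band-pass of order
#'   `n` is realized as an order-`n` high-pass cascaded with an order-`n`
#'   low-pass).
#' @param cutoffs_hz one cutoff frequency in Hz (low/high-pass) or two
#'   increasing frequencies (band-pass).
#' @return an object of class `ch_filter_spec`.
#' @export
filter_spec <- function(kind = c("low_pass", "high_pass", "band_pass"),
                        order, cutoffs_hz) {
  kind <- match.arg(kind)
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("`order` must be a positive integer")
  }
  nc <- if (kind == "band_pass") 2L else 1L
  if (length(cutoffs_hz) != nc || any(cutoffs_hz <= 0)) {
    stop(sprintf("`cutoffs_hz` must be %d positive frequencies for kind '%s'",
                 nc, kind))
  }
  if (nc == 2L && diff(cutoffs_hz) <= 0) {
    stop("band-pass cutoffs must be increasing")
  }
  structure(list(kind = kind, order = as.integer(order),
                 cutoffs_hz = as.numeric(cutoffs_hz)),
            class = "ch_filter_spec")
}

## Analog Butterworth prototype poles (unit cutoff), left half-plane.
butter_proto_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

## Design a digital Butterworth low- or high-pass as a list of biquads.
## Each section: list(b = c(b0,b1,b2), a = c(1,a1,a2)).
butter_sos <- function(order, fc_hz, rate_hz,
                       type = c("low", "high")) {
  type <- match.arg(type)
  if (fc_hz <= 0 || fc_hz >= rate_hz / 2) {
    stop(sprintf("cutoff %.3g Hz must lie in (0, rate/2) = (0, %.3g)",
                 fc_hz, rate_hz / 2))
  }
  fs2 <- 2 * rate_hz                      # bilinear constant 2/T
  wc <- fs2 * tan(pi * fc_hz / rate_hz)   # prewarped analog cutoff (rad/s)
  poles <- butter_proto_poles(order)
  poles <- if (type == "low") poles * wc else wc / poles
  ## pair conjugate poles; any real pole (odd order) becomes a 1st-order section
  used <- rep(FALSE, order)
  sections <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) < 1e-9 * abs(p)) {       # real pole -> first-order section
      used[i] <- TRUE
      zp <- (fs2 + Re(p)) / (fs2 - Re(p))   # digital pole
      if (type == "low") {
        b <- c(1, 1, 0); a <- c(1, -zp, 0)
      } else {
        b <- c(1, -1, 0); a <- c(1, -zp, 0)
      }
      sections[[length(sections) + 1L]] <- list(b = b, a = a)
    } else {
      j <- which(!used & abs(poles - Conj(p)) < 1e-6 * abs(p))[1]
      used[c(i, j)] <- TRUE
      zp <- (fs2 + p) / (fs2 - p)
      a <- c(1, -2 * Re(zp), Mod(zp)^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
      sections[[length(sections) + 1L]] <- list(b = b, a = a)
    }
  }
  ## normalize each section's gain at the reference frequency
  zref <- if (type == "low") 1 + 0i else -1 + 0i
  for (s in seq_along(sections)) {
    bb <- sections[[s]]$b; aa <- sections[[s]]$a
    g <- sum(aa * zref^(0:-2)) / sum(bb * zref^(0:-2))
    sections[[s]]$b <- bb * Re(g)
  }
  rmax <- max(vapply(sections, function(s) {
    max(Mod(polyroot(rev(s$a))), 0)
  }, numeric(1)))
  structure(sections, class = "ch_sos", rmax = rmax)
}

## Build the section cascade for a filter_spec (band-pass = HP %then% LP).
spec_to_sos <- function(spec, rate_hz) {
  stopifnot(inherits(spec, "ch_filter_spec"))
  if (any(spec$cutoffs_hz >= rate_hz / 2)) {
    stop("filter cutoffs must be below the Nyquist frequency")
  }
  sos <- switch(spec$kind,
    low_pass  = butter_sos(spec$order, spec$cutoffs_hz[1], rate_hz, "low"),
    high_pass = butter_sos(spec$order, spec$cutoffs_hz[1], rate_hz, "high"),
    band_pass = {
      hp <- butter_sos(spec$order, spec$cutoffs_hz[1], rate_hz, "high")
      lp <- butter_sos(spec$order, spec$cutoffs_hz[2], rate_hz, "low")
      structure(c(hp, lp), class = "ch_sos",
                rmax = max(attr(hp, "rmax"), attr(lp, "rmax")))
    })
  sos
}

## Single-pass causal run through one biquad (zero initial state), using the
## C loops in stats::filter.
biquad_apply <- function(sec, x) {
  b <- sec$b; a <- sec$a
  n <- length(x)
  v <- stats::filter(x, b, method = "convolution", sides = 1)
  v <- as.numeric(v)
  ## leading samples where the convolution window hangs off the start
  v[1] <- b[1] * x[1]
  if (n >= 2) v[2] <- b[1] * x[2] + b[2] * x[1]
  if (abs(a[2]) > 0 || abs(a[3]) > 0) {
    v <- as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
  }
  v
}

sos_apply <- function(sos, x) {
  for (sec in sos) x <- biquad_apply(sec, x)
  x
}

## Padding long enough for the slowest pole's transient to decay below ~1e-12.
sos_padlen <- function(sos, n) {
  rmax <- attr(sos, "rmax")
  need <- if (is.null(rmax) || rmax >= 1 || rmax <= 0) 3L * length(sos) * 3L
          else ceiling(-27.7 / log(rmax))
  max(9L, min(n - 1L, as.integer(need)))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies a second-order-section cascade forward and backward over the
#' signal, with odd-reflection padding at both ends so that edge transients
#' decay inside the padding rather than in the data. The squared magnitude
#' response of the design is obtained; phase is zero (offline processing).
#'
#' @param x numeric vector.
#' @param spec a [filter_spec()].
#' @param rate_hz sampling rate in Hz.
#' @return filtered numeric vector, same length as `x`.
#' @export
zero_phase_filter <- function(x, spec, rate_hz) {
  sos <- spec_to_sos(spec, rate_hz)
  sos_filtfilt(sos, x)
}

sos_filtfilt <- function(sos, x) {
  n <- length(x)
  if (n < 4L) stop("signal too short to filter (need at least 4 samples)")
  p <- sos_padlen(sos, n)
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  xe <- c(head_pad, x, tail_pad)
  y <- sos_apply(sos, xe)
  y <- rev(sos_apply(sos, rev(y)))
  y[(p + 1):(p + n)]
}

#' Filter magnitude response
#'
#' Evaluates the single-pass magnitude response of a designed filter at the
#' given frequencies by direct complex evaluation of the biquad cascade.
#' Note that [zero_phase_filter()] applies the filter twice, so its effective
#' magnitude response is the square of this value.
#'
#' @param spec a [filter_spec()].
#' @param freq_hz frequencies (Hz) at which to evaluate.
#' @param rate_hz sampling rate in Hz.
#' @param db if `TRUE`, return the response in decibels (20 log10 |H|).
#' @return numeric vector of |H(f)| (or dB values).
#' @export
filter_response <- function(spec, freq_hz, rate_hz, db = FALSE) {
  sos <- spec_to_sos(spec, rate_hz)
  w <- 2 * pi * freq_hz / rate_hz
  z1 <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (sec in sos) {
    num <- sec$b[1] + sec$b[2] * z1 + sec$b[3] * z1^2
    den <- sec$a[1] + sec$a[2] * z1 + sec$a[3] * z1^2
    h <- h * num / den
  }
  m <- Mod(h)
  if (db) 20 * log10(m) else m
}
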