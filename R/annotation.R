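#' Physical infant-caregiver interaction annotation
#'
#' Annotations label time intervals with one of five interaction categories
#' plus an out-of-screen mask:
#' \describe{
#'   \item{IM}{independent movement -- no outside contact with the infant.}
#'   \item{PS}{passive support -- contact, infant self-supported, contact not
#'     moving the infant.}
#'   \item{AS}{active support -- as PS but the contact moves the infant.}
#'   \item{PC}{passive carry -- the contact maintains the infant's postural
#'     balance, without moving the infant.}
#'   \item{AC}{active carry -- the infant is being moved while carried.}
#'   \item{OOS}{out of screen -- the infant is not visible on the reference
#'     video; these periods are masked from training loss and evaluation and
#'     are never a training target.}
#' }
#'
#' @name annotation
NULL

#' Interaction categories
#' @export
CH_CATEGORIES <- c("IM", "PS", "AS", "PC", "AC")

#' Out-of-screen code
#' @export
CH_OOS <- "OOS"

#' Construct an annotation track
#'
#' Intervals are validated (sorted, non-overlapping, start < end, known
#' category codes) and gaps in the annotated span are filled with OOS.
#'
#' @param intervals data.frame with columns `start_s`, `end_s`, `category`.
#' @param annotator_id identifier of the annotator.
#' @param span optional length-2 numeric: the full annotated span; uncovered
#'   time at the edges is filled with OOS. Defaults to the intervals' range.
#' @return an object of class `ch_track`.
#' @export
annotation_track <- function(intervals, annotator_id = "gt", span = NULL) {
  req <- c("start_s", "end_s", "category")
  if (!all(req %in% names(intervals))) {
    stop("`intervals` needs columns start_s, end_s, category")
  }
  iv <- data.frame(start_s = as.numeric(intervals$start_s),
                   end_s = as.numeric(intervals$end_s),
                   category = as.character(intervals$category),
                   stringsAsFactors = FALSE)
  bad <- which(!iv$category %in% c(CH_CATEGORIES, CH_OOS))
  if (length(bad)) {
    stop(sprintf("unknown category code '%s' (interval %d)",
                 iv$category[bad[1]], bad[1]))
  }
  bad <- which(iv$end_s <= iv$start_s)
  if (length(bad)) {
    stop(sprintf("interval %d has end <= start", bad[1]))
  }
  iv <- iv[order(iv$start_s), , drop = FALSE]
  rownames(iv) <- NULL
  if (nrow(iv) > 1L) {
    ov <- which(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-9)
    if (length(ov)) {
      stop(sprintf("overlap at %.1f s (intervals %d and %d)",
                   iv$start_s[ov[1] + 1L], ov[1], ov[1] + 1L))
    }
  }
  if (is.null(span)) span <- c(iv$start_s[1], max(iv$end_s))
  ## fill gaps (and uncovered edges) with OOS
  pieces <- list()
  cursor <- span[1]
  for (i in seq_len(nrow(iv))) {
    if (iv$start_s[i] > cursor + 1e-9) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(start_s = cursor, end_s = iv$start_s[i], category = CH_OOS)
    }
    pieces[[length(pieces) + 1L]] <- iv[i, ]
    cursor <- max(cursor, iv$end_s[i])
  }
  if (span[2] > cursor + 1e-9) {
    pieces[[length(pieces) + 1L]] <-
      data.frame(start_s = cursor, end_s = span[2], category = CH_OOS)
  }
  iv <- do.call(rbind, pieces)
  rownames(iv) <- NULL
  structure(list(annotator_id = as.character(annotator_id), intervals = iv,
                 span = c(iv$start_s[1], max(iv$end_s))),
            class = "ch_track")
}

#' @export
print.ch_track <- function(x, ...) {
  cat(sprintf("<ch_track> annotator=%s  %d intervals over %.1f s\n",
              x$annotator_id, nrow(x$intervals), diff(x$span)))
  invisible(x)
}

#' Read an annotation CSV
#'
#' Expected columns: `start_s,end_s,category` with categories in
#' IM/PS/AS/PC/AC/OOS. Overlaps or unknown codes raise a parse error naming
#' the offending line.
#'
#' @param path CSV file path.
#' @param annotator_id annotator identifier; defaults to the
#'   `<recording_id>.<annotator_id>.csv` file-name convention when matched.
#' @export
load_annotations <- function(path, annotator_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(annotator_id)) {
    parts <- strsplit(basename(path), ".", fixed = TRUE)[[1]]
    annotator_id <- if (length(parts) >= 3L) parts[length(parts) - 1L] else "a1"
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(annotation_track(df, annotator_id = annotator_id),
           error = function(e) {
             stop(sprintf("parse error in %s: %s", path, conditionMessage(e)),
                  call. = FALSE)
           })
}

#' Write an annotation track to CSV
#' @param track a `ch_track`.
#' @param path output path.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "ch_track"))
  utils::write.csv(track$intervals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Label schemes
## ---------------------------------------------------------------------------

SCHEME_DEFS <- list(
  raw5            = list(IM = "IM", PS = "PS", AS = "AS", PC = "PC", AC = "AC"),
  passive_active3 = list(IM = "IM", PS = "passive", PC = "passive",
                         AS = "active", AC = "active"),
  support_carry3  = list(IM = "IM", PS = "support", AS = "support",
                         PC = "carry", AC = "carry"),
  def1 = c("AC"),
  def2 = c("PC", "AC"),
  def3 = c("AS", "AC"),
  def4 = c("AS", "PC", "AC"),
  def5 = c("PS", "AS", "PC", "AC")
)

#' Label schemes: category collations
#'
#' A scheme maps the five interaction categories onto the classifier's
#' output classes. The binary carrying/holding definitions range from strict
#' to loose: def1 carry = \{AC\}; def2 carry = \{PC, AC\}; def3 carry =
#' \{AS, AC\}; def4 carry = \{AS, PC, AC\}; def5 carry = \{PS, AS, PC, AC\}
#' (i.e. independent movement vs. everything else). Three-class variants
#' group by whether the contact moves the infant (`passive_active3`:
#' IM / \{PS, PC\} / \{AS, AC\}) or by whether it carries the infant
#' (`support_carry3`: IM / \{PS, AS\} / \{PC, AC\}). For binary schemes the
#' positive class is always `"carry"`.
#'
#' @param name one of `"raw5"`, `"passive_active3"`, `"support_carry3"`,
#'   `"def1"` ... `"def5"`.
#' @return object of class `ch_scheme` with fields `name`, `mapping` (named
#'   character: category -> class), `classes` (ordered class labels).
#' @export
label_scheme <- function(name = c("raw5", "passive_active3", "support_carry3",
                                  "def1", "def2", "def3", "def4", "def5")) {
  name <- match.arg(name)
  def <- SCHEME_DEFS[[name]]
  if (is.list(def)) {
    mapping <- unlist(def)
    classes <- unique(unname(mapping[CH_CATEGORIES]))
  } else {
    mapping <- ifelse(CH_CATEGORIES %in% def, "carry", "non_carry")
    names(mapping) <- CH_CATEGORIES
    classes <- c("non_carry", "carry")
  }
  structure(list(name = name, mapping = mapping, classes = classes,
                 n_classes = length(classes)),
            class = "ch_scheme")
}

scheme_class_idx <- function(scheme, categories) {
  match(scheme$mapping[categories], scheme$classes)
}

#' Frame-level labels
#'
#' Internal constructor: `class_idx` indexes `scheme$classes`, `NA` where the
#' frame is masked; `valid` marks frames that carry a label.
#' @noRd
frame_labels <- function(class_idx, scheme, frame_times = NULL) {
  valid <- !is.na(class_idx)
  structure(list(class_idx = as.integer(class_idx), valid = valid,
                 scheme = scheme, n = length(class_idx),
                 frame_times = frame_times),
            class = "ch_frame_labels")
}

#' @export
print.ch_frame_labels <- function(x, ...) {
  cat(sprintf("<ch_frame_labels> %d frames, scheme=%s, %d masked\n",
              x$n, x$scheme$name, sum(!x$valid)))
  if (any(x$valid)) {
    print(table(factor(x$scheme$classes[x$class_idx[x$valid]],
                       levels = x$scheme$classes)))
  }
  invisible(x)
}

## covered time of sorted disjoint [starts, ends) below each t (vectorized)
interval_coverage <- function(starts, ends, t) {
  if (!length(starts)) return(numeric(length(t)))
  cum <- cumsum(ends - starts)
  i <- findInterval(t, starts)
  out <- numeric(length(t))
  pos <- i > 0
  ip <- i[pos]
  out[pos] <- cum[ip] - pmax(ends[ip] - t[pos], 0)
  out
}

#' Derive per-frame labels from an annotation track
#'
#' Each frame receives the category occupying the largest share of its
#' window (ties break toward the canonical category order), mapped through
#' the scheme. A frame is masked when OOS covers at least half of its
#' window; OOS never competes in the majority vote otherwise.
#'
#' @param track a `ch_track`.
#' @param frames a `ch_frames`, or an F x 2 matrix of frame start/end times.
#' @param scheme a [label_scheme()] (or scheme name).
#' @param oos_threshold OOS share at or above which a frame is masked.
#' @return a `ch_frame_labels`.
#' @export
to_frame_labels <- function(track, frames, scheme = label_scheme("raw5"),
                            oos_threshold = 0.5) {
  stopifnot(inherits(track, "ch_track"))
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  times <- if (inherits(frames, "ch_frames")) frames$frame_times
           else as.matrix(frames)
  nf <- nrow(times)
  iv <- track$intervals
  cats <- c(CH_CATEGORIES, CH_OOS)
  shares <- matrix(0, nf, length(cats), dimnames = list(NULL, cats))
  for (cat_i in cats) {
    rows <- iv[iv$category == cat_i, , drop = FALSE]
    if (!nrow(rows)) next
    shares[, cat_i] <- interval_coverage(rows$start_s, rows$end_s, times[, 2]) -
      interval_coverage(rows$start_s, rows$end_s, times[, 1])
  }
  win <- times[, 2] - times[, 1]
  ## time not covered by the track at all behaves as OOS
  uncovered <- pmax(win - rowSums(shares), 0)
  oos_share <- (shares[, CH_OOS] + uncovered) / win
  masked <- oos_share >= oos_threshold
  maj <- max.col(shares[, CH_CATEGORIES, drop = FALSE], ties.method = "first")
  no_label <- rowSums(shares[, CH_CATEGORIES, drop = FALSE]) <= 0
  cls <- scheme_class_idx(scheme, CH_CATEGORIES[maj])
  cls[masked | no_label] <- NA_integer_
  frame_labels(cls, scheme, frame_times = times)
}

#' Consensus of two annotators' frame labels
#'
#' Frames keep their label where both annotators agree and both are valid;
#' all other frames are masked. Evaluating against the consensus restricts
#' metrics to the frames where the human annotators were in agreement.
#'
#' @param a,b `ch_frame_labels` of equal length and scheme.
#' @return a `ch_frame_labels`.
#' @export
agreement_mask <- function(a, b) {
  stopifnot(inherits(a, "ch_frame_labels"), inherits(b, "ch_frame_labels"))
  if (a$n != b$n) stop("frame label tracks have different lengths")
  if (!identical(a$scheme$name, b$scheme$name)) {
    stop(sprintf("scheme mismatch: '%s' vs '%s'", a$scheme$name, b$scheme$name))
  }
  agree <- a$valid & b$valid & a$class_idx == b$class_idx
  cls <- ifelse(!is.na(agree) & agree, a$class_idx, NA_integer_)
  frame_labels(cls, a$scheme, frame_times = a$frame_times)
}

#' Segment durations per class under a scheme
#'
#' Maps the track's intervals through the scheme (OOS intervals break runs),
#' merges adjacent intervals that map to the same class, and returns the
#' durations of the maximal constant-class runs.
#'
#' @param track a `ch_track`.
#' @param scheme a [label_scheme()] or scheme name.
#' @return named list: for each class, a numeric vector of segment durations
#'   in seconds.
#' @export
segment_lengths <- function(track, scheme = label_scheme("raw5")) {
  stopifnot(inherits(track, "ch_track"))
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  iv <- track$intervals
  out <- stats::setNames(rep(list(numeric(0)), scheme$n_classes),
                         scheme$classes)
  if (!nrow(iv)) return(out)
  cls <- ifelse(iv$category == CH_OOS, NA_character_,
                scheme$mapping[iv$category])
  ## merge adjacent intervals with the same mapped class (contiguous in time)
  run_cls <- character(0); run_dur <- numeric(0)
  cur <- NA_character_; cur_end <- -Inf; cur_dur <- 0
  for (i in seq_len(nrow(iv))) {
    ci <- cls[i]
    contiguous <- abs(iv$start_s[i] - cur_end) < 1e-9
    if (!is.na(ci) && !is.na(cur) && ci == cur && contiguous) {
      cur_dur <- cur_dur + (iv$end_s[i] - iv$start_s[i])
    } else {
      if (!is.na(cur)) {
        run_cls <- c(run_cls, cur); run_dur <- c(run_dur, cur_dur)
      }
      cur <- ci
      cur_dur <- iv$end_s[i] - iv$start_s[i]
    }
    cur_end <- iv$end_s[i]
  }
  if (!is.na(cur)) {
    run_cls <- c(run_cls, cur); run_dur <- c(run_dur, cur_dur)
  }
  for (k in scheme$classes) out[[k]] <- run_dur[run_cls == k]
  out
}
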