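#' Ablation harness: sensor subsets x sampling rates x modalities
#'
#' Systematic benchmarking of the recording constellation: every cell of the
#' grid (a sensor subset, a simulated sampling rate, an input modality) is
#' trained and evaluated with the same cross-validation fold partition, so
#' per-fold scores are paired across cells; paired two-tailed t-tests
#' compare cells that differ in exactly one grid axis.
#'
#' @name experiments
NULL

#' Default sensor subsets studied in the ablation
#' @export
default_sensor_subsets <- function() {
  list(
    all4      = CH_PLACEMENTS,
    arm2legs  = c("left_arm", "left_leg", "right_leg"),
    arms1leg  = c("left_arm", "right_arm", "left_leg"),
    arm_leg   = c("left_arm", "left_leg"),
    legs      = c("left_leg", "right_leg"),
    one_arm   = "left_arm",
    one_leg   = "left_leg"
  )
}

#' Ablation grid
#'
#' @param sensor_subsets named list of placement vectors.
#' @param rates simulated sampling rates (Hz), subset of c(52, 26, 13).
#' @param modalities input modalities.
#' @param scheme label scheme used as the benchmark task (default `"def2"`).
#' @export
ablation_grid <- function(sensor_subsets = default_sensor_subsets(),
                          rates = c(52, 26, 13),
                          modalities = c("acc_gyro", "acc_preprocessed",
                                         "acc_raw"),
                          scheme = "def2") {
  if (!length(sensor_subsets) || !length(rates) || !length(modalities)) {
    stop("all grid axes must be non-empty")
  }
  for (ss in sensor_subsets) canonical_sensors(ss)
  if (is.null(names(sensor_subsets))) {
    names(sensor_subsets) <- vapply(sensor_subsets, paste, character(1),
                                    collapse = "+")
  }
  structure(list(sensor_subsets = sensor_subsets, rates = rates,
                 modalities = modalities, scheme = scheme),
            class = "ch_ablation_grid")
}

#' Prepare classifier items for one ablation cell
#'
#' Applies sensor selection, sampling-rate simulation and modality assembly
#' to each dataset entry and derives frame labels (consensus of the entry's
#' annotators when present, ground truth otherwise).
#'
#' @param dataset list of entries `list(id, rec, truth, annotations)` as
#'   produced by [synth_dataset()].
#' @param subset placements to keep.
#' @param rate_hz simulated sampling rate.
#' @param modality input modality.
#' @param scheme label scheme (name or object).
#' @param fcfg a [framing_config()].
#' @param use_truth force ground-truth labels even when annotations exist.
#' @return list of items suitable for [crossvalidate()].
#' @export
prepare_items <- function(dataset, subset = CH_PLACEMENTS, rate_hz = 52,
                          modality = "acc_gyro", scheme = "def2",
                          fcfg = framing_config(), use_truth = FALSE) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  lapply(dataset, function(e) {
    rec <- select_sensors(e$rec, subset)
    if (rate_hz != rec$rate_hz) rec <- simulate_rate(rec, rate_hz)
    fr <- make_frames(assemble_input(rec, modality), fcfg)
    use_ann <- !use_truth && length(e$annotations) >= 1L
    fl <- if (use_ann && length(e$annotations) >= 2L) {
      agreement_mask(
        to_frame_labels(e$annotations[[1]], fr, scheme),
        to_frame_labels(e$annotations[[2]], fr, scheme))
    } else if (use_ann) {
      to_frame_labels(e$annotations[[1]], fr, scheme)
    } else {
      to_frame_labels(e$truth, fr, scheme)
    }
    list(id = e$id, x = fr$frames, y = fl$class_idx,
         subject = if (!is.null(e$subject)) e$subject)
  })
}

#' Run the ablation over a grid
#'
#' Every cell reuses the same fold partition (determined by the seed in
#' `tcfg` and the recording ids), satisfying the pairing precondition of the
#' cell-to-cell t-tests. A failed cell is recorded with NA scores rather
#' than dropped.
#'
#' @param dataset as in [prepare_items()].
#' @param grid an [ablation_grid()].
#' @param mcfg_fn function(n_sensors, active_heads) returning the
#'   [model_config()] for a cell (so width can scale with the layout), or a
#'   single `ch_model_config` used as a template whose `n_sensors` and
#'   `active_heads` are adapted per cell.
#' @param tcfg a [training_config()].
#' @param fcfg a [framing_config()].
#' @param use_truth label source override, see [prepare_items()].
#' @param verbose print progress.
#' @return object of class `ch_ablation`: `results` (subset, rate, modality,
#'   fold, kappa, accuracy), `cells` (per-cell mean/IQR), the grid and
#'   configs.
#' @export
run_ablation <- function(dataset, grid, mcfg_fn, tcfg,
                         fcfg = framing_config(), use_truth = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(grid, "ch_ablation_grid"))
  if (inherits(mcfg_fn, "ch_model_config")) {
    template <- mcfg_fn
    mcfg_fn <- function(n_sensors, active_heads) {
      model_config(n_sensors = n_sensors, active_heads = active_heads,
                   n_classes = template$n_classes,
                   latent_dim = template$latent_dim,
                   enc_filters = template$enc_filters,
                   enc_kernels = template$enc_kernels,
                   enc_strides = template$enc_strides,
                   n_blocks = template$n_blocks,
                   ts_kernel = template$ts_kernel,
                   dilations = template$dilations, gated = template$gated,
                   frame_len = template$frame_len)
    }
  }
  results <- list()
  for (sname in names(grid$sensor_subsets)) {
    for (rate in grid$rates) {
      for (mod in grid$modalities) {
        cell <- sprintf("%s/%g/%s", sname, rate, mod)
        if (verbose) message("cell ", cell)
        res <- tryCatch({
          items <- prepare_items(dataset, grid$sensor_subsets[[sname]],
                                 rate, mod, grid$scheme, fcfg,
                                 use_truth = use_truth)
          heads <- if (mod == "acc_raw") "acc" else c("acc", "gyro")
          mcfg <- mcfg_fn(length(grid$sensor_subsets[[sname]]), heads)
          cv <- crossvalidate(items, mcfg, tcfg, verbose = verbose)
          cv$fold_stats
        }, error = function(e) {
          warning(sprintf("cell %s failed: %s", cell, conditionMessage(e)))
          data.frame(fold = seq_len(tcfg$n_folds), kappa = NA_real_,
                     accuracy = NA_real_)
        })
        res$subset <- sname; res$rate <- rate; res$modality <- mod
        results[[length(results) + 1L]] <- res
      }
    }
  }
  results <- do.call(rbind, results)
  cells <- do.call(rbind, lapply(
    split(results, results[c("subset", "rate", "modality")], drop = TRUE),
    function(d) data.frame(
      subset = d$subset[1], rate = d$rate[1], modality = d$modality[1],
      mean_kappa = mean(d$kappa, na.rm = TRUE),
      iqr_kappa = if (all(is.na(d$kappa))) NA_real_ else
        stats::IQR(d$kappa, na.rm = TRUE),
      mean_accuracy = mean(d$accuracy, na.rm = TRUE),
      n_missing = sum(is.na(d$kappa)))))
  rownames(cells) <- NULL
  structure(list(results = results, cells = cells, grid = grid, tcfg = tcfg),
            class = "ch_ablation")
}

#' @export
print.ch_ablation <- function(x, ...) {
  cat("<ch_ablation>\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Paired two-tailed t-test on fold scores
#'
#' Classic paired t on the per-fold differences (df = n - 1). Degenerate
#' cases are flagged: zero variance of the differences with a non-zero mean
#' reports an infinite t; all-zero differences report t = 0, p = 1.
#'
#' @param a,b equal-length numeric vectors of per-fold scores, paired by
#'   fold.
#' @return list: `t`, `p`, `df`, `mean_diff`, `flag` (NULL or a string).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired scores")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                  flag = "all differences zero"))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_diff = mean(d), flag = "zero variance of differences"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       flag = NULL)
}

#' Pairwise tests between ablation cells
#'
#' Enumerates cell pairs that differ in exactly one grid axis ("otherwise
#' equivalent systems") and applies [paired_ttest()] to their per-fold
#' kappa scores. `mode = "pooled"` instead pools, for each value of the
#' varied axis, the fold scores across all settings of the other axes
#' before testing (larger df). No multiple-testing correction is applied;
#' the number of tests is reported.
#'
#' @param ablation a `ch_ablation`.
#' @param mode `"pairwise"` or `"pooled"`.
#' @return data.frame: cell_a, cell_b, axis, t, df, p, mean_diff; attribute
#'   `n_tests`.
#' @export
ablation_tests <- function(ablation, mode = c("pairwise", "pooled")) {
  mode <- match.arg(mode)
  res <- ablation$results
  res$cell <- sprintf("%s/%g/%s", res$subset, res$rate, res$modality)
  axes <- c("subset", "rate", "modality")
  out <- list()
  if (mode == "pairwise") {
    cells <- unique(res[c("subset", "rate", "modality", "cell")])
    for (i in seq_len(nrow(cells) - 1L)) {
      for (j in (i + 1L):nrow(cells)) {
        differ <- vapply(axes, function(ax) {
          cells[[ax]][i] != cells[[ax]][j]
        }, logical(1))
        if (sum(differ) != 1L) next
        a <- res[res$cell == cells$cell[i], ]
        b <- res[res$cell == cells$cell[j], ]
        a <- a[order(a$fold), ]; b <- b[order(b$fold), ]
        if (any(is.na(a$kappa)) || any(is.na(b$kappa))) next
        tt <- paired_ttest(a$kappa, b$kappa)
        out[[length(out) + 1L]] <- data.frame(
          cell_a = cells$cell[i], cell_b = cells$cell[j],
          axis = axes[differ], t = tt$t, df = tt$df, p = tt$p,
          mean_diff = tt$mean_diff)
      }
    }
  } else {
    for (ax in axes) {
      lv <- unique(res[[ax]])
      if (length(lv) < 2L) next
      others <- setdiff(axes, ax)
      for (i in seq_len(length(lv) - 1L)) {
        for (j in (i + 1L):length(lv)) {
          a <- res[res[[ax]] == lv[i], ]
          b <- res[res[[ax]] == lv[j], ]
          key <- function(d) do.call(paste, c(d[others], list(d$fold)))
          common <- intersect(key(a), key(b))
          a <- a[match(common, key(a)), ]
          b <- b[match(common, key(b)), ]
          if (nrow(a) < 2L || any(is.na(a$kappa)) || any(is.na(b$kappa))) next
          tt <- paired_ttest(a$kappa, b$kappa)
          out[[length(out) + 1L]] <- data.frame(
            cell_a = as.character(lv[i]), cell_b = as.character(lv[j]),
            axis = ax, t = tt$t, df = tt$df, p = tt$p,
            mean_diff = tt$mean_diff)
        }
      }
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_a = character(0), cell_b = character(0),
               axis = character(0), t = numeric(0), df = numeric(0),
               p = numeric(0), mean_diff = numeric(0))
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Scaled end-to-end benchmark on synthetic data
#'
#' The package's reference experiment: generates a labelled synthetic
#' dataset, trains the binary carrying classifier (def2) with
#' cross-validation, benchmarks the actigraphy baseline on the same frames,
#' and trains the two key ablation cells (single-arm recording; raw
#' accelerometer without gyroscope) with the identical fold partition. All
#' quantities are computed against the generator's ground-truth labels.
#'
#' @param seed master seed for data generation, fold assignment and training.
#' @param n_recordings number of synthetic recordings.
#' @param duration_s duration per recording (s).
#' @param epochs training epochs per fold.
#' @param n_folds cross-validation folds.
#' @param latent_dim,enc_filters model width (reduced by default to keep the
#'   experiment tractable on one CPU; the vignette discusses the choice).
#' @param run_ablation_cells also train the one-arm and raw-accelerometer
#'   cells.
#' @param verbose print progress.
#' @return list with pooled and per-fold classifier scores, actigraphy sweep
#'   results, and (optionally) ablation cell scores.
#' @export
ch_benchmark <- function(seed = 1L, n_recordings = 20L, duration_s = 600,
                         epochs = 30L, n_folds = 5L, latent_dim = 32L,
                         enc_filters = c(8L, 16L),
                         run_ablation_cells = TRUE, verbose = FALSE) {
  scfg <- synth_config(duration_s = duration_s)
  fcfg <- framing_config()
  ds <- synth_dataset(n_recordings, scfg, seed = seed, n_annotators = 0L)
  tcfg <- training_config(epochs = epochs, learning_rate = 1e-3,
                          n_folds = n_folds, seed = seed,
                          class_weight_power = 0.5)
  cell <- function(subset, modality) {
    items <- prepare_items(ds, subset = subset, modality = modality,
                           scheme = "def2", fcfg = fcfg, use_truth = TRUE)
    heads <- if (modality == "acc_raw") "acc" else c("acc", "gyro")
    mcfg <- model_config(n_sensors = length(subset), active_heads = heads,
                         latent_dim = latent_dim, enc_filters = enc_filters)
    crossvalidate(items, mcfg, tcfg, verbose = verbose)
  }
  cv_full <- cell(CH_PLACEMENTS, "acc_gyro")
  ## pooled kappa/accuracy over all held-out predictions
  items_ref <- prepare_items(ds, scheme = "def2", fcfg = fcfg,
                             use_truth = TRUE)
  pred <- unlist(lapply(cv_full$predictions, `[[`, "label"))
  ref <- unlist(lapply(items_ref, `[[`, "y"))
  ok <- !is.na(ref)
  cm <- confusion(pred[ok], ref[ok], classes = 1:2)
  ## actigraphy on the same frames, pooled sweep
  counts <- unlist(lapply(ds, function(e) {
    actigraphy_counts(e$rec, "left_arm", fcfg)$counts
  }))
  sweep <- threshold_sweep(counts, ref)
  out <- list(classifier_kappa = kappa_multiclass(cm),
              classifier_accuracy = accuracy(cm),
              fold_stats = cv_full$fold_stats,
              actigraphy_kappa = sweep$best$kappa,
              actigraphy_threshold = sweep$best$threshold,
              n_frames = sum(ok), seed = seed)
  if (run_ablation_cells) {
    cv_arm <- cell("left_arm", "acc_gyro")
    cv_raw <- cell(CH_PLACEMENTS, "acc_raw")
    out$one_arm_fold_kappa <- cv_arm$fold_stats$kappa
    out$acc_raw_fold_kappa <- cv_raw$fold_stats$kappa
    out$one_arm_mean_kappa <- mean(cv_arm$fold_stats$kappa)
    out$acc_raw_mean_kappa <- mean(cv_raw$fold_stats$kappa)
    out$full_mean_kappa <- mean(cv_full$fold_stats$kappa)
    out$ttest_full_vs_one_arm <-
      paired_ttest(cv_full$fold_stats$kappa, cv_arm$fold_stats$kappa)
    out$ttest_full_vs_acc_raw <-
      paired_ttest(cv_full$fold_stats$kappa, cv_raw$fold_stats$kappa)
  }
  out
}
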