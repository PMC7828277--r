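#' Evaluate a classifier on one held-out fold
#'
#' @param state A trained `classifier_state`.
#' @param dataset A `signature_dataset` with folds.
#' @param fold Held-out fold id.
#' @return Macro F1 against the fold's true labels.
#' @export
evaluate_fold <- function(state, dataset, fold) {
  idx <- fold_indices(dataset, fold)
  pred <- predict_proba(state, dataset$signatures[, , idx, drop = FALSE])
  macro_f1(pred$labels, dataset$labels[idx], state$class_list)
}

#' Train the per-fold baseline classifiers at time point 0
#'
#' One classifier per cross-validation fold, initialized with a seed
#' derived from `seed` and the fold id and trained on the other folds of
#' the first time point. All three update strategies start from these
#' states, so differences downstream are attributable to the update rule
#' alone.
#'
#' @param seq A `timepoint_sequence`.
#' @param classifier_spec `"linear_baseline"` or `"dual_cnn"`.
#' @param seed Strategy seed.
#' @param hyper Optional classifier hyperparameter overrides.
#' @return List of `classifier_state`, one per fold.
#' @export
train_base_states <- function(seq, classifier_spec, seed, hyper = list()) {
  stopifnot(inherits(seq, "timepoint_sequence"))
  ds0 <- seq$timepoints[[1]]
  n_folds <- max(ds0$folds)
  lapply(seq_len(n_folds), function(f) {
    st <- build_classifier(classifier_spec,
                           seed = derive_seed(seed, paste0("init/fold", f)),
                           hyper = hyper)
    train(st, ds0, train_folds = setdiff(seq_len(n_folds), f))
  })
}

new_strategy_run <- function(strategy, seq, f1, counts = NULL,
                             stopped_at = NULL, config = list()) {
  structure(list(
    strategy = strategy,
    scenario = seq$scenario,
    snr_db = seq$snr_db,
    f1 = f1,
    counts = counts,
    stopped_at = stopped_at,
    config = config
  ), class = "strategy_run")
}

#' @export
print.strategy_run <- function(x, ...) {
  agg <- stats::aggregate(f1 ~ timepoint, data = x$f1, FUN = mean)
  cat(sprintf("<strategy_run> %s on %s @ %g dB%s\n", x$strategy,
              x$scenario, x$snr_db,
              if (is.null(x$stopped_at)) "" else
                sprintf(" (stopped at %s)", x$stopped_at)))
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Mean macro F1 per time point of a strategy run
#' @param run A `strategy_run`.
#' @return Named numeric vector (time point order preserved).
#' @export
run_mean_f1 <- function(run, timepoints = unique(run$f1$timepoint)) {
  vapply(timepoints, function(tp) {
    mean(run$f1$f1[run$f1$timepoint == tp])
  }, numeric(1))
}

#' Baseline calibration: train once, never update
#'
#' The classifier is trained once on four folds of the first time point
#' and then evaluated on the held-out fold of every time point without any
#' further modification (the control condition of the study).
#'
#' @inheritParams train_base_states
#' @param base_states Optional precomputed [train_base_states()] result.
#' @return A `strategy_run`.
#' @export
run_baseline_calibration <- function(seq, classifier_spec = "linear_baseline",
                                     seed = 1L, hyper = list(),
                                     base_states = NULL) {
  stopifnot(inherits(seq, "timepoint_sequence"),
            length(seq$timepoints) >= 2L)
  states <- base_states %||%
    train_base_states(seq, classifier_spec, seed, hyper)
  rows <- list()
  for (tp in names(seq$timepoints)) {
    ds <- seq$timepoints[[tp]]
    for (f in seq_along(states)) {
      rows[[length(rows) + 1L]] <-
        data.frame(timepoint = tp, fold = f,
                   f1 = evaluate_fold(states[[f]], ds, f))
    }
  }
  new_strategy_run("baseline_calibration", seq, do.call(rbind, rows),
                   config = list(classifier_spec = classifier_spec,
                                 seed = seed))
}

#' Periodic recalibration: supervised warm-start retraining
#'
#' At each new time point the classifier is initialized with the final
#' learned weights of the previous time point and retrained on the new
#' time point's four training folds with true labels, then tested on the
#' held-out fold.
#'
#' @inheritParams run_baseline_calibration
#' @return A `strategy_run`.
#' @export
run_periodic_recalibration <- function(seq,
                                       classifier_spec = "linear_baseline",
                                       seed = 1L, hyper = list(),
                                       base_states = NULL) {
  stopifnot(inherits(seq, "timepoint_sequence"),
            length(seq$timepoints) >= 2L)
  states <- base_states %||%
    train_base_states(seq, classifier_spec, seed, hyper)
  n_folds <- length(states)
  tps <- names(seq$timepoints)
  rows <- list()
  for (f in seq_len(n_folds)) {
    st <- states[[f]]
    for (k in seq_along(tps)) {
      ds <- seq$timepoints[[k]]
      if (k > 1L) {
        st <- train(st, ds, train_folds = setdiff(seq_len(n_folds), f))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(timepoint = tps[k], fold = f,
                   f1 = evaluate_fold(st, ds, f))
    }
    gc(FALSE)
  }
  f1 <- do.call(rbind, rows)
  f1 <- f1[order(match(f1$timepoint, tps), f1$fold), ]
  rownames(f1) <- NULL
  new_strategy_run("periodic_recalibration", seq, f1,
                   config = list(classifier_spec = classifier_spec,
                                 seed = seed))
}

#' Build a self-labelled training subset
#'
#' Samples in the training folds whose maximum predicted probability
#' reaches the confidence threshold are kept with their predicted
#' (pseudo) labels; true labels are discarded. An empty subset is legal
#' and reported through the per-class counts.
#'
#' @param state A trained `classifier_state`.
#' @param dataset A `signature_dataset` with folds.
#' @param train_folds Folds forming the unlabeled pool.
#' @param threshold Confidence threshold in `(0, 1)` (default 0.95).
#' @return List with `indices` (into the dataset), `labels` (pseudo),
#'   `confidences`, and `counts` (named per-class vector).
#' @export
build_self_labelled <- function(state, dataset, train_folds,
                                threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  pool <- fold_indices(dataset, train_folds)
  pred <- predict_proba(state,
                        dataset$signatures[, , pool, drop = FALSE])
  conf <- apply(pred$probabilities, 1L, max)
  keep <- conf >= threshold
  labels <- pred$labels[keep]
  list(
    indices = pool[keep],
    labels = labels,
    confidences = conf[keep],
    counts = vapply(state$class_list, function(cl) sum(labels == cl),
                    numeric(1))
  )
}

#' Self-learning: confidence-thresholded pseudo-label retraining
#'
#' At each new time point the previous classifier predicts the new
#' training folds; samples predicted with confidence at or above the
#' threshold form a self-labelled set on which the classifier is
#' warm-start retrained (no true labels are used for training). Held-out
#' evaluation still uses true labels. The run stops at the first time
#' point where any class's self-labelled count falls below
#' `min_per_class` (no retraining or evaluation at or after that point
#' for the affected fold); the run-level `stopped_at` is the earliest
#' stopping time point over folds.
#'
#' @inheritParams run_baseline_calibration
#' @param threshold Confidence threshold (default 0.95).
#' @param min_per_class Minimum self-labelled samples per class to
#'   continue (default 200).
#' @param replay Also train on the first time point's explicitly labelled
#'   training folds at every update (default FALSE: retrain on the
#'   self-labelled subset only).
#' @return A `strategy_run` with per-time-point self-labelled counts.
#' @export
run_self_learning <- function(seq, classifier_spec = "linear_baseline",
                              threshold = 0.95, min_per_class = 200L,
                              seed = 1L, hyper = list(),
                              base_states = NULL, replay = FALSE) {
  stopifnot(inherits(seq, "timepoint_sequence"),
            length(seq$timepoints) >= 2L)
  states <- base_states %||%
    train_base_states(seq, classifier_spec, seed, hyper)
  n_folds <- length(states)
  tps <- names(seq$timepoints)
  rows <- list()
  count_rows <- list()
  stopped <- rep(NA_integer_, n_folds)
  for (f in seq_len(n_folds)) {
    st <- states[[f]]
    for (k in seq_along(tps)) {
      ds <- seq$timepoints[[k]]
      if (k > 1L) {
        sl <- build_self_labelled(st, ds, setdiff(seq_len(n_folds), f),
                                  threshold)
        count_rows[[length(count_rows) + 1L]] <-
          data.frame(timepoint = tps[k], fold = f,
                     class = names(sl$counts), n = unname(sl$counts))
        if (any(sl$counts < min_per_class)) {
          stopped[f] <- k
          break
        }
        if (replay) {
          # labelled data exist only at calibration time; replay mixes the
          # Base training folds into every pseudo-labelled update
          ds0 <- seq$timepoints[[1]]
          base_idx <- fold_indices(ds0, setdiff(seq_len(n_folds), f))
          mix <- signature_dataset(
            array(c(ds$signatures[, , sl$indices, drop = FALSE],
                    ds0$signatures[, , base_idx, drop = FALSE]),
                  dim = c(dim(ds$signatures)[1:2],
                          length(sl$indices) + length(base_idx))),
            c(as.character(sl$labels), as.character(ds0$labels[base_idx])),
            snr_db = ds$snr_db, timepoint_id = ds$timepoint_id)
          st <- train(st, mix, indices = seq_along(mix$labels),
                      labels = mix$labels)
        } else {
          st <- train(st, ds, indices = sl$indices, labels = sl$labels)
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(timepoint = tps[k], fold = f,
                   f1 = evaluate_fold(st, ds, f))
    }
    gc(FALSE)
  }
  stopped_at <- if (all(is.na(stopped))) NULL else tps[min(stopped,
                                                           na.rm = TRUE)]
  f1 <- do.call(rbind, rows)
  f1 <- f1[order(match(f1$timepoint, tps), f1$fold), ]
  rownames(f1) <- NULL
  new_strategy_run("self_learning", seq, f1,
                   counts = do.call(rbind, count_rows),
                   stopped_at = stopped_at,
                   config = list(classifier_spec = classifier_spec,
                                 threshold = threshold,
                                 min_per_class = min_per_class,
                                 seed = seed))
}

#' Self-learning between two time points at a higher training frequency
#'
#' A frequency multiplier `m` inserts `m - 1` linearly interpolated
#' datasets between the two real time points (weights `k/m`); the
#' self-learning update is applied at every interpolated step and at the
#' endpoint, and performance is reported at the real time points.
#'
#' @param ds_a,ds_b Corresponding `signature_dataset`s at the two real
#'   time points (e.g. ET1 and ET2).
#' @param m Frequency multiplier, one of 1, 2, 4, 8 unless
#'   `allow_any_frequency`.
#' @param states Per-fold starting `classifier_state`s at `ds_a` (e.g.
#'   from [build_initial_levels()]).
#' @param threshold Confidence threshold (default 0.95).
#' @param min_per_class Stopping rule threshold (default 200).
#' @param allow_any_frequency Permit multipliers outside `{1, 2, 4, 8}`.
#' @return List with `f1` (timepoint in `{"start", "end"}`, fold, f1),
#'   `counts`, and `stopped` (logical per fold).
#' @export
run_frequency_experiment <- function(ds_a, ds_b, m, states,
                                     threshold = 0.95,
                                     min_per_class = 200L,
                                     allow_any_frequency = FALSE) {
  if (!m %in% c(1L, 2L, 4L, 8L) && !allow_any_frequency) {
    stop("`m` must be one of 1, 2, 4, 8", call. = FALSE)
  }
  n_folds <- length(states)
  rows <- list()
  count_rows <- list()
  stopped <- logical(n_folds)
  # interpolated steps are built on demand (not all held at once): at
  # m = 8 the full ladder of intermediate datasets would dominate memory
  step_at <- function(k) {
    if (k == m) ds_b else interpolate_datasets(ds_a, ds_b, k / m)
  }
  for (f in seq_len(n_folds)) {
    st <- states[[f]]
    rows[[length(rows) + 1L]] <-
      data.frame(timepoint = "start", fold = f,
                 f1 = evaluate_fold(st, ds_a, f))
    for (k in seq_len(m)) {
      ds_k <- step_at(k)
      sl <- build_self_labelled(st, ds_k, setdiff(seq_len(n_folds), f),
                                threshold)
      count_rows[[length(count_rows) + 1L]] <-
        data.frame(step = k, fold = f, class = names(sl$counts),
                   n = unname(sl$counts))
      if (any(sl$counts < min_per_class)) {
        stopped[f] <- TRUE
        break
      }
      st <- train(st, ds_k, indices = sl$indices, labels = sl$labels)
      rm(ds_k)
      gc(FALSE)
    }
    if (!stopped[f]) {
      rows[[length(rows) + 1L]] <-
        data.frame(timepoint = "end", fold = f,
                   f1 = evaluate_fold(st, ds_b, f))
    }
  }
  list(f1 = do.call(rbind, rows), counts = do.call(rbind, count_rows),
       stopped = stopped)
}

#' Build the high- and low-performance initial states at ET1
#'
#' Starting from the shared fresh-implant (Base) classifiers, the
#' high-performance (HP) level applies one periodic-recalibration step at
#' the second time point, while the low-performance (LP) level applies
#' one self-learning step there; both lineages share identical Base
#' weights.
#'
#' @param seq A `timepoint_sequence` whose first two time points are Base
#'   and ET1.
#' @param classifier_spec,seed,hyper As in [train_base_states()].
#' @param threshold Confidence threshold for the LP self-learning step.
#' @param base_states Optional precomputed Base states.
#' @return List with elements `HP` and `LP`, each a list of per-fold
#'   states (`states`) and the mean F1 at ET1 (`f1`).
#' @export
build_initial_levels <- function(seq, classifier_spec = "linear_baseline",
                                 seed = 1L, hyper = list(),
                                 threshold = 0.95, base_states = NULL) {
  stopifnot(inherits(seq, "timepoint_sequence"),
            length(seq$timepoints) >= 2L)
  states <- base_states %||%
    train_base_states(seq, classifier_spec, seed, hyper)
  n_folds <- length(states)
  ds1 <- seq$timepoints[[2]]
  hp <- lapply(seq_len(n_folds), function(f) {
    train(states[[f]], ds1, train_folds = setdiff(seq_len(n_folds), f))
  })
  lp <- lapply(seq_len(n_folds), function(f) {
    sl <- build_self_labelled(states[[f]], ds1,
                              setdiff(seq_len(n_folds), f), threshold)
    if (length(sl$indices) == 0L) return(states[[f]])
    train(states[[f]], ds1, indices = sl$indices, labels = sl$labels)
  })
  f1_of <- function(sts) {
    mean(vapply(seq_len(n_folds), function(f) {
      evaluate_fold(sts[[f]], ds1, f)
    }, numeric(1)))
  }
  list(HP = list(states = hp, f1 = f1_of(hp)),
       LP = list(states = lp, f1 = f1_of(lp)))
}

#' Slope difference between a strategy and its no-update control
#'
#' Both runs must report macro F1 at the two real time points; the cell is
#' `(F1_strategy(t2) - F1_strategy(t1)) - (F1_control(t2) - F1_control(t1))`.
#' A positive value means the strategy declined more slowly than the
#' control.
#'
#' @param strategy_run,control_run `strategy_run`s, or any lists with an
#'   `f1` data frame holding `timepoint` and `f1` columns.
#' @param t1,t2 Time point labels (defaults `"start"`, `"end"`).
#' @return The slope difference (per unit time point).
#' @export
compute_slope_difference <- function(strategy_run, control_run,
                                     t1 = "start", t2 = "end") {
  grab <- function(run, tp) {
    v <- run$f1$f1[run$f1$timepoint == tp]
    if (length(v) == 0L) {
      stop("run is missing time point: ", tp, call. = FALSE)
    }
    mean(v)
  }
  (grab(strategy_run, t2) - grab(strategy_run, t1)) -
    (grab(control_run, t2) - grab(control_run, t1))
}

#' Training-frequency / initial-performance slope grid
#'
#' For each initial level (HP, LP) and frequency multiplier, runs the
#' self-learning frequency experiment between the two real time points
#' and compares its ET1-to-ET2 slope with the no-update control (the
#' initial state frozen at ET1).
#'
#' @param ds_a,ds_b Datasets at the two real time points (ET1, ET2).
#' @param levels A [build_initial_levels()] result.
#' @param frequencies Integer multipliers (default `c(1, 2, 4, 8)`).
#' @param threshold,min_per_class Self-learning parameters.
#' @return Data frame with columns `level`, `frequency`, `f1_start`,
#'   `f1_end`, `control_end`, `slope_difference`, `stopped`.
#' @export
run_slope_grid <- function(ds_a, ds_b, levels,
                           frequencies = c(1L, 2L, 4L, 8L),
                           threshold = 0.95, min_per_class = 200L) {
  out <- list()
  for (lv in names(levels)) {
    states <- levels[[lv]]$states
    n_folds <- length(states)
    control_f1 <- data.frame(
      timepoint = rep(c("start", "end"), each = n_folds),
      fold = rep(seq_len(n_folds), 2L),
      f1 = c(
        vapply(seq_len(n_folds), function(f) {
          evaluate_fold(states[[f]], ds_a, f)
        }, numeric(1)),
        vapply(seq_len(n_folds), function(f) {
          evaluate_fold(states[[f]], ds_b, f)
        }, numeric(1))
      ))
    control <- list(f1 = control_f1)
    for (m in frequencies) {
      fx <- run_frequency_experiment(ds_a, ds_b, m, states, threshold,
                                     min_per_class)
      sd_cell <- if (any(fx$stopped)) NA_real_ else
        compute_slope_difference(fx, control)
      out[[length(out) + 1L]] <- data.frame(
        level = lv, frequency = m,
        f1_start = mean(fx$f1$f1[fx$f1$timepoint == "start"]),
        f1_end = if (any(fx$stopped)) NA_real_ else
          mean(fx$f1$f1[fx$f1$timepoint == "end"]),
        control_end = mean(control_f1$f1[control_f1$timepoint == "end"]),
        slope_difference = sd_cell,
        stopped = any(fx$stopped))
    }
  }
  do.call(rbind, out)
}
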