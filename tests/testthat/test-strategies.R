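test_that("baseline calibration on a drift-free sequence has a flat trajectory", {
  seqc <- constant_sequence(3L)
  run <- run_baseline_calibration(seqc, "linear_baseline", seed = 31L)
  f1 <- run_mean_f1(run)
  expect_length(f1, 3L)
  expect_equal(unname(f1[2]), unname(f1[1]))
  expect_equal(unname(f1[3]), unname(f1[1]))
  # at time point 0 it is ordinary 5-fold cross-validation
  expect_equal(nrow(run$f1), 15L)
  expect_true(all(run$f1$f1 >= 0 & run$f1$f1 <= 1))
  # determinism: identical rerun
  run2 <- run_baseline_calibration(seqc, "linear_baseline", seed = 31L)
  expect_identical(run$f1, run2$f1)
})

test_that("periodic recalibration never falls behind on a drift-free sequence", {
  seqc <- constant_sequence(3L)
  base_states <- train_base_states(seqc, "linear_baseline", 31L)
  rb <- run_baseline_calibration(seqc, base_states = base_states)
  rp <- run_periodic_recalibration(seqc, base_states = base_states)
  fb <- run_mean_f1(rb)
  fp <- run_mean_f1(rp)
  expect_equal(unname(fp[1]), unname(fb[1])) # shared starting point
  expect_true(all(fp >= fb - 0.02))
})

test_that("self-labelling applies the confidence threshold rule exactly", {
  ds <- micro_dataset(-5)
  st <- build_classifier("linear_baseline", seed = 33L)
  st <- train(st, ds, train_folds = 1:4)
  sl <- build_self_labelled(st, ds, 1:4, threshold = 0.95)
  expect_true(all(sl$confidences >= 0.95))
  expect_true(all(sl$indices %in% fold_indices(ds, 1:4)))
  expect_equal(unname(sl$counts),
               as.vector(table(sl$labels)[c("tibial", "peroneal", "sural")]))
  expect_true(all(sl$counts >= 0))
  # a near-zero threshold admits the entire training pool
  sl_all <- build_self_labelled(st, ds, 1:4, threshold = 1e-9)
  expect_equal(sort(sl_all$indices), fold_indices(ds, 1:4))
  # pseudo-labels are the argmax predictions, not the true labels
  pred <- predict_proba(st, ds$signatures[, , sl$indices, drop = FALSE])
  expect_identical(sl$labels, pred$labels)
  expect_error(build_self_labelled(st, ds, 1:4, threshold = 1), "\\(0, 1\\)")
})

test_that("self-learning logs counts and stops when confidence collapses", {
  seqm <- micro_sequence(-5, 3L)
  n_folds <- max(seqm$timepoints[[1]]$folds)
  # untrained classifiers predict ~uniform probabilities (< 0.95), so the
  # <min_per_class rule must halt the run at the first update
  untrained <- lapply(seq_len(n_folds), function(f) {
    build_classifier("linear_baseline", seed = f)
  })
  halted <- run_self_learning(seqm, base_states = untrained,
                              min_per_class = 5L, seed = 35L)
  expect_equal(halted$stopped_at, names(seqm$timepoints)[2])
  # no retrained results at or after the stop
  expect_true(all(halted$f1$timepoint == names(seqm$timepoints)[1]))
  expect_true(all(halted$counts$timepoint == names(seqm$timepoints)[2]))
  # a trained start with a permissive rule runs to the end
  run <- run_self_learning(seqm, min_per_class = 1L, seed = 35L)
  expect_null(run$stopped_at)
  expect_setequal(unique(run$f1$timepoint), names(seqm$timepoints))
  expect_true(all(run$counts$n >= 0))
  # replay mixes the Base folds in; same structure, different updates
  run_rp <- run_self_learning(seqm, min_per_class = 1L, seed = 35L,
                              replay = TRUE)
  expect_setequal(unique(run_rp$f1$timepoint), names(seqm$timepoints))
  # the first update starts from the same state, so its self-labelled
  # selection is identical; later updates diverge
  tp1 <- names(seqm$timepoints)[2]
  expect_identical(run_rp$counts[run_rp$counts$timepoint == tp1, ],
                   run$counts[run$counts$timepoint == tp1, ])
  expect_identical(run_rp$f1[c("timepoint", "fold")],
                   run$f1[c("timepoint", "fold")])
  expect_true(all(run_rp$f1$f1 >= 0 & run_rp$f1$f1 <= 1))
})

test_that("slope differences follow the hand arithmetic", {
  mk <- function(a, b) {
    list(f1 = data.frame(timepoint = c("start", "end"), f1 = c(a, b)))
  }
  expect_equal(compute_slope_difference(mk(0.9, 0.8), mk(0.9, 0.7)), 0.1)
  expect_equal(compute_slope_difference(mk(0.9, 0.8), mk(0.9, 0.8)), 0)
  expect_equal(compute_slope_difference(mk(0.9, 0.6), mk(0.9, 0.7)), -0.1)
  expect_error(compute_slope_difference(mk(0.9, 0.8),
                                        list(f1 = data.frame(
                                          timepoint = "start", f1 = 0.9))),
               "missing time point")
})

test_that("the frequency experiment reduces to plain self-learning at m = 1", {
  ds_a <- micro_dataset(-5, fill = 0)
  ds_b <- micro_dataset(-5, fill = 1)
  n_folds <- max(ds_a$folds)
  states <- lapply(seq_len(n_folds), function(f) {
    st <- build_classifier("linear_baseline", seed = 40L + f)
    train(st, ds_a, train_folds = setdiff(seq_len(n_folds), f))
  })
  fx1 <- run_frequency_experiment(ds_a, ds_b, 1L, states,
                                  min_per_class = 1L)
  expect_false(any(fx1$stopped))
  expect_equal(sort(unique(fx1$f1$timepoint)), c("end", "start"))
  expect_equal(max(fx1$counts$step), 1L)
  # m = 2 inserts exactly one interpolated retraining step
  fx2 <- run_frequency_experiment(ds_a, ds_b, 2L, states,
                                  min_per_class = 1L)
  expect_equal(max(fx2$counts$step), 2L)
  expect_error(run_frequency_experiment(ds_a, ds_b, 3L, states), "1, 2, 4, 8")
  fx3 <- run_frequency_experiment(ds_a, ds_b, 3L, states,
                                  min_per_class = 1L,
                                  allow_any_frequency = TRUE)
  expect_equal(max(fx3$counts$step), 3L)
  # drift-free pair: different frequencies end at matching performance
  # (shared seeds and states; differences are training noise only)
  fx_same1 <- run_frequency_experiment(ds_a, ds_a, 1L, states,
                                       threshold = 0.5, min_per_class = 1L)
  fx_same2 <- run_frequency_experiment(ds_a, ds_a, 2L, states,
                                       threshold = 0.5, min_per_class = 1L)
  end1 <- mean(fx_same1$f1$f1[fx_same1$f1$timepoint == "end"])
  end2 <- mean(fx_same2$f1$f1[fx_same2$f1$timepoint == "end"])
  expect_lt(abs(end1 - end2), 0.1)
})

test_that("initial performance levels share the Base lineage", {
  seqm <- micro_sequence(-5, 3L)
  base_states <- train_base_states(seqm, "linear_baseline", 44L)
  lev <- build_initial_levels(seqm, base_states = base_states,
                              threshold = 0.5)
  expect_named(lev, c("HP", "LP"))
  expect_length(lev$HP$states, length(base_states))
  expect_true(is.numeric(lev$HP$f1) && is.numeric(lev$LP$f1))
  # both lineages continue from the same Base weights (same call count + 1)
  expect_equal(lev$HP$states[[1]]$n_train_calls,
               base_states[[1]]$n_train_calls + 1L)
  expect_equal(lev$LP$states[[1]]$n_train_calls,
               base_states[[1]]$n_train_calls + 1L)
  expect_identical(lev$HP$states[[1]]$seed, lev$LP$states[[1]]$seed)
})

test_that("the slope grid covers levels x frequencies with finite cells", {
  ds_a <- micro_dataset(-5, fill = 0)
  ds_b <- micro_dataset(-5, fill = 1)
  seqm <- micro_sequence(-5, 3L)
  lev <- build_initial_levels(seqm, "linear_baseline", 46L, threshold = 0.5)
  grid <- run_slope_grid(ds_a, ds_b, lev, frequencies = c(1L, 2L),
                         threshold = 0.5, min_per_class = 1L)
  expect_equal(nrow(grid), 4L)
  expect_setequal(grid$level, c("HP", "LP"))
  expect_setequal(grid$frequency, c(1L, 2L))
  expect_true(all(is.finite(grid$slope_difference[!grid$stopped])))
})
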