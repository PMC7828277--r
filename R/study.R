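#' Run the full simulation study
#'
#' Executes, for each requested scenario and SNR: dataset-sequence
#' generation, the three update strategies (baseline calibration, periodic
#' recalibration, self-learning) on shared data and initializations, and
#' (for the encapsulation scenario) the training-frequency /
#' initial-performance slope grid between ET1 and ET2. Tidy CSV results
#' and a JSON manifest are written under `config$output_root`.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param scenarios Scenario names (default: all configured).
#' @param snr_grid SNRs in dB (default: the config grid).
#' @param include_slope_grid Run the slope analysis (default TRUE; only
#'   applies to the encapsulation scenario).
#' @return A run manifest (list) with the config hash, artifact paths and
#'   wall-time log, invisibly also written as JSON.
#' @export
run_full_study <- function(config = default_config(),
                           scenarios = names(config$scenarios),
                           snr_grid = config$snr_grid,
                           include_slope_grid = TRUE) {
  validate_config(config)
  for (sc in scenarios) validate_config(config, sc)
  root <- config$output_root
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  f1_rows <- list()
  count_rows <- list()
  slope_rows <- list()
  timings <- list()
  for (sc in scenarios) {
    for (snr in snr_grid) {
      t0 <- Sys.time()
      seqd <- build_timepoint_sequence(config, sc, snr)
      strat_seed <- derive_seed(config$master_seed,
                                sprintf("strategy/%s/%g", sc, snr))
      hyper <- classifier_hyper(config)
      base_states <- train_base_states(seqd, config$classifier$spec,
                                       strat_seed, hyper)
      runs <- list(
        run_baseline_calibration(seqd, config$classifier$spec, strat_seed,
                                 hyper, base_states = base_states),
        run_periodic_recalibration(seqd, config$classifier$spec,
                                   strat_seed, hyper,
                                   base_states = base_states),
        run_self_learning(seqd, config$classifier$spec,
                          threshold = config$strategy$threshold,
                          min_per_class = config$strategy$min_per_class,
                          seed = strat_seed, hyper = hyper,
                          base_states = base_states,
                          replay = isTRUE(config$strategy$replay))
      )
      for (run in runs) {
        df <- run$f1
        df$strategy <- run$strategy
        df$scenario <- sc
        df$snr_db <- snr
        f1_rows[[length(f1_rows) + 1L]] <- df
        if (!is.null(run$counts)) {
          cf <- run$counts
          cf$strategy <- run$strategy
          cf$scenario <- sc
          cf$snr_db <- snr
          count_rows[[length(count_rows) + 1L]] <- cf
        }
      }
      if (include_slope_grid && sc == "encapsulation") {
        levels <- build_initial_levels(seqd, config$classifier$spec,
                                       strat_seed, hyper,
                                       threshold = config$strategy$threshold,
                                       base_states = base_states)
        grid <- run_slope_grid(seqd$timepoints[[2]], seqd$timepoints[[3]],
                               levels, config$strategy$frequencies,
                               config$strategy$threshold,
                               config$strategy$min_per_class)
        grid$snr_db <- snr
        slope_rows[[length(slope_rows) + 1L]] <- grid
      }
      timings[[sprintf("%s/%g", sc, snr)]] <-
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      rm(seqd, base_states, runs)
      gc(FALSE)
    }
  }
  paths <- list(f1 = file.path(root, "f1_trajectories.csv"),
                counts = file.path(root, "self_labelled_counts.csv"),
                slopes = file.path(root, "slope_grid.csv"),
                manifest = file.path(root, "run_manifest.json"))
  f1_all <- do.call(rbind, f1_rows)
  utils::write.csv(f1_all, paths$f1, row.names = FALSE)
  if (length(count_rows)) {
    utils::write.csv(do.call(rbind, count_rows), paths$counts,
                     row.names = FALSE)
  }
  if (length(slope_rows)) {
    utils::write.csv(do.call(rbind, slope_rows), paths$slopes,
                     row.names = FALSE)
  }
  manifest <- list(
    config_hash = config_hash(config),
    master_seed = config$master_seed,
    scenarios = scenarios,
    snr_grid = snr_grid,
    artifacts = paths[file.exists(unlist(paths)) |
                        names(paths) == "manifest"],
    wall_time_s = timings
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Build report figures and tables from study results
#'
#' Produces per-scenario macro-F1 trajectory plots (one curve per update
#' strategy, faceted by SNR, with fold-level dispersion) and, when the
#' slope grid is present, a frequency-by-initial-level slope-difference
#' table per SNR.
#'
#' @param results_dir Directory holding the CSVs written by
#'   [run_full_study()].
#' @return List with `plots` (named list of ggplot objects) and `tables`
#'   (data frames). Errors if no results are present.
#' @export
make_report <- function(results_dir = "results") {
  f1_path <- file.path(results_dir, "f1_trajectories.csv")
  if (!file.exists(f1_path)) {
    stop("no results found in ", results_dir, call. = FALSE)
  }
  f1 <- utils::read.csv(f1_path)
  plots <- list()
  tables <- list()
  for (sc in unique(f1$scenario)) {
    d <- f1[f1$scenario == sc, ]
    d$timepoint <- factor(d$timepoint, levels = unique(d$timepoint))
    plots[[paste0("f1_", sc)]] <-
      ggplot2::ggplot(d, ggplot2::aes(x = timepoint, y = f1,
                                      colour = strategy,
                                      group = strategy)) +
      ggplot2::stat_summary(fun = mean, geom = "line") +
      ggplot2::stat_summary(fun = mean, geom = "point") +
      ggplot2::stat_summary(fun.data = function(y) {
        m <- mean(y)
        s <- stats::sd(y)
        data.frame(y = m, ymin = m - s, ymax = m + s)
      }, geom = "errorbar", width = 0.15) +
      ggplot2::facet_wrap(~snr_db, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "time point", y = "macro F1",
                    title = sprintf("Update strategies: %s", sc)) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_bw()
  }
  slope_path <- file.path(results_dir, "slope_grid.csv")
  if (file.exists(slope_path)) {
    slopes <- utils::read.csv(slope_path)
    tables$slope_grid <- slopes
    plots$slope_grid <-
      ggplot2::ggplot(slopes,
                      ggplot2::aes(x = factor(frequency), y = level,
                                   fill = slope_difference)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = sprintf("%.3f", slope_difference))) +
      ggplot2::facet_wrap(~snr_db, labeller = ggplot2::label_both) +
      ggplot2::scale_fill_gradient2() +
      ggplot2::labs(x = "training frequency multiplier",
                    y = "initial performance level",
                    fill = "slope\ndifference") +
      ggplot2::theme_bw()
  }
  tables$f1_summary <- stats::aggregate(
    f1 ~ strategy + scenario + snr_db + timepoint, data = f1, FUN = mean)
  list(plots = plots, tables = tables)
}
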