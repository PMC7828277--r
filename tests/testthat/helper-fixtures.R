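# Shared fixtures, built in code. Micro-scale configurations keep each
# test cheap; expensive intermediates are cached per test run.

micro_config <- function(master_seed = 1L) {
  cfg <- default_config(master_seed)
  cfg$pathway$n_traj <- 3L
  cfg$pathway$n_control <- 5L
  cfg$n_per_class <- 45L # 9 per class per fold
  cfg$classifier$epochs <- 6L
  cfg
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

micro_dataset <- function(snr_db = -5, fill = 0, seed = 1L) {
  cached(sprintf("ds/%g/%g/%d", snr_db, fill, seed), {
    simulate_timepoint_dataset(micro_config(), sprintf("fill%g", fill),
                               snr_db, fill = fill, seed = seed)
  })
}

micro_sequence <- function(snr_db = -5, n_tp = 3L) {
  cached(sprintf("seq/%g/%d", snr_db, n_tp), {
    cfg <- micro_config()
    fills <- encapsulation_fills()[seq_len(n_tp)]
    cfg$scenarios$encapsulation <- list(timepoints = names(fills),
                                        fills = unname(fills))
    build_timepoint_sequence(cfg, "encapsulation", snr_db)
  })
}

# a drift-free sequence: the same dataset at every time point
constant_sequence <- function(n_tp = 3L, snr_db = -5) {
  ds <- micro_dataset(snr_db)
  tps <- stats::setNames(rep(list(ds), n_tp), paste0("T", seq_len(n_tp) - 1L))
  structure(list(timepoints = tps, scenario = "encapsulation",
                 snr_db = snr_db, seed = 1L),
            class = "timepoint_sequence")
}

# tiny leadfield helpers
unit_geometry <- function(...) cuff_geometry(...)

homogeneous_tissue <- function(sigma = 0.5) {
  cond <- default_conductivities()
  for (nm in names(cond)) cond[[nm]] <- sigma
  tissue_model(conductivities = cond)
}

# toy linearly separable signatures: class means far apart, tiny noise
toy_dataset <- function(n_per_class = 15L, seed = 42L, sd = 0.01) {
  arr <- array(0, dim = c(56L, 100L, 3L * n_per_class))
  labels <- rep(c("tibial", "peroneal", "sural"), each = n_per_class)
  means <- list(tibial = 1, peroneal = 2, sural = 3)
  set.seed(seed)
  for (i in seq_along(labels)) {
    mu <- matrix(0, 56, 100)
    mu[means[[labels[i]]] * 10, ] <- 0.5
    arr[, , i] <- mu + matrix(rnorm(5600, sd = sd), 56, 100)
  }
  ds <- signature_dataset(arr, labels, snr_db = NULL, timepoint_id = "toy")
  ds <- normalize_dataset(ds)
  build_dataset(ds, n_folds = 5L, seed = seed)
}
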