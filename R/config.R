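#' Default study configuration
#'
#' A single nested list drives every stage of the pipeline; each stochastic
#' stage derives its own seed from `master_seed` and a stage label, so all
#' strategies compare on identical data. The default profile is scaled for
#' a single desktop CPU (1000 CAPs per class per time point and the linear
#' classifier); [full_profile()] switches to the study-scale sizes
#' (10,000 CAPs per class, dual-branch CNN).
#'
#' @param master_seed Master seed (default 1).
#' @return A `run_config` list.
#' @export
default_config <- function(master_seed = 1L) {
  structure(list(
    geometry = list(),          # cuff_geometry() arguments
    tissue = list(),            # tissue_model() arguments
    pathway = list(n_traj = 20L, z_range = c(-4, 27), n_control = 9L,
                   wiggle_frac = 0.05),
    template = list(width_ms = 0.1, amplitude = 1),
    sampling_rate_hz = 30000,
    clip_ms = 10 / 3,           # 100 samples at 30 kHz
    n_per_class = 1000L,        # CAPs per pathway per time point
    event_density_hz = 10000 / 53.333, # study series: 10,000 CAPs / 53.333 s
    snr_grid = c(-5, -10, -15),
    n_folds = 5L,
    classifier = list(spec = "linear_baseline", epochs = 8L,
                      batch_size = 256L, lr = 0.01,
                      cnn_filters = c(8L, 16L), cnn_kernel = 3L,
                      cnn_epochs = 4L, cnn_batch_size = 32L),
    strategy = list(threshold = 0.95, min_per_class = 200L,
                    frequencies = c(1L, 2L, 4L, 8L), replay = FALSE),
    scenarios = list(
      encapsulation = list(timepoints = names(encapsulation_fills()),
                           fills = unname(encapsulation_fills())),
      rotation = list(timepoints = paste0("rot", seq(0, 45, by = 5)),
                      rotations_deg = seq(0, 45, by = 5))
    ),
    master_seed = as.integer(master_seed),
    output_root = "results"
  ), class = "run_config")
}

#' Study-scale profile
#'
#' @param config A `run_config`.
#' @return The config with study-scale sizes (10,000 CAPs per class and the
#'   dual-branch CNN classifier).
#' @export
full_profile <- function(config = default_config()) {
  config$n_per_class <- 10000L
  config$classifier$spec <- "dual_cnn"
  config
}

#' Validate a run configuration
#'
#' @param config A `run_config`.
#' @param scenario Optional scenario name to check against the config.
#' @return The config, invisibly; errors on an invalid configuration.
#' @export
validate_config <- function(config, scenario = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  req <- c("pathway", "template", "sampling_rate_hz", "clip_ms",
           "n_per_class", "event_density_hz", "snr_grid", "n_folds",
           "classifier", "strategy", "scenarios", "master_seed")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    stop("config is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(scenario) && !scenario %in% names(config$scenarios)) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  if (config$strategy$threshold <= 0 || config$strategy$threshold >= 1) {
    stop("confidence threshold must lie in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' Round-trips the configuration losslessly (numeric vectors and nested
#' lists preserved).
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$master_seed <- as.integer(cfg$master_seed)
  structure(cfg, class = "run_config")
}

#' Classifier hyperparameters implied by a configuration
#'
#' Maps the configuration's classifier block onto the hyperparameter list
#' understood by [build_classifier()] for the configured spec.
#'
#' @param config A `run_config`.
#' @return Named list of hyperparameters.
#' @export
classifier_hyper <- function(config) {
  cl <- config$classifier
  if (identical(cl$spec, "dual_cnn")) {
    list(lr = cl$lr, epochs = cl$cnn_epochs, batch_size = cl$cnn_batch_size,
         filters = cl$cnn_filters, kernel = cl$cnn_kernel)
  } else {
    list(lr = cl$lr, epochs = cl$epochs, batch_size = cl$batch_size)
  }
}

#' Stable hash of a configuration
#'
#' FNV-1a over the deparsed scientific configuration (the output location
#' is excluded, so runs of one configuration into different directories
#' share a hash); used to tag run manifests.
#'
#' @param config A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_root <- NULL
  txt <- paste(deparse(cfg), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^32
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
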