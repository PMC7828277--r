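#' Extract per-CAP spatiotemporal signatures from a series
#'
#' Windows of 100 samples (49 before and 50 after the CAP peak, 3.333 ms at
#' 30 kHz) are cut from a noisy series at the peak locations detected on
#' the clean signal (peak detection from noisy data is deliberately
#' bypassed). Events whose window would cross a series edge are skipped
#' with a warning.
#'
#' @param noisy_series A `multichannel_recording`.
#' @param clean_event_peaks Integer vector of 1-based peak sample indices
#'   from the clean series.
#' @param n_before,n_after Samples kept before/after the peak (defaults 49
#'   and 50; the window includes the peak sample).
#' @return List of channel x 100 signature matrices.
#' @export
extract_signatures <- function(noisy_series, clean_event_peaks,
                               n_before = 49L, n_after = 50L) {
  stopifnot(inherits(noisy_series, "multichannel_recording"))
  n <- ncol(noisy_series$samples)
  lo <- clean_event_peaks - n_before
  hi <- clean_event_peaks + n_after
  ok <- lo >= 1L & hi <= n
  if (any(!ok)) {
    warning(sprintf("skipped %d event(s) too close to the series edge",
                    sum(!ok)), call. = FALSE)
  }
  lapply(which(ok), function(k) {
    noisy_series$samples[, lo[k]:hi[k], drop = FALSE]
  })
}

#' Bundle signatures and labels into a dataset
#'
#' @param signatures List of channel x time matrices (one shape), or a
#'   3-D array `channels x time x N`.
#' @param labels Factor (or character) of pathway labels, length N.
#' @param snr_db Nominal SNR tag (or NULL).
#' @param timepoint_id Time point tag (e.g. `"Base"`, `"ET2"`, `"rot15"`).
#' @return A `signature_dataset` (unnormalized, no folds yet).
#' @export
signature_dataset <- function(signatures, labels, snr_db = NULL,
                              timepoint_id = NULL) {
  if (is.list(signatures)) {
    d <- dim(signatures[[1]])
    arr <- array(unlist(signatures), dim = c(d, length(signatures)))
  } else {
    arr <- signatures
  }
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == length(labels))
  labels <- factor(as.character(labels),
                   levels = c("tibial", "peroneal", "sural"))
  if (anyNA(labels)) stop("unknown pathway labels", call. = FALSE)
  structure(list(
    signatures = arr,
    labels = labels,
    folds = NULL,
    snr_db = snr_db,
    timepoint_id = timepoint_id,
    normalization_constant = NULL
  ), class = "signature_dataset")
}

#' @export
print.signature_dataset <- function(x, ...) {
  d <- dim(x$signatures)
  cat(sprintf(
    "<signature_dataset> %d signatures (%d x %d), timepoint %s, SNR %s dB, %s\n",
    d[3], d[1], d[2], x$timepoint_id %||% "?",
    format(x$snr_db %||% NA), if (is.null(x$folds)) "no folds" else
      sprintf("%d folds", max(x$folds))))
  invisible(x)
}

n_signatures <- function(dataset) dim(dataset$signatures)[3]

#' Normalize a dataset into [-1, 1]
#'
#' Divides every signature by the single maximum absolute value observed
#' across the whole dataset, so the global maximum magnitude becomes
#' exactly 1. The constant is stored for cross-time-point inspection.
#'
#' @param dataset A `signature_dataset`.
#' @return The normalized dataset with `normalization_constant` set.
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "signature_dataset"))
  m <- max(abs(dataset$signatures))
  if (m == 0) stop("all-zero dataset cannot be normalized", call. = FALSE)
  dataset$signatures <- dataset$signatures / m
  dataset$normalization_constant <- m
  dataset
}

#' Row permutation for signature channel orderings
#'
#' Raw signatures are ring-major ("spatial emphasis": ring 1 slots 1..8,
#' then ring 2, ...). "Temporal emphasis" orders contacts longitudinally:
#' slot 1 rings 1..7, then slot 2, ...
#'
#' @param mode `"spatial"` or `"temporal"`.
#' @param n_rings,contacts_per_ring Cuff layout (defaults 7 and 8).
#' @return Integer permutation `p`: row `i` of the reordered signature is
#'   row `p[i]` of the raw one.
#' @export
reorder_permutation <- function(mode = c("spatial", "temporal"),
                                n_rings = 7L, contacts_per_ring = 8L) {
  mode <- match.arg(mode)
  if (mode == "spatial") return(seq_len(n_rings * contacts_per_ring))
  as.vector(vapply(seq_len(contacts_per_ring), function(s) {
    (seq_len(n_rings) - 1L) * contacts_per_ring + s
  }, integer(n_rings)))
}

#' Reorder a signature's channels
#'
#' @param signature A channels x time matrix in raw (ring-major) order.
#' @param mode `"spatial"` (identity for ring-major input) or `"temporal"`.
#' @param n_rings,contacts_per_ring Cuff layout (defaults 7 and 8).
#' @return The row-permuted signature.
#' @export
reorder_signature <- function(signature, mode,
                              n_rings = 7L, contacts_per_ring = 8L) {
  p <- reorder_permutation(mode, n_rings, contacts_per_ring)
  signature[p, , drop = FALSE]
}

#' Assign stratified cross-validation folds
#'
#' Within each class, indices are shuffled (seeded) and dealt round-robin,
#' so class counts per fold differ by at most one; with 10,000 signatures
#' per class and 5 folds, every fold holds 6000 signatures, 2000 per class.
#'
#' @param labels Factor of class labels.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
assign_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < n_folds)) {
    stop("every class needs at least `n_folds` samples", call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Attach stratified folds to a dataset
#'
#' @param dataset A `signature_dataset`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return The dataset with `folds` set.
#' @export
build_dataset <- function(dataset, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "signature_dataset"))
  dataset$folds <- assign_folds(dataset$labels, n_folds, seed)
  dataset
}

#' Linearly interpolate between two corresponding datasets
#'
#' Both datasets must come from the same generator seeds and source banks,
#' so their signatures correspond one-to-one in order; each output matrix
#' is `(1 - alpha) * A + alpha * B`. Labels and folds are inherited.
#'
#' @param ds_a,ds_b `signature_dataset`s of identical size, labels, folds.
#' @param alpha Interpolation weight in `[0, 1]` (0 gives `ds_a` exactly).
#' @return The interpolated dataset.
#' @export
interpolate_datasets <- function(ds_a, ds_b, alpha) {
  stopifnot(inherits(ds_a, "signature_dataset"),
            inherits(ds_b, "signature_dataset"))
  stop_if_not_scalar_finite(alpha, "alpha")
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!identical(dim(ds_a$signatures), dim(ds_b$signatures)) ||
      !identical(as.character(ds_a$labels), as.character(ds_b$labels))) {
    stop("datasets do not correspond (size or labels differ)", call. = FALSE)
  }
  if (!identical(ds_a$folds, ds_b$folds)) {
    stop("datasets do not correspond (folds differ)", call. = FALSE)
  }
  out <- ds_a
  out$signatures <- if (alpha == 0) {
    ds_a$signatures # endpoints are exact, not a floating-point blend
  } else if (alpha == 1) {
    ds_b$signatures
  } else {
    (1 - alpha) * ds_a$signatures + alpha * ds_b$signatures
  }
  out$timepoint_id <- sprintf("%s+%0.3f(%s)", ds_a$timepoint_id %||% "A",
                              alpha, ds_b$timepoint_id %||% "B")
  out$normalization_constant <- NULL
  out
}

#' Subset a dataset by signature indices
#' @param dataset A `signature_dataset`.
#' @param idx Integer indices.
#' @return The subsetted dataset.
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "signature_dataset"))
  out <- dataset
  out$signatures <- dataset$signatures[, , idx, drop = FALSE]
  out$labels <- dataset$labels[idx]
  out$folds <- dataset$folds[idx]
  out
}

#' Indices of the signatures in the given folds
#' @param dataset A `signature_dataset` with folds assigned.
#' @param folds Integer vector of fold ids.
#' @return Integer indices.
#' @export
fold_indices <- function(dataset, folds) {
  stopifnot(inherits(dataset, "signature_dataset"), !is.null(dataset$folds))
  which(dataset$folds %in% folds)
}

#' Summarize a dataset's composition
#'
#' Per-class (and, when folds are assigned, per-fold) signature counts,
#' with the dataset's tags; suitable for CSV export alongside the study
#' results.
#'
#' @param dataset A `signature_dataset`.
#' @param path Optional CSV path to write the summary to.
#' @return The summary data frame (invisibly when `path` is given).
#' @export
dataset_summary <- function(dataset, path = NULL) {
  stopifnot(inherits(dataset, "signature_dataset"))
  if (is.null(dataset$folds)) {
    out <- as.data.frame(table(class = dataset$labels),
                         responseName = "n")
    out$fold <- NA_integer_
  } else {
    out <- as.data.frame(table(class = dataset$labels,
                               fold = dataset$folds),
                         responseName = "n")
    out$fold <- as.integer(as.character(out$fold))
  }
  out$timepoint_id <- dataset$timepoint_id %||% NA_character_
  out$snr_db <- dataset$snr_db %||% NA_real_
  out$normalization_constant <- dataset$normalization_constant %||% NA_real_
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
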