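#' Charge-balanced source current template
#'
#' The transmembrane current injected at each node of Ranvier is modeled as
#' a Ricker wavelet (negative second derivative of a Gaussian), which is
#' charge balanced by construction: its time integral is zero. All nodes
#' share one template, time-shifted by the propagation delay, consistent
#' with constant-velocity propagation of a synchronous fiber population.
#'
#' @param width_ms Gaussian width parameter in ms (default 0.1; the main
#'   lobe of the resulting wavelet is ~0.3 ms wide).
#' @param amplitude Source current scale (default 1).
#' @param support_ms Half-support in ms beyond which the template is
#'   treated as zero (default `8 * width_ms`).
#' @param sampling_rate_hz Sampling rate for the sampled view (default 30000).
#' @return A `source_template` with an analytic evaluator `fun(t_s)`
#'   (time in seconds) and a sampled waveform `samples`.
#' @export
source_template <- function(width_ms = 0.1, amplitude = 1,
                            support_ms = 8 * width_ms,
                            sampling_rate_hz = 30000) {
  stopifnot(width_ms > 0, support_ms > 0)
  w_s <- width_ms / 1000
  sup_s <- support_ms / 1000
  fun <- function(t_s) {
    out <- numeric(length(t_s))
    inside <- abs(t_s) <= sup_s
    x <- t_s[inside] / w_s
    out[inside] <- amplitude * (1 - x^2) * exp(-x^2 / 2)
    out
  }
  t_samp <- seq(-sup_s, sup_s, by = 1 / sampling_rate_hz)
  structure(list(
    fun = fun,
    samples = fun(t_samp),
    sample_times_s = t_samp,
    width_ms = width_ms,
    amplitude = amplitude,
    support_ms = support_ms,
    duration_ms = 2 * support_ms,
    sampling_rate_hz = sampling_rate_hz
  ), class = "source_template")
}

#' Simulate the multi-channel recording of one propagating CAP
#'
#' Each node of Ranvier injects the shared source template delayed by its
#' arc length divided by the conduction velocity; channel i is the
#' leadfield-weighted sum `sum_k gains[i, k] * template(t - s_k / v)`.
#'
#' @param leadfield A [compute_leadfield()] result whose columns are the
#'   node positions (`ncol(gains)` must equal `nrow(nodes)`).
#' @param nodes Node positions as returned by [place_nodes()] (must carry
#'   the `"arc_length_mm"` attribute).
#' @param template A [source_template()].
#' @param velocity_m_s Conduction velocity in m/s.
#' @param clip_ms If non-NULL, clip the result to this window centered on
#'   the global peak (see [clip_recording()]).
#' @param sampling_rate_hz Sampling rate (default 30000).
#' @return A `multichannel_recording` (unreferenced).
#' @export
simulate_cap <- function(leadfield, nodes, template, velocity_m_s,
                         clip_ms = NULL, sampling_rate_hz = 30000) {
  stopifnot(inherits(leadfield, "leadfield"),
            inherits(template, "source_template"))
  if (!is.numeric(velocity_m_s) || velocity_m_s <= 0) {
    stop("`velocity_m_s` must be positive", call. = FALSE)
  }
  nodes <- as.matrix(nodes)
  if (ncol(leadfield$gains) != nrow(nodes)) {
    stop("every node must have a leadfield column", call. = FALSE)
  }
  s_mm <- attr(nodes, "arc_length_mm")
  if (is.null(s_mm)) {
    stop("`nodes` must carry the \"arc_length_mm\" attribute", call. = FALSE)
  }
  delays_s <- (s_mm / 1000) / velocity_m_s
  sup_s <- template$support_ms / 1000
  pad_s <- max(clip_ms %||% 0, 3.3334) / 1000 # room for peak-centered clips
  t <- seq(min(delays_s) - sup_s - pad_s,
           max(delays_s) + sup_s + pad_s,
           by = 1 / sampling_rate_hz)
  # K x T matrix of shifted templates, then one matrix product
  shifted <- vapply(t, function(tn) template$fun(tn - delays_s),
                    numeric(length(delays_s)))
  if (is.null(dim(shifted))) shifted <- matrix(shifted, nrow = 1L)
  samples <- leadfield$gains %*% shifted
  rec <- structure(list(
    samples = samples,
    sampling_rate_hz = sampling_rate_hz,
    t0_s = t[1],
    referenced = FALSE,
    event_peaks = integer(0),
    snr_db = NULL
  ), class = "multichannel_recording")
  if (!is.null(clip_ms)) rec <- clip_recording(rec, clip_ms) else rec
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf(
    "<multichannel_recording> %d channels x %d samples @ %g Hz, %s%s\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
    if (x$referenced) "tripole-referenced" else "unreferenced",
    if (is.null(x$snr_db)) "" else sprintf(", SNR %g dB", x$snr_db)))
  invisible(x)
}

#' Tripole-reference a recording
#'
#' Subtracts, at every time instant, the instantaneous mean of all
#' outer-ring contacts (rings 1 and the last ring; 16 contacts in the
#' default 7 x 8 layout) from every channel. Referencing twice is an error.
#'
#' @param recording An unreferenced `multichannel_recording`.
#' @param geometry The [cuff_geometry()] that produced it.
#' @return The referenced recording.
#' @export
tripole_reference <- function(recording, geometry) {
  stopifnot(inherits(recording, "multichannel_recording"),
            inherits(geometry, "cuff_geometry"))
  if (isTRUE(recording$referenced)) {
    stop("recording is already tripole-referenced", call. = FALSE)
  }
  if (nrow(recording$samples) != geometry$n_contacts) {
    stop("channel count does not match the geometry", call. = FALSE)
  }
  idx <- contact_index(geometry)
  outer <- idx$channel[idx$ring %in% c(1L, geometry$n_rings)]
  ref <- colMeans(recording$samples[outer, , drop = FALSE])
  recording$samples <- sweep(recording$samples, 2L, ref, "-")
  recording$referenced <- TRUE
  recording
}

#' Clip a recording to a window centered on its global peak
#'
#' The peak is the global maximum of `|samples|` across all channels; ties
#' are broken toward the earliest sample, then the lowest channel. The
#' window holds `round(clip_ms * rate / 1000)` samples with the peak at
#' position `floor(n/2) + 1` (sample 50 of 100 for the default 3.333 ms
#' window, i.e. 49 samples before the peak and 50 after).
#'
#' @param recording A `multichannel_recording`.
#' @param clip_ms Window length in ms (default 10/3 ms = 100 samples at
#'   30 kHz).
#' @return The clipped recording, with attribute-style field
#'   `peak_sample` giving the in-window peak position.
#' @export
clip_recording <- function(recording, clip_ms = 10 / 3) {
  stopifnot(inherits(recording, "multichannel_recording"))
  n_clip <- as.integer(round(clip_ms * recording$sampling_rate_hz / 1000))
  x <- recording$samples
  if (ncol(x) < n_clip) stop("recording shorter than the clip", call. = FALSE)
  absx <- abs(x)
  peak_col <- which.max(apply(absx, 2L, max)) # earliest column on ties
  n_before <- n_clip %/% 2L - 1L
  lo <- peak_col - n_before
  hi <- lo + n_clip - 1L
  if (lo < 1L) { lo <- 1L; hi <- n_clip }
  if (hi > ncol(x)) { hi <- ncol(x); lo <- hi - n_clip + 1L }
  recording$samples <- x[, lo:hi, drop = FALSE]
  recording$t0_s <- recording$t0_s + (lo - 1L) / recording$sampling_rate_hz
  recording$peak_sample <- peak_col - lo + 1L
  recording
}

#' Assemble a long time series from a bank of CAP clips
#'
#' Onset times are drawn uniformly (seeded) with minimum separation of one
#' clip length, so events never overlap; successive events cycle through
#' the bank entries (the per-pathway radial offsets).
#'
#' @param cap_bank List of clipped, referenced `multichannel_recording`s
#'   sharing one shape (channels x clip length).
#' @param n_events Number of CAPs to place.
#' @param duration_s Series duration in seconds.
#' @param seed Integer seed.
#' @param sampling_rate_hz Sampling rate (default 30000).
#' @return A `multichannel_recording` whose `event_peaks` field logs the
#'   1-based peak sample of every event (increasing), with the event log
#'   in field `events` (onset sample, bank entry).
#' @export
assemble_time_series <- function(cap_bank, n_events, duration_s, seed,
                                 sampling_rate_hz = 30000) {
  stopifnot(is.list(cap_bank), length(cap_bank) >= 1L, n_events >= 1L)
  clip_len <- ncol(cap_bank[[1]]$samples)
  n_ch <- nrow(cap_bank[[1]]$samples)
  for (b in cap_bank) {
    stopifnot(ncol(b$samples) == clip_len, nrow(b$samples) == n_ch)
  }
  n_samples <- round(duration_s * sampling_rate_hz)
  slack <- n_samples - n_events * clip_len
  if (slack < 0) {
    stop(sprintf(
      "cannot pack %d events of %d samples into %d samples", n_events,
      clip_len, n_samples), call. = FALSE)
  }
  onsets <- with_seed(seed, {
    sort(runif(n_events, 0, slack))
  })
  onsets <- floor(onsets) + (seq_len(n_events) - 1L) * clip_len + 1L
  x <- matrix(0, nrow = n_ch, ncol = n_samples)
  entry <- ((seq_len(n_events) - 1L) %% length(cap_bank)) + 1L
  peak_off <- vapply(cap_bank, function(b) b$peak_sample %||% 1L, integer(1))
  for (k in seq_len(n_events)) {
    cols <- onsets[k]:(onsets[k] + clip_len - 1L)
    x[, cols] <- x[, cols] + cap_bank[[entry[k]]]$samples
  }
  structure(list(
    samples = x,
    sampling_rate_hz = sampling_rate_hz,
    t0_s = 0,
    referenced = isTRUE(cap_bank[[1]]$referenced),
    event_peaks = onsets + peak_off[entry] - 1L,
    events = data.frame(onset = onsets, bank_entry = entry),
    snr_db = NULL
  ), class = "multichannel_recording")
}

#' Add white Gaussian noise at a target SNR
#'
#' One noise standard deviation is used for all channels:
#' `sigma^2 = P_signal / 10^(snr_db / 10)`, where `P_signal` is the mean
#' squared value of the (referenced) series pooled over all channels and
#' the full duration, silence included. Independent Gaussian samples are
#' added per channel.
#'
#' @param recording A `multichannel_recording`.
#' @param snr_db Target signal-to-noise ratio in dB (the study grid is
#'   -5, -10, -15).
#' @param seed Integer seed.
#' @return The noisy recording, with `snr_db` and `noise_sigma` recorded.
#' @export
add_noise <- function(recording, snr_db, seed) {
  stopifnot(inherits(recording, "multichannel_recording"))
  stop_if_not_scalar_finite(snr_db, "snr_db")
  p_signal <- mean(recording$samples^2)
  if (p_signal == 0) {
    stop("zero-signal series: SNR is undefined", call. = FALSE)
  }
  sigma <- sqrt(p_signal / 10^(snr_db / 10))
  noise <- with_seed(seed, {
    matrix(stats::rnorm(length(recording$samples), sd = sigma),
           nrow = nrow(recording$samples))
  })
  recording$samples <- recording$samples + noise
  recording$snr_db <- snr_db
  recording$noise_sigma <- sigma
  recording
}

#' Noise standard deviation implied by a bank, an event count and a duration
#'
#' Computes the full-series signal power analytically from the clip
#' energies of the bank entries that the event cycling would place
#' (events never overlap and the series is silent elsewhere), and returns
#' the white-noise standard deviation for the target SNR. This allows
#' noise to be materialized per extracted window while remaining
#' identical in distribution to noising the full series.
#'
#' @param cap_bank List of clipped recordings (the per-pathway bank).
#' @param n_events Number of events in the notional series.
#' @param duration_s Series duration in seconds.
#' @param snr_db Target SNR in dB.
#' @param sampling_rate_hz Sampling rate (default 30000).
#' @return Noise standard deviation.
#' @export
series_noise_sigma <- function(cap_bank, n_events, duration_s, snr_db,
                               sampling_rate_hz = 30000) {
  n_ch <- nrow(cap_bank[[1]]$samples)
  n_samples <- round(duration_s * sampling_rate_hz)
  entry <- ((seq_len(n_events) - 1L) %% length(cap_bank)) + 1L
  energies <- vapply(cap_bank, function(b) sum(b$samples^2), numeric(1))
  p_signal <- sum(energies[entry]) / (n_samples * n_ch)
  sqrt(p_signal / 10^(snr_db / 10))
}
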