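# ERP waveforms, pink noise, SNR calibration and epoch simulation.

#' Half-sine ERP component waveform
#'
#' A single non-negative half-cycle of a sinusoid: zero outside
#' `[onset, onset + duration]`, peaking at `onset + duration/2` with value
#' `amplitude`.  The duration must equal half a cycle of `freq`
#' (`1000 / (2 freq)` ms) to within one sample.
#'
#' @param freq waveform frequency in Hz (default 5, giving a 100 ms lobe).
#' @param onset lobe onset in ms post-stimulus.
#' @param duration lobe duration in ms.
#' @param amplitude peak amplitude (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param n_samples number of samples in the epoch.
#' @param t0 time of the first sample in ms (stimulus at 0).
#' @return numeric vector of length `n_samples`.
#' @examples
#' w <- erp_waveform(onset = 100, n_samples = 250, t0 = -200)
#' range(which(w > 0))  # samples strictly inside (100, 200) ms
#' @export
erp_waveform <- function(freq = 5, onset = 100, duration = 1000 / (2 * freq),
                         amplitude = 1, fs = 250, n_samples = 250,
                         t0 = -200) {
  if (abs(duration - 1000 / (2 * freq)) > 1000 / fs) {
    stop_invalid("duration must equal half a cycle of freq within one sample")
  }
  if (onset < t0) stop_invalid("onset lies before the epoch start")
  t_end <- t0 + (n_samples - 1) * 1000 / fs
  if (onset + duration > t_end) {
    stop_invalid("waveform extends beyond the epoch")
  }
  t <- t0 + (seq_len(n_samples) - 1) * 1000 / fs
  w <- numeric(n_samples)
  inside <- t > onset & t < onset + duration
  w[inside] <- amplitude * sin(pi * (t[inside] - onset) / duration)
  w
}

#' Generate channels of pink (1/f) noise
#'
#' White Gaussian noise is shaped in the frequency domain with an amplitude
#' spectrum proportional to `1/sqrt(f)` (power proportional to `1/f`), the DC
#' component is removed (exact zero mean), and each channel is standardized to
#' unit variance.  Channels are independent; output is deterministic given
#' `seed`.
#'
#' @param n_channels number of independent channels.
#' @param n_samples samples per channel, at least 64.
#' @param fs sampling rate in Hz.
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return `n_channels x n_samples` matrix.
#' @export
pink_noise <- function(n_channels, n_samples, fs, seed = NULL) {
  if (n_samples < 64) stop_invalid("n_samples must be at least 64")
  if (n_channels < 1) stop_invalid("n_channels must be at least 1")
  white <- with_seed(seed,
    matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels))
  k <- seq_len(n_samples) - 1
  freq <- pmin(k, n_samples - k) * fs / n_samples  # two-sided bin frequencies
  amp <- ifelse(freq > 0, 1 / sqrt(freq), 0)       # DC removed
  shaped <- Re(stats::mvfft(stats::mvfft(white) * amp, inverse = TRUE)) / n_samples
  shaped <- sweep(shaped, 2, colMeans(shaped))
  sds <- sqrt(colMeans(shaped^2))
  t(sweep(shaped, 2, sds, "/"))
}

epoch_time <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1) * 1000 / epochs$fs
}

#' Construct an epoch-set container
#'
#' @param data `n_epochs x n_sensors x n_samples` array (volts, arbitrary
#'   overall scale).
#' @param condition per-epoch labels, `"erp"` or `"noise"`.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in ms (stimulus at 0).
#' @param montage_id provenance key of the montage.
#' @param ... further metadata stored alongside (e.g. `seed`, `snr_db`,
#'   `network`).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, condition, fs, t0, montage_id = NA_character_,
                      ...) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(condition))
  condition <- as.character(condition)
  if (!all(condition %in% c("erp", "noise"))) {
    stop_invalid("condition labels must be 'erp' or 'noise'")
  }
  structure(list(data = data, condition = condition, fs = fs, t0 = t0,
                 montage_id = montage_id, meta = list(...)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs (%d erp / %d noise) x %d sensors x %d samples @ %g Hz, t0 = %g ms\n",
    d[1], sum(x$condition == "erp"), sum(x$condition == "noise"),
    d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' Measure the SNR of an epoch set
#'
#' Implements the peak-to-peak-based definition: the SNR is the ratio of the
#' peak amplitude of the ERP component to the peak-to-peak amplitude in the
#' pre-stimulus window, in dB.  Operationally: take the ERP component
#' waveform (the noiseless sensor-space ERP stored by [simulate_epochs()] in
#' `meta$clean_erp`; for epoch sets without it, the average of the
#' erp-condition epochs is used as the component estimate); find the sensor
#' with the largest post-stimulus absolute component amplitude; `A_peak` is
#' that amplitude and `A_pp` is the mean over erp-condition epochs of the
#' pre-stimulus peak-to-peak amplitude at that same sensor.  Returns
#' `20 log10(A_peak / A_pp)`; `Inf` when the pre-stimulus window is
#' noise-free (`A_pp = 0`).
#'
#' Using the clean component for `A_peak` keeps the measure faithful to "the
#' peak amplitude of the ERP component" at strongly negative SNRs: a peak
#' read off the noisy condition average is itself inflated by noise, which
#' saturates the measure near -16 dB and would make the lower end of the
#' studied SNR range unreachable.  The condition-average fallback inherits
#' that saturation and is only reliable above about -15 dB.
#'
#' @param epochs an [epoch_set] with erp-condition epochs present.
#' @return SNR in dB.
#' @export
measure_snr <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  t <- epoch_time(epochs)
  pre <- t < 0; post <- t >= 0
  if (!any(pre)) stop_invalid("no pre-stimulus samples in the epoch")
  erp_idx <- which(epochs$condition == "erp")
  if (length(erp_idx) == 0) stop_invalid("no erp-condition epochs")
  avg <- if (!is.null(epochs$meta$clean_erp)) epochs$meta$clean_erp
         else apply(epochs$data[erp_idx, , , drop = FALSE], c(2, 3), mean)
  peak_by_sensor <- apply(abs(avg[, post, drop = FALSE]), 1, max)
  s_star <- which.max(peak_by_sensor)
  a_peak <- peak_by_sensor[s_star]
  pp <- vapply(erp_idx, function(e) {
    x <- epochs$data[e, s_star, pre]
    max(x) - min(x)
  }, 0)
  a_pp <- mean(pp)
  if (a_pp == 0) return(Inf)
  20 * log10(a_peak / a_pp)
}

#' Calibrate the noise scale for a target SNR
#'
#' Finds the factor by which `noise_prototype` must be scaled so that epochs
#' built as `clean ERP + scale * noise` measure `target_snr_db` under
#' [measure_snr()].  Solved by bisection on the log scale against the exact
#' noise realizations that will enter the epochs, so the round trip through
#' `measure_snr` lands within `tol_db`.
#'
#' @param clean_sensor_erp `n_sensors x n_samples` noiseless sensor-space ERP.
#' @param noise_prototype `n_epochs x n_sensors x n_samples` unit-scale noise
#'   array; the first half of the epochs will carry the ERP.
#' @param target_snr_db target SNR in dB.
#' @param fs,t0 timing metadata of the epochs.
#' @param tol_db calibration tolerance in dB (default 0.05).
#' @param max_iter bisection iteration cap (default 40).
#' @return scalar noise scale factor.
#' @export
calibrate_noise_scale <- function(clean_sensor_erp, noise_prototype,
                                  target_snr_db, fs = 250, t0 = -200,
                                  tol_db = 0.05, max_iter = 40L) {
  if (!is.finite(target_snr_db)) stop_invalid("target SNR must be finite")
  n_epochs <- dim(noise_prototype)[1]
  if (is.null(n_epochs) || n_epochs < 2) {
    stop_invalid("noise_prototype must be an epochs x sensors x samples array")
  }
  nscale <- sqrt(mean(noise_prototype^2))
  if (nscale == 0) stop_invalid("noise prototype is identically zero")
  cond <- rep(c("erp", "noise"), c(ceiling(n_epochs / 2), floor(n_epochs / 2)))

  measured <- function(log_scale) {
    sc <- 10^log_scale
    data <- noise_prototype * sc
    for (e in which(cond == "erp")) data[e, , ] <- data[e, , ] + clean_sensor_erp
    measure_snr(epoch_set(data, cond, fs = fs, t0 = t0,
                          clean_erp = clean_sensor_erp))
  }

  # initial guess from amplitude ratios, then a widening bracket
  peak <- max(abs(clean_sensor_erp))
  guess <- log10(peak / (4 * nscale)) - target_snr_db / 20
  lo <- guess - 2; hi <- guess + 2
  f_lo <- measured(lo); f_hi <- measured(hi)  # SNR decreases with scale
  widen <- 0L
  while (f_lo < target_snr_db && widen < 6L) { lo <- lo - 2; f_lo <- measured(lo); widen <- widen + 1L }
  while (f_hi > target_snr_db && widen < 12L) { hi <- hi + 2; f_hi <- measured(hi); widen <- widen + 1L }
  if (f_lo < target_snr_db || f_hi > target_snr_db) {
    stop_numeric("noise calibration failed to bracket the target SNR (",
                 "f(lo) = ", signif(f_lo, 4), ", f(hi) = ", signif(f_hi, 4),
                 ", target = ", target_snr_db, " dB)")
  }
  mid <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- measured(mid)
    if (abs(f_mid - target_snr_db) <= tol_db) return(10^mid)
    if (f_mid > target_snr_db) lo <- mid else hi <- mid
  }
  stop_numeric("noise calibration did not converge within ", max_iter,
               " bisection steps (last measured ", signif(measured(mid), 4),
               " dB, target ", target_snr_db, " dB)")
}

#' Simulation configuration
#'
#' Bundles the epoch-level simulation parameters.  Defaults mirror the study
#' conditions: 80 epochs of 1000 ms at 250 Hz with a 200 ms pre-stimulus
#' window, a 5 Hz half-cycle ERP lobe of 100 ms, and half the epochs carrying
#' only noise.
#'
#' @param n_epochs even epoch count (half per condition).
#' @param epoch_length epoch length in ms.
#' @param prestim pre-stimulus window length in ms.
#' @param fs sampling rate in Hz.
#' @param snr_db target SNR in dB.
#' @param erp_freq ERP lobe frequency in Hz.
#' @param erp_duration ERP lobe duration in ms.
#' @param amplitude peak source amplitude of full-scale ROIs (arbitrary units).
#' @param noise_site `"source"` (default) or `"sensor"`: where the pink noise
#'   is injected.  Source-space noise places independent pink-noise currents
#'   on every dipole and projects them through the generating forward model,
#'   so the noise shares the spatial structure of brain activity; sensor-space
#'   noise is spatially white at the electrodes.  The SNR calibration is exact
#'   either way (it measures the assembled sensor-space epochs).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_epochs = 80L, epoch_length = 1000, prestim = 200,
                       fs = 250, snr_db = -10, erp_freq = 5,
                       erp_duration = 1000 / (2 * erp_freq), amplitude = 1,
                       noise_site = c("source", "sensor"), seed = 1L) {
  noise_site <- match.arg(noise_site)
  if (n_epochs %% 2 != 0 || n_epochs < 2) {
    stop_invalid("n_epochs must be even and at least 2")
  }
  if (prestim >= epoch_length) stop_invalid("prestim must be below epoch_length")
  structure(list(n_epochs = as.integer(n_epochs), epoch_length = epoch_length,
                 prestim = prestim, fs = fs, snr_db = snr_db,
                 erp_freq = erp_freq, erp_duration = erp_duration,
                 amplitude = amplitude, noise_site = noise_site,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate sensor-space ERP epochs for one subject
#'
#' Builds the per-ROI source activity (every dipole of ROI `k` carries the
#' ROI-`k` half-sine waveform with a radial orientation, scaled by the ROI's
#' amplitude scale), projects it to the sensors through the subject's own
#' generating leadfield, and adds pink noise -- calibrated so the resulting
#' epochs measure `config$snr_db` -- to all epochs.  The first half of the
#' epochs carries ERP plus noise, the second half noise only.
#'
#' @param network a [network_spec] or [resolved_network][resolve_network].
#' @param subject_leadfield the subject's generating [leadfield]
#'   [compute_leadfield] (the detailed model of their own geometry).
#' @param sources the [source_space][make_source_space] the leadfield was
#'   computed on.
#' @param config a [sim_config].
#' @return an [epoch_set] with `meta` carrying `seed`, `snr_db`,
#'   `noise_scale`, `network`, and the clean sensor ERP (`clean_erp`).
#' @export
simulate_epochs <- function(network, subject_leadfield, sources, config = sim_config()) {
  stopifnot(inherits(subject_leadfield, "leadfield"),
            inherits(sources, "source_space"), inherits(config, "sim_config"))
  if (!identical(subject_leadfield$source_space_id, sources$id)) {
    stop_provenance("leadfield was not computed on this source space (",
                    subject_leadfield$source_space_id, " vs ", sources$id, ")")
  }
  net <- if (inherits(network, "resolved_network")) network
         else resolve_network(network, sources)
  if (!identical(net$source_space_id, sources$id)) {
    stop_provenance("network was resolved on a different source space")
  }
  fs <- config$fs; t0 <- -config$prestim
  n_samples <- round(config$epoch_length * fs / 1000)
  n_epochs <- config$n_epochs
  n_sensors <- subject_leadfield$n_sensors

  # clean sensor-space ERP: radial unit moments, ROI waveform per member dipole
  clean <- matrix(0, n_sensors, n_samples)
  unit_pos <- unit_rows(sources$positions)
  for (k in seq_len(4)) {
    w <- erp_waveform(freq = config$erp_freq, onset = net$onsets[k],
                      duration = config$erp_duration,
                      amplitude = config$amplitude * net$amplitude_scales[k],
                      fs = fs, n_samples = n_samples, t0 = t0)
    g <- numeric(n_sensors)
    for (i in net$dipole_sets[[k]]) {
      cols <- (3 * (i - 1) + 1):(3 * i)
      g <- g + subject_leadfield$gain[, cols] %*% unit_pos[i, ]
    }
    clean <- clean + g %*% t(w)
  }

  cond <- rep(c("erp", "noise"), each = n_epochs / 2)
  if (config$noise_site == "sensor") {
    noise_flat <- pink_noise(n_epochs * n_sensors, n_samples, fs,
                             seed = config$seed)
    noise <- array(noise_flat, dim = c(n_epochs, n_sensors, n_samples))
  } else {
    # source-space variant: independent pink noise on every dipole (radial
    # moment), projected through the same leadfield
    n_src <- subject_leadfield$n_sources
    noise <- array(0, dim = c(n_epochs, n_sensors, n_samples))
    radial <- radial_projection_matrix(subject_leadfield, sources)
    for (e in seq_len(n_epochs)) {
      src_noise <- pink_noise(n_src, n_samples, fs,
                              seed = derive_seed(config$seed, e))
      noise[e, , ] <- radial %*% src_noise
    }
  }
  scale <- calibrate_noise_scale(clean, noise, config$snr_db, fs = fs, t0 = t0)
  data <- noise * scale
  for (e in which(cond == "erp")) data[e, , ] <- data[e, , ] + clean

  epoch_set(data, cond, fs = fs, t0 = t0,
            montage_id = subject_leadfield$montage_id,
            seed = config$seed, snr_db = config$snr_db, noise_scale = scale,
            network = net$network, clean_erp = clean,
            source_space_id = sources$id)
}

# sensors x sources matrix mapping radial source amplitudes to sensors
radial_projection_matrix <- function(leadfield, sources) {
  unit_pos <- unit_rows(sources$positions)
  n_src <- leadfield$n_sources
  out <- 0
  for (k in 1:3) {
    Gk <- leadfield$gain[, seq(k, by = 3, length.out = n_src), drop = FALSE]
    out <- out + sweep(Gk, 2, unit_pos[, k], "*")
  }
  out
}

#' Condition-averaged sensor-space evoked response
#'
#' @param epochs an [epoch_set].
#' @param condition which condition to average.
#' @return `n_sensors x n_samples` matrix.
#' @export
sensor_evoked <- function(epochs, condition = "erp") {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$condition == condition)
  if (length(idx) == 0) stop_invalid("no epochs with condition '", condition, "'")
  apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
}
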