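# ERP waveforms, ROI selection, pink noise, SNR measurement/calibration and
# epoch simulation.

test_that("half-sine lobe has the right support, peak and integral", {
  w <- erp_waveform(freq = 5, onset = 100, duration = 100, amplitude = 1,
                    fs = 250, n_samples = 250, t0 = -200)
  t <- -200 + (0:249) * 4
  expect_true(all(w[t <= 100 | t >= 200] == 0))
  expect_true(all(w[t > 100 & t < 200] > 0))
  expect_equal(t[which.max(w)], 148)  # sample nearest the 150 ms peak
  expect_equal(max(w), sin(pi * 48 / 100))
  # peak equals amplitude exactly when the peak falls on a sample
  w2 <- erp_waveform(onset = 100, fs = 250, n_samples = 250, t0 = -202)
  expect_equal(max(w2), 1)
  # integral of the lobe: amplitude * (2/pi) * duration, within 2% at 250 Hz
  expect_lt(abs(sum(w) * 4 - (2 / pi) * 100) / ((2 / pi) * 100), 0.02)
  expect_identical(erp_waveform(amplitude = 0, n_samples = 250), rep(0, 250))
})

test_that("waveform preconditions are enforced", {
  expect_error(erp_waveform(freq = 5, duration = 150, n_samples = 250),
               class = "erplocsim_invalid_argument")
  expect_error(erp_waveform(onset = -300, n_samples = 250, t0 = -200),
               class = "erplocsim_invalid_argument")
  expect_error(erp_waveform(onset = 900, n_samples = 250, t0 = -200),
               class = "erplocsim_invalid_argument")
})

test_that("ROI selection returns exactly the dipoles within the radius", {
  mod <- make_shell_model("bem_default")
  ss <- make_source_space(mod, spacing = 3)
  center <- ss$positions[100, ]
  idx <- select_roi_dipoles(ss, list(center = center, radius_mm = 10))
  d <- sqrt(colSums((t(ss$positions) - center)^2)) * 1000
  expect_identical(idx, which(d <= 10))
  expect_true(length(idx) >= 10 && length(idx) <= 60)  # 10 mm ROI on 3 mm grid
  # radius of half the spacing centered on a dipole selects just that dipole
  expect_identical(select_roi_dipoles(ss, list(center = center, radius_mm = 1.5)),
                   100L)
  expect_error(select_roi_dipoles(ss, list(center = c(0, 0, 0), radius_mm = 10)),
               class = "erplocsim_empty_roi")
})

test_that("pink noise has a 1/f power spectrum and independent channels", {
  x <- pink_noise(100, 5000, fs = 250, seed = 4)
  # periodogram log-log slope over 1-40 Hz, averaged over channels
  n <- 5000
  freq <- (0:(n / 2 - 1)) * 250 / n
  sel <- freq >= 1 & freq <= 40
  pows <- apply(x, 1, function(ch) abs(fft(ch)[1:(n / 2)])^2)
  mp <- rowMeans(pows)[sel]
  slope <- coef(lm(log10(mp) ~ log10(freq[sel])))[2]
  expect_lt(abs(slope + 1), 0.15)
  expect_identical(x, pink_noise(100, 5000, fs = 250, seed = 4))
  expect_false(identical(x, pink_noise(100, 5000, fs = 250, seed = 5)))
  expect_lt(abs(cor(x[1, ], x[2, ])), 0.1)
  expect_lt(max(abs(rowMeans(x))), 1e-10)
  expect_error(pink_noise(2, 32, 250), class = "erplocsim_invalid_argument")
})

test_that("SNR measure reproduces its defining ratios on constructed epochs", {
  # build epochs with a known peak and known pre-stimulus peak-to-peak
  n_sens <- 4; n_samp <- 100; t0 <- -200; fs <- 250
  make_data <- function(peak, pp) {
    data <- array(0, dim = c(4, n_sens, n_samp))
    t <- t0 + (0:(n_samp - 1)) * 1000 / fs
    for (e in 1:2) {
      data[e, 2, which(t >= 0)[10]] <- peak       # post-stimulus peak
      data[e, 2, 3] <- pp / 2; data[e, 2, 5] <- -pp / 2  # prestim
    }
    epoch_set(data, c("erp", "erp", "noise", "noise"), fs = fs, t0 = t0)
  }
  expect_equal(measure_snr(make_data(1, 1)), 0)
  expect_equal(measure_snr(make_data(0.1, 1)), -20)
  expect_equal(measure_snr(make_data(2, 1)), 20 * log10(2))
  expect_identical(measure_snr(make_data(1, 0)), Inf)  # noiseless guard
})

test_that("noise calibration round-trips through the SNR measure", {
  fx <- small_setup()
  net <- resolve_network(network_spec("fronto_occipital"), fx$sources)
  for (target in c(-10, 0)) {
    ep <- simulate_epochs(net, fx$lf, fx$sources,
                          sim_config(snr_db = target, seed = 2))
    expect_lt(abs(measure_snr(ep) - target), 0.5)
  }
  # doubling the noise scale lowers the measured SNR by about 6.02 dB
  ep <- simulate_epochs(net, fx$lf, fx$sources, sim_config(snr_db = -5, seed = 2))
  sc <- ep$meta$noise_scale
  clean <- ep$meta$clean_erp
  noise <- ep$data
  for (e in which(ep$condition == "erp")) noise[e, , ] <- noise[e, , ] - clean
  data2 <- noise * 2
  for (e in which(ep$condition == "erp")) data2[e, , ] <- data2[e, , ] + clean
  ep2 <- epoch_set(data2, ep$condition, fs = ep$fs, t0 = ep$t0,
                   clean_erp = clean)
  expect_lt(abs((measure_snr(ep) - measure_snr(ep2)) - 20 * log10(2)), 1.0)
})

test_that("simulated epochs have the stated counts, balance and determinism", {
  fx <- sim_setup()
  ep <- fx$epochs
  expect_identical(dim(ep$data)[1], 80L)
  expect_identical(sum(ep$condition == "erp"), 40L)
  expect_identical(sum(ep$condition == "noise"), 40L)
  expect_identical(dim(ep$data)[3], 250L)   # 1000 ms at 250 Hz
  expect_equal(ep$t0, -200)
  ep2 <- simulate_epochs(fx$net, fx$lf, fx$sources,
                         sim_config(snr_db = -5, seed = 11))
  expect_identical(ep$data, ep2$data)
  ep3 <- simulate_epochs(fx$net, fx$lf, fx$sources,
                         sim_config(snr_db = -5, seed = 12))
  expect_false(identical(ep$data, ep3$data))
})

test_that("source timing and amplitude scaling follow the network spec", {
  net <- network_spec("temporo_occipital")
  onsets <- sapply(net$rois, `[[`, "onset")
  scales <- sapply(net$rois, `[[`, "amplitude_scale")
  expect_identical(onsets, c(100, 110, 120, 120))
  expect_identical(scales, c(1, 1, 0.8, 0.8))
  # waveform lags between ROI-1 and ROI-2 are 10 ms, ROI-1 and ROI-3 20 ms
  # (exact at a sampling rate whose grid contains the onsets); peaks scale 0.8
  w <- lapply(1:4, function(k)
    erp_waveform(onset = onsets[k], amplitude = scales[k],
                 fs = 1000, n_samples = 1000, t0 = -200))
  expect_identical(which.max(w[[2]]) - which.max(w[[1]]), 10L)
  expect_identical(which.max(w[[3]]) - which.max(w[[1]]), 20L)
  expect_equal(max(w[[3]]) / max(w[[1]]), 0.8)
})

test_that("noise-only epochs carry no ERP on average", {
  # with many epochs the noise-condition average shrinks toward zero
  fx <- small_setup()
  net <- resolve_network(network_spec("fronto_occipital"), fx$sources)
  ep <- simulate_epochs(net, fx$lf, fx$sources,
                        sim_config(n_epochs = 400, snr_db = 0, seed = 9,
                                   noise_site = "sensor"))
  noise_avg <- sensor_evoked(ep, "noise")
  sc <- ep$meta$noise_scale
  n_noise <- sum(ep$condition == "noise")
  # channel sd is sc, so the average of n sd-sc channels has sd sc/sqrt(n)
  expect_lt(max(abs(noise_avg)), 6 * sc / sqrt(n_noise))
})

test_that("fronto-occipital topography separates into distinct sensor groups", {
  fx <- sim_setup()
  ep <- fx$epochs
  t <- ep$t0 + (seq_len(dim(ep$data)[3]) - 1) * 1000 / ep$fs
  topo <- abs(ep$meta$clean_erp[, which.min(abs(t - 150))])
  top <- order(topo, decreasing = TRUE)[seq_len(ceiling(0.1 * length(topo)))]
  pos <- fx$montage$positions[top, ]
  # connected components of the top-sensor set under a 3 cm adjacency
  d <- as.matrix(dist(pos))
  adj <- d < 0.03
  reach <- adj
  for (i in seq_len(nrow(adj))) reach <- (reach %*% adj) > 0
  expect_gt(length(unique(apply(reach, 1, function(r) min(which(r))))), 1)
})

test_that("mismatched provenance is rejected", {
  fx <- small_setup()
  other <- make_source_space(fx$model, spacing = 14)
  expect_error(
    simulate_epochs(network_spec("fronto_occipital"), fx$lf, other,
                    sim_config()),
    class = "erplocsim_provenance_error")
})
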