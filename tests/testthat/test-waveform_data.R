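# Synthetic generator, simulation loader, IO round-trips and detection.

test_that("generated spike sets satisfy the container invariants", {
  for (seed in 1:3) {
    sp <- easy_spikes(seed = seed, duration = 30, multiunit = TRUE)
    expect_s3_class(sp, "spike_set")
    expect_equal(ncol(sp$waveforms), 79L)
    expect_equal(length(sp$labels), nrow(sp$waveforms))
    expect_true(all(sp$labels >= 0L))
    expect_true(all(sp$peak_indices >= 1L & sp$peak_indices <= 79L))
    expect_true(0L %in% sp$labels)       # multi-unit cluster present
  }
})

test_that("generation is bit-reproducible for a fixed seed and spec", {
  spec <- simulation_spec(n_single_units = 3L, duration = 20)
  a <- generate_labeled_spikes(spec, seed = 42L)
  b <- generate_labeled_spikes(spec, seed = 42L)
  expect_identical(a$waveforms, b$waveforms)
  expect_identical(a$labels, b$labels)
  c <- generate_labeled_spikes(spec, seed = 43L)
  expect_false(identical(a$waveforms, c$waveforms))
})

test_that("noise-free single-unit waveforms are scalar multiples of one template", {
  spec <- simulation_spec(n_single_units = 1L, duration = 60,
                          noise_sd = 0, peak_jitter = 0L,
                          multiunit_n_shapes = 0L, rate_low = 1,
                          rate_high = 1)
  sp <- generate_labeled_spikes(spec, seed = 7L)
  expect_gt(n_spikes(sp), 10L)
  w <- sp$waveforms
  # every pair of waveforms perfectly correlated
  cors <- stats::cor(t(w))
  expect_true(all(abs(cors - 1) < 1e-12))
  # and each is template * amplitude: ratio of any two rows is constant
  ratio <- w[2, ] / w[1, ]
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-9)
})

test_that("within-unit correlation is 1 without noise or jitter (several units)", {
  spec <- simulation_spec(n_single_units = 4L, duration = 40, noise_sd = 0,
                          peak_jitter = 0L, multiunit_n_shapes = 0L)
  sp <- generate_labeled_spikes(spec, seed = 5L)
  for (u in unique(sp$labels)) {
    w <- sp$waveforms[sp$labels == u, , drop = FALSE]
    if (nrow(w) < 2L) next
    expect_true(all(abs(stats::cor(t(w)) - 1) < 1e-12))
  }
})

test_that("empirical firing rates fall inside exact Poisson intervals", {
  # oracle: exact Poisson 99% interval for the realized duration
  duration <- 400
  spec <- simulation_spec(n_single_units = 3L, duration = duration,
                          rate_low = 1, rate_high = 1,
                          multiunit_n_shapes = 0L)
  sp <- generate_labeled_spikes(spec, seed = 11L)
  counts <- table(sp$labels)
  lo <- stats::qpois(0.005, 1 * duration)
  hi <- stats::qpois(0.995, 1 * duration)
  for (u in names(counts)) {
    expect_gte(as.integer(counts[[u]]), lo)
    expect_lte(as.integer(counts[[u]]), hi)
  }
})

test_that("recordings honour the minimum separation and reproduce templates", {
  spec <- simulation_spec(n_single_units = 3L, duration = 20, noise_sd = 0,
                          rate_low = 1, rate_high = 2,
                          multiunit_n_shapes = 5L)
  rec <- generate_recording(spec, seed = 9L)
  gaps <- diff(rec$true_spike_times)
  expect_true(all(gaps >= spec$min_separation * spec$sampling_rate))
  # noise-free: cutting a window at a true peak reproduces an inserted
  # spike exactly (peak value equals the template peak times an amplitude
  # within the configured range)
  peaks <- rec$signal[rec$true_spike_times]
  single <- rec$true_labels > 0L
  # overlap-free single-unit peaks lie within the amplitude interval
  isolated <- single & c(Inf, diff(rec$true_spike_times)) > 79 &
    c(diff(rec$true_spike_times), Inf) > 79
  if (any(isolated)) {
    expect_true(all(peaks[isolated] >= spec$amplitude_low - 1e-9))
    expect_true(all(peaks[isolated] <= spec$amplitude_high + 1e-9))
  }
})

test_that("multi-unit composite rate matches shapes x unit rate (Poisson interval)", {
  # 20 shapes x 0.25 Hz = 5 Hz composite
  duration <- 240
  spec <- simulation_spec(n_single_units = 1L, duration = duration,
                          rate_low = 0.1, rate_high = 0.1,
                          multiunit_n_shapes = 20L,
                          multiunit_unit_rate = 0.25)
  sp <- generate_labeled_spikes(spec, seed = 13L)
  n_mu <- sum(sp$labels == 0L)
  expect_gte(n_mu, stats::qpois(0.005, 5 * duration))
  expect_lte(n_mu, stats::qpois(0.995, 5 * duration))
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulation_spec(amplitude_low = 2, amplitude_high = 1),
               "amplitude_low")
  expect_error(simulation_spec(min_separation = -1), "min_separation")
  expect_error(simulation_spec(rate_low = 0), "rates")
  expect_error(simulation_spec(samples_per_spike = 2), "samples_per_spike")
})

test_that("waveform CSV and binary containers round-trip", {
  sp <- easy_spikes(seed = 2L, duration = 10)
  csv <- tempfile(fileext = ".csv")
  write_waveforms_csv(sp, csv)
  rd <- read_waveforms_csv(csv, sampling_rate = sp$sampling_rate)
  expect_identical(rd$labels, sp$labels)
  expect_equal(rd$waveforms, sp$waveforms, ignore_attr = TRUE,
               tolerance = 1e-12)
  bin <- tempfile(fileext = ".swb")
  write_waveforms_bin(sp, bin)
  rb <- read_waveforms_bin(bin)
  expect_identical(rb$labels, sp$labels)      # integer fields bit-exact
  expect_identical(rb$waveforms, unname(sp$waveforms))
})

test_that("MAT containers round-trip and feed the simulation loader", {
  sp <- easy_spikes(seed = 4L, duration = 10, multiunit = TRUE)
  path <- tempfile(fileext = ".mat")
  write_mat(list(spikes = sp$waveforms,
                 cluster_class = as.numeric(sp$labels)), path)
  loaded <- load_simulation(path)
  expect_equal(n_spikes(loaded), n_spikes(sp))
  expect_identical(loaded$labels, sp$labels)
  expect_equal(length(unique(loaded$labels)), length(unique(sp$labels)))
  expect_identical(unname(loaded$waveforms), unname(sp$waveforms))
})

test_that("simulation loader cuts windows from a continuous trace", {
  spec <- simulation_spec(n_single_units = 2L, duration = 10, noise_sd = 0.02,
                          rate_low = 1, rate_high = 2,
                          multiunit_n_shapes = 0L)
  rec <- generate_recording(spec, seed = 6L)
  path <- tempfile(fileext = ".mat")
  write_mat(list(data = rec$signal,
                 spike_times = as.numeric(rec$true_spike_times),
                 spike_class = as.numeric(rec$true_labels)), path)
  loaded <- load_simulation(path)
  expect_equal(ncol(loaded$waveforms), 79L)
  expect_lte(n_spikes(loaded), length(rec$true_spike_times))
  # windows are centred on the true peak
  mid <- floor(79 / 2) + 1L
  kept <- match(loaded$starts + mid - 1L, rec$true_spike_times)
  expect_false(anyNA(kept))
  expect_equal(loaded$waveforms[, mid],
               rec$signal[rec$true_spike_times[kept]])
})

test_that("loader errors name the missing mapped variable", {
  path <- tempfile(fileext = ".mat")
  write_mat(list(spikes = matrix(1:10, 2)), path)
  expect_error(load_simulation(path), "cluster_class")
  expect_error(load_simulation(tempfile()), "not found")
  path2 <- tempfile(fileext = ".mat")
  write_mat(list(data = rnorm(100)), path2)
  expect_error(load_simulation(path2), "spike_times")
})

test_that("edge spikes are skipped and counted when cutting windows", {
  rec <- spike_recording(rnorm(500), 24000)
  expect_message(out <- cut_windows(rec, c(5L, 250L, 499L), 79L),
                 "2 spike window")
  expect_equal(n_spikes(out), 1L)
})

test_that("spike detection recovers inserted spikes and rejects pure noise", {
  spec <- simulation_spec(n_single_units = 2L, duration = 10,
                          noise_sd = 0.05, rate_low = 1, rate_high = 2,
                          multiunit_n_shapes = 0L)
  rec <- generate_recording(spec, seed = 5L)
  # amplitudes >= 0.9 are ~18x the 0.05 noise SD: all should be found
  det <- detect_spikes(rec, threshold_k = 4, lockout = 40L)
  dt <- attr(det, "detected_times")
  recall <- mean(vapply(rec$true_spike_times,
                        function(t) any(abs(dt - t) <= 2L), logical(1)))
  expect_gte(recall, 0.95)
  expect_null(det$labels)
  # pure noise with a 10 SD threshold: nothing to find
  noise <- spike_recording(stats::rnorm(48000), 24000)
  expect_equal(n_spikes(detect_spikes(noise, threshold_k = 10)), 0L)
  # invalid bands rejected
  expect_error(detect_spikes(rec, band_low = 5000, band_high = 300),
               "band_low")
  expect_error(detect_spikes(rec, band_high = 20000), "band")
})

test_that("default detection threshold lies in the conventional 3-5 SD range", {
  k <- eval(formals(detect_spikes)$threshold_k)
  expect_gte(k, 3)
  expect_lte(k, 5)
})
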