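#' Procedural biphasic spike templates
#'
#' The public benchmark simulations were built from a library of recorded
#' spike shapes that cannot be redistributed, so this generator uses a
#' procedural family instead: each template is a difference of two Gaussian
#' lobes (a sharp depolarisation peak followed by a slower
#' after-hyperpolarisation trough) whose width, trough delay, trough width
#' and trough depth vary per unit. Parameters are stratified across units
#' (evenly spaced with a small seeded jitter) so that distinct units have
#' reliably distinct shapes, and each template is rolled so its maximum sits
#' exactly at the window middle, `floor(n/2) + 1`. Templates are normalised
#' to a peak amplitude of 1.
#'
#' @param n_units number of templates to generate.
#' @param n_samples samples per template.
#' @param seed integer RNG seed.
#' @return a `n_units x n_samples` matrix of unit-peak templates.
#' @export
spike_templates <- function(n_units, n_samples, seed = 1L) {
  with_seed(seed, {
    u <- seq_len(n_units)
    frac <- (u - 0.5) / n_units
    # stratified shape parameters, in samples (scaled to the window
    # length); each parameter is spread over its range in an independent
    # random unit order so units differ along several shape axes at once
    sc <- n_samples / 79
    strat <- function(lo, hi, jit) {
      (lo + frac[sample.int(n_units)] * (hi - lo) +
         stats::runif(n_units, -jit, jit))
    }
    peak_w <- strat(1.5, 6, 0.25) * sc
    delay <- strat(3, 12, 0.6) * sc
    trough_w <- strat(2.5, 9, 0.4) * sc
    depth <- strat(0.25, 0.95, 0.03)
    pre_dip <- strat(0, 0.45, 0.02)
    pre_w <- strat(2, 5, 0.3) * sc
    bump <- strat(0, 0.3, 0.02)
    mid <- floor(n_samples / 2) + 1L
    x <- seq_len(n_samples)
    tm <- matrix(0, n_units, n_samples)
    for (i in u) {
      s <- exp(-0.5 * ((x - mid) / peak_w[i])^2) -
        depth[i] * exp(-0.5 * ((x - mid - delay[i]) / trough_w[i])^2) -
        pre_dip[i] * exp(-0.5 * ((x - mid + 2.2 * peak_w[i]) / pre_w[i])^2) +
        bump[i] * exp(-0.5 * ((x - mid - delay[i] - 2.5 * trough_w[i]) /
                                (2 * trough_w[i]))^2)
      # roll so the discrete argmax is exactly at the middle
      s <- shift_pad(s, mid - which.max(s))
      tm[i, ] <- s / max(s)
    }
    tm
  })
}

# Per-unit mean firing rates and expected spike counts for a spec.
draw_unit_rates <- function(spec) {
  stats::runif(spec$n_single_units, spec$rate_low, spec$rate_high)
}

# Characteristic mean amplitude per unit: spread across the amplitude
# interval (emulating distinct electrode distances), mildly jittered, and
# randomly assigned to units.
draw_unit_amplitudes <- function(spec) {
  k <- spec$n_single_units
  span <- spec$amplitude_high - spec$amplitude_low
  mu <- spec$amplitude_low + (seq_len(k) - 0.5) / k * span
  mu <- mu + stats::runif(k, -0.1, 0.1) * span / k
  sample(pmin(pmax(mu, spec$amplitude_low), spec$amplitude_high))
}

# Per-spike amplitudes: normal around the unit mean, truncated to the
# dataset's amplitude interval.
draw_spike_amplitudes <- function(n, mu, spec) {
  pmin(pmax(stats::rnorm(n, mu, spec$amplitude_sd), spec$amplitude_low),
       spec$amplitude_high)
}

#' Generate a labeled set of spike waveforms
#'
#' Draws spike counts for each single unit from a Poisson distribution
#' (rate uniform in `[rate_low, rate_high]` Hz over `duration` seconds) and
#' for each multi-unit component at `multiunit_unit_rate` Hz. Single-unit
#' waveforms are their unit's template scaled by a per-spike amplitude: the
#' amplitudes are drawn from a normal distribution and min-max rescaled into
#' `[amplitude_low, amplitude_high]` across the whole dataset. Multi-unit
#' spikes (label 0) draw among `multiunit_n_shapes` templates at the fixed
#' amplitude `multiunit_amplitude`. Gaussian noise of sd `noise_sd` is added
#' and, if `peak_jitter > 0`, each waveform is shifted by a uniform integer
#' in `[-peak_jitter, peak_jitter]` samples (edge values replicated).
#' Spikes are returned ordered by label, as in the benchmark simulations;
#' use [shuffle_spikes()] before training.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer RNG seed; output is bit-reproducible for a fixed
#'   seed and spec.
#' @return a [spike_set()] with labels (0 = multi-unit) and `peak_indices`.
#' @export
generate_labeled_spikes <- function(spec, seed = 1L) {
  validate_simulation_spec(spec)
  with_seed(seed, {
    p <- spec$samples_per_spike
    mid <- floor(p / 2) + 1L
    templates <- spike_templates(spec$n_single_units, p,
                                 seed = stats::runif(1, 1, 2^30))
    mu_templates <- spike_templates(spec$multiunit_n_shapes, p,
                                    seed = stats::runif(1, 1, 2^30))
    rates <- draw_unit_rates(spec)
    counts <- stats::rpois(spec$n_single_units, rates * spec$duration)
    mu_counts <- stats::rpois(spec$multiunit_n_shapes,
                              spec$multiunit_unit_rate * spec$duration)
    n_single <- sum(counts)
    n_mu <- sum(mu_counts)
    n <- n_single + n_mu
    if (n == 0L) {
      warning("spec produced no spikes (duration too short for the rates)")
      return(spike_set(matrix(numeric(0), 0L, p), spec$sampling_rate,
                       labels = integer(0), source = "synthetic"))
    }
    unit_mu <- draw_unit_amplitudes(spec)
    amps <- if (n_single > 0L) {
      draw_spike_amplitudes(n_single,
                            rep.int(unit_mu, counts), spec)
    } else numeric(0)
    labels <- c(rep.int(seq_len(spec$n_single_units), counts),
                rep.int(0L, n_mu))
    w <- matrix(0, n, p)
    if (n_single > 0L) {
      w[seq_len(n_single), ] <-
        templates[rep.int(seq_len(spec$n_single_units), counts), ,
                  drop = FALSE] * amps
    }
    if (n_mu > 0L) {
      w[n_single + seq_len(n_mu), ] <-
        mu_templates[rep.int(seq_len(spec$multiunit_n_shapes), mu_counts), ,
                     drop = FALSE] * spec$multiunit_amplitude
    }
    peaks <- rep.int(mid, n)
    if (spec$peak_jitter > 0L) {
      shifts <- sample.int(2L * spec$peak_jitter + 1L, n, replace = TRUE) -
        spec$peak_jitter - 1L
      for (i in which(shifts != 0L)) w[i, ] <- shift_pad(w[i, ], shifts[i])
      peaks <- peaks + shifts
    }
    if (spec$noise_sd > 0) {
      w <- w + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    }
    spike_set(w, spec$sampling_rate, labels = labels, peak_indices = peaks,
              source = sprintf("synthetic(units=%d, seed=%d)",
                               spec$n_single_units, as.integer(seed)))
  })
}

#' Generate a continuous recording with ground truth
#'
#' Simulates independent Poisson spike trains for every single unit and
#' every multi-unit component, merges them, and greedily thins the merged
#' train so consecutive events are at least `min_separation` seconds apart
#' (no temporally overlapping spikes, as in the benchmark simulations).
#' Templates scaled by their per-spike amplitudes are added onto a Gaussian
#' noise floor; the true peak sample index and unit label of every inserted
#' spike are returned.
#'
#' @inheritParams generate_labeled_spikes
#' @return a [spike_recording()] with `true_spike_times` (peak sample
#'   indices) and `true_labels`.
#' @export
generate_recording <- function(spec, seed = 1L) {
  validate_simulation_spec(spec)
  with_seed(seed, {
    p <- spec$samples_per_spike
    fs <- spec$sampling_rate
    n_samp <- ceiling(spec$duration * fs)
    templates <- spike_templates(spec$n_single_units, p,
                                 seed = stats::runif(1, 1, 2^30))
    mu_templates <- spike_templates(spec$multiunit_n_shapes, p,
                                    seed = stats::runif(1, 1, 2^30))
    rates <- draw_unit_rates(spec)
    poisson_train <- function(rate) {
      t <- cumsum(stats::rexp(max(10, ceiling(rate * spec$duration * 2) + 20),
                              rate))
      t[t < spec$duration]
    }
    ev_t <- numeric(0); ev_lab <- integer(0); ev_shape <- integer(0)
    for (u in seq_len(spec$n_single_units)) {
      t <- poisson_train(rates[u])
      ev_t <- c(ev_t, t)
      ev_lab <- c(ev_lab, rep.int(u, length(t)))
      ev_shape <- c(ev_shape, rep.int(u, length(t)))
    }
    for (m in seq_len(spec$multiunit_n_shapes)) {
      t <- poisson_train(spec$multiunit_unit_rate)
      ev_t <- c(ev_t, t)
      ev_lab <- c(ev_lab, rep.int(0L, length(t)))
      ev_shape <- c(ev_shape, rep.int(-m, length(t)))
    }
    ord <- order(ev_t)
    ev_t <- ev_t[ord]; ev_lab <- ev_lab[ord]; ev_shape <- ev_shape[ord]
    # greedy thinning: keep an event only if it clears the last kept one
    keep <- logical(length(ev_t))
    last <- -Inf
    for (i in seq_along(ev_t)) {
      if (ev_t[i] - last >= spec$min_separation) {
        keep[i] <- TRUE
        last <- ev_t[i]
      }
    }
    ev_t <- ev_t[keep]; ev_lab <- ev_lab[keep]; ev_shape <- ev_shape[keep]
    # keep only spikes whose full window fits inside the signal
    pre <- floor(p / 2)
    peak_idx <- round(ev_t * fs) + 1L
    ok <- peak_idx - pre >= 1L & peak_idx - pre + p - 1L <= n_samp
    peak_idx <- peak_idx[ok]; ev_lab <- ev_lab[ok]; ev_shape <- ev_shape[ok]
    signal <- if (spec$noise_sd > 0) {
      stats::rnorm(n_samp, 0, spec$noise_sd)
    } else numeric(n_samp)
    n_ev <- length(peak_idx)
    if (n_ev == 0L) {
      warning("no spikes placed (duration too short for the rates)")
      return(spike_recording(signal, fs, integer(0), integer(0)))
    }
    unit_mu <- draw_unit_amplitudes(spec)
    amps <- numeric(n_ev)
    single <- ev_lab > 0L
    if (any(single)) {
      amps[single] <- draw_spike_amplitudes(sum(single),
                                            unit_mu[ev_lab[single]], spec)
    }
    amps[!single] <- spec$multiunit_amplitude
    for (i in seq_len(n_ev)) {
      tmpl <- if (ev_shape[i] > 0L) templates[ev_shape[i], ]
              else mu_templates[-ev_shape[i], ]
      at <- (peak_idx[i] - pre):(peak_idx[i] - pre + p - 1L)
      signal[at] <- signal[at] + tmpl * amps[i]
    }
    spike_recording(signal, fs, true_spike_times = peak_idx,
                    true_labels = ev_lab)
  })
}

#' Cut fixed-length windows around spike times
#'
#' Windows are centred on the given peak sample with `floor(window/2)`
#' pre-peak samples. Spikes whose window would cross the signal edge are
#' skipped with a message reporting the count.
#'
#' @param rec a [spike_recording()].
#' @param times integer sample indices of spike peaks.
#' @param window window length in samples.
#' @param labels optional labels carried onto the kept spikes.
#' @return a [spike_set()]; the kept windows' `starts` record their
#'   position in the signal.
#' @export
cut_windows <- function(rec, times, window, labels = NULL) {
  pre <- floor(window / 2)
  starts <- as.integer(times) - pre
  ok <- starts >= 1L & starts + window - 1L <= length(rec$signal)
  if (any(!ok)) {
    message(sum(!ok), " spike window(s) exceed the signal bounds; skipped")
  }
  starts <- starts[ok]
  w <- t(vapply(starts,
                function(s) rec$signal[s:(s + window - 1L)],
                numeric(window)))
  if (length(starts) == 0L) w <- matrix(numeric(0), 0L, window)
  spike_set(w, rec$sampling_rate,
            labels = if (!is.null(labels)) labels[ok],
            peak_indices = rep.int(pre + 1L, length(starts)),
            starts = starts, source = "cut_windows")
}
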