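# Pulsed drive-current model: waveform synthesis, harmonic decomposition and
# band-limited reconstruction of per-voxel field time courses.
#
# The clinical stimulator delivers a unipolar current pulse (active phase
# ~1.3 ms) repeating at 75 Hz through the coil, with a 240 A peak. Only peak,
# active-phase duration and repetition rate are published, so the waveform
# shape is a configurable model choice (trapezoid by default).

#' Specification of the pulsed coil drive current
#'
#' @param peak_current Peak current in amperes (default 240 A).
#' @param active_phase Duration of the active phase in seconds (default
#'   1.3 ms). Must be shorter than one repetition period.
#' @param repetition_frequency Pulse repetition rate in Hz (default 75).
#' @param waveform_shape One of `"trapezoid"`, `"raised_cosine"`,
#'   `"exponential_decay"`.
#' @param rise_fraction For the trapezoid: rise (= fall) time as a fraction of
#'   the active phase. The default 0.1 puts the ramp time at about
#'   1/f_max of the simulated band, so the band retains essentially all of
#'   the pulse's spectral energy.
#' @param decay_fraction For `"exponential_decay"`: time constant as a
#'   fraction of the active phase.
#' @param sample_rate Waveform sampling rate in Hz; default 4096 samples per
#'   period.
#' @return An object of class `pulsed_signal_spec`.
#' @examples
#' spec <- pulsed_signal_spec()
#' spec$active_phase / (1 / spec$repetition_frequency)  # active fraction ~0.0975
#' @export
pulsed_signal_spec <- function(peak_current = 240,
                               active_phase = 1.3e-3,
                               repetition_frequency = 75,
                               waveform_shape = c("trapezoid", "raised_cosine",
                                                  "exponential_decay"),
                               rise_fraction = 0.1,
                               decay_fraction = 0.2,
                               sample_rate = 4096 * repetition_frequency) {
  waveform_shape <- match.arg(waveform_shape)
  if (!is_scalar_number(peak_current) || peak_current < 0)
    stopf("peak_current must be a non-negative number")
  if (!is_scalar_number(active_phase) || active_phase <= 0)
    stopf("active_phase must be a positive duration in seconds")
  if (!is_scalar_number(repetition_frequency) || repetition_frequency <= 0)
    stopf("repetition_frequency must be positive")
  if (active_phase >= 1 / repetition_frequency)
    stopf("active_phase (%g s) must be shorter than the period (%g s)",
          active_phase, 1 / repetition_frequency)
  if (rise_fraction < 0 || rise_fraction > 0.5)
    stopf("rise_fraction must lie in [0, 0.5]")
  structure(list(peak_current = peak_current,
                 active_phase = active_phase,
                 repetition_frequency = repetition_frequency,
                 waveform_shape = waveform_shape,
                 rise_fraction = rise_fraction,
                 decay_fraction = decay_fraction,
                 sample_rate = sample_rate),
            class = "pulsed_signal_spec")
}

#' @export
print.pulsed_signal_spec <- function(x, ...) {
  cat(sprintf("Pulsed signal: %s, peak %g A, active phase %g ms, %g Hz repetition\n",
              x$waveform_shape, x$peak_current, 1e3 * x$active_phase,
              x$repetition_frequency))
  invisible(x)
}

#' Synthesize one period of the pulsed drive current
#'
#' @param spec A [pulsed_signal_spec()].
#' @param n_samples Number of uniform samples over one period (>= 16).
#' @return List with `times` (s, starting at 0), `current` (A), `period` (s),
#'   class `pemf_pulse`.
#' @export
synthesize_pulse <- function(spec, n_samples = 4096) {
  stopifnot(inherits(spec, "pulsed_signal_spec"))
  if (n_samples < 16) stopf("n_samples must be at least 16")
  period <- 1 / spec$repetition_frequency
  t <- (seq_len(n_samples) - 1) / n_samples * period
  ta <- spec$active_phase
  A <- spec$peak_current
  i <- switch(spec$waveform_shape,
    trapezoid = {
      tr <- spec$rise_fraction * ta
      if (tr == 0) {
        ifelse(t < ta, 1, 0)
      } else {
        ifelse(t >= ta, 0,
               pmin(1, pmin(t / tr, (ta - t) / tr)))
      }
    },
    raised_cosine = ifelse(t < ta, 0.5 * (1 - cos(2 * pi * t / ta)), 0),
    exponential_decay = ifelse(t < ta, exp(-t / (spec$decay_fraction * ta)), 0)
  ) * A
  structure(list(times = t, current = i, period = period, spec = spec),
            class = "pemf_pulse")
}

#' Construct a harmonic set
#'
#' A `harmonic_set` holds the complex one-sided Fourier amplitudes of a
#' periodic drive current on a uniform frequency grid, plus the DC (mean)
#' component. The waveform is recovered as
#' `i(t) = dc + sum_k Re(a_k exp(1i 2 pi f_k t))`.
#'
#' @param frequencies Strictly increasing, uniformly spaced frequencies (Hz).
#' @param amplitudes Complex one-sided amplitudes (A), one per frequency.
#' @param dc Real DC component (A), default 0.
#' @param fundamental Fundamental frequency of the decomposed waveform (Hz),
#'   or `NA` when unknown.
#' @export
harmonic_set <- function(frequencies, amplitudes, dc = 0, fundamental = NA_real_) {
  if (length(frequencies) == 0) stopf("harmonic set must contain at least one frequency")
  if (length(frequencies) != length(amplitudes))
    stopf("frequencies and amplitudes differ in length")
  if (is.unsorted(frequencies, strictly = TRUE))
    stopf("frequencies must be strictly increasing")
  if (length(frequencies) > 1) {
    steps <- diff(frequencies)
    if (max(abs(steps - steps[1])) > 1e-9 * steps[1])
      stopf("frequencies must be uniformly spaced")
    step <- steps[1]
  } else step <- frequencies[1]
  structure(list(frequencies = as.numeric(frequencies),
                 amplitudes = as.complex(amplitudes),
                 dc = as.numeric(dc),
                 band = c(f_min = frequencies[1],
                          f_max = frequencies[length(frequencies)],
                          step = step),
                 fundamental = fundamental),
            class = "harmonic_set")
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat(sprintf("Harmonic set: %d components, [%g, %g] Hz step %g Hz, DC %.3g A\n",
              length(x$frequencies), x$band["f_min"], x$band["f_max"],
              x$band["step"], x$dc))
  invisible(x)
}

#' Frequencies of a uniform band
#'
#' Validates that `f_step` divides the band width and returns the grid; the
#' band `[50, 7500]` Hz at 50 Hz step yields exactly 150 frequencies.
#' @param f_min,f_max,f_step Band limits and step in Hz.
#' @export
band_frequencies <- function(f_min, f_max, f_step) {
  if (f_min <= 0 || f_step <= 0 || f_max < f_min)
    stopf("band must satisfy 0 < f_min <= f_max and f_step > 0")
  n_steps <- (f_max - f_min) / f_step
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stopf("f_step (%g Hz) must divide the band width (%g Hz)", f_step, f_max - f_min)
  f_min + f_step * (0:round(n_steps))
}

#' Harmonic decomposition of a periodic pulse onto a frequency band
#'
#' Computes the true Fourier-series coefficients of the sampled periodic
#' waveform (at multiples of its fundamental) and places them on the requested
#' uniform frequency grid. Grid frequencies that are not multiples of the
#' fundamental carry zero amplitude: a periodic signal has no spectral content
#' off its harmonic comb. With the default 75 Hz repetition rate, the
#' "native" grid of 75 Hz multiples up to 7500 Hz retains every in-band
#' harmonic; a 50 Hz-spaced replication grid retains only multiples of 150 Hz.
#'
#' @param pulse A sampled waveform from [synthesize_pulse()].
#' @param band Numeric `c(f_min, f_max, f_step)` in Hz, or `NULL` to use the
#'   native harmonic grid up to `f_max_native`.
#' @param f_max_native Upper limit of the native grid (default 7500 Hz).
#' @return A [harmonic_set()].
#' @export
decompose_harmonics <- function(pulse, band = NULL, f_max_native = 7500) {
  stopifnot(inherits(pulse, "pemf_pulse"))
  n <- length(pulse$current)
  f0 <- 1 / pulse$period
  if (is.null(band)) band <- c(f0, floor(f_max_native / f0) * f0, f0)
  freqs <- band_frequencies(band[1], band[2], band[3])
  nyquist <- n / 2 * f0
  if (band[2] > nyquist)
    stopf("band upper limit %g Hz exceeds the waveform Nyquist limit %g Hz",
          band[2], nyquist)
  X <- stats::fft(pulse$current) / n
  k <- freqs / f0
  amps <- complex(length.out = length(freqs))
  harmonic <- abs(k - round(k)) < 1e-9
  kk <- round(k[harmonic])
  amps[harmonic] <- 2 * X[kk + 1]
  harmonic_set(freqs, amps, dc = Re(X[1]), fundamental = f0)
}

#' Reconstruct a per-voxel field time course by harmonic superposition
#'
#' Given one complex field phasor per harmonic frequency (the field produced
#' by unit coil current at that frequency, at one voxel), recomposes the real
#' time series `dc_phasor * dc + sum_k Re(phasor_k a_k exp(1i w_k t))` over
#' one signal period.
#'
#' For the magnetic flux density the transfer is frequency-independent
#' (`phasor_k` identical for all k), so the time course is the spatial unit
#' field times the band-limited current waveform, DC included. For induced
#' current density the DC term must be zero (`dc_phasor = 0`): a static
#' current induces nothing.
#'
#' @param phasors Complex vector, one unit-current field phasor per harmonic.
#' @param harmonics A [harmonic_set()].
#' @param n_samples Time samples over one period.
#' @param dc_phasor Real field-per-ampere transfer at DC (default 0).
#' @param quantity Label for the reconstructed quantity.
#' @param voxel Optional integer triple recorded in the result.
#' @return List with `times` (s), `values`, `quantity`, `voxel`; class
#'   `field_time_course`.
#' @export
reconstruct_time_course <- function(phasors, harmonics, n_samples = 4096,
                                    dc_phasor = 0,
                                    quantity = "B_magnitude", voxel = NULL) {
  stopifnot(inherits(harmonics, "harmonic_set"))
  if (length(phasors) != length(harmonics$frequencies))
    stopf("phasors (%d) and harmonic frequencies (%d) differ in length",
          length(phasors), length(harmonics$frequencies))
  period <- if (is.finite(harmonics$fundamental)) 1 / harmonics$fundamental
            else 1 / harmonics$band[["step"]]
  t <- (seq_len(n_samples) - 1) / n_samples * period
  a <- harmonics$amplitudes * as.complex(phasors)
  keep <- Mod(a) > 0
  vals <- rep(dc_phasor * harmonics$dc, n_samples)
  for (k in which(keep)) {
    vals <- vals + Re(a[k] * exp(2i * pi * harmonics$frequencies[k] * t))
  }
  structure(list(times = t, values = vals, quantity = quantity, voxel = voxel),
            class = "field_time_course")
}

#' Band-limited current waveform implied by a harmonic set
#'
#' Convenience wrapper: reconstruction with unit transfer at every frequency
#' (and at DC), i.e. the band-limited approximation of `i(t)` itself.
#' @inheritParams reconstruct_time_course
#' @export
bandlimited_current <- function(harmonics, n_samples = 4096) {
  reconstruct_time_course(rep(1, length(harmonics$frequencies)), harmonics,
                          n_samples = n_samples, dc_phasor = 1,
                          quantity = "current")
}
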