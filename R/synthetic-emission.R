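#' Phenomenological microbubble emission model
#'
#' Describes when the sub-harmonic (0.5 f0) and ultra-harmonic (1.5 f0)
#' microbubble emission tones appear as the applied acoustic pressure rises.
#' The model is deliberately phenomenological: it stands in for hydrophone
#' recordings by injecting narrowband tones onto a noise floor once the
#' respective onset pressure is reached, without simulating bubble dynamics.
#'
#' @param onset_pressure_uh pressure (MPa) at or above which the ultra-harmonic
#'   tone at 1.5 f0 appears.
#' @param onset_pressure_sh pressure (MPa) at or above which the sub-harmonic
#'   tone at 0.5 f0 appears.
#' @param tone_level_db height of an injected tone above the noise floor, in
#'   dB (amplitude convention, i.e. a factor of `10^(dB/20)`).
#' @param noise_floor baseline spectral magnitude (arbitrary linear units).
#' @param seed integer seed; identical seeds reproduce identical spectra
#'   bit-for-bit.
#' @return an object of class `emission_model`.
#' @seealso [make_emission_spectrum()], [run_controller()]
#' @export
#' @examples
#' m <- emission_model(onset_pressure_uh = 0.36)
#' sp <- make_emission_spectrum(0.4, m)
emission_model <- function(onset_pressure_uh = 0.36,
                           onset_pressure_sh = Inf,
                           tone_level_db = 10,
                           noise_floor = 1,
                           seed = 1L) {
  stop_if_not_number(onset_pressure_uh, "onset_pressure_uh", 0, allow_zero = FALSE)
  if (!identical(onset_pressure_sh, Inf)) {
    stop_if_not_number(onset_pressure_sh, "onset_pressure_sh", 0, allow_zero = FALSE)
  }
  stop_if_not_number(tone_level_db, "tone_level_db", 0, allow_zero = FALSE)
  stop_if_not_number(noise_floor, "noise_floor", 0, allow_zero = FALSE)
  structure(
    list(onset_pressure_uh = onset_pressure_uh,
         onset_pressure_sh = onset_pressure_sh,
         tone_level_db = tone_level_db,
         noise_floor = noise_floor,
         seed = as.integer(seed)),
    class = "emission_model"
  )
}

#' Synthesise a one-burst emission spectrum
#'
#' Builds the magnitude spectrum recorded during one ultrasound burst at a
#' given applied pressure. The spectrum is a noise floor with mild log-normal
#' ripple; when `pressure` reaches the model's sub- or ultra-harmonic onset,
#' the bin nearest 0.5 f0 or 1.5 f0 is set to
#' `noise_floor * 10^(tone_level_db / 20)`.
#'
#' @param pressure applied peak-negative pressure (MPa), non-negative.
#' @param model an [emission_model()].
#' @param f0 transducer centre frequency (MHz).
#' @param n_bins number of frequency bins; must resolve the harmonic bands.
#' @param burst_index 0-based burst counter; together with the model seed it
#'   makes each burst's ripple reproducible.
#' @return an `emission_spectrum`: list with `frequency` (MHz), `magnitude`
#'   (linear units) and `f0`.
#' @export
make_emission_spectrum <- function(pressure, model, f0 = 1.68,
                                   n_bins = 2048L, burst_index = 0L) {
  if (!inherits(model, "emission_model")) {
    stop("`model` must be an emission_model", call. = FALSE)
  }
  stop_if_not_number(pressure, "pressure", 0)
  stop_if_not_number(f0, "f0", 0, allow_zero = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 64L) stop("`n_bins` too small to resolve harmonic bands", call. = FALSE)
  fmax <- 2.5 * f0
  freq <- seq(0, fmax, length.out = n_bins)
  if (1.5 * f0 >= fmax) stop("`f0` outside spectral range", call. = FALSE)

  mag <- with_seed(combine_seed(model$seed, burst_index), {
    model$noise_floor * exp(stats::rnorm(n_bins, 0, 0.05))
  })
  tone <- model$noise_floor * 10^(model$tone_level_db / 20)
  if (pressure >= model$onset_pressure_sh) {
    mag[which.min(abs(freq - 0.5 * f0))] <- tone
  }
  if (pressure >= model$onset_pressure_uh) {
    mag[which.min(abs(freq - 1.5 * f0))] <- tone
  }
  structure(list(frequency = freq, magnitude = mag, f0 = f0),
            class = "emission_spectrum")
}
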