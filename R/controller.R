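#' Sonication and feedback-controller configuration
#'
#' All constants of the acoustic-emission feedback controller: a 1.68 MHz
#' transducer firing 10 ms bursts at 1 Hz for 2 minutes, ramping the applied
#' pressure from 0.2 MPa in 0.02 MPa steps (one step per burst) until a
#' harmonic emission is detected, then dropping to 25% of the peak pressure
#' for the remainder of the sonication. Also carries the derating constants
#' (skull insertion loss and brain-tissue attenuation) and the spectral
#' detector settings.
#'
#' @param f0 centre frequency (MHz).
#' @param burst_length burst duration (s).
#' @param prf pulse repetition frequency (Hz).
#' @param duration total sonication time (s); `duration * prf` must be a
#'   whole number of bursts.
#' @param start_pressure ramp starting pressure (MPa).
#' @param step ramp increment per burst (MPa).
#' @param drop_fraction fraction of peak pressure applied after detection.
#' @param insertion_loss fractional pressure loss through the skull.
#' @param tissue_attenuation brain attenuation coefficient (Np/m/MHz).
#' @param tissue_depth depth of the focus in tissue (m).
#' @param detect_band_halfwidth half-width of each harmonic detection band (MHz).
#' @param detect_threshold_db detection threshold above the noise floor (dB,
#'   amplitude convention). The real-time detector's original threshold is
#'   not published; 6 dB is this package's declared default.
#' @param trigger_mode `"ultra_only"` drops pressure on the ultra-harmonic
#'   alone (sub-harmonic detections are still recorded); `"sub_or_ultra"`
#'   triggers on either.
#' @return an object of class `sonication_config`.
#' @export
sonication_config <- function(f0 = 1.68,
                              burst_length = 0.010,
                              prf = 1,
                              duration = 120,
                              start_pressure = 0.2,
                              step = 0.02,
                              drop_fraction = 0.25,
                              insertion_loss = 0.18,
                              tissue_attenuation = 5,
                              tissue_depth = 0.0025,
                              detect_band_halfwidth = 0.04,
                              detect_threshold_db = 6,
                              trigger_mode = c("ultra_only", "sub_or_ultra")) {
  trigger_mode <- match.arg(trigger_mode)
  stop_if_not_number(step, "step", 0, allow_zero = FALSE)
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop("`drop_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (insertion_loss < 0 || insertion_loss >= 1) {
    stop("`insertion_loss` must be in [0, 1)", call. = FALSE)
  }
  n_bursts <- duration * prf
  if (abs(n_bursts - round(n_bursts)) > 1e-9) {
    stop("`duration * prf` must be an integer number of bursts", call. = FALSE)
  }
  structure(
    list(f0 = f0, burst_length = burst_length, prf = prf, duration = duration,
         start_pressure = start_pressure, step = step,
         drop_fraction = drop_fraction, insertion_loss = insertion_loss,
         tissue_attenuation = tissue_attenuation, tissue_depth = tissue_depth,
         detect_band_halfwidth = detect_band_halfwidth,
         detect_threshold_db = detect_threshold_db,
         trigger_mode = trigger_mode,
         n_bursts = as.integer(round(n_bursts))),
    class = "sonication_config"
  )
}

#' Derate source pressure to in-situ pressure
#'
#' Scales the transducer source pressure by the skull insertion loss and by
#' exponential attenuation through brain tissue,
#' `p * (1 - insertion_loss) * exp(-attenuation * f0 * depth)` with the
#' attenuation in Np/m/MHz, `f0` in MHz and depth in metres. With the default
#' constants (18% loss, 5 Np/m/MHz, 1.68 MHz, 2.5 mm) the derating factor is
#' about 0.803.
#'
#' @param source_pressure source pressure (MPa), non-negative (vectorised).
#' @param config a [sonication_config()].
#' @return in-situ pressure (MPa).
#' @export
#' @examples
#' derate_pressure(1.0, sonication_config())
derate_pressure <- function(source_pressure, config = sonication_config()) {
  if (any(!is.finite(source_pressure)) || any(source_pressure < 0)) {
    stop("`source_pressure` must be non-negative", call. = FALSE)
  }
  factor <- (1 - config$insertion_loss) *
    exp(-config$tissue_attenuation * config$f0 * config$tissue_depth)
  source_pressure * factor
}

#' Detect sub- and ultra-harmonic tones in an emission spectrum
#'
#' Band power is the maximum magnitude within `detect_band_halfwidth` of
#' 0.5 f0 (sub-harmonic) and 1.5 f0 (ultra-harmonic). The noise floor is the
#' median magnitude outside all harmonic bands (0.5, 1, 1.5 and 2 x f0). A
#' tone is detected when its band power reaches
#' `noise_floor * 10^(detect_threshold_db / 20)`.
#'
#' @param spectrum an `emission_spectrum` (see [make_emission_spectrum()]) or
#'   a list with numeric `frequency` (MHz) and `magnitude`.
#' @param config a [sonication_config()].
#' @return list of class `harmonic_detection` with `sub_detected`,
#'   `ultra_detected`, `band_power_sub`, `band_power_ultra`, `noise_floor`.
#' @export
detect_harmonics <- function(spectrum, config = sonication_config()) {
  freq <- spectrum$frequency
  mag <- spectrum$magnitude
  stopifnot(length(freq) == length(mag))
  f0 <- config$f0
  hw <- config$detect_band_halfwidth
  if (min(freq) > 0.5 * f0 - hw || max(freq) < 1.5 * f0 + hw) {
    stop("spectrum does not cover the sub/ultra-harmonic bands", call. = FALSE)
  }
  in_band <- function(target) abs(freq - target) <= hw
  sub_band <- in_band(0.5 * f0)
  ultra_band <- in_band(1.5 * f0)
  if (!any(sub_band) || !any(ultra_band)) {
    stop("frequency grid too coarse for the detection bands", call. = FALSE)
  }
  harmonic <- in_band(0.5 * f0) | in_band(1.0 * f0) |
    in_band(1.5 * f0) | in_band(2.0 * f0)
  noise_floor <- stats::median(mag[!harmonic])
  thr <- noise_floor * 10^(config$detect_threshold_db / 20)
  bp_sub <- max(mag[sub_band])
  bp_ultra <- max(mag[ultra_band])
  structure(
    list(sub_detected = bp_sub >= thr,
         ultra_detected = bp_ultra >= thr,
         band_power_sub = bp_sub,
         band_power_ultra = bp_ultra,
         noise_floor = noise_floor),
    class = "harmonic_detection"
  )
}

#' Run the feedback pressure controller for one focal spot
#'
#' Simulates the per-burst control loop: the applied pressure starts at
#' `start_pressure` and increases by `step` each burst; each burst's emission
#' spectrum is checked for harmonic tones, and on the first detection (per
#' `trigger_mode`) the detecting burst's pressure is recorded as the peak and
#' every subsequent burst runs at `drop_fraction * peak`. If nothing is
#' detected over the full sonication the trace is the complete monotone ramp,
#' flagged `no_detection`.
#'
#' @param emission_model an [emission_model()].
#' @param config a [sonication_config()].
#' @param focus_id identifier carried into the trace.
#' @param n_bins spectral bins per burst.
#' @return a `pressure_trace`: list with `pressure` (MPa, one per burst),
#'   `burst_index` (0-based), `phase` (`"ramp"`/`"plateau"`),
#'   `detection_burst` (0-based index or `NA`), `peak_pressure`,
#'   `plateau_pressure` (`NA` if no detection), `no_detection`, `focus_id`.
#' @export
#' @examples
#' tr <- run_controller(emission_model(onset_pressure_uh = 0.36))
#' tr$plateau_pressure / tr$peak_pressure  # 0.25
run_controller <- function(emission_model, config = sonication_config(),
                           focus_id = "f1", n_bins = 2048L) {
  if (!inherits(emission_model, "emission_model")) {
    stop("`emission_model` must be an emission_model", call. = FALSE)
  }
  n <- config$n_bursts
  pressure <- numeric(n)
  phase <- rep("ramp", n)
  detection_burst <- NA_integer_
  peak <- NA_real_
  plateau <- NA_real_
  for (k in 0:(n - 1L)) {
    p <- if (is.na(detection_burst)) {
      config$start_pressure + k * config$step
    } else {
      plateau
    }
    pressure[k + 1L] <- p
    if (!is.na(detection_burst)) {
      phase[k + 1L] <- "plateau"
      next
    }
    sp <- make_emission_spectrum(p, emission_model, f0 = config$f0,
                                 n_bins = n_bins, burst_index = k)
    det <- detect_harmonics(sp, config)
    triggered <- switch(config$trigger_mode,
                        ultra_only = det$ultra_detected,
                        sub_or_ultra = det$sub_detected || det$ultra_detected)
    if (triggered) {
      detection_burst <- k
      peak <- p
      plateau <- config$drop_fraction * peak
    }
  }
  if (is.na(detection_burst)) peak <- pressure[n]
  structure(
    list(pressure = pressure,
         burst_index = 0:(n - 1L),
         phase = phase,
         detection_burst = detection_burst,
         peak_pressure = peak,
         plateau_pressure = plateau,
         no_detection = is.na(detection_burst),
         focus_id = focus_id),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat("<pressure_trace>", x$focus_id, "-", length(x$pressure), "bursts\n")
  if (x$no_detection) {
    cat("  no harmonic detection; full ramp to", x$peak_pressure, "MPa\n")
  } else {
    cat(sprintf("  detection at burst %d: peak %.3f MPa, plateau %.3f MPa\n",
                x$detection_burst, x$peak_pressure, x$plateau_pressure))
  }
  invisible(x)
}

#' Tabulate peak pressures across foci
#'
#' Collects the recorded peak pressure of each focal spot's trace into a
#' long-format table joined to the experimental design, ready for
#' [two_way_anova()] / [tukey_hsd()]. Traces without a harmonic detection
#' carry no peak threshold and are dropped with a warning.
#'
#' @param traces list of `pressure_trace` objects.
#' @param design data frame with one row per trace: columns `mouse`, `focus`,
#'   `genotype`, `treatment` (recycled in order of `traces`).
#' @param derated if `TRUE`, report in-situ pressures via [derate_pressure()].
#' @param config used for derating.
#' @return data frame `mouse, focus, genotype, treatment, value` (peak MPa).
#' @export
summarize_peaks <- function(traces, design, derated = FALSE,
                            config = sonication_config()) {
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  stopifnot(is.data.frame(design), nrow(design) == length(traces))
  keep <- !vapply(traces, `[[`, logical(1), "no_detection")
  if (!all(keep)) {
    warning(sum(!keep), " trace(s) without harmonic detection excluded",
            call. = FALSE)
  }
  if (!any(keep)) stop("no detecting traces to summarise", call. = FALSE)
  peaks <- vapply(traces[keep], `[[`, numeric(1), "peak_pressure")
  if (derated) peaks <- derate_pressure(peaks, config)
  out <- design[keep, c("mouse", "focus", "genotype", "treatment"), drop = FALSE]
  out$value <- peaks
  rownames(out) <- NULL
  out
}
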