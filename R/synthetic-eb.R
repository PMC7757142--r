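#' Generate Evans-blue calibration standards
#'
#' Simulates fluorescent detection of known Evans-blue quantities spotted on
#' filter paper: average radiance is linear in `log10(ng)` up to an optional
#' saturation quantity, above which the detector response flattens (creating
#' the non-linear top portion that a standard-curve fit must exclude).
#'
#' @param slope radiance increase per decade of dye quantity.
#' @param intercept radiance at 1 ng.
#' @param ng_levels positive, strictly ascending dye quantities (ng).
#' @param noise_sd additive radiance noise standard deviation.
#' @param saturation_ng quantity above which the response saturates
#'   (`Inf` for none).
#' @param seed integer seed.
#' @return data frame with columns `ng` and `radiance`, of class
#'   `eb_standards`.
#' @seealso [fit_semilog()]
#' @export
#' @examples
#' std <- generate_eb_standards(noise_sd = 0)
#' fit_semilog(std)
generate_eb_standards <- function(slope = 100, intercept = 5,
                                  ng_levels = c(5, 10, 20, 40, 80, 160, 320, 640),
                                  noise_sd = 0, saturation_ng = Inf,
                                  seed = 1L) {
  if (any(ng_levels <= 0)) stop("`ng_levels` must be positive", call. = FALSE)
  if (is.unsorted(ng_levels, strictly = TRUE)) {
    stop("`ng_levels` must be strictly ascending", call. = FALSE)
  }
  stop_if_not_number(noise_sd, "noise_sd", 0)
  eff_ng <- pmin(ng_levels, saturation_ng)
  radiance <- slope * log10(eff_ng) + intercept
  if (noise_sd > 0) {
    radiance <- radiance +
      with_seed(combine_seed(seed, 2L), stats::rnorm(length(ng_levels), 0, noise_sd))
  }
  structure(data.frame(ng = ng_levels, radiance = radiance),
            class = c("eb_standards", "data.frame"))
}

#' Generate peak-pressure samples for the four-group design
#'
#' Draws per-focus peak ultra-harmonic threshold pressures for the 2 x 2
#' genotype-by-treatment design. By default the TgCRND8-VT group mean sits
#' 25% below the common mean of the other three groups — inside the 21-29%
#' reduction band the threshold comparison is built around — with equal
#' within-group standard deviations.
#'
#' @param group_means named numeric vector of group mean pressures (MPa), one
#'   per group label (see [closure_fixture_table()] for the labels).
#' @param sd common within-group standard deviation (MPa), `>= 0`.
#' @param n_per_group foci per group, `>= 2`.
#' @param seed integer seed.
#' @return data frame with columns `value` (MPa), `genotype`, `treatment`,
#'   `mouse`, `focus`, suitable for [two_way_anova()] and [tukey_hsd()].
#' @export
generate_threshold_samples <- function(group_means = NULL, sd = 0.06,
                                       n_per_group = 24L, seed = 1L) {
  if (is.null(group_means)) {
    base <- 0.44
    group_means <- c("nonTg-PBS" = base, "nonTg-VT" = base,
                     "TgCRND8-PBS" = base, "TgCRND8-VT" = 0.75 * base)
  }
  if (is.null(names(group_means)) ||
      !setequal(names(group_means), .group_labels)) {
    stop("`group_means` must be named with the four group labels", call. = FALSE)
  }
  stop_if_not_number(sd, "sd", 0)
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("`n_per_group` must be >= 2", call. = FALSE)

  values <- with_seed(combine_seed(seed, 3L), {
    unlist(lapply(.group_labels, function(g) {
      stats::rnorm(n_per_group, group_means[[g]], sd)
    }))
  })
  parts <- strsplit(rep(.group_labels, each = n_per_group), "-", fixed = TRUE)
  data.frame(
    value = values,
    genotype = vapply(parts, `[`, "", 1L),
    treatment = vapply(parts, `[`, "", 2L),
    mouse = rep(paste0("m", rep(1:6, each = ceiling(n_per_group / 6))[seq_len(n_per_group)]),
                times = 4L),
    focus = rep(seq_len(n_per_group), times = 4L),
    stringsAsFactors = FALSE
  )
}
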