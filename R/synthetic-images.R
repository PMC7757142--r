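#' Specification for a synthetic enhancement image series
#'
#' Describes one mouse's contrast-enhanced image series: a 2D axial slice
#' (default 96 x 96 voxels) split into a sonicated and a contralateral
#' hemisphere, with up to four Gaussian focal enhancement spots in the
#' sonicated hemisphere. Each focus carries a programmed closure time;
#' at every assessment timepoint at or after that time the focus renders as
#' background plus noise only (a step to background, matching an
#' observation schedule that samples closure only at 6/12/20 h).
#'
#' @param shape integer vector, image dimensions (rows, columns).
#' @param boundary_col last column of the sonicated hemisphere; columns
#'   `1:boundary_col` are sonicated, the rest are contralateral control.
#' @param centers integer matrix (n_foci x 2) of focus centres `(row, col)`,
#'   1-based, all within the sonicated hemisphere.
#' @param amplitude peak enhancement above background (intensity units).
#' @param sigma Gaussian width of a focal spot (voxels).
#' @param background baseline tissue intensity.
#' @param noise_sd additive Gaussian noise standard deviation. Openings are
#'   reliably detectable when `amplitude > 2 * noise_sd`; smaller amplitudes
#'   are allowed (e.g. to model failed openings) but trip a warning.
#' @param closure_times numeric vector, one per focus: hours at which the
#'   barrier reseals, in `(0, 20]`, or `Inf` for a focus still open at 20 h.
#' @param timepoints assessment times in hours.
#' @return an object of class `image_gen_spec`.
#' @export
image_gen_spec <- function(shape = c(96L, 96L),
                           boundary_col = 48L,
                           centers = default_focus_centers(),
                           amplitude = 100,
                           sigma = 2.5,
                           background = 100,
                           noise_sd = 10,
                           closure_times = rep(Inf, nrow(centers)),
                           timepoints = c(0, 6, 12, 20)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 8L))
  boundary_col <- as.integer(boundary_col)
  if (boundary_col < 1L || boundary_col >= shape[2]) {
    stop("`boundary_col` must split the grid into two non-empty hemispheres",
         call. = FALSE)
  }
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || nrow(centers) < 1L) {
    stop("`centers` must be an n x 2 matrix of (row, col) indices", call. = FALSE)
  }
  if (any(centers[, 1] < 1) || any(centers[, 1] > shape[1]) ||
      any(centers[, 2] < 1) || any(centers[, 2] > shape[2])) {
    stop("focus centre outside the image grid", call. = FALSE)
  }
  if (any(centers[, 2] > boundary_col)) {
    stop("all focus centres must lie in the sonicated hemisphere", call. = FALSE)
  }
  stop_if_not_number(amplitude, "amplitude", 0)
  stop_if_not_number(sigma, "sigma", 0, allow_zero = FALSE)
  stop_if_not_number(noise_sd, "noise_sd", 0)
  if (length(closure_times) != nrow(centers)) {
    stop("`closure_times` must have one entry per focus", call. = FALSE)
  }
  if (any(closure_times <= 0)) {
    stop("closure times must be positive (Inf for still-open foci)", call. = FALSE)
  }
  if (amplitude <= 2 * noise_sd && amplitude > 0) {
    warning("amplitude <= 2 * noise_sd: openings may not be detectable",
            call. = FALSE)
  }
  structure(
    list(shape = shape, boundary_col = boundary_col, centers = centers,
         amplitude = amplitude, sigma = sigma, background = background,
         noise_sd = noise_sd, closure_times = as.numeric(closure_times),
         timepoints = as.numeric(timepoints)),
    class = "image_gen_spec"
  )
}

#' Default four-focus layout on a 96 x 96 slice
#'
#' Four well-separated targets in the sonicated (left) hemisphere, mirroring
#' a four-spot sonication grid with the contralateral hemisphere untouched.
#'
#' @return a 4 x 2 integer matrix of (row, col) centres.
#' @export
default_focus_centers <- function() {
  cbind(row = c(24L, 24L, 72L, 72L), col = c(14L, 34L, 14L, 34L))
}

#' Generate one mouse's multi-timepoint image series
#'
#' Renders the image stack described by an [image_gen_spec()]: at time 0
#' every focus is a Gaussian bump of the specified amplitude on a noisy
#' background; at each later timepoint a focus whose closure time has passed
#' renders as background plus noise only, while an open focus keeps its full
#' amplitude. The contralateral hemisphere is never enhanced.
#'
#' @param spec an [image_gen_spec()].
#' @param seed integer seed; output is bit-reproducible.
#' @param mouse mouse identifier.
#' @param group group label carried through to downstream records.
#' @return an `image_series`: list with `images` (named list of matrices, one
#'   per timepoint), `hemisphere_mask` (logical matrix, `TRUE` = sonicated),
#'   `focus_coords` (as in the spec), `boundary_col`, `timepoints`, `mouse`,
#'   `group`, and the ground-truth `closure_times`.
#' @export
generate_image_series <- function(spec, seed = 1L, mouse = "m1",
                                  group = NA_character_) {
  if (!inherits(spec, "image_gen_spec")) {
    stop("`spec` must be an image_gen_spec", call. = FALSE)
  }
  nr <- spec$shape[1]; nc <- spec$shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  bump <- function(center) {
    spec$amplitude * exp(-((rows - center[1])^2 + (cols - center[2])^2) /
                           (2 * spec$sigma^2))
  }
  bumps <- lapply(seq_len(nrow(spec$centers)),
                  function(i) bump(spec$centers[i, ]))

  images <- with_seed(combine_seed(seed, 0L), {
    out <- vector("list", length(spec$timepoints))
    names(out) <- as.character(spec$timepoints)
    for (ti in seq_along(spec$timepoints)) {
      t <- spec$timepoints[ti]
      img <- matrix(spec$background, nr, nc) +
        matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      for (fi in seq_along(bumps)) {
        open <- t < spec$closure_times[fi]
        if (open) img <- img + bumps[[fi]]
      }
      out[[ti]] <- img
    }
    out
  })

  mask <- cols <= spec$boundary_col
  structure(
    list(images = images,
         hemisphere_mask = mask,
         focus_coords = spec$centers,
         boundary_col = spec$boundary_col,
         timepoints = spec$timepoints,
         mouse = mouse,
         group = group,
         closure_times = spec$closure_times),
    class = "image_series"
  )
}

#' Simulate image series for a whole experimental group
#'
#' Expands a group closure fixture into per-focus closure times, distributes
#' the foci over mice (four per mouse, the remainder on the last mouse) and
#' generates one [generate_image_series()] stack per mouse.
#'
#' @param fixture a [generate_group_fixture()] row, or a group label.
#' @param seed integer seed.
#' @param noise_sd,amplitude image noise and enhancement amplitude passed to
#'   [image_gen_spec()] (default 10:1 amplitude-to-noise).
#' @param ... further arguments forwarded to [image_gen_spec()].
#' @return list of `image_series`, one per mouse, each carrying its
#'   ground-truth closure times.
#' @export
#' @examples
#' series <- simulate_group_images("TgCRND8-VT", seed = 17)
#' length(series)
simulate_group_images <- function(fixture, seed = 1L,
                                  noise_sd = 10, amplitude = 100, ...) {
  if (is.character(fixture)) fixture <- generate_group_fixture(fixture)
  stopifnot(is.data.frame(fixture), nrow(fixture) == 1L)
  ## representative closure hours inside each interval; Inf = censored
  times <- rep(c(3, 9, 15, Inf),
               times = c(fixture$closed_by_6h, fixture$closed_6_12h,
                         fixture$closed_12_20h, fixture$permeable_20h))
  times <- with_seed(combine_seed(seed, 1L), sample(times))
  n <- length(times)
  n_mice <- ceiling(n / 4)
  centers <- default_focus_centers()
  out <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    idx <- ((m - 1) * 4 + 1):min(m * 4, n)
    spec <- image_gen_spec(centers = centers[seq_along(idx), , drop = FALSE],
                           closure_times = times[idx],
                           noise_sd = noise_sd, amplitude = amplitude, ...)
    out[[m]] <- generate_image_series(spec, seed = combine_seed(seed, m + 1L),
                                      mouse = sprintf("%s-m%02d", fixture$group, m),
                                      group = fixture$group)
  }
  out
}
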