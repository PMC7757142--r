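## Gadolinium-enhancement quantification and the 2-SD closure classifier.

## Extract the 2D slice holding a coordinate; images may be 2D matrices or 3D
## arrays (the ROI is 3x3 in-plane; the third index picks the slice).
.get_slice <- function(image, coord) {
  d <- dim(image)
  if (length(d) == 2L) {
    list(slice = image, rc = coord[1:2])
  } else if (length(d) == 3L) {
    if (length(coord) < 3L) stop("3D image needs a (row, col, slice) coordinate",
                                 call. = FALSE)
    if (coord[3] < 1 || coord[3] > d[3]) stop("coordinate outside grid", call. = FALSE)
    list(slice = image[, , coord[3]], rc = coord[1:2])
  } else {
    stop("`image` must be a 2D matrix or 3D array", call. = FALSE)
  }
}

#' Mean intensity of the 3x3 region of interest around a voxel
#'
#' Arithmetic mean of the 3x3 in-plane neighbourhood centred on `coord`
#' (1-based `(row, col)` or `(row, col, slice)`). Neighbourhoods are clipped
#' at image edges: the mean runs over the in-bounds voxels only.
#'
#' @param image 2D matrix or 3D array of intensities.
#' @param coord integer coordinate of the ROI centre.
#' @return mean ROI intensity.
#' @export
#' @examples
#' roi_mean(matrix(1:9, 3, 3, byrow = TRUE), c(2, 2))  # 5
roi_mean <- function(image, coord) {
  g <- .get_slice(image, coord)
  d <- dim(g$slice)
  r <- g$rc[1]; c <- g$rc[2]
  if (r < 1 || r > d[1] || c < 1 || c > d[2]) {
    stop("coordinate outside grid", call. = FALSE)
  }
  rows <- max(1, r - 1):min(d[1], r + 1)
  cols <- max(1, c - 1):min(d[2], c + 1)
  mean(g$slice[rows, cols])
}

#' Mean and SD of the unenhanced (contralateral) hemisphere
#'
#' @param image 2D matrix (or 3D array, pooled over all slices).
#' @param hemisphere_mask logical array of the same shape, `TRUE` for the
#'   sonicated hemisphere; statistics are computed over the complement.
#' @return list with `mean` and `sd` (sample SD, n-1 denominator).
#' @export
contralateral_stats <- function(image, hemisphere_mask) {
  if (!identical(dim(image), dim(hemisphere_mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  vox <- image[!hemisphere_mask]
  if (length(vox) < 9L) {
    stop("contralateral region must contain at least 9 voxels", call. = FALSE)
  }
  list(mean = mean(vox), sd = stats::sd(vox))
}

#' Classify a focus as permeable or closed (2-SD rule)
#'
#' A focus is closed when its ROI mean falls below the contralateral mean
#' plus two contralateral standard deviations; a focus exactly at the
#' boundary is classified permeable (conservative toward continued
#' permeability).
#'
#' @param roi_mean focus ROI mean intensity.
#' @param contra_mean,contra_sd contralateral-hemisphere statistics
#'   (`contra_sd >= 0`).
#' @return `TRUE` if permeable, `FALSE` if closed (vectorised).
#' @export
classify_closure <- function(roi_mean, contra_mean, contra_sd) {
  if (any(contra_sd < 0)) stop("`contra_sd` must be >= 0", call. = FALSE)
  roi_mean >= contra_mean + 2 * contra_sd
}

#' Locate focal spots as local maxima of the time-0 image
#'
#' Finds the `n_foci` strongest strict local maxima (8-neighbourhood) of the
#' enhancement image within the sonicated hemisphere, selected greedily in
#' decreasing intensity with an exclusion radius so one enhancement bump is
#' never picked twice.
#'
#' @param image_t0 2D matrix acquired immediately after sonication.
#' @param hemisphere_mask logical matrix, `TRUE` = sonicated hemisphere.
#' @param n_foci number of foci to locate.
#' @param exclusion_radius minimum distance (voxels) between selected foci.
#' @return integer matrix (`n_foci` x 2) of `(row, col)` coordinates, in
#'   decreasing order of peak intensity.
#' @export
locate_peak_enhancement <- function(image_t0, hemisphere_mask, n_foci,
                                    exclusion_radius = 8) {
  if (!identical(dim(image_t0), dim(hemisphere_mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  n_foci <- as.integer(n_foci)
  if (n_foci < 1L) stop("`n_foci` must be >= 1", call. = FALSE)
  d <- dim(image_t0)
  ## strict local maxima over the 8-neighbourhood, computed by shifting
  pad <- matrix(-Inf, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- image_t0
  is_max <- matrix(TRUE, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(d[1] + 1 + dr), (2 + dc):(d[2] + 1 + dc)]
    is_max <- is_max & (image_t0 > nb)
  }
  is_max <- is_max & hemisphere_mask
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("found 0 distinct local maxima (need ", n_foci, ")", call. = FALSE)
  }
  ord <- order(image_t0[is_max], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  picked <- matrix(NA_integer_, 0, 2)
  for (i in seq_len(nrow(idx))) {
    if (nrow(picked) == 0L ||
        all(sqrt((picked[, 1] - idx[i, 1])^2 +
                 (picked[, 2] - idx[i, 2])^2) >= exclusion_radius)) {
      picked <- rbind(picked, idx[i, , drop = FALSE])
      if (nrow(picked) == n_foci) break
    }
  }
  if (nrow(picked) < n_foci) {
    stop("found ", nrow(picked), " distinct local maxima (need ", n_foci, ")",
         call. = FALSE)
  }
  colnames(picked) <- c("row", "col")
  rownames(picked) <- NULL
  picked
}

#' Enhancement ratio between hemispheres
#'
#' Per-focus ratio of the 3x3 ROI mean to the contralateral-hemisphere mean
#' of the same image — the initial-enhancement readout of the factorial
#' comparison.
#'
#' @param image 2D matrix (typically the time-0 image).
#' @param focus_coords matrix of `(row, col)` coordinates, one row per focus.
#' @param hemisphere_mask logical matrix, `TRUE` = sonicated hemisphere.
#' @return numeric vector of ratios, one per focus.
#' @export
enhancement_ratio <- function(image, focus_coords, hemisphere_mask) {
  cs <- contralateral_stats(image, hemisphere_mask)
  if (cs$mean <= 0) {
    stop("contralateral mean must be positive for a ratio", call. = FALSE)
  }
  focus_coords <- as.matrix(focus_coords)
  apply(focus_coords, 1L, function(co) roi_mean(image, co)) / cs$mean
}

#' Quantify enhancement for a whole image series
#'
#' Locates the focal spots on the time-0 image (or reuses supplied
#' coordinates) and quantifies every focus at every timepoint with the same
#' coordinates — follow-up images are never re-localised. Each record carries
#' the ROI mean, contralateral statistics of that timepoint's image, and the
#' 2-SD permeable/closed classification. A focus that is classified closed
#' and later permeable again is still re-measured; re-openings are surfaced
#' by [build_closure_table()].
#'
#' @param series an `image_series` (see [generate_image_series()]).
#' @param coords optional focus coordinates; default locates them on the
#'   time-0 image via [locate_peak_enhancement()].
#' @param contra `"hemisphere"` compares each focus with whole
#'   contralateral-hemisphere statistics (default); `"mirrored"` with the
#'   3x3 ROI mirrored across the hemisphere boundary.
#' @return data frame of class `enhancement_records` with columns `mouse`,
#'   `group`, `focus`, `timepoint_h`, `roi_mean`, `contra_mean`, `contra_sd`,
#'   `permeable`.
#' @export
quantify_series <- function(series, coords = NULL,
                            contra = c("hemisphere", "mirrored")) {
  contra <- match.arg(contra)
  if (!inherits(series, "image_series")) {
    stop("`series` must be an image_series", call. = FALSE)
  }
  if (is.null(coords)) {
    coords <- locate_peak_enhancement(series$images[[1]],
                                      series$hemisphere_mask,
                                      n_foci = nrow(series$focus_coords))
  }
  coords <- as.matrix(coords)
  n_foci <- nrow(coords)
  recs <- vector("list", length(series$timepoints) * n_foci)
  i <- 0L
  for (ti in seq_along(series$timepoints)) {
    img <- series$images[[ti]]
    if (contra == "hemisphere") {
      cs <- contralateral_stats(img, series$hemisphere_mask)
    }
    for (fi in seq_len(n_foci)) {
      if (contra == "mirrored") {
        mc <- coords[fi, ]
        mc[2] <- 2L * series$boundary_col + 1L - mc[2]
        d <- dim(img)
        rows <- max(1, mc[1] - 1):min(d[1], mc[1] + 1)
        cols <- max(1, mc[2] - 1):min(d[2], mc[2] + 1)
        vox <- img[rows, cols]
        cs <- list(mean = mean(vox), sd = stats::sd(vox))
      }
      rm_ <- roi_mean(img, coords[fi, ])
      i <- i + 1L
      recs[[i]] <- data.frame(
        mouse = series$mouse, group = series$group, focus = fi,
        timepoint_h = series$timepoints[ti],
        roi_mean = rm_, contra_mean = cs$mean, contra_sd = cs$sd,
        permeable = classify_closure(rm_, cs$mean, cs$sd),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, recs)
  class(out) <- c("enhancement_records", "data.frame")
  out
}

#' Quantify every mouse of a simulated group
#'
#' Convenience wrapper running [quantify_series()] over a list of series
#' (e.g. from [simulate_group_images()]) and row-binding the records.
#'
#' @param series_list list of `image_series`.
#' @param ... forwarded to [quantify_series()].
#' @return combined `enhancement_records` data frame.
#' @export
quantify_group <- function(series_list, ...) {
  out <- do.call(rbind, lapply(series_list, quantify_series, ...))
  class(out) <- c("enhancement_records", "data.frame")
  out
}
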