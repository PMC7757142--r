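## On-disk interchange: NIfTI image stacks with a JSON sidecar, CSV tables.

#' Write an image series to disk
#'
#' Stores the timepoint images as a single NIfTI volume (one slice per
#' timepoint) next to a JSON sidecar holding the acquisition metadata:
#' timepoints, focus coordinates (serialized 0-based for interoperability
#' with array-indexed tooling), hemisphere boundary column (0-based), mouse
#' and group labels, and the ground-truth closure times when present.
#'
#' @param series an `image_series`.
#' @param path output stem; writes `<path>.nii.gz` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  vol <- simplify2array(series$images)
  RNifti::writeNifti(RNifti::asNifti(vol), paste0(path, ".nii.gz"))
  meta <- list(
    timepoints_h = series$timepoints,
    focus_coords_0based = unname(series$focus_coords) - 1L,
    boundary_col_0based = series$boundary_col - 1L,
    mouse = series$mouse,
    group = series$group,
    closure_times_h = series$closure_times
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image series written by [write_image_series()]
#'
#' @param path stem used when writing.
#' @return an `image_series`.
#' @export
read_image_series <- function(path) {
  vol <- as.array(RNifti::readNifti(paste0(path, ".nii.gz")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tps <- as.numeric(meta$timepoints_h)
  images <- lapply(seq_along(tps), function(i) vol[, , i])
  names(images) <- as.character(tps)
  boundary <- as.integer(meta$boundary_col_0based) + 1L
  nc <- ncol(images[[1]])
  mask <- matrix(rep(seq_len(nc) <= boundary, each = nrow(images[[1]])),
                 nrow(images[[1]]), nc)
  coords <- matrix(as.integer(unlist(meta$focus_coords_0based)) + 1L,
                   ncol = 2L, byrow = is.null(dim(meta$focus_coords_0based)))
  if (!is.null(dim(meta$focus_coords_0based))) {
    coords <- as.matrix(meta$focus_coords_0based) + 1L
  }
  colnames(coords) <- c("row", "col")
  ct <- meta$closure_times_h
  ct <- if (is.null(ct)) rep(NA_real_, nrow(coords)) else as.numeric(ct)
  structure(
    list(images = images, hemisphere_mask = mask, focus_coords = coords,
         boundary_col = boundary, timepoints = tps,
         mouse = meta$mouse %||% NA_character_,
         group = meta$group %||% NA_character_,
         closure_times = ct),
    class = "image_series"
  )
}

#' Write a closure fixture, closure table, or records to CSV
#'
#' Thin wrapper over [utils::write.csv()] that drops row names, so fixture
#' and event tables round-trip cleanly.
#'
#' @param x data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_table_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
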