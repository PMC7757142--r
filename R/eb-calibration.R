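## Evans-blue semi-log standard curve and interpolation.

#' Fit the semi-log Evans-blue standard curve
#'
#' Ordinary least squares of radiance on `log10(ng)` over the linear portion
#' of the standard curve. When `linear_range` is not given, the fit selects
#' the contiguous span of at least four standards that maximises R-squared
#' (ties broken toward the longest span, then the lowest starting index) —
#' this automatically excludes a saturated top end of the curve.
#'
#' @param standards data frame with columns `ng` (positive, strictly
#'   ascending) and `radiance`; at least 4 rows.
#' @param linear_range optional integer vector `c(first, last)` of standard
#'   indices to fit (at least 4 points).
#' @return an `eb_calibration`: list with `slope` (radiance per decade),
#'   `intercept`, `r_squared`, `linear_range`, and the calibrated `ng_span`
#'   and `radiance_span`.
#' @export
#' @examples
#' std <- generate_eb_standards(slope = 100, intercept = 5, noise_sd = 0)
#' fit_semilog(std)
fit_semilog <- function(standards, linear_range = NULL) {
  stopifnot(is.data.frame(standards),
            all(c("ng", "radiance") %in% names(standards)))
  if (any(standards$ng <= 0)) stop("standard quantities must be positive",
                                   call. = FALSE)
  if (is.unsorted(standards$ng, strictly = TRUE)) {
    stop("standard quantities must be strictly ascending", call. = FALSE)
  }
  n <- nrow(standards)
  if (n < 4L) stop("need at least 4 usable standards, got ", n, call. = FALSE)
  lx <- log10(standards$ng)
  y <- standards$radiance

  r2_of <- function(i, j) {
    fit <- stats::lm(y[i:j] ~ lx[i:j])
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y[i:j] - mean(y[i:j]))^2)
    if (ss_tot == 0) return(list(r2 = 1, fit = fit))
    list(r2 = 1 - ss_res / ss_tot, fit = fit)
  }

  if (is.null(linear_range)) {
    best <- NULL
    for (i in 1:(n - 3L)) {
      for (j in (i + 3L):n) {
        cand <- r2_of(i, j)
        len <- j - i + 1L
        if (is.null(best) ||
            cand$r2 > best$r2 + 1e-12 ||
            (abs(cand$r2 - best$r2) <= 1e-12 &&
               (len > best$len || (len == best$len && i < best$i)))) {
          best <- list(r2 = cand$r2, fit = cand$fit, i = i, j = j, len = len)
        }
      }
    }
    linear_range <- c(best$i, best$j)
    fit <- best$fit
    r2 <- best$r2
  } else {
    linear_range <- as.integer(linear_range)
    if (length(linear_range) != 2L || linear_range[1] < 1L ||
        linear_range[2] > n || diff(linear_range) < 3L) {
      stop("`linear_range` must span at least 4 standards", call. = FALSE)
    }
    got <- r2_of(linear_range[1], linear_range[2])
    fit <- got$fit
    r2 <- got$r2
  }
  sel <- linear_range[1]:linear_range[2]
  co <- stats::coef(fit)
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2,
         linear_range = linear_range,
         ng_span = range(standards$ng[sel]),
         radiance_span = range(standards$radiance[sel])),
    class = "eb_calibration"
  )
}

#' @export
print.eb_calibration <- function(x, ...) {
  cat(sprintf(paste0("<eb_calibration> radiance = %.4g * log10(ng) + %.4g ",
                     "(R^2 = %.4f, standards %d-%d)\n"),
              x$slope, x$intercept, x$r_squared,
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Interpolate radiance to Evans-blue quantity
#'
#' Inverts the semi-log calibration: `ng = 10^((radiance - intercept) /
#' slope)`. Radiances outside the calibrated radiance span are still
#' converted but flagged as extrapolated (with a warning), since a brain
#' imaged immediately after sonication may exceed the top standard.
#'
#' @param radiance numeric vector of measured ROI radiances.
#' @param calibration an [fit_semilog()] result.
#' @return numeric vector of quantities (ng) with a logical attribute
#'   `extrapolated`.
#' @export
interpolate_ng <- function(radiance, calibration) {
  stopifnot(inherits(calibration, "eb_calibration"))
  if (calibration$slope == 0) stop("calibration slope is zero", call. = FALSE)
  ng <- 10^((radiance - calibration$intercept) / calibration$slope)
  extra <- radiance < min(calibration$radiance_span) |
    radiance > max(calibration$radiance_span)
  if (any(extra)) {
    warning(sum(extra), " radiance value(s) outside the calibrated span; ",
            "extrapolated", call. = FALSE)
  }
  attr(ng, "extrapolated") <- extra
  ng
}

#' Quantify Evans blue in measured regions of interest
#'
#' Converts each region's radiance to nanograms via [interpolate_ng()] and
#' totals them. Regions whose implied quantity falls below the lowest
#' calibrated standard are reported as below detection (0 ng, flagged).
#'
#' @param roi_radiances data frame with columns `region` and `radiance`
#'   (a bare numeric vector is also accepted).
#' @param calibration an [fit_semilog()] result.
#' @return list with `regions` (data frame: `region`, `radiance`, `ng`,
#'   `below_detection`, `extrapolated`) and `total_ng`.
#' @export
quantify_regions <- function(roi_radiances, calibration) {
  if (is.numeric(roi_radiances)) {
    roi_radiances <- data.frame(region = seq_along(roi_radiances),
                                radiance = roi_radiances)
  }
  stopifnot(is.data.frame(roi_radiances),
            "radiance" %in% names(roi_radiances))
  ng <- suppressWarnings(interpolate_ng(roi_radiances$radiance, calibration))
  below <- ng < min(calibration$ng_span)
  ng_rep <- ifelse(below, 0, as.numeric(ng))
  regions <- data.frame(
    region = roi_radiances$region %||% seq_len(nrow(roi_radiances)),
    radiance = roi_radiances$radiance,
    ng = ng_rep,
    below_detection = below,
    extrapolated = attr(ng, "extrapolated") & !below,
    stringsAsFactors = FALSE
  )
  list(regions = regions, total_ng = sum(ng_rep))
}
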