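## Canonical four-group closure fixtures.
##
## The study design crosses genotype (nonTg vs TgCRND8, an amyloid-precursor-
## protein transgenic with cerebral amyloid angiopathy) with treatment (PBS
## vehicle vs Vasculotide, an angiopoietin-1 mimetic). Per-focus closure
## counts are reconstructed so that, with 21-24 foci per group, the fraction
## of foci still permeable at 6/12/20 h rounds to the published integer
## percentages for each survival curve.

.group_labels <- c("nonTg-PBS", "nonTg-VT", "TgCRND8-PBS", "TgCRND8-VT")

.canonical_fixtures <- data.frame(
  group           = .group_labels,
  n_foci          = c(24L, 23L, 21L, 23L),
  closed_by_6h    = c(4L,  9L,  4L, 17L),
  closed_6_12h    = c(7L,  8L,  2L,  2L),
  closed_12_20h   = c(3L,  0L,  5L,  1L),
  permeable_20h   = c(10L, 6L, 10L,  3L),
  stringsAsFactors = FALSE
)

#' Closure fixture for one experimental group
#'
#' Returns the canonical per-group closure-count fixture: how many of the
#' group's focal spots closed within (0,6], (6,12] and (12,20] hours after
#' sonication, and how many were still permeable to gadolinium at 20 h.
#'
#' @param group_label one of `"nonTg-PBS"`, `"nonTg-VT"`, `"TgCRND8-PBS"`,
#'   `"TgCRND8-VT"`.
#' @return a one-row data frame of class `closure_fixture` with columns
#'   `group`, `n_foci`, `closed_by_6h`, `closed_6_12h`, `closed_12_20h`,
#'   `permeable_20h`.
#' @seealso [closure_fixture_table()], [simulate_group_images()]
#' @export
#' @examples
#' generate_group_fixture("TgCRND8-VT")
generate_group_fixture <- function(group_label) {
  if (!is.character(group_label) || length(group_label) != 1L ||
      !group_label %in% .group_labels) {
    stop("unknown group label; expected one of: ",
         paste(.group_labels, collapse = ", "), call. = FALSE)
  }
  out <- .canonical_fixtures[.canonical_fixtures$group == group_label, ,
                             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("closure_fixture", "data.frame")
  out
}

#' All four canonical group fixtures
#'
#' @return data frame with one row per group (see [generate_group_fixture()]).
#' @export
closure_fixture_table <- function() {
  out <- .canonical_fixtures
  class(out) <- c("closure_fixture", "data.frame")
  out
}

#' Percent of foci permeable implied by a fixture
#'
#' @param fixture a row from [generate_group_fixture()].
#' @return numeric vector of percent permeable at 0, 6, 12, 20 h.
#' @export
fixture_percent_permeable <- function(fixture) {
  stopifnot(is.data.frame(fixture), nrow(fixture) == 1L)
  closed <- cumsum(c(fixture$closed_by_6h, fixture$closed_6_12h,
                     fixture$closed_12_20h))
  perm <- c(fixture$n_foci, fixture$n_foci - closed)
  stats::setNames(100 * perm / fixture$n_foci, c("0", "6", "12", "20"))
}
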