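#' Equivalent-sphere conversions
#'
#' Tumour volumes are converted to the radius of the sphere of equal volume
#' (V = 4/3 pi r^3, 1 cc = 1 cm^3), giving a comparable one-dimensional size
#' measure: twice the radius is a lower bound on the tumour's maximum
#' diameter.
#'
#' @param radius_cm Sphere radius in cm, `>= 0`.
#' @return `sphere_volume()`: volume in cc; `sphere_radius()`: radius in cm.
#'   Both vectorised.
#' @export
#' @examples
#' sphere_volume(2)       # 33.51 cc, printed as 34 cc
#' sphere_radius(36.6)    # 2.06 cm, printed as 2.1 cm
sphere_volume <- function(radius_cm) {
  if (any(radius_cm < 0, na.rm = TRUE))
    abort_validation("radius must be non-negative")
  4 / 3 * pi * radius_cm^3
}

#' @rdname sphere_volume
#' @param volume_cc Volume in cc, `>= 0`.
#' @export
sphere_radius <- function(volume_cc) {
  if (any(volume_cc < 0, na.rm = TRUE))
    abort_validation("volume must be non-negative")
  (3 * volume_cc / (4 * pi))^(1 / 3)
}

#' Dichotomise a cohort by equivalent-sphere tumour volume
#'
#' Splits patients into a small-volume and a large-volume group at the
#' volume of a sphere with radius `r_cut_cm`: `small` if volume <
#' V(r_cut), `large` if volume >= V(r_cut) (the boundary case goes to the
#' large group; change `boundary` to `"small"` to flip). Patients flagged
#' as excluded (e.g. distant, distinct tumoural lesions that make a single
#' volume meaningless) belong to neither group.
#'
#' @param cohort A tibble with one row per patient.
#' @param r_cut_cm Cut radius in cm (default 2).
#' @param volume_col Name of the column holding the re-treatment GTV volume
#'   in cc (default `"gtv_rert_cc"`).
#' @param exclude_col Name of a logical column flagging patients excluded
#'   from the volume analysis (default `"distant_lesions"`; if absent no
#'   patient is excluded).
#' @param boundary Which group receives a volume exactly at the cut
#'   (`"large"`, the default, or `"small"`).
#' @return `cohort` with an added factor column `volume_group`
#'   (`"small"`/`"large"`, `NA` for excluded patients). Group sizes are
#'   attached as `attr(, "group_sizes")` and available via
#'   [dichotomy_sizes()].
#' @export
volume_dichotomy <- function(cohort, r_cut_cm = 2,
                             volume_col = "gtv_rert_cc",
                             exclude_col = "distant_lesions",
                             boundary = c("large", "small")) {
  boundary <- match.arg(boundary)
  if (!volume_col %in% names(cohort))
    abort_validation(sprintf("cohort has no volume column '%s'", volume_col))
  if (any(r_cut_cm <= 0)) abort_validation("cut radius must be > 0")
  vol <- cohort[[volume_col]]
  excl <- if (exclude_col %in% names(cohort)) cohort[[exclude_col]] else
    rep(FALSE, nrow(cohort))
  excl[is.na(excl)] <- FALSE
  if (any(is.na(vol) & !excl))
    abort_validation("missing tumour volume for non-excluded patient(s)")
  v_cut <- sphere_volume(r_cut_cm)
  big <- if (boundary == "large") vol >= v_cut else vol > v_cut
  grp <- factor(ifelse(big, "large", "small"), levels = c("small", "large"))
  grp[excl] <- NA
  out <- dplyr::mutate(cohort, volume_group = grp)
  attr(out, "group_sizes") <- c(small = sum(grp == "small", na.rm = TRUE),
                                large = sum(grp == "large", na.rm = TRUE),
                                excluded = sum(excl))
  out
}

#' @rdname volume_dichotomy
#' @param x Output of [volume_dichotomy()].
#' @export
dichotomy_sizes <- function(x) attr(x, "group_sizes")
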