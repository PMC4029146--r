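#' Dose-volume histograms
#'
#' A `dvh` is a tibble holding one structure's dose-volume histogram in
#' either cumulative or differential form, always with *relative* (fractional)
#' volumes. Cumulative form: one row per dose edge with the volume fraction
#' receiving at least that dose; `volume_fraction` starts at 1 and is
#' non-increasing. Differential form: one row per dose bin with columns
#' `dose_lo`, `dose_hi`, `dose_gy` (the bin midpoint, the representative dose
#' used in all dose sums) and the volume fraction in the bin; fractions sum
#' to the total cumulative volume (1 for a complete histogram).
#'
#' The absolute structure volume in cc is carried as metadata only
#' (`attr(x, "absolute_volume_cc")`); all dose metrics are volume-fraction
#' based.
#'
#' @param dose_gy Strictly increasing, non-negative dose edges in Gy
#'   (cumulative) starting at 0.
#' @param volume_fraction Volume fractions in `[0, 1]`, same length as
#'   `dose_gy`, non-increasing with `volume_fraction[1] == 1`.
#' @param structure Structure label, e.g. `"optic_chiasm"`.
#' @param absolute_volume_cc Optional absolute structure volume in cc.
#' @return A `dvh` tibble.
#' @export
#' @examples
#' dvh_cumulative(c(0, 20, 40, 60), c(1, 1, 0.5, 0), structure = "brainstem")
dvh_cumulative <- function(dose_gy, volume_fraction, structure = "structure",
                           absolute_volume_cc = NA_real_) {
  x <- tibble::tibble(dose_gy = as.numeric(dose_gy),
                      volume_fraction = as.numeric(volume_fraction))
  new_dvh(x, structure = structure, mode = "cumulative",
          absolute_volume_cc = absolute_volume_cc)
}

#' @rdname dvh_cumulative
#' @param dose_lo,dose_hi Bin edges in Gy (differential form); `dose_lo` must
#'   equal the previous bin's `dose_hi`.
#' @export
dvh_differential <- function(dose_lo, dose_hi, volume_fraction,
                             structure = "structure",
                             absolute_volume_cc = NA_real_) {
  x <- tibble::tibble(dose_lo = as.numeric(dose_lo),
                      dose_hi = as.numeric(dose_hi),
                      dose_gy = (as.numeric(dose_lo) + as.numeric(dose_hi)) / 2,
                      volume_fraction = as.numeric(volume_fraction))
  new_dvh(x, structure = structure, mode = "differential",
          absolute_volume_cc = absolute_volume_cc)
}

new_dvh <- function(x, structure, mode, absolute_volume_cc = NA_real_,
                    validate = TRUE) {
  out <- tibble::new_tibble(x, structure = structure, mode = mode,
                            absolute_volume_cc = absolute_volume_cc,
                            class = "dvh")
  if (validate) validate_dvh(out)
  out
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s (%s)%s\n", dvh_structure(x), dvh_mode(x),
              if (is.finite(dvh_absolute_volume(x)))
                sprintf(", %.2f cc", dvh_absolute_volume(x)) else ""))
  NextMethod()
}

#' DVH metadata accessors
#' @param x A `dvh`.
#' @return The structure label, mode string, or absolute volume in cc.
#' @export
dvh_structure <- function(x) attr(x, "structure")

#' @rdname dvh_structure
#' @export
dvh_mode <- function(x) attr(x, "mode")

#' @rdname dvh_structure
#' @export
dvh_absolute_volume <- function(x) attr(x, "absolute_volume_cc") %||% NA_real_

#' Validate DVH invariants
#'
#' Cumulative: `volume_fraction` in `[0, 1]`, starts at 1 (within 1e-9),
#' non-increasing over strictly increasing non-negative dose edges.
#' Differential: non-negative fractions over contiguous strictly increasing
#' bins. Errors name the first offending row.
#'
#' @param x A `dvh`.
#' @return `x`, invisibly, if valid.
#' @export
validate_dvh <- function(x) {
  mode <- dvh_mode(x)
  tol <- 1e-9
  if (identical(mode, "cumulative")) {
    d <- x$dose_gy
    v <- x$volume_fraction
    if (length(d) < 2L) abort_validation("cumulative DVH needs >= 2 dose edges")
    if (any(d < 0)) abort_validation("dose edges must be non-negative")
    if (any(diff(d) <= 0)) {
      i <- which(diff(d) <= 0)[1L]
      abort_validation(sprintf("dose edges not strictly increasing at index %d", i + 1L))
    }
    if (any(v < -tol) || any(v > 1 + tol))
      abort_validation("cumulative volume fractions must lie in [0, 1]")
    if (abs(v[1L] - 1) > tol)
      abort_validation(sprintf("cumulative DVH must start at volume fraction 1 (got %.6g)", v[1L]))
    inc <- which(diff(v) > tol)
    if (length(inc))
      abort_validation(sprintf("cumulative volume increases at index %d", inc[1L] + 1L))
  } else if (identical(mode, "differential")) {
    if (nrow(x) < 1L) abort_validation("differential DVH needs >= 1 bin")
    if (any(x$dose_lo < 0)) abort_validation("bin edges must be non-negative")
    if (any(x$dose_hi <= x$dose_lo)) {
      i <- which(x$dose_hi <= x$dose_lo)[1L]
      abort_validation(sprintf("bin %d has non-positive width", i))
    }
    if (nrow(x) > 1L && any(abs(x$dose_lo[-1L] - x$dose_hi[-nrow(x)]) > tol))
      abort_validation("differential bins must be contiguous")
    if (any(x$volume_fraction < -tol)) {
      i <- which(x$volume_fraction < -tol)[1L]
      abort_validation(sprintf("negative bin fraction at bin %d", i))
    }
  } else {
    abort_validation(sprintf("unknown DVH mode '%s'", mode))
  }
  invisible(x)
}

#' Convert a cumulative DVH to differential form
#'
#' Bin fraction = cumulative(left edge) - cumulative(right edge); the bin's
#' representative dose is the midpoint of its edges. The differential
#' fractions sum to the cumulative value at the first edge.
#'
#' @param dvh A cumulative `dvh`.
#' @return A differential `dvh` on the same edges.
#' @export
#' @examples
#' to_differential(dvh_cumulative(c(0, 20, 40, 60), c(1, 1, 0.5, 0)))
to_differential <- function(dvh) {
  if (identical(dvh_mode(dvh), "differential")) return(dvh)
  validate_dvh(dvh)
  n <- nrow(dvh)
  dvh_differential(
    dose_lo = dvh$dose_gy[-n],
    dose_hi = dvh$dose_gy[-1L],
    volume_fraction = -diff(dvh$volume_fraction),
    structure = dvh_structure(dvh),
    absolute_volume_cc = dvh_absolute_volume(dvh)
  )
}

#' Convert a differential DVH to cumulative form
#'
#' The cumulative value at each bin edge is the summed fraction of all bins
#' whose representative dose lies at or above that edge.
#'
#' @param dvh A differential `dvh`.
#' @return A cumulative `dvh` on the bin edges.
#' @export
to_cumulative <- function(dvh) {
  if (identical(dvh_mode(dvh), "cumulative")) return(dvh)
  validate_dvh(dvh)
  edges <- c(dvh$dose_lo, dvh$dose_hi[nrow(dvh)])
  cum <- vapply(edges, function(e) sum(dvh$volume_fraction[dvh$dose_gy >= e]),
                numeric(1))
  dvh_cumulative(edges, cum,
                 structure = dvh_structure(dvh),
                 absolute_volume_cc = dvh_absolute_volume(dvh))
}

#' Resample a cumulative DVH onto a new dose grid
#'
#' Linear interpolation within the histogram's support, 0 beyond the last
#' edge; monotonicity is preserved by linearity.
#'
#' @param dvh A cumulative `dvh`.
#' @param grid Strictly increasing dose values in Gy starting at 0.
#' @return A cumulative `dvh` on `grid`.
#' @export
resample_cumulative <- function(dvh, grid) {
  if (!identical(dvh_mode(dvh), "cumulative"))
    abort_validation("resample_cumulative() needs a cumulative DVH")
  validate_dvh(dvh)
  if (length(grid) < 2L) abort_validation("resampling grid needs >= 2 values")
  if (grid[1L] != 0) abort_validation("resampling grid must start at 0")
  if (any(diff(grid) <= 0)) abort_validation("resampling grid must be strictly increasing")
  v <- stats::approx(dvh$dose_gy, dvh$volume_fraction, xout = grid,
                     method = "linear", rule = 2)$y
  v[grid > max(dvh$dose_gy)] <- 0
  dvh_cumulative(grid, v,
                 structure = dvh_structure(dvh),
                 absolute_volume_cc = dvh_absolute_volume(dvh))
}

#' Default dose grid
#'
#' 0.1 Gy bins from 0 to one bin beyond the maximum dose.
#'
#' @param max_dose_gy Largest dose to cover, Gy.
#' @param bin_gy Bin width in Gy (default 0.1).
#' @return Numeric dose grid.
#' @export
default_dose_grid <- function(max_dose_gy, bin_gy = 0.1) {
  seq(0, ceiling(max_dose_gy / bin_gy) * bin_gy + bin_gy, by = bin_gy)
}

#' Build a cumulative DVH from digitised curve points
#'
#' Cleans point lists extracted from printed (hardcopy) DVH curves: sorts by
#' dose, clips volume fractions to `[0, 1]`, enforces monotone non-increase
#' by a running minimum (each value replaced by the minimum of itself and all
#' values at lower dose), and prepends the point (0, 1) if absent.
#'
#' @param points A data frame / tibble with columns `dose_gy` and
#'   `volume_fraction`, or a 2-column matrix, of at least two digitised
#'   points with non-negative doses.
#' @param structure,absolute_volume_cc Metadata, see [dvh_cumulative()].
#' @return A valid cumulative `dvh`.
#' @export
#' @examples
#' pts <- data.frame(dose_gy = c(40, 0, 20), volume_fraction = c(0.5, 1, 0.98))
#' ingest_digitized_points(pts)
ingest_digitized_points <- function(points, structure = "structure",
                                    absolute_volume_cc = NA_real_) {
  if (is.matrix(points)) points <- tibble::tibble(dose_gy = points[, 1L],
                                                  volume_fraction = points[, 2L])
  d <- as.numeric(points$dose_gy)
  v <- as.numeric(points$volume_fraction)
  if (length(d) < 2L) abort_validation("need at least 2 digitised points")
  if (any(d < 0)) abort_validation("digitised doses must be non-negative")
  if (length(unique(d)) < 2L) abort_validation("digitised doses are all equal")
  o <- order(d)
  d <- d[o]
  v <- pmin(pmax(v[o], 0), 1)
  # collapse duplicate doses to their minimum (conservative for a cumulative curve)
  if (anyDuplicated(d)) {
    v <- vapply(split(v, d), min, numeric(1))
    d <- sort(unique(d))
  }
  v <- cummin(v)
  if (d[1L] > 0) {
    d <- c(0, d)
    v <- c(1, v)
  } else {
    v[1L] <- 1
    v <- cummin(v)
  }
  dvh_cumulative(d, v, structure = structure,
                 absolute_volume_cc = absolute_volume_cc)
}

#' Minimum, mean and maximum dose of a DVH
#'
#' `d_mean` is the fraction-weighted sum of bin midpoint doses. `d_max`
#' (`d_min`) is where the piecewise-linear cumulative curve crosses
#' `eps` (`1 - eps`): the highest dose still covering more than `eps`
#' (at least `1 - eps`) of the structure volume.
#'
#' @param dvh A `dvh` in either mode.
#' @param eps Near-min/near-max volume threshold (default 1e-6 of the
#'   structure volume).
#' @return One-row tibble with `structure`, `d_min`, `d_mean`, `d_max` (Gy).
#' @export
#' @examples
#' dose_summary(dvh_cumulative(c(0, 20, 40, 60), c(1, 1, 0.5, 0)))
dose_summary <- function(dvh, eps = 1e-6) {
  diffd <- to_differential(dvh)
  cum <- to_cumulative(dvh)
  validate_dvh(cum)
  d_mean <- sum(diffd$volume_fraction * diffd$dose_gy)
  d <- cum$dose_gy
  v <- cum$volume_fraction
  cross_down <- function(level) {
    # highest dose at which the (non-increasing, piecewise-linear) curve is
    # still >= level; d[length(d)] if it never drops below
    below <- which(v < level)
    if (!length(below)) return(d[length(d)])
    i <- below[1L]
    if (i == 1L) return(d[1L])
    # interpolate between (d[i-1], v[i-1]) and (d[i], v[i]) at v == level
    d[i - 1L] + (v[i - 1L] - level) / (v[i - 1L] - v[i]) * (d[i] - d[i - 1L])
  }
  tibble::tibble(
    structure = dvh_structure(dvh),
    d_min = cross_down(1 - eps),
    d_mean = d_mean,
    d_max = cross_down(eps)
  )
}

#' Read / write DVH CSV files
#'
#' The on-disk dialect has the header
#' `patient_id,course,structure,mode,dose_gy,volume_fraction,absolute_volume_cc`
#' with one row per cumulative dose edge or differential bin (for
#' differential rows `dose_gy` is the bin midpoint; edges are reconstructed
#' on read as midpoints between midpoints with symmetric extension at the
#' boundaries, which is exact on uniform grids). `course` is `RT1` or
#' `ReRT`; doses in Gy, volumes fractional, dot decimal separator.
#'
#' @param path File path.
#' @return `read_dvh_csv()`: a tibble with columns `patient_id`, `course`,
#'   `structure` and a `dvh` list-column, one row per histogram. Each parsed
#'   histogram is validated; violations raise an error naming the offending
#'   histogram.
#' @export
read_dvh_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("patient_id", "course", "structure", "mode", "dose_gy",
                "volume_fraction", "absolute_volume_cc")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    abort_validation(paste0("DVH CSV missing required column(s): ",
                            paste(missing, collapse = ", ")))
  bad_mode <- setdiff(unique(raw$mode), c("cumulative", "differential"))
  if (length(bad_mode))
    abort_validation(paste0("unknown DVH mode token(s): ",
                            paste(bad_mode, collapse = ", ")))
  if (!is.numeric(raw$dose_gy) || !is.numeric(raw$volume_fraction))
    abort_validation("dose_gy and volume_fraction must be numeric")
  if (!all(raw$course %in% c("RT1", "ReRT")))
    abort_validation("course must be RT1 or ReRT")
  raw |>
    dplyr::group_by(.data$patient_id, .data$course, .data$structure) |>
    dplyr::group_modify(function(g, key) {
      mode <- g$mode[1L]
      vol <- g$absolute_volume_cc[1L]
      h <- tryCatch({
        if (identical(mode, "cumulative")) {
          dvh_cumulative(g$dose_gy, g$volume_fraction,
                         structure = key$structure, absolute_volume_cc = vol)
        } else {
          mids <- g$dose_gy
          o <- order(mids)
          mids <- mids[o]
          fr <- g$volume_fraction[o]
          edges <- edges_from_midpoints(mids)
          dvh_differential(edges[-length(edges)], edges[-1L], fr,
                           structure = key$structure, absolute_volume_cc = vol)
        }
      }, reirrad_validation_error = function(e) {
        abort_validation(sprintf("%s / %s / %s: %s", key$patient_id,
                                 key$course, key$structure, conditionMessage(e)))
      })
      tibble::tibble(dvh = list(h))
    }) |>
    dplyr::ungroup()
}

edges_from_midpoints <- function(mids) {
  if (length(mids) == 1L) {
    w <- max(mids * 0.01, 0.05)
    return(c(max(mids - w, 0), mids + w))
  }
  inner <- (mids[-1L] + mids[-length(mids)]) / 2
  first <- max(mids[1L] - (inner[1L] - mids[1L]), 0)
  last <- mids[length(mids)] + (mids[length(mids)] - inner[length(inner)])
  c(first, inner, last)
}

#' @rdname read_dvh_csv
#' @param dvhs A tibble as returned by [read_dvh_csv()] (columns
#'   `patient_id`, `course`, `structure`, `dvh`).
#' @export
write_dvh_csv <- function(dvhs, path) {
  rows <- purrr::pmap(dvhs, function(patient_id, course, structure, dvh, ...) {
    tibble::tibble(
      patient_id = patient_id, course = course, structure = structure,
      mode = dvh_mode(dvh),
      dose_gy = round(dvh$dose_gy, 6),
      volume_fraction = round(dvh$volume_fraction, 6),
      absolute_volume_cc = round(dvh_absolute_volume(dvh), 6)
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Plot a cumulative DVH
#'
#' @param object A `dvh`.
#' @param ... Unused.
#' @return A ggplot of the cumulative curve.
#' @export
autoplot.dvh <- function(object, ...) {
  cum <- to_cumulative(object)
  ggplot2::ggplot(tibble::tibble(dose_gy = cum$dose_gy,
                                 volume_fraction = cum$volume_fraction),
                  ggplot2::aes(x = .data$dose_gy, y = .data$volume_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose [Gy]", y = "Relative volume",
                  title = dvh_structure(object)) +
    ggplot2::theme_minimal()
}
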