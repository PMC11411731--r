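#' Great-circle distance between two points
#'
#' Haversine distance on a sphere. The relocation scoring only uses the rank
#' order of distances and whether a distance is exactly zero, so a spherical
#' model is fully adequate; no ellipsoidal refinement is attempted.
#'
#' @param a,b Numeric length-2 vectors `c(lat, lon)` in decimal degrees.
#' @param earth_radius_km Sphere radius in kilometres.
#' @return Distance in kilometres.
#' @examples
#' haversine_distance(c(50, 8), c(50, 8))          # 0
#' haversine_distance(c(0, 0), c(0, 180))          # pi * R, antipodal
#' @export
haversine_distance <- function(a, b, earth_radius_km = 6371.0) {
  stopifnot(length(a) == 2, length(b) == 2)
  check_coord_range(a[1], a[2])
  check_coord_range(b[1], b[2])
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                           r = earth_radius_km * 1000) / 1000
}

check_coord_range <- function(lat, lon) {
  if (any(!is.na(lat) & (lat < -90 | lat > 90)) ||
      any(!is.na(lon) & (lon < -180 | lon > 180))) {
    stop("Coordinate out of range: lat must lie in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Pairwise distance matrix between two cohorts
#'
#' Computes the full |cohort1| x |cohort2| great-circle distance matrix in
#' kilometres, snapping distances at or below `zero_distance_epsilon_m` to
#' exactly zero (geocoding jitter must not turn an unmoved site into an
#' apparent relocation). Records without coordinates get `NA` distances and
#' never enter any nearest set. Row/column minima and their argmin sets —
#' the forward and backward nearest-neighbour structure — are precomputed.
#'
#' @param cohort1,cohort2 [facility_cohort()] objects for the two years.
#' @param config A [link_config()].
#' @return An object of class `distance_matrix`: a list with `d` (km matrix,
#'   rows = year-one ids, columns = year-two ids), `ids1`, `ids2`,
#'   `row_min`/`col_min` (minimal finite distance per row/column, `NA` when
#'   none) and `row_argmin`/`col_argmin` (lists of id vectors attaining the
#'   minimum, empty when none).
#' @export
distance_matrix <- function(cohort1, cohort2, config = link_config()) {
  stopifnot(inherits(cohort1, "facility_cohort"),
            inherits(cohort2, "facility_cohort"))
  if (nrow(cohort1) == 0 || nrow(cohort2) == 0) {
    stop("Both cohorts must be non-empty to build a distance matrix",
         call. = FALSE)
  }
  p1 <- cbind(cohort1$lon, cohort1$lat)
  p2 <- cbind(cohort2$lon, cohort2$lat)
  ok1 <- stats::complete.cases(p1)
  ok2 <- stats::complete.cases(p2)

  d <- matrix(NA_real_, nrow(cohort1), nrow(cohort2),
              dimnames = list(cohort1$record_id, cohort2$record_id))
  if (any(ok1) && any(ok2)) {
    r_m <- config$earth_radius_km * 1000
    d[ok1, ok2] <- geosphere::distm(
      p1[ok1, , drop = FALSE], p2[ok2, , drop = FALSE],
      fun = function(x, y) geosphere::distHaversine(x, y, r = r_m)
    ) / 1000
  }
  d[!is.na(d) & d <= config$zero_distance_epsilon_m / 1000] <- 0

  structure(
    list(
      d = d,
      ids1 = cohort1$record_id,
      ids2 = cohort2$record_id,
      row_min = apply_min(d, 1),
      col_min = apply_min(d, 2),
      row_argmin = apply_argmin(d, 1),
      col_argmin = apply_argmin(d, 2)
    ),
    class = "distance_matrix"
  )
}

# minimal finite value per margin; NA when a row/column has no finite distance
apply_min <- function(d, margin) {
  apply(d, margin, function(x) {
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  })
}

# ids attaining the margin minimum, within a 1e-9 km absolute tolerance so
# that analytically tied distances are not split by floating-point rounding
apply_argmin <- function(d, margin, tol = 1e-9) {
  other <- if (margin == 1) colnames(d) else rownames(d)
  res <- apply(d, margin, function(x) {
    if (all(is.na(x))) return(character(0))
    m <- min(x, na.rm = TRUE)
    other[!is.na(x) & x <= m + tol]
  }, simplify = FALSE)
  res
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix>", length(x$ids1), "x", length(x$ids2),
      "sites, km range",
      if (all(is.na(x$d))) "all-NA" else
        paste0("[", signif(min(x$d, na.rm = TRUE), 4), ", ",
               signif(max(x$d, na.rm = TRUE), 4), "]"), "\n")
  invisible(x)
}

#' Nearest-neighbour sets in one direction
#'
#' `direction = "forward"` maps each year-one record to its nearest year-two
#' records; `"backward"` maps each year-two record to its nearest year-one
#' records. Ties at the minimal distance are preserved as sets: tied
#' candidates are later scored identically.
#'
#' @param dm A [distance_matrix()].
#' @param direction `"forward"` or `"backward"`.
#' @return A named list (by record id) of lists with elements `ids`
#'   (character vector of argmin ids, possibly empty), `min_distance` (km,
#'   `NA` when no finite distance exists) and `is_zero`.
#' @export
nearest_sets <- function(dm, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(dm, "distance_matrix"))
  if (direction == "forward") {
    ids <- dm$ids1; mins <- dm$row_min; arg <- dm$row_argmin
  } else {
    ids <- dm$ids2; mins <- dm$col_min; arg <- dm$col_argmin
  }
  out <- lapply(seq_along(ids), function(i) {
    list(ids = arg[[i]], min_distance = mins[[i]],
         is_zero = !is.na(mins[[i]]) && mins[[i]] == 0)
  })
  names(out) <- ids
  out
}
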