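#' Run configuration for longitudinal linkage
#'
#' Bundles the tunable parameters of the linkage pipeline. All linkage
#' operations take a `link_config`; the defaults reproduce the reference
#' workflow (full IIC+SC code comparison, any positive score acceptable,
#' municipality filter on).
#'
#' @param sc_mode How the site code (SC) participates in the code sub-score.
#'   `"full"` compares the IIC and SC jointly; `"iic_only"` compares only the
#'   institution identification code (IIC), the regime needed when the SC
#'   numbering system changes between the two years being linked.
#' @param zero_distance_epsilon_m Distances at or below this many metres are
#'   snapped to exactly zero, so that geocoding jitter does not turn an
#'   unmoved site into an apparent relocation. Default 10 m.
#' @param tolerance_threshold Minimum total similarity score (1--8) for a
#'   candidate pair to be an acceptable linkage. Default 1: any positive
#'   score is admissible.
#' @param same_municipality_required If `TRUE`, an accepted linkage whose two
#'   endpoints lie in different municipalities is discarded after selection.
#' @param earth_radius_km Sphere radius used for great-circle distances.
#' @param seed Optional integer seed for stochastic components.
#'
#' @return An object of class `link_config` (a named list).
#' @examples
#' cfg <- link_config(sc_mode = "iic_only", tolerance_threshold = 2)
#' cfg$tolerance_threshold
#' @export
link_config <- function(sc_mode = c("full", "iic_only"),
                        zero_distance_epsilon_m = 10,
                        tolerance_threshold = 1,
                        same_municipality_required = TRUE,
                        earth_radius_km = 6371.0,
                        seed = NULL) {
  sc_mode <- match.arg(sc_mode)
  stopifnot(
    is.numeric(zero_distance_epsilon_m), length(zero_distance_epsilon_m) == 1,
    zero_distance_epsilon_m >= 0,
    is.numeric(tolerance_threshold), length(tolerance_threshold) == 1,
    is.logical(same_municipality_required), length(same_municipality_required) == 1,
    is.numeric(earth_radius_km), earth_radius_km > 0
  )
  if (tolerance_threshold < 1 || tolerance_threshold > 8) {
    stop("`tolerance_threshold` must lie in [1, 8]", call. = FALSE)
  }
  structure(
    list(
      sc_mode = sc_mode,
      zero_distance_epsilon_m = zero_distance_epsilon_m,
      tolerance_threshold = tolerance_threshold,
      same_municipality_required = same_municipality_required,
      earth_radius_km = earth_radius_km,
      seed = seed
    ),
    class = "link_config"
  )
}

#' @export
print.link_config <- function(x, ...) {
  cat("<link_config>\n")
  cat("  sc_mode:                   ", x$sc_mode, "\n")
  cat("  tolerance_threshold:       ", x$tolerance_threshold, "\n")
  cat("  zero_distance_epsilon_m:   ", x$zero_distance_epsilon_m, "\n")
  cat("  same_municipality_required:", x$same_municipality_required, "\n")
  cat("  earth_radius_km:           ", x$earth_radius_km, "\n")
  if (!is.null(x$seed)) cat("  seed:                      ", x$seed, "\n")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Any field of [link_config()] may appear in the file; missing fields take
#' the defaults. Unknown fields raise an error so typos do not pass silently.
#'
#' @param path Path to a YAML file.
#' @return A `link_config`.
#' @export
read_link_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(link_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    stop("Unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(link_config, vals)
}
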