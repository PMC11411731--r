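#' Link two annual cohorts end to end
#'
#' Runs the full pairwise workflow: build the similarity matrix, select at
#' most one linkage per facility, apply the municipality filter, and
#' classify continuity. The returned run report restates the configuration
#' and the per-stage counts, which satisfy the accounting identity
#' `cohort size = accepted + unlinked + pending ties` on both sides.
#'
#' @param cohort1,cohort2 [facility_cohort()] objects for adjacent years.
#' @param config A [link_config()].
#' @param resolutions Optional data frame of review-queue resolutions
#'   (`group_id`, `id1`, `id2`), applied after the city filter.
#' @return A list of class `link_run` with elements `similarity`
#'   (similarity matrix), `links` (`link_set`), `continuity`
#'   (continuity table) and `report` (named list of counts suitable for
#'   JSON serialization).
#' @export
link_cohorts <- function(cohort1, cohort2, config = link_config(),
                         resolutions = NULL) {
  sm <- build_similarity_matrix(cohort1, cohort2, config)
  links <- select_linkages(sm, config)
  links <- apply_city_filter(links, cohort1, cohort2, config)
  if (!is.null(resolutions)) links <- resolve_review(links, resolutions)
  continuity <- classify_continuity(links, sm)

  type_tally <- table(factor(continuity$continuity_type, levels = 1:4))
  report <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    year1 = attr(links, "year1"),
    year2 = attr(links, "year2"),
    n_year1 = nrow(cohort1),
    n_year2 = nrow(cohort2),
    similarity_pairs = nrow(sm),
    accepted = nrow(links$accepted),
    unlinked_year1 = length(links$unlinked_year1),
    unlinked_year2 = length(links$unlinked_year2),
    review_queue_groups = length(unique(links$review_queue$group_id)),
    review_queue_pairs = nrow(links$review_queue),
    rejected_cross_city = nrow(links$rejected_cross_city),
    continuity_types = list(
      constant = unname(type_tally[["1"]]),
      changed = unname(type_tally[["2"]]),
      newly_opened = unname(type_tally[["3"]]),
      closed = unname(type_tally[["4"]])
    ),
    score_tally = as.list(table(links$accepted$total))
  )
  structure(list(similarity = sm, links = links, continuity = continuity,
                 report = report),
            class = "link_run")
}

#' @export
print.link_run <- function(x, ...) {
  r <- x$report
  cat("<link_run>", r$year1, "->", r$year2, "\n")
  cat("  cohort sizes:", r$n_year1, "/", r$n_year2,
      "; similarity pairs:", r$similarity_pairs, "\n")
  cat("  accepted:", r$accepted,
      "; queued pairs:", r$review_queue_pairs,
      "; cross-city rejected:", r$rejected_cross_city, "\n")
  cat("  continuity: constant", r$continuity_types$constant,
      "| changed", r$continuity_types$changed,
      "| opened", r$continuity_types$newly_opened,
      "| closed", r$continuity_types$closed, "\n")
  invisible(x)
}

#' Link a multi-year sequence of cohorts into a panel
#'
#' Applies [link_cohorts()] to every adjacent year pair and chains the
#' accepted linkages into a longitudinal panel with stable identifiers.
#'
#' @param cohorts List of [facility_cohort()] objects in consecutive year
#'   order.
#' @param config A [link_config()].
#' @return A list of class `panel_run` with `runs` (list of `link_run` per
#'   transition), `panel` (the [chain_linkages()] table) and `report`
#'   (per-transition reports).
#' @export
link_panel <- function(cohorts, config = link_config()) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2)
  runs <- list()
  for (k in seq_len(length(cohorts) - 1)) {
    runs[[k]] <- link_cohorts(cohorts[[k]], cohorts[[k + 1]], config)
  }
  panel <- chain_linkages(lapply(runs, `[[`, "links"))
  structure(list(runs = runs, panel = panel,
                 report = lapply(runs, `[[`, "report")),
            class = "panel_run")
}

#' Write a run report as JSON
#'
#' @param report A report list from [link_cohorts()] or [link_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
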