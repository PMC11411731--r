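#' Code-only baseline linker
#'
#' The comparison method: link exactly those pairs whose hospital
#' identification codes are identical — IIC and SC jointly under
#' `mode = "full"`, IIC alone under `mode = "iic_only"` — with no use of
#' location. Codes occurring more than once on either side are ambiguous and
#' left unlinked (reported via a message), keeping the result a partial
#' matching.
#'
#' @param cohort1,cohort2 [facility_cohort()] objects.
#' @param mode `"full"` or `"iic_only"`.
#' @return A `link_set` whose accepted pairs carry a code sub-score of 4 and
#'   no location information.
#' @export
baseline_code_linker <- function(cohort1, cohort2,
                                 mode = c("full", "iic_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort1, "facility_cohort"),
            inherits(cohort2, "facility_cohort"))
  key <- function(cohort) {
    if (mode == "full") {
      paste(cohort$iic, normalize_sc(cohort$sc), sep = "\r")
    } else {
      cohort$iic
    }
  }
  k1 <- key(cohort1)
  k2 <- key(cohort2)
  ambiguous <- union(k1[duplicated(k1)], k2[duplicated(k2)])
  if (length(ambiguous) > 0) {
    message("Baseline linker: ", length(ambiguous),
            " ambiguous duplicate code(s) left unlinked")
  }
  usable <- !(k1 %in% ambiguous) & k1 %in% setdiff(k2, ambiguous)
  m <- match(k1[usable], k2)
  accepted <- tibble::tibble(
    id1 = cohort1$record_id[usable],
    id2 = cohort2$record_id[m],
    code_subscore = 4L, forward = NA_integer_, backward = NA_integer_,
    location_subscore = NA_integer_, total = 4L, distance_km = NA_real_
  )
  accepted <- accepted[order(accepted$id1), , drop = FALSE]
  new_link_set(
    accepted = accepted,
    review_queue = tibble::tibble(group_id = character(), id1 = character(),
                                  id2 = character(), total = integer(),
                                  distance_km = numeric()),
    rejected_cross_city = empty_rejected(),
    ids1 = cohort1$record_id, ids2 = cohort2$record_id,
    year1 = cohort_year(cohort1), year2 = cohort_year(cohort2),
    config = link_config(sc_mode = mode)
  )
}

#' Score a link set against a gold standard
#'
#' Counts true matches (accepted pairs that are reference pairs), false
#' matches (accepted pairs absent from the reference) and missed matches
#' (reference pairs not recovered). Every reference pair is either found or
#' missed, so `true + missed = total` always. The success rate is
#' `true / total`; false matches are reported relative to the same
#' denominator but do not enter it.
#'
#' @param links A `link_set`.
#' @param gold A [gold_standard()] (or data frame with `id_year1`,
#'   `id_year2`).
#' @return A list of class `evaluation_report`: counts `true_matches`,
#'   `false_matches`, `missed_matches`, `total_linkage_number`; percentage
#'   rates `true_rate`, `false_rate`, `missed_rate`; and tibbles
#'   `false_pairs`, `missed_pairs` for inspection.
#' @export
score_against_gold <- function(links, gold) {
  stopifnot(inherits(links, "link_set"))
  if (!inherits(gold, "gold_standard")) {
    gold <- gold_standard(gold$id_year1, gold$id_year2)
  }
  gkey <- paste(gold$id_year1, gold$id_year2, sep = "\r")
  akey <- paste(links$accepted$id1, links$accepted$id2, sep = "\r")
  true_n <- sum(akey %in% gkey)
  false_sel <- !(akey %in% gkey)
  missed_sel <- !(gkey %in% akey)
  total <- nrow(gold)
  pct <- function(x) if (total == 0) NA_real_ else 100 * x / total
  structure(
    list(
      true_matches = true_n,
      false_matches = sum(false_sel),
      missed_matches = sum(missed_sel),
      total_linkage_number = total,
      true_rate = pct(true_n),
      false_rate = pct(sum(false_sel)),
      missed_rate = pct(sum(missed_sel)),
      false_pairs = links$accepted[false_sel, c("id1", "id2", "total")],
      missed_pairs = gold[missed_sel, , drop = FALSE]
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> reference pairs:", x$total_linkage_number, "\n")
  cat(sprintf("  true matches:   %d (%.1f%%)\n", x$true_matches, x$true_rate))
  cat(sprintf("  false matches:  %d (%.1f%%)\n", x$false_matches, x$false_rate))
  cat(sprintf("  missed matches: %d (%.1f%%)\n", x$missed_matches,
              x$missed_rate))
  invisible(x)
}

#' Profile a variable's distinction and value stability
#'
#' The two quantitative criteria for selecting linkage key variables:
#' *distinction* — the number of distinct values the variable takes in each
#' year (a variable cannot separate facilities it does not distinguish) —
#' and *value stability* — the number of facilities whose value is unchanged
#' across each adjacent year pair (an unstable variable cannot re-identify).
#' Stability is counted over facility pairs matched either by a supplied
#' gold standard or, by default, by identical (IIC, SC) codes.
#'
#' @param cohorts A list of [facility_cohort()] objects in year order.
#' @param variable Name of the column to profile (must exist in every
#'   cohort).
#' @param gold Optional list of [gold_standard()] tables, one per adjacent
#'   year pair, giving the identity mapping to count stability over; when
#'   `NULL`, records are paired by identical (IIC, SC).
#' @return A tibble of class `variable_profile` with columns `measure`
#'   (`"distinction"` or `"value_stability"`), `span` (a year or a year
#'   pair) and `value`.
#' @export
profile_variable <- function(cohorts, variable, gold = NULL) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            all(vapply(cohorts, inherits, logical(1), "facility_cohort")))
  for (cohort in cohorts) {
    if (!variable %in% names(cohort)) {
      stop("Variable not present in every cohort: ", variable, call. = FALSE)
    }
  }
  years <- vapply(cohorts, cohort_year, integer(1))

  distinct_rows <- tibble::tibble(
    measure = "distinction",
    span = as.character(years),
    value = vapply(cohorts, function(x)
      length(unique(x[[variable]][!is.na(x[[variable]])])), integer(1))
  )

  stab_rows <- list()
  if (length(cohorts) >= 2) {
    for (k in seq_len(length(cohorts) - 1)) {
      a <- cohorts[[k]]
      b <- cohorts[[k + 1]]
      if (!is.null(gold)) {
        g <- gold[[k]]
        ia <- match(g$id_year1, a$record_id)
        ib <- match(g$id_year2, b$record_id)
      } else {
        ka <- paste(a$iic, normalize_sc(a$sc), sep = "\r")
        kb <- paste(b$iic, normalize_sc(b$sc), sep = "\r")
        shared <- intersect(ka[!duplicated(ka)], kb[!duplicated(kb)])
        shared <- setdiff(shared, c(ka[duplicated(ka)], kb[duplicated(kb)]))
        ia <- match(shared, ka)
        ib <- match(shared, kb)
      }
      va <- a[[variable]][ia]
      vb <- b[[variable]][ib]
      stab_rows[[k]] <- tibble::tibble(
        measure = "value_stability",
        span = paste(years[k], years[k + 1], sep = "-"),
        value = sum(!is.na(va) & !is.na(vb) & va == vb)
      )
    }
  }
  out <- dplyr::bind_rows(distinct_rows, dplyr::bind_rows(stab_rows))
  class(out) <- c("variable_profile", class(out))
  out
}
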