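#' Select at most one linkage per facility from a similarity matrix
#'
#' Turns the similarity matrix into a partial matching: candidate pairs are
#' taken in deterministic order (total score descending, then distance
#' ascending, then lexicographic ids) and accepted greedily when neither
#' endpoint is already matched and the total reaches the tolerance
#' threshold. When a facility's best still-available candidates tie on the
#' total score, the whole connected group of tied candidates is sent to the
#' review queue for manual resolution (see [resolve_review()]) and the
#' facilities involved stay provisionally unlinked; a tie is not declared
#' when the competing candidate's partner was already matched at a higher
#' score.
#'
#' @param sm A [build_similarity_matrix()] result.
#' @param config A [link_config()]; defaults to the configuration the matrix
#'   was built with.
#' @return An object of class `link_set`: a list with `accepted` (tibble of
#'   pairs with full score decomposition), `unlinked_year1` /
#'   `unlinked_year2` (ids with no accepted linkage and no pending tie),
#'   `review_queue` (tibble `group_id`, `id1`, `id2`, `total`,
#'   `distance_km`), and `rejected_cross_city` (empty here; filled by
#'   [apply_city_filter()]). Years and config are carried as attributes.
#' @export
select_linkages <- function(sm, config = NULL) {
  stopifnot(inherits(sm, "similarity_matrix"))
  if (is.null(config)) config <- attr(sm, "config")
  cand <- sm_pairs(sm)[sm$total >= config$tolerance_threshold, ,
                       drop = FALSE]
  # deterministic order: total desc, distance asc (NA last), ids
  cand <- cand[order(-cand$total, cand$distance_km, cand$id1, cand$id2,
                     method = "radix"), , drop = FALSE]

  taken1 <- character(0)  # matched or queued year-one ids
  taken2 <- character(0)
  accepted <- logical(nrow(cand))
  queued <- integer(nrow(cand))  # 0 = not queued, else group number
  n_groups <- 0L

  i <- 1L
  while (i <= nrow(cand)) {
    if (accepted[i] || queued[i] > 0 ||
        cand$id1[i] %in% taken1 || cand$id2[i] %in% taken2) {
      i <- i + 1L
      next
    }
    # available same-total competitors
    grp <- which(cand$total == cand$total[i] & !accepted & queued == 0 &
                 !(cand$id1 %in% taken1) & !(cand$id2 %in% taken2))
    # connected component (by shared endpoints) of pair i within the group
    cluster <- i
    repeat {
      grow <- grp[cand$id1[grp] %in% cand$id1[cluster] |
                  cand$id2[grp] %in% cand$id2[cluster]]
      if (length(setdiff(grow, cluster)) == 0) break
      cluster <- sort(union(cluster, grow))
    }
    if (length(cluster) > 1) {
      n_groups <- n_groups + 1L
      queued[cluster] <- n_groups
      taken1 <- c(taken1, unique(cand$id1[cluster]))
      taken2 <- c(taken2, unique(cand$id2[cluster]))
    } else {
      accepted[i] <- TRUE
      taken1 <- c(taken1, cand$id1[i])
      taken2 <- c(taken2, cand$id2[i])
    }
    i <- i + 1L
  }

  acc <- tibble::as_tibble(cand[accepted, , drop = FALSE])
  queue <- tibble::tibble(
    group_id = sprintf("g%03d", queued[queued > 0]),
    tibble::as_tibble(cand[queued > 0, , drop = FALSE])
  )
  queue <- queue[order(queue$group_id, queue$id1, queue$id2), , drop = FALSE]

  new_link_set(
    accepted = acc,
    review_queue = queue,
    rejected_cross_city = empty_rejected(),
    ids1 = attr(sm, "ids1"), ids2 = attr(sm, "ids2"),
    year1 = attr(sm, "year1"), year2 = attr(sm, "year2"),
    config = config
  )
}

new_link_set <- function(accepted, review_queue, rejected_cross_city,
                         ids1, ids2, year1, year2, config) {
  pending1 <- unique(review_queue$id1)
  pending2 <- unique(review_queue$id2)
  structure(
    list(
      accepted = accepted,
      unlinked_year1 = setdiff(ids1, c(accepted$id1, pending1)),
      unlinked_year2 = setdiff(ids2, c(accepted$id2, pending2)),
      review_queue = review_queue,
      rejected_cross_city = rejected_cross_city
    ),
    ids1 = ids1, ids2 = ids2, year1 = year1, year2 = year2, config = config,
    class = "link_set"
  )
}

empty_rejected <- function() {
  tibble::tibble(id1 = character(), id2 = character(), total = integer(),
                 municipality1 = character(), municipality2 = character())
}

#' @export
print.link_set <- function(x, ...) {
  cat("<link_set>", attr(x, "year1"), "->", attr(x, "year2"), "\n")
  cat("  accepted:           ", nrow(x$accepted), "\n")
  cat("  unlinked year one:  ", length(x$unlinked_year1), "\n")
  cat("  unlinked year two:  ", length(x$unlinked_year2), "\n")
  cat("  review queue pairs: ", nrow(x$review_queue),
      "in", length(unique(x$review_queue$group_id)), "group(s)\n")
  cat("  rejected cross-city:", nrow(x$rejected_cross_city), "\n")
  invisible(x)
}

#' Discard accepted linkages that cross a municipality boundary
#'
#' A selected linkage whose endpoints lie in different municipalities is
#' disregarded: the pair moves to `rejected_cross_city` and both facilities
#' become unlinked. Freed facilities are not re-offered their next-best
#' candidate (single-pass semantics). Municipality names are compared after
#' [normalize_municipality()]; a pair with a missing municipality on either
#' side is kept with a warning, since the filter cannot be evaluated.
#' A no-op when `same_municipality_required` is `FALSE`.
#'
#' @param links A [select_linkages()] result.
#' @param cohort1,cohort2 The cohorts the links were built from (municipality
#'   lookup).
#' @param config A [link_config()]; defaults to the link set's own.
#' @return The filtered `link_set`.
#' @export
apply_city_filter <- function(links, cohort1, cohort2, config = NULL) {
  stopifnot(inherits(links, "link_set"))
  if (is.null(config)) config <- attr(links, "config")
  if (!config$same_municipality_required || nrow(links$accepted) == 0) {
    return(links)
  }
  m1 <- cohort1$municipality[match(links$accepted$id1, cohort1$record_id)]
  m2 <- cohort2$municipality[match(links$accepted$id2, cohort2$record_id)]
  n1 <- normalize_municipality(m1)
  n2 <- normalize_municipality(m2)
  unknown <- is.na(n1) | is.na(n2)
  if (any(unknown)) {
    warning("Municipality missing for ", sum(unknown),
            " accepted pair(s); city filter not evaluated for: ",
            paste(utils::head(paste(links$accepted$id1[unknown],
                                    links$accepted$id2[unknown], sep = "-"),
                              5), collapse = ", "),
        call. = FALSE)
  }
  cross <- !unknown & n1 != n2
  rejected <- tibble::tibble(
    id1 = links$accepted$id1[cross],
    id2 = links$accepted$id2[cross],
    total = as.integer(links$accepted$total[cross]),
    municipality1 = m1[cross],
    municipality2 = m2[cross]
  )
  new_link_set(
    accepted = links$accepted[!cross, , drop = FALSE],
    review_queue = links$review_queue,
    rejected_cross_city = dplyr::bind_rows(links$rejected_cross_city, rejected),
    ids1 = attr(links, "ids1"), ids2 = attr(links, "ids2"),
    year1 = attr(links, "year1"), year2 = attr(links, "year2"),
    config = config
  )
}

#' Merge manual review decisions back into a link set
#'
#' The review queue is resolved externally: the analyst inspects each tie
#' group (e.g. against registry attributes or hospital websites) and chooses
#' at most one pair per group. Automated guessing is deliberately refused.
#'
#' @param links A `link_set` with a non-empty review queue.
#' @param resolutions Data frame with columns `group_id`, `id1`, `id2`: the
#'   chosen pair per resolved group. Groups absent from `resolutions` remain
#'   queued.
#' @return The updated `link_set`; chosen pairs move to `accepted` with
#'   their original scores.
#' @export
resolve_review <- function(links, resolutions) {
  stopifnot(inherits(links, "link_set"))
  resolutions <- tibble::as_tibble(resolutions)
  stopifnot(all(c("group_id", "id1", "id2") %in% names(resolutions)))
  queue <- links$review_queue
  chosen_key <- paste(resolutions$group_id, resolutions$id1, resolutions$id2)
  queue_key <- paste(queue$group_id, queue$id1, queue$id2)
  if (!all(chosen_key %in% queue_key)) {
    stop("Resolution refers to pair(s) not present in the review queue",
         call. = FALSE)
  }
  if (anyDuplicated(resolutions$group_id)) {
    stop("At most one pair may be chosen per review group", call. = FALSE)
  }
  chosen <- queue[queue_key %in% chosen_key, , drop = FALSE]
  if (anyDuplicated(chosen$id1) || anyDuplicated(chosen$id2) ||
      any(chosen$id1 %in% links$accepted$id1) ||
      any(chosen$id2 %in% links$accepted$id2)) {
    stop("Chosen resolutions violate the one-linkage-or-none rule",
         call. = FALSE)
  }
  chosen$group_id <- NULL
  accepted <- dplyr::bind_rows(links$accepted, chosen)
  remaining <- queue[!(queue$group_id %in% resolutions$group_id), , drop = FALSE]
  new_link_set(
    accepted = accepted,
    review_queue = remaining,
    rejected_cross_city = links$rejected_cross_city,
    ids1 = attr(links, "ids1"), ids2 = attr(links, "ids2"),
    year1 = attr(links, "year1"), year2 = attr(links, "year2"),
    config = attr(links, "config")
  )
}

#' Classify longitudinal continuity of every facility
#'
#' Assigns each facility of both years one of four continuity types:
#' type 1 *constant* (accepted linkage with total score 8, i.e. no change in
#' code or location), type 2 *changed* (accepted linkage with total below
#' 8), type 3 *newly opened* (year-two facility without an accepted
#' linkage) and type 4 *closed* (year-one facility without one). Division
#' and merging are not separate types of the final matching — a division
#' appears as one changed and one newly opened facility, a merger as one
#' changed and one closed facility — so they are reported as flags:
#' `division_flag` marks year-one facilities that had two or more
#' above-threshold candidates before one-or-none selection, `merge_flag`
#' the symmetric situation for year-two facilities.
#'
#' @param links A final `link_set` (ties resolved or left unlinked).
#' @param sm The similarity matrix the links came from (pre-selection
#'   candidate multiplicity).
#' @return A tibble with columns `record_id`, `year`, `role`
#'   (`"year1"`/`"year2"`), `continuity_type` (1--4), `type_label`,
#'   `division_flag`, `merge_flag`.
#' @export
classify_continuity <- function(links, sm) {
  stopifnot(inherits(links, "link_set"), inherits(sm, "similarity_matrix"))
  config <- attr(links, "config")
  thr <- config$tolerance_threshold
  above <- sm_pairs(sm)[sm$total >= thr, , drop = FALSE]
  multi1 <- names(which(table(above$id1) >= 2))
  multi2 <- names(which(table(above$id2) >= 2))

  labels <- c("constant", "changed", "newly_opened", "closed")
  ids1 <- attr(links, "ids1")
  ids2 <- attr(links, "ids2")
  acc <- links$accepted

  t1 <- ifelse(ids1 %in% acc$id1,
               ifelse(ids1 %in% acc$id1[acc$total == 8], 1L, 2L), 4L)
  t2 <- ifelse(ids2 %in% acc$id2,
               ifelse(ids2 %in% acc$id2[acc$total == 8], 1L, 2L), 3L)

  out <- tibble::tibble(
    record_id = c(ids1, ids2),
    year = c(rep(attr(links, "year1"), length(ids1)),
             rep(attr(links, "year2"), length(ids2))),
    role = c(rep("year1", length(ids1)), rep("year2", length(ids2))),
    continuity_type = c(t1, t2),
    type_label = labels[c(t1, t2)],
    division_flag = c(ids1 %in% multi1, rep(FALSE, length(ids2))),
    merge_flag = c(rep(FALSE, length(ids1)), ids2 %in% multi2)
  )
  class(out) <- c("continuity_table", class(out))
  out
}
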