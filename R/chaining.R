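#' Chain pairwise link sets into a longitudinal panel
#'
#' Assembles the accepted linkages of consecutive year pairs (e.g.
#' 2016--2017, 2017--2018, ...) into chains with stable longitudinal
#' identifiers. Each chain is a maximal run of consecutive-year presences
#' connected through accepted linkages; a facility with no accepted link
#' into the next year terminates its chain, and a facility appearing without
#' a link from the previous year starts a new one. Gaps are never bridged:
#' a facility absent in an intermediate year and reappearing later gets a
#' fresh identifier, consistent with treating the disappearance as a
#' closure and the reappearance as an opening.
#'
#' The longitudinal identifier is `"<first year>:<first record_id>"`, which
#' makes identifiers reproducible across runs and across panel extensions:
#' appending a further year pair never renames existing chains.
#'
#' @param linksets A list of `link_set` objects ordered by year, covering
#'   consecutive year pairs (the year-two of each must be the year-one of
#'   the next).
#' @return A tibble of class `panel_table` with columns `longitudinal_id`,
#'   `year`, `record_id`, `score_from_previous` (total score of the linkage
#'   into this year, `NA` for a chain's first year), `continuity_type`
#'   describing the transition into the year (1 constant, 2 changed, 3
#'   newly opened for a chain starting after the first panel year, `NA` for
#'   first-panel-year rows) and `closes_after` (`TRUE` on the last row of a
#'   chain that ends before the final panel year — a closure, type 4, at the
#'   following transition).
#' @export
chain_linkages <- function(linksets) {
  stopifnot(is.list(linksets), length(linksets) >= 1,
            all(vapply(linksets, inherits, logical(1), "link_set")))
  y1 <- vapply(linksets, attr, integer(1), "year1")
  y2 <- vapply(linksets, attr, integer(1), "year2")
  if (any(y2 != y1 + 1L)) {
    stop("Each link set must span a single year step (year2 = year1 + 1)",
         call. = FALSE)
  }
  if (length(linksets) > 1 && any(y1[-1] != y2[-length(y2)])) {
    stop("Link sets must cover consecutive, non-overlapping year pairs",
         call. = FALSE)
  }

  years <- c(y1, y2[length(y2)])
  # node key "(year, record_id)"
  nk <- function(year, id) paste(year, id, sep = ":")

  # successor map through accepted linkages
  succ <- new.env(parent = emptyenv())
  score_in <- new.env(parent = emptyenv())
  for (k in seq_along(linksets)) {
    acc <- linksets[[k]]$accepted
    for (j in seq_len(nrow(acc))) {
      assign(nk(y1[k], acc$id1[j]), acc$id2[j], envir = succ)
      assign(nk(y2[k], acc$id2[j]), acc$total[j], envir = score_in)
    }
  }

  # membership per year: ids present in each cohort
  ids_by_year <- vector("list", length(years))
  names(ids_by_year) <- as.character(years)
  for (k in seq_along(linksets)) {
    ids_by_year[[as.character(y1[k])]] <-
      union(ids_by_year[[as.character(y1[k])]], attr(linksets[[k]], "ids1"))
    ids_by_year[[as.character(y2[k])]] <-
      union(ids_by_year[[as.character(y2[k])]], attr(linksets[[k]], "ids2"))
  }

  # chain starts: first-year records, plus records not reached by a linkage
  linked_into <- new.env(parent = emptyenv())
  for (k in seq_along(linksets)) {
    for (id in linksets[[k]]$accepted$id2) {
      assign(nk(y2[k], id), TRUE, envir = linked_into)
    }
  }

  rows <- list()
  for (yi in seq_along(years)) {
    yr <- years[yi]
    for (id in sort(ids_by_year[[as.character(yr)]])) {
      if (yi > 1 && !is.null(get0(nk(yr, id), envir = linked_into))) next
      # walk the chain from this start
      lid <- paste(yr, id, sep = ":")
      cur_year <- yr
      cur_id <- id
      repeat {
        sc <- get0(nk(cur_year, cur_id), envir = score_in)
        rows[[length(rows) + 1]] <- tibble::tibble(
          longitudinal_id = lid, year = cur_year, record_id = cur_id,
          score_from_previous = if (is.null(sc) || cur_year == yr)
            NA_integer_ else as.integer(sc)
        )
        nxt <- get0(nk(cur_year, cur_id), envir = succ)
        if (is.null(nxt)) break
        cur_year <- cur_year + 1L
        cur_id <- nxt
      }
    }
  }
  panel <- dplyr::bind_rows(rows)
  panel <- panel[order(panel$longitudinal_id, panel$year), , drop = FALSE]

  first_year <- min(years)
  last_year <- max(years)
  by_lid <- split(seq_len(nrow(panel)), panel$longitudinal_id)
  panel$continuity_type <- NA_integer_
  panel$closes_after <- FALSE
  for (idx in by_lid) {
    ys <- panel$year[idx]
    start <- idx[which.min(ys)]
    end <- idx[which.max(ys)]
    linked <- idx[!is.na(panel$score_from_previous[idx])]
    panel$continuity_type[linked] <-
      ifelse(panel$score_from_previous[linked] == 8L, 1L, 2L)
    if (panel$year[start] > first_year) panel$continuity_type[start] <- 3L
    if (panel$year[end] < last_year) panel$closes_after[end] <- TRUE
  }
  class(panel) <- c("panel_table", class(panel))
  attr(panel, "years") <- years
  panel
}

#' Write a longitudinal panel to CSV
#'
#' @param panel A [chain_linkages()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
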