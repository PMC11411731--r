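link_csv_cols <- c("status", "group_id", "year1", "year2", "id1", "id2",
                   "code_subscore", "forward", "backward",
                   "location_subscore", "total", "distance_km",
                   "municipality1", "municipality2")

#' Write a link set to CSV
#'
#' One row per accepted linkage with its full score decomposition, one row
#' per unlinked facility, one row per queued tie candidate (with its review
#' group id) and one row per pair rejected by the city filter; the `status`
#' column distinguishes them. Column order is fixed, so output is bit-stable
#' for identical inputs. [read_linkages()] inverts this exactly.
#'
#' @param links A `link_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkages <- function(links, path) {
  stopifnot(inherits(links, "link_set"))
  rows <- dplyr::bind_rows(
    dplyr::mutate(links$accepted, status = "accepted"),
    tibble::tibble(status = rep("unlinked_year1",
                                length(links$unlinked_year1)),
                   id1 = links$unlinked_year1),
    tibble::tibble(status = rep("unlinked_year2",
                                length(links$unlinked_year2)),
                   id2 = links$unlinked_year2),
    dplyr::mutate(links$review_queue, status = "queued"),
    dplyr::mutate(links$rejected_cross_city, status = "rejected_cross_city")
  )
  for (col in setdiff(link_csv_cols, names(rows))) rows[[col]] <- NA
  rows$year1 <- attr(links, "year1")
  rows$year2 <- attr(links, "year2")
  rows <- rows[, link_csv_cols]
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a link set written by [write_linkages()]
#'
#' @param path Path to a linkage CSV.
#' @param config Optional [link_config()] to attach; defaults to
#'   `link_config()`.
#' @return A `link_set`.
#' @export
read_linkages <- function(path, config = link_config()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(link_csv_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("Linkage file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw[raw == ""] <- NA
  num <- function(x) as.numeric(x)
  int <- function(x) as.integer(x)
  score_tbl <- function(rows) {
    tibble::tibble(
      id1 = rows$id1, id2 = rows$id2,
      code_subscore = int(rows$code_subscore),
      forward = int(rows$forward), backward = int(rows$backward),
      location_subscore = int(rows$location_subscore),
      total = int(rows$total), distance_km = num(rows$distance_km)
    )
  }
  acc <- score_tbl(raw[raw$status == "accepted", , drop = FALSE])
  qrows <- raw[raw$status == "queued", , drop = FALSE]
  queue <- tibble::tibble(group_id = qrows$group_id, score_tbl(qrows))
  rrows <- raw[raw$status == "rejected_cross_city", , drop = FALSE]
  rejected <- tibble::tibble(
    id1 = rrows$id1, id2 = rrows$id2, total = int(rrows$total),
    municipality1 = rrows$municipality1, municipality2 = rrows$municipality2
  )
  un1 <- raw$id1[raw$status == "unlinked_year1"]
  un2 <- raw$id2[raw$status == "unlinked_year2"]
  new_link_set(
    accepted = acc, review_queue = queue, rejected_cross_city = rejected,
    ids1 = c(acc$id1, un1, unique(queue$id1)),
    ids2 = c(acc$id2, un2, unique(queue$id2)),
    year1 = int(raw$year1[1]), year2 = int(raw$year2[1]),
    config = config
  )
}

#' Read a gold-standard linkage table
#'
#' A gold standard is the set of reference ("correct") linkages between two
#' annual cohorts: a CSV with columns `id_year1` and `id_year2`, at most one
#' row per facility on either side.
#'
#' @param path Path to the CSV.
#' @return A tibble of class `gold_standard`.
#' @export
read_gold <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("id_year1", "id_year2") %in% names(raw))) {
    stop("Gold-standard file needs columns id_year1 and id_year2",
         call. = FALSE)
  }
  gold_standard(raw$id_year1, raw$id_year2)
}

#' Construct a gold standard
#'
#' @param id_year1,id_year2 Character vectors of paired record ids.
#' @return A tibble of class `gold_standard`.
#' @export
gold_standard <- function(id_year1, id_year2) {
  out <- tibble::tibble(id_year1 = as.character(id_year1),
                        id_year2 = as.character(id_year2))
  if (anyDuplicated(out$id_year1) || anyDuplicated(out$id_year2)) {
    stop("Gold standard must be a partial matching: each id at most once",
         call. = FALSE)
  }
  class(out) <- c("gold_standard", class(out))
  out
}
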