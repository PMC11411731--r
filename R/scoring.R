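#' Administrative-code sub-score for a candidate pair
#'
#' Compares the hospital identification code of two records. Under
#' `mode = "full"` the institution identification code (IIC) and the site
#' code (SC) are compared jointly: an identical IIC-SC combination scores 4,
#' an identical IIC with a differing SC scores 2, and different IICs score 0.
#' A missing SC on either side cannot confirm site identity and therefore
#' counts as a differing SC. Under `mode = "iic_only"` — the regime for year
#' pairs straddling an SC renumbering — an identical IIC scores 4, anything
#' else 0.
#'
#' Site codes are compared after [normalize_sc()].
#'
#' @param iic1,iic2 Character vectors of IICs (recycled to common length).
#' @param sc1,sc2 Character vectors of SCs; may be `NA`.
#' @param mode `"full"` or `"iic_only"`.
#' @return Integer vector with values 0, 2 or 4.
#' @examples
#' code_subscore("X", "X", "01", "01")          # 4
#' code_subscore("X", "X", "01", "02")          # 2
#' code_subscore("X", "Y", "01", "01")          # 0
#' @export
code_subscore <- function(iic1, iic2, sc1 = NA, sc2 = NA,
                          mode = c("full", "iic_only")) {
  mode <- match.arg(mode)
  n <- max(length(iic1), length(iic2), length(sc1), length(sc2))
  iic1 <- rep_len(as.character(iic1), n)
  iic2 <- rep_len(as.character(iic2), n)
  if (any(is.na(iic1)) || any(is.na(iic2)) ||
      any(iic1 == "") || any(iic2 == "")) {
    stop("Every record must carry an IIC to be code-scored", call. = FALSE)
  }
  same_iic <- iic1 == iic2
  if (mode == "iic_only") {
    return(ifelse(same_iic, 4L, 0L))
  }
  s1 <- rep_len(normalize_sc(sc1), n)
  s2 <- rep_len(normalize_sc(sc2), n)
  same_sc <- !is.na(s1) & !is.na(s2) & s1 == s2
  ifelse(same_iic & same_sc, 4L, ifelse(same_iic, 2L, 0L))
}

#' Location sub-score components for all candidate pairs
#'
#' Derives, from the nearest-neighbour structure of a distance matrix, the
#' forward and backward components of the location sub-score. A pair (A, B)
#' earns a forward component of 2 when B lies in A's nearest set at zero
#' distance, 1 when in the nearest set at positive distance, 0 otherwise;
#' the backward component is symmetric from B's side. The location sub-score
#' is their sum, attaining 4 (same address), 2 (mutually nearest after a
#' move), 1 (one-way nearest) or 0. A sum of 3 cannot occur: a zero-distance
#' pair is automatically nearest in both directions.
#'
#' @param dm A [distance_matrix()].
#' @return A tibble with one row per pair having a positive component:
#'   `id1`, `id2`, `forward`, `backward`, `location_subscore`, `distance_km`.
#' @export
location_subscores <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  fwd <- component_edges(dm$ids1, dm$row_argmin, dm$row_min)
  names(fwd) <- c("id1", "id2", "forward")
  bwd <- component_edges(dm$ids2, dm$col_argmin, dm$col_min)
  names(bwd) <- c("id2", "id1", "backward")
  pairs <- dplyr::full_join(fwd, bwd, by = c("id1", "id2"))
  pairs$forward[is.na(pairs$forward)] <- 0L
  pairs$backward[is.na(pairs$backward)] <- 0L
  pairs$location_subscore <- pairs$forward + pairs$backward
  pairs$distance_km <- dm$d[cbind(match(pairs$id1, dm$ids1),
                                  match(pairs$id2, dm$ids2))]
  pairs <- pairs[order(pairs$id1, pairs$id2), , drop = FALSE]
  tibble::as_tibble(pairs[, c("id1", "id2", "forward", "backward",
                              "location_subscore", "distance_km")])
}

# edges (focal id, argmin partner, component score) for one direction
component_edges <- function(ids, argmins, mins) {
  k <- unname(lengths(argmins))
  tibble::tibble(
    from = rep(ids, k),
    to = unlist(argmins, use.names = FALSE),
    comp = rep(unname(ifelse(!is.na(mins) & mins == 0, 2L, 1L)), k)
  )
}

#' Build the similarity matrix between two annual cohorts
#'
#' Scores every year-one x year-two pair on the two key variables —
#' administrative code and location — and stores all pairs with a positive
#' total. The total score is the sum of the code sub-score (0/2/4) and the
#' location sub-score (0/1/2/4); its attainable values are 0, 1, 2, 3, 4, 5,
#' 6 and 8 (7 is impossible because a location sub-score of 3 cannot occur),
#' and a total of 8 means no change in either key variable.
#'
#' Records without coordinates take location components of 0 against every
#' pair but can still link through their codes; such records are reported
#' via a message.
#'
#' @param cohort1,cohort2 [facility_cohort()] objects.
#' @param config A [link_config()].
#' @return An object of class `similarity_matrix`: a tibble of pairs with
#'   columns `id1`, `id2`, `code_subscore`, `forward`, `backward`,
#'   `location_subscore`, `total`, `distance_km`, sorted by
#'   (`total` desc, `distance_km` asc, `id1`, `id2`), with attributes
#'   `year1`, `year2`, `n1`, `n2` and `config`.
#' @examples
#' c1 <- facility_cohort(data.frame(record_id = "A", iic = "X", sc = "01",
#'                                  lat = 50, lon = 8, municipality = "M"), 2016)
#' c2 <- facility_cohort(data.frame(record_id = "B", iic = "X", sc = "01",
#'                                  lat = 50, lon = 8, municipality = "M"), 2017)
#' build_similarity_matrix(c1, c2)   # single pair, total 8
#' @export
build_similarity_matrix <- function(cohort1, cohort2, config = link_config()) {
  stopifnot(inherits(cohort1, "facility_cohort"),
            inherits(cohort2, "facility_cohort"))
  if (nrow(cohort1) == 0 || nrow(cohort2) == 0) {
    stop("Both cohorts must be non-empty to build a similarity matrix",
         call. = FALSE)
  }
  no_xy <- c(cohort1$record_id[is.na(cohort1$lat) | is.na(cohort1$lon)],
             cohort2$record_id[is.na(cohort2$lat) | is.na(cohort2$lon)])
  if (length(no_xy) > 0) {
    message("Record(s) without coordinates take location sub-score 0: ",
            paste(no_xy, collapse = ", "))
  }

  dm <- distance_matrix(cohort1, cohort2, config)
  loc <- location_subscores(dm)

  # candidate pairs = positive location component OR shared IIC
  code_pairs <- dplyr::inner_join(
    tibble::tibble(id1 = cohort1$record_id, iic = cohort1$iic),
    tibble::tibble(id2 = cohort2$record_id, iic = cohort2$iic),
    by = "iic", relationship = "many-to-many"
  )[, c("id1", "id2")]
  pairs <- dplyr::full_join(loc, code_pairs, by = c("id1", "id2"))
  for (col in c("forward", "backward", "location_subscore")) {
    pairs[[col]][is.na(pairs[[col]])] <- 0L
  }
  miss_d <- is.na(pairs$distance_km)
  if (any(miss_d)) {
    pairs$distance_km[miss_d] <- dm$d[cbind(match(pairs$id1[miss_d], dm$ids1),
                                            match(pairs$id2[miss_d], dm$ids2))]
  }

  i1 <- match(pairs$id1, cohort1$record_id)
  i2 <- match(pairs$id2, cohort2$record_id)
  pairs$code_subscore <- code_subscore(cohort1$iic[i1], cohort2$iic[i2],
                                       cohort1$sc[i1], cohort2$sc[i2],
                                       mode = config$sc_mode)
  pairs$total <- pairs$code_subscore + pairs$location_subscore
  pairs <- pairs[pairs$total > 0, , drop = FALSE]
  pairs <- pairs[order(-pairs$total, pairs$distance_km, pairs$id1, pairs$id2,
                       method = "radix"), , drop = FALSE]
  pairs <- tibble::as_tibble(pairs[, c("id1", "id2", "code_subscore",
                                       "forward", "backward",
                                       "location_subscore", "total",
                                       "distance_km")])
  structure(pairs,
            year1 = cohort_year(cohort1), year2 = cohort_year(cohort2),
            n1 = nrow(cohort1), n2 = nrow(cohort2),
            ids1 = cohort1$record_id, ids2 = cohort2$record_id,
            config = config,
            class = c("similarity_matrix", class(pairs)))
}

# plain data.frame of the pair table, without the matrix's metadata
# attributes (which would otherwise stow away on subsets)
sm_pairs <- function(sm) {
  out <- as.data.frame(sm)
  for (a in c("year1", "year2", "n1", "n2", "ids1", "ids2", "config")) {
    attr(out, a) <- NULL
  }
  class(out) <- "data.frame"
  out
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix>", attr(x, "year1"), "->", attr(x, "year2"),
      ":", nrow(x), "positive-score pairs from",
      attr(x, "n1"), "x", attr(x, "n2"), "sites\n")
  NextMethod()
}

#' Export a similarity matrix for audit
#'
#' Long-format CSV with one row per positive-score pair, in the matrix's
#' deterministic sort order.
#'
#' @param sm A [build_similarity_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sm, path) {
  utils::write.csv(as.data.frame(sm), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
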