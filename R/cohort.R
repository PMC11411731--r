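#' Construct an annual facility cohort
#'
#' A `facility_cohort` is a tibble with one row per hospital site observed in
#' one reporting year. The modelled columns are `record_id` (unique within
#' the cohort), `year`, `iic` (institution identification code), `sc` (site
#' code, may be `NA`), `lat`/`lon` (WGS84 decimal degrees, may be `NA` when a
#' site could not be geocoded) and `municipality`. Additional columns
#' (name, ownership, beds, ...) are carried along untouched and are used only
#' for reporting and variable profiling, never for scoring.
#'
#' @param records A data frame holding at least `record_id`, `iic`,
#'   `lat`, `lon` and `municipality`; `sc` is optional and filled with `NA`
#'   when absent.
#' @param year Integer calendar year of the cohort.
#'
#' @return A tibble of class `facility_cohort` with a `year` attribute.
#' @examples
#' facility_cohort(
#'   data.frame(record_id = "h1", iic = "260000001", sc = "01",
#'              lat = 50.0, lon = 8.0, municipality = "Marburg"),
#'   year = 2016
#' )
#' @export
facility_cohort <- function(records, year) {
  stopifnot(is.data.frame(records))
  year <- as.integer(year)
  stopifnot(length(year) == 1, !is.na(year))
  records <- tibble::as_tibble(records)
  required <- c("record_id", "iic", "lat", "lon", "municipality")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("Cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sc" %in% names(records)) records$sc <- NA_character_
  records$record_id <- as.character(records$record_id)
  records$iic <- as.character(records$iic)
  records$sc <- as.character(records$sc)
  records$lat <- as.numeric(records$lat)
  records$lon <- as.numeric(records$lon)
  records$municipality <- as.character(records$municipality)
  records$year <- year

  if (anyDuplicated(records$record_id)) {
    dup <- unique(records$record_id[duplicated(records$record_id)])
    stop("Duplicate record_id within cohort: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(records$lat) & (records$lat < -90 | records$lat > 90) |
               !is.na(records$lon) & (records$lon < -180 | records$lon > 180))
  if (length(bad) > 0) {
    stop("Coordinates out of range (lat in [-90, 90], lon in [-180, 180]) ",
         "for record(s): ",
         paste(utils::head(records$record_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  front <- c("record_id", "year", "iic", "sc", "lat", "lon", "municipality")
  records <- records[, c(front, setdiff(names(records), front))]
  structure(records, year = year,
            class = c("facility_cohort", class(records)))
}

#' @export
print.facility_cohort <- function(x, ...) {
  cat("<facility_cohort> year", attr(x, "year"), "with", nrow(x), "sites\n")
  NextMethod()
}

cohort_year <- function(cohort) attr(cohort, "year")

#' Read an annual cohort from a CSV file
#'
#' Columns in the file are mapped onto the modelled fields through `schema`,
#' so arbitrarily named source files can be ingested without editing them.
#' Rows whose coordinates cannot be parsed or fall outside the valid
#' latitude/longitude ranges are dropped with a warning that lists the
#' offending record ids; their count and ids are also attached as the
#' `rejected` attribute of the result.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param year Calendar year of the cohort.
#' @param schema Named character vector mapping modelled field names
#'   (`record_id`, `iic`, `sc`, `lat`, `lon`, `municipality`) to column names
#'   in the file. Defaults to the identity mapping. `sc` is optional.
#' @return A [facility_cohort()].
#' @export
read_cohort <- function(path, year, schema = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("Empty cohort file: ", path, call. = FALSE)

  default <- c(record_id = "record_id", iic = "iic", sc = "sc",
               lat = "lat", lon = "lon", municipality = "municipality")
  if (!is.null(schema)) default[names(schema)] <- schema
  schema <- default

  required <- setdiff(names(schema), "sc")
  missing_cols <- required[!schema[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("Cohort file lacks required column(s): ",
         paste(schema[missing_cols], collapse = ", "),
         " (available: ", paste(names(raw), collapse = ", "), ")",
         call. = FALSE)
  }

  out <- tibble::tibble(
    record_id = raw[[schema[["record_id"]]]],
    iic = raw[[schema[["iic"]]]],
    sc = if (schema[["sc"]] %in% names(raw)) raw[[schema[["sc"]]]] else NA_character_,
    lat = suppressWarnings(as.numeric(raw[[schema[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[schema[["lon"]]]])),
    municipality = raw[[schema[["municipality"]]]]
  )
  out$sc[!is.na(out$sc) & out$sc == ""] <- NA_character_

  lat_raw <- raw[[schema[["lat"]]]]
  lon_raw <- raw[[schema[["lon"]]]]
  bad_parse <- (is.na(out$lat) & !is.na(lat_raw) & lat_raw != "") |
               (is.na(out$lon) & !is.na(lon_raw) & lon_raw != "")
  bad_range <- (!is.na(out$lat) & (out$lat < -90 | out$lat > 90)) |
               (!is.na(out$lon) & (out$lon < -180 | out$lon > 180))
  bad <- bad_parse | bad_range
  rejected <- out$record_id[bad]
  if (length(rejected) > 0) {
    warning("Dropped ", length(rejected),
            " row(s) with unparseable or out-of-range coordinates: ",
            paste(utils::head(rejected, 10), collapse = ", "),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("No valid rows remain in ", path, call. = FALSE)
  cohort <- facility_cohort(out, year = year)
  attr(cohort, "rejected") <- rejected
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] on the modelled fields: writing then reading a
#' cohort reproduces it exactly.
#'
#' @param cohort A [facility_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort and report data-quality diagnostics
#'
#' Flags patterns that experience with self-reported registry data shows to
#' be common input errors: duplicate (IIC, SC) code pairs, records at
#' identical coordinates but with different IICs (often a mis-geocoded
#' address), and missing municipality values. Validation never mutates the
#' cohort; duplicates are warnings for the analyst, not errors.
#'
#' @param cohort A [facility_cohort()].
#' @return A tibble with columns `type` (`duplicate_code`, `co_located`,
#'   `missing_municipality`), `record_ids` (semicolon-joined) and `detail`,
#'   ordered deterministically. Zero rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "facility_cohort"))
  diags <- list()

  key <- paste(cohort$iic, normalize_sc(cohort$sc), sep = "\r")
  dup_keys <- sort(unique(key[duplicated(key)]))
  for (k in dup_keys) {
    ids <- sort(cohort$record_id[key == k])
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    diags[[length(diags) + 1]] <- tibble::tibble(
      type = "duplicate_code",
      record_ids = paste(ids, collapse = ";"),
      detail = paste0("IIC=", parts[1], " SC=", parts[2])
    )
  }

  has_xy <- !is.na(cohort$lat) & !is.na(cohort$lon)
  xy <- paste(cohort$lat, cohort$lon, sep = ",")
  xy[!has_xy] <- NA
  for (p in sort(unique(xy[!is.na(xy) & duplicated(xy)]))) {
    sel <- !is.na(xy) & xy == p
    if (length(unique(cohort$iic[sel])) > 1) {
      diags[[length(diags) + 1]] <- tibble::tibble(
        type = "co_located",
        record_ids = paste(sort(cohort$record_id[sel]), collapse = ";"),
        detail = paste0("coordinates (", p, ") shared across different IICs")
      )
    }
  }

  miss <- is.na(cohort$municipality) | cohort$municipality == ""
  if (any(miss)) {
    diags[[length(diags) + 1]] <- tibble::tibble(
      type = "missing_municipality",
      record_ids = paste(sort(cohort$record_id[miss]), collapse = ";"),
      detail = paste0(sum(miss), " record(s) without municipality")
    )
  }

  if (length(diags) == 0) {
    return(tibble::tibble(type = character(), record_ids = character(),
                          detail = character()))
  }
  dplyr::arrange(dplyr::bind_rows(diags), .data$type, .data$record_ids)
}

#' Normalize a site code for comparison
#'
#' Site codes are compared exactly after trimming whitespace and leading
#' zeros, so that e.g. `"01"` and `"1"` denote the same site. `NA` stays
#' `NA`; a code consisting only of zeros normalizes to `"0"`.
#'
#' @param sc Character vector of site codes.
#' @return Normalized character vector.
#' @export
normalize_sc <- function(sc) {
  out <- trimws(as.character(sc))
  out <- sub("^0+(?=.)", "", out, perl = TRUE)
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Normalize a municipality name for comparison
#'
#' Case-folds and strips whitespace and punctuation so that formatting
#' variants of the same city name compare equal. Used by the city-crossing
#' filter; the underlying columns are never modified.
#'
#' @param x Character vector of municipality names.
#' @return Normalized character vector.
#' @export
normalize_municipality <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[[:space:][:punct:]]+", "", out)
  out[!is.na(out) & out == ""] <- NA_character_
  out
}
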