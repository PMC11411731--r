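#' Configuration for the synthetic facility-panel generator
#'
#' Defines the generative model for a multi-year panel of hospital sites
#' with known ground-truth linkage. Facilities live in municipalities laid
#' out as Gaussian clusters on a latitude/longitude patch of Germany-like
#' extent (47--55 deg N, 6--15 deg E). At each year-to-year transition every
#' facility experiences exactly one event: it persists unchanged, changes
#' its site code, changes its institution code, relocates within its
#' municipality, closes, splits off a new site, or is merged away; new
#' facilities additionally open. The default rates are the magnitudes
#' observed in national hospital-registry panels: roughly 96% of sites
#' unchanged per year, 1--6% site-code changes, about 1% institution-code
#' changes, about 0.5% relocations and a few openings/closures per thousand.
#'
#' @param n_facilities Number of facilities in the first year.
#' @param n_years Number of annual cohorts.
#' @param n_municipalities Number of municipality clusters.
#' @param p_sc_change,p_iic_change,p_relocate,p_close,p_split,p_merge
#'   Per-facility, per-transition event probabilities; whatever probability
#'   mass they leave is the probability of persisting unchanged.
#' @param p_open Expected openings per transition, as a fraction of the
#'   current cohort size.
#' @param relocation_km Typical within-municipality relocation scale:
#'   standard deviation (in km) of the Gaussian coordinate cluster, also
#'   used when drawing a relocated position.
#' @param coordinate_jitter_m Geocoding noise: each recorded coordinate is
#'   independently displaced by this many metres on average (0 = exact).
#' @param sc_regime_switch_year Optional year from which site codes are
#'   renumbered to a new 9-digit scheme, emulating a national SC system
#'   change; linking across the switch then requires `sc_mode = "iic_only"`.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   panel exactly.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_facilities = 1000,
                              n_years = 5,
                              n_municipalities = 80,
                              p_sc_change = 0.02,
                              p_iic_change = 0.009,
                              p_relocate = 0.006,
                              p_close = 0.005,
                              p_split = 0,
                              p_merge = 0,
                              p_open = 0.005,
                              relocation_km = 2,
                              coordinate_jitter_m = 0,
                              sc_regime_switch_year = NULL,
                              seed = 1) {
  probs <- c(p_sc_change = p_sc_change, p_iic_change = p_iic_change,
             p_relocate = p_relocate, p_close = p_close,
             p_split = p_split, p_merge = p_merge)
  if (any(probs < 0) || any(probs > 1) || p_open < 0 || p_open > 1) {
    stop("All event probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(probs) > 1) {
    stop("Event probabilities sum to more than 1 (",
         signif(sum(probs), 4), ")", call. = FALSE)
  }
  stopifnot(n_facilities >= 1, n_years >= 1, n_municipalities >= 1,
            relocation_km > 0, coordinate_jitter_m >= 0)
  structure(
    c(list(n_facilities = n_facilities, n_years = n_years,
           n_municipalities = n_municipalities),
      as.list(probs),
      list(p_open = p_open, p_constant = 1 - sum(probs),
           relocation_km = relocation_km,
           coordinate_jitter_m = coordinate_jitter_m,
           sc_regime_switch_year = sc_regime_switch_year,
           seed = as.integer(seed))),
    class = "simulation_config"
  )
}

# ~ km per degree of latitude; longitude scaled by cos(lat) at draw time
KM_PER_DEG <- 111.32

#' Generate a synthetic multi-year facility panel with ground truth
#'
#' Draws a first-year cohort across municipality clusters and evolves it
#' year by year under the event model of [simulation_config()]. The result
#' carries, for every adjacent year pair, the gold-standard linkage (a
#' facility has a gold pair exactly when its event that transition was not a
#' closure or merger, and openings have none) and a complete event log.
#'
#' @param config A [simulation_config()].
#' @param start_year First calendar year of the panel.
#' @return A list of class `synthetic_panel` with elements `cohorts` (list
#'   of [facility_cohort()] by year), `gold` (list of [gold_standard()] per
#'   adjacent year pair, named `"year1-year2"`), `events` (tibble: `fid`,
#'   `year`, `event`) and `config`.
#' @examples
#' panel <- generate_panel(simulation_config(n_facilities = 50, n_years = 2,
#'                                           seed = 7))
#' nrow(panel$gold[[1]])
#' @export
generate_panel <- function(config, start_year = 2016) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  start_year <- as.integer(start_year)

  muni <- tibble::tibble(
    name = sprintf("City%03d", seq_len(config$n_municipalities)),
    lat = stats::runif(config$n_municipalities, 47, 55),
    lon = stats::runif(config$n_municipalities, 6, 15)
  )

  counters <- new.env(parent = emptyenv())
  counters$fid <- 0L
  counters$iic <- 0L
  counters$sc9 <- 0L

  new_iic <- function() {
    counters$iic <- counters$iic + 1L
    sprintf("%09d", 260000000L + counters$iic)
  }
  draw_site <- function(m_idx) {
    counters$fid <- counters$fid + 1L
    sd_deg <- config$relocation_km / KM_PER_DEG
    lat <- muni$lat[m_idx] + stats::rnorm(1, 0, sd_deg)
    lon <- muni$lon[m_idx] +
      stats::rnorm(1, 0, sd_deg / cos(muni$lat[m_idx] * pi / 180))
    tibble::tibble(
      fid = sprintf("f%05d", counters$fid),
      iic = new_iic(), sc = "01",
      lat = lat, lon = lon,
      municipality = muni$name[m_idx], m_idx = m_idx,
      beds = stats::rpois(1, 250) + 20L
    )
  }
  new_sc <- function(old, post_switch) {
    if (post_switch) {
      counters$sc9 <- counters$sc9 + 1L
      sprintf("%09d", 770000000L + counters$sc9)
    } else {
      # next two-digit code, distinct from the old one
      cur <- suppressWarnings(as.integer(old))
      sprintf("%02d", if (is.na(cur)) 2L else cur %% 98L + 1L)
    }
  }
  relocate <- function(state, i) {
    sd_deg <- config$relocation_km / KM_PER_DEG
    m_idx <- state$m_idx[i]
    repeat {
      lat <- muni$lat[m_idx] + stats::rnorm(1, 0, sd_deg)
      lon <- muni$lon[m_idx] +
        stats::rnorm(1, 0, sd_deg / cos(muni$lat[m_idx] * pi / 180))
      moved_km <- haversine_distance(c(state$lat[i], state$lon[i]), c(lat, lon))
      if (moved_km > 0.05) break  # a relocation must be a visible move
    }
    state$lat[i] <- lat
    state$lon[i] <- lon
    state
  }

  state <- dplyr::bind_rows(lapply(
    sample.int(config$n_municipalities, config$n_facilities, replace = TRUE),
    draw_site
  ))

  years <- start_year + seq_len(config$n_years) - 1L
  cohorts <- list()
  gold <- list()
  events <- list()

  post_switch <- function(year) {
    !is.null(config$sc_regime_switch_year) &&
      year >= config$sc_regime_switch_year
  }
  renumber_if_switch <- function(state, year) {
    if (post_switch(year)) {
      old <- !startsWith(state$sc, "77")
      state$sc[old] <- vapply(state$sc[old], function(s) new_sc(s, TRUE),
                              character(1))
    }
    state
  }

  state <- renumber_if_switch(state, years[1])
  cohorts[[as.character(years[1])]] <- state_to_cohort(state, years[1], config)

  for (k in seq_len(config$n_years - 1)) {
    y1 <- years[k]
    y2 <- years[k + 1]
    n <- nrow(state)
    u <- stats::runif(n)
    edges <- cumsum(c(config$p_sc_change, config$p_iic_change,
                      config$p_relocate, config$p_close,
                      config$p_split, config$p_merge))
    ev <- c("sc_change", "iic_change", "relocate", "close", "split",
            "merge", "constant")[findInterval(u, edges) + 1L]

    next_state <- state
    survivors <- rep(TRUE, n)
    newborn <- list()
    for (i in seq_len(n)) {
      e <- ev[i]
      if (e == "sc_change") {
        next_state$sc[i] <- new_sc(state$sc[i], post_switch(y2))
      } else if (e == "iic_change") {
        next_state$iic[i] <- new_iic()
      } else if (e == "relocate") {
        next_state <- relocate(next_state, i)
      } else if (e %in% c("close", "merge")) {
        survivors[i] <- FALSE
      } else if (e == "split") {
        # continuing site keeps codes; the split-off site opens nearby
        # under the same IIC with a new SC
        child <- draw_site(state$m_idx[i])
        child$iic <- state$iic[i]
        child$sc <- new_sc(state$sc[i], post_switch(y2))
        newborn[[length(newborn) + 1]] <- child
      }
      events[[length(events) + 1]] <- tibble::tibble(
        fid = state$fid[i], year = y1, event = e
      )
    }

    n_open <- stats::rbinom(1, n, config$p_open)
    for (j in seq_len(n_open)) {
      child <- draw_site(sample.int(config$n_municipalities, 1))
      if (post_switch(y2)) child$sc <- new_sc(child$sc, TRUE)
      newborn[[length(newborn) + 1]] <- child
      events[[length(events) + 1]] <- tibble::tibble(
        fid = child$fid, year = y1, event = "open"
      )
    }

    gold[[paste(y1, y2, sep = "-")]] <- gold_standard(
      record_id_for(state$fid[survivors], y1),
      record_id_for(state$fid[survivors], y2)
    )

    state <- dplyr::bind_rows(next_state[survivors, , drop = FALSE],
                              dplyr::bind_rows(newborn))
    state <- renumber_if_switch(state, y2)
    cohorts[[as.character(y2)]] <- state_to_cohort(state, y2, config)
  }

  structure(
    list(cohorts = cohorts, gold = gold,
         events = if (length(events)) dplyr::bind_rows(events) else
           tibble::tibble(fid = character(), year = integer(),
                          event = character()),
         config = config),
    class = "synthetic_panel"
  )
}

record_id_for <- function(fid, year) {
  if (length(fid) == 0) return(character(0))
  paste0("y", year, "_", fid)
}

state_to_cohort <- function(state, year, config) {
  lat <- state$lat
  lon <- state$lon
  if (config$coordinate_jitter_m > 0) {
    sd_deg <- config$coordinate_jitter_m / 1000 / KM_PER_DEG
    lat <- lat + stats::rnorm(length(lat), 0, sd_deg)
    lon <- lon + stats::rnorm(length(lon), 0, sd_deg)
  }
  facility_cohort(
    tibble::tibble(
      record_id = record_id_for(state$fid, year),
      iic = state$iic, sc = state$sc,
      lat = lat, lon = lon,
      municipality = state$municipality,
      beds = state$beds
    ),
    year = year
  )
}

#' @export
print.synthetic_panel <- function(x, ...) {
  sizes <- vapply(x$cohorts, nrow, integer(1))
  cat("<synthetic_panel>", length(x$cohorts), "years,",
      paste(names(sizes), "=", sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Corrupt a fraction of addresses in a synthetic panel
#'
#' Emulates single-year address input errors: each facility is selected
#' independently with probability `error_rate`, and in exactly one randomly
#' chosen year of its presence its recorded coordinates are displaced by
#' 0.1--1 km (well above any zero-distance tolerance). Corrupted records are
#' appended to the event log as `address_error` events. Gold-standard pairs
#' are unaffected — the errors are in the recorded data, not in the truth.
#'
#' @param panel A [generate_panel()] result.
#' @param error_rate Per-facility probability of one corrupted year.
#' @param seed Integer seed for the corruption draws.
#' @return The modified `synthetic_panel`.
#' @export
perturb_addresses <- function(panel, error_rate, seed = 1) {
  stopifnot(inherits(panel, "synthetic_panel"),
            error_rate >= 0, error_rate <= 1)
  if (error_rate == 0) return(panel)
  set.seed(as.integer(seed))

  presence <- list()
  for (yr in names(panel$cohorts)) {
    ids <- panel$cohorts[[yr]]$record_id
    fid <- sub("^y[0-9]+_", "", ids)
    presence[[yr]] <- fid
  }
  all_fids <- sort(unique(unlist(presence)))
  hit <- all_fids[stats::runif(length(all_fids)) < error_rate]

  new_events <- list()
  for (f in hit) {
    yrs <- names(presence)[vapply(presence, function(p) f %in% p, logical(1))]
    yr <- if (length(yrs) == 1) yrs else sample(yrs, 1)
    cohort <- panel$cohorts[[yr]]
    i <- match(record_id_for(f, as.integer(yr)), cohort$record_id)
    bearing <- stats::runif(1, 0, 2 * pi)
    shift_km <- stats::runif(1, 0.1, 1)
    cohort$lat[i] <- cohort$lat[i] + shift_km * cos(bearing) / KM_PER_DEG
    cohort$lon[i] <- cohort$lon[i] + shift_km * sin(bearing) /
      (KM_PER_DEG * cos(cohort$lat[i] * pi / 180))
    panel$cohorts[[yr]] <- cohort
    new_events[[length(new_events) + 1]] <- tibble::tibble(
      fid = f, year = as.integer(yr), event = "address_error"
    )
  }
  if (length(new_events)) {
    panel$events <- dplyr::bind_rows(panel$events,
                                     dplyr::bind_rows(new_events))
  }
  panel
}

#' Write a synthetic panel's cohorts and gold standards to CSV files
#'
#' Emits one cohort CSV per year (`cohort_<year>.csv`) and one gold CSV per
#' adjacent year pair (`gold_<y1>-<y2>.csv`) into a directory, in the
#' formats [read_cohort()] and [read_gold()] consume.
#'
#' @param panel A `synthetic_panel`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_panel_csvs <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (yr in names(panel$cohorts)) {
    write_cohort(panel$cohorts[[yr]], file.path(dir,
                                                paste0("cohort_", yr, ".csv")))
  }
  for (span in names(panel$gold)) {
    utils::write.csv(as.data.frame(panel$gold[[span]]),
                     file.path(dir, paste0("gold_", span, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}
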