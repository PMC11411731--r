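# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive re-derivations (exhaustive scans, set
# arithmetic) that never call the code paths they check.

mk_cohort <- function(id, iic, sc = "01", lat = 50, lon = 8,
                      municipality = "Marburg", year = 2016, ...) {
  facility_cohort(
    data.frame(record_id = id, iic = iic, sc = sc, lat = lat, lon = lon,
               municipality = municipality, ...),
    year = year
  )
}

# random cohort pair over a small municipality layout; codes overlap
# between years so all code-score branches are exercised
random_cohort_pair <- function(n1, n2, seed, n_muni = 3, share_codes = 0.6) {
  set.seed(seed)
  centers <- data.frame(m = paste0("town", seq_len(n_muni)),
                        lat = runif(n_muni, 48, 54),
                        lon = runif(n_muni, 7, 14))
  draw <- function(n, year, iic_pool) {
    m <- sample(n_muni, n, replace = TRUE)
    data.frame(
      record_id = sprintf("y%d_%02d", year, seq_len(n)),
      iic = sample(iic_pool, n, replace = TRUE),
      sc = sample(c("01", "02", NA), n, replace = TRUE),
      lat = centers$lat[m] + rnorm(n, 0, 0.03),
      lon = centers$lon[m] + rnorm(n, 0, 0.03),
      municipality = centers$m[m]
    )
  }
  pool <- sprintf("I%03d", seq_len(max(3, ceiling((n1 + n2) * share_codes / 2))))
  list(
    c1 = facility_cohort(draw(n1, 2016, pool), 2016),
    c2 = facility_cohort(draw(n2, 2017, pool), 2017)
  )
}

# brute-force spherical distance, written independently of R/geo.R
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, r_km = 6371) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad; dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r_km * asin(pmin(1, sqrt(a)))
}

# exhaustive per-row/col argmin over an explicit loop, with the same
# epsilon snapping contract
oracle_nearest <- function(cohort1, cohort2, eps_m = 10, tol = 1e-9) {
  d <- matrix(NA_real_, nrow(cohort1), nrow(cohort2))
  for (i in seq_len(nrow(cohort1))) {
    for (j in seq_len(nrow(cohort2))) {
      d[i, j] <- oracle_haversine_km(cohort1$lat[i], cohort1$lon[i],
                                     cohort2$lat[j], cohort2$lon[j])
    }
  }
  d[d <= eps_m / 1000] <- 0
  fwd <- lapply(seq_len(nrow(d)), function(i) {
    m <- min(d[i, ]); cohort2$record_id[d[i, ] <= m + tol]
  })
  bwd <- lapply(seq_len(ncol(d)), function(j) {
    m <- min(d[, j]); cohort1$record_id[d[, j] <= m + tol]
  })
  list(d = d, fwd = fwd, bwd = bwd)
}

# independent one-or-none selection: repeatedly scan the full candidate
# table for the best remaining pair (no sorting machinery shared with R/)
oracle_select <- function(cand, threshold = 1) {
  cand <- cand[cand$total >= threshold, , drop = FALSE]
  acc <- list(); queued <- list()
  taken1 <- character(0); taken2 <- character(0)
  repeat {
    avail <- !(cand$id1 %in% taken1) & !(cand$id2 %in% taken2)
    if (!any(avail)) break
    best_total <- max(cand$total[avail])
    pool <- which(avail & cand$total == best_total)
    # pick by distance then ids among the pool
    ord <- pool[order(cand$distance_km[pool], cand$id1[pool],
                      cand$id2[pool], na.last = TRUE)]
    i <- ord[1]
    # tie cluster: same-total available pairs transitively sharing endpoints
    cluster <- i
    repeat {
      grow <- pool[cand$id1[pool] %in% cand$id1[cluster] |
                   cand$id2[pool] %in% cand$id2[cluster]]
      if (length(setdiff(grow, cluster)) == 0) break
      cluster <- union(cluster, grow)
    }
    if (length(cluster) > 1) {
      queued[[length(queued) + 1]] <- cand[sort(cluster), , drop = FALSE]
      taken1 <- c(taken1, cand$id1[cluster])
      taken2 <- c(taken2, cand$id2[cluster])
    } else {
      acc[[length(acc) + 1]] <- cand[i, , drop = FALSE]
      taken1 <- c(taken1, cand$id1[i])
      taken2 <- c(taken2, cand$id2[i])
    }
  }
  list(accepted = if (length(acc)) do.call(rbind, acc) else
         cand[0, , drop = FALSE],
       queued = queued)
}

# exhaustive maximum-total one-to-one matching on tiny instances
oracle_best_matching <- function(cand) {
  best <- 0
  n <- nrow(cand)
  recurse <- function(i, used1, used2, sum) {
    if (i > n) { best <<- max(best, sum); return(invisible()) }
    recurse(i + 1, used1, used2, sum)
    if (!(cand$id1[i] %in% used1) && !(cand$id2[i] %in% used2)) {
      recurse(i + 1, c(used1, cand$id1[i]), c(used2, cand$id2[i]),
              sum + cand$total[i])
    }
  }
  recurse(1, character(0), character(0), 0)
  best
}
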