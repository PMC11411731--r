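test_that("the highest-scoring candidate wins and lower ones are discarded", {
  # A's candidates: B (same codes, same place, 8) and C (same IIC only, 2)
  c1 <- mk_cohort("A", "X", "01")
  c2 <- mk_cohort(c("B", "C"), c("X", "X"), c("01", "02"),
                  lat = c(50, 50.3), lon = c(8, 8), year = 2017)
  run <- select_linkages(build_similarity_matrix(c1, c2))
  expect_equal(nrow(run$accepted), 1)
  expect_equal(run$accepted$id2, "B")
  expect_equal(run$accepted$total, 8L)
  expect_equal(nrow(run$review_queue), 0)
  expect_equal(run$unlinked_year2, "C")
})

test_that("tied top scores go to the review queue, facility left unlinked", {
  # B1, B2 both share A's IIC-SC and are equidistant: two candidates at 6
  c1 <- mk_cohort("A", "X", "01", lat = 50, lon = 8)
  c2 <- mk_cohort(c("B1", "B2"), c("X", "X"), c("01", "01"),
                  lat = c(50, 50), lon = c(7.99, 8.01), year = 2017)
  links <- select_linkages(build_similarity_matrix(c1, c2))
  expect_equal(nrow(links$accepted), 0)
  expect_equal(nrow(links$review_queue), 2)
  expect_equal(length(unique(links$review_queue$group_id)), 1)
  # provisionally unlinked: not in unlinked lists, pending review
  expect_false("A" %in% links$unlinked_year1)

  # manual resolution merges the chosen pair back
  resolved <- resolve_review(links, data.frame(
    group_id = links$review_queue$group_id[1],
    id1 = "A", id2 = "B1"
  ))
  expect_equal(resolved$accepted$id2, "B1")
  expect_equal(nrow(resolved$review_queue), 0)
  expect_true("B2" %in% resolved$unlinked_year2)
})

test_that("a tie broken by an already-matched endpoint is no tie", {
  # all four sites co-located, one IIC: (A1,B1), (A1,B2), (A2,B1) all score
  # 6, (A2,B2) scores 8. Once A2-B2 is matched at 8, A1's only remaining
  # candidate is B1 -> no tie, no review
  c1 <- mk_cohort(c("A1", "A2"), c("X", "X"), c("01", "03"),
                  lat = c(50, 50), lon = c(8, 8))
  c2 <- mk_cohort(c("B1", "B2"), c("X", "X"), c("02", "03"),
                  lat = c(50, 50), lon = c(8, 8), year = 2017)
  links <- select_linkages(build_similarity_matrix(c1, c2))
  expect_equal(nrow(links$review_queue), 0)
  acc <- links$accepted[order(links$accepted$id1), ]
  expect_equal(acc$id1, c("A1", "A2"))
  expect_equal(acc$id2, c("B1", "B2"))
  expect_equal(acc$total, c(6L, 8L))
})

test_that("selection agrees with an independent oracle on random instances", {
  for (seed in 1:60) {
    set.seed(seed)
    pair <- random_cohort_pair(sample(3:20, 1), sample(3:20, 1), seed = seed)
    sm <- build_similarity_matrix(pair$c1, pair$c2)
    links <- select_linkages(sm)
    oracle <- oracle_select(as.data.frame(sm))
    key <- function(d) sort(paste(d$id1, d$id2))
    expect_equal(key(links$accepted), key(oracle$accepted),
                 info = paste("seed", seed))
    expect_equal(nrow(links$review_queue),
                 sum(vapply(oracle$queued, nrow, integer(1))))
  }
})

test_that("greedy selection attains the exhaustive-matching optimum on tie-free instances", {
  agree <- 0; total_checked <- 0
  for (seed in 101:140) {
    set.seed(seed)
    pair <- random_cohort_pair(sample(2:6, 1), sample(2:6, 1), seed = seed)
    sm <- build_similarity_matrix(pair$c1, pair$c2)
    if (nrow(sm) == 0 || nrow(sm) > 12) next
    links <- select_linkages(sm)
    if (nrow(links$review_queue) > 0) next  # ties defer to manual review
    best <- oracle_best_matching(as.data.frame(sm))
    total_checked <- total_checked + 1
    if (sum(links$accepted$total) == best) agree <- agree + 1
    expect_lte(sum(links$accepted$total), best)
  }
  expect_gte(total_checked, 10)
  # greedy is not guaranteed optimal, but must coincide in the large majority
  expect_gte(agree / total_checked, 0.8)
})

test_that("one-or-none holds after selection and filtering", {
  for (seed in 1:15) {
    pair <- random_cohort_pair(12, 12, seed = seed)
    run <- link_cohorts(pair$c1, pair$c2)
    acc <- run$links$accepted
    expect_false(anyDuplicated(acc$id1) > 0)
    expect_false(anyDuplicated(acc$id2) > 0)
    expect_true(all(acc$total >= 1))
    # counting identity on both sides
    queued1 <- unique(run$links$review_queue$id1)
    queued2 <- unique(run$links$review_queue$id2)
    expect_equal(nrow(acc) + length(run$links$unlinked_year1) +
                   length(queued1), nrow(pair$c1))
    expect_equal(nrow(acc) + length(run$links$unlinked_year2) +
                   length(queued2), nrow(pair$c2))
  }
})

test_that("raising the threshold never increases accepted linkages", {
  pair <- random_cohort_pair(15, 15, seed = 5)
  sm <- build_similarity_matrix(pair$c1, pair$c2)
  counts <- vapply(1:8, function(thr) {
    nrow(select_linkages(sm, link_config(tolerance_threshold = thr))$accepted)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the municipality filter rejects cross-city links and only those", {
  c1 <- mk_cohort(c("A1", "A2"), c("X", "Y"), c("01", "01"),
                  lat = c(50, 51), lon = c(8, 9),
                  municipality = c("Marburg", "Gießen"))
  c2 <- mk_cohort(c("B1", "B2"), c("X", "Y"), c("01", "01"),
                  lat = c(50, 51), lon = c(9, 9),
                  municipality = c("Gießen", "  gießen "), year = 2017)
  sm <- build_similarity_matrix(c1, c2)
  links <- select_linkages(sm)
  filtered <- apply_city_filter(links, c1, c2)
  # A1 (Marburg) -> B1 (Gießen) crosses; A2 matches up to normalization
  expect_equal(filtered$rejected_cross_city$id1, "A1")
  expect_true("A1" %in% filtered$unlinked_year1)
  expect_true("B1" %in% filtered$unlinked_year2)
  expect_true("A2" %in% filtered$accepted$id1)
  # disabled filter is the identity
  off <- apply_city_filter(links, c1, c2,
                           link_config(same_municipality_required = FALSE))
  expect_equal(off$accepted, links$accepted)
  expect_equal(nrow(off$rejected_cross_city), 0)
})

test_that("a missing municipality keeps the pair with a warning", {
  c1 <- mk_cohort("A", "X", municipality = NA)
  c2 <- mk_cohort("B", "X", year = 2017)
  links <- select_linkages(build_similarity_matrix(c1, c2))
  expect_warning(filtered <- apply_city_filter(links, c1, c2), "missing")
  expect_equal(nrow(filtered$accepted), 1)
})

test_that("continuity types follow the linkage outcome", {
  # A1-B1 constant (8); A2-B2 changed (6); A3 closes; B3 opens
  c1 <- mk_cohort(c("A1", "A2", "A3"), c("X", "Y", "Z"),
                  c("01", "01", "01"),
                  lat = c(50, 50.5, 51), lon = c(8, 8, 8))
  c2 <- mk_cohort(c("B1", "B2", "B3"), c("X", "Y", "Q"),
                  c("01", "02", "01"),
                  lat = c(50, 50.5, 53), lon = c(8, 8, 8), year = 2017)
  # threshold 2: a lone one-way-nearest score of 1 is not an acceptable link
  run <- link_cohorts(c1, c2, link_config(tolerance_threshold = 2))
  ct <- run$continuity
  get <- function(id) ct[ct$record_id == id, ]
  expect_equal(get("A1")$continuity_type, 1L)
  expect_equal(get("B1")$continuity_type, 1L)
  expect_equal(get("A2")$continuity_type, 2L)
  expect_equal(get("B2")$type_label, "changed")
  expect_equal(get("A3")$type_label, "closed")
  expect_equal(get("B3")$type_label, "newly_opened")
  expect_false(any(ct$division_flag | ct$merge_flag))
})

test_that("division appears as changed + opened with the division flag", {
  # one year-one facility with two above-threshold candidates
  c1 <- mk_cohort("A", "X", "01", lat = 50, lon = 8)
  c2 <- mk_cohort(c("B1", "B2"), c("X", "X"), c("01", "02"),
                  lat = c(50, 50.02), lon = c(8, 8), year = 2017)
  run <- link_cohorts(c1, c2)
  expect_equal(run$links$accepted$id2, "B1")  # higher score wins
  ct <- run$continuity
  expect_equal(ct$continuity_type[ct$record_id == "A"], 1L)
  expect_true(ct$division_flag[ct$record_id == "A"])
  expect_equal(ct$type_label[ct$record_id == "B2"], "newly_opened")
  # symmetric merge flag
  run2 <- link_cohorts(
    mk_cohort(c("A1", "A2"), c("X", "X"), c("01", "02"),
              lat = c(50, 50.02), lon = c(8, 8)),
    mk_cohort("B", "X", "01", lat = 50, lon = 8, year = 2017)
  )
  ct2 <- run2$continuity
  expect_true(ct2$merge_flag[ct2$record_id == "B"])
  expect_equal(ct2$type_label[ct2$record_id == "A2"], "closed")
})
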