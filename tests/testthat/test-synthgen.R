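test_that("the same seed and config reproduce the panel exactly", {
  cfg <- simulation_config(n_facilities = 80, n_years = 3, seed = 17)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$cohorts, p2$cohorts)
  expect_identical(p1$gold, p2$gold)
  expect_identical(p1$events, p2$events)
  # and a different seed does not
  p3 <- generate_panel(simulation_config(n_facilities = 80, n_years = 3,
                                         seed = 18))
  expect_false(identical(p1$cohorts, p3$cohorts))
})

test_that("an all-constant panel is identical up to ids, gold = identity", {
  panel <- generate_panel(simulation_config(
    n_facilities = 30, n_years = 3, p_sc_change = 0, p_iic_change = 0,
    p_relocate = 0, p_close = 0, p_open = 0, seed = 5
  ))
  for (k in 1:2) {
    a <- panel$cohorts[[k]]; b <- panel$cohorts[[k + 1]]
    expect_equal(a$iic, b$iic)
    expect_equal(a$sc, b$sc)
    expect_equal(a$lat, b$lat)
    expect_equal(a$lon, b$lon)
    g <- panel$gold[[k]]
    expect_equal(nrow(g), 30)
    expect_equal(sub("^y[0-9]+_", "", g$id_year1),
                 sub("^y[0-9]+_", "", g$id_year2))
  }
  expect_true(all(panel$events$event == "constant"))
})

test_that("certain closure empties the next cohort and the gold standard", {
  panel <- generate_panel(simulation_config(
    n_facilities = 10, n_years = 2, p_sc_change = 0, p_iic_change = 0,
    p_relocate = 0, p_close = 1, p_open = 0, seed = 5
  ))
  expect_equal(nrow(panel$cohorts[[2]]), 0)
  expect_equal(nrow(panel$gold[[1]]), 0)
})

test_that("realized event counts stay within 3 binomial standard deviations", {
  n <- 1000
  cfg <- simulation_config(n_facilities = n, n_years = 2, seed = 23)
  panel <- generate_panel(cfg)
  tab <- table(panel$events$event)
  for (ev in c("sc_change", "iic_change", "relocate", "close")) {
    p <- cfg[[paste0("p_", ev)]]
    got <- if (ev %in% names(tab)) tab[[ev]] else 0
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1,
              label = paste(ev, "count", got))
  }
})

test_that("the event log reproduces the gold standard exactly", {
  panel <- generate_panel(simulation_config(
    n_facilities = 200, n_years = 3, p_sc_change = 0.05, p_iic_change = 0.01,
    p_relocate = 0.01, p_close = 0.02, p_open = 0.02, seed = 9
  ))
  years <- as.integer(names(panel$cohorts))
  for (k in seq_len(length(years) - 1)) {
    y <- years[k]
    ev <- panel$events[panel$events$year == y, ]
    surviving <- ev$fid[!ev$event %in% c("close", "merge", "open")]
    g <- panel$gold[[k]]
    expect_setequal(sub("^y[0-9]+_", "", g$id_year1), surviving)
  }
})

test_that("gold pairs are matchings and exist in their cohorts", {
  panel <- generate_panel(simulation_config(n_facilities = 150, n_years = 4,
                                            p_split = 0.01, p_merge = 0.01,
                                            seed = 13))
  years <- names(panel$cohorts)
  for (k in seq_len(length(years) - 1)) {
    g <- panel$gold[[k]]
    expect_false(anyDuplicated(g$id_year1) > 0)
    expect_false(anyDuplicated(g$id_year2) > 0)
    expect_true(all(g$id_year1 %in% panel$cohorts[[years[k]]]$record_id))
    expect_true(all(g$id_year2 %in% panel$cohorts[[years[k + 1]]]$record_id))
  }
})

test_that("split events add a same-IIC site; open events add new facilities", {
  panel <- generate_panel(simulation_config(n_facilities = 100, n_years = 2,
                                            p_split = 0.2, p_open = 0.1,
                                            p_close = 0, seed = 3))
  ev <- panel$events
  n_split <- sum(ev$event == "split")
  n_open <- sum(ev$event == "open")
  expect_gt(n_split, 0)
  expect_gt(n_open, 0)
  expect_equal(nrow(panel$cohorts[[2]]), 100 + n_split + n_open)
  # split children share the parent IIC
  parents <- ev$fid[ev$event == "split"]
  c2 <- panel$cohorts[[2]]
  parent_iic <- panel$cohorts[[1]]$iic[
    match(paste0("y2016_", parents), panel$cohorts[[1]]$record_id)]
  expect_true(all(vapply(parent_iic, function(i) sum(c2$iic == i) >= 2,
                         logical(1))))
})

test_that("the SC regime switch renumbers site codes without touching gold", {
  cfg <- simulation_config(n_facilities = 50, n_years = 3,
                           p_sc_change = 0, p_iic_change = 0,
                           p_relocate = 0, p_close = 0, p_open = 0,
                           sc_regime_switch_year = 2018, seed = 6)
  panel <- generate_panel(cfg)
  expect_false(any(startsWith(panel$cohorts[["2017"]]$sc, "77")))
  expect_true(all(startsWith(panel$cohorts[["2018"]]$sc, "77")))
  expect_equal(nrow(panel$gold[["2017-2018"]]), 50)
  # across the switch the full method needs the IIC-only regime
  links_iic <- link_cohorts(panel$cohorts[["2017"]], panel$cohorts[["2018"]],
                            link_config(sc_mode = "iic_only"))$links
  rep <- score_against_gold(links_iic, panel$gold[["2017-2018"]])
  expect_equal(rep$true_rate, 100)
  # the code-only baseline with full SC comparison misses everything
  base <- baseline_code_linker(panel$cohorts[["2017"]],
                               panel$cohorts[["2018"]], mode = "full")
  expect_equal(nrow(base$accepted), 0)
})

test_that("address perturbation corrupts one year per hit facility", {
  panel <- generate_panel(simulation_config(
    n_facilities = 1, n_years = 3, p_sc_change = 0, p_iic_change = 0,
    p_relocate = 0, p_close = 0, p_open = 0, seed = 2
  ))
  same <- perturb_addresses(panel, 0)
  expect_identical(same$cohorts, panel$cohorts)

  pert <- perturb_addresses(panel, 1, seed = 7)
  errs <- pert$events[pert$events$event == "address_error", ]
  expect_equal(nrow(errs), 1)
  moved <- vapply(names(panel$cohorts), function(yr) {
    any(panel$cohorts[[yr]]$lat != pert$cohorts[[yr]]$lat |
        panel$cohorts[[yr]]$lon != pert$cohorts[[yr]]$lon)
  }, logical(1))
  expect_equal(sum(moved), 1)
  expect_equal(as.integer(names(which(moved))), errs$year)
})

test_that("corrupted records link with a reduced location sub-score", {
  panel <- generate_panel(simulation_config(
    n_facilities = 40, n_years = 2, p_sc_change = 0, p_iic_change = 0,
    p_relocate = 0, p_close = 0, p_open = 0, seed = 8
  ))
  pert <- perturb_addresses(panel, 0.3, seed = 9)
  errs <- pert$events[pert$events$event == "address_error", ]
  expect_gt(nrow(errs), 0)
  links <- link_cohorts(pert$cohorts[[1]], pert$cohorts[[2]])$links
  acc <- links$accepted
  hit_fids <- errs$fid
  fid_of <- function(id) sub("^y[0-9]+_", "", id)
  # clean facilities score 8; corrupted ones link on codes at total < 8
  clean <- acc[!(fid_of(acc$id1) %in% hit_fids), ]
  corrupted <- acc[fid_of(acc$id1) %in% hit_fids, ]
  expect_true(all(clean$total == 8))
  expect_true(all(corrupted$total < 8))
  expect_true(all(corrupted$code_subscore == 4))
})

test_that("invalid rates are rejected", {
  expect_error(simulation_config(p_sc_change = 0.7, p_close = 0.5), "sum")
  expect_error(simulation_config(p_relocate = -0.1), "\\[0, 1\\]")
})

test_that("panel CSV export is consumable by the readers", {
  panel <- generate_panel(simulation_config(n_facilities = 20, n_years = 2,
                                            seed = 14))
  dir <- withr::local_tempdir()
  write_panel_csvs(panel, dir)
  back <- read_cohort(file.path(dir, "cohort_2016.csv"), 2016)
  expect_equal(back$record_id, panel$cohorts[[1]]$record_id)
  expect_equal(back$lat, panel$cohorts[[1]]$lat)
  g <- read_gold(file.path(dir, "gold_2016-2017.csv"))
  expect_equal(as.data.frame(g), as.data.frame(panel$gold[[1]]))
})
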