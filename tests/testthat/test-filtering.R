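test_that("each filter rule removes exactly its violators", {
  cases <- list(
    list(cl = mk_checklist("ok", dur = 60), keep = TRUE, rule = NA),
    list(cl = mk_checklist("short", dur = 4), keep = FALSE, rule = "duration"),
    list(cl = mk_checklist("edge5", dur = 5), keep = FALSE, rule = "duration"),
    list(cl = mk_checklist("long", dur = 241), keep = FALSE, rule = "duration"),
    list(cl = mk_checklist("far", dist = 6), keep = FALSE, rule = "distance_area"),
    list(cl = mk_checklist("area_big", dist = NA_real_, area = 600), keep = FALSE,
         rule = "distance_area"),
    list(cl = mk_checklist("stationary", dist = NA_real_), keep = TRUE, rule = NA),
    list(cl = mk_checklist("night", start = 3), keep = FALSE, rule = "diurnal"),
    list(cl = mk_checklist("incomplete", complete = FALSE), keep = FALSE,
         rule = "complete"),
    list(cl = mk_checklist("four_species", n_sp = 4), keep = FALSE,
         rule = "list_length"),
    list(cl = mk_checklist("five_species", n_sp = 5), keep = TRUE, rule = NA)
  )
  for (case in cases) {
    res <- quiet(filter_checklists(case$cl))
    expect_equal(nrow(res$checklists) == 1, case$keep, label = case$cl$checklist_id)
    if (!case$keep) {
      expect_equal(res$report$rule[res$report$removed == 1], case$rule,
                   label = case$cl$checklist_id)
    }
  }
})

test_that("the 8-checklist audit fixture retains 5 with the constructed attrition", {
  path <- system.file("extdata", "filter_fixture.tsv", package = "samplingvalue")
  cl <- collapse_to_checklists(quiet(read_observations(path)))
  expect_equal(nrow(cl), 8)
  res <- quiet(filter_checklists(cl))
  expect_setequal(res$checklists$checklist_id, c("F1", "F2", "F6", "F7", "F8"))
  removed <- setNames(res$report$removed, res$report$rule)
  expect_equal(removed[["complete"]], 1)       # F3 incomplete
  expect_equal(removed[["duration"]], 1)       # F4: 4 minutes
  expect_equal(removed[["distance_area"]], 1)  # F5: 6 km travelled
  expect_equal(removed[["diurnal"]], 0)
  expect_equal(removed[["list_length"]], 0)
  expect_equal(attr(res$report, "n_input") - sum(res$report$removed),
               attr(res$report, "n_retained"))
})

test_that("species selection applies the strict observation threshold and allow-list", {
  cl <- dplyr::bind_rows(lapply(1:51, function(i) {
    out <- mk_checklist(sprintf("C%02d", i), n_sp = 5)
    out$species_observed <- list(c("Common", if (i <= 50) "Borderline"))
    out
  }))
  cfg <- filter_config()
  expect_equal(quiet(select_species(cl, cfg)), "Common")  # 51 vs 50 observations
  cfg_allow <- filter_config(terrestrial_species = "Waterbird")
  expect_error(select_species(cl, cfg_allow), "threshold")
  cfg_low <- filter_config(species_min_obs_exclusive = 10,
                           terrestrial_species = "Borderline")
  expect_equal(select_species(cl, cfg_low), "Borderline")
})

test_that("filtering is idempotent and monotone in its thresholds", {
  chain <- world_chain(world_config(n_checklists = 400, n_species = 12,
                                    width_km = 40, height_km = 40), seed = 21)
  once <- quiet(filter_checklists(chain$checklists))
  twice <- quiet(filter_checklists(once$checklists))
  expect_equal(nrow(twice$checklists), nrow(once$checklists))
  expect_true(all(twice$report$removed == 0))

  n_kept <- function(cfg) nrow(quiet(filter_checklists(chain$checklists, cfg))$checklists)
  base <- n_kept(filter_config())
  expect_lte(n_kept(filter_config(min_duration_minutes = 20)), base)
  expect_lte(n_kept(filter_config(max_distance_km = 2)), base)
  expect_lte(n_kept(filter_config(min_species_exclusive = 6)), base)
  expect_lte(n_kept(filter_config(diurnal_window = c(7, 17))), base)
})
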