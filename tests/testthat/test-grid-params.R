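test_that("grids tile the region deterministically", {
  g <- make_grid(c(0, 20, 0, 20), 5)
  expect_equal(nrow(g$cells), 16)
  expect_equal(g$cells$cell_id, 1:16)
  expect_equal(g$cells$cx[[1]], 2.5)

  g1 <- make_grid(c(0, 20, 0, 20), 50)
  expect_equal(nrow(g1$cells), 1)

  expect_error(make_grid(c(0, 20, 0, 20), 0), "side_km")
  expect_error(make_grid(c(150, 151, -34, -33), 5, crs = "lonlat"), "anchor")
  gll <- make_grid(c(150, 151, -34, -33), 5, crs = "lonlat", anchor = c(150, -34))
  expect_gt(nrow(gll$cells), 100)  # ~92 x 111 km of ground
})

test_that("points are assigned by the half-open cell convention", {
  g <- make_grid(c(0, 20, 0, 20), 5)
  pts <- tibble::tibble(
    checklist_id = c("centroid", "edge", "outside"),
    x = c(2.5, 5, 25), y = c(2.5, 2.5, 2.5)
  )
  a <- quiet(assign_cells(pts, g))
  expect_equal(a$cell_id[a$checklist_id == "centroid"], 1L)
  # a point on the shared edge belongs to the cell it half-opens into
  expect_equal(a$cell_id[a$checklist_id == "edge"], 2L)
  expect_false("outside" %in% a$checklist_id)
  expect_equal(attr(a, "n_dropped"), 1)
})

test_that("sampling-history parameters match hand computation", {
  g <- make_grid(c(0, 20, 0, 20), 5)
  hist <- readr::read_csv(system.file("extdata", "grid_fixture.csv",
                                      package = "samplingvalue"),
                          show_col_types = FALSE)
  hist$date <- as.Date(hist$date)
  p <- daily_parameters(g, hist, as.Date("2018-01-10"))

  # cell 6 sampled on days 1, 3, 7 -> gaps {2, 4}, queried on day 10
  c6 <- p[p$cell_id == 6, ]
  expect_true(c6$ever_sampled)
  expect_equal(c6$median_interval, 3)
  expect_equal(c6$days_since_last, 3)
  expect_equal(c6$sampling_duration, 6)
  expect_equal(c6$n_unique_days, 3)
  expect_equal(c6$dist_nearest_sampled, 0)
  # nearest *other* sampled cell is 11 (one diagonal step away)
  expect_equal(c6$neighbor_dist_km, 5 * sqrt(2))
  expect_equal(c6$neighbor_median_interval, 1)  # cell 11: single sampled day

  # an unsampled cell adjacent to cell 6
  c5 <- p[p$cell_id == 5, ]
  expect_false(c5$ever_sampled)
  expect_equal(c5$dist_nearest_sampled, 5)
  expect_equal(c5$n_unique_days, 0)
  expect_true(is.na(c5$median_interval))
})

test_that("a cell sampled only yesterday has the floor parameter values", {
  g <- make_grid(c(0, 10, 0, 10), 5)
  p <- daily_parameters(g, tibble::tibble(cell_id = 1L, date = 9L), 10L)
  c1 <- p[p$cell_id == 1, ]
  expect_equal(c1$days_since_last, 1)
  expect_equal(c1$n_unique_days, 1)
  expect_equal(c1$sampling_duration, 0)
  expect_equal(c1$median_interval, 1)  # single-day history floor
})

test_that("future checklists never alter parameters at earlier dates", {
  g <- make_grid(c(0, 20, 0, 20), 5)
  for (s in 1:40) {
    hist <- random_history(g, n_events = 30, last_day = 120, seed = 900 + s)
    qd <- with_seed(1000 + s, sort(sample(60:120, 3)))
    before <- daily_parameter_panel(g, hist, qd)
    future <- tibble::tibble(cell_id = sample.int(16, 1), date = max(qd) + 5L)
    after <- daily_parameter_panel(g, dplyr::bind_rows(hist, future), qd)
    expect_identical(before, after)
  }
})

test_that("history accumulates monotonically through time", {
  g <- make_grid(c(0, 20, 0, 20), 5)
  hist <- random_history(g, n_events = 50, last_day = 200, seed = 77)
  panel <- daily_parameter_panel(g, hist, seq(2L, 220L, by = 7L))
  for (cid in unique(panel$cell_id)) {
    rows <- panel[panel$cell_id == cid, ]
    rows <- rows[order(rows$date), ]
    expect_true(all(diff(rows$n_unique_days) >= 0))
    expect_true(all(diff(rows$ever_sampled) >= 0))
    ints <- rows$median_interval[!is.na(rows$median_interval)]
    if (length(ints)) expect_true(min(ints) >= 1)
  }
})
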