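# A tiny end-to-end grid world for join/predict tests: 4 cells, history in
# cells 1 and 2, evaluation checklists in year 2018.
tiny_world <- function() {
  g <- make_grid(c(0, 10, 0, 10), 5)
  hist <- tibble::tibble(
    cell_id = c(1L, 1L, 1L, 2L, 2L),
    date = as.Date(c("2017-03-01", "2017-06-01", "2017-12-01",
                     "2017-05-01", "2017-11-15"))
  )
  eval_dates <- as.Date("2018-01-01") + 0:30
  panel <- daily_parameter_panel(g, hist, eval_dates)
  list(grid = g, hist = hist, panel = panel, eval_dates = eval_dates)
}

test_that("training rows join the leverage values to strictly-prior cell history", {
  tw <- tiny_world()
  cl <- dplyr::bind_rows(lapply(1:10, function(i) {
    mk_checklist(sprintf("E%02d", i), date = as.Date("2018-01-10") + i %% 5)
  }))
  cells <- tibble::tibble(checklist_id = cl$checklist_id,
                          cell_id = rep(c(1L, 2L, 3L, 4L, 1L), 2))
  lev <- structure(list(values = tibble::tibble(
    checklist_id = cl$checklist_id, marginal_value = seq(0.1, 1, by = 0.1)
  )), class = "leverage_table")

  rows <- join_training_table(lev, tw$panel, cells, cl, 2018)
  expect_equal(nrow(rows), 10)
  expect_equal(sum(rows$unsampled), 4)  # cells 3 and 4 have no history
  expect_error(join_training_table(lev, tw$panel, cells, cl, 2016), "2016")
  # a panel that does not cover the checklist dates is a causality bug
  expect_error(join_training_table(lev, tw$panel[tw$panel$date < as.Date("2018-01-05"), ],
                                   cells, cl, 2018),
               "parameter record")
})

test_that("the collinearity screen always excludes duration and reports r = 1 pairs", {
  rows <- value_rows(300, beta = rep(0.3, 5), sigma = 0.2, seed = 4)
  # log1p(duration) == log(median_interval): exactly collinear on the model scale
  rows$sampling_duration <- rows$median_interval - 1
  scr <- collinearity_screen(rows)
  expect_false("sampling_duration" %in% scr$retained)
  expect_true(scr$duration_excluded)
  hit <- scr$flagged[scr$flagged$var1 == "median_interval" &
                       scr$flagged$var2 == "sampling_duration", ]
  expect_equal(hit$r, 1)

  indep <- value_rows(2000, beta = rep(0, 5), sigma = 1, seed = 5)
  indep$sampling_duration <- with_seed(6, 1 + rpois(2000, 50))
  scr2 <- collinearity_screen(indep, threshold = 0.7)
  expect_equal(nrow(scr2$flagged), 0)
})

test_that("planted value-model coefficients are recovered", {
  beta <- c(0.5, 0.8, -0.3, 0.2, -0.6)
  noisy <- fit_value_model(value_rows(2000, beta, sigma = 0.5, seed = 11))
  est <- noisy$coef_table[match(noisy$covariates_used, noisy$coef_table$term), ]
  expect_true(all(abs(est$estimate - beta) <= 3 * est$se))
  # applying the fit to its own training rows reproduces the fitted values
  rows <- value_rows(2000, beta, sigma = 0.5, seed = 11)
  expect_equal(unname(predict_value(noisy, rows)),
               unname(stats::fitted(noisy$model)), tolerance = 1e-12)
})

test_that("effect sizes are invariant to covariate input order", {
  rows <- value_rows(500, beta = c(0.4, -0.2, 0.1, 0.3, -0.5), sigma = 0.3, seed = 21)
  f1 <- fit_value_model(rows)
  f2 <- fit_value_model(rows, covariates = rev(VALUE_COVARIATES))
  ct1 <- f1$coef_table[order(f1$coef_table$term), ]
  ct2 <- f2$coef_table[order(f2$coef_table$term), ]
  expect_equal(ct1$estimate, ct2$estimate, tolerance = 1e-12)
  expect_equal(ct1$se, ct2$se, tolerance = 1e-12)
})

test_that("degenerate covariates are dropped with a warning, fatal only when none remain", {
  rows <- value_rows(200, beta = rep(0.2, 5), sigma = 0.2, seed = 31)
  rows$neighbor_dist_km <- 5  # structurally constant at dense coverage
  expect_warning(fit <- fit_value_model(rows), "neighbor_dist_km")
  expect_false("neighbor_dist_km" %in% fit$covariates_used)
  expect_equal(length(fit$covariates_used), 4)

  flat <- rows
  for (nm in VALUE_COVARIATES) flat[[nm]] <- 7
  expect_error(quiet(fit_value_model(flat)), "rank deficient")

  aliased <- value_rows(200, beta = rep(0.2, 5), sigma = 0.2, seed = 32)
  aliased$neighbor_median_interval <- aliased$median_interval
  expect_warning(fa <- fit_value_model(aliased), "neighbor_median_interval")
  expect_equal(length(fa$covariates_used), 4)
})

test_that("the unsampled-site test estimates a planted effect and knows when it cannot", {
  rows <- value_rows(1000, beta = rep(0, 5), sigma = 0.4, seed = 41)
  none <- test_unsampled_effect(rows, grain = 5)
  expect_false(none$feasible)

  delta <- 0.8
  rows$unsampled <- with_seed(42, runif(1000) < 0.2)
  rows$marginal_value <- rows$marginal_value * exp(delta * rows$unsampled)
  eff <- test_unsampled_effect(rows, grain = 5)
  expect_true(eff$feasible)
  expect_lt(abs(eff$effect - delta), 3 * eff$se)
})

test_that("daily maps impute never-sampled cells at the sampled-cell mean", {
  tw <- tiny_world()
  rows <- value_rows(400, beta = c(0.5, 0.4, -0.2, 0.1, 0.2), sigma = 0.3, seed = 51)
  fit <- quiet(fit_value_model(rows))
  params <- tw$panel[tw$panel$date == as.Date("2018-01-20"), ]
  map <- predict_daily_map(fit, params, seed = 1)
  expect_equal(nrow(map), 4)
  modelled <- map$expected_log_value[map$provenance == "modelled"]
  imputed <- map$expected_log_value[map$provenance == "mean-imputed"]
  expect_equal(length(modelled), 2)
  expect_identical(unique(imputed), mean(modelled))

  # all covariates at the training means predict exactly the intercept
  at_mean <- params[params$cell_id == 1, ]
  for (nm in fit$covariates_used) {
    tr <- fit$transforms[[nm]]
    at_mean[[nm]] <- if (tr$log == "log1p") expm1(tr$mean) else exp(tr$mean)
  }
  expect_equal(unname(predict_value(fit, at_mean)),
               unname(stats::coef(fit$model)[["(Intercept)"]]), tolerance = 1e-10)

  # same seed, same map -- bit identical, even with multi-checklist cells
  day_cells <- tibble::tibble(checklist_id = c("a", "b", "c"),
                              cell_id = c(1L, 1L, 2L))
  m1 <- predict_daily_map(fit, params, day_cells = day_cells, seed = 99)
  m2 <- predict_daily_map(fit, params, day_cells = day_cells, seed = 99)
  expect_identical(m1, m2)
})
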