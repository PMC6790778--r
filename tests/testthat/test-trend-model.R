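test_that("the design encodes day, county and the list-length offset as specified", {
  cl <- dplyr::bind_rows(
    mk_checklist("A", n_sp = 5, date = as.Date("2010-01-01"), county = "B_county"),
    mk_checklist("B", n_sp = 7, date = as.Date("2010-03-02"), county = "A_county"),
    mk_checklist("C", n_sp = 6, date = as.Date("2011-01-01"), county = "C_county")
  )
  d <- build_design(cl, day_origin = as.Date("2010-01-01"))
  expect_equal(d$data$day, c(0, 60, 365))
  expect_equal(d$data$log_list_length[[1]], log(5))
  # 3 counties -> reference coding: intercept + 2 one-hot columns (+ day)
  X <- stats::model.matrix(stats::as.formula(paste("~", d$formula_rhs)), d$data)
  expect_equal(ncol(X), 4)
  expect_equal(levels(d$data$county)[[1]], "A_county")

  expect_error(build_design(cl, county_levels = c("A_county", "B_county")),
               "C_county")
})

test_that("degenerate responses are flagged instead of fitted", {
  cl <- dplyr::bind_rows(lapply(1:30, function(i) {
    mk_checklist(sprintf("C%02d", i), date = as.Date("2018-01-01") + i)
  }))
  d <- build_design(cl)
  f <- fit_species_trend(d, rep(1, 30), "always_there")
  expect_false(f$converged)
  expect_match(f$reason, "degenerate")
})

test_that("hat diagonals of a converged fit sum to the parameter count", {
  chain <- world_chain(world_config(n_checklists = 500, n_species = 8,
                                    width_km = 40, height_km = 40), seed = 3)
  for (f in chain$fits) {
    if (!f$converged) next
    expect_true(all(f$hat >= 0 & f$hat <= 1))
    expect_equal(sum(f$hat), f$p, tolerance = 1e-6)
  }
})

test_that("rescaling all list lengths shifts only the intercept, never the day slope", {
  chain <- world_chain(world_config(n_checklists = 400, n_species = 6,
                                    width_km = 40, height_km = 40), seed = 9)
  s <- names(chain$fits)[[1]]
  f1 <- chain$fits[[s]]
  cl2 <- chain$checklists
  cl2$list_length <- cl2$list_length * 3L
  d2 <- build_design(cl2, day_origin = chain$design$day_origin)
  f2 <- quiet(fit_species_trend(d2, chain$P[, s], s))
  expect_equal(f2$coefficients[["day"]], f1$coefficients[["day"]], tolerance = 1e-8)
  expect_equal(f2$coefficients[["(Intercept)"]] - f1$coefficients[["(Intercept)"]],
               -log(3), tolerance = 1e-6)
})

test_that("a zero-trend world yields slope estimates centred on zero", {
  cfg <- world_config(n_checklists = 700, n_species = 5, width_km = 40,
                      height_km = 40, beta_day_sd = 0,
                      base_prevalence_range = c(0.25, 0.45))
  truth <- draw_truth(cfg, seed = 100)
  ests <- unlist(lapply(1:25, function(r) {
    chain <- world_chain(cfg, seed = 200 + r, truth = truth)
    vapply(chain$fits[vapply(chain$fits, `[[`, logical(1), "converged")],
           function(f) f$coefficients[["day"]], numeric(1))
  }))
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * mc_se)
})

test_that("fit_all_trends flags a constant species column and keeps the rest", {
  chain <- world_chain(world_config(n_checklists = 300, n_species = 5,
                                    width_km = 40, height_km = 40), seed = 17)
  P <- cbind(chain$P, NeverSeen = 0L)
  fits <- quiet(fit_all_trends(chain$design, P))
  expect_false(fits$NeverSeen$converged)
  expect_equal(sum(vapply(fits, `[[`, logical(1), "converged")),
               sum(vapply(chain$fits, `[[`, logical(1), "converged")))
})

test_that("slope estimates tighten with sample size and the half-SE point is found", {
  cfg <- world_config(n_checklists = 4000, n_species = 8, width_km = 60,
                      height_km = 60, base_prevalence_range = c(0.2, 0.5))
  chain <- world_chain(cfg, seed = 31,
                       filters = filter_config(min_species_exclusive = 0,
                                               species_min_obs_exclusive = 20))
  species <- chain$species[1:5]
  res <- quiet(slope_convergence(chain$checklists, species,
                                 sizes = c(250, 500, 1000, 2000),
                                 replicates = 2, seed = 77,
                                 day_origin = cfg$origin_date))
  expect_lte(res$mean_se[res$n == 2000], res$mean_se[res$n == 250])
  expect_lte(res$mean_abs_dev[res$n == 2000], res$mean_abs_dev[res$n == 250])
  # SE scales ~ 1/sqrt(n): halving needs ~4x checklists, inside this grid
  expect_equal(attr(res, "n50_se"), 1000)
})

test_that("a full-data 'subsample' reproduces the full fit exactly", {
  cfg <- world_config(n_checklists = 300, n_species = 5, width_km = 40,
                      height_km = 40)
  chain <- world_chain(cfg, seed = 41,
                       filters = filter_config(min_species_exclusive = 0,
                                               species_min_obs_exclusive = 10))
  res <- quiet(slope_convergence(chain$checklists, chain$species[1:3],
                                 sizes = nrow(chain$checklists),
                                 replicates = 1, seed = 5,
                                 day_origin = cfg$origin_date))
  expect_equal(res$mean_abs_dev, 0, tolerance = 1e-8)
})
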