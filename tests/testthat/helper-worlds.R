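# Shared builders for the test suite. Everything is generated in code at
# test time; the only on-disk fixtures are the tiny hand-written tables in
# inst/extdata.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Write an observation tibble as an EBD-style TSV and return the path.
obs_tsv <- function(obs) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(obs, path, na = "")
  path
}

# One collapsed checklist row, for filter tests (bypasses the TSV layer).
mk_checklist <- function(id, n_sp = 6, complete = TRUE, start = 8,
                         dur = 60, dist = 2, area = NA_real_,
                         date = as.Date("2018-06-10"), county = "County_1") {
  tibble::tibble(
    checklist_id = id, latitude = -33.8, longitude = 150.9,
    county = county, date = date, start_time = start,
    duration_minutes = dur, distance_km = dist, area_ha = area,
    is_complete = complete, protocol = NA_character_,
    species_observed = list(sprintf("Sp%02d", seq_len(n_sp))),
    list_length = n_sp
  )
}

# Simulate a world and run it through read -> collapse -> filter -> design
# -> per-species fits. `fit_all_species` bypasses the >50-observation rule
# and fits every *modelled* (non-background) species, which is what the
# recovery tests need; `FALSE` applies the standard species selection.
world_chain <- function(config, seed, truth = NULL,
                        filters = filter_config(),
                        fit_all_species = TRUE) {
  world <- simulate_world(config, seed = seed, truth = truth)
  quiet({
    cl <- collapse_to_checklists(read_observations(obs_tsv(world$observations)))
    fr <- filter_checklists(cl, filters)
    species <- if (fit_all_species) {
      sort(intersect(world$truth$species$species_code,
                     unique(unlist(fr$checklists$species_observed))))
    } else {
      select_species(fr$checklists, filters)
    }
    P <- zero_fill(fr$checklists, species)
    design <- build_design(fr$checklists, day_origin = config$origin_date)
    fits <- fit_all_trends(design, P)
  })
  list(world = world, checklists = fr$checklists, report = fr$report,
       species = species, P = P, design = design, fits = fits)
}

# Synthetic value-model rows with a planted coefficient vector on the five
# log-standardized covariates; the independent oracle for recovery tests.
value_rows <- function(n, beta, sigma, seed, intercept = -9) {
  with_seed(seed, {
    raw <- tibble::tibble(
      median_interval = 1 + rpois(n, 30),
      n_unique_days = 1 + rpois(n, 40),
      days_since_last = 1 + rpois(n, 60),
      neighbor_dist_km = stats::rlnorm(n, log(8), 0.6),
      neighbor_median_interval = 1 + rpois(n, 25)
    )
    covs <- names(raw)
    Z <- sapply(covs, function(nm) {
      z <- if (nm == "neighbor_dist_km") log1p(raw[[nm]]) else log(raw[[nm]])
      (z - mean(z)) / stats::sd(z)
    })
    log_value <- intercept + as.numeric(Z %*% beta) + stats::rnorm(n, 0, sigma)
    raw$marginal_value <- exp(log_value)
    raw$unsampled <- FALSE
    raw
  })
}

# Random sampling history over a small grid, for causality properties.
random_history <- function(grid, n_events, last_day, seed) {
  with_seed(seed, tibble::tibble(
    cell_id = sample.int(nrow(grid$cells), n_events, replace = TRUE),
    date = sample.int(last_day, n_events, replace = TRUE)
  ))
}
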