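#' Configuration of a synthetic checklist world
#'
#' The simulator emulates the structure of semi-structured checklist data:
#' complete checklists whose species lists are drawn from per-species
#' logistic occupancy models with a linear day trend, county effects and a
#' list-length effort term; hotspot-biased spatial effort (power-law cell
#' weights); multi-year date coverage; and realistic effort fields
#' (duration, distance/area, start time).
#'
#' Effort enters exactly the way the trend model corrects for it: each
#' checklist draws a target list length `L`, the modelled species are
#' detected with `logit p = intercept + beta_day * day + county effect +
#' log(L / list_target_mean)`, and unmodelled "background" species (the
#' region's many species that never enter the trend analysis) fill the list
#' up to `L`. The realized list length therefore equals the detection count,
#' and a binomial GLM with a `log(list_length)` offset is the *true*
#' conditional model of every modelled species -- which is what makes exact
#' parameter-recovery checks meaningful. Setting `effort_sd > 0` adds
#' unexplained observer heterogeneity on top, deliberately breaking that
#' exactness for robustness studies.
#'
#' Defaults give a regional-scale world (120 km square, matching the extent
#' at which 5-50 km grains are all meaningful) with enough checklists for
#' stable per-species GLMs.
#'
#' @param width_km,height_km World extent in km.
#' @param grain_km Base-cell side for effort weights and counties.
#' @param n_counties Number of contiguous (Voronoi) county blocks.
#' @param n_species Number of modelled species.
#' @param years Span of the record; dates are uniform over it.
#' @param n_checklists Number of checklists.
#' @param hotspot_exponent Pareto tail exponent of cell effort weights;
#'   smaller = more concentrated effort.
#' @param beta_day_mean,beta_day_sd Distribution (per day) of true trend
#'   slopes across species.
#' @param base_prevalence_range Range of day-0 detection probabilities at
#'   the reference list length (`list_target_mean`).
#' @param county_sd SD of per-species county effects (logit scale).
#' @param list_target_min,list_target_mean Target list length is
#'   `min + Poisson(mean - min)`; its log (centred at the mean) is the
#'   effort term.
#' @param n_background_species Pool of unmodelled species that pad each
#'   list up to its target length.
#' @param effort_sd SD of *additional* unexplained per-checklist effort
#'   (logit scale); default 0 keeps the offset model exactly specified.
#' @param duration_meanlog,duration_sdlog Log-normal duration (minutes).
#' @param distance_mean_km Mean of exponential travelling distances.
#' @param p_stationary,p_area Protocol mix (remainder is travelling).
#' @param p_incomplete Fraction of incomplete checklists.
#' @param start_time_mean,start_time_sd Normal start time (decimal hours,
#'   clipped to the day); the tails supply naturally nocturnal lists.
#' @param origin_date First day of the record (also the trend-day origin).
#' @param anchor `c(lon, lat)` placing the planar world on the globe.
#' @return A `world_config` list.
#' @export
world_config <- function(width_km = 120, height_km = 120,
                         grain_km = 5,
                         n_counties = 3,
                         n_species = 20,
                         years = 4,
                         n_checklists = 6000,
                         hotspot_exponent = 1.2,
                         beta_day_mean = 0, beta_day_sd = 5e-4,
                         base_prevalence_range = c(0.10, 0.50),
                         county_sd = 0.5,
                         list_target_min = 5, list_target_mean = 15,
                         n_background_species = 80,
                         effort_sd = 0,
                         duration_meanlog = log(60), duration_sdlog = 0.6,
                         distance_mean_km = 2,
                         p_stationary = 0.30, p_area = 0.05,
                         p_incomplete = 0.03,
                         start_time_mean = 10, start_time_sd = 3,
                         origin_date = as.Date("2015-01-01"),
                         anchor = c(150.6, -33.8)) {
  stopifnot(width_km > 0, height_km > 0, grain_km > 0, n_counties >= 1,
            n_species >= 1, years >= 1, n_checklists >= 1,
            hotspot_exponent > 0, effort_sd >= 0, county_sd >= 0,
            list_target_min >= 1, list_target_mean > list_target_min,
            n_background_species >= 1)
  stopifnot(all(base_prevalence_range > 0), all(base_prevalence_range < 1))
  structure(as.list(environment()), class = "world_config")
}

#' Draw the fixed truth of a synthetic world
#'
#' Cell effort weights (Pareto), Voronoi counties over base cells, and the
#' per-species true trend model (intercept, day slope, county effects).
#' Kept separate from [simulate_world()] so replicate simulations can share
#' one truth.
#'
#' @param config A [world_config()].
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return A `world_truth` list: `grid` (base grid), `cells` (tibble with
#'   `cell_id`, `county`, `weight`), `county_names`, `species` (tibble with
#'   `species_code`, `intercept`, `beta_day`), `county_effects` (species x
#'   county matrix), `config`.
#' @export
draw_truth <- function(config, seed = NULL) {
  stopifnot(inherits(config, "world_config"))
  with_seed(seed, {
    grid <- make_grid(c(0, config$width_km, 0, config$height_km), config$grain_km)
    ncell <- nrow(grid$cells)
    weight <- stats::runif(ncell)^(-1 / config$hotspot_exponent)
    weight <- weight / sum(weight)

    seeds <- sample.int(ncell, config$n_counties)
    d2 <- sapply(seeds, function(s) {
      (grid$cells$cx - grid$cells$cx[[s]])^2 + (grid$cells$cy - grid$cells$cy[[s]])^2
    })
    county_idx <- max.col(-matrix(d2, nrow = ncell), ties.method = "first")
    county_names <- sprintf("County_%d", seq_len(config$n_counties))

    species <- tibble::tibble(
      species_code = sprintf("Species_%02d", seq_len(config$n_species)),
      intercept = stats::qlogis(stats::runif(config$n_species,
                                             config$base_prevalence_range[[1]],
                                             config$base_prevalence_range[[2]])),
      beta_day = stats::rnorm(config$n_species, config$beta_day_mean,
                              config$beta_day_sd)
    )
    county_effects <- matrix(stats::rnorm(config$n_species * config$n_counties,
                                          0, config$county_sd),
                             nrow = config$n_species,
                             dimnames = list(species$species_code, county_names))

    structure(
      list(grid = grid,
           cells = tibble::tibble(cell_id = grid$cells$cell_id,
                                  county = county_names[county_idx],
                                  weight = weight),
           county_names = county_names,
           species = species,
           county_effects = county_effects,
           config = config),
      class = "world_truth"
    )
  })
}

span_days <- function(config) {
  end <- seq(config$origin_date, by = "year", length.out = config$years + 1)[[config$years + 1]]
  as.integer(end - config$origin_date)
}

#' Simulate a synthetic checklist world
#'
#' Draws checklist locations from the truth's hotspot-weighted cells, dates
#' uniformly over the span, effort fields from the configured distributions,
#' each checklist's modelled species from per-species Bernoulli draws with
#' `logit p = intercept + beta_day * day + county effect + log-list-length
#' effort`, and background species padding the list to its target length
#' (see [world_config()] for why this keeps the offset model exactly
#' specified). The emitted table uses the EBD-style schema, so it
#' round-trips through [read_observations()] unchanged; identical seeds
#' give byte-identical output. Species that end up never detected have
#' their intercept bumped and are redrawn (with a warning).
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @param truth Optional `world_truth` to reuse; default draws one from the
#'   same stream.
#' @return List: `observations` (EBD-style tibble, one row per checklist x
#'   detected species), `truth` (with two extra elements: `checklists`, the
#'   per-checklist cell/effort table including zero-species lists, and
#'   `expected_prevalence`, the per-species mean detection probability).
#' @export
simulate_world <- function(config = world_config(), seed = 1, truth = NULL) {
  stopifnot(inherits(config, "world_config"))
  with_seed(seed, {
    if (is.null(truth)) truth <- draw_truth(config, seed = NULL)
    grid <- truth$grid
    n <- config$n_checklists
    ncell <- nrow(grid$cells)

    cell <- sample.int(ncell, n, replace = TRUE, prob = truth$cells$weight)
    x <- grid$cells$x0[cell] + stats::runif(n) * config$grain_km
    y <- grid$cells$y0[cell] + stats::runif(n) * config$grain_km
    day <- sample.int(span_days(config), n, replace = TRUE) - 1L
    date <- config$origin_date + day
    start_time <- pmin(pmax(stats::rnorm(n, config$start_time_mean,
                                         config$start_time_sd), 0), 23.98)
    duration <- stats::rlnorm(n, config$duration_meanlog, config$duration_sdlog)
    u <- stats::runif(n)
    protocol <- ifelse(u < config$p_stationary, "Stationary",
                       ifelse(u < config$p_stationary + config$p_area, "Area",
                              "Traveling"))
    distance <- ifelse(protocol == "Traveling",
                       stats::rexp(n, 1 / config$distance_mean_km), NA_real_)
    area <- ifelse(protocol == "Area", stats::rlnorm(n, log(100), 0.8), NA_real_)
    complete <- stats::runif(n) >= config$p_incomplete
    target_ll <- config$list_target_min +
      stats::rpois(n, config$list_target_mean - config$list_target_min)
    effort <- log(target_ll) - log(config$list_target_mean) +
      stats::rnorm(n, 0, config$effort_sd)
    county_i <- match(truth$cells$county[cell], truth$county_names)

    draw_species <- function(s) {
      eta <- truth$species$intercept[[s]] + truth$species$beta_day[[s]] * day +
        truth$county_effects[s, county_i] + effort
      p <- stats::plogis(eta)
      list(y = stats::rbinom(n, 1, p), p = p)
    }
    Y <- matrix(0L, n, config$n_species)
    P <- matrix(0, n, config$n_species)
    for (s in seq_len(config$n_species)) {
      d <- draw_species(s)
      Y[, s] <- d$y
      P[, s] <- d$p
    }
    for (tries in seq_len(20)) {
      empty <- which(colSums(Y) == 0)
      if (length(empty) == 0) break
      warning(sprintf("resampling %d all-absent species with raised prevalence",
                      length(empty)), call. = FALSE)
      for (s in empty) {
        truth$species$intercept[[s]] <- truth$species$intercept[[s]] + 0.5
        d <- draw_species(s)
        Y[, s] <- d$y
        P[, s] <- d$p
      }
    }
    truth$expected_prevalence <- stats::setNames(colMeans(P),
                                                 truth$species$species_code)

    checklist_id <- sprintf("S%06d", seq_len(n))
    ll <- unproject_xy(x, y, config$anchor)

    # background species pad each list up to its target length
    n_detected <- rowSums(Y)
    n_background <- pmin(pmax(0L, target_ll - n_detected),
                         config$n_background_species)
    bg_pool <- sprintf("Background_%03d", seq_len(config$n_background_species))
    bg_codes <- lapply(seq_len(n), function(i) {
      if (n_background[[i]] == 0) character(0)
      else sort(sample(bg_pool, n_background[[i]]))
    })

    hits <- which(Y == 1L, arr.ind = TRUE)
    species_by_cl <- split(truth$species$species_code[hits[, 2]],
                           factor(hits[, 1], levels = seq_len(n)))
    i <- rep(seq_len(n), times = n_detected + n_background)
    sp_col <- unlist(lapply(seq_len(n), function(k) {
      sort(c(species_by_cl[[k]], bg_codes[[k]]))
    }), use.names = FALSE)
    hh <- floor(start_time[i]); mm <- round((start_time[i] - hh) * 60)

    obs <- tibble::tibble(
      `SAMPLING EVENT IDENTIFIER` = checklist_id[i],
      `SCIENTIFIC NAME` = sp_col,
      LATITUDE = round(ll$lat[i], 6),
      LONGITUDE = round(ll$lon[i], 6),
      COUNTY = truth$cells$county[cell[i]],
      `OBSERVATION DATE` = format(date[i], "%Y-%m-%d"),
      `TIME OBSERVATIONS STARTED` = sprintf("%02d:%02d:00", hh, mm),
      `DURATION MINUTES` = round(duration[i], 1),
      `EFFORT DISTANCE KM` = round(distance[i], 3),
      `EFFORT AREA HA` = round(area[i], 1),
      `ALL SPECIES REPORTED` = as.integer(complete[i]),
      `PROTOCOL TYPE` = protocol[i]
    )
    truth$checklists <- tibble::tibble(
      checklist_id = checklist_id, cell_id = grid$cells$cell_id[cell],
      x = x, y = y, day = day, date = date, effort = effort,
      target_list_length = target_ll,
      list_length = n_detected + n_background, is_complete = complete
    )
    list(observations = obs, truth = truth)
  })
}

#' Write a simulated world to disk
#'
#' Emits the EBD-style TSV plus plain-CSV truth sidecars (species truth and
#' per-cell weights/counties).
#'
#' @param world Result of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    observations = file.path(dir, "world.tsv"),
    species_truth = file.path(dir, "truth_species.csv"),
    cell_truth = file.path(dir, "truth_cells.csv")
  )
  readr::write_tsv(world$observations, paths[["observations"]], na = "")
  readr::write_csv(world$truth$species, paths[["species_truth"]])
  readr::write_csv(world$truth$cells, paths[["cell_truth"]])
  invisible(paths)
}

#' Write the small hand-auditable fixtures
#'
#' Tiny deterministic tables used by the worked examples and tests: an
#' 8-checklist filter-audit table with exactly three single-rule violations
#' (one incomplete list, one 4-minute list, one 6-km travelling list), a
#' 16-cell grid sampling history with one cell sampled on days 1, 3 and 7,
#' and a 5-point Gaussian dataset for the exact leave-one-out dfBeta check.
#'
#' @param dir Output directory.
#' @return Named character vector of paths, invisibly.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  species_for <- function(k) sprintf("Species_%02d", seq_len(k))
  mk <- function(id, n_species, complete = 1, start = "08:00:00",
                 duration = 60, distance = 2, area = NA, protocol = "Traveling") {
    tibble::tibble(
      `SAMPLING EVENT IDENTIFIER` = id,
      `SCIENTIFIC NAME` = species_for(n_species),
      LATITUDE = -33.8, LONGITUDE = 150.9, COUNTY = "County_1",
      `OBSERVATION DATE` = "2018-06-10",
      `TIME OBSERVATIONS STARTED` = start,
      `DURATION MINUTES` = duration,
      `EFFORT DISTANCE KM` = distance,
      `EFFORT AREA HA` = area,
      `ALL SPECIES REPORTED` = complete,
      `PROTOCOL TYPE` = protocol
    )
  }
  filter_fixture <- dplyr::bind_rows(
    mk("F1", 6),                                             # retained
    mk("F2", 5, distance = NA, protocol = "Stationary"),     # retained (stationary)
    mk("F3", 6, complete = 0),                               # removed: incomplete
    mk("F4", 6, duration = 4),                               # removed: duration
    mk("F5", 6, distance = 6),                               # removed: distance/area
    mk("F6", 7, distance = NA, area = 300, protocol = "Area"), # retained (area)
    mk("F7", 5, duration = 239),                             # retained (edge pass)
    mk("F8", 8)                                              # retained
  )

  grid_fixture <- tibble::tibble(
    cell_id = c(6L, 6L, 6L, 11L),
    date = c("2018-01-01", "2018-01-03", "2018-01-07", "2018-01-05")
  )

  gaussian_toy <- tibble::tibble(
    x = c(0.5, 1.3, 2.2, 3.1, 4.7),
    y = c(1.10, 2.30, 2.90, 4.80, 5.60)
  )

  paths <- c(
    filter_fixture = file.path(dir, "filter_fixture.tsv"),
    grid_fixture = file.path(dir, "grid_fixture.csv"),
    gaussian_toy = file.path(dir, "gaussian_toy.csv")
  )
  readr::write_tsv(filter_fixture, paths[["filter_fixture"]], na = "")
  readr::write_csv(grid_fixture, paths[["grid_fixture"]])
  readr::write_csv(gaussian_toy, paths[["gaussian_toy"]])
  invisible(paths)
}
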