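#' Pipeline configuration
#'
#' Bundles everything the end-to-end run needs: the synthetic world (or an
#' existing EBD-style file), the checklist filters, the grain sizes, the
#' evaluation year and the seeds.
#'
#' @param world A [world_config()] describing the synthetic input; ignored
#'   when `input_path` points at an existing EBD-style TSV.
#' @param input_path Optional path to an observation table to use instead of
#'   simulating.
#' @param filters A [filter_config()].
#' @param grains Grid-cell side lengths (km) to analyse.
#' @param day_origin Trend-day origin; defaults to the world's origin date.
#' @param eval_year Evaluation year; defaults to the world's final year.
#' @param anchor Projection anchor `c(lon, lat)`; defaults to the world's.
#' @param bbox Planar bounding box `c(xmin, xmax, ymin, ymax)` km; defaults
#'   to the world's extent.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for all artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(),
                            input_path = NULL,
                            filters = filter_config(),
                            grains = c(5, 10, 25, 50),
                            day_origin = NULL,
                            eval_year = NULL,
                            anchor = NULL,
                            bbox = NULL,
                            seed = 1,
                            out_dir = file.path(tempdir(), "samplingvalue-run")) {
  stopifnot(all(grains > 0))
  final_year <- as.integer(format(world$origin_date, "%Y")) + world$years - 1L
  structure(
    list(world = world, input_path = input_path, filters = filters,
         grains = grains,
         day_origin = day_origin %||% world$origin_date,
         eval_year = eval_year %||% final_year,
         anchor = anchor %||% world$anchor,
         bbox = bbox %||% c(0, world$width_km, 0, world$height_km),
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

value_fit_csv <- function(fit) {
  out <- fit$coef_table
  out$r_squared <- fit$r_squared
  out$n <- fit$n
  out$dropped <- paste(fit$dropped, collapse = ";")
  out
}

#' Run the whole marginal-value pipeline
#'
#' One-shot run: simulate (or read) the observation table, filter, fit the
#' per-species trend models, compute the leverage table and per-checklist
#' marginal values, and then for every grain size compute daily
#' sampling-history parameters over the evaluation year, fit the value
#' model, test the unsampled-site effect and predict the expected-value map
#' for every evaluation day. All artifacts are written to
#' `config$out_dir` as CSV/TSV/GeoJSON plus a JSON manifest with md5 hashes
#' and the seeds used, so a rerun with the same config is verifiably
#' identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add_path <- function(p) paths[[length(paths) + 1]] <<- p

  obs_path <- stage("simulate", {
    if (!is.null(config$input_path)) {
      config$input_path
    } else {
      world <- simulate_world(config$world, seed = config$seed)
      wp <- write_world(world, config$out_dir)
      for (p in wp) add_path(p)
      wp[["observations"]]
    }
  })

  cl <- stage("read", {
    obs <- read_observations(obs_path)
    collapse_to_checklists(obs)
  })

  fr <- stage("filter", {
    res <- filter_checklists(cl, config$filters)
    rp <- file.path(config$out_dir, "filter_report.csv")
    readr::write_csv(res$report, rp)
    add_path(rp)
    res
  })

  fits <- stage("fit-trends", {
    sp <- select_species(fr$checklists, config$filters)
    P <- zero_fill(fr$checklists, sp)
    design <- build_design(fr$checklists, day_origin = config$day_origin)
    fits <- fit_all_trends(design, P)
    coefs <- purrr::map_dfr(fits, function(f) {
      if (!f$converged) {
        return(tibble::tibble(species_code = f$species_code, term = NA_character_,
                              estimate = NA_real_, se = NA_real_,
                              converged = FALSE))
      }
      tibble::tibble(species_code = f$species_code,
                     term = names(f$coefficients),
                     estimate = unname(f$coefficients),
                     se = sqrt(diag(f$vcov)), converged = TRUE)
    })
    cp <- file.path(config$out_dir, "trend_coefficients.csv")
    readr::write_csv(coefs, cp)
    add_path(cp)
    fits
  })

  lev <- stage("leverage", {
    lev <- build_leverage_table(fits)
    vp <- file.path(config$out_dir, "marginal_values.csv")
    readr::write_csv(lev$values, vp)
    add_path(vp)
    lev
  })

  xy <- stage("project", {
    pr <- project_lonlat(fr$checklists$longitude, fr$checklists$latitude,
                         config$anchor)
    tibble::tibble(checklist_id = fr$checklists$checklist_id, x = pr$x, y = pr$y)
  })

  eval_dates <- seq(as.Date(sprintf("%d-01-01", config$eval_year)),
                    as.Date(sprintf("%d-12-31", config$eval_year)), by = "day")

  effects <- list()
  grain_summaries <- list()
  for (grain in config$grains) {
    tag <- sprintf("grain%g", grain)
    res <- stage(paste0("grid-params/", tag), {
      grid <- make_grid(config$bbox, grain)
      cells <- assign_cells(xy, grid)
      cell_days <- cells |>
        dplyr::inner_join(fr$checklists[, c("checklist_id", "date")],
                          by = "checklist_id")
      panel <- daily_parameter_panel(grid, cell_days[, c("cell_id", "date")],
                                     eval_dates)
      pp <- file.path(config$out_dir, sprintf("daily_parameters_%s.csv", tag))
      readr::write_csv(panel, pp)
      add_path(pp)
      gp <- file.path(config$out_dir, sprintf("grid_%s.geojson", tag))
      write_grid_geojson(grid, gp)
      add_path(gp)
      list(grid = grid, cells = cells, cell_days = cell_days, panel = panel)
    })

    vm <- stage(paste0("fit-value/", tag), {
      rows <- join_training_table(lev, res$panel, res$cells, fr$checklists,
                                  config$eval_year)
      screen <- collinearity_screen(rows)
      spath <- file.path(config$out_dir, sprintf("collinearity_%s.csv", tag))
      readr::write_csv(screen$flagged, spath)
      add_path(spath)
      fit <- fit_value_model(rows)
      fp <- file.path(config$out_dir, sprintf("value_model_%s.csv", tag))
      readr::write_csv(value_fit_csv(fit), fp)
      add_path(fp)
      effects[[tag]] <- test_unsampled_effect(rows, grain)
      list(fit = fit, rows = rows)
    })

    stage(paste0("predict-map/", tag), {
      day_cells <- res$cells |>
        dplyr::inner_join(fr$checklists[, c("checklist_id", "date")],
                          by = "checklist_id")
      maps <- purrr::map_dfr(seq_along(eval_dates), function(k) {
        d <- eval_dates[[k]]
        predict_daily_map(
          vm$fit, res$panel[res$panel$date == d, , drop = FALSE],
          day_cells = day_cells[day_cells$date == d, , drop = FALSE],
          seed = (config$seed + 7919L * k) %% .Machine$integer.max
        )
      })
      mp <- file.path(config$out_dir, sprintf("expected_value_maps_%s.csv", tag))
      readr::write_csv(maps, mp)
      add_path(mp)
    })

    grain_summaries[[tag]] <- list(
      grain_km = grain,
      n_cells = nrow(res$grid$cells),
      n_training_rows = nrow(vm$rows),
      value_r_squared = vm$fit$r_squared,
      dropped_covariates = vm$fit$dropped
    )
  }

  eff_tbl <- purrr::map_dfr(effects, function(e) {
    tibble::tibble(grain_km = e$grain, effect = e$effect, se = e$se,
                   p = e$p, n_unsampled = e$n_unsampled, feasible = e$feasible)
  })
  ep <- file.path(config$out_dir, "unsampled_effects.csv")
  readr::write_csv(eff_tbl, ep)
  add_path(ep)

  manifest <- list(
    seed = config$seed,
    eval_year = config$eval_year,
    grains = config$grains,
    n_checklists_retained = nrow(fr$checklists),
    n_species_modelled = sum(vapply(fits, `[[`, logical(1), "converged")),
    grain_summaries = grain_summaries,
    files = lapply(stats::setNames(paths, basename(unlist(paths))), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("run_all: %d artifacts written to %s", length(paths), config$out_dir)
  invisible(manifest)
}
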