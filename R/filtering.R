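#' Checklist and species filter configuration
#'
#' Defaults encode the standard quality filters for trend estimation from
#' semi-structured checklist data: complete checklists only, diurnal starts,
#' duration strictly between 5 and 240 minutes, travelling distance under
#' 5 km or survey area under 500 ha, and more than four species per list
#' (shorter lists are usually targeted searches). Species enter the modelled
#' set only with more than 50 observations; an optional allow-list restricts
#' the set to, e.g., terrestrial species.
#'
#' @param require_complete Keep only complete checklists (default `TRUE`).
#' @param min_duration_minutes,max_duration_minutes Strict duration bounds in
#'   minutes; a checklist is kept iff `min < duration < max`.
#' @param max_distance_km,max_area_ha Strict upper bounds; a checklist with
#'   effort fields is kept iff distance `< max_distance_km` *or* area
#'   `< max_area_ha`; stationary checklists (neither field) pass.
#' @param min_species_exclusive Keep checklists with `list_length >` this.
#' @param diurnal_window Numeric `c(start, end)` local start-time window in
#'   decimal hours, half-open `[start, end)`; `NULL` disables the rule.
#'   Checklists without a start time are removed while the rule is active.
#' @param terrestrial_species Optional character allow-list of species codes;
#'   `NULL` skips the taxonomy rule (with a logged note).
#' @param species_min_obs_exclusive Keep species recorded on more than this
#'   many retained checklists.
#' @return A `filter_config` list.
#' @export
filter_config <- function(require_complete = TRUE,
                          min_duration_minutes = 5,
                          max_duration_minutes = 240,
                          max_distance_km = 5,
                          max_area_ha = 500,
                          min_species_exclusive = 4,
                          diurnal_window = c(5, 20),
                          terrestrial_species = NULL,
                          species_min_obs_exclusive = 50) {
  if (min_duration_minutes >= max_duration_minutes) {
    abort_fmt("min_duration_minutes must be < max_duration_minutes")
  }
  if (!is.null(diurnal_window)) {
    stopifnot(length(diurnal_window) == 2)
    if (diurnal_window[[1]] >= diurnal_window[[2]]) {
      abort_fmt("diurnal_window start must be before end")
    }
  }
  structure(
    list(require_complete = require_complete,
         min_duration_minutes = min_duration_minutes,
         max_duration_minutes = max_duration_minutes,
         max_distance_km = max_distance_km,
         max_area_ha = max_area_ha,
         min_species_exclusive = min_species_exclusive,
         diurnal_window = diurnal_window,
         terrestrial_species = terrestrial_species,
         species_min_obs_exclusive = species_min_obs_exclusive),
    class = "filter_config"
  )
}

# Rule order fixed for attrition attribution (a removed checklist is counted
# at the FIRST rule it fails).
.filter_rules <- c("complete", "diurnal", "duration", "distance_area", "list_length")

#' Filter checklists for trend modelling
#'
#' Applies the configured rules in a fixed order (complete, diurnal,
#' duration, distance/area, list length). A checklist is retained iff it
#' passes every active rule; the report attributes each removal to the first
#' failing rule so the attrition audit sums to the input total.
#'
#' @param checklists Tibble from [collapse_to_checklists()].
#' @param config A [filter_config()].
#' @return A list with `checklists` (retained rows) and `report` (a tibble
#'   with one row per rule: `rule`, `removed`, plus attributes `n_input`,
#'   `n_retained`).
#' @export
filter_checklists <- function(checklists, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n_input <- nrow(checklists)

  fails <- list(
    complete = if (config$require_complete) !checklists$is_complete
               else rep(FALSE, n_input),
    diurnal = if (!is.null(config$diurnal_window)) {
      is.na(checklists$start_time) |
        checklists$start_time < config$diurnal_window[[1]] |
        checklists$start_time >= config$diurnal_window[[2]]
    } else rep(FALSE, n_input),
    duration = is.na(checklists$duration_minutes) |
      checklists$duration_minutes <= config$min_duration_minutes |
      checklists$duration_minutes >= config$max_duration_minutes,
    distance_area = {
      has_dist <- !is.na(checklists$distance_km)
      has_area <- !is.na(checklists$area_ha)
      pass <- (has_dist & checklists$distance_km < config$max_distance_km) |
        (has_area & checklists$area_ha < config$max_area_ha) |
        (!has_dist & !has_area)  # stationary checklists pass
      !pass
    },
    list_length = checklists$list_length <= config$min_species_exclusive
  )

  first_fail <- rep(NA_character_, n_input)
  for (rule in .filter_rules) {
    hit <- is.na(first_fail) & fails[[rule]]
    first_fail[hit] <- rule
  }

  report <- tibble::tibble(
    rule = .filter_rules,
    removed = vapply(.filter_rules, function(r) sum(first_fail == r, na.rm = TRUE),
                     integer(1))
  )
  retained <- checklists[is.na(first_fail), , drop = FALSE]
  attr(report, "n_input") <- n_input
  attr(report, "n_retained") <- nrow(retained)
  log_msg("filter_checklists: %d of %d checklists retained (%s)",
          nrow(retained), n_input,
          paste(sprintf("%s: %d", report$rule, report$removed), collapse = ", "))
  list(checklists = retained, report = report)
}

#' Select the species to model
#'
#' Keeps species recorded on strictly more than
#' `config$species_min_obs_exclusive` retained checklists, optionally
#' intersected with an allow-list (e.g. terrestrial species). Order is
#' deterministic (sorted species code).
#'
#' @param checklists Retained checklists from [filter_checklists()].
#' @param config A [filter_config()].
#' @return Sorted character vector of species codes.
#' @export
select_species <- function(checklists, config = filter_config()) {
  counts <- table(unlist(checklists$species_observed))
  keep <- names(counts)[counts > config$species_min_obs_exclusive]
  if (is.null(config$terrestrial_species)) {
    log_msg("select_species: no allow-list supplied; taxonomy rule skipped")
  } else {
    keep <- intersect(keep, config$terrestrial_species)
  }
  if (length(keep) == 0) {
    abort_fmt("no species passes the observation threshold (> %d); no models can be fitted",
              config$species_min_obs_exclusive)
  }
  sort(keep)
}
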