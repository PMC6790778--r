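#' Column map for eBird Basic Dataset style tables
#'
#' The pipeline reads tab-separated checklist tables whose headers follow the
#' eBird Basic Dataset (EBD) convention. The column map decouples internal
#' field names from file headers, so non-default exports (or the synthetic
#' simulator, which writes the same schema) can be read by overriding
#' individual entries.
#'
#' @param checklist_id,species_code,latitude,longitude,county,date,start_time,duration_minutes,distance_km,area_ha,is_complete,protocol
#'   File header for the corresponding internal field.
#' @return A named list mapping internal field names to file headers.
#' @export
#' @examples
#' ebd_column_map(county = "COUNTY NAME")
ebd_column_map <- function(checklist_id = "SAMPLING EVENT IDENTIFIER",
                           species_code = "SCIENTIFIC NAME",
                           latitude = "LATITUDE",
                           longitude = "LONGITUDE",
                           county = "COUNTY",
                           date = "OBSERVATION DATE",
                           start_time = "TIME OBSERVATIONS STARTED",
                           duration_minutes = "DURATION MINUTES",
                           distance_km = "EFFORT DISTANCE KM",
                           area_ha = "EFFORT AREA HA",
                           is_complete = "ALL SPECIES REPORTED",
                           protocol = "PROTOCOL TYPE") {
  list(
    checklist_id = checklist_id, species_code = species_code,
    latitude = latitude, longitude = longitude, county = county,
    date = date, start_time = start_time,
    duration_minutes = duration_minutes, distance_km = distance_km,
    area_ha = area_ha, is_complete = is_complete, protocol = protocol
  )
}

# Internal fields that must be present in every input file.
.mandatory_fields <- c(
  "checklist_id", "species_code", "latitude", "longitude",
  "county", "date", "is_complete"
)

parse_clock_time <- function(x) {
  # "HH:MM" or "HH:MM:SS" -> decimal hours; empty/NA -> NA; junk -> NaN marker
  out <- rep(NA_real_, length(x))
  has <- !is.na(x) & nzchar(trimws(x))
  if (!any(has)) return(out)
  parts <- strsplit(trimws(x[has]), ":", fixed = TRUE)
  out[has] <- vapply(parts, function(p) {
    n <- suppressWarnings(as.numeric(p))
    if (length(n) < 2 || length(n) > 3 || anyNA(n)) return(NaN)
    h <- n[[1]] + n[[2]] / 60 + if (length(n) == 3) n[[3]] / 3600 else 0
    if (h < 0 || h >= 24) NaN else h
  }, numeric(1))
  out
}

parse_logical_flag <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("1", "TRUE", "T", "YES")] <- TRUE
  out[up %in% c("0", "FALSE", "F", "NO")] <- FALSE
  out
}

#' Read an EBD-style observation table
#'
#' Reads a tab-separated table with one row per species observation, maps the
#' columns via `column_map`, types the fields, rejects rows whose date, time
#' or coordinates cannot be parsed, and collapses duplicate
#' (checklist, species) rows to one. Counts of rejected and deduplicated rows
#' are attached as attributes and logged.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param column_map Mapping from internal field names to file headers, as
#'   produced by [ebd_column_map()].
#' @return A tibble of typed species-observation rows (one per checklist x
#'   species), with attributes `n_input`, `n_rejected`, `n_duplicates`.
#' @export
read_observations <- function(path, column_map = ebd_column_map()) {
  if (!file.exists(path)) abort_fmt("input file does not exist: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA"))
  missing <- vapply(.mandatory_fields, function(f) {
    !(column_map[[f]] %in% names(raw))
  }, logical(1))
  if (any(missing)) {
    abort_fmt("mandatory column(s) missing from %s: %s", path,
              paste(unlist(column_map[.mandatory_fields[missing]]), collapse = ", "))
  }

  pick <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }

  obs <- tibble::tibble(
    checklist_id = pick("checklist_id"),
    species_code = pick("species_code"),
    latitude = suppressWarnings(as.numeric(pick("latitude"))),
    longitude = suppressWarnings(as.numeric(pick("longitude"))),
    county = pick("county"),
    date = suppressWarnings(as.Date(pick("date"))),
    start_time = parse_clock_time(pick("start_time")),
    duration_minutes = suppressWarnings(as.numeric(pick("duration_minutes"))),
    distance_km = suppressWarnings(as.numeric(pick("distance_km"))),
    area_ha = suppressWarnings(as.numeric(pick("area_ha"))),
    is_complete = parse_logical_flag(pick("is_complete")),
    protocol = pick("protocol")
  )

  bad <- is.na(obs$checklist_id) | is.na(obs$species_code) |
    is.na(obs$date) | is.nan(obs$start_time) |
    is.na(obs$latitude) | is.na(obs$longitude) |
    abs(obs$latitude) > 90 | abs(obs$longitude) > 180 |
    is.na(obs$is_complete)
  n_rejected <- sum(bad)
  obs <- obs[!bad, , drop = FALSE]

  n_before <- nrow(obs)
  obs <- dplyr::distinct(obs, .data$checklist_id, .data$species_code, .keep_all = TRUE)
  n_dup <- n_before - nrow(obs)

  log_msg("read_observations: %d rows read, %d rejected, %d duplicate (checklist, species) rows collapsed",
          nrow(raw), n_rejected, n_dup)
  attr(obs, "n_input") <- nrow(raw)
  attr(obs, "n_rejected") <- n_rejected
  attr(obs, "n_duplicates") <- n_dup
  obs
}

#' Collapse observation rows to one record per checklist
#'
#' Groups deduplicated species-observation rows by checklist id, verifies that
#' per-checklist metadata (location, date, effort fields) are identical across
#' a checklist's rows, and returns one row per checklist with its species set
#' and list length (the number of distinct species recorded -- the effort
#' proxy used as the trend-model offset).
#'
#' @param rows Tibble from [read_observations()].
#' @return A tibble with one row per checklist: metadata fields,
#'   `species_observed` (list-column of sorted species codes) and
#'   `list_length`.
#' @export
collapse_to_checklists <- function(rows) {
  meta <- c("latitude", "longitude", "county", "date", "start_time",
            "duration_minutes", "distance_km", "area_ha", "is_complete",
            "protocol")
  meta <- intersect(meta, names(rows))

  consistency <- rows |>
    dplyr::group_by(.data$checklist_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(meta), dplyr::n_distinct),
                     .groups = "drop")
  conflict <- consistency |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(meta), ~ .x > 1))
  if (nrow(conflict) > 0) {
    fields <- meta[vapply(meta, function(f) any(conflict[[f]] > 1), logical(1))]
    abort_fmt("inconsistent checklist metadata (%s) for checklist id(s): %s",
              paste(fields, collapse = ", "),
              paste(utils::head(conflict$checklist_id, 5), collapse = ", "))
  }

  rows |>
    dplyr::group_by(.data$checklist_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta), dplyr::first),
      species_observed = list(sort(unique(.data$species_code))),
      list_length = dplyr::n_distinct(.data$species_code),
      .groups = "drop"
    )
}

#' Zero-fill checklists into a presence/absence matrix
#'
#' Builds the binary checklist-by-species matrix used by the per-species
#' trend models. Absence (a zero) is only a valid inference for complete
#' checklists -- the observer reported everything identified -- so the
#' function refuses incomplete checklists.
#'
#' @param checklists Tibble from [collapse_to_checklists()] (complete
#'   checklists only).
#' @param species_set Character vector of species to include as columns.
#' @return An integer matrix with checklist ids as row names and sorted
#'   species codes as column names; entry 1 iff the species was recorded.
#' @export
zero_fill <- function(checklists, species_set) {
  if (length(species_set) == 0) abort_fmt("species_set is empty: nothing to model")
  if (!all(checklists$is_complete)) {
    abort_fmt("zero_fill requires complete checklists (absence is only inferable when all species were reported)")
  }
  species_set <- sort(unique(species_set))
  y <- vapply(species_set, function(s) {
    vapply(checklists$species_observed, function(set) as.integer(s %in% set), integer(1))
  }, integer(nrow(checklists)))
  y <- matrix(y, nrow = nrow(checklists), ncol = length(species_set),
              dimnames = list(checklists$checklist_id, species_set))
  y
}

#' Write / read a checklist table as plain CSV
#'
#' The species set is serialised as a `;`-separated string so the table
#' round-trips through a single flat file.
#'
#' @param checklists Tibble from [collapse_to_checklists()].
#' @param path Output/input CSV path.
#' @return `write_checklists()` returns `path` invisibly; `read_checklists()`
#'   returns the checklist tibble.
#' @export
write_checklists <- function(checklists, path) {
  out <- checklists
  out$species_observed <- vapply(out$species_observed, paste, character(1), collapse = ";")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_checklists
#' @export
read_checklists <- function(path) {
  out <- readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(
      checklist_id = readr::col_character(),
      latitude = readr::col_double(), longitude = readr::col_double(),
      county = readr::col_character(), date = readr::col_date(),
      start_time = readr::col_double(),
      duration_minutes = readr::col_double(),
      distance_km = readr::col_double(), area_ha = readr::col_double(),
      is_complete = readr::col_logical(), protocol = readr::col_character(),
      species_observed = readr::col_character(),
      list_length = readr::col_integer()
    )
  )
  out$species_observed <- lapply(strsplit(out$species_observed, ";", fixed = TRUE),
                                 function(x) sort(x))
  out
}
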