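#' Tile a region with square grid cells
#'
#' Builds the square-cell grid ("sites") at a given grain. The grain is the
#' cell *side length* in kilometres. Cells tile the bounding box without
#' overlap on a projected plane; ids are row-major (west to east, then south
#' to north) and deterministic.
#'
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)`. With `crs = "planar"`
#'   these are kilometres; with `crs = "lonlat"` they are decimal degrees and
#'   an `anchor` (projection origin, see [project_lonlat()]) is required.
#' @param side_km Cell side length in km (> 0).
#' @param crs `"planar"` (default) or `"lonlat"`.
#' @param anchor Projection origin `c(lon, lat)`, required for `"lonlat"`.
#' @return A `sampling_grid` list: `cells` tibble (`cell_id`, `ix`, `iy`,
#'   `x0`, `x1`, `y0`, `y1`, `cx`, `cy`), `side_km`, `nx`, `ny`, `bbox`,
#'   `anchor`.
#' @export
make_grid <- function(bbox, side_km, crs = c("planar", "lonlat"), anchor = NULL) {
  crs <- match.arg(crs)
  stopifnot(length(bbox) == 4, is.numeric(bbox))
  if (!is.finite(side_km) || side_km <= 0) abort_fmt("side_km must be > 0")
  if (crs == "lonlat") {
    if (is.null(anchor)) {
      abort_fmt("geographic bounding box given without a projection anchor; supply anchor = c(lon, lat)")
    }
    lo <- project_lonlat(bbox[[1]], bbox[[3]], anchor)
    hi <- project_lonlat(bbox[[2]], bbox[[4]], anchor)
    bbox <- c(lo$x, hi$x, lo$y, hi$y)
  }
  width <- bbox[[2]] - bbox[[1]]
  height <- bbox[[4]] - bbox[[3]]
  if (width <= 0 || height <= 0) abort_fmt("region must have positive area")
  nx <- ceiling(width / side_km)
  ny <- ceiling(height / side_km)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  cells <- tibble::tibble(
    cell_id = seq_len(nx * ny),
    ix = ix, iy = iy,
    x0 = bbox[[1]] + ix * side_km, x1 = bbox[[1]] + (ix + 1) * side_km,
    y0 = bbox[[3]] + iy * side_km, y1 = bbox[[3]] + (iy + 1) * side_km
  )
  cells$cx <- (cells$x0 + cells$x1) / 2
  cells$cy <- (cells$y0 + cells$y1) / 2
  structure(
    list(cells = cells, side_km = side_km, nx = nx, ny = ny,
         bbox = bbox, anchor = anchor),
    class = "sampling_grid"
  )
}

#' Assign points to grid cells
#'
#' Point-in-cell assignment with the half-open convention
#' `[x0, x1) x [y0, y1)`: a point exactly on a shared edge belongs to the
#' cell whose lower-left corner it touches. Points outside the gridded
#' region are dropped and counted.
#'
#' @param points Tibble with `checklist_id`, `x`, `y` (same plane/units as
#'   the grid).
#' @param grid A `sampling_grid`.
#' @return Tibble `checklist_id`, `cell_id` for in-region points, with
#'   attribute `n_dropped`.
#' @export
assign_cells <- function(points, grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  ix <- floor((points$x - grid$bbox[[1]]) / grid$side_km)
  iy <- floor((points$y - grid$bbox[[3]]) / grid$side_km)
  inside <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny &
    is.finite(points$x) & is.finite(points$y)
  out <- tibble::tibble(
    checklist_id = points$checklist_id[inside],
    cell_id = as.integer(iy[inside] * grid$nx + ix[inside] + 1)
  )
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    log_msg("assign_cells: %d point(s) outside the gridded region dropped", n_dropped)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

as_day_int <- function(d) {
  if (inherits(d, "Date")) as.integer(d) else as.integer(d)
}

#' Sampling-history parameters for every cell on given dates
#'
#' Computes, for each cell and each query date `d`, the seven dynamic
#' sampling-history parameters using *only checklists strictly before* `d`
#' (future sampling never enters):
#' whether the cell was ever sampled; distance to the nearest sampled cell
#' (0 for a sampled cell, centroid-to-centroid otherwise); the cell's median
#' sampling interval (median gap between consecutive distinct sampled days;
#' defined as 1 when fewer than two sampled days exist); days since the
#' last sample; sampling duration (last minus first sampled day); and the
#' number of unique sampled days. Multiple checklists in a cell on one day
#' count as one sampled day.
#'
#' Two neighbour fields describe the nearest *other* sampled cell --
#' `neighbor_dist_km` (centroid-to-centroid) and `neighbor_median_interval`
#' (that cell's median interval), `NA` while no other cell has been sampled.
#' Keeping the neighbour distinct from the focal cell is what lets these act
#' as covariates for checklists in already-sampled cells, where the
#' nearest-sampled distance is identically zero.
#'
#' @param grid A `sampling_grid`.
#' @param cell_days Tibble `cell_id`, `date` of sampled cell-days (dates as
#'   `Date` or integer days; duplicates fine).
#' @param dates Query dates (vector).
#' @return Long tibble: `cell_id`, `date`, `ever_sampled`,
#'   `dist_nearest_sampled`, `median_interval`, `days_since_last`,
#'   `sampling_duration`, `n_unique_days`, `neighbor_dist_km`,
#'   `neighbor_median_interval`. Within-cell history fields of a
#'   never-sampled cell are `NA` (and `n_unique_days = 0`); its
#'   `dist_nearest_sampled` equals its neighbour distance when any cell has
#'   been sampled.
#' @export
daily_parameter_panel <- function(grid, cell_days, dates) {
  stopifnot(inherits(grid, "sampling_grid"))
  ncell <- nrow(grid$cells)
  qdates <- as_day_int(dates)
  nq <- length(qdates)
  out_date <- if (inherits(dates, "Date")) dates else qdates

  hist_tbl <- tibble::tibble(cell_id = as.integer(cell_days$cell_id),
                             day = as_day_int(cell_days$date))
  hist <- vector("list", ncell)
  split_days <- split(hist_tbl$day, hist_tbl$cell_id)
  for (nm in names(split_days)) hist[[as.integer(nm)]] <- sort(unique(split_days[[nm]]))
  first_day <- vapply(hist, function(d) if (length(d)) d[[1]] else Inf, numeric(1))

  # per-cell, per-date counts of strictly-prior sampled days (vectorised over dates)
  NP <- matrix(0L, nrow = ncell, ncol = nq)
  M_med <- matrix(NA_real_, ncell, nq)
  M_dsl <- matrix(NA_real_, ncell, nq)
  M_dur <- matrix(NA_real_, ncell, nq)
  for (c_id in seq_len(ncell)) {
    D <- hist[[c_id]]
    if (is.null(D) || length(D) == 0) next
    np <- findInterval(qdates - 1L, D)  # number of sampled days < query date
    NP[c_id, ] <- np
    pos <- np >= 1L
    if (!any(pos)) next
    gaps <- diff(D)
    ks <- sort(unique(np[pos]))
    med_at <- vapply(ks, function(k) {
      if (k < 2L) 1 else stats::median(gaps[seq_len(k - 1L)])
    }, numeric(1))
    med_lookup <- stats::setNames(med_at, ks)
    M_med[c_id, pos] <- med_lookup[as.character(np[pos])]
    M_dsl[c_id, pos] <- qdates[pos] - D[np[pos]]
    M_dur[c_id, pos] <- D[np[pos]] - D[[1]]
  }

  cmat <- as.matrix(grid$cells[, c("cx", "cy")])
  dmat <- as.matrix(stats::dist(cmat))
  diag(dmat) <- Inf  # a cell is never its own neighbour

  # nearest *other* sampled cell, tracked incrementally: the sampled set only
  # grows with the date, so each newly sampled cell can only shorten distances
  ord <- order(qdates)
  nd <- rep(Inf, ncell)       # current nearest-other-sampled distance
  nn <- rep(NA_integer_, ncell)
  in_set <- rep(FALSE, ncell)
  M_nd <- matrix(NA_real_, ncell, nq)
  M_nn <- matrix(NA_integer_, ncell, nq)
  for (t in ord) {
    newly <- which(!in_set & first_day <= qdates[[t]] - 1L)
    for (s in newly) {
      in_set[[s]] <- TRUE
      cand <- dmat[, s]
      improve <- cand < nd
      nd[improve] <- cand[improve]
      nn[improve] <- s
      # the new cell's own neighbour among the existing set
      if (any(in_set[-s])) {
        others <- which(in_set)
        others <- others[others != s]
        k <- others[[which.min(dmat[s, others])]]
        if (dmat[s, k] < nd[[s]]) {
          nd[[s]] <- dmat[s, k]
          nn[[s]] <- k
        }
      }
    }
    has <- is.finite(nd)
    M_nd[has, t] <- nd[has]
    M_nn[has, t] <- nn[has]
  }

  M_nmed <- matrix(NA_real_, ncell, nq)
  idx <- which(!is.na(M_nn))
  M_nmed[idx] <- M_med[cbind(M_nn[idx], ((idx - 1L) %/% ncell) + 1L)]

  sampled_now <- NP >= 1L
  M_dist <- M_nd
  M_dist[sampled_now] <- 0

  tibble::tibble(
    cell_id = rep(seq_len(ncell), times = nq),
    date = rep(out_date, each = ncell),
    ever_sampled = as.vector(sampled_now),
    dist_nearest_sampled = as.vector(M_dist),
    median_interval = as.vector(M_med),
    days_since_last = as.vector(M_dsl),
    sampling_duration = as.vector(M_dur),
    n_unique_days = as.vector(NP),
    neighbor_dist_km = as.vector(M_nd),
    neighbor_median_interval = as.vector(M_nmed)
  )
}

#' @rdname daily_parameter_panel
#' @param date A single query date.
#' @export
daily_parameters <- function(grid, cell_days, date) {
  stopifnot(length(date) == 1)
  daily_parameter_panel(grid, cell_days, date)
}

cell_polygon_coords <- function(cell, anchor = NULL) {
  xs <- c(cell$x0, cell$x1, cell$x1, cell$x0, cell$x0)
  ys <- c(cell$y0, cell$y0, cell$y1, cell$y1, cell$y0)
  if (!is.null(anchor)) {
    ll <- unproject_xy(xs, ys, anchor)
    xs <- ll$lon
    ys <- ll$lat
  }
  lapply(seq_along(xs), function(i) c(xs[[i]], ys[[i]]))
}

#' Write a grid (optionally with per-cell values) as GeoJSON
#'
#' Cell polygons are emitted in lon/lat when the grid carries a projection
#' anchor, otherwise in the planar coordinates of the grid.
#'
#' @param grid A `sampling_grid`.
#' @param path Output path.
#' @param values Optional tibble with `cell_id` plus value columns copied
#'   into each feature's properties.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path, values = NULL) {
  stopifnot(inherits(grid, "sampling_grid"))
  cells <- grid$cells
  features <- lapply(seq_len(nrow(cells)), function(i) {
    props <- list(cell_id = cells$cell_id[[i]])
    if (!is.null(values)) {
      row <- values[values$cell_id == cells$cell_id[[i]], , drop = FALSE]
      if (nrow(row) == 1) {
        for (nm in setdiff(names(row), "cell_id")) props[[nm]] <- row[[nm]][[1]]
      }
    }
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(cell_polygon_coords(cells[i, ], grid$anchor))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
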