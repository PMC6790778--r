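# Small internal helpers shared across modules.

# Kilometres per degree of latitude on a spherical Earth (R = 6371 km).
KM_PER_DEG <- pi * 6371 / 180

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded operations never perturb the caller's
#' random stream. With `seed = NULL` the expression runs on the current
#' stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Project longitude/latitude to local planar kilometres
#'
#' Equirectangular projection about an anchor point: adequate at the regional
#' extents (tens to ~150 km) this package targets. The same anchor inverts the
#' projection exactly, which is how the synthetic simulator places its planar
#' world on the globe.
#'
#' @param lon,lat Numeric vectors of decimal degrees.
#' @param anchor Length-2 numeric `c(lon, lat)` of the projection origin.
#' @return A tibble with columns `x`, `y` in kilometres east/north of `anchor`.
#' @export
project_lonlat <- function(lon, lat, anchor) {
  stopifnot(length(anchor) == 2, is.finite(anchor))
  tibble::tibble(
    x = (lon - anchor[[1]]) * KM_PER_DEG * cos(anchor[[2]] * pi / 180),
    y = (lat - anchor[[2]]) * KM_PER_DEG
  )
}

#' @rdname project_lonlat
#' @param x,y Planar kilometres east/north of `anchor`.
#' @return For `unproject_xy()`, a tibble with columns `lon`, `lat`.
#' @export
unproject_xy <- function(x, y, anchor) {
  stopifnot(length(anchor) == 2, is.finite(anchor))
  tibble::tibble(
    lon = anchor[[1]] + x / (KM_PER_DEG * cos(anchor[[2]] * pi / 180)),
    lat = anchor[[2]] + y / KM_PER_DEG
  )
}

# stop() without the call, with sprintf-style formatting
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# message() with a consistent stage prefix for pipeline logs
log_msg <- function(fmt, ...) message(sprintf(fmt, ...))
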