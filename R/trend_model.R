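#' Build the shared trend-model design
#'
#' Every species' trend model shares one design: an intercept, a continuous
#' day term (integer days since `day_origin`), a categorical county term
#' (reference level = first sorted level), and an offset of `log(list_length)`
#' correcting for observer effort.
#'
#' @param checklists Retained checklists from [filter_checklists()].
#' @param county_levels Factor levels for the county term; defaults to the
#'   sorted counties present. A checklist county outside the levels is fatal.
#' @param day_origin Date that maps to day 0.
#' @return A `trend_design` list: `data` (model frame with `day`, `county`,
#'   `log_list_length`), `formula_rhs`, `checklist_id`, `county_levels`,
#'   `day_origin`.
#' @export
build_design <- function(checklists,
                         county_levels = NULL,
                         day_origin = as.Date("2010-01-01")) {
  county_levels <- county_levels %||% sort(unique(checklists$county))
  unseen <- setdiff(unique(checklists$county), county_levels)
  if (length(unseen) > 0) {
    abort_fmt("county level(s) not in county_levels: %s",
              paste(unseen, collapse = ", "))
  }
  data <- tibble::tibble(
    checklist_id = checklists$checklist_id,
    day = as.numeric(checklists$date - day_origin),
    county = factor(checklists$county, levels = county_levels),
    log_list_length = log(checklists$list_length)
  )
  if (any(!is.finite(data$log_list_length))) {
    abort_fmt("non-finite offset: every checklist needs list_length >= 1")
  }
  # county enters the formula only when it can be contrast-coded
  rhs <- if (length(county_levels) > 1) "day + county" else "day"
  structure(
    list(data = data, formula_rhs = rhs, checklist_id = data$checklist_id,
         county_levels = county_levels, day_origin = day_origin),
    class = "trend_design"
  )
}

#' Extract influence diagnostics from a fitted GLM
#'
#' Wraps any `glm` fit into the diagnostic bundle the leverage module
#' consumes: coefficients, unscaled covariance of the weighted design,
#' hat diagonals, working residuals and IRLS weights at convergence.
#'
#' @param fit A fitted `glm` object.
#' @param species_code Optional label.
#' @param converged Convergence flag; defaults to the fit's own.
#' @return A `trend_fit` list.
#' @export
as_trend_fit <- function(fit, species_code = NA_character_, converged = NULL) {
  sm <- summary(fit)
  structure(
    list(
      species_code = species_code,
      coefficients = stats::coef(fit),
      vcov = sm$cov.scaled %||% (sm$cov.unscaled * sm$dispersion),
      cov_unscaled = sm$cov.unscaled,
      X = stats::model.matrix(fit),
      hat = stats::hatvalues(fit),
      working_residuals = stats::residuals(fit, type = "working"),
      weights = stats::weights(fit, type = "working"),
      offset = fit$offset %||% rep(0, length(fit$y)),
      y = fit$y,
      fitted = stats::fitted(fit),
      converged = converged %||% (fit$converged && !fit$boundary),
      reason = NA_character_,
      n = length(fit$y),
      p = fit$rank
    ),
    class = "trend_fit"
  )
}

unconverged_stub <- function(species_code, reason, n) {
  structure(
    list(species_code = species_code, coefficients = NULL, vcov = NULL,
         cov_unscaled = NULL, X = NULL, hat = NULL,
         working_residuals = NULL, weights = NULL, offset = NULL,
         y = NULL, fitted = NULL, converged = FALSE, reason = reason,
         n = n, p = NA_integer_),
    class = "trend_fit"
  )
}

#' Fit one species' presence/absence trend model
#'
#' Logistic GLM of presence/absence on day + county with the log list-length
#' offset, fitted by iteratively reweighted least squares via [stats::glm()].
#' Degenerate responses (all present or all absent) and fits showing
#' numerical separation are flagged unconverged and excluded downstream.
#'
#' @param design A `trend_design` from [build_design()].
#' @param y Binary presence vector aligned with the design rows.
#' @param species_code Label attached to the fit.
#' @return A `trend_fit` (see [as_trend_fit()]) with a `converged` flag.
#' @export
fit_species_trend <- function(design, y, species_code = NA_character_) {
  stopifnot(inherits(design, "trend_design"))
  if (length(y) != nrow(design$data)) {
    abort_fmt("response length (%d) does not match design rows (%d)",
              length(y), nrow(design$data))
  }
  if (length(unique(y)) < 2) {
    return(unconverged_stub(species_code, "degenerate response (all present or all absent)",
                            length(y)))
  }
  df <- design$data
  df$.y <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(paste(".y ~", design$formula_rhs)),
               family = stats::binomial(), data = df,
               offset = log_list_length),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  out <- as_trend_fit(fit, species_code,
                      converged = fit$converged && !fit$boundary && !separated)
  rownames(out$X) <- design$data$checklist_id
  if (!out$converged) {
    out$reason <- if (separated) "separation" else "IRLS did not converge"
  }
  out
}

#' Fit the trend model for every species
#'
#' @param design A `trend_design` shared by all species.
#' @param presence Zero-filled presence matrix from [zero_fill()]; rows must
#'   align with the design.
#' @return A named list of `trend_fit` objects (class `trend_fits`);
#'   unconverged species are logged.
#' @export
fit_all_trends <- function(design, presence) {
  stopifnot(inherits(design, "trend_design"))
  if (nrow(presence) != nrow(design$data)) {
    abort_fmt("presence matrix rows (%d) do not match design rows (%d)",
              nrow(presence), nrow(design$data))
  }
  fits <- lapply(colnames(presence), function(s) {
    fit_species_trend(design, presence[, s], species_code = s)
  })
  names(fits) <- colnames(presence)
  bad <- names(fits)[!vapply(fits, `[[`, logical(1), "converged")]
  if (length(bad) > 0) {
    log_msg("fit_all_trends: %d species flagged unconverged: %s",
            length(bad), paste(bad, collapse = ", "))
  }
  structure(fits, class = "trend_fits")
}

#' Trend-slope convergence versus number of checklists
#'
#' Quantifies how the day-slope estimate stabilises as checklists accumulate:
#' for each sample size, checklists are subsampled without replacement and
#' every species' model refitted. Two per-size summaries are recorded, the
#' mean over species of the absolute deviation of the subsample slope from
#' the full-data slope, and the mean slope standard error. The reported
#' convergence point is the smallest size at which the mean SE falls to half
#' its value at the smallest size (the deviation-based analogue is also
#' attached).
#'
#' @param checklists Retained checklists.
#' @param species_set Species codes to refit (a subset keeps this cheap).
#' @param sizes Integer vector of subsample sizes (each `<= nrow(checklists)`).
#' @param replicates Subsample replicates per size.
#' @param seed RNG seed for the subsampling.
#' @param day_origin Passed to [build_design()].
#' @return A tibble with columns `n`, `mean_abs_dev`, `mean_se` and
#'   attributes `n50_se`, `n50_dev` (smallest size reaching 50% of the
#'   smallest-size metric; `NA` if never reached).
#' @export
slope_convergence <- function(checklists, species_set, sizes,
                              replicates = 3, seed = 1,
                              day_origin = as.Date("2010-01-01")) {
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > nrow(checklists))) {
    abort_fmt("subsample size exceeds the number of checklists (%d)", nrow(checklists))
  }
  if (any(sizes < 100)) {
    warning("subsample sizes below 100 give unstable GLM fits", call. = FALSE)
  }

  fit_slopes <- function(cl) {
    design <- build_design(cl, day_origin = day_origin)
    P <- zero_fill(cl, species_set)
    fits <- fit_all_trends(design, P)
    ok <- vapply(fits, `[[`, logical(1), "converged")
    slope <- rep(NA_real_, length(fits))
    se <- rep(NA_real_, length(fits))
    slope[ok] <- vapply(fits[ok], function(f) f$coefficients[["day"]], numeric(1))
    se[ok] <- vapply(fits[ok], function(f) sqrt(f$vcov["day", "day"]), numeric(1))
    list(slope = slope, se = se)
  }
  full <- fit_slopes(checklists)

  res <- with_seed(seed, {
    purrr::map_dfr(sizes, function(nk) {
      reps <- purrr::map_dfr(seq_len(replicates), function(r) {
        idx <- sample.int(nrow(checklists), nk)
        sub <- fit_slopes(checklists[idx, , drop = FALSE])
        tibble::tibble(
          abs_dev = mean(abs(sub$slope - full$slope), na.rm = TRUE),
          se = mean(sub$se, na.rm = TRUE)
        )
      })
      tibble::tibble(n = nk,
                     mean_abs_dev = mean(reps$abs_dev),
                     mean_se = mean(reps$se))
    })
  })

  half_point <- function(metric) {
    target <- 0.5 * metric[[1]]
    hit <- which(metric <= target)
    if (length(hit) == 0) NA_integer_ else res$n[[min(hit)]]
  }
  attr(res, "n50_se") <- half_point(res$mean_se)
  attr(res, "n50_dev") <- half_point(res$mean_abs_dev)
  res
}
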