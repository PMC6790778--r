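#' One-step dfBeta of every observation on one coefficient
#'
#' Approximates, for each observation i, the change in a chosen coefficient
#' when that observation is omitted and the model refitted:
#' `dfBeta_i = [(X'WX)^{-1} x_i] w_i r_i / (1 - h_i)`, using the weighted
#' design, IRLS weights, working residuals and hat diagonals of the converged
#' fit. For a Gaussian linear model (W = I, r = ordinary residuals) this is
#' the classical closed form and equals the exact leave-one-out refit
#' difference; for a logistic fit it is the standard one-step approximation.
#' The sign convention is "full-data estimate minus deleted estimate": a
#' positive value means removing the observation would decrease the
#' coefficient.
#'
#' @param fit A converged `trend_fit` (from [fit_species_trend()] or
#'   [as_trend_fit()]).
#' @param coef Column label of the target coefficient (default `"day"`, the
#'   trend term).
#' @param standardized Divide by the coefficient's standard error (the
#'   conventional dfBetas scaling). Default `FALSE`: raw dfBeta.
#' @return Named numeric vector (one entry per observation). Observations
#'   with hat diagonal at 1 (within 1e-8) get `NA` and a warning: their
#'   leave-one-out change is not defined by the one-step form.
#' @export
dfbeta_one_step <- function(fit, coef = "day", standardized = FALSE) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!isTRUE(fit$converged)) {
    abort_fmt("dfbeta_one_step requires a converged fit (species %s: %s)",
              fit$species_code, fit$reason)
  }
  j <- match(coef, colnames(fit$X))
  if (is.na(j)) {
    abort_fmt("coefficient '%s' not in the design (have: %s)",
              coef, paste(colnames(fit$X), collapse = ", "))
  }
  denom <- 1 - fit$hat
  bad <- fit$hat >= 1 - 1e-8
  d <- as.numeric(fit$X %*% fit$cov_unscaled[, j]) *
    fit$weights * fit$working_residuals / denom
  if (any(bad)) {
    d[bad] <- NA_real_
    warning(sprintf("%d observation(s) with hat diagonal ~1 flagged non-finite", sum(bad)),
            call. = FALSE)
  }
  if (standardized) d <- d / sqrt(fit$vcov[j, j])
  names(d) <- rownames(fit$X) %||% as.character(seq_along(d))
  d
}

#' Per-checklist, per-species dfBeta table and marginal values
#'
#' Fills a checklist-by-species matrix of dfBeta values on the trend (day)
#' coefficient and sums absolute values across species into each checklist's
#' marginal value -- its cumulative influence on the region's species-trend
#' knowledge. Absences contribute exactly like presences: under zero-filling
#' a non-detection is an observation in every species' model. Unconverged
#' species contribute nothing (logged); non-finite entries (hat ~ 1) are
#' treated as zero in the sum and the checklist flagged.
#'
#' @param fits A `trend_fits` list sharing one set of checklist rows.
#' @param coef Target coefficient label (default `"day"`).
#' @param standardized Passed to [dfbeta_one_step()].
#' @return A `leverage_table` list: `dfbeta` (matrix), `values` (tibble of
#'   `checklist_id`, `marginal_value`), `flagged` (checklist ids holding a
#'   non-finite entry), `skipped_species`.
#' @export
build_leverage_table <- function(fits, coef = "day", standardized = FALSE) {
  ok <- vapply(fits, `[[`, logical(1), "converged")
  skipped <- names(fits)[!ok]
  if (length(skipped) > 0) {
    log_msg("build_leverage_table: skipping %d unconverged species: %s",
            length(skipped), paste(skipped, collapse = ", "))
  }
  usable <- fits[ok]
  if (length(usable) == 0) abort_fmt("no converged fits to tabulate")

  ids <- rownames(usable[[1]]$X) %||% as.character(seq_len(usable[[1]]$n))
  cols <- suppressWarnings(lapply(usable, function(f) {
    f_ids <- rownames(f$X) %||% as.character(seq_len(f$n))
    if (!identical(f_ids, ids)) {
      abort_fmt("checklist rows differ across fits (species %s)", f$species_code)
    }
    dfbeta_one_step(f, coef = coef, standardized = standardized)
  }))
  D <- do.call(cbind, cols)
  dimnames(D) <- list(ids, names(usable))

  absD <- abs(D)
  flagged <- ids[rowSums(is.na(absD)) > 0]
  absD[is.na(absD)] <- 0
  structure(
    list(
      dfbeta = D,
      values = tibble::tibble(checklist_id = ids,
                              marginal_value = unname(rowSums(absD))),
      flagged = flagged,
      skipped_species = skipped
    ),
    class = "leverage_table"
  )
}
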