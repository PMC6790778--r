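# The five sampling-history covariates of the value model: within-cell
# median sampling interval, number of unique sampled days, days since the
# last sample, distance to the nearest *other* sampled cell, and that
# neighbour's median interval. Duration is computed alongside them but
# excluded from the model (collinear with the median sampling interval).
VALUE_COVARIATES <- c("median_interval", "n_unique_days", "days_since_last",
                      "neighbor_dist_km", "neighbor_median_interval")

# log for strictly-positive covariates; log1p for fields with a meaningful
# zero (distances, which are 0 for sampled cells, and sampling duration,
# which is 0 for single-day histories).
cov_log_kind <- function(name) {
  if (name %in% c("dist_nearest_sampled", "neighbor_dist_km", "sampling_duration")) {
    "log1p"
  } else {
    "log"
  }
}

cov_log <- function(name, x) {
  if (cov_log_kind(name) == "log1p") log1p(x) else log(x)
}

#' Build the value-model training table
#'
#' One row per evaluation-year checklist: the response is its marginal value
#' (summed absolute dfBeta over species) and the covariates are its grid
#' cell's sampling-history parameters on its date -- parameters computed from
#' strictly earlier sampling, so the row describes what was known *before*
#' the checklist happened. Rows whose cell had never been sampled before are
#' flagged `unsampled`; they feed the unsampled-site effect test, not the
#' main fit (they lack within-cell history covariates).
#'
#' @param leverage A `leverage_table` from [build_leverage_table()].
#' @param panel Daily parameters from [daily_parameter_panel()] covering the
#'   evaluation-year dates.
#' @param cells Checklist-to-cell map from [assign_cells()].
#' @param checklists Retained checklists (for dates).
#' @param eval_year Calendar year whose checklists form the training rows.
#' @return Tibble: `checklist_id`, `cell_id`, `date`, `marginal_value`,
#'   the seven parameters, `unsampled`.
#' @export
join_training_table <- function(leverage, panel, cells, checklists, eval_year) {
  stopifnot(inherits(leverage, "leverage_table"))
  cl <- checklists[format(checklists$date, "%Y") == as.character(eval_year),
                   c("checklist_id", "date")]
  if (nrow(cl) == 0) abort_fmt("no checklists in evaluation year %s", eval_year)
  rows <- cl |>
    dplyr::inner_join(cells, by = "checklist_id") |>
    dplyr::inner_join(leverage$values, by = "checklist_id")
  if (nrow(rows) == 0) abort_fmt("no evaluation-year checklists fall inside the grid")
  joined <- dplyr::left_join(rows, panel, by = c("cell_id", "date"))
  if (anyNA(joined$ever_sampled)) {
    abort_fmt("missing daily parameter record for %d checklist(s); panel does not cover the evaluation dates",
              sum(is.na(joined$ever_sampled)))
  }
  joined$unsampled <- !joined$ever_sampled
  joined
}

#' Collinearity screen for the sampling-history covariates
#'
#' Pairwise correlations of the log-transformed covariates (including
#' sampling duration) on the sampled-cell training rows. Duration is
#' excluded from the model unconditionally -- it tracks the median sampling
#' interval; any other pair exceeding the threshold is reported, not
#' dropped.
#'
#' @param rows Training table from [join_training_table()].
#' @param threshold Absolute correlation that flags a pair (default 0.7).
#' @return List: `correlations` (matrix), `flagged` (tibble of pairs with
#'   `|r| > threshold`), `retained` (the five model covariates),
#'   `duration_excluded = TRUE`.
#' @export
collinearity_screen <- function(rows, threshold = 0.7) {
  covs <- c(VALUE_COVARIATES, "sampling_duration")
  use <- rows[!rows$unsampled, covs, drop = FALSE]
  all_na <- vapply(use, function(x) all(is.na(x)), logical(1))
  use <- use[, !all_na, drop = FALSE]
  covs <- names(use)
  use <- use[stats::complete.cases(use), , drop = FALSE]
  logged <- as.data.frame(lapply(stats::setNames(covs, covs), function(nm) {
    cov_log(nm, use[[nm]])
  }))
  ok <- vapply(logged, function(x) isTRUE(stats::sd(x) > 0), logical(1))
  cm <- matrix(NA_real_, length(covs), length(covs), dimnames = list(covs, covs))
  diag(cm) <- 1
  if (sum(ok) >= 2) {
    cm[ok, ok] <- stats::cor(logged[, ok, drop = FALSE])
  }
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = rownames(cm)[pairs[, 1]],
    var2 = colnames(cm)[pairs[, 2]],
    r = cm[pairs]
  )
  list(correlations = cm, flagged = flagged,
       retained = VALUE_COVARIATES, duration_excluded = TRUE)
}

#' Fit the marginal-value regression
#'
#' Ordinary least squares of `log(marginal value)` on the five
#' log-transformed, standardized sampling-history covariates. Because the
#' covariates are standardized with *training* means and SDs (stored on the
#' fit and reused at prediction time), the coefficients are directly
#' comparable effect sizes. Covariates that are constant on the training
#' rows, or aliased with an earlier covariate, are structurally
#' uninformative at that grain (e.g. the nearest-sampled distance once every
#' cell has been sampled); they are dropped with a warning and recorded.
#'
#' @param rows Training table from [join_training_table()]; `unsampled` rows
#'   and non-positive responses are dropped (counted).
#' @param covariates Covariate names (default the five model covariates).
#' @return A `value_model_fit`: `model` (the `lm`), `transforms` (per
#'   covariate: log kind, mean, sd), `covariates_used`, `dropped`,
#'   `coef_table` (term, estimate, se, p), `n`, `r_squared`.
#' @export
fit_value_model <- function(rows, covariates = VALUE_COVARIATES) {
  if ("unsampled" %in% names(rows)) rows <- rows[!rows$unsampled, , drop = FALSE]
  n_nonpos <- sum(rows$marginal_value <= 0)
  if (n_nonpos > 0) {
    log_msg("fit_value_model: dropping %d row(s) with non-positive marginal value", n_nonpos)
    rows <- rows[rows$marginal_value > 0, , drop = FALSE]
  }
  if (nrow(rows) == 0) abort_fmt("no usable training rows")

  # covariates with no information at this grain (e.g. neighbour fields on a
  # single-cell grid) are dropped; remaining rows must be complete
  dropped <- covariates[vapply(covariates, function(nm) all(is.na(rows[[nm]])),
                               logical(1))]
  covariates <- setdiff(covariates, dropped)
  cc <- stats::complete.cases(rows[, covariates, drop = FALSE])
  if (!all(cc)) {
    log_msg("fit_value_model: dropping %d row(s) with incomplete covariates", sum(!cc))
    rows <- rows[cc, , drop = FALSE]
  }
  if (nrow(rows) == 0) abort_fmt("no usable training rows")

  transforms <- list()
  Z <- list()
  for (nm in covariates) {
    z <- cov_log(nm, rows[[nm]])
    mu <- mean(z)
    sd_z <- stats::sd(z)
    if (!is.finite(sd_z) || sd_z == 0) {
      dropped <- c(dropped, nm)
      next
    }
    transforms[[nm]] <- list(log = cov_log_kind(nm), mean = mu, sd = sd_z)
    Z[[nm]] <- (z - mu) / sd_z
  }
  if (length(Z) == 0) {
    abort_fmt("value-model design is rank deficient: every covariate is constant on the training rows")
  }
  Zm <- as.data.frame(Z)
  # drop covariates aliased with earlier ones (identical up to affine terms)
  qrz <- qr(cbind(1, as.matrix(Zm)))
  if (qrz$rank < ncol(Zm) + 1) {
    keep_idx <- qrz$pivot[seq_len(qrz$rank)]
    keep <- names(Zm)[sort(keep_idx[keep_idx > 1] - 1)]
    dropped <- c(dropped, setdiff(names(Zm), keep))
    transforms <- transforms[keep]
    Zm <- Zm[, keep, drop = FALSE]
  }
  if (ncol(Zm) == 0) {
    abort_fmt("value-model design is rank deficient: no informative covariate remains")
  }
  if (length(dropped) > 0) {
    warning(sprintf("fit_value_model: dropped uninformative covariate(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (nrow(rows) <= 10 * ncol(Zm)) {
    warning(sprintf("only %d training rows for %d covariates", nrow(rows), ncol(Zm)),
            call. = FALSE)
  }

  df <- cbind(.log_value = log(rows$marginal_value), Zm)
  model <- stats::lm(.log_value ~ ., data = df)
  sm <- summary(model)
  ct <- stats::coef(sm)
  structure(
    list(
      model = model,
      transforms = transforms,
      covariates_used = names(Zm),
      dropped = dropped,
      coef_table = tibble::tibble(
        term = rownames(ct),
        estimate = ct[, "Estimate"],
        se = ct[, "Std. Error"],
        p = ct[, "Pr(>|t|)"]
      ),
      n = nrow(rows),
      r_squared = sm$r.squared
    ),
    class = "value_model_fit"
  )
}

#' Predict expected log marginal value for parameter rows
#'
#' Applies the fit's stored training transforms (log, then standardize by
#' training mean/SD) before predicting; rows must carry the fit's covariates.
#'
#' @param fit A `value_model_fit`.
#' @param rows Tibble of parameter rows (e.g. from
#'   [daily_parameter_panel()]).
#' @return Numeric vector of predicted log marginal values.
#' @export
predict_value <- function(fit, rows) {
  stopifnot(inherits(fit, "value_model_fit"))
  Z <- lapply(stats::setNames(fit$covariates_used, fit$covariates_used), function(nm) {
    tr <- fit$transforms[[nm]]
    (cov_log(nm, rows[[nm]]) - tr$mean) / tr$sd
  })
  stats::predict(fit$model, newdata = as.data.frame(Z))
}

#' Test whether never-sampled cells yield more valuable checklists
#'
#' Regresses log marginal value on a binary "cell never sampled before"
#' indicator, separately from the five-covariate model (unsampled cells lack
#' the within-cell history covariates). Infeasible -- and flagged so --
#' when the evaluation rows contain no unsampled (or no sampled) cells, as
#' happens at coarse grains once every site has been visited.
#'
#' @param rows Training table from [join_training_table()].
#' @param grain Grain label carried into the result.
#' @return An `effect_estimate` list: `grain`, `effect`, `se`, `p`,
#'   `n_unsampled`, `feasible`.
#' @export
test_unsampled_effect <- function(rows, grain = NA_real_) {
  rows <- rows[rows$marginal_value > 0, , drop = FALSE]
  n_uns <- sum(rows$unsampled)
  if (n_uns == 0 || n_uns == nrow(rows)) {
    return(structure(list(grain = grain, effect = NA_real_, se = NA_real_,
                          p = NA_real_, n_unsampled = n_uns, feasible = FALSE),
                     class = "effect_estimate"))
  }
  fit <- stats::lm(log(marginal_value) ~ unsampled, data = rows)
  ct <- stats::coef(summary(fit))["unsampledTRUE", ]
  structure(
    list(grain = grain, effect = unname(ct[["Estimate"]]),
         se = unname(ct[["Std. Error"]]), p = unname(ct[["Pr(>|t|)"]]),
         n_unsampled = n_uns, feasible = TRUE),
    class = "effect_estimate"
  )
}

#' Predict the expected-marginal-value map for one date
#'
#' Cells sampled before the date get a model prediction from their
#' sampling-history parameters (training transforms applied); never-sampled
#' cells are imputed with the mean of the sampled cells' predictions for
#' that date. Where a cell hosted several checklists that day, one of the
#' per-checklist expected values is selected uniformly at random (seeded),
#' mirroring how observed days with multiple lists are resolved.
#'
#' @param fit A `value_model_fit`.
#' @param params Parameter rows for a single date (all cells).
#' @param day_cells Optional tibble `checklist_id`, `cell_id` of that day's
#'   observed checklists (drives the multi-checklist selection).
#' @param seed RNG seed for the selection step; same seed, same map.
#' @return An `expected_value_map` tibble: `cell_id`, `date`,
#'   `expected_log_value`, `provenance` (`"modelled"` or `"mean-imputed"`).
#' @export
predict_daily_map <- function(fit, params, day_cells = NULL, seed = NULL) {
  stopifnot(inherits(fit, "value_model_fit"))
  if (length(unique(params$date)) != 1) {
    abort_fmt("predict_daily_map expects parameter rows for exactly one date")
  }
  sampled <- params$ever_sampled
  if (!any(sampled)) abort_fmt("no cell sampled before this date; nothing to predict from")

  pred <- rep(NA_real_, nrow(params))
  pred[sampled] <- predict_value(fit, params[sampled, , drop = FALSE])

  out <- tibble::tibble(
    cell_id = params$cell_id,
    date = params$date,
    expected_log_value = pred,
    provenance = ifelse(sampled, "modelled", "mean-imputed")
  )
  out$expected_log_value[!sampled] <- mean(pred[sampled])

  if (!is.null(day_cells) && nrow(day_cells) > 0) {
    multi <- table(day_cells$cell_id)
    multi <- as.integer(names(multi)[multi > 1])
    if (length(multi) > 0) {
      out$expected_log_value <- with_seed(seed, {
        v <- out$expected_log_value
        for (cid in multi) {
          i <- match(cid, out$cell_id)
          # one checklist-level expectation chosen at random among the day's
          # lists (equal under cell-day covariates, but the draw keeps the
          # selection contract explicit and seeded)
          cand <- rep(v[[i]], sum(day_cells$cell_id == cid))
          v[[i]] <- cand[[sample.int(length(cand), 1)]]
        }
        v
      })
    }
  }
  structure(out, class = c("expected_value_map", class(out)))
}
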