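# Model performance battery: mean absolute error, residual exceedance
# rates, within- and out-of-sample correlation, holdout error, model
# comparison tables, and the rank-task consistency statistics.

align_values <- function(predicted, observed) {
  if (is.null(names(predicted)) || is.null(names(observed))) {
    stop("predicted and observed must be named by state label", call. = FALSE)
  }
  missing_states <- setdiff(names(observed), names(predicted))
  extra_states <- setdiff(names(predicted), names(observed))
  if (length(missing_states) || length(extra_states)) {
    stop(sprintf("state keys differ; missing predictions: %s; missing observations: %s",
                 paste(missing_states, collapse = ", "),
                 paste(extra_states, collapse = ", ")), call. = FALSE)
  }
  list(predicted = predicted[names(observed)], observed = observed)
}

#' Mean absolute error between predicted and observed state values
#'
#' @param predicted,observed named numeric vectors over the same state
#'   labels; a key mismatch is an error listing the offending states.
#' @return Mean of the absolute differences, in the units of the inputs
#'   (VAS points on the raw scale, value units on a rescaled scale).
#' @export
mae <- function(predicted, observed) {
  a <- align_values(predicted, observed)
  mean(abs(a$predicted - a$observed))
}

#' Percentage of residuals exceeding a threshold
#'
#' Strict inequality: `100 * mean(|predicted - observed| > threshold)`.
#' The conventional thresholds are 5 VAS points on the raw scale and 0.05
#' on a rescaled scale.
#'
#' @inheritParams mae
#' @param threshold numeric threshold on the scale of the inputs.
#' @return Percentage in 0-100.
#' @export
pct_residuals_above <- function(predicted, observed, threshold) {
  a <- align_values(predicted, observed)
  100 * mean(abs(a$predicted - a$observed) > threshold)
}

#' Correlation between predicted and observed state values
#'
#' @inheritParams mae
#' @param method `"pearson"` or `"spearman"` (midranks for ties).
#' @return Correlation coefficient.
#' @export
value_correlation <- function(predicted, observed, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- align_values(predicted, observed)
  if (length(a$observed) < 3) stop("need at least 3 shared states", call. = FALSE)
  if (stats::sd(a$observed) == 0 || stats::sd(a$predicted) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(a$predicted, a$observed, method = method)
}

default_threshold <- function(scale) if (scale == "raw") 5 else 0.05

observed_from_table <- function(table, scale, states) {
  sm <- resolve_state_means(table, scale)
  missing_states <- setdiff(states, names(sm$values))
  if (length(missing_states)) {
    stop(sprintf("observed table lacks state(s): %s",
                 paste(missing_states, collapse = ", ")), call. = FALSE)
  }
  sm$values[states]
}

#' Evaluate a fitted model against observed state values
#'
#' Computes the criteria battery for one model/data pair: MAE (also
#' expressed in percent: x100 on a rescaled scale, VAS points read as
#' percent on the raw scale), the percentage of absolute residuals above
#' the conventional threshold, and Pearson and Spearman correlations.
#'
#' @param model a `"vas_model"`.
#' @param observed a state value table carrying the model's scale (default:
#'   the model's own training values, giving within-sample criteria).
#' @param states evaluation states (default: the model's inclusion set).
#' @param anchor_full_health predict 11111 at the scale top (tariff
#'   convention)? Defaults to `TRUE`, the convention under which published
#'   study batteries are reproduced; the plain linear form is used when
#'   `FALSE`.
#' @param threshold residual threshold; default 5 raw VAS points or 0.05
#'   rescaled.
#' @return An object of class `"vas_evaluation"`: list with `mae`,
#'   `mae_pct`, `pct_above`, `threshold`, `pearson`, `spearman`, `n`,
#'   `scale`.
#' @export
evaluate <- function(model, observed = NULL, states = model$states,
                     anchor_full_health = TRUE, threshold = NULL) {
  obs <- if (is.null(observed)) {
    model$observed[states]
  } else {
    observed_from_table(observed, model$spec$scale, states)
  }
  pred <- predict(model, states, anchor_full_health = anchor_full_health)
  if (is.null(threshold)) threshold <- default_threshold(model$spec$scale)
  m <- mae(pred, obs)
  structure(list(
    mae = m,
    mae_pct = if (model$spec$scale == "raw") m else 100 * m,
    pct_above = pct_residuals_above(pred, obs, threshold),
    threshold = threshold,
    pearson = value_correlation(pred, obs, "pearson"),
    spearman = value_correlation(pred, obs, "spearman"),
    n = length(states), scale = model$spec$scale
  ), class = "vas_evaluation")
}

#' @export
print.vas_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation over %d states (%s scale):\n", x$n, x$scale))
  cat(sprintf("  MAE %.2f%%  | residuals > %s: %.0f%%\n", x$mae_pct,
              format(x$threshold), x$pct_above))
  cat(sprintf("  correlation: pearson %.4f, spearman %.4f\n", x$pearson, x$spearman))
  invisible(x)
}

#' Out-of-sample evaluation against another set's observed values
#'
#' Evaluates a model fitted on one valuation set against the observed
#' means of the other set, over that set's own inclusion states. The
#' observed table must carry values on the model's scale; comparing a
#' raw-scale model against rescaled observations is an error.
#'
#' @param model a `"vas_model"`.
#' @param observed state value table for the out-of-sample set.
#' @param states evaluation states (default: every non-dead state in
#'   `observed`).
#' @param anchor_full_health see [evaluate()].
#' @return A `"vas_evaluation"`.
#' @export
cross_evaluate <- function(model, observed, states = NULL,
                           anchor_full_health = TRUE) {
  if (is.null(states)) {
    states <- observed$state[!is_dead(observed$state)]
    states <- unique(parse_state(states))
  }
  evaluate(model, observed, states, anchor_full_health = anchor_full_health)
}

#' Holdout mean absolute error
#'
#' MAE over designated holdout states only. The holdouts must be disjoint
#' from the model's fit inclusion set.
#'
#' @param model a `"vas_model"`.
#' @param holdout_observed named numeric vector of observed holdout values
#'   on the model's scale.
#' @param anchor_full_health see [evaluate()].
#' @return MAE over the holdout states (value units).
#' @export
holdout_evaluate <- function(model, holdout_observed, anchor_full_health = TRUE) {
  hs <- names(holdout_observed)
  overlap <- intersect(hs, model$states)
  if (length(overlap)) {
    stop(sprintf("holdout state(s) %s were used in fitting",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  pred <- predict(model, hs, anchor_full_health = anchor_full_health)
  mae(pred, holdout_observed)
}

#' Model comparison table
#'
#' Assembles a coefficient-and-criteria comparison across models fitted on
#' the same data context: one column per model, rows for the constant, the
#' ten dummies, any extra terms, and the evaluation criteria (adjusted
#' R-squared, correlation, MAE, % residuals above threshold, optional
#' holdout MAE). Internally invalid models are flagged and can be dropped.
#'
#' @param models named list of `"vas_model"` objects.
#' @param observed common observed state value table (default: each
#'   model's training values).
#' @param holdout_observed optional named vector of holdout values.
#' @param anchor_full_health prediction convention for the criteria rows
#'   (`FALSE` reproduces published combined-set batteries).
#' @param drop_invalid drop internally invalid models instead of flagging?
#' @return Data frame with one row per term/criterion, one column per
#'   model; attribute `"validity"` holds the per-model validity flags.
#' @export
comparison_table <- function(models, observed = NULL, holdout_observed = NULL,
                             anchor_full_health = FALSE, drop_invalid = FALSE) {
  if (inherits(models, "vas_model")) models <- list(model = models)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  validity <- vapply(models, function(m) internal_validity(m)$valid, logical(1))
  if (drop_invalid) models <- models[validity]
  terms <- unique(unlist(lapply(models, function(m) names(m$coefficients))))
  terms <- c(intersect(c("Constant", dummy_names()), terms),
             setdiff(terms, c("Constant", dummy_names())))
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    ev <- evaluate(m, observed = observed, anchor_full_health = anchor_full_health)
    crit <- c(`Adj R Sq` = m$adj_r_squared,
              `Correl Model vs Observed` = ev$pearson,
              `% MAE Model vs Observed` = ev$mae_pct,
              `% Residuals above threshold` = ev$pct_above)
    if (!is.null(holdout_observed)) {
      hm <- holdout_evaluate(m, holdout_observed,
                             anchor_full_health = anchor_full_health)
      crit <- append(crit, c(`% MAE Model vs Holdouts` =
                               if (m$spec$scale == "raw") hm else 100 * hm),
                     after = 3)
    }
    coefs <- stats::setNames(m$coefficients[terms], terms)
    c(coefs, crit)
  })
  out <- as.data.frame(stats::setNames(rows, names(models)), check.names = FALSE)
  attr(out, "validity") <- validity
  out
}

#' Rank-task versus VAS-task consistency
#'
#' For each respondent carrying rank data, the Spearman correlation
#' (midranks for ties) between the elicited ranks and the ranking induced
#' by the VAS ratings (higher rating = better rank), and whether the
#' respondent preserved the rank order — the two orderings identical up to
#' ties — in moving from the ranking task to the VAS task.
#'
#' @param data long respondent data frame with `rank` column (rank 1 =
#'   best).
#' @return List with `per_respondent` (data frame: respondent_id,
#'   spearman, preserved), `mean_spearman` and `pct_preserved`.
#' @export
rank_consistency <- function(data) {
  data <- check_respondent_data(data, require_rank = TRUE)
  if (any(is.na(data$rank))) stop("missing rank data", call. = FALSE)
  ids <- unique(data$respondent_id)
  res <- lapply(ids, function(id) {
    d <- data[data$respondent_id == id, ]
    elicited <- rank(d$rank, ties.method = "average")
    by_vas <- rank(-d$vas_raw, ties.method = "average")
    data.frame(respondent_id = id,
               spearman = stats::cor(elicited, by_vas),
               preserved = isTRUE(all.equal(elicited, by_vas)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, res)
  list(per_respondent = per,
       mean_spearman = mean(per$spearman),
       pct_preserved = 100 * mean(per$preserved))
}
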