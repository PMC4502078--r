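# Utility-function estimation. One fitting function, vas_model(), covering
# the six baseline specifications (raw / individually rescaled / aggregate
# rescaled response, with or without a constant) and the extended
# specifications with one N-term or count-term, fitted by weighted least
# squares on state means. A pooled respondent-level fit and a state-means
# fit weighted by observation counts are algebraically identical, so
# respondent-level data are collapsed internally.

# collapse whatever the caller supplied into named state means + weights
resolve_state_means <- function(data, scale) {
  if ("respondent_id" %in% names(data)) {
    if (scale == "individual") {
      data <- rescale_individual(data)
      val <- data$vas_ind
    } else {
      data <- check_respondent_data(data)
      val <- data$vas_raw
    }
    keep <- data$state != dead_token
    means <- tapply(val[keep], data$state[keep], mean)
    n <- tapply(val[keep], data$state[keep], length)
    if (scale == "aggregate") {
      dead_mean <- mean(data$vas_raw[data$state == dead_token])
      full_mean <- mean(data$vas_raw[data$state == "11111"])
      means <- rescale_aggregate(means, dead_mean, full_mean)
    }
    return(list(values = means[order(names(means))],
                n = as.numeric(n[order(names(n))])))
  }
  if (!"state" %in% names(data)) {
    stop("data must be respondent-level records or a state value table", call. = FALSE)
  }
  col <- switch(scale, raw = "raw_mean", individual = "ind_mean",
                aggregate = "agg_mean")
  if (!col %in% names(data)) {
    stop(sprintf("state value table lacks the '%s' column required for the %s scale",
                 col, scale), call. = FALSE)
  }
  keep <- !is_dead(data$state)
  d <- data[keep, , drop = FALSE]
  if (anyDuplicated(d$state)) {
    # per-set rows for shared states: pool weighted by n
    n <- if ("n" %in% names(d)) d$n else rep(1, nrow(d))
    v <- tapply(d[[col]] * n, d$state, sum) / tapply(n, d$state, sum)
    w <- tapply(n, d$state, sum)
    return(list(values = v[order(names(v))], n = as.numeric(w[order(names(w))])))
  }
  ord <- order(d$state)
  list(values = stats::setNames(d[[col]][ord], d$state[ord]),
       n = if ("n" %in% names(d)) as.numeric(d$n[ord]) else rep(1, nrow(d)))
}

#' Fit a VAS utility model
#'
#' Estimates dimension-level value decrements by weighted ordinary least
#' squares on state mean values. The model family covers the six baseline
#' specifications — response on the raw 0-100 VAS scale, the individually
#' rescaled 0-1 scale, or the aggregate-rescaled 0-1 scale, each with a
#' constant term (direct response) or through the origin (complement
#' response, `top - value`) — and extensions adding one presence or count
#' term (`N1`..`C3Sq`) to the ten dimension dummies.
#'
#' `data` may be respondent-level records (long form with `respondent_id`,
#' `state`, `vas_raw`), which are collapsed to state means weighted by
#' observation counts — algebraically identical to the pooled
#' respondent-level regression — or a state value table such as produced by
#' [aggregate_table()] or [table2_means()]. The solve uses a QR
#' decomposition (never normal equations).
#'
#' The constant of a with-constant model is interpreted as the value of any
#' state minimally departing from full health; the plain linear form
#' therefore predicts state 11111 at the constant, not at the scale top
#' (see [predict.vas_model()] for the anchored tariff convention).
#'
#' @param data respondent-level records or a state value table.
#' @param scale `"raw"`, `"individual"` or `"aggregate"`.
#' @param constant include a constant term? If `FALSE` the complement
#'   response is fitted through the origin.
#' @param extra one of [extra_terms].
#' @param states inclusion set: labels of the states entering the fit
#'   (default: every non-dead state in `data`). The conventional per-set
#'   inclusion is the 18 design states plus 11111 and 33333.
#' @param weights per-state weights aligned with `states`; defaults to the
#'   per-state observation counts (or uniform when no counts are known).
#' @param singular_ok allow a rank-deficient design? If `FALSE` (default)
#'   rank deficiency is an error naming the collinear columns; if `TRUE`
#'   aliased coefficients are `NA` and the model is flagged, which is how
#'   the exactly collinear `C1`/`C2`/`C3` extensions are handled.
#' @return An object of class `"vas_model"`.
#' @examples
#' fit <- vas_model(table2_means(), scale = "individual", extra = "N3")
#' coef(fit)
#' @export
vas_model <- function(data, scale = c("raw", "individual", "aggregate"),
                      constant = TRUE, extra = "none", states = NULL,
                      weights = NULL, singular_ok = FALSE) {
  scale <- match.arg(scale)
  sm <- resolve_state_means(data, scale)
  if (is.null(states)) {
    states <- names(sm$values)
  } else {
    states <- parse_state(states)
    missing_states <- setdiff(states, names(sm$values))
    if (length(missing_states)) {
      stop(sprintf("no observed values for state(s): %s",
                   paste(missing_states, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(states) == 0) stop("empty inclusion set", call. = FALSE)
  y_obs <- sm$values[states]
  w <- if (is.null(weights)) sm$n[match(states, names(sm$values))] else weights
  if (length(w) != length(states) || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and aligned with the inclusion set", call. = FALSE)
  }
  top <- if (scale == "raw") 100 else 1
  X <- design_matrix(states, extra = extra, constant = constant)
  y <- if (constant) as.numeric(y_obs) else top - as.numeric(y_obs)
  p <- ncol(X)
  if (length(states) < p) {
    stop(sprintf("only %d states for %d free coefficients", length(states), p),
         call. = FALSE)
  }
  fit <- stats::lm.wfit(X, y, w)
  aliased <- names(which(is.na(fit$coefficients)))
  if (length(aliased) && !singular_ok) {
    stop(sprintf("rank-deficient design: column(s) %s collinear with the remaining regressors (use singular_ok = TRUE to drop them)",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  beta <- fit$coefficients
  beta_filled <- ifelse(is.na(beta), 0, beta)
  fitted_y <- drop(X %*% beta_filled)
  fitted_values <- if (constant) fitted_y else top - fitted_y
  resid_values <- as.numeric(y_obs) - fitted_values
  rss <- sum(w * (y - fitted_y)^2)
  df_res <- length(y) - fit$rank
  if (constant) {
    wmean <- sum(w * y) / sum(w)
    tss <- sum(w * (y - wmean)^2)
    df_tot <- length(y) - 1L
  } else {
    tss <- sum(w * y^2) # uncentered: through-origin convention
    df_tot <- length(y)
  }
  adj_r2 <- if (df_res > 0 && tss > 0) 1 - (rss / df_res) / (tss / df_tot) else NA_real_
  # coefficient standard errors from the weighted QR (descriptive only)
  se <- rep(NA_real_, p)
  names(se) <- colnames(X)
  if (df_res > 0 && length(aliased) == 0) {
    XtWXinv <- chol2inv(qr.R(qr(sqrt(w) * X)))
    se <- sqrt(diag(XtWXinv) * rss / df_res)
    names(se) <- colnames(X)
  }
  structure(list(
    coefficients = beta,
    se = se,
    aliased = aliased,
    spec = list(scale = scale, constant = constant, extra = extra, top = top),
    states = states,
    weights = stats::setNames(w, states),
    observed = stats::setNames(as.numeric(y_obs), states),
    fitted.values = stats::setNames(fitted_values, states),
    residuals = stats::setNames(resid_values, states),
    rss = rss, tss = tss,
    df.residual = df_res,
    rank = fit$rank,
    adj_r_squared = adj_r2
  ), class = "vas_model")
}

#' Construct a vas_model from published coefficients
#'
#' Wraps a named coefficient vector (value scale: `Constant` plus the ten
#' dummies plus an optional extra term) as a `"vas_model"` object so it can
#' be used with [predict.vas_model()], [tariff()] and
#' [internal_validity()]. Used for packaged published models; fit
#' diagnostics are absent.
#'
#' @param coefficients named numeric vector; names from the design-matrix
#'   columns (`MO2`..`AD3`, optional extra term, `Constant`).
#' @param scale value scale of the coefficients.
#' @param extra the extra term present in `coefficients`, or `"none"`.
#' @return A `"vas_model"` object without fit diagnostics.
#' @export
as_vas_model <- function(coefficients, scale = "individual", extra = "none") {
  constant <- "Constant" %in% names(coefficients)
  expected <- colnames(design_matrix("11111", extra = extra, constant = constant))
  if (!setequal(names(coefficients), expected)) {
    stop(sprintf("coefficient names must be exactly: %s",
                 paste(expected, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    coefficients = coefficients[expected],
    se = NULL, aliased = character(),
    spec = list(scale = scale, constant = constant, extra = extra,
                top = if (scale == "raw") 100 else 1),
    states = character(), weights = NULL, observed = NULL,
    fitted.values = NULL, residuals = NULL,
    rss = NA_real_, tss = NA_real_, df.residual = NA_integer_,
    rank = length(coefficients), adj_r_squared = NA_real_
  ), class = "vas_model")
}

#' @export
coef.vas_model <- function(object, ...) object$coefficients

#' @export
fitted.vas_model <- function(object, ...) object$fitted.values

#' @export
residuals.vas_model <- function(object, ...) object$residuals

#' Predict state values from a fitted VAS model
#'
#' Evaluates the fitted linear form on the value scale: constant (if any)
#' plus the active dummy and extra-term coefficients; through-origin models
#' fit the complement response, so their predictions are converted back
#' (`top - decrement`). Under the plain form a with-constant model predicts
#' state 11111 at its constant. With `anchor_full_health = TRUE` the
#' prediction for 11111 is anchored at the scale top (100 or 1), the
#' standard tariff convention in which the constant is the decrement for
#' any departure from full health; through-origin models already predict
#' the top at 11111.
#'
#' @param object a `"vas_model"`.
#' @param states character vector of state labels (default: the model's
#'   inclusion set).
#' @param anchor_full_health anchor the 11111 prediction at the scale top?
#' @param ... unused.
#' @return Named numeric vector of predicted values.
#' @export
predict.vas_model <- function(object, states = object$states,
                              anchor_full_health = FALSE, ...) {
  states <- parse_state(states)
  X <- design_matrix(states, extra = object$spec$extra,
                     constant = object$spec$constant)
  beta <- ifelse(is.na(object$coefficients), 0, object$coefficients)
  pred <- drop(X %*% beta[colnames(X)])
  if (!object$spec$constant) pred <- object$spec$top - pred
  if (isTRUE(anchor_full_health)) pred[states == "11111"] <- object$spec$top
  stats::setNames(pred, states)
}

#' Tariff: predicted values for the full 243-state space
#'
#' @param model a `"vas_model"`.
#' @param anchor_full_health see [predict.vas_model()].
#' @return Data frame with columns `state` (all 243 labels, lexicographic)
#'   and `value`.
#' @export
tariff <- function(model, anchor_full_health = FALSE) {
  states <- all_states()
  data.frame(state = states,
             value = as.numeric(predict(model, states,
                                        anchor_full_health = anchor_full_health)),
             stringsAsFactors = FALSE)
}

#' Per-term value decrements of a fitted model
#'
#' Returns decrements as positive magnitudes on the value scale for the ten
#' dimension dummies and any extra term (with-constant models carry
#' negative value-scale coefficients; through-origin models carry positive
#' decrement-scale coefficients).
#'
#' @param model a `"vas_model"`.
#' @return Named numeric vector of decrements (aliased terms are `NA`).
#' @export
decrements <- function(model) {
  beta <- model$coefficients
  beta <- beta[setdiff(names(beta), "Constant")]
  if (model$spec$constant) -beta else beta
}

#' Internal validity of a fitted utility model
#'
#' A tariff model is internally valid when every estimated decrement is
#' non-negative and, within each dimension, the level-3 decrement is at
#' least as large in magnitude as the level-2 decrement. Models with
#' aliased (collinear, dropped) terms are not estimable as specified and
#' are flagged invalid.
#'
#' @param model a `"vas_model"`.
#' @return An object of class `"internal_validity"`: list with `valid`,
#'   a `violations` data frame (dimension, level-2 and level-3 decrement)
#'   and `aliased`.
#' @export
internal_validity <- function(model) {
  dec <- decrements(model)
  viol <- data.frame(dimension = character(), level2 = numeric(),
                     level3 = numeric(), stringsAsFactors = FALSE)
  for (d in eq5d_dimensions) {
    d2 <- dec[paste0(d, "2")]
    d3 <- dec[paste0(d, "3")]
    if (is.na(d2) || is.na(d3)) next
    if (abs(d3) < abs(d2) || d2 < 0 || d3 < 0) {
      viol <- rbind(viol, data.frame(dimension = d, level2 = unname(d2),
                                     level3 = unname(d3)))
    }
  }
  structure(list(valid = nrow(viol) == 0 && length(model$aliased) == 0,
                 violations = viol, aliased = model$aliased),
            class = "internal_validity")
}

#' @export
print.internal_validity <- function(x, ...) {
  cat("Internal validity:", if (x$valid) "valid" else "NOT valid", "\n")
  if (length(x$aliased)) {
    cat("  aliased term(s) dropped from the fit:",
        paste(x$aliased, collapse = ", "), "\n")
  }
  if (nrow(x$violations)) {
    cat("  counterintuitive decrements (|level 2| > |level 3| or negative):\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Adjusted R-squared of a fitted model
#'
#' `1 - (RSS/df_res) / (TSS/df_tot)` with the centred total sum of squares
#' for with-constant models and the uncentred (through-origin) convention
#' for no-constant models. Weighted by the fit weights.
#'
#' @param model a `"vas_model"`.
#' @return Numeric scalar.
#' @export
adjusted_r_squared <- function(model) {
  if (!is.finite(model$tss) || model$tss <= 0) {
    stop("zero total variation: adjusted R-squared undefined", call. = FALSE)
  }
  model$adj_r_squared
}

model_label <- function(model) {
  sprintf("%s scale, %s%s",
          model$spec$scale,
          if (model$spec$constant) "with constant" else "through origin",
          if (model$spec$extra != "none") paste0(", + ", model$spec$extra) else "")
}

#' @export
print.vas_model <- function(x, digits = 4, ...) {
  cat("VAS utility model:", model_label(x), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (length(x$aliased)) {
    cat("Aliased (dropped):", paste(x$aliased, collapse = ", "), "\n")
  }
  if (length(x$states)) {
    cat(sprintf("Fitted on %d states; adjusted R-squared %.4f\n",
                length(x$states), x$adj_r_squared))
  }
  invisible(x)
}

#' @export
summary.vas_model <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = if (is.null(object$se)) NA_real_ else object$se)
  iv <- internal_validity(object)
  structure(list(label = model_label(object), coefficients = tab,
                 n_states = length(object$states),
                 adj_r_squared = object$adj_r_squared,
                 rss = object$rss, df_residual = object$df.residual,
                 internal_validity = iv),
            class = "summary.vas_model")
}

#' @export
print.summary.vas_model <- function(x, digits = 4, ...) {
  cat("VAS utility model:", x$label, "\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\n%d states, residual df %s, adjusted R-squared %.4f\n",
              x$n_states, format(x$df_residual), x$adj_r_squared))
  cat("Internally", if (x$internal_validity$valid) "valid" else "NOT valid", "\n")
  invisible(x)
}

#' Simulate synthetic valuation studies from a fitted model
#'
#' Uses the fitted coefficients (rescaled to the 0-1 value scale if
#' necessary) as the generating utility function of a synthetic study; see
#' [simulate_study()].
#'
#' @param object a `"vas_model"` with a constant term.
#' @param nsim number of studies.
#' @param seed master seed (required for reproducibility).
#' @param ... overrides passed to [sim_config()].
#' @return A single study data frame (`nsim = 1`) or a list of them.
#' @export
simulate.vas_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$spec$constant) {
    stop("simulate() requires a with-constant model", call. = FALSE)
  }
  beta <- object$coefficients
  if (object$spec$top == 100) beta <- beta / 100
  cfg <- sim_config(true_coefficients = beta, extra = object$spec$extra, ...)
  if (is.null(seed)) seed <- 1L
  studies <- lapply(seq_len(nsim), function(i) simulate_study(cfg, seed = seed + i - 1L))
  if (nsim == 1) studies[[1]] else studies
}
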