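# VAS rescaling onto the dead = 0 / full-health = 1 scale, at the level of
# the individual respondent and at aggregate level, plus construction of the
# dependent variable for each model specification.
#
# Respondent-level data are held in long form: one row per (respondent,
# state) with columns respondent_id, set, state, vas_raw and optionally
# rank. The state column uses bare 5-digit labels plus the dead token.

# validate the long respondent data frame; returns it with normalised state column
check_respondent_data <- function(data, require_rank = FALSE) {
  need <- c("respondent_id", "state", "vas_raw")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("respondent data lack column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  data$state <- ifelse(is_dead(data$state), dead_token, as.character(data$state))
  parse_state(data$state[data$state != dead_token])
  if (any(!is.finite(data$vas_raw)) || any(data$vas_raw < 0 | data$vas_raw > 100)) {
    bad <- which(!is.finite(data$vas_raw) | data$vas_raw < 0 | data$vas_raw > 100)[1]
    stop(sprintf("vas_raw outside [0,100] at row %d (value %s)", bad,
                 format(data$vas_raw[bad])), call. = FALSE)
  }
  if (anyDuplicated(data[, c("respondent_id", "state")])) {
    stop("duplicate (respondent, state) rating", call. = FALSE)
  }
  if (require_rank && !"rank" %in% names(data)) {
    stop("respondent data carry no rank column", call. = FALSE)
  }
  data
}

#' Rescale raw VAS ratings at the level of the individual respondent
#'
#' Applies the anchor transformation
#' `(vas_raw - dead_raw) / (full_raw - dead_raw)` within each respondent,
#' where `full_raw` and `dead_raw` are the respondent's own ratings of state
#' 11111 and of Dead. By construction 11111 maps to exactly 1 and Dead to
#' exactly 0; states rated worse than dead keep their negative values.
#'
#' Respondents whose 11111 rating does not exceed their Dead rating have an
#' undefined transformation and are excluded with a warning (their ids are
#' returned in the `"excluded"` attribute); respondents missing either
#' anchor rating raise an error.
#'
#' @param data long respondent data frame (columns `respondent_id`,
#'   `state`, `vas_raw`, ...).
#' @return The data frame restricted to valid respondents, with an added
#'   `vas_ind` column; attribute `"excluded"` lists excluded respondent ids.
#' @export
rescale_individual <- function(data) {
  data <- check_respondent_data(data)
  split_idx <- split(seq_len(nrow(data)), data$respondent_id)
  excluded <- character()
  data$vas_ind <- NA_real_
  for (id in names(split_idx)) {
    idx <- split_idx[[id]]
    st <- data$state[idx]
    if (!"11111" %in% st || !dead_token %in% st) {
      stop(sprintf("respondent '%s' lacks a rating for %s; individual rescaling is impossible",
                   id, if ("11111" %in% st) "Dead" else "state 11111"), call. = FALSE)
    }
    full_raw <- data$vas_raw[idx][st == "11111"]
    dead_raw <- data$vas_raw[idx][st == dead_token]
    if (full_raw <= dead_raw) {
      excluded <- c(excluded, id)
      next
    }
    data$vas_ind[idx] <- (data$vas_raw[idx] - dead_raw) / (full_raw - dead_raw)
  }
  if (length(excluded)) {
    warning(sprintf("excluded %d respondent(s) with 11111 rating <= Dead rating: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
    data <- data[!data$respondent_id %in% excluded, , drop = FALSE]
  }
  attr(data, "excluded") <- excluded
  data
}

#' Rescale aggregate mean VAS values
#'
#' The same anchor transformation applied to aggregated data:
#' `(mean_raw - dead_mean) / (full_mean - dead_mean)`.
#'
#' @param mean_raw numeric vector of state mean raw VAS values.
#' @param dead_mean mean raw rating of Dead.
#' @param full_mean mean raw rating of state 11111.
#' @return Numeric vector on the dead/full-health scale.
#' @examples
#' rescale_aggregate(73.1, dead_mean = 1.5, full_mean = 97.5)
#' @export
rescale_aggregate <- function(mean_raw, dead_mean, full_mean) {
  if (!is.finite(full_mean) || !is.finite(dead_mean) || full_mean <= dead_mean) {
    stop("degenerate anchor means: full-health mean must exceed dead mean",
         call. = FALSE)
  }
  (mean_raw - dead_mean) / (full_mean - dead_mean)
}

state_stats <- function(v) {
  c(n = length(v), mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
}

#' Aggregate respondent records into a state value table
#'
#' Computes, per state and valuation set: the number of observations, mean
#' and sample standard deviation (n - 1 denominator) of the raw VAS values;
#' the mean and standard deviation of the individually rescaled values; and
#' the aggregate-rescaled value obtained by applying the anchor
#' transformation to the state's raw mean with the set's own anchor means.
#' States valued by both sets (the anchors) are pooled into rows with
#' `set = "Both"`, using pooled anchor means for the aggregate column; the
#' pooled n of a shared state equals the sum of the per-set n.
#'
#' The aggregate column's dispersion is reported as the raw standard
#' deviation mapped through the (linear) aggregate transformation,
#' `raw_sd / (full_mean - dead_mean)`.
#'
#' @param data long respondent data frame with a `set` column.
#' @param pool_shared pool states valued by every set into `"Both"` rows
#'   (the published table layout)? If `FALSE`, shared states keep one row
#'   per set.
#' @return Data frame with columns `state`, `set`, `n`, `raw_mean`,
#'   `raw_sd`, `ind_mean`, `ind_sd`, `agg_mean`, `agg_sd`, ordered by
#'   decreasing raw mean.
#' @export
aggregate_table <- function(data, pool_shared = TRUE) {
  if (!"set" %in% names(data)) data$set <- "All"
  data <- rescale_individual(data)
  sets <- unique(data$set)
  shared <- Reduce(intersect, split(data$state, data$set))
  rows <- list()
  add_rows <- function(d, set_label, dead_mean, full_mean) {
    for (s in unique(d$state)) {
      v <- d[d$state == s, ]
      raw <- state_stats(v$vas_raw)
      ind <- state_stats(v$vas_ind)
      rows[[length(rows) + 1L]] <<- data.frame(
        state = s, set = set_label, n = as.integer(raw["n"]),
        raw_mean = raw["mean"], raw_sd = raw["sd"],
        ind_mean = ind["mean"], ind_sd = ind["sd"],
        agg_mean = rescale_aggregate(raw["mean"], dead_mean, full_mean),
        agg_sd = raw["sd"] / (full_mean - dead_mean),
        row.names = NULL)
    }
  }
  pooled <- pool_shared && length(sets) > 1 && length(shared) > 0
  for (sn in sets) {
    d <- data[data$set == sn, ]
    dead_mean <- mean(d$vas_raw[d$state == dead_token])
    full_mean <- mean(d$vas_raw[d$state == "11111"])
    keep <- if (pooled) !d$state %in% shared else rep(TRUE, nrow(d))
    add_rows(d[keep, , drop = FALSE], sn, dead_mean, full_mean)
  }
  if (pooled) {
    dead_mean <- mean(data$vas_raw[data$state == dead_token])
    full_mean <- mean(data$vas_raw[data$state == "11111"])
    add_rows(data[data$state %in% shared, , drop = FALSE], "Both",
             dead_mean, full_mean)
  }
  out <- do.call(rbind, rows)
  out[order(-out$raw_mean), , drop = FALSE]
}

# the six baseline specifications: value scale and constant term
model_specs <- data.frame(
  model_id = 1:6,
  scale = c("raw", "raw", "individual", "individual", "aggregate", "aggregate"),
  constant = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Dependent variable for the six baseline model specifications
#'
#' Models 1/3/5 fit decrements through the origin, so their response is the
#' complement of the value (`100 - v` on the raw scale, `1 - v` on either
#' rescaled scale); models 2/4/6 use the value itself and include a
#' constant.
#'
#' @param values numeric vector of state values on the scale the model
#'   requires (raw for models 1-2, individually rescaled for 3-4,
#'   aggregate-rescaled for 5-6).
#' @param model_id integer in 1-6.
#' @return Numeric vector of response values.
#' @export
dependent_variable <- function(values, model_id) {
  if (length(model_id) != 1L || !model_id %in% 1:6) {
    stop("model_id must be a single integer in 1-6", call. = FALSE)
  }
  spec <- model_specs[model_specs$model_id == model_id, ]
  top <- if (spec$scale == "raw") 100 else 1
  if (spec$constant) values else top - values
}
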