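# Packaged fixtures: the published state-mean table, the five published
# combined-set model columns, and the canonical design-state lists. The
# tables are stored as plain CSV (reviewable against the source) and
# checksum-verified on load.

.fixture_md5 <- c(
  table2_means = "5dcab7dc03c378b3d32a29283cf73837",
  table4_models = "0185f2936773ac25fb2715dc316d1600"
)

fixture_path <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "eqvas")
  if (path == "") stop(sprintf("fixture file '%s.csv' not found", name), call. = FALSE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[name]))) {
    stop(sprintf("fixture '%s' is corrupted (checksum %s does not match packaged %s)",
                 name, sum, .fixture_md5[name]), call. = FALSE)
  }
  path
}

#' The published state value table
#'
#' Mean observed and rescaled VAS values for the 38 directly valued EQ-5D
#' states plus Dead: per state, the valuation set (Green, Blue, or Both
#' for the shared anchors), the number of observations, and mean/standard
#' deviation on the raw 0-100 scale, the individually rescaled scale and
#' the aggregate-rescaled scale.
#'
#' One aggregate-scale cell (state 31332) duplicates another row's value in
#' the published source and is flagged `transcription_error`; with
#' `repair = TRUE` (default) it is replaced by the aggregate anchor
#' transformation applied to the row's own raw mean with the pooled anchor
#' means, `(18.7 - 1.5) / (97.5 - 1.5)`, the construction that matches the
#' unflagged rows to within about 0.001.
#'
#' @param repair replace the flagged aggregate cell (with a message)?
#' @return Data frame with 39 rows and columns `state`, `set`, `n`,
#'   `raw_mean`, `raw_sd`, `ind_mean`, `ind_sd`, `agg_mean`, `agg_sd`,
#'   `flag`.
#' @export
table2_means <- function(repair = TRUE) {
  tab <- utils::read.csv(fixture_path("table2_means"),
                         colClasses = c(state = "character", flag = "character"))
  tab$flag[is.na(tab$flag)] <- ""
  stopifnot(nrow(tab) == 39)
  if (repair) {
    flagged <- which(tab$flag == "transcription_error")
    if (length(flagged)) {
      dead_mean <- tab$raw_mean[tab$state == dead_token]
      full_mean <- tab$raw_mean[tab$state == "11111"]
      tab$agg_mean[flagged] <- rescale_aggregate(tab$raw_mean[flagged],
                                                 dead_mean, full_mean)
      message(sprintf("repaired flagged aggregate cell(s) for state(s) %s via the anchor transformation",
                      paste(tab$state[flagged], collapse = ", ")))
    }
  }
  tab
}

#' The published combined-set model coefficients
#'
#' The five internally valid utility functions fitted on the combined
#' (Green plus Blue) individually rescaled data: the baseline
#' dummy-variable model and its N1-, N2-, N3- and C3Sq-extended variants.
#'
#' @return Data frame with a `term` column and one numeric column per
#'   model (`Baseline`, `N1`, `N2`, `N3`, `C3Sq`); absent terms are `NA`.
#' @export
table4_models <- function() {
  utils::read.csv(fixture_path("table4_models"),
                  colClasses = c(term = "character"))
}

#' A packaged published model as a vas_model object
#'
#' @param name which published column to wrap: `"Baseline"`, `"N1"`,
#'   `"N2"`, `"N3"` or `"C3Sq"`.
#' @return A `"vas_model"` (individually rescaled scale, with constant)
#'   carrying the published coefficients; see [as_vas_model()].
#' @examples
#' predict(fixture_model("N3"), "11111") # the published constant
#' @export
fixture_model <- function(name = c("N3", "Baseline", "N1", "N2", "C3Sq")) {
  name <- match.arg(name)
  tab <- table4_models()
  beta <- stats::setNames(tab[[name]], tab$term)
  beta <- beta[!is.na(beta)]
  as_vas_model(beta, scale = "individual",
               extra = if (name == "Baseline") "none" else name)
}

#' Load a packaged fixture by name
#'
#' @param name one of `"table2_means"`, `"table4_models"`,
#'   `"canonical_sets"`.
#' @param ... passed to the specific loader.
#' @return The fixture object.
#' @export
load_fixture <- function(name, ...) {
  switch(name,
         table2_means = table2_means(...),
         table4_models = table4_models(),
         canonical_sets = canonical_sets(),
         stop(sprintf("unknown fixture '%s'", name), call. = FALSE))
}
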