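# File interchange (plain CSV / JSON only) and the end-to-end pipeline
# runner. Respondent files are long CSV with a documented header; fitted
# models serialize to JSON; tariffs to CSV.

#' Read a respondent data file
#'
#' Expects a CSV with header columns `respondent_id`, `set`, `state`,
#' `vas_raw` and optionally `rank`. State labels are bare 5-digit codes;
#' the dead token (`DEAD`, case-insensitive) marks the dead state.
#' Validation failures (unknown label, rating outside 0-100, duplicate
#' respondent/state pair, missing Dead or 11111 row) are reported with
#' their location.
#'
#' @param path file path.
#' @return Long respondent data frame.
#' @export
read_respondent_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  data <- utils::read.csv(path, colClasses = "character")
  need <- c("respondent_id", "set", "state", "vas_raw")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  data$vas_raw <- suppressWarnings(as.numeric(data$vas_raw))
  if (anyNA(data$vas_raw)) {
    stop(sprintf("%s: non-numeric vas_raw at row %d", path, which(is.na(data$vas_raw))[1]),
         call. = FALSE)
  }
  if ("rank" %in% names(data)) data$rank <- as.numeric(data$rank)
  check_respondent_data(data)
}

#' Write a respondent data file
#'
#' @param records long respondent data frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_respondent_file <- function(records, path) {
  records <- check_respondent_data(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write valuation-set files
#'
#' A valuation set serializes as a two-column CSV: `label` (state label or
#' the dead token) and `role` (`design`, `anchor` or `holdout`).
#'
#' @param path file path.
#' @return `read_valuation_set`: a [valuation_set()];
#'   `write_valuation_set`: `path`, invisibly.
#' @export
read_valuation_set <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("label", "role") %in% names(tab)))
  name <- if ("name" %in% names(tab)) tab$name[1] else "custom"
  valuation_set(tab$label[tab$role == "design"],
                holdouts = tab$label[tab$role == "holdout"],
                name = name)
}

#' @rdname read_valuation_set
#' @param set a [valuation_set()].
#' @export
write_valuation_set <- function(set, path) {
  stopifnot(inherits(set, "valuation_set"))
  tab <- data.frame(
    label = c(set$design, set$anchors, set$holdouts),
    role = c(rep("design", length(set$design)),
             rep("anchor", length(set$anchors)),
             rep("holdout", length(set$holdouts))),
    name = set$name, stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

model_to_list <- function(model) {
  list(spec = model$spec[c("scale", "constant", "extra")],
       states = model$states,
       coefficients = as.list(model$coefficients),
       aliased = model$aliased,
       diagnostics = list(rss = model$rss, df_residual = model$df.residual,
                          adj_r_squared = model$adj_r_squared))
}

#' Serialize a fitted model to JSON
#'
#' @param model a `"vas_model"`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' Reconstructs a coefficient-only `"vas_model"` (see [as_vas_model()]).
#'
#' @param path JSON path written by [write_model_json()].
#' @return A `"vas_model"`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_vas_model(unlist(x$coefficients), scale = x$spec$scale,
               extra = x$spec$extra)
}

#' Run the full pipeline and write its artifacts
#'
#' Obtains a state value table from the requested source (the packaged
#' fixture, a respondent CSV, or a freshly simulated study), fits the
#' requested models, and writes per-model JSON, tariff CSVs, an
#' evaluation report and a machine-readable manifest (inputs, seed,
#' package version, artifact checksums) into `outdir`. Partially written
#' artifacts are removed on failure; the manifest suffices to re-run the
#' invocation identically.
#'
#' @param outdir output directory (created if needed).
#' @param source `"fixture"`, `"file"` or `"simulate"`.
#' @param file respondent CSV path (for `source = "file"`).
#' @param seed master seed (for `source = "simulate"`).
#' @param config a [sim_config()] (for `source = "simulate"`).
#' @param models list of model specifications, each a list with elements
#'   `scale`, `constant`, `extra`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(outdir,
                         source = c("fixture", "file", "simulate"),
                         file = NULL, seed = 1L, config = NULL,
                         models = list(list(scale = "individual",
                                            constant = TRUE, extra = "N3"))) {
  source <- match.arg(source)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    tab <- switch(source,
                  fixture = table2_means(),
                  file = aggregate_table(read_respondent_file(file)),
                  simulate = aggregate_table(
                    simulate_study(if (is.null(config)) sim_config() else config,
                                   seed = seed)))
    evals <- list()
    for (i in seq_along(models)) {
      ms <- models[[i]]
      m <- vas_model(tab, scale = ms$scale, constant = isTRUE(ms$constant),
                     extra = if (is.null(ms$extra)) "none" else ms$extra)
      mp <- file.path(outdir, sprintf("model_%02d.json", i))
      tp <- file.path(outdir, sprintf("tariff_%02d.csv", i))
      write_model_json(m, mp)
      utils::write.csv(tariff(m), tp, row.names = FALSE, quote = FALSE)
      written <- c(written, mp, tp)
      ev <- evaluate(m, anchor_full_health = FALSE)
      evals[[i]] <- list(model = i, mae = ev$mae, mae_pct = ev$mae_pct,
                         pct_above = ev$pct_above, pearson = ev$pearson,
                         internally_valid = internal_validity(m)$valid)
    }
    ep <- file.path(outdir, "evaluation.json")
    jsonlite::write_json(evals, ep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, ep)
    manifest <- list(
      source = source, file = file,
      seed = if (source == "simulate") seed else NULL,
      models = models,
      package_version = as.character(utils::packageVersion("eqvas")),
      artifacts = as.list(tools::md5sum(written)),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(manifest)
  }, error = on_fail)
}
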