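#' Default candidate model set
#'
#' The formulas compared by AIC: main effects of month, latitude and
#' habitat in all combinations, plus the month x habitat interaction on
#' top of the full main-effects model and the month+habitat model.
#'
#' @return list of character term vectors.
#' @export
default_models <- function() {
  list(
    c("month"),
    c("latitude"),
    c("habitat"),
    c("month", "latitude"),
    c("latitude", "habitat"),
    c("month", "latitude", "habitat"),
    c("month", "habitat", "month:habitat"),
    c("month", "latitude", "habitat", "month:habitat")
  )
}

#' Assemble a full-run configuration
#'
#' @param input path to a consumer sample file, or `NULL` to run on
#'   synthetic data.
#' @param sample_config sample-format config (list or YAML path) for
#'   `input`.
#' @param synth a [synth_config()] used when `input` is `NULL`.
#' @param calibration an [hprint_calibration()].
#' @param models list of candidate term vectors (default
#'   [default_models()]).
#' @param treatment treatment coefficient for the sensitivity analysis.
#' @param alpha significance level.
#' @param whiskers box-plot whisker convention.
#' @param threshold iPOC % exceedance threshold.
#' @param seed RNG seed (synthetic runs).
#' @param out_dir output directory (created if needed).
#' @param encoding model encoding options (see [encode_design()]).
#' @return list of class `"ipoc_run_config"`.
#' @export
run_config <- function(input = NULL, sample_config = NULL,
                       synth = synth_config(),
                       calibration = hprint_calibration(),
                       models = default_models(),
                       treatment = "habitat", alpha = 0.05,
                       whiskers = c("tukey", "minmax"), threshold = 50,
                       seed = 1L, out_dir = "ipoc_report",
                       encoding = list()) {
  whiskers <- match.arg(whiskers)
  structure(mget(c("input", "sample_config", "synth", "calibration",
                   "models", "treatment", "alpha", "whiskers", "threshold",
                   "seed", "out_dir", "encoding")),
            class = "ipoc_run_config")
}

#' Statistical stage shared by [run_all()] and [replicate_deposited()]
#'
#' Fits every candidate model on the common included-with-month sample,
#' ranks by AIC, and runs the sensitivity analysis on the best-ranked
#' model containing the treatment.
#'
#' @param results pipeline results (with metadata columns).
#' @param models list of term vectors.
#' @param treatment,alpha,encoding see [run_config()].
#' @return list: `comparison`, `fits`, `best_fit`, `sensitivity`,
#'   `n_model_sample`, `n_missing_month`.
#' @export
model_stage <- function(results, models = default_models(),
                        treatment = "habitat", alpha = 0.05,
                        encoding = list()) {
  inc <- included_results(results)
  vars <- unique(c("ipoc_pct", unlist(lapply(models, term_vars))))
  keep <- stats::complete.cases(inc[intersect(vars, names(inc))])
  d <- inc[keep, , drop = FALSE]
  fits <- lapply(models, function(tm) fit_ols(d, tm, encoding = encoding))
  comparison <- compare_models(fits)
  sens <- NULL; best_with_treatment <- NULL
  for (f in attr(comparison, "fits")) {
    if (treatment %in% names(f$coefficients)) { best_with_treatment <- f; break }
  }
  if (!is.null(best_with_treatment))
    sens <- sensitivity(best_with_treatment, treatment, alpha = alpha)
  list(comparison = comparison, fits = fits,
       best_fit = attr(comparison, "fits")[[1]],
       best_fit_with_treatment = best_with_treatment,
       sensitivity = sens, n_model_sample = nrow(d),
       n_missing_month = sum(!keep))
}

#' Run the whole pipeline and write a report bundle
#'
#' Orchestrates validate -> compute -> summaries -> models -> sensitivity
#' as one reproducible run. Writes, into `out_dir`: `results.csv`,
#' `exclusions.txt`, `species_summary.csv`, `monthly_summary.csv`,
#' `model_comparison.csv`, `sensitivity.csv`, and `manifest.json` (config
#' hash, package version, stage counts). Outputs are deterministic for a
#' fixed config and seed; the manifest carries no timestamps so reruns
#' are bitwise identical.
#'
#' @param config an [run_config()] object.
#' @return the manifest, invisibly.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "ipoc_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)

  if (is.null(config$input)) {
    gen <- generate_samples(config$synth, seed = config$seed)
    samples <- gen$samples
    n_rejected <- 0L
  } else {
    rd <- read_samples(config$input, config$sample_config)
    samples <- rd$samples
    n_rejected <- nrow(rd$errors)
    if (nrow(samples) == 0L) stop("no valid samples in input")
  }

  pipe <- run_pipeline(samples, config$calibration)
  results <- pipe$results
  if (all(results$classification == "excluded_no_hbis"))
    stop("every sample was excluded (no measurable HBIs); nothing to analyze")

  write_results(results, p("results.csv"))
  writeLines(pipe$exclusion_log, p("exclusions.txt"))

  sp <- species_summary(results, whiskers = config$whiskers)
  write_summary_csv(sp$summary, p("species_summary.csv"))
  mo <- monthly_summary(results, whiskers = config$whiskers)
  write_summary_csv(mo$summary, p("monthly_summary.csv"))

  ms <- model_stage(results, config$models, config$treatment,
                    config$alpha, config$encoding)
  utils::write.csv(ms$comparison, p("model_comparison.csv"), row.names = FALSE)
  sens <- ms$sensitivity
  sens_df <- if (is.null(sens)) data.frame() else
    data.frame(treatment = sens$treatment_term, t_value = sens$t_value,
               df_residual = sens$df_residual,
               partial_r2_outcome = sens$partial_r2_outcome,
               robustness_value = sens$robustness_value,
               robustness_value_alpha = sens$robustness_value_alpha,
               q = sens$q, alpha = sens$alpha)
  utils::write.csv(sens_df, p("sensitivity.csv"), row.names = FALSE)

  thr <- proportion_above(results, config$threshold)
  manifest <- list(
    package = "ipoctrace",
    version = as.character(utils::packageVersion("ipoctrace")),
    seed = config$seed,
    config_hash = config_hash(config),
    input = if (is.null(config$input)) "synthetic" else config$input,
    counts = list(
      n_input_rows_rejected = n_rejected,
      n_samples = nrow(results),
      n_excluded_no_hbis = length(pipe$exclusion_log),
      n_included = thr$n_included,
      n_missing_month_in_models = ms$n_missing_month,
      n_model_sample = ms$n_model_sample
    ),
    threshold = list(value = config$threshold, count = thr$count,
                     proportion = thr$proportion),
    best_model = ms$comparison$formula[1],
    files = c("results.csv", "exclusions.txt", "species_summary.csv",
              "monthly_summary.csv", "model_comparison.csv",
              "sensitivity.csv", "manifest.json")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_summary_csv <- function(summary, path) {
  s <- summary
  s$outlier_values <- vapply(s$outlier_values, function(v)
    paste(sprintf("%.4f", v), collapse = ";"), character(1))
  utils::write.csv(s, path, row.names = FALSE)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # hash the analytic config, not the output location
  ser <- jsonlite::serializeJSON(cfg, digits = 12)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(ser), tmp)
  unname(tools::md5sum(tmp))
}

#' Recompute the headline statistics from a deposited per-individual table
#'
#' Entry point for replicating the survey-scale analysis from an archived
#' per-individual dataset (canonical column names, see [read_samples()]).
#' Runs the complete pipeline and returns the headline quantities:
#' source-class proportions, the 50% iPOC exceedance, the AIC ranking,
#' and the sensitivity of the habitat term.
#'
#' @param path path to the deposited delimited-text table.
#' @param sample_config optional sample-format config.
#' @param config an [run_config()] providing models, treatment, alpha,
#'   threshold and calibration.
#' @return list: `n_total`, `n_excluded`, `pct_both_sources`,
#'   `pct_pelagic_only`, `pct_above_threshold`, `n_above_threshold`,
#'   `comparison`, `sensitivity`, `results`.
#' @export
replicate_deposited <- function(path, sample_config = NULL,
                                config = run_config()) {
  rd <- read_samples(path, sample_config)
  if (nrow(rd$samples) == 0L) stop("no valid samples in ", path)
  pipe <- run_pipeline(rd$samples, config$calibration)
  results <- pipe$results
  inc <- included_results(results)
  thr <- proportion_above(results, config$threshold)
  ms <- model_stage(results, config$models, config$treatment,
                    config$alpha, config$encoding)
  list(
    n_total = nrow(results),
    n_excluded = length(pipe$exclusion_log),
    pct_both_sources = 100 * mean(inc$classification == "both_sources"),
    pct_pelagic_only = 100 * mean(inc$classification == "pelagic_only"),
    n_above_threshold = thr$count,
    pct_above_threshold = 100 * thr$proportion,
    comparison = ms$comparison,
    sensitivity = ms$sensitivity,
    results = results
  )
}
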