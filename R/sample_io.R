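#' Controlled vocabularies for consumer sample metadata
#'
#' The pipeline aggregates heterogeneous legacy datasets, so categorical
#' metadata is validated against fixed vocabularies: four foraging
#' habitats, six major taxon groups, and four benthic feeding strategies.
#'
#' @return A named list of character vectors: `habitat`, `taxon_group`,
#'   `feeding_strategy`, `classification`.
#' @export
ipoc_vocabulary <- function() {
  list(
    habitat = c("benthic", "mixed", "pelagic", "sympagic"),
    taxon_group = c("benthic_invertebrate", "zooplankton",
                    "ice_associated_invertebrate", "fish", "seabird",
                    "marine_mammal"),
    feeding_strategy = c("surface_deposit", "subsurface_deposit",
                         "suspension", "predator_scavenger"),
    classification = c("both_sources", "pelagic_only", "excluded_no_hbis")
  )
}

# Field sets for the consumer-sample schema. Latitude/year bounds are the
# study's observed ranges, so breaches warn rather than reject.
.mandatory_fields <- c("sample_id", "species", "taxon_group", "habitat",
                       "latitude", "year", "ip25", "hbi2", "hbi3")
.optional_fields <- c("feeding_strategy", "longitude", "month", "tissue")
.lat_range <- c(55, 82)
.year_range <- c(1982, 2019)

#' Read a sample-format configuration
#'
#' The column map is config-driven because source datasets share no single
#' schema. The YAML file may contain `delimiter` (default `","`),
#' `decimal` (must be `"."`), and a `columns` map from canonical field
#' names (`sample_id`, `species`, `taxon_group`, `habitat`,
#' `feeding_strategy`, `latitude`, `longitude`, `year`, `month`, `tissue`,
#' `ip25`, `hbi2`, `hbi3`) to the column headers used in the file.
#' Unmapped fields default to their canonical names.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @return A list with elements `delimiter` and `columns`.
#' @export
read_sample_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  delimiter <- cfg$delimiter %||% ","
  if (!is.null(cfg$decimal) && cfg$decimal != ".")
    stop("only '.' decimal separators are supported")
  fields <- c(.mandatory_fields, .optional_fields)
  columns <- stats::setNames(as.list(fields), fields)
  if (!is.null(cfg$columns)) {
    unknown <- setdiff(names(cfg$columns), fields)
    if (length(unknown))
      stop("unknown field(s) in column map: ", paste(unknown, collapse = ", "))
    columns <- utils::modifyList(columns, cfg$columns)
  }
  list(delimiter = delimiter, columns = columns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a consumer biomarker sample table
#'
#' Reads delimited text, maps headers to canonical fields via the config,
#' and validates every row. Validation is total: each input row becomes
#' either a validated sample or one-or-more entries in the error report;
#' nothing is silently dropped. A missing mandatory column is a hard
#' failure naming the column; row-level problems (out-of-vocabulary
#' habitat, negative intensity, impossible month) reject only that row.
#' Latitude/year outside the study's observed ranges produce warnings,
#' not rejections. A blank month is kept as `NA` — "month unknown" is a
#' representable state, distinct from any valid month.
#'
#' @param path Path to a delimited text file (UTF-8, `.` decimal).
#' @param config A config list from [read_sample_config()], or a path to
#'   a YAML config, or `NULL` for defaults.
#' @return A list with components `samples` (validated data.frame),
#'   `errors` (data.frame: `row`, `sample_id`, `field`, `message`), and
#'   `warnings` (same shape).
#' @export
read_samples <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(config)) config <- read_sample_config(config)
  if (is.null(config)) config <- read_sample_config()

  raw <- utils::read.table(path, header = TRUE, sep = config$delimiter,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = c("NA", ""), encoding = "UTF-8",
                           colClasses = "character", check.names = FALSE)
  have <- unlist(config$columns[.mandatory_fields])
  missing_cols <- .mandatory_fields[!have %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (expected header '%s')", missing_cols,
                       unlist(config$columns[missing_cols])), collapse = ", "))

  df <- data.frame(row = seq_len(nrow(raw)), stringsAsFactors = FALSE)
  for (f in names(config$columns)) {
    hdr <- config$columns[[f]]
    df[[f]] <- if (hdr %in% names(raw)) raw[[hdr]] else NA_character_
  }
  validate_samples(df)
}

#' Validate a raw sample table
#'
#' Workhorse behind [read_samples()]; exported so in-memory tables can be
#' validated directly. Accepts character or typed columns.
#'
#' @param df A data.frame with the canonical field names (a `row` column
#'   is added if absent).
#' @return Same structure as [read_samples()].
#' @export
validate_samples <- function(df) {
  stopifnot(is.data.frame(df))
  if (is.null(df$row)) df$row <- seq_len(nrow(df))
  vocab <- ipoc_vocabulary()
  errs <- list(); warns <- list()
  note <- function(store, row, id, field, msg)
    c(store, list(data.frame(row = row, sample_id = id, field = field,
                             message = msg, stringsAsFactors = FALSE)))

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(row = df$row, sample_id = as.character(df$sample_id),
                    stringsAsFactors = FALSE)
  out$species <- as.character(df$species)
  out$taxon_group <- as.character(df$taxon_group)
  out$habitat <- as.character(df$habitat)
  out$feeding_strategy <- as.character(df$feeding_strategy %||% rep(NA, nrow(df)))
  out$latitude <- num(df$latitude)
  out$longitude <- num(df$longitude %||% rep(NA, nrow(df)))
  out$year <- num(df$year)
  out$month <- num(df$month %||% rep(NA, nrow(df)))
  out$tissue <- as.character(df$tissue %||% rep(NA, nrow(df)))
  out$ip25 <- num(df$ip25); out$hbi2 <- num(df$hbi2); out$hbi3 <- num(df$hbi3)

  bad <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    id <- out$sample_id[i]; r <- out$row[i]
    fail <- function(field, msg) { errs <<- note(errs, r, id, field, msg); bad[i] <<- TRUE }
    warn <- function(field, msg) warns <<- note(warns, r, id, field, msg)

    if (is.na(id) || !nzchar(id)) fail("sample_id", "missing sample id")
    if (is.na(out$habitat[i]) || !out$habitat[i] %in% vocab$habitat)
      fail("habitat", sprintf("habitat '%s' not in {%s}", out$habitat[i],
                              paste(vocab$habitat, collapse = ", ")))
    if (is.na(out$taxon_group[i]) || !out$taxon_group[i] %in% vocab$taxon_group)
      fail("taxon_group", sprintf("taxon_group '%s' not recognised", out$taxon_group[i]))
    fs <- out$feeding_strategy[i]
    if (!is.na(fs)) {
      if (!fs %in% vocab$feeding_strategy)
        fail("feeding_strategy", sprintf("feeding_strategy '%s' not recognised", fs))
      else if (identical(out$taxon_group[i], "benthic_invertebrate") == FALSE)
        warn("feeding_strategy", "feeding strategy given for a non-benthic-invertebrate")
    }
    for (f in c("ip25", "hbi2", "hbi3")) {
      v <- out[[f]][i]
      if (is.na(v) || !is.finite(v)) fail(f, "intensity missing or non-finite")
      else if (v < 0) fail(f, "intensity negative")
    }
    lat <- out$latitude[i]
    if (is.na(lat)) fail("latitude", "latitude missing or non-numeric")
    else if (lat < .lat_range[1] || lat > .lat_range[2])
      warn("latitude", sprintf("latitude %.2f outside observed range [%d, %d]",
                               lat, .lat_range[1], .lat_range[2]))
    yr <- out$year[i]
    if (is.na(yr) || yr != round(yr)) fail("year", "year missing or non-integer")
    else if (yr < .year_range[1] || yr > .year_range[2])
      warn("year", sprintf("year %d outside observed range [%d, %d]",
                           as.integer(yr), .year_range[1], .year_range[2]))
    mo <- out$month[i]
    if (!is.na(mo) && (mo != round(mo) || mo < 1 || mo > 12))
      fail("month", sprintf("month %s not in 1..12 (leave blank if unknown)", mo))
  }

  samples <- out[!bad, , drop = FALSE]
  samples$year <- as.integer(samples$year)
  samples$month <- as.integer(samples$month)
  rownames(samples) <- NULL
  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else
    data.frame(row = integer(), sample_id = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  list(samples = samples, errors = bind(errs), warnings = bind(warns))
}

#' Write pipeline results to delimited text
#'
#' One row per sample: id, species, habitat, month, H-Print %, raw and
#' clamped iPOC %, classification. Numeric values are written with four
#' decimals and round-trip losslessly at that precision through
#' [read_results()]. Excluded samples (no measurable HBIs) have their
#' H-Print/iPOC fields emitted as the explicit missing marker `NA`,
#' never as 0.
#'
#' @param results Results data.frame from [run_pipeline()]; must be
#'   non-empty.
#' @param path Output file path.
#' @param delimiter Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, delimiter = ",") {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("refusing to write an empty result set")
  need <- c("sample_id", "hprint_pct", "ipoc_raw_pct", "ipoc_pct", "classification")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(sample_id = results$sample_id, stringsAsFactors = FALSE)
  for (f in c("species", "habitat", "month"))
    out[[f]] <- if (f %in% names(results)) results[[f]] else NA
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.4f", x))
  out$hprint_pct <- fmt(results$hprint_pct)
  out$ipoc_raw_pct <- fmt(results$ipoc_raw_pct)
  out$ipoc_pct <- fmt(results$ipoc_pct)
  out$classification <- results$classification
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     qmethod = "double", na = "NA")
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path Path to the results file.
#' @param delimiter Field delimiter (default `","`).
#' @return A data.frame with typed columns.
#' @export
read_results <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (f in c("hprint_pct", "ipoc_raw_pct", "ipoc_pct"))
    df[[f]] <- as.numeric(df[[f]])
  if (!is.null(df$month)) df$month <- as.integer(df$month)
  df
}
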