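#' Construct a sediment core profile
#'
#' A profile is an ordered stack of layers with depth intervals (mm below
#' the sediment surface), total organic carbon (TOC, mg per g dry
#' sediment), and either the three HBI intensities or a precomputed
#' sediment H-Print (%), plus a constant sedimentation rate and the
#' calendar year of core collection. Layers must be sorted by depth and
#' non-overlapping.
#'
#' @param layers data.frame with columns `depth_top_mm`,
#'   `depth_bottom_mm`, `toc_mg_per_g`, and either (`ip25`, `hbi2`,
#'   `hbi3`) or `hprint_pct` (mutually exclusive).
#' @param sedimentation_rate_mm_per_y constant sedimentation rate,
#'   mm per year (> 0; default 1, the Amundsen Gulf shelf value).
#' @param sampling_year calendar year the core was collected.
#' @param station_meta optional free-text station description.
#' @return An object of class `"sediment_profile"`.
#' @export
sediment_profile <- function(layers, sedimentation_rate_mm_per_y = 1.0,
                             sampling_year, station_meta = NULL) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1L,
            all(c("depth_top_mm", "depth_bottom_mm", "toc_mg_per_g") %in% names(layers)),
            is.numeric(sedimentation_rate_mm_per_y),
            length(sedimentation_rate_mm_per_y) == 1L,
            is.numeric(sampling_year), length(sampling_year) == 1L)
  if (sedimentation_rate_mm_per_y <= 0)
    stop("sedimentation rate must be positive")
  has_intensities <- all(c("ip25", "hbi2", "hbi3") %in% names(layers))
  has_hprint <- "hprint_pct" %in% names(layers)
  if (has_intensities && has_hprint)
    stop("supply either HBI intensities or hprint_pct, not both")
  if (!has_intensities && !has_hprint)
    stop("layers need either (ip25, hbi2, hbi3) or hprint_pct")
  if (any(layers$depth_top_mm >= layers$depth_bottom_mm))
    stop("each layer needs depth_top_mm < depth_bottom_mm")
  o <- order(layers$depth_top_mm)
  layers <- layers[o, , drop = FALSE]
  if (any(layers$depth_bottom_mm[-nrow(layers)] > layers$depth_top_mm[-1] + 1e-9))
    stop("layers overlap")
  if (any(is.na(layers$toc_mg_per_g)) || any(layers$toc_mg_per_g < 0))
    stop("toc_mg_per_g must be non-negative")
  if (has_hprint && any(!is.na(layers$hprint_pct) &
                        (layers$hprint_pct < 0 | layers$hprint_pct > 100)))
    stop("hprint_pct must lie in [0, 100]")
  rownames(layers) <- NULL
  structure(list(layers = layers,
                 sedimentation_rate_mm_per_y = sedimentation_rate_mm_per_y,
                 sampling_year = sampling_year,
                 station_meta = station_meta,
                 has_intensities = has_intensities),
            class = "sediment_profile")
}

#' Read a sediment core table from delimited text
#'
#' Expected columns: `depth_top_mm`, `depth_bottom_mm`, `toc_mg_per_g`,
#' then either (`ip25`, `hbi2`, `hbi3`) or `hprint_pct`.
#'
#' @param path file path.
#' @param delimiter field delimiter (default `","`).
#' @inheritParams sediment_profile
#' @return A `"sediment_profile"` object.
#' @export
read_core <- function(path, sedimentation_rate_mm_per_y = 1.0, sampling_year,
                      station_meta = NULL, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  layers <- utils::read.table(path, header = TRUE, sep = delimiter,
                              stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sediment_profile(layers, sedimentation_rate_mm_per_y, sampling_year, station_meta)
}

#' Theoretical-maximum iPOC content of sediment layers
#'
#' For each layer: H-Print from the intensities (or passthrough of a
#' measured sediment H-Print), the clamped calibrated sea-ice carbon
#' fraction (iPOC% / 100), and the theoretical maximum iPOC per gram of
#' dry sediment, TOC x fraction. "Theoretical maximum" is literal: the
#' entire TOC share attributed to the sea-ice fraction with no
#' degradation, mixing, or burial-efficiency discount. Layers whose
#' H-Print is undefined (all-zero intensities) are flagged, not dropped.
#'
#' @param profile a `"sediment_profile"`.
#' @param cal an [hprint_calibration()].
#' @return data.frame: the layers plus `hprint_pct`, `ipoc_fraction`,
#'   `ipoc_mg_per_g`, `defined` (logical flag).
#' @export
layer_ipoc <- function(profile, cal = hprint_calibration()) {
  stopifnot(inherits(profile, "sediment_profile"))
  ly <- profile$layers
  h <- if (profile$has_intensities)
    compute_hprint(ly$ip25, ly$hbi2, ly$hbi3) else as.numeric(ly$hprint_pct)
  raw <- cal$intercept + cal$slope * h
  frac <- pmin(1, pmax(0, raw / 100))  # fraction always clamped: it scales TOC
  out <- ly
  out$hprint_pct <- h
  out$ipoc_fraction <- frac
  out$ipoc_mg_per_g <- ly$toc_mg_per_g * frac
  out$defined <- !is.na(h)
  out
}

#' Constant-rate age model for a sediment profile
#'
#' Depth converts linearly to calendar age:
#' age(d) = sampling_year - d / rate. No compaction correction is
#' applied. Ages get strictly older with depth.
#'
#' @param profile a `"sediment_profile"`.
#' @param depth_mm optional depths (mm) at which to evaluate the model;
#'   default: every layer boundary.
#' @return If `depth_mm` is given, a numeric vector of calendar years;
#'   otherwise the layer table with `age_top` and `age_bottom` columns.
#' @export
age_model <- function(profile, depth_mm = NULL) {
  stopifnot(inherits(profile, "sediment_profile"))
  rate <- profile$sedimentation_rate_mm_per_y
  age_at <- function(d) profile$sampling_year - d / rate
  if (!is.null(depth_mm)) {
    stopifnot(all(depth_mm >= 0))
    return(age_at(depth_mm))
  }
  ly <- profile$layers
  ly$age_top <- age_at(ly$depth_top_mm)
  ly$age_bottom <- age_at(ly$depth_bottom_mm)
  ly
}

#' Bioturbation-accessible iPOC inventory
#'
#' Burrowing infauna can access sediment down to a bioturbation horizon
#' (default 70 mm). This reports the range (min, max) of per-layer iPOC
#' concentration over layers intersecting \[0, horizon\] — a partially
#' overlapping layer counts whole, which is conservative for a maximum
#' estimate — and the age of the deepest accessible sediment.
#'
#' @param profile a `"sediment_profile"`.
#' @param cal an [hprint_calibration()].
#' @param horizon_mm bioturbation depth horizon in mm (> 0; default 70).
#' @return list: `min_ipoc_mg_per_g`, `max_ipoc_mg_per_g`,
#'   `oldest_accessible_age` (calendar year at the horizon),
#'   `accessible_horizon_mm`, `n_layers`, and the per-layer table
#'   `layers`.
#' @export
accessible_inventory <- function(profile, cal = hprint_calibration(),
                                 horizon_mm = 70) {
  stopifnot(inherits(profile, "sediment_profile"),
            is.numeric(horizon_mm), length(horizon_mm) == 1L)
  if (horizon_mm <= 0) stop("horizon must be a positive depth in mm")
  li <- layer_ipoc(profile, cal)
  hit <- li$depth_top_mm < horizon_mm & li$depth_bottom_mm > 0 & li$defined
  if (!any(hit)) stop("no defined layers intersect the 0-", horizon_mm, " mm horizon")
  acc <- li[hit, , drop = FALSE]
  list(min_ipoc_mg_per_g = min(acc$ipoc_mg_per_g),
       max_ipoc_mg_per_g = max(acc$ipoc_mg_per_g),
       oldest_accessible_age = age_model(profile, depth_mm = horizon_mm),
       accessible_horizon_mm = horizon_mm,
       n_layers = nrow(acc),
       layers = acc)
}

#' Full sediment workflow: per-layer iPOC, ages, and inventory
#'
#' @inheritParams accessible_inventory
#' @return list: `layers` (per-layer iPOC and ages) and `inventory`
#'   (see [accessible_inventory()]).
#' @export
compute_sediment <- function(profile, cal = hprint_calibration(),
                             horizon_mm = 70) {
  li <- layer_ipoc(profile, cal)
  ages <- age_model(profile)
  li$age_top <- ages$age_top
  li$age_bottom <- ages$age_bottom
  list(layers = li,
       inventory = accessible_inventory(profile, cal, horizon_mm))
}
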