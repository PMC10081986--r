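#' Compute the H-Print index from HBI intensities
#'
#' H-Print expresses the pelagic (phytoplankton) share of the three
#' source-diagnostic HBI lipids as a percentage:
#' 100 x HBI III / (IP25 + HBI II + HBI III). IP25 (m/z 350.3) and HBI II
#' (m/z 348.3) trace sea-ice diatoms; HBI III (m/z 346.3) traces pelagic
#' phytoplankton. H-Print 0 is a fully sympagic signal, 100 fully pelagic.
#'
#' Intensities are response-normalized GC-MS selected-ion-monitoring peak
#' areas in arbitrary units; the index is a ratio so any common scale
#' cancels. When all three intensities are zero the index is undefined and
#' `NA` is returned (such samples carry no HBI carbon-source information).
#'
#' @param ip25,hbi2,hbi3 Non-negative intensity vectors (recycled to a
#'   common length).
#' @return Numeric vector of H-Print values in \[0, 100\], `NA` where the
#'   denominator is zero.
#' @examples
#' compute_hprint(1, 1, 1)   # 33.33
#' compute_hprint(0, 0, 7.3) # 100
#' compute_hprint(0, 0, 0)   # NA: no measurable HBIs
#' @export
compute_hprint <- function(ip25, hbi2, hbi3) {
  check_intensities(ip25, hbi2, hbi3)
  n <- max(length(ip25), length(hbi2), length(hbi3))
  ip25 <- rep_len(ip25, n); hbi2 <- rep_len(hbi2, n); hbi3 <- rep_len(hbi3, n)
  denom <- ip25 + hbi2 + hbi3
  # the ratio lies in [0, 100] mathematically; guard against fp overshoot
  ifelse(denom > 0, pmin(100, pmax(0, 100 * hbi3 / denom)), NA_real_)
}

check_intensities <- function(ip25, hbi2, hbi3) {
  for (nm in c("ip25", "hbi2", "hbi3")) {
    x <- get(nm, inherits = FALSE)
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop("intensity '", nm, "' must be finite and non-missing")
    if (any(x < 0))
      stop("intensity '", nm, "' must be non-negative")
  }
  invisible(TRUE)
}

#' Convert H-Print to an iPOC estimate
#'
#' Applies the linear calibration iPOC = intercept + slope x H-Print.
#' Because the calibration line exceeds 100% at H-Print 0 and falls below
#' 0% at H-Print 100, the clamped value (restricted to \[0, 100\]) is what
#' the pipeline reports as a carbon percentage; the raw prediction is
#' returned alongside.
#'
#' @param h H-Print values in \[0, 100\] (`NA` allowed, propagated).
#' @param cal An [hprint_calibration()] object.
#' @return A data.frame with columns `ipoc_raw_pct` and `ipoc_pct`.
#' @export
hprint_to_ipoc <- function(h, cal = hprint_calibration()) {
  stopifnot(inherits(cal, "hprint_calibration"))
  if (!is.numeric(h)) stop("h must be numeric")
  bad <- !is.na(h) & (h < 0 | h > 100)
  if (any(bad))
    stop("H-Print values outside [0, 100]: ", paste(h[bad][1:min(3, sum(bad))], collapse = ", "))
  raw <- cal$intercept + cal$slope * h
  clamped <- if (cal$clamp) pmin(100, pmax(0, raw)) else raw
  data.frame(ipoc_raw_pct = raw, ipoc_pct = clamped)
}

#' Classify a sample's carbon-source signature
#'
#' Three mutually exclusive classes cover every zero/nonzero pattern of
#' the intensities:
#' \describe{
#'   \item{`excluded_no_hbis`}{all three intensities zero; no iPOC value
#'     can be calculated and the sample is excluded.}
#'   \item{`pelagic_only`}{both sea-ice HBIs (IP25, HBI II) zero but
#'     HBI III present: only phytoplankton carbon detected.}
#'   \item{`both_sources`}{any sea-ice HBI present.}
#' }
#' Classification works from the intensities directly, not from an iPOC
#' threshold.
#'
#' @inheritParams compute_hprint
#' @return Character vector over the three classes.
#' @export
classify_sample <- function(ip25, hbi2, hbi3) {
  check_intensities(ip25, hbi2, hbi3)
  n <- max(length(ip25), length(hbi2), length(hbi3))
  ip25 <- rep_len(ip25, n); hbi2 <- rep_len(hbi2, n); hbi3 <- rep_len(hbi3, n)
  ifelse(ip25 + hbi2 + hbi3 == 0, "excluded_no_hbis",
         ifelse(ip25 == 0 & hbi2 == 0, "pelagic_only", "both_sources"))
}

#' Run the H-Print/iPOC pipeline over a sample table
#'
#' Computes H-Print, raw and clamped iPOC, and the source classification
#' for every sample; samples with no measurable HBIs are flagged as
#' excluded (their H-Print and iPOC are `NA`) and listed in the exclusion
#' log rather than dropped.
#'
#' @param samples A data.frame of validated biomarker samples, as produced
#'   by [read_samples()] or [generate_samples()]; must contain `sample_id`,
#'   `ip25`, `hbi2`, `hbi3`, and carries any metadata columns
#'   (`species`, `habitat`, `month`, ...) through to the results.
#' @param cal An [hprint_calibration()] object.
#' @return A list with components:
#'   \describe{
#'     \item{`results`}{data.frame with one row per input sample: the
#'       metadata columns plus `hprint_pct`, `ipoc_raw_pct`, `ipoc_pct`,
#'       `classification`.}
#'     \item{`exclusion_log`}{character vector of `sample_id`s classified
#'       `excluded_no_hbis`.}
#'   }
#' @examples
#' s <- data.frame(sample_id = c("a", "b"), ip25 = c(1, 0),
#'                 hbi2 = c(1, 0), hbi3 = c(1, 0))
#' run_pipeline(s)$results
#' @export
run_pipeline <- function(samples, cal = hprint_calibration()) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) stop("no samples to process")
  need <- c("sample_id", "ip25", "hbi2", "hbi3")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("samples table lacks column(s): ", paste(missing_cols, collapse = ", "))

  h <- compute_hprint(samples$ip25, samples$hbi2, samples$hbi3)
  ip <- hprint_to_ipoc(h, cal)
  cls <- classify_sample(samples$ip25, samples$hbi2, samples$hbi3)

  results <- samples
  results$hprint_pct <- h
  results$ipoc_raw_pct <- ip$ipoc_raw_pct
  results$ipoc_pct <- ip$ipoc_pct
  results$classification <- cls
  excluded <- results$sample_id[cls == "excluded_no_hbis"]
  stopifnot(all(is.finite(results$ipoc_pct[cls != "excluded_no_hbis"])))
  list(results = results, exclusion_log = as.character(excluded))
}
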