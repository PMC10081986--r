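#' @title Box-plot style group summaries of iPOC estimates
#' @description Internal workhorse: one summary row per group, with
#'   quartiles by linear interpolation (type-7 quantiles) and a
#'   configurable whisker convention.
#' @param values numeric vector (iPOC %)
#' @param keys grouping vector, same length
#' @param whiskers `"tukey"` (1.5 x IQR fences, points beyond are
#'   outliers) or `"minmax"` (whiskers at the extremes, no outliers)
#' @return data.frame with one row per group and a list-column
#'   `outlier_values`
#' @keywords internal
summarize_groups <- function(values, keys, whiskers = c("tukey", "minmax")) {
  whiskers <- match.arg(whiskers)
  stopifnot(length(values) == length(keys), !anyNA(values))
  groups <- split(values, keys)
  rows <- lapply(names(groups), function(k) {
    x <- groups[[k]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    if (whiskers == "tukey") {
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[3] + 1.5 * iqr
      inside <- x >= lo_fence & x <= hi_fence
      wl <- min(x[inside]); wh <- max(x[inside])
      outl <- x[!inside]
    } else {
      wl <- min(x); wh <- max(x); outl <- numeric()
    }
    data.frame(group_key = k, n = length(x), mean = mean(x),
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = wl, whisker_high = wh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$outlier_values <- lapply(names(groups), function(k) {
    x <- groups[[k]]
    if (whiskers == "minmax") return(numeric())
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    sort(x[x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr])
  })
  rownames(out) <- NULL
  out
}

included_results <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("ipoc_pct", "classification") %in% names(results)))
  results[results$classification != "excluded_no_hbis", , drop = FALSE]
}

#' Species-binned iPOC summaries
#'
#' One box-plot summary per species over included (non-excluded) samples,
#' ordered by taxon group then species so benthic invertebrates,
#' zooplankton, fish, and birds/mammals stay contiguous. Species whose
#' samples were all excluded are omitted from the table and reported in
#' the log.
#'
#' @param results Results data.frame from [run_pipeline()]; must carry
#'   `species` (and ideally `taxon_group`) metadata columns.
#' @param whiskers Whisker convention, see [summarize_groups()].
#' @return A list: `summary` (data.frame, one row per species, with
#'   `taxon_group` when available) and `dropped_species` (character).
#' @export
species_summary <- function(results, whiskers = c("tukey", "minmax")) {
  whiskers <- match.arg(whiskers)
  stopifnot("species" %in% names(results))
  inc <- included_results(results)
  if (nrow(inc) == 0L) stop("no included results to summarize")
  dropped <- setdiff(unique(results$species), unique(inc$species))
  out <- summarize_groups(inc$ipoc_pct, inc$species, whiskers)
  names(out)[names(out) == "group_key"] <- "species"
  if ("taxon_group" %in% names(inc)) {
    tg <- tapply(inc$taxon_group, inc$species, function(x) x[1])
    out$taxon_group <- as.character(tg[out$species])
    out <- out[order(out$taxon_group, out$species), , drop = FALSE]
    rownames(out) <- NULL
  }
  list(summary = out, dropped_species = dropped)
}

#' Monthly-binned iPOC summaries
#'
#' One summary per calendar month (at most 12 bins) over included samples
#' with a recorded month; samples without a month cannot be placed in a
#' bin, so they are excluded from this summary and counted in the log.
#'
#' @inheritParams species_summary
#' @return A list: `summary` (data.frame keyed by integer `month`) and
#'   `n_missing_month` (count of included samples lacking a month).
#' @export
monthly_summary <- function(results, whiskers = c("tukey", "minmax")) {
  whiskers <- match.arg(whiskers)
  stopifnot("month" %in% names(results))
  inc <- included_results(results)
  if (nrow(inc) == 0L) stop("no included results to summarize")
  n_missing <- sum(is.na(inc$month))
  inc <- inc[!is.na(inc$month), , drop = FALSE]
  if (nrow(inc) == 0L) stop("every included sample lacks a recorded month")
  out <- summarize_groups(inc$ipoc_pct, sprintf("%02d", inc$month), whiskers)
  out$month <- as.integer(out$group_key)
  out$group_key <- NULL
  out <- out[order(out$month), c("month", setdiff(names(out), "month"))]
  rownames(out) <- NULL
  list(summary = out, n_missing_month = n_missing)
}

#' Count samples exceeding an iPOC threshold
#'
#' The 50% iPOC line is the minimum threshold for an organism to carry a
#' stronger sea-ice carbon signature than phytoplankton; exceedance is
#' strict (`>`), so a sample at exactly the threshold does not count.
#' Only included (non-excluded) samples enter the denominator.
#'
#' @param results Results data.frame from [run_pipeline()].
#' @param threshold iPOC % threshold in \[0, 100\] (default 50).
#' @return A list: `count`, `proportion`, `n_included`.
#' @export
proportion_above <- function(results, threshold = 50) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 100)
  inc <- included_results(results)
  if (nrow(inc) == 0L) stop("no included samples")
  count <- sum(inc$ipoc_pct > threshold)
  list(count = count, proportion = count / nrow(inc), n_included = nrow(inc))
}
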