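#' H-Print to iPOC calibration line
#'
#' Constructs the linear calibration used to convert an H-Print value (%)
#' into an estimate of sea-ice particulate organic carbon (iPOC, % of
#' marine-origin carbon). The default coefficients are those of the
#' published controlled feeding-experiment calibration
#' (iPOC = 101.08 - 1.02 x H-Print, R^2 = 0.97, df = 23). The coefficients
#' are data, not code constants: alternative calibrations can be injected
#' anywhere a calibration is accepted.
#'
#' @param intercept Intercept of the calibration line, in iPOC %.
#'   Must be positive.
#' @param slope Slope in iPOC % per H-Print unit. Must be negative: more
#'   pelagic HBI III (higher H-Print) always means less sea-ice carbon.
#' @param r_squared Coefficient of determination of the original
#'   calibration fit (informational only).
#' @param df Residual degrees of freedom of the original calibration fit
#'   (informational only).
#' @param clamp If `TRUE` (default), predicted iPOC is clamped to
#'   \[0, 100\]; the raw (unclamped) prediction is always retained
#'   alongside so the bare calibration line is recoverable.
#' @return An object of class `"hprint_calibration"`.
#' @examples
#' cal <- hprint_calibration()
#' hprint_to_ipoc(0, cal)    # intercept, clamped to 100
#' hprint_to_ipoc(50, cal)   # 50.08
#' @export
hprint_calibration <- function(intercept = 101.08, slope = -1.02,
                               r_squared = 0.97, df = 23, clamp = TRUE) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.logical(clamp), length(clamp) == 1L)
  if (intercept <= 0)
    stop("calibration intercept must be positive, got ", intercept)
  if (slope >= 0)
    stop("calibration slope must be negative, got ", slope)
  structure(
    list(intercept = intercept, slope = slope,
         r_squared = r_squared, df = df, clamp = clamp),
    class = "hprint_calibration"
  )
}

#' @export
print.hprint_calibration <- function(x, ...) {
  cat(sprintf("H-Print calibration: iPOC(%%) = %.4g %+.4g x H-Print\n",
              x$intercept, x$slope))
  cat(sprintf("  (R^2 = %.3g, df = %d, clamp to [0,100]: %s)\n",
              x$r_squared, as.integer(x$df), x$clamp))
  invisible(x)
}

#' Read a calibration from a YAML file
#'
#' @param path Path to a YAML file with any of the fields `intercept`,
#'   `slope`, `r_squared`, `df`, `clamp`; missing fields take the
#'   published defaults.
#' @return An `"hprint_calibration"` object.
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- formals(hprint_calibration)
  args <- utils::modifyList(lapply(defaults, eval), cfg[names(cfg) %in% names(defaults)])
  do.call(hprint_calibration, args)
}
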