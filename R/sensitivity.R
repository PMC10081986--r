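#' Partial R-squared of a regression term with the outcome
#'
#' Fraction of the residual outcome variance explained by one regressor,
#' computed from its t-statistic: t^2 / (t^2 + df).
#'
#' @param t t-statistic of the term.
#' @param df residual degrees of freedom of the fit.
#' @return value in \[0, 1\].
#' @export
partial_r2 <- function(t, df) {
  stopifnot(is.numeric(t), is.numeric(df), df >= 1)
  t^2 / (t^2 + df)
}

#' Robustness value for omitted-variable bias
#'
#' The robustness value RV_q is the minimal strength of association —
#' partial R-squared with both the treatment and the outcome — that an
#' unobserved confounder would need in order to reduce the treatment
#' estimate by a proportion `q` (q = 1: explain it away entirely). With
#' the partial Cohen's f of the treatment, f = |t| / sqrt(df), and
#' f_q = q f, the closed form is
#' RV_q = (sqrt(f_q^4 + 4 f_q^2) - f_q^2) / 2.
#'
#' With `alpha < 1` the target is instead to drive the adjusted
#' t-statistic (on df - 1 degrees of freedom, one lost to the confounder)
#' down to the alpha-critical value rather than to zero:
#' f_{q,alpha} = f_q - |t*_{alpha, df-1}| / sqrt(df - 1), and RV uses the
#' same closed form on f_{q,alpha}, floored at 0 when the observed effect
#' is already not significant at `alpha`. An extreme-case correction
#' applies when f_{q,alpha} > 1 / f_crit, where the confounder would need
#' partial R-squared with the outcome above 1.
#'
#' @param t observed t-statistic of the treatment term.
#' @param df residual degrees of freedom.
#' @param q proportion of the estimate to be explained away (default 1).
#' @param alpha significance level defining "overturned"; `alpha = 1`
#'   means reduce the point estimate itself.
#' @return value in \[0, 1\].
#' @export
robustness_value <- function(t, df, q = 1, alpha = 1) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t),
            df >= 2, q > 0, alpha > 0, alpha <= 1)
  fq <- q * abs(t) / sqrt(df)
  f_crit <- abs(stats::qt(alpha / 2, df = df - 1)) / sqrt(df - 1)
  fqa <- fq - f_crit
  if (fqa < 0) return(0)
  rv <- 0.5 * (sqrt(fqa^4 + 4 * fqa^2) - fqa^2)
  if (f_crit > 0 && fqa > 0 && fq > 1 / f_crit)
    rv <- (fq^2 - f_crit^2) / (1 + fq^2)
  rv
}

#' Sensitivity of a fitted treatment effect to omitted confounders
#'
#' Given an OLS fit and one column of its design as the treatment,
#' reports the treatment's partial R-squared with the outcome, the
#' robustness value at q (how strong a confounder must be to explain away
#' the whole estimate), and the robustness value at (q, alpha) (how
#' strong to make it lose significance at `alpha`). Small values mean a
#' weak confounder could overturn the result; values near 1 mean only a
#' confounder explaining nearly all residual variance could.
#'
#' @param fit an `"ipoc_ols"` object from [fit_ols()].
#' @param treatment name of a single fitted coefficient (e.g.
#'   `"habitat"` under score coding, or `"habitat.sympagic"` under
#'   contrast coding). The intercept is not a valid treatment.
#' @param q proportion of the estimate to explain away (default 1).
#' @param alpha significance level (default 0.05).
#' @return An object of class `"ipoc_sensitivity"`.
#' @export
sensitivity <- function(fit, treatment, q = 1, alpha = 0.05) {
  stopifnot(inherits(fit, "ipoc_ols"), is.character(treatment),
            length(treatment) == 1L)
  if (treatment == "(Intercept)") stop("the intercept cannot be the treatment")
  if (!treatment %in% names(fit$coefficients))
    stop("treatment '", treatment, "' is not a fitted coefficient; available: ",
         paste(setdiff(names(fit$coefficients), "(Intercept)"), collapse = ", "))
  if (fit$df_residual < 2) stop("need df_residual >= 2 for sensitivity analysis")
  se <- fit$se[[treatment]]
  if (!is.finite(se) || se <= 0) stop("treatment standard error is zero or undefined")
  t <- fit$t_values[[treatment]]
  structure(
    list(treatment_term = treatment,
         t_value = t, df_residual = fit$df_residual,
         partial_r2_outcome = partial_r2(t, fit$df_residual),
         robustness_value = robustness_value(t, fit$df_residual, q = q, alpha = 1),
         robustness_value_alpha = robustness_value(t, fit$df_residual, q = q, alpha = alpha),
         q = q, alpha = alpha),
    class = "ipoc_sensitivity"
  )
}

#' @export
print.ipoc_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity of '%s' (t = %.3f, df = %d):\n",
              x$treatment_term, x$t_value, x$df_residual))
  cat(sprintf("  partial R2 with outcome: %.4f\n", x$partial_r2_outcome))
  cat(sprintf("  robustness value (q = %g): %.4f\n", x$q, x$robustness_value))
  cat(sprintf("  robustness value (q = %g, alpha = %g): %.4f\n",
              x$q, x$alpha, x$robustness_value_alpha))
  invisible(x)
}

#' Refit a month-bearing model under a seasonal shift
#'
#' Sanity check on seasonal confounding: every observation's month is
#' shifted (default three months earlier) with modular wraparound
#' (January - 3 = October), the model is refitted, and the two fits are
#' reported side by side together with sensitivity results for a chosen
#' treatment. If conclusions (sign and significance of the treatment)
#' survive the shift, a simple seasonal offset alone cannot explain the
#' fitted structure.
#'
#' @param results results data.frame (from [run_pipeline()]) with a
#'   `month` column and the model's other predictors.
#' @param terms model terms; must involve `month`.
#' @param shift integer month shift (default -3 = three months earlier).
#' @param treatment treatment coefficient for the sensitivity comparison
#'   (default `"habitat"`); `NULL` to omit.
#' @param response,encoding passed to [fit_ols()].
#' @param alpha significance level for the sensitivity analysis.
#' @return list with `original`, `shifted` (both `"ipoc_ols"`),
#'   `comparison` (data.frame of coefficients and t-values side by side),
#'   and `sensitivity_original`/`sensitivity_shifted` when a treatment is
#'   given.
#' @export
month_shift_check <- function(results, terms, shift = -3, treatment = "habitat",
                              response = "ipoc_pct", encoding = list(),
                              alpha = 0.05) {
  if (!any(grepl("month", terms)))
    stop("the shift check needs a model with a month term")
  stopifnot("month" %in% names(results), shift == round(shift))
  keep <- !is.na(results$month)
  d <- results[keep, , drop = FALSE]
  original <- fit_ols(d, terms, response = response, encoding = encoding)
  d_shift <- d
  d_shift$month <- shift_month(d$month, shift)
  shifted <- fit_ols(d_shift, terms, response = response, encoding = encoding)
  comparison <- data.frame(
    term = names(original$coefficients),
    coef_original = unname(original$coefficients),
    coef_shifted = unname(shifted$coefficients),
    t_original = unname(original$t_values),
    t_shifted = unname(shifted$t_values),
    p_original = unname(original$p_values),
    p_shifted = unname(shifted$p_values),
    stringsAsFactors = FALSE
  )
  out <- list(original = original, shifted = shifted, comparison = comparison,
              shift = shift)
  if (!is.null(treatment)) {
    out$sensitivity_original <- sensitivity(original, treatment, alpha = alpha)
    out$sensitivity_shifted <- sensitivity(shifted, treatment, alpha = alpha)
  }
  out
}

#' Shift calendar months with wraparound
#'
#' @param month integer months in 1..12 (`NA` allowed).
#' @param shift integer shift (negative = earlier).
#' @return shifted months in 1..12.
#' @export
shift_month <- function(month, shift) {
  stopifnot(all(is.na(month) | (month %in% 1:12)))
  ((month - 1 + shift) %% 12) + 1
}
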