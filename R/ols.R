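#' Encode predictors into a numeric design matrix
#'
#' The candidate models regress iPOC on combinations of month, year,
#' latitude, habitat, species, taxon group, and the month x habitat
#' interaction. Encodings follow the reporting conventions of the
#' analysis:
#' \itemize{
#'   \item `month` enters as a numeric 1-12 covariate by default (a single
#'     coefficient/t-value per month term); `month_coding = "circular"`
#'     replaces it with sine/cosine components of period 12.
#'   \item `habitat` enters as a single ordered score column by default
#'     (`habitat_scores`, pelagic < sympagic < mixed < benthic, reflecting
#'     increasing access to sea-ice carbon via the benthos), again giving
#'     a single coefficient; `habitat_coding = "contrast"` switches to
#'     treatment contrasts (3 dummy columns, reference = first vocabulary
#'     level present) with per-level coefficients.
#'   \item `species` and `taxa` (taxon group) always use treatment
#'     contrasts.
#'   \item interactions `a:b` are elementwise products of the encoded
#'     columns of `a` and `b`.
#' }
#'
#' @param data data.frame holding the predictor columns (`month`, `year`,
#'   `latitude`, `habitat`, `species`, `taxon_group`).
#' @param terms character vector of term labels, e.g.
#'   `c("month", "latitude", "habitat", "month:habitat")`.
#' @param encoding list with optional elements `habitat_coding`
#'   (`"score"`/`"contrast"`), `habitat_scores` (named numeric), and
#'   `month_coding` (`"numeric"`/`"circular"`).
#' @return numeric matrix (no intercept column) with one or more named
#'   columns per term.
#' @export
encode_design <- function(data, terms, encoding = list()) {
  habitat_coding <- encoding$habitat_coding %||% "score"
  month_coding <- encoding$month_coding %||% "numeric"
  habitat_scores <- encoding$habitat_scores %||%
    c(pelagic = 1, sympagic = 2, mixed = 3, benthic = 4)

  base_cols <- function(term) {
    switch(term,
      month = {
        m <- as.numeric(data$month)
        if (month_coding == "circular")
          cbind(month_sin = sin(2 * pi * m / 12), month_cos = cos(2 * pi * m / 12))
        else cbind(month = m)
      },
      year = cbind(year = as.numeric(data$year)),
      latitude = cbind(latitude = as.numeric(data$latitude)),
      habitat = {
        h <- as.character(data$habitat)
        unknown <- setdiff(unique(h[!is.na(h)]), names(habitat_scores))
        if (length(unknown))
          stop("no habitat score for: ", paste(unknown, collapse = ", "))
        if (habitat_coding == "contrast") dummy_cols(h, "habitat")
        else cbind(habitat = unname(habitat_scores[h]))
      },
      species = dummy_cols(as.character(data$species), "species"),
      taxa = dummy_cols(as.character(data$taxon_group), "taxa"),
      stop("unknown model term: ", term)
    )
  }
  one_term <- function(term) {
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("only two-way interactions supported: ", term)
      a <- base_cols(parts[1]); b <- base_cols(parts[2])
      cols <- do.call(cbind, lapply(seq_len(ncol(a)), function(i)
        sapply(seq_len(ncol(b)), function(j) a[, i] * b[, j])))
      cols <- matrix(cols, nrow = nrow(a))
      colnames(cols) <- as.vector(outer(colnames(a), colnames(b),
                                        function(x, y) paste(x, y, sep = ":")))
      cols
    } else base_cols(term)
  }
  X <- do.call(cbind, lapply(terms, one_term))
  rownames(X) <- NULL
  X
}

dummy_cols <- function(x, prefix) {
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) < 2L)
    stop("term '", prefix, "' has fewer than 2 levels")
  ref <- lev[1]
  cols <- sapply(lev[-1], function(l) as.numeric(x == l))
  cols <- matrix(cols, nrow = length(x))
  colnames(cols) <- paste(prefix, lev[-1], sep = ".")
  cols
}

#' Ordinary least squares with Gaussian AIC, from first principles
#'
#' Exact least-squares solution by QR decomposition of the design matrix
#' (intercept always included). Standard errors come from the unscaled
#' covariance (X'X)^-1 via the R factor; t-statistics are coefficient/SE
#' with two-sided p-values on `df_residual` degrees of freedom. The
#' log-likelihood is the full Gaussian likelihood at the ML variance
#' estimate (constants included), and AIC = 2k - 2*logLik with k counting
#' every estimated parameter, error variance included — so values are
#' directly comparable to standard statistical software.
#'
#' @param data data.frame with the response and predictor columns. Rows
#'   with missing values in the response or any used predictor are
#'   dropped (count reported in the fit); pre-filter if several models
#'   must share an identical response vector.
#' @param terms character vector of predictor terms (see
#'   [encode_design()]).
#' @param response name of the response column (default `"ipoc_pct"`).
#' @param encoding encoding options passed to [encode_design()].
#' @return An object of class `"ipoc_ols"`: coefficients, `se`,
#'   `t_values`, `p_values`, `df_residual`, `n`, `rss`, `log_likelihood`,
#'   `aic`, `n_params`, plus the response vector used (for model
#'   comparison) and bookkeeping fields.
#' @examples
#' d <- data.frame(latitude = 1:6, y = 3 + 2 * (1:6))
#' f <- fit_ols(d, "latitude", response = "y")
#' f$coefficients  # intercept 3, slope exactly 2
#' @export
fit_ols <- function(data, terms, response = "ipoc_pct", encoding = list()) {
  stopifnot(is.data.frame(data), length(terms) >= 1L)
  if (!response %in% names(data)) stop("response column '", response, "' not found")
  vars <- unique(c(response, term_vars(terms)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("data lacks column(s): ", paste(missing_vars, collapse = ", "))
  keep <- stats::complete.cases(data[vars])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]

  y <- as.numeric(d[[response]])
  X <- cbind(`(Intercept)` = 1, encode_design(d, terms, encoding))
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations (", n, ") than parameters (", p, ")")

  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  R <- qr.R(qrx)
  unpivot <- order(qrx$pivot)
  xtx_inv <- chol2inv(R)[unpivot, unpivot, drop = FALSE]
  se <- stats::setNames(sqrt(pmax(diag(xtx_inv), 0) * sigma2), names(beta))
  tv <- beta / se
  pv <- 2 * stats::pt(-abs(tv), df_res)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- p + 1L  # + error variance
  structure(
    list(terms = terms, formula_label = paste(terms, collapse = " + "),
         response_name = response, coefficients = beta, se = se,
         t_values = tv, p_values = pv, df_residual = df_res, n = n,
         n_dropped = n_dropped, rss = rss, log_likelihood = ll,
         n_params = k, aic = 2 * k - 2 * ll, response = y,
         encoding = encoding),
    class = "ipoc_ols"
  )
}

term_vars <- function(terms) {
  atoms <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  map <- c(month = "month", year = "year", latitude = "latitude",
           habitat = "habitat", species = "species", taxa = "taxon_group")
  unknown <- setdiff(atoms, names(map))
  if (length(unknown)) stop("unknown model term(s): ", paste(unknown, collapse = ", "))
  unname(map[atoms])
}

#' @export
print.ipoc_ols <- function(x, ...) {
  cat("OLS fit:", x$response_name, "~", x$formula_label, "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    t = x$t_values, p = signif(x$p_values, 3))
  print(tab, ...)
  cat(sprintf("n = %d (%d dropped), df_residual = %d, logLik = %.3f, AIC = %.3f\n",
              x$n, x$n_dropped, x$df_residual, x$log_likelihood, x$aic))
  invisible(x)
}

#' Rank candidate models by AIC
#'
#' All fits must be on the identical response vector (same samples, same
#' order) — otherwise AIC values are not comparable and an error is
#' raised. Models are ranked by ascending AIC; exact ties are broken by
#' parsimony (fewer parameters), then by formula label.
#'
#' @param fits list of `"ipoc_ols"` objects.
#' @return data.frame with columns `formula`, `k`, `log_likelihood`,
#'   `aic`, `delta_aic`, `rank`, ordered best-first.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "ipoc_ols")))
  y0 <- fits[[1]]$response
  for (f in fits)
    if (length(f$response) != length(y0) || !isTRUE(all.equal(f$response, y0)))
      stop("fits are not on the identical response vector; refit on a common sample")
  tab <- data.frame(
    formula = vapply(fits, `[[`, character(1), "formula_label"),
    k = vapply(fits, `[[`, integer(1), "n_params"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aic, tab$k, tab$formula)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
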