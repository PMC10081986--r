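habitat_score_default <- c(pelagic = 1, sympagic = 2, mixed = 3, benthic = 4)

random_fit_data <- function(n, seed) {
  set.seed(seed)
  data.frame(
    month = runif(n, 1, 12), year = runif(n, 1982, 2019),
    latitude = runif(n, 55, 82),
    habitat = sample(names(habitat_score_default), n, replace = TRUE),
    ipoc_pct = runif(n, 0, 100)
  )
}

test_that("a noiseless line is fit exactly", {
  d <- data.frame(latitude = 1:5, y = 2 * (1:5))
  f <- fit_ols(d, "latitude", response = "y")
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
  expect_lt(f$rss, 1e-20)
})

test_that("t-statistics equal coefficient over standard error", {
  f <- fit_ols(random_fit_data(40, 5), c("month", "latitude", "habitat"))
  expect_equal(f$t_values, f$coefficients / f$se, tolerance = 1e-14)
  expect_equal(f$p_values,
               2 * pt(-abs(f$t_values), f$df_residual), tolerance = 1e-14)
})

test_that("QR solution matches the normal-equations oracle", {
  for (seed in 1:5) {
    # small 6x3 system
    d6 <- random_fit_data(6, seed)
    f6 <- fit_ols(d6, c("month", "latitude"))
    o6 <- ols_oracle(cbind(1, d6$month, d6$latitude), d6$ipoc_pct)
    expect_equal(unname(f6$coefficients), o6$beta, tolerance = 1e-8)
    expect_equal(unname(f6$se), o6$se, tolerance = 1e-8)
    # 50x5 system with an encoded habitat score
    d <- random_fit_data(50, seed + 100)
    f <- fit_ols(d, c("month", "year", "latitude", "habitat"))
    X <- cbind(1, d$month, d$year, d$latitude,
               habitat_score_default[d$habitat])
    o <- ols_oracle(X, d$ipoc_pct)
    expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-8)
    expect_equal(unname(f$se), o$se, tolerance = 1e-8)
    expect_equal(f$rss, o$rss, tolerance = 1e-8)
    expect_equal(f$df_residual, o$df)
  }
})

test_that("likelihood, AIC and per-term statistics agree with lm()", {
  d <- random_fit_data(80, 77)
  d$hab_score <- habitat_score_default[d$habitat]
  f <- fit_ols(d, c("month", "latitude", "habitat", "month:habitat"))
  ref <- lm(ipoc_pct ~ month + latitude + hab_score + I(month * hab_score),
            data = d)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(coef(summary(ref))[, 2]), tolerance = 1e-10)
  expect_equal(f$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(f$aic, AIC(ref), tolerance = 1e-10)
  expect_equal(f$aic, 2 * f$n_params - 2 * f$log_likelihood)
})

test_that("rank deficiency is refused, naming a collinear column", {
  d <- random_fit_data(30, 3)
  d$year <- 2 * d$latitude
  expect_error(fit_ols(d, c("latitude", "year")), "year|latitude")
})

test_that("contrast coding of habitat yields per-level coefficients", {
  d <- random_fit_data(60, 8)
  f <- fit_ols(d, "habitat", encoding = list(habitat_coding = "contrast"))
  expect_equal(sum(grepl("^habitat\\.", names(f$coefficients))), 3)
  ref <- lm(ipoc_pct ~ habitat, data = transform(d, habitat = factor(habitat)))
  expect_equal(sort(unname(f$coefficients)), sort(unname(coef(ref))),
               tolerance = 1e-10)
})

test_that("nested models with identical RSS differ by exactly 2 AIC per extra parameter", {
  set.seed(21)
  n <- 30
  d <- data.frame(latitude = runif(n, 55, 82))
  d$ipoc_pct <- 10 + 0.5 * d$latitude + rnorm(n)
  small <- fit_ols(d, "latitude")
  # construct a predictor orthogonal to the design and to the residuals:
  # its estimate is 0, so the RSS cannot change
  X <- cbind(1, d$latitude)
  r <- d$ipoc_pct - X %*% solve(crossprod(X), crossprod(X, d$ipoc_pct))
  v <- rnorm(n)
  z <- v - X %*% solve(crossprod(X), crossprod(X, v))
  z <- z - drop(crossprod(z, r) / crossprod(r, r)) * r
  d$year <- drop(z)
  big <- fit_ols(d, c("latitude", "year"))
  expect_equal(big$rss, small$rss, tolerance = 1e-10)
  expect_equal(big$aic - small$aic, 2, tolerance = 1e-8)
})

test_that("model comparison ranks by AIC with parsimony tie-breaks", {
  d <- random_fit_data(100, 15)
  fits <- lapply(list("month", c("month", "latitude"),
                      c("month", "latitude", "habitat")),
                 function(tm) fit_ols(d, tm))
  cmp <- compare_models(fits)
  expect_equal(cmp$delta_aic[1], 0)
  expect_true(all(diff(cmp$aic) >= 0))
  expect_equal(cmp$rank, 1:3)
  # a duplicated fit ties exactly; both orderings keep parsimony intact
  cmp2 <- compare_models(list(fits[[2]], fits[[2]]))
  expect_equal(cmp2$delta_aic, c(0, 0))
  # single fit is its own best model
  cmp1 <- compare_models(fits[1])
  expect_equal(cmp1$delta_aic, 0)
})

test_that("model comparison refuses fits on differing response vectors", {
  d <- random_fit_data(50, 31)
  f1 <- fit_ols(d, "month")
  f2 <- fit_ols(d[1:40, ], "month")
  expect_error(compare_models(list(f1, f2)), "identical response")
})
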