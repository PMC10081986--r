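# Shared fixtures and independent oracles, built in code at test time.

# Write a small consumer-sample CSV and return its path (session tempdir,
# cleaned up by R on exit).
write_sample_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

valid_sample_rows <- function(n = 3) {
  data.frame(
    sample_id = sprintf("F%03d", seq_len(n)),
    species = rep_len(c("Boreogadus saida", "Astarte borealis",
                        "Calanus glacialis"), n),
    taxon_group = rep_len(c("fish", "benthic_invertebrate", "zooplankton"), n),
    habitat = rep_len(c("pelagic", "benthic", "pelagic"), n),
    feeding_strategy = rep_len(c(NA, "suspension", NA), n),
    latitude = rep_len(c(71.2, 68.0, 75.5), n),
    longitude = rep_len(c(-150.1, 20.4, -60.0), n),
    year = rep_len(c(2015L, 2007L, 1999L), n),
    month = rep_len(c(5L, 8L, 11L), n),
    tissue = rep_len(c("muscle", NA, NA), n),
    ip25 = rep_len(c(1.2, 3.4, 0.0), n),
    hbi2 = rep_len(c(0.5, 1.1, 0.2), n),
    hbi3 = rep_len(c(2.0, 0.8, 4.5), n),
    stringsAsFactors = FALSE
  )
}

# Minimal results table for the summary/statistics operations.
make_results <- function(ipoc, species = "sp", month = 6L,
                         habitat = "benthic", latitude = 70,
                         classification = "both_sources",
                         taxon_group = "benthic_invertebrate") {
  n <- length(ipoc)
  data.frame(
    sample_id = sprintf("R%04d", seq_len(n)),
    species = rep_len(species, n), taxon_group = rep_len(taxon_group, n),
    habitat = rep_len(habitat, n), month = rep_len(month, n),
    latitude = rep_len(latitude, n), year = rep_len(2010L, n),
    hprint_pct = rep_len(NA_real_, n), ipoc_raw_pct = ipoc, ipoc_pct = ipoc,
    classification = rep_len(classification, n),
    stringsAsFactors = FALSE
  )
}

# Normal-equations OLS oracle: beta = (X'X)^-1 X'y, SEs from the same
# inverse. Deliberately naive and independent of the QR path under test.
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  se <- sqrt(diag(xtx_inv) * rss / df)
  list(beta = beta, se = se, rss = rss, df = df)
}

# Numeric oracle for the robustness value, independent of the closed
# form under test. RV is the smallest bound x such that a confounder with
# partial R2 at most x with the treatment (kx) and at most x with the
# outcome (ky) can drive the bias-adjusted t-statistic, on df - 1
# degrees of freedom, down to the alpha-critical threshold (0 when
# alpha = 1). The adjusted statistic is
#   t_adj(kx, ky) = (f - sqrt(ky*kx/(1-kx))) * sqrt((1-kx)/(1-ky)) * sqrt(df-1)
# with f the (q-scaled) partial Cohen's f of the treatment. For fixed kx,
# writing u = sqrt(ky), t_adj is proportional to (f - a*u)/sqrt(1-u^2)
# with a = sqrt(kx/(1-kx)), whose minimum over u sits at u = a/f; the
# outer minimization over kx <= x is monotone, so feasibility of a bound
# x is checked at kx = x with ky at the inner optimum (capped at x), and
# the oracle bisects on x.
rv_oracle <- function(t, df, q = 1, alpha = 1) {
  f <- q * abs(t) / sqrt(df)
  t_crit <- if (alpha >= 1) 0 else abs(stats::qt(alpha / 2, df - 1))
  t_adj_min <- function(x) {
    a2 <- x / (1 - x)
    if (a2 <= f^2 * x) {        # inner optimum ky = a2/f^2 is admissible
      sqrt(max(f^2 - a2, 0)) * sqrt(1 - x) * sqrt(df - 1)
    } else {                    # ky capped at the bound: equal strengths
      (f - sqrt(x * a2)) * sqrt(df - 1)
    }
  }
  if (t_adj_min(0) <= t_crit) return(0)
  lo <- 0; hi <- 1 - 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (t_adj_min(mid) <= t_crit) hi <- mid else lo <- mid
  }
  hi
}

# Sort-based box-plot oracle (no quantile() call).
boxstats_oracle <- function(x, whiskers = "tukey") {
  s <- sort(x)
  n <- length(s)
  interp_q <- function(p) {  # type-7 linear interpolation, by hand
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- interp_q(0.25); med <- interp_q(0.5); q3 <- interp_q(0.75)
  if (whiskers == "minmax") {
    list(q1 = q1, median = med, q3 = q3, whisker_low = s[1],
         whisker_high = s[n], outliers = numeric())
  } else {
    iqr <- q3 - q1
    inside <- s[s >= q1 - 1.5 * iqr & s <= q3 + 1.5 * iqr]
    list(q1 = q1, median = med, q3 = q3, whisker_low = min(inside),
         whisker_high = max(inside),
         outliers = s[s < q1 - 1.5 * iqr | s > q3 + 1.5 * iqr])
  }
}

# Build a "(15 of 54)"-shaped zooplankton fixture: 54 late-summer
# individuals of which 15 have no measurable HBIs.
late_summer_zooplankton <- function() {
  n <- 54; n_zero <- 15
  df <- data.frame(
    sample_id = sprintf("Z%03d", seq_len(n)),
    species = "Pseudocalanus sp.", taxon_group = "zooplankton",
    habitat = "pelagic", latitude = 76.1, year = 2018L, month = 8L,
    ip25 = c(rep(0, n_zero), runif(n - n_zero, 0.01, 1)),
    hbi2 = c(rep(0, n_zero), runif(n - n_zero, 0.01, 1)),
    hbi3 = c(rep(0, n_zero), runif(n - n_zero, 0.5, 5)),
    stringsAsFactors = FALSE
  )
  df
}
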