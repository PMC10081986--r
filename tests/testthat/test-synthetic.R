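test_that("the same seed reproduces the survey exactly", {
  cfg <- synth_config(n_samples = 300)
  g1 <- generate_samples(cfg, seed = 99)
  g2 <- generate_samples(cfg, seed = 99)
  expect_identical(g1$samples, g2$samples)
  expect_identical(g1$truth$true_ipoc, g2$truth$true_ipoc)
  g3 <- generate_samples(cfg, seed = 100)
  expect_false(identical(g1$samples$ip25, g3$samples$ip25))
})

test_that("generated samples satisfy the consumer-sample schema", {
  gen <- generate_samples(synth_config(n_samples = 400), seed = 2)
  rd <- validate_samples(gen$samples)
  expect_equal(nrow(rd$samples), 400)
  expect_equal(nrow(rd$errors), 0)
  expect_true(all(gen$samples$habitat %in% ipoc_vocabulary()$habitat))
  benthic <- gen$samples$taxon_group == "benthic_invertebrate"
  expect_true(all(!is.na(gen$samples$feeding_strategy[benthic])))
  expect_true(all(is.na(gen$samples$feeding_strategy[!benthic])))
})

test_that("without noise or corruption the pipeline recovers truth exactly", {
  cfg <- synth_config(n_samples = 200, noise_sd = 0, dropout_rate = 0,
                      pelagic_only_rate = 0)
  gen <- generate_samples(cfg, seed = 5)
  res <- run_pipeline(gen$samples)$results
  expect_equal(res$ipoc_pct, gen$truth$true_ipoc, tolerance = 1e-9)
  expect_equal(res$hprint_pct, gen$truth$true_hprint, tolerance = 1e-9)
  expect_true(all(res$classification == "both_sources"))
})

test_that("detection dropout hits at the configured binomial rate", {
  cfg <- synth_config(n_samples = 1000, dropout_rate = 0.1,
                      pelagic_only_rate = 0)
  gen <- generate_samples(cfg, seed = 8)
  n_zero <- sum(gen$samples$ip25 == 0 & gen$samples$hbi2 == 0 &
                gen$samples$hbi3 == 0)
  expect_equal(n_zero, sum(gen$truth$dropout))
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_zero, ci[1])
  expect_lte(n_zero, ci[2])
  # the pipeline excludes exactly those samples
  pipe <- run_pipeline(gen$samples)
  expect_setequal(pipe$exclusion_log, gen$samples$sample_id[gen$truth$dropout])
})

test_that("pelagic-only corruption removes exactly the sea-ice HBIs", {
  cfg <- synth_config(n_samples = 1000, dropout_rate = 0,
                      pelagic_only_rate = 0.08)
  gen <- generate_samples(cfg, seed = 21)
  po <- gen$truth$pelagic_only
  ci <- qbinom(c(0.005, 0.995), 1000, 0.08)
  expect_gte(sum(po), ci[1])
  expect_lte(sum(po), ci[2])
  expect_true(all(gen$samples$ip25[po] == 0 & gen$samples$hbi2[po] == 0))
  expect_true(all(gen$samples$hbi3[po] > 0))
  res <- run_pipeline(gen$samples)$results
  expect_true(all(res$classification[po] == "pelagic_only"))
  expect_true(all(res$ipoc_pct[po] == 0))
})

test_that("infeasible mean configurations are rejected up front", {
  expect_error(synth_config(habitat_base_ipoc = c(benthic = 120, mixed = 55,
                                                  pelagic = 40, sympagic = 65)),
               "infeasible")
  expect_error(synth_config(habitat_base_ipoc = c(benthic = 70, mixed = 55,
                                                  pelagic = 20, sympagic = 65),
                            pelagic_seasonal_amplitude = 30),
               "infeasible")
  expect_error(synth_config(habitat_probs = c(benthic = 0.9, mixed = 0.9,
                                              pelagic = 0, sympagic = 0)),
               "sum to 1")
  expect_error(synth_config(dropout_rate = 1.4), "rates")
})

test_that("habitat-group mean iPOC matches the configured structure within 2 SE", {
  cfg <- synth_config(n_samples = 2000, dropout_rate = 0, pelagic_only_rate = 0)
  gen <- generate_samples(cfg, seed = 3)
  res <- run_pipeline(gen$samples)$results
  # expectation from config alone: base mean, minus the seasonal dip
  # diluted over the 3 dip months of 12 (latitudes average out at the
  # reference)
  expected <- cfg$habitat_base_ipoc - cfg$pelagic_seasonal_amplitude *
    cfg$seasonal_habitat_weight[names(cfg$habitat_base_ipoc)] * 3 / 12
  for (h in names(expected)) {
    x <- res$ipoc_pct[res$habitat == h]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected[[h]]), 2 * se + 0.5,
              label = sprintf("habitat %s mean", h))
  }
})

test_that("synthetic cores honour profile shapes and seeds", {
  core <- generate_core(7, layer_thickness_mm = 10, toc_mg_per_g = 20,
                        hprint_pct = 30)
  prof <- sediment_profile(core, sampling_year = 2008)
  expect_equal(layer_ipoc(prof)$ipoc_mg_per_g, rep(14.096, 7))
  # monotone H-Print increase means monotone iPOC decrease
  inc <- generate_core(10, hprint_pct = function(d) 20 + 0.5 * d)
  li <- layer_ipoc(sediment_profile(inc, sampling_year = 2008))
  expect_true(all(diff(li$ipoc_mg_per_g) < 0))
  # seeded noisy cores regenerate identically
  n1 <- generate_core(10, toc_sd = 2, hprint_sd = 4, seed = 31)
  n2 <- generate_core(10, toc_sd = 2, hprint_sd = 4, seed = 31)
  expect_identical(n1, n2)
  expect_error(generate_core(3, hprint_pct = 130), "\\[0, 100\\]")
})
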