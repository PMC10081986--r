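core_fixture <- function(ipoc_span = c(9, 14), n = 7, toc = 20) {
  # choose per-layer H-Print so layer iPOC concentrations span ipoc_span
  frac <- seq(ipoc_span[1], ipoc_span[2], length.out = n) / toc
  h <- (101.08 - 100 * frac) / 1.02
  generate_core(n, layer_thickness_mm = 10, toc_mg_per_g = toc, hprint_pct = h)
}

test_that("layer iPOC follows TOC times the clamped calibrated fraction", {
  prof <- sediment_profile(generate_core(1, toc_mg_per_g = 20, hprint_pct = 30),
                           sampling_year = 2008)
  li <- layer_ipoc(prof)
  expect_equal(li$ipoc_fraction, (101.08 - 30 * 1.02) / 100)
  expect_equal(li$ipoc_fraction, 0.7048)
  expect_equal(li$ipoc_mg_per_g, 14.096)
  # pure pelagic layer clamps to zero
  p100 <- sediment_profile(generate_core(1, hprint_pct = 100), sampling_year = 2008)
  expect_equal(layer_ipoc(p100)$ipoc_mg_per_g, 0)
  # no organic carbon, no iPOC, whatever the H-Print
  p0 <- sediment_profile(generate_core(1, toc_mg_per_g = 0, hprint_pct = 10),
                         sampling_year = 2008)
  expect_equal(layer_ipoc(p0)$ipoc_mg_per_g, 0)
})

test_that("a layer's iPOC never exceeds its TOC", {
  set.seed(27)
  core <- generate_core(30, toc_mg_per_g = function(d) 25 - 0.1 * d,
                        hprint_pct = function(d) pmin(100, 20 + d / 4),
                        toc_sd = 2, hprint_sd = 5, seed = 27)
  li <- layer_ipoc(sediment_profile(core, sampling_year = 2008))
  expect_true(all(li$ipoc_mg_per_g <= li$toc_mg_per_g + 1e-12))
  expect_true(all(li$ipoc_fraction >= 0 & li$ipoc_fraction <= 1))
})

test_that("sediment layers with HBI intensities use the H-Print ratio", {
  layers <- data.frame(depth_top_mm = c(0, 10), depth_bottom_mm = c(10, 20),
                       toc_mg_per_g = 20, ip25 = c(1, 0), hbi2 = c(1, 0),
                       hbi3 = c(1, 0))
  prof <- sediment_profile(layers, sampling_year = 2008)
  li <- layer_ipoc(prof)
  expect_equal(li$hprint_pct[1], 100 / 3)
  expect_false(li$defined[2])  # all-zero layer flagged, not dropped
  expect_true(is.na(li$ipoc_mg_per_g[2]))
})

test_that("malformed profiles are refused", {
  good <- generate_core(3)
  expect_error(sediment_profile(transform(good, depth_top_mm = depth_bottom_mm),
                                sampling_year = 2008), "depth_top_mm")
  overlap <- good; overlap$depth_top_mm[2] <- 5
  expect_error(sediment_profile(overlap, sampling_year = 2008), "overlap")
  both <- good; both$ip25 <- 1; both$hbi2 <- 1; both$hbi3 <- 1
  expect_error(sediment_profile(both, sampling_year = 2008), "not both")
  expect_error(sediment_profile(good, sedimentation_rate_mm_per_y = 0,
                                sampling_year = 2008), "positive")
})

test_that("the constant-rate age model is linear in depth and rate", {
  prof <- sediment_profile(generate_core(8), sampling_year = 2008)
  expect_equal(age_model(prof, depth_mm = 0), 2008)
  expect_equal(age_model(prof, depth_mm = 70), 1938)
  fast <- sediment_profile(generate_core(8), sedimentation_rate_mm_per_y = 2,
                           sampling_year = 2008)
  expect_equal(age_model(fast, depth_mm = 70), 2008 - 35)
  ages <- age_model(prof)
  expect_true(all(ages$age_bottom < ages$age_top))  # strictly older with depth
  # doubling the rate halves the age span
  span <- function(p) {a <- age_model(p); a$age_top[1] - min(a$age_bottom)}
  expect_equal(span(prof) / span(fast), 2)
})

test_that("the accessible inventory reports the min/max over the horizon", {
  prof <- sediment_profile(core_fixture(c(9, 14)), sampling_year = 2008)
  inv <- accessible_inventory(prof, horizon_mm = 70)
  expect_equal(inv$min_ipoc_mg_per_g, 9)
  expect_equal(inv$max_ipoc_mg_per_g, 14)
  expect_equal(inv$n_layers, 7)
  expect_equal(inv$oldest_accessible_age, 1938)
  expect_error(accessible_inventory(prof, horizon_mm = 0), "positive")
  one <- sediment_profile(generate_core(1, hprint_pct = 30), sampling_year = 2008)
  inv1 <- accessible_inventory(one)
  expect_equal(inv1$min_ipoc_mg_per_g, inv1$max_ipoc_mg_per_g)
})

test_that("a partially overlapping layer counts whole towards the range", {
  core <- core_fixture(c(9, 14), n = 8)  # layer 8 spans 70-80 mm
  prof <- sediment_profile(core, sampling_year = 2008)
  inv <- accessible_inventory(prof, horizon_mm = 75)
  expect_equal(inv$n_layers, 8)
  expect_equal(inv$max_ipoc_mg_per_g, 14)
})

test_that("the inventory range is invariant to splitting a homogeneous layer", {
  whole <- sediment_profile(generate_core(1, layer_thickness_mm = 70,
                                          hprint_pct = 40),
                            sampling_year = 2008)
  split <- sediment_profile(generate_core(7, layer_thickness_mm = 10,
                                          hprint_pct = 40),
                            sampling_year = 2008)
  iw <- accessible_inventory(whole); is_ <- accessible_inventory(split)
  expect_equal(iw$min_ipoc_mg_per_g, is_$min_ipoc_mg_per_g)
  expect_equal(iw$max_ipoc_mg_per_g, is_$max_ipoc_mg_per_g)
})

test_that("a core table round-trips through delimited text", {
  core <- core_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(core, path, row.names = FALSE)
  prof <- read_core(path, sampling_year = 2008)
  out <- compute_sediment(prof, horizon_mm = 70)
  expect_equal(out$inventory$min_ipoc_mg_per_g, 9, tolerance = 1e-6)
  expect_equal(out$inventory$max_ipoc_mg_per_g, 14, tolerance = 1e-6)
  expect_equal(out$layers$age_top[1], 2008)
})
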