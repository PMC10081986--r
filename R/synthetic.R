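#' Configuration for the synthetic consumer-survey generator
#'
#' Defines the statistical structure the analysis assumes in real Arctic
#' consumer data: habitat-structured mean iPOC, a latitude gradient,
#' seasonality concentrated in pelagic-feeding habitats, logit-normal
#' individual variation, lognormal total HBI abundance, and two
#' detection-driven corruptions (complete HBI dropout; loss of the
#' sea-ice HBIs only).
#'
#' Two seasonal modes are available. `"pulse"` (default) emulates the
#' field pattern: iPOC dips in months following phytoplankton blooms
#' (May, September) and in mid-winter (December), scaled per habitat by
#' `seasonal_habitat_weight` — strongest in pelagic consumers, absent in
#' benthic ones, reflecting rapid HBI turnover (days to weeks) in
#' consumers versus year-round benthic access to sedimentary stores.
#' `"linear"` draws the mean from an explicit linear model in month,
#' latitude, habitat score and month x habitat — the mode used for
#' parameter-recovery studies, where estimates must be comparable to
#' generating coefficients.
#'
#' @param n_samples number of consumers to simulate.
#' @param seed default RNG seed used by [generate_samples()] when none is
#'   passed there.
#' @param habitat_base_ipoc named mean iPOC (%) per habitat at the
#'   reference latitude (pulse mode).
#' @param habitat_probs named sampling probabilities per habitat.
#' @param seasonal_mode `"pulse"` or `"linear"`.
#' @param pelagic_seasonal_amplitude depth of the seasonal dip (%) for a
#'   habitat with weight 1 (pulse mode).
#' @param dip_months months carrying the dip (default May, September,
#'   December).
#' @param seasonal_habitat_weight named per-habitat multiplier of the
#'   dip amplitude.
#' @param linear_coefficients named list/vector for linear mode:
#'   `intercept`, `habitat`, `month`, `month_habitat` (latitude uses
#'   `latitude_effect`); habitat enters via `habitat_scores`.
#' @param habitat_scores ordered numeric habitat coding used in linear
#'   mode and by the default model encoding.
#' @param latitude_effect iPOC % per degree latitude (applied to
#'   latitude minus `latitude_reference`).
#' @param latitude_reference,latitude_range reference point and uniform
#'   sampling range for latitude (degrees N).
#' @param noise_sd individual-level noise SD on the logit of iPOC/100
#'   (keeps simulated values inside (0, 100) without truncation).
#' @param intensity_meanlog,intensity_sdlog lognormal parameters of the
#'   total HBI intensity (arbitrary area units).
#' @param ip25_to_hbi2_ratio_mean,ip25_to_hbi2_ratio_cv mean and CV of
#'   the IP25:HBI II split of the sea-ice intensity (gamma-distributed;
#'   CV 0 = constant).
#' @param dropout_rate probability a sample has all three HBIs below
#'   detection (all-zero; excluded downstream).
#' @param pelagic_only_rate probability the sea-ice HBIs alone are absent
#'   (sample keeps HBI III only).
#' @param target_exceedance optional: shift the simulated iPOC
#'   distribution (on the logit scale) so that this fraction of true
#'   values exceeds 50%.
#' @param year_range inclusive sampling years.
#' @param calibration [hprint_calibration()] inverted to produce
#'   intensities from true iPOC.
#' @return validated list of class `"synth_config"`.
#' @export
synth_config <- function(
    n_samples = 2000,
    seed = 1L,
    habitat_base_ipoc = c(benthic = 70, mixed = 55, pelagic = 40, sympagic = 65),
    habitat_probs = c(benthic = 0.40, mixed = 0.15, pelagic = 0.30, sympagic = 0.15),
    seasonal_mode = c("pulse", "linear"),
    pelagic_seasonal_amplitude = 25,
    dip_months = c(5L, 9L, 12L),
    seasonal_habitat_weight = c(benthic = 0, mixed = 0.5, pelagic = 1, sympagic = 0.25),
    linear_coefficients = c(intercept = 55, habitat = 6, month = 0.3,
                            month_habitat = -1.2),
    habitat_scores = c(pelagic = 1, sympagic = 2, mixed = 3, benthic = 4),
    latitude_effect = 0.5,
    latitude_reference = 68.5,
    latitude_range = c(55, 82),
    noise_sd = 0.5,
    intensity_meanlog = log(50),
    intensity_sdlog = 1,
    ip25_to_hbi2_ratio_mean = 1.5,
    ip25_to_hbi2_ratio_cv = 0.3,
    dropout_rate = 0.03,
    pelagic_only_rate = 0.04,
    target_exceedance = NULL,
    year_range = c(1982L, 2019L),
    calibration = hprint_calibration()) {
  seasonal_mode <- match.arg(seasonal_mode)
  habitats <- ipoc_vocabulary()$habitat
  stopifnot(n_samples >= 1, all(habitats %in% names(habitat_base_ipoc)),
            all(habitats %in% names(habitat_probs)),
            all(habitats %in% names(seasonal_habitat_weight)),
            all(habitats %in% names(habitat_scores)),
            noise_sd >= 0, inherits(calibration, "hprint_calibration"))
  probs <- habitat_probs[habitats]
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("habitat_probs must be non-negative and sum to 1")
  for (r in c(dropout_rate, pelagic_only_rate))
    if (r < 0 || r > 1) stop("corruption rates must lie in [0, 1]")
  if (!is.null(target_exceedance) &&
      (target_exceedance <= 0 || target_exceedance >= 1))
    stop("target_exceedance must lie in (0, 1)")

  fields <- c("n_samples", "seed", "habitat_base_ipoc", "habitat_probs",
              "seasonal_mode", "pelagic_seasonal_amplitude", "dip_months",
              "seasonal_habitat_weight", "linear_coefficients",
              "habitat_scores", "latitude_effect", "latitude_reference",
              "latitude_range", "noise_sd", "intensity_meanlog",
              "intensity_sdlog", "ip25_to_hbi2_ratio_mean",
              "ip25_to_hbi2_ratio_cv", "dropout_rate", "pelagic_only_rate",
              "target_exceedance", "year_range", "calibration")
  cfg <- structure(mget(fields), class = "synth_config")
  mu <- .mu_grid(cfg)
  if (any(mu <= 0) || any(mu >= 100))
    stop("infeasible config: mean iPOC leaves (0, 100) (range ",
         sprintf("%.2f..%.2f", min(mu), max(mu)), ")")
  cfg
}

# Mean iPOC over the habitat x month x latitude-extreme grid, used both
# for feasibility checks and for the generator itself.
.synth_mu <- function(cfg, habitat, month, latitude) {
  lat_term <- cfg$latitude_effect * (latitude - cfg$latitude_reference)
  if (cfg$seasonal_mode == "pulse") {
    dip <- as.numeric(month %in% cfg$dip_months)
    cfg$habitat_base_ipoc[habitat] + lat_term -
      cfg$pelagic_seasonal_amplitude * cfg$seasonal_habitat_weight[habitat] * dip
  } else {
    b <- cfg$linear_coefficients
    s <- cfg$habitat_scores[habitat]
    b[["intercept"]] + b[["habitat"]] * s + lat_term +
      b[["month"]] * month + b[["month_habitat"]] * month * s
  }
}

.mu_grid <- function(cfg) {
  g <- expand.grid(habitat = ipoc_vocabulary()$habitat, month = 1:12,
                   latitude = cfg$latitude_range, stringsAsFactors = FALSE)
  .synth_mu(cfg, g$habitat, g$month, g$latitude)
}

# Location parameter of a logit-normal with given mean.
#
# Noise is added on the logit scale to keep values in (0, 1), but the
# configured values are *means*, so the location must be adjusted for the
# curvature of the inverse logit: solve E[plogis(z0 + sd*eps)] = p for z0.
# Solved by bisection on a fine grid of p and interpolated per sample;
# quadrature over eps uses midpoint quantiles of the standard normal.
.logitnorm_location <- function(p, sd) {
  stopifnot(all(p > 0 & p < 1), sd >= 0)
  if (sd == 0) return(stats::qlogis(p))
  nodes <- stats::qnorm(seq(0.5 / 256, 1 - 0.5 / 256, length.out = 256))
  mean_at <- function(z0) rowMeans(stats::plogis(outer(z0, sd * nodes, `+`)))
  grid_p <- seq(min(p), max(p), length.out = 400)
  lo <- rep(-40, length(grid_p)); hi <- rep(40, length(grid_p))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    too_high <- mean_at(mid) > grid_p
    hi[too_high] <- mid[too_high]
    lo[!too_high] <- mid[!too_high]
  }
  z_grid <- (lo + hi) / 2
  if (length(grid_p) < 2 || max(p) - min(p) < 1e-12) return(rep(z_grid[1], length(p)))
  stats::approx(grid_p, z_grid, xout = p, rule = 2)$y
}

# Small species pools keep the synthetic survey taxonomically plausible.
.species_pool <- list(
  benthic = data.frame(
    species = c("Astarte borealis", "Ophiura sarsii",
                "Ctenodiscus crispatus", "Buccinum glaciale"),
    taxon_group = "benthic_invertebrate",
    feeding_strategy = c("suspension", "predator_scavenger",
                         "subsurface_deposit", "predator_scavenger"),
    stringsAsFactors = FALSE),
  pelagic = data.frame(
    species = c("Calanus glacialis", "Themisto libellula", "Boreogadus saida"),
    taxon_group = c("zooplankton", "zooplankton", "fish"),
    feeding_strategy = NA_character_, stringsAsFactors = FALSE),
  sympagic = data.frame(
    species = c("Apherusa glacialis", "Onisimus glacialis"),
    taxon_group = "ice_associated_invertebrate",
    feeding_strategy = NA_character_, stringsAsFactors = FALSE),
  mixed = data.frame(
    species = c("Somateria mollissima", "Odobenus rosmarus",
                "Myoxocephalus scorpius"),
    taxon_group = c("seabird", "marine_mammal", "fish"),
    feeding_strategy = NA_character_, stringsAsFactors = FALSE)
)

#' Generate a synthetic consumer survey with ground truth
#'
#' Draws each consumer's habitat, species, location and date; computes
#' its expected iPOC from the configured structure; adds logit-normal
#' individual noise; inverts the calibration line (unclamped, restricted
#' to H-Print in \[0, 100\]) to the implied H-Print; partitions a
#' lognormal total intensity into HBI III = (H-Print/100) x total with
#' the remainder split between IP25 and HBI II by the configured ratio;
#' and finally applies the detection corruptions (complete dropout;
#' sea-ice-HBI-only loss). Output is reproducible: the same seed yields
#' identical tables.
#'
#' The `truth` table carries per-sample true iPOC/H-Print and the
#' corruption flags; its attributes record the generating coefficients
#' (linear mode), and the realized 50%-exceedance of true iPOC. Truth is
#' diagnostic output only — the pipeline under test never consumes it.
#'
#' @param config a [synth_config()].
#' @param seed integer RNG seed; defaults to `config$seed`.
#' @return list with data.frames `samples` (valid biomarker-sample
#'   schema) and `truth`.
#' @export
generate_samples <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_samples
  habitats <- ipoc_vocabulary()$habitat

  habitat <- sample(habitats, n, replace = TRUE,
                    prob = config$habitat_probs[habitats])
  sp_idx <- vapply(habitat, function(h) sample.int(nrow(.species_pool[[h]]), 1L),
                   integer(1))
  pool <- do.call(rbind, lapply(seq_len(n), function(i)
    .species_pool[[habitat[i]]][sp_idx[i], ]))
  latitude <- stats::runif(n, config$latitude_range[1], config$latitude_range[2])
  longitude <- stats::runif(n, -180, 180)
  month <- sample.int(12L, n, replace = TRUE)
  year <- sample(seq(config$year_range[1], config$year_range[2]), n, replace = TRUE)

  mu <- .synth_mu(config, habitat, month, latitude)
  z <- .logitnorm_location(mu / 100, config$noise_sd) +
    stats::rnorm(n, sd = config$noise_sd)
  if (!is.null(config$target_exceedance))
    z <- z - stats::quantile(z, 1 - config$target_exceedance, names = FALSE)
  true_ipoc <- 100 * stats::plogis(z)

  cal <- config$calibration
  h <- (cal$intercept - true_ipoc) / (-cal$slope)
  if (any(h < 0 | h > 100))
    stop("internal error: implied H-Print left [0, 100]")
  total <- stats::rlnorm(n, config$intensity_meanlog, config$intensity_sdlog)
  hbi3 <- h / 100 * total
  rest <- total - hbi3
  cv <- config$ip25_to_hbi2_ratio_cv
  ratio <- if (cv > 0)
    stats::rgamma(n, shape = 1 / cv^2,
                  scale = config$ip25_to_hbi2_ratio_mean * cv^2)
  else rep(config$ip25_to_hbi2_ratio_mean, n)
  ip25 <- rest * ratio / (1 + ratio)
  hbi2 <- rest / (1 + ratio)

  u <- stats::runif(n)
  dropout <- u < config$dropout_rate
  pelagic_only <- !dropout &
    u < config$dropout_rate + config$pelagic_only_rate
  ip25[dropout | pelagic_only] <- 0
  hbi2[dropout | pelagic_only] <- 0
  hbi3[dropout] <- 0

  id <- sprintf("SYN%05d", seq_len(n))
  samples <- data.frame(
    sample_id = id, species = pool$species, taxon_group = pool$taxon_group,
    habitat = habitat, feeding_strategy = pool$feeding_strategy,
    latitude = latitude, longitude = longitude, year = as.integer(year),
    month = as.integer(month), tissue = NA_character_,
    ip25 = ip25, hbi2 = hbi2, hbi3 = hbi3,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = id, true_ipoc = true_ipoc, true_hprint = h,
    expected_ipoc = mu, dropout = dropout, pelagic_only = pelagic_only,
    stringsAsFactors = FALSE
  )
  if (config$seasonal_mode == "linear") {
    b <- config$linear_coefficients
    attr(truth, "coefficients") <- c(
      `(Intercept)` = unname(b[["intercept"]]) -
        config$latitude_effect * config$latitude_reference,
      habitat = unname(b[["habitat"]]),
      latitude = config$latitude_effect,
      month = unname(b[["month"]]),
      `month:habitat` = unname(b[["month_habitat"]])
    )
  }
  attr(truth, "exceedance_50") <- mean(true_ipoc > 50)
  attr(truth, "config") <- config
  list(samples = samples, truth = truth)
}

#' Generate a synthetic sediment core
#'
#' Builds an ordered stack of equal-thickness layers with configurable
#' TOC and H-Print depth profiles (constants, vectors, or functions of
#' layer mid-depth), optionally perturbed by Gaussian noise (truncated to
#' the valid ranges).
#'
#' @param n_layers number of layers (>= 1).
#' @param layer_thickness_mm thickness of every layer, mm.
#' @param toc_mg_per_g TOC profile: scalar, length-`n_layers` vector, or
#'   function of mid-depth (mm).
#' @param hprint_pct H-Print profile, same conventions.
#' @param toc_sd,hprint_sd optional Gaussian noise SDs.
#' @param seed RNG seed (only consulted when noise is requested).
#' @return data.frame of layers suitable for [sediment_profile()].
#' @export
generate_core <- function(n_layers, layer_thickness_mm = 10,
                          toc_mg_per_g = 20, hprint_pct = 30,
                          toc_sd = 0, hprint_sd = 0, seed = 1L) {
  stopifnot(n_layers >= 1, layer_thickness_mm > 0)
  top <- (seq_len(n_layers) - 1) * layer_thickness_mm
  mid <- top + layer_thickness_mm / 2
  eval_profile <- function(p) {
    v <- if (is.function(p)) p(mid) else rep_len(p, n_layers)
    as.numeric(v)
  }
  toc <- eval_profile(toc_mg_per_g)
  h <- eval_profile(hprint_pct)
  if (toc_sd > 0 || hprint_sd > 0) {
    set.seed(seed)
    toc <- pmax(0, toc + stats::rnorm(n_layers, sd = toc_sd))
    h <- pmin(100, pmax(0, h + stats::rnorm(n_layers, sd = hprint_sd)))
  }
  if (any(h < 0 | h > 100)) stop("hprint profile must lie in [0, 100]")
  if (any(toc < 0)) stop("toc profile must be non-negative")
  data.frame(depth_top_mm = top, depth_bottom_mm = top + layer_thickness_mm,
             toc_mg_per_g = toc, hprint_pct = h)
}
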