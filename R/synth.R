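# Forward simulators for every input the pipeline consumes, with full
# ground truth, so classification, mixing, the seed-impression model and
# the arrival model can all be scored by parameter recovery. All
# generators are deterministic given the seed in their config.

#' Default isotopic and molecular source endpoints
#'
#' One row per food-source class: mean compound-specific delta13C
#' endpoints and spreads (per mil), typical palmitic/stearic acid
#' concentrations (relative units; animal fats are lipid-rich, plant
#' tissues lean), the APAA-C18 E/H log-mean for the class (cereals high,
#' everything else low), the phytanic SRR% center, and the class's true
#' aquatic/cereal character. Values are generator parameters chosen to
#' mimic the qualitative separation of published reference products; the
#' rice endpoint sits at the mean of rice-dominated archaeological food
#' crusts (-33.3, -32.1 per mil).
#'
#' @return data.frame, one row per source class.
#' @export
source_endpoints <- function() {
  data.frame(
    class_label = c("Marine", "Freshwater", "Ruminant", "WildBoar",
                    "C3Nuts", "Rice", "MilletC4"),
    d13c_16 = c(-24.5, -30.5, -28.5, -25.5, -31.5, -33.3, -19.5),
    d13c_18 = c(-22.5, -28.5, -31.5, -27.0, -31.0, -32.1, -21.0),
    sd_16 = c(1.2, 1.5, 1.2, 1.2, 1.5, 1.0, 1.0),
    sd_18 = c(1.2, 1.5, 1.2, 1.2, 1.5, 1.0, 1.0),
    conc_16 = c(65, 55, 60, 60, 15, 8, 6),
    conc_18 = c(25, 30, 40, 35, 8, 4, 3),
    eh_meanlog = log(c(1.5, 1.8, 1.2, 1.3, 2.0, 10, 10)),
    eh_sdlog = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.35, 0.35),
    srr_mean = c(85, 85, 45, 45, 40, 40, 40),
    srr_sd = c(6, 6, 12, 12, 12, 12, 12),
    is_aquatic = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_cereal = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-study configuration
#'
#' Bundles every tunable of the generators with defaults that emulate a
#' six-site residue survey across two regions (coastal plain and inland
#' highlands) spanning the forager-to-farmer transition: 254 sampled
#' sherds, mixed-source vessel contents, partial APAA preservation,
#' imperfect miliacin recovery, per-sherd seed-impression rates spanning
#' 0.001-0.5 with site-level heterogeneity, and regional arrival dates
#' around 2700 cal BP measured through a toy calibration curve.
#'
#' @param seed Integer master seed (recorded in every output).
#' @param n_samples Number of sherds in the residue table.
#' @param miliacin_sensitivity Probability that a vessel that held millet
#'   still yields detectable miliacin (degradation makes this < 1).
#' @param apaa_preservation Probability a sherd preserves APAA-C18.
#' @param d13c_coverage Probability a sherd yields measurable delta13C.
#' @param d13c_noise Analytical + mixing noise on measured delta13C
#'   (per mil, 1-sigma).
#' @param endpoint_sd_scale Multiplier on the endpoint spreads of
#'   [source_endpoints()]; 0 makes every ingredient sit exactly at its
#'   class endpoint.
#' @param class_weights Named sampling weights over source classes.
#' @param n_sites_per_cell Sites per region x phase cell in the
#'   seed-count block.
#' @param lambda_range True per-sherd impression rates are spread
#'   log-evenly over this range across cells.
#' @param site_effect_sd SD of the lognormal site random effect.
#' @param dispersion Negative-binomial size parameter per taxon.
#' @param sherds_meanlog,sherds_sdlog Lognormal sherd-count distribution
#'   per site.
#' @param arrival True arrival date per region, cal BP.
#' @param phase_length Length of the dated phase, calendar years.
#' @param n_dates Rice-associated dates per region.
#' @param date_sigma Radiocarbon measurement error, 14C years.
#' @param curve_step,curve_sd,curve_wiggle_amp,curve_wiggle_period Toy
#'   calibration curve: grid step, 1-sigma, and sinusoidal wiggle.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_samples = 254,
                         miliacin_sensitivity = 0.8,
                         apaa_preservation = 0.2,
                         d13c_coverage = 0.82,
                         d13c_noise = 0.3,
                         endpoint_sd_scale = 1,
                         class_weights = c(Marine = 0.15, Freshwater = 0.2,
                                           Ruminant = 0.2, WildBoar = 0.15,
                                           C3Nuts = 0.1, Rice = 0.08,
                                           MilletC4 = 0.12),
                         n_sites_per_cell = 15,
                         lambda_range = c(0.001, 0.5),
                         site_effect_sd = 0.5,
                         dispersion = 1.5,
                         sherds_meanlog = log(150),
                         sherds_sdlog = 0.5,
                         arrival = c(Tokai = 2700, CentralHighlands = 2750),
                         phase_length = 400,
                         n_dates = 20,
                         date_sigma = 25,
                         curve_step = 5,
                         curve_sd = 10,
                         curve_wiggle_amp = 0,
                         curve_wiggle_period = 500) {
  stopifnot(seed == round(seed), n_samples >= 1,
            miliacin_sensitivity >= 0, miliacin_sensitivity <= 1,
            apaa_preservation >= 0, apaa_preservation <= 1,
            all(class_weights >= 0), sum(class_weights) > 0,
            endpoint_sd_scale >= 0,
            n_sites_per_cell >= 1, all(lambda_range >= 0),
            site_effect_sd >= 0, dispersion > 0, phase_length > 0,
            n_dates >= 2, date_sigma > 0, curve_step > 0, curve_sd > 0)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

synth_sites <- function() {
  # emulates the sampled-site layout: three coastal-plain and three
  # highland sites spanning the transition
  data.frame(
    site = c("UshimakiS", "MamizukaS", "AsahiS_early", "AsahiS_mid",
             "NakayaS", "NakamichiS", "TenshojiS"),
    region = c("Tokai", "Tokai", "Tokai", "Tokai",
               "CentralHighlands", "CentralHighlands", "CentralHighlands"),
    phase = c("FinalJomon", "FinalJomon", "EarlyYayoi", "MiddleYayoi",
              "LateJomon", "FinalJomon", "EarlyYayoi"),
    weight = c(35, 35, 54, 54, 30, 15, 15),
    stringsAsFactors = FALSE
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic residue sample table with ground truth
#'
#' Per sherd: draws a 1-3 component source mixture, computes the measured
#' delta13C pair by concentration-weighted mixing plus analytical noise,
#' draws APAA-C18 isomer areas whose E/H ratio follows the dominant
#' source's distribution (cereals parameterised to exceed 6 in
#' expectation), draws SRR% (aquatic sources centred above 75%), sets
#' C20/C22 APAA and isoprenoid markers for aquatic-dominated vessels, and
#' flags miliacin for millet-containing mixtures with the configured
#' sensitivity. The truth table records every latent assignment.
#'
#' @param config A [synth_config()].
#' @return List with `samples` (a table valid under
#'   [validate_sample_table()]) and `truth` (per-sample latent truth:
#'   dominant class, component list, true flags, noiseless delta13C).
#' @export
gen_residue_table <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  src <- source_endpoints()
  sites <- synth_sites()
  n <- config$n_samples
  w <- config$class_weights[src$class_label]
  w[is.na(w)] <- 0

  site_idx <- sample(nrow(sites), n, replace = TRUE,
                     prob = sites$weight / sum(sites$weight))
  rows <- vector("list", n)
  truth <- vector("list", n)
  src$sd_16 <- src$sd_16 * config$endpoint_sd_scale
  src$sd_18 <- src$sd_18 * config$endpoint_sd_scale
  for (i in seq_len(n)) {
    n_comp <- min(sample(1:3, 1, prob = c(0.3, 0.45, 0.25)), sum(w > 0))
    comp <- sample(src$class_label, n_comp, replace = FALSE, prob = w)
    frac <- as.numeric(stats::rgamma(n_comp, 1)); frac <- frac / sum(frac)
    ci <- match(comp, src$class_label)
    spec <- data.frame(class_label = comp, fraction = frac,
                       conc_16 = src$conc_16[ci], conc_18 = src$conc_18[ci],
                       d13c_16 = stats::rnorm(n_comp, src$d13c_16[ci], src$sd_16[ci]),
                       d13c_18 = stats::rnorm(n_comp, src$d13c_18[ci], src$sd_18[ci]))
    mixed <- mix_isotopes(spec)
    dom <- ci[which.max(frac)]

    has_d13c <- stats::runif(1) < config$d13c_coverage
    d16 <- if (has_d13c)
      max(min(mixed[["d13c_16"]] + stats::rnorm(1, 0, config$d13c_noise), -5), -45)
    else NA_real_
    d18 <- if (has_d13c)
      max(min(mixed[["d13c_18"]] + stats::rnorm(1, 0, config$d13c_noise), -5), -45)
    else NA_real_

    has_apaa <- stats::runif(1) < config$apaa_preservation
    eh_true <- stats::rlnorm(1, src$eh_meanlog[dom], src$eh_sdlog[dom])
    apaa <- rep(NA_real_, 9); names(apaa) <- APAA_ISOMERS
    if (has_apaa) {
      h_area <- stats::rlnorm(1, log(100), 0.4)
      apaa[] <- stats::rlnorm(9, log(60), 0.5)
      apaa["H"] <- h_area
      apaa["E"] <- eh_true * h_area
    }
    aquatic_true <- src$is_aquatic[dom]
    a20 <- if (aquatic_true && stats::runif(1) < 0.6)
      stats::rlnorm(1, log(30), 0.5) else if (stats::runif(1) < 0.02)
        stats::rlnorm(1, log(5), 0.5) else 0
    a22 <- if (aquatic_true && stats::runif(1) < 0.4)
      stats::rlnorm(1, log(15), 0.5) else 0
    srr <- if (stats::runif(1) < 0.8)
      rtrunc_norm(1, src$srr_mean[dom], src$srr_sd[dom], 0, 100) else NA_real_
    iso_p <- aquatic_true && stats::runif(1) < 0.7
    millet_true <- "MilletC4" %in% comp
    miliacin <- millet_true && stats::runif(1) < config$miliacin_sensitivity
    resin <- if (stats::runif(1) < 0.1) "dehydroabietic acid" else ""

    sid <- sprintf("SYN_%03d", i)
    rows[[i]] <- data.frame(
      sample_id = sid, site = sites$site[site_idx[i]],
      region = sites$region[site_idx[i]], phase = sites$phase[site_idx[i]],
      vessel_style = sample(c("Ongagawa", "Jokonmon", "unknown"), 1,
                            prob = c(0.3, 0.3, 0.4)),
      vessel_form = sample(c("cooking", "bowl", "jar", "unknown"), 1,
                           prob = c(0.5, 0.2, 0.2, 0.1)),
      lipid_conc = stats::rlnorm(1, log(50), 1),
      fa_C16_0 = stats::rlnorm(1, log(500), 0.6),
      fa_C18_0 = stats::rlnorm(1, log(300), 0.6),
      apaa_c18_A = apaa[["A"]], apaa_c18_B = apaa[["B"]],
      apaa_c18_C = apaa[["C"]], apaa_c18_D = apaa[["D"]],
      apaa_c18_E = apaa[["E"]], apaa_c18_F = apaa[["F"]],
      apaa_c18_G = apaa[["G"]], apaa_c18_H = apaa[["H"]],
      apaa_c18_I = apaa[["I"]],
      apaa_c20_area = a20, apaa_c22_area = a22,
      phytanic_srr_pct = srr,
      pristanic_present = iso_p, tmtd_present = iso_p && stats::runif(1) < 0.5,
      miliacin_present = miliacin, resin_markers = resin,
      d13c_16 = d16, d13c_18 = d18,
      stringsAsFactors = FALSE
    )
    truth[[i]] <- data.frame(
      sample_id = sid, dominant_class = src$class_label[dom],
      components = paste(comp, collapse = ";"),
      fractions = paste(signif(frac, 4), collapse = ";"),
      millet_true = millet_true, aquatic_true = aquatic_true,
      cereal_true = src$is_cereal[dom],
      eh_true = eh_true, apaa_preserved = has_apaa,
      d13c_16_true = mixed[["d13c_16"]], d13c_18_true = mixed[["d13c_18"]],
      stringsAsFactors = FALSE
    )
  }
  samples <- validate_sample_table(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  attr(samples, "seed") <- config$seed
  list(samples = samples, truth = truth)
}

#' Generate synthetic seed-impression counts with ground truth
#'
#' Region x phase cells each hold `n_sites_per_cell` sites; each site has
#' a lognormal sherd count, a shared Normal(0, site_effect_sd) random
#' effect on the log scale, and negative-binomial impression counts per
#' taxon with mean `lambda * n_sherds * exp(u)`. True rates are spread
#' log-evenly over `lambda_range` across cells, alternating taxa.
#'
#' @param config A [synth_config()].
#' @return List with `records` (validated seed-count table) and `truth`
#'   (list: `lambda` table, `site_effect_sd`, `dispersion`, site
#'   effects).
#' @export
gen_seed_counts <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  regions <- c("Tokai", "CentralHighlands")
  phases <- c("LateJomon", "EarlyYayoi", "MiddleYayoi")
  cells <- expand.grid(region = regions, phase = phases,
                       taxon = TAXON_LEVELS, stringsAsFactors = FALSE)
  cells <- cells[order(cells$region, cells$phase, cells$taxon), ]
  rownames(cells) <- NULL
  cells$lambda <- if (all(config$lambda_range > 0)) {
    lr <- log(config$lambda_range)
    exp(seq(lr[1], lr[2], length.out = nrow(cells)))
  } else {
    seq(config$lambda_range[1], config$lambda_range[2],
        length.out = nrow(cells))
  }

  site_cells <- unique(cells[, c("region", "phase")])
  recs <- list(); effects <- list()
  for (j in seq_len(nrow(site_cells))) {
    reg <- site_cells$region[j]; ph <- site_cells$phase[j]
    for (s in seq_len(config$n_sites_per_cell)) {
      site <- sprintf("%s_%s_site%02d", reg, ph, s)
      n_sherds <- max(20L, as.integer(round(
        stats::rlnorm(1, config$sherds_meanlog, config$sherds_sdlog))))
      u <- stats::rnorm(1, 0, config$site_effect_sd)
      effects[[site]] <- u
      for (tx in TAXON_LEVELS) {
        lam <- cells$lambda[cells$region == reg & cells$phase == ph &
                              cells$taxon == tx]
        mu <- lam * n_sherds * exp(u)
        y <- stats::rnbinom(1, size = config$dispersion, mu = mu)
        recs[[length(recs) + 1]] <- data.frame(
          site = site, region = reg, phase = ph, taxon = tx,
          n_impressions = y, n_sherds = n_sherds, stringsAsFactors = FALSE)
      }
    }
  }
  records <- validate_seed_count_table(do.call(rbind, recs))
  attr(records, "seed") <- config$seed
  list(records = records,
       truth = list(lambda = cells, site_effect_sd = config$site_effect_sd,
                    dispersion = config$dispersion,
                    site_effects = unlist(effects)))
}

#' Toy calibration curve
#'
#' A synthetic IntCal-style curve for tests and simulations: radiocarbon
#' age equal to calendar age plus an optional sinusoidal wiggle, with
#' constant 1-sigma. With zero wiggle the curve is exactly linear, which
#' gives the calibration step a closed-form cross-check.
#'
#' @param cal_min,cal_max Grid range, cal BP.
#' @param step Grid step, years.
#' @param sd Curve 1-sigma, 14C years.
#' @param wiggle_amp,wiggle_period Sinusoidal deviation (years).
#' @return A [calibration_curve()].
#' @export
toy_calibration_curve <- function(cal_min = 0, cal_max = 6000, step = 5,
                                  sd = 10, wiggle_amp = 0,
                                  wiggle_period = 500) {
  grid <- seq(cal_min, cal_max, by = step)
  mu <- grid + wiggle_amp * sin(2 * pi * grid / wiggle_period)
  calibration_curve(grid, mu, rep(sd, length(grid)))
}

#' Generate synthetic radiocarbon dates with ground truth
#'
#' For each region, event times are drawn uniformly within the dated
#' phase (from the true arrival back no further than `phase_length`
#' years), mapped through the toy curve, and measured with Normal error.
#'
#' @param config A [synth_config()].
#' @return List with `dates` (validated radiocarbon table), `curve` (the
#'   toy [calibration_curve()]) and `truth` (arrival per region, event
#'   times).
#' @export
gen_radiocarbon_dates <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  curve <- toy_calibration_curve(step = config$curve_step,
                                 sd = config$curve_sd,
                                 wiggle_amp = config$curve_wiggle_amp,
                                 wiggle_period = config$curve_wiggle_period)
  rows <- list(); events <- list()
  for (reg in names(config$arrival)) {
    a <- config$arrival[[reg]]
    theta <- stats::runif(config$n_dates, a - config$phase_length, a)
    cv <- curve_at(curve, theta)
    cra <- stats::rnorm(config$n_dates, cv$mu, config$date_sigma)
    rows[[reg]] <- data.frame(
      lab_id = sprintf("%s_%03d", substr(reg, 1, 3), seq_along(theta)),
      cra_bp = round(cra), sigma = config$date_sigma, region = reg,
      rice_associated = TRUE, stringsAsFactors = FALSE)
    events[[reg]] <- theta
  }
  dates <- read_c14_validate(do.call(rbind, rows))
  attr(dates, "seed") <- config$seed
  list(dates = dates, curve = curve,
       truth = list(arrival = config$arrival,
                    phase_length = config$phase_length,
                    event_times = events))
}

# validate a radiocarbon data.frame built in memory (same checks as the
# file reader)
read_c14_validate <- function(df) {
  df$cra_bp <- coerce_numeric_col(df$cra_bp, "cra_bp")
  df$sigma <- coerce_numeric_col(df$sigma, "sigma")
  bad <- which(df$cra_bp <= 0)
  if (length(bad) > 0) stop_cell(bad[1], "cra_bp", "cra_bp must be > 0")
  bad <- which(df$sigma <= 0)
  if (length(bad) > 0) stop_cell(bad[1], "sigma", "sigma must be > 0")
  df$region <- check_enum_col(df$region, "region", REGION_LEVELS)
  rownames(df) <- NULL
  df
}
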