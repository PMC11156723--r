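# Radiocarbon calibration and Bayesian estimation of a regional crop
# arrival date. Calibration follows the standard normal-likelihood model
# on a calendar grid; arrival estimation uses a uniform-phase boundary
# model: every rice-associated event time is uniform between the regional
# arrival date a and the end of the modelled phase b (a > b in years BP),
# and the posterior over (a, b) is sampled by random-walk Metropolis.

curve_at <- function(curve, theta) {
  list(mu = stats::approx(curve$cal_bp, curve$mu, xout = theta)$y,
       sd = stats::approx(curve$cal_bp, curve$sd, xout = theta)$y)
}

#' Calibrate a single radiocarbon determination
#'
#' Evaluates, on a regular calendar grid, the posterior density of the
#' calendar age theta given the measured conventional radiocarbon age:
#' `density(theta) propto Normal(cra_bp; mu(theta), sigma^2 + sd(theta)^2)`
#' under a uniform calendar prior, normalized to integrate to 1.
#'
#' @param cra_bp Conventional radiocarbon age, 14C years BP.
#' @param sigma Measurement error (1-sigma), 14C years, > 0.
#' @param curve A [calibration_curve()] object.
#' @param resolution Grid step in calendar years, default 1.
#' @return Object of class `cal_density`: `cal_bp` (grid), `density`
#'   (per-year density summing to 1/resolution).
#' @export
calibrate_date <- function(cra_bp, sigma, curve, resolution = 1) {
  stopifnot(inherits(curve, "cal_curve"), sigma > 0, resolution > 0)
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  cv <- curve_at(curve, grid)
  dens <- stats::dnorm(cra_bp, mean = cv$mu, sd = sqrt(sigma^2 + cv$sd^2))
  total <- sum(dens) * resolution
  if (!is.finite(total) || total <= 1e-12)
    stop("date lies outside the calibration curve range", call. = FALSE)
  structure(list(cal_bp = grid, density = dens / total,
                 cra_bp = cra_bp, sigma = sigma),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  med <- cal_density_quantile(x, 0.5)
  cat(sprintf("Calibrated %d +/- %d BP: median %.0f cal BP\n",
              round(x$cra_bp), round(x$sigma), med))
  invisible(x)
}

#' Quantiles of a calibrated density
#'
#' @param cd A [calibrate_date()] result.
#' @param probs Probabilities.
#' @return Calendar ages (cal BP) at the requested quantiles.
#' @export
cal_density_quantile <- function(cd, probs = c(0.025, 0.5, 0.975)) {
  step <- diff(cd$cal_bp[1:2])
  cum <- cumsum(cd$density) * step
  vapply(probs, function(p) cd$cal_bp[which.max(cum >= p)], numeric(1))
}

#' Estimate a regional arrival date from radiocarbon evidence
#'
#' Uniform-phase boundary model: each rice-associated dated event is
#' assumed to have occurred at a calendar time uniformly distributed
#' between the (unknown) regional arrival date `a` and the end of the
#' modelled phase `b`, with `a > b` on the BP scale. Marginalising the
#' event times gives, per date i, the likelihood
#' `L_i(a, b) = (1/(a-b)) * integral_b^a N(cra_i; mu(theta), sigma_i^2 +
#' sd(theta)^2) dtheta`. Priors on `a` (and `b`, unless fixed) are uniform
#' over the curve window. The posterior is sampled by adaptive random-walk
#' Metropolis (adaptation frozen after warm-up, so a fixed seed gives
#' bit-identical draws).
#'
#' @param dates Radiocarbon date table ([read_c14_table()]); only rows
#'   with `rice_associated == TRUE` enter the model. At least 2 required.
#' @param curve A [calibration_curve()] object.
#' @param region Optional region filter applied to `dates`.
#' @param phase_end Fixed end-of-phase bound in cal BP, or `NULL`
#'   (default) to estimate `b` with a uniform hyperprior.
#' @param arrival_range Optional `c(min, max)` cal BP prior window for
#'   `a`; defaults to the curve window.
#' @param n_draws Retained draws, default 4000.
#' @param n_warmup Warm-up iterations (discarded, used for proposal
#'   adaptation), default 1000.
#' @param seed Integer seed.
#' @param resolution Integration grid step, calendar years, default 1.
#' @return Object of class `arrival_posterior`: `draws` (arrival a, cal
#'   BP), `draws_b`, `hpd95_bp`, `hpd95_bce` (older/younger, BCE
#'   convention), `acceptance`, `n_dates`.
#' @export
estimate_arrival <- function(dates, curve, region = NULL, phase_end = NULL,
                             arrival_range = NULL, n_draws = 4000,
                             n_warmup = 1000, seed = 1, resolution = 1) {
  stopifnot(inherits(curve, "cal_curve"))
  df <- as.data.frame(dates)
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  if ("rice_associated" %in% names(df))
    df <- df[df$rice_associated, , drop = FALSE]
  if (nrow(df) < 2)
    stop("need at least 2 rice-associated dates in the region", call. = FALSE)

  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  cv <- curve_at(curve, grid)
  # per-date cumulative integral of the likelihood over calendar time,
  # so that integral_b^a L_i = C_i(a) - C_i(b) by interpolation
  lik <- vapply(seq_len(nrow(df)), function(i)
    stats::dnorm(df$cra_bp[i], cv$mu, sqrt(df$sigma[i]^2 + cv$sd^2)),
    numeric(length(grid)))
  cumint <- apply(lik, 2, function(l) cumsum(l) * resolution)
  ng <- length(grid)
  C <- function(theta) {
    # linear interpolation of every date's cumulative integral at theta;
    # the grid is regular, so index arithmetic replaces a search
    pos <- (theta - grid[1]) / resolution + 1
    pos <- min(max(pos, 1), ng)
    i0 <- floor(pos); i1 <- min(i0 + 1, ng); frac <- pos - i0
    cumint[i0, ] * (1 - frac) + cumint[i1, ] * frac
  }
  win <- if (is.null(arrival_range)) range(grid) else sort(arrival_range)
  b_fixed <- !is.null(phase_end)
  if (b_fixed) stopifnot(phase_end >= min(grid), phase_end <= max(grid))

  log_post <- function(a, b) {
    if (a <= b || a < win[1] || a > win[2]) return(-Inf)
    if (b < min(grid) || b > max(grid)) return(-Inf)
    mass <- C(a) - C(b)
    if (any(mass <= 0)) return(-Inf)
    sum(log(mass)) - nrow(df) * log(a - b)
  }

  set.seed(seed)
  meds <- vapply(seq_len(nrow(df)), function(i)
    grid[which.max(lik[, i])], numeric(1))
  a <- min(max(meds) + 10, win[2])
  b <- if (b_fixed) phase_end else max(min(meds) - 10, min(grid))
  lp <- log_post(a, b)
  if (!is.finite(lp)) { a <- win[2]; b <- if (b_fixed) phase_end else min(grid)
    lp <- log_post(a, b) }
  if (!is.finite(lp))
    stop("prior window excludes all posterior mass", call. = FALSE)

  step <- max(diff(range(meds)) / 4, stats::median(df$sigma), 10)
  total <- n_warmup + n_draws
  draws_a <- numeric(n_draws); draws_b <- numeric(n_draws)
  n_acc <- 0
  for (it in seq_len(total)) {
    a_new <- a + stats::rnorm(1, 0, step)
    b_new <- if (b_fixed) b else b + stats::rnorm(1, 0, step)
    lp_new <- log_post(a_new, b_new)
    if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
      a <- a_new; b <- b_new; lp <- lp_new
      if (it > n_warmup) n_acc <- n_acc + 1
      acc <- 1
    } else acc <- 0
    if (it <= n_warmup)   # Robbins-Monro adaptation toward 30% acceptance
      step <- max(step * exp((acc - 0.3) / sqrt(it)), 1e-3)
    if (it > n_warmup) {
      draws_a[it - n_warmup] <- a
      draws_b[it - n_warmup] <- b
    }
  }

  hpd_bp <- hpd_interval(draws_a, 0.95)
  structure(list(region = if (is.null(region)) NA_character_ else region,
                 draws = draws_a, draws_b = draws_b,
                 hpd95_bp = c(older = unname(hpd_bp["upper"]),
                              younger = unname(hpd_bp["lower"])),
                 hpd95_bce = c(older = bp_to_bce(unname(hpd_bp["upper"]))$year,
                               younger = bp_to_bce(unname(hpd_bp["lower"]))$year),
                 acceptance = n_acc / n_draws, n_dates = nrow(df),
                 phase_end = if (b_fixed) phase_end else NA_real_,
                 seed = seed),
            class = "arrival_posterior")
}

#' @export
print.arrival_posterior <- function(x, ...) {
  older <- bp_to_bce(x$hpd95_bp[["older"]])
  younger <- bp_to_bce(x$hpd95_bp[["younger"]])
  cat(sprintf(
    "Arrival posterior%s: 95%% HPD %.0f-%.0f cal BP (%.0f %s to %.0f %s), %d dates\n",
    if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
    x$hpd95_bp[["older"]], x$hpd95_bp[["younger"]],
    older$year, older$era, younger$year, younger$era, x$n_dates))
  invisible(x)
}

#' Convert calendar years BP to the BCE/CE convention
#'
#' The BP datum is 1950 CE: ages over 1950 BP map to `BP - 1950` BCE,
#' ages at or below 1950 BP map to `1950 - BP` CE.
#'
#' @param cal_bp Calendar years BP (vectorised).
#' @return data.frame with `year` and `era` (`"BCE"` or `"CE"`).
#' @export
bp_to_bce <- function(cal_bp) {
  bce <- cal_bp > 1950
  data.frame(year = ifelse(bce, cal_bp - 1950, 1950 - cal_bp),
             era = ifelse(bce, "BCE", "CE"), stringsAsFactors = FALSE)
}

#' Convert BCE/CE years to calendar years BP
#'
#' Inverse of [bp_to_bce()].
#'
#' @param year Year value (non-negative).
#' @param era `"BCE"` or `"CE"` (vectorised).
#' @return Calendar years BP.
#' @export
bce_to_bp <- function(year, era = "BCE") {
  stopifnot(all(era %in% c("BCE", "CE")))
  ifelse(era == "BCE", year + 1950, 1950 - year)
}
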