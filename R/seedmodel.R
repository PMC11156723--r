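# Hierarchical negative-binomial model of crop seed impressions per
# potsherd. Counts at site s for taxon t are modelled as
#   y_{s,t} ~ NegBin(mean = lambda_{region(s), phase(s), t} * n_sherds_s
#                           * exp(u_s),  size = phi_t)
#   u_s ~ Normal(0, sigma_u)
# with sherd count as an exposure offset and a site-level lognormal random
# intercept absorbing between-site heterogeneity. Posterior sampling is
# delegated to JAGS; the model, priors and summaries live here.

#' Prior specification for the seed-impression model
#'
#' Weakly informative defaults on the plausible per-sherd scale
#' (impressions per sherd between 1e-4 and 1): Normal(-3, 2) on each
#' cell's log rate, half-Normal(0, 1) on the site-effect SD, and
#' half-Normal(0, 1) on the reciprocal square root of the dispersion. The
#' dispersion scale is deliberately tight: a diffuse prior on phi^(-1/2)
#' lets a cell of all-zero counts be absorbed by extreme overdispersion
#' instead of a near-zero rate, leaving the rate prior-dominated.
#'
#' @param log_rate_mean,log_rate_sd Normal prior on log lambda.
#' @param site_sd_scale Scale of the half-Normal prior on sigma_u.
#' @param disp_scale Scale of the half-Normal prior on phi^(-1/2).
#' @return List of prior hyperparameters.
#' @export
seed_model_priors <- function(log_rate_mean = -3, log_rate_sd = 2,
                              site_sd_scale = 1, disp_scale = 1) {
  stopifnot(log_rate_sd > 0, site_sd_scale > 0, disp_scale > 0)
  list(log_rate_mean = log_rate_mean, log_rate_sd = log_rate_sd,
       site_sd_scale = site_sd_scale, disp_scale = disp_scale)
}

seed_model_code <- "
model {
  for (i in 1:n_obs) {
    y[i] ~ dnegbin(p[i], phi[taxon[i]])
    p[i] <- phi[taxon[i]] / (phi[taxon[i]] + mu[i])
    mu[i] <- lambda[cell[i]] * sherds[i] * exp(u[site[i]])
  }
  for (c in 1:n_cells) {
    log_lambda[c] ~ dnorm(log_rate_mean, 1 / pow(log_rate_sd, 2))
    lambda[c] <- exp(log_lambda[c])
  }
  for (s in 1:n_sites) {
    u[s] ~ dnorm(0, tau_u)
  }
  sigma_u ~ dnorm(0, 1 / pow(site_sd_scale, 2)) T(0,)
  tau_u <- 1 / pow(sigma_u + 1e-9, 2)
  for (t in 1:n_taxa) {
    inv_sqrt_phi[t] ~ dnorm(0, 1 / pow(disp_scale, 2)) T(0,)
    phi[t] <- 1 / pow(inv_sqrt_phi[t] + 1e-9, 2)
  }
}
"

#' Fit the hierarchical negative-binomial seed-impression model
#'
#' One per-sherd impression rate lambda is estimated for every observed
#' region x phase x taxon cell, with a shared site-level random intercept
#' and one dispersion parameter per taxon. Sampling is by Gibbs/slice
#' MCMC (JAGS); draws are bit-reproducible under a fixed seed.
#'
#' @param records Validated seed-count table
#'   ([read_seed_count_table()]).
#' @param priors A [seed_model_priors()] list.
#' @param n_chains Number of MCMC chains (default 2).
#' @param n_draws Retained draws per chain (default 1000).
#' @param n_warmup Adaptation + burn-in iterations (default 1000).
#' @param seed Integer seed controlling all chains.
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return Object of class `seed_posterior`: `draws` (matrix, one column
#'   per parameter, `n_chains * n_draws` rows), `cells` (data.frame
#'   mapping lambda columns to region/phase/taxon), `diagnostics`
#'   (per-parameter R-hat and effective sample size), and the call
#'   settings.
#' @export
fit_seed_model <- function(records, priors = seed_model_priors(),
                           n_chains = 2, n_draws = 1000, n_warmup = 1000,
                           seed = 1, quiet = TRUE) {
  records <- validate_seed_count_table(as.data.frame(records))
  if (any(records$n_impressions != round(records$n_impressions)))
    stop("impression counts must be integers", call. = FALSE)
  stopifnot(n_chains >= 1, n_draws >= 1, n_warmup >= 1)

  cells <- unique(records[, c("region", "phase", "taxon")])
  cells <- cells[order(cells$region, cells$phase, cells$taxon), , drop = FALSE]
  rownames(cells) <- NULL
  cell_key <- function(df) paste(df$region, df$phase, df$taxon, sep = "|")
  cell_idx <- match(cell_key(records), cell_key(cells))
  sites <- sort(unique(records$site))
  site_idx <- match(records$site, sites)
  taxa <- sort(unique(records$taxon))
  taxon_idx <- match(records$taxon, taxa)

  data <- list(y = records$n_impressions, sherds = records$n_sherds,
               cell = cell_idx, site = site_idx, taxon = taxon_idx,
               n_obs = nrow(records), n_cells = nrow(cells),
               n_sites = length(sites), n_taxa = length(taxa),
               log_rate_mean = priors$log_rate_mean,
               log_rate_sd = priors$log_rate_sd,
               site_sd_scale = priors$site_sd_scale,
               disp_scale = priors$disp_scale)
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = seed * 1000 + ch))

  run <- function() {
    model <- rjags::jags.model(textConnection(seed_model_code), data = data,
                               inits = inits, n.chains = n_chains,
                               n.adapt = ceiling(n_warmup / 2), quiet = quiet)
    update(model, n.iter = ceiling(n_warmup / 2), progress.bar = "none")
    rjags::coda.samples(model, c("lambda", "sigma_u", "phi", "u"),
                        n.iter = n_draws, progress.bar = "none")
  }
  samples <- if (quiet) suppressMessages(run()) else run()

  draws <- do.call(rbind, lapply(samples, as.matrix))
  # JAGS drops the [1] index on length-one parameter vectors
  rename_par <- function(cn, base, new_names) {
    old <- if (length(new_names) == 1 && base %in% cn) base
           else paste0(base, "[", seq_along(new_names), "]")
    cn[match(old, cn)] <- new_names
    cn
  }
  nice <- paste("lambda", cells$region, cells$phase, cells$taxon, sep = ".")
  cn <- colnames(draws)
  cn <- rename_par(cn, "lambda", nice)
  cn <- rename_par(cn, "phi", paste0("phi.", taxa))
  cn <- rename_par(cn, "u", paste0("u.", sites))
  colnames(draws) <- cn

  diag <- seed_model_diagnostics(samples)
  diag$parameter <- colnames(draws)   # same order, renamed in place
  structure(list(draws = draws, cells = cells, sites = sites, taxa = taxa,
                 diagnostics = diag,
                 settings = list(n_chains = n_chains, n_draws = n_draws,
                                 n_warmup = n_warmup, seed = seed,
                                 priors = priors)),
            class = "seed_posterior")
}

seed_model_diagnostics <- function(samples) {
  pars <- colnames(samples[[1]])
  ess <- tryCatch(coda::effectiveSize(samples), error = function(e)
    stats::setNames(rep(NA_real_, length(pars)), pars))
  rhat <- rep(NA_real_, length(pars))
  if (length(samples) >= 2) {
    gd <- tryCatch(coda::gelman.diag(samples, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, length(pars)))
    rhat <- as.numeric(gd)
  }
  data.frame(parameter_raw = pars, rhat = rhat, ess = as.numeric(ess),
             stringsAsFactors = FALSE)
}

#' @export
print.seed_posterior <- function(x, ...) {
  cat(sprintf(
    "Seed-impression model posterior: %d cells, %d sites, %d draws (%d chains)\n",
    nrow(x$cells), length(x$sites), nrow(x$draws), x$settings$n_chains))
  print(summarize_rates(x, check_convergence = FALSE))
  invisible(x)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `prob` of the empirical
#' distribution of the draws: after sorting, the window of
#' `ceiling(prob * n)` consecutive draws with the smallest spread.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param prob Target mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 100)
    stop("need at least 100 draws for an HPD interval", call. = FALSE)
  stopifnot(prob > 0, prob < 1)
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(prob * n)
  if (k >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k])
}

#' Posterior rate summary table
#'
#' One row per region x phase x taxon cell with the posterior median and
#' 95% HPD interval of the per-sherd impression rate. By default refuses
#' to summarise an unconverged posterior (any rate R-hat above
#' `rhat_max`).
#'
#' @param posterior A [fit_seed_model()] result.
#' @param prob HPD mass, default 0.95.
#' @param rhat_max Convergence gate on the rate parameters, default 1.05.
#' @param check_convergence Set `FALSE` to override the gate.
#' @return data.frame: `region`, `phase`, `taxon`, `median`, `hpd_low`,
#'   `hpd_high` (all rates per sherd).
#' @export
summarize_rates <- function(posterior, prob = 0.95, rhat_max = 1.05,
                            check_convergence = TRUE) {
  stopifnot(inherits(posterior, "seed_posterior"))
  nice <- paste("lambda", posterior$cells$region, posterior$cells$phase,
                posterior$cells$taxon, sep = ".")
  if (check_convergence) {
    d <- posterior$diagnostics
    bad <- d$parameter %in% nice & !is.na(d$rhat) & d$rhat > rhat_max
    if (any(bad))
      stop("rate parameters failed the R-hat gate (> ", rhat_max, "): ",
           paste(d$parameter[bad], collapse = ", "),
           "; rerun with more draws or check_convergence = FALSE",
           call. = FALSE)
  }
  rows <- lapply(seq_along(nice), function(i) {
    dr <- posterior$draws[, nice[i]]
    h <- hpd_interval(dr, prob)
    data.frame(posterior$cells[i, , drop = FALSE],
               median = stats::median(dr),
               hpd_low = h[["lower"]], hpd_high = h[["upper"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
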