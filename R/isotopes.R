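# Compound-specific carbon isotope interpretation: Suess correction of
# modern references, 68% confidence reference ellipses in
# delta13C16:0 x delta13C18:0 space, Mahalanobis source assignment,
# the Delta13C discriminator, and concentration-weighted mixing.

#' Suess-effect correction of a modern delta13C value
#'
#' Fossil-fuel CO2 has depleted atmospheric delta13C since the industrial
#' era, so modern reference tissues must be shifted back onto the
#' pre-industrial scale before comparison with archaeological residues.
#' With an atmospheric record the correction is the additive offset
#' `preindustrial_ref - atm_record(year)`; without one, a constant offset
#' is applied to samples collected after `fallback_after`.
#'
#' @param d13c Measured delta13C, per mil VPDB.
#' @param sampling_year Calendar year of tissue collection.
#' @param atm_record Optional data.frame with columns `year` and `d13c_atm`
#'   (atmospheric CO2 delta13C); linearly interpolated between entries.
#' @param preindustrial_ref Pre-industrial atmospheric delta13C, per mil;
#'   default -6.4.
#' @param fallback_offset Constant correction (per mil) applied when no
#'   record is supplied; default +1.9.
#' @param fallback_after Calendar year after which the constant fallback
#'   applies; earlier samples are returned unchanged. Default 2010.
#' @param preindustrial_until Years at or before this are treated as
#'   pre-industrial and returned unchanged; default 1850.
#' @return Corrected delta13C, per mil.
#' @export
suess_correct <- function(d13c, sampling_year, atm_record = NULL,
                          preindustrial_ref = -6.4, fallback_offset = 1.9,
                          fallback_after = 2010, preindustrial_until = 1850) {
  stopifnot(length(d13c) == length(sampling_year))
  out <- d13c
  post <- !is.na(sampling_year) & sampling_year > preindustrial_until
  if (!any(post)) return(out)
  if (is.null(atm_record)) {
    late <- post & sampling_year > fallback_after
    out[late] <- d13c[late] + fallback_offset
    return(out)
  }
  stopifnot(all(c("year", "d13c_atm") %in% names(atm_record)))
  yrs <- sampling_year[post]
  rng <- range(atm_record$year)
  if (any(yrs < rng[1] | yrs > rng[2]))
    stop("sampling_year outside the atmospheric record (",
         rng[1], "-", rng[2], ")", call. = FALSE)
  atm <- stats::approx(atm_record$year, atm_record$d13c_atm, xout = yrs)$y
  out[post] <- d13c[post] + (preindustrial_ref - atm)
  out
}

#' Fit a bivariate-normal confidence ellipse to reference products
#'
#' The "68% confidence range" of a reference product class in
#' delta13C16:0 x delta13C18:0 space is realised as the Mahalanobis
#' contour of a bivariate normal fitted by sample mean and covariance,
#' scaled by the chi-square(2 df) quantile of the coverage level.
#'
#' @param points Two-column matrix or data.frame of (delta13C16:0,
#'   delta13C18:0) pairs; at least 3 non-collinear points.
#' @param level Coverage probability in (0, 1); default 0.68.
#' @param class_label Optional product-class label carried in the result.
#' @return Object of class `ref_ellipse` with fields `class_label`,
#'   `center`, `covariance`, `level`, `n_ref`.
#' @export
fit_reference_ellipse <- function(points, level = 0.68, class_label = NA_character_) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two columns", call. = FALSE)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3)
    stop("need at least 3 complete reference points", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps * max(diag(S))^2)
    stop("reference points are (near-)collinear: singular covariance",
         call. = FALSE)
  structure(list(class_label = class_label,
                 center = as.numeric(ctr),
                 covariance = S,
                 level = level,
                 n_ref = nrow(pts)),
            class = "ref_ellipse")
}

#' @export
print.ref_ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% reference ellipse%s: center (%.2f, %.2f) permil, n = %d\n",
              100 * x$level,
              if (is.na(x$class_label)) "" else paste0(" [", x$class_label, "]"),
              x$center[1], x$center[2], x$n_ref))
  invisible(x)
}

#' Points on the boundary of a reference ellipse
#'
#' Convenience for plotting: returns `n` points on the Mahalanobis contour
#' at the ellipse's coverage level.
#'
#' @param ellipse A [fit_reference_ellipse()] object.
#' @param n Number of boundary points.
#' @return `n` x 2 matrix.
#' @export
ellipse_boundary <- function(ellipse, n = 181) {
  stopifnot(inherits(ellipse, "ref_ellipse"))
  r <- sqrt(stats::qchisq(ellipse$level, df = 2))
  eig <- eigen(ellipse$covariance, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta)) * r
  t(ellipse$center + eig$vectors %*% (sqrt(eig$values) * circ))
}

#' Assign an isotope pair to reference product classes
#'
#' Computes, for each reference ellipse, the Mahalanobis distance of the
#' sample's (delta13C16:0, delta13C18:0) pair from the class center, and
#' whether the sample falls inside the class's confidence region
#' (squared distance <= chi-square(2) quantile at the ellipse level).
#'
#' @param d13c_16,d13c_18 Sample delta13C values, per mil.
#' @param ellipses List of [fit_reference_ellipse()] objects.
#' @return data.frame sorted by increasing distance, with columns
#'   `class_label`, `mahalanobis` (distance, not squared), `inside`.
#' @export
assign_source <- function(d13c_16, d13c_18, ellipses) {
  if (inherits(ellipses, "ref_ellipse")) ellipses <- list(ellipses)
  if (length(ellipses) == 0) stop("need at least one ellipse", call. = FALSE)
  x <- c(d13c_16, d13c_18)
  rows <- lapply(ellipses, function(e) {
    d2 <- as.numeric(stats::mahalanobis(matrix(x, nrow = 1), e$center,
                                        e$covariance))
    data.frame(class_label = e$class_label,
               mahalanobis = sqrt(d2),
               inside = d2 <= stats::qchisq(e$level, df = 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mahalanobis), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delta13C: the stearic-minus-palmitic discriminator
#'
#' `Delta13C = delta13C18:0 - delta13C16:0`. Ruminant carcass fats are
#' depleted in the C18:0 acid relative to C16:0, so strongly negative
#' values indicate ruminant fat; values near zero or positive indicate
#' non-ruminant or aquatic inputs.
#'
#' @param d13c_18,d13c_16 delta13C values, per mil; `NA` propagates.
#' @return `d13c_18 - d13c_16`, per mil.
#' @export
big_delta <- function(d13c_18, d13c_16) {
  d13c_18 - d13c_16
}

#' Concentration-weighted isotopic mixing
#'
#' The delta13C of a fatty acid extracted from a mixed residue reflects
#' the contribution of each ingredient weighted by its fraction in the
#' mix and its original concentration of that fatty acid:
#' `delta_mix = sum(f_i c_i delta_i) / sum(f_i c_i)`, per fatty acid.
#'
#' @param spec data.frame with columns `fraction` (>= 0, summing to 1),
#'   `conc_16`, `conc_18` (> 0, concentration of each fatty acid in the
#'   ingredient), `d13c_16`, `d13c_18` (ingredient endpoints, per mil).
#'   A `class_label` column is allowed and ignored.
#' @return Named numeric vector `c(d13c_16 = ..., d13c_18 = ...)`, always
#'   within the convex hull of the component endpoints.
#' @export
mix_isotopes <- function(spec) {
  need <- c("fraction", "conc_16", "conc_18", "d13c_16", "d13c_18")
  miss <- setdiff(need, names(spec))
  if (length(miss) > 0)
    stop("mixture spec lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  f <- spec$fraction
  if (any(f < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  if (any(spec$conc_16 <= 0) || any(spec$conc_18 <= 0))
    stop("concentrations must be positive", call. = FALSE)
  mix_one <- function(conc, delta) {
    w <- f * conc
    tot <- sum(w)
    if (tot <= 0) stop("all-zero weighted concentration", call. = FALSE)
    sum(w * delta) / tot
  }
  c(d13c_16 = mix_one(spec$conc_16, spec$d13c_16),
    d13c_18 = mix_one(spec$conc_18, spec$d13c_18))
}
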