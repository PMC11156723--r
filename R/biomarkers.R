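# Molecular criteria for vessel-content assignment: APAA-C18 E/H isomer
# ratio (heated starchy grains), C20/C22 APAA and phytanic-diastereomer
# criteria (heated aquatic oils), miliacin (broomcorn millet) and conifer
# resin flags.

#' APAA-C18 isomeric E/H ratio
#'
#' Ratio of the E and H positional isomers of the C18
#' omega-(o-alkylphenyl)alkanoic acid, formed by prolonged heating of
#' unsaturated fats. Heated rice and millet oils give distinctly high
#' ratios, so E/H is a crude discriminator for starchy cereal grains.
#'
#' @param apaa_c18_areas Named numeric vector of integrated isomer peak
#'   areas; names are isomer labels `A` ... `I`. Isomers may be absent.
#' @return `area(E) / area(H)`, or `NA` if either isomer is absent or the
#'   H area is zero. The ratio is invariant under rescaling of all areas.
#' @export
compute_eh_ratio <- function(apaa_c18_areas) {
  areas <- apaa_c18_areas[!is.na(apaa_c18_areas)]
  if (any(areas < 0))
    stop("APAA isomer areas must be non-negative", call. = FALSE)
  if (!all(c("E", "H") %in% names(areas))) return(NA_real_)
  if (areas[["H"]] == 0) return(NA_real_)
  unname(areas[["E"]] / areas[["H"]])
}

#' Cereal-consistency criterion on the E/H ratio
#'
#' A sample is consistent with heated starchy cereals when its APAA-C18
#' E/H ratio strictly exceeds the threshold (default 6). The inequality is
#' strict: a ratio exactly at the threshold is not called.
#'
#' @param eh_ratio E/H ratio(s); `NA` propagates to `NA`.
#' @param threshold Decision threshold, default 6.
#' @return Logical vector.
#' @export
classify_cereal <- function(eh_ratio, threshold = 6) {
  stopifnot(is.numeric(threshold), threshold > 0)
  eh_ratio > threshold
}

#' Aquatic-oil classification criteria
#'
#' Bundles the thresholds for calling heated aquatic oils: presence of
#' C20/C22 APAAs, the phytanic-acid diastereomer ratio (SRR%), and the
#' APAA C20-to-C18 abundance ratio. By default any one criterion suffices
#' (the criteria are OR-combined); `require_isoprenoid = TRUE` selects a
#' stricter mode in which APAA evidence must be accompanied by an
#' isoprenoid fatty acid (phytanic/pristanic/TMTD).
#'
#' @param srr_threshold_pct SRR% strict threshold, default 75.
#' @param apaa20_over_18_threshold Strict threshold on
#'   `area(APAA-C20) / total area(APAA-C18)`, default 0.06.
#' @param require_isoprenoid Logical; stricter AND-mode described above.
#' @return An object of class `aquatic_criteria`.
#' @export
aquatic_criteria <- function(srr_threshold_pct = 75,
                             apaa20_over_18_threshold = 0.06,
                             require_isoprenoid = FALSE) {
  stopifnot(srr_threshold_pct > 0, apaa20_over_18_threshold > 0,
            is.logical(require_isoprenoid))
  structure(list(srr_threshold_pct = srr_threshold_pct,
                 apaa20_over_18_threshold = apaa20_over_18_threshold,
                 require_isoprenoid = require_isoprenoid),
            class = "aquatic_criteria")
}

sample_field <- function(sample, field) {
  if (!field %in% names(sample)) return(NA)
  v <- sample[[field]]
  if (length(v) == 0) NA else v[[1]]
}

apaa_c18_from_sample <- function(sample) {
  cols <- paste0("apaa_c18_", APAA_ISOMERS)
  v <- vapply(cols, function(cl) {
    x <- sample_field(sample, cl)
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  names(v) <- APAA_ISOMERS
  v
}

#' Classify a sample as containing heated aquatic oils
#'
#' Evidence classes: `apaa_c20` / `apaa_c22` (presence of the long-chain
#' APAA homologs formed from aquatic polyunsaturated fats), `apaa_ratio`
#' (C20 APAA abundance relative to total C18 APAA above threshold), `srr`
#' (phytanic diastereomer ratio above threshold), and `isoprenoids`
#' (phytanic/pristanic/TMTD presence, recorded as supporting evidence but
#' never sufficient on its own). Missing fields simply cannot contribute.
#'
#' @param sample A single-row data.frame or named list with the residue
#'   sample fields (see [read_sample_table()]).
#' @param criteria An [aquatic_criteria()] object.
#' @return List with `aquatic` (logical) and `evidence` (character vector
#'   of satisfied criteria; non-empty whenever `aquatic` is `TRUE`).
#' @export
classify_aquatic <- function(sample, criteria = aquatic_criteria()) {
  stopifnot(inherits(criteria, "aquatic_criteria"))
  evidence <- character(0)
  num <- function(field) {
    v <- sample_field(sample, field)
    if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  }
  a20 <- num("apaa_c20_area"); a22 <- num("apaa_c22_area")
  if (!is.na(a20) && a20 > 0) evidence <- c(evidence, "apaa_c20")
  if (!is.na(a22) && a22 > 0) evidence <- c(evidence, "apaa_c22")
  c18 <- apaa_c18_from_sample(sample)
  c18_total <- if (all(is.na(c18))) NA_real_ else sum(c18, na.rm = TRUE)
  if (!is.na(a20) && !is.na(c18_total) && c18_total > 0 &&
      a20 / c18_total > criteria$apaa20_over_18_threshold)
    evidence <- c(evidence, "apaa_ratio")
  srr <- num("phytanic_srr_pct")
  if (!is.na(srr) && srr > criteria$srr_threshold_pct)
    evidence <- c(evidence, "srr")
  iso <- isTRUE(sample_field(sample, "pristanic_present")) ||
    isTRUE(sample_field(sample, "tmtd_present"))
  if (iso) evidence <- c(evidence, "isoprenoids")

  decisive <- setdiff(evidence, "isoprenoids")
  aquatic <- length(decisive) > 0
  if (criteria$require_isoprenoid) {
    apaa_based <- any(c("apaa_c20", "apaa_c22", "apaa_ratio") %in% evidence)
    aquatic <- ("srr" %in% evidence) || (apaa_based && iso)
  }
  if (!aquatic) evidence <- character(0) else evidence <- unique(evidence)
  list(aquatic = aquatic, evidence = evidence)
}

#' Full molecular classification of one residue sample
#'
#' Combines the E/H cereal criterion, the aquatic-oil criteria, the
#' miliacin millet flag and the conifer resin flag into one record.
#' Deterministic in its input.
#'
#' @inheritParams classify_aquatic
#' @param eh_threshold Threshold for [classify_cereal()].
#' @return One-row data.frame: `sample_id`, `site`, `phase`, `eh_ratio`,
#'   `cereal_consistent`, `aquatic`, `aquatic_evidence` (semicolon-joined),
#'   `millet`, `resin`, `notes`.
#' @export
classify_sample <- function(sample, criteria = aquatic_criteria(),
                            eh_threshold = 6) {
  eh <- compute_eh_ratio(apaa_c18_from_sample(sample))
  aq <- classify_aquatic(sample, criteria)
  millet <- isTRUE(sample_field(sample, "miliacin_present"))
  resin_raw <- sample_field(sample, "resin_markers")
  resin <- !is.null(resin_raw) && !is.na(resin_raw) &&
    nzchar(trimws(as.character(resin_raw)))
  notes <- character(0)
  if (millet && !is.na(eh) && eh > eh_threshold)
    notes <- c(notes, "miliacin corroborated by high E/H")
  if (millet && aq$aquatic)
    notes <- c(notes, "millet and aquatic markers co-occur")
  data.frame(
    sample_id = as.character(sample_field(sample, "sample_id")),
    site = as.character(sample_field(sample, "site")),
    phase = as.character(sample_field(sample, "phase")),
    eh_ratio = eh,
    cereal_consistent = classify_cereal(eh, eh_threshold),
    aquatic = aq$aquatic,
    aquatic_evidence = paste(aq$evidence, collapse = ";"),
    millet = millet,
    resin = resin,
    notes = paste(notes, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Classify every sample in a residue table
#'
#' Row-wise application of [classify_sample()]; the result is identical to
#' classifying each row separately.
#'
#' @param samples Validated sample table ([read_sample_table()]).
#' @inheritParams classify_sample
#' @return data.frame with one classification row per sample.
#' @export
classify_samples <- function(samples, criteria = aquatic_criteria(),
                             eh_threshold = 6) {
  rows <- lapply(seq_len(nrow(samples)), function(i)
    classify_sample(samples[i, , drop = FALSE], criteria, eh_threshold))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate classification flags by grouping variables
#'
#' Counts, per group, how many samples carry each molecular flag. Marginal
#' totals are conserved: `n` sums to the number of classifications.
#'
#' @param classifications Output of [classify_samples()].
#' @param by Grouping columns, default `c("site", "phase")`.
#' @return data.frame with the grouping columns, `n` (group size) and one
#'   integer count column per flag (`millet`, `aquatic`,
#'   `cereal_consistent`, `resin`).
#' @export
summarize_flags <- function(classifications, by = c("site", "phase")) {
  if (nrow(classifications) == 0) stop("no classifications", call. = FALSE)
  miss <- setdiff(by, names(classifications))
  if (length(miss) > 0)
    stop("grouping column(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  flags <- c("millet", "aquatic", "cereal_consistent", "resin")
  key <- interaction(classifications[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(classifications)), key)
  rows <- lapply(groups, function(idx) {
    g <- classifications[idx[1], by, drop = FALSE]
    counts <- vapply(flags, function(f)
      sum(classifications[[f]][idx], na.rm = TRUE), numeric(1))
    cbind(g, n = length(idx), as.data.frame(as.list(counts)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
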