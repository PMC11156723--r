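# Tabular I/O and validation for residue samples, reference products,
# seed-impression counts, radiocarbon dates and calibration curves.

REGION_LEVELS <- c("Tokai", "CentralHighlands", "other")
PHASE_LEVELS <- c("LateJomon", "FinalJomon", "InitialYayoi", "EarlyYayoi",
                  "MiddleYayoi", "other")
STYLE_LEVELS <- c("Ongagawa", "Jokonmon", "other", "unknown")
FORM_LEVELS <- c("cooking", "bowl", "jar", "unknown")
APAA_ISOMERS <- LETTERS[1:9]
TAXON_LEVELS <- c("rice", "millet")
REF_CLASSES <- c("Marine", "Freshwater", "Ruminant", "WildBoar", "C3Nuts",
                 "Rice", "MilletC4")

#' Default missing-value sentinels
#'
#' Supplementary residue tables mix conventions for "not detected"; the
#' readers map any of these strings (plus the empty field) to `NA`.
#'
#' @return Character vector of strings interpreted as missing.
#' @export
default_na_strings <- function() c("", "NA", "ND", "nd", "n.d.", "N.D.", "-")

stop_cell <- function(row, col, msg) {
  stop(sprintf("row %d, column '%s': %s", row, col, msg), call. = FALSE)
}

# Coerce a character/any column to numeric, reporting the first offending row.
coerce_numeric_col <- function(x, col) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad) > 0)
    stop_cell(bad[1], col, sprintf("malformed numeric value '%s'", x[bad[1]]))
  out
}

coerce_logical_col <- function(x, col) {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  map <- c("true" = TRUE, "t" = TRUE, "yes" = TRUE, "y" = TRUE, "1" = TRUE,
           "false" = FALSE, "f" = FALSE, "no" = FALSE, "n" = FALSE, "0" = FALSE)
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(x) & nzchar(key))
  if (length(bad) > 0)
    stop_cell(bad[1], col, sprintf("malformed logical value '%s'", x[bad[1]]))
  out
}

check_enum_col <- function(x, col, levels) {
  x <- as.character(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0)
    stop_cell(bad[1], col, sprintf(
      "value '%s' not one of {%s}", x[bad[1]], paste(levels, collapse = ", ")))
  x
}

check_range_col <- function(x, col, lo = -Inf, hi = Inf, allow_na = TRUE) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad) > 0)
    stop_cell(bad[1], col, sprintf("value %g outside [%g, %g]", x[bad[1]], lo, hi))
  if (!allow_na && anyNA(x))
    stop_cell(which(is.na(x))[1], col, "missing value not allowed")
  x
}

read_delim_table <- function(path, sep = NULL, na_strings = default_na_strings()) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, na.strings = na_strings,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"", strip.white = TRUE)
}

apply_schema <- function(df, schema) {
  if (is.null(schema)) return(df)
  for (canonical in names(schema)) {
    src <- schema[[canonical]]
    if (!src %in% names(df))
      stop(sprintf("schema maps '%s' to missing column '%s'", canonical, src),
           call. = FALSE)
    names(df)[names(df) == src] <- canonical
  }
  df
}

#' Read a per-sample residue table
#'
#' Reads a delimited text table of per-sherd molecular and isotopic
#' measurements and validates every field. One row is one sampled sherd.
#' Recognised columns (all except the first four optional):
#' `sample_id`, `site`, `region`, `phase`, `vessel_style`, `vessel_form`,
#' `lipid_conc` (µg/g sherd), any number of fatty-acid peak areas prefixed
#' `fa_`, APAA-C18 positional-isomer areas `apaa_c18_A` ... `apaa_c18_I`,
#' `apaa_c20_area`, `apaa_c22_area`, `phytanic_srr_pct`,
#' `pristanic_present`, `tmtd_present`, `miliacin_present`,
#' `resin_markers` (semicolon-separated labels), `d13c_16`, `d13c_18`
#' (per mil VPDB).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param sep Field separator; `NULL` chooses by file extension
#'   (tab for `.tsv`/`.txt`, comma otherwise).
#' @param na_strings Strings mapped to missing, see [default_na_strings()].
#' @param schema Optional named character vector mapping canonical column
#'   names (the names) to the file's column headers (the values), so
#'   foreign layouts load without editing the file.
#' @return A validated `data.frame`, one row per sample, row order preserved.
#' @export
read_sample_table <- function(path, sep = NULL,
                              na_strings = default_na_strings(),
                              schema = NULL) {
  df <- apply_schema(read_delim_table(path, sep, na_strings), schema)
  validate_sample_table(df)
}

#' Validate a residue sample table
#'
#' Enforces the field invariants of a per-sample residue table: unique
#' sample ids, non-negative areas and concentrations, `phytanic_srr_pct`
#' within \[0, 100\], and delta13C values within a plausibility band of
#' \[-45, -5\] per mil.
#'
#' @param df A data.frame as described in [read_sample_table()].
#' @return The validated (type-coerced) data.frame.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "site", "region", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  dup <- duplicated(df$sample_id)
  if (any(dup))
    stop_cell(which(dup)[1], "sample_id",
              sprintf("duplicate sample_id '%s'", df$sample_id[which(dup)[1]]))
  df$region <- check_enum_col(df$region, "region", REGION_LEVELS)
  df$phase <- check_enum_col(df$phase, "phase", PHASE_LEVELS)
  if ("vessel_style" %in% names(df))
    df$vessel_style <- check_enum_col(df$vessel_style, "vessel_style", STYLE_LEVELS)
  if ("vessel_form" %in% names(df))
    df$vessel_form <- check_enum_col(df$vessel_form, "vessel_form", FORM_LEVELS)

  area_cols <- c(grep("^fa_", names(df), value = TRUE),
                 paste0("apaa_c18_", APAA_ISOMERS), "apaa_c20_area",
                 "apaa_c22_area", "lipid_conc")
  for (col in intersect(area_cols, names(df))) {
    df[[col]] <- coerce_numeric_col(df[[col]], col)
    check_range_col(df[[col]], col, lo = 0)
  }
  if ("phytanic_srr_pct" %in% names(df)) {
    df$phytanic_srr_pct <- coerce_numeric_col(df$phytanic_srr_pct, "phytanic_srr_pct")
    check_range_col(df$phytanic_srr_pct, "phytanic_srr_pct", 0, 100)
  }
  for (col in intersect(c("d13c_16", "d13c_18"), names(df))) {
    df[[col]] <- coerce_numeric_col(df[[col]], col)
    check_range_col(df[[col]], col, -45, -5)
  }
  for (col in intersect(c("pristanic_present", "tmtd_present", "miliacin_present"),
                        names(df)))
    df[[col]] <- coerce_logical_col(df[[col]], col)
  if ("resin_markers" %in% names(df)) {
    # empty set, not missing: absence of resin markers is observable
    df$resin_markers <- as.character(df$resin_markers)
    df$resin_markers[is.na(df$resin_markers)] <- ""
  }
  rownames(df) <- NULL
  df
}

#' Write a residue sample table
#'
#' Inverse of [read_sample_table()]: missing values become empty fields, so
#' a write/read round trip reproduces the table.
#'
#' @param df Sample table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a reference product table
#'
#' Authentic reference products (modern tissues or archaeological food
#' crusts of known origin) with their compound-specific delta13C values.
#' Columns: `class_label` (one of Marine, Freshwater, Ruminant, WildBoar,
#' C3Nuts, Rice, MilletC4), `d13c_16`, `d13c_18`, `is_modern`,
#' `sampling_year` (required for modern entries, used for the Suess
#' correction).
#'
#' @inheritParams read_sample_table
#' @return Validated data.frame.
#' @export
read_reference_table <- function(path, sep = NULL,
                                 na_strings = default_na_strings(),
                                 schema = NULL) {
  df <- apply_schema(read_delim_table(path, sep, na_strings), schema)
  need <- c("class_label", "d13c_16", "d13c_18", "is_modern")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$class_label <- check_enum_col(df$class_label, "class_label", REF_CLASSES)
  for (col in c("d13c_16", "d13c_18")) {
    df[[col]] <- coerce_numeric_col(df[[col]], col)
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) stop_cell(bad[1], col, "delta13C must be finite")
  }
  df$is_modern <- coerce_logical_col(df$is_modern, "is_modern")
  if (!"sampling_year" %in% names(df)) df$sampling_year <- NA_real_
  df$sampling_year <- coerce_numeric_col(df$sampling_year, "sampling_year")
  bad <- which(df$is_modern & is.na(df$sampling_year))
  if (length(bad) > 0)
    stop_cell(bad[1], "sampling_year", "modern reference lacks sampling_year")
  rownames(df) <- NULL
  df
}

#' Read a seed-impression count table
#'
#' Per-site counts of crop seed impressions observed in pottery fabric.
#' Columns: `site`, `region`, `phase`, `taxon` (`rice` or `millet`),
#' `n_impressions` (integer, >= 0), `n_sherds` (integer, >= 1).
#'
#' @inheritParams read_sample_table
#' @return Validated data.frame.
#' @export
read_seed_count_table <- function(path, sep = NULL,
                                  na_strings = default_na_strings(),
                                  schema = NULL) {
  df <- apply_schema(read_delim_table(path, sep, na_strings), schema)
  validate_seed_count_table(df)
}

#' Validate a seed-impression count table
#' @param df data.frame as in [read_seed_count_table()].
#' @return Validated data.frame.
#' @export
validate_seed_count_table <- function(df) {
  need <- c("site", "region", "phase", "taxon", "n_impressions", "n_sherds")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$region <- check_enum_col(df$region, "region", REGION_LEVELS)
  df$phase <- check_enum_col(df$phase, "phase", PHASE_LEVELS)
  df$taxon <- check_enum_col(df$taxon, "taxon", TAXON_LEVELS)
  for (col in c("n_impressions", "n_sherds")) {
    df[[col]] <- coerce_numeric_col(df[[col]], col)
    bad <- which(is.na(df[[col]]) | df[[col]] != round(df[[col]]))
    if (length(bad) > 0) stop_cell(bad[1], col, "count must be a whole number")
    df[[col]] <- as.integer(round(df[[col]]))
  }
  check_range_col(df$n_impressions, "n_impressions", lo = 0)
  check_range_col(df$n_sherds, "n_sherds", lo = 1)
  rownames(df) <- NULL
  df
}

#' Read a radiocarbon date table
#'
#' Columns: `lab_id`, `cra_bp` (conventional radiocarbon age, years BP),
#' `sigma` (1-sigma measurement error, years), `region`,
#' `rice_associated` (logical: is the dated event tied to rice use).
#'
#' @inheritParams read_sample_table
#' @return Validated data.frame.
#' @export
read_c14_table <- function(path, sep = NULL,
                           na_strings = default_na_strings(),
                           schema = NULL) {
  df <- apply_schema(read_delim_table(path, sep, na_strings), schema)
  need <- c("lab_id", "cra_bp", "sigma", "region")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$lab_id <- as.character(df$lab_id)
  df$cra_bp <- coerce_numeric_col(df$cra_bp, "cra_bp")
  df$sigma <- coerce_numeric_col(df$sigma, "sigma")
  check_range_col(df$cra_bp, "cra_bp", lo = .Machine$double.eps, allow_na = FALSE)
  bad <- which(is.na(df$sigma) | df$sigma <= 0)
  if (length(bad) > 0) stop_cell(bad[1], "sigma", "sigma must be > 0")
  df$region <- check_enum_col(df$region, "region", REGION_LEVELS)
  if (!"rice_associated" %in% names(df)) df$rice_associated <- TRUE
  df$rice_associated <- coerce_logical_col(df$rice_associated, "rice_associated")
  rownames(df) <- NULL
  df
}

#' Construct a calibration curve
#'
#' An IntCal-style calibration curve: for each calendar age (cal BP) the
#' curve radiocarbon age and its 1-sigma uncertainty. The constructor
#' sorts the grid ascending, drops exactly duplicated rows, and rejects
#' a grid that is still not strictly increasing or a non-positive sd.
#'
#' @param cal_bp Calendar ages, years BP.
#' @param mu Curve radiocarbon age at each grid point, 14C years BP.
#' @param sd Curve 1-sigma at each grid point, 14C years (> 0).
#' @return An object of class `cal_curve`.
#' @export
calibration_curve <- function(cal_bp, mu, sd) {
  if (length(cal_bp) != length(mu) || length(cal_bp) != length(sd))
    stop("cal_bp, mu and sd must have equal length", call. = FALSE)
  if (anyNA(cal_bp) || anyNA(mu) || anyNA(sd))
    stop("calibration curve contains missing values", call. = FALSE)
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; mu <- mu[o]; sd <- sd[o]
  keep <- !duplicated(data.frame(cal_bp, mu, sd))
  cal_bp <- cal_bp[keep]; mu <- mu[keep]; sd <- sd[keep]
  if (any(diff(cal_bp) <= 0))
    stop("calibration grid not strictly increasing after de-duplication",
         call. = FALSE)
  if (any(sd <= 0))
    stop("calibration curve sd must be > 0 everywhere", call. = FALSE)
  structure(list(cal_bp = as.numeric(cal_bp), mu = as.numeric(mu),
                 sd = as.numeric(sd)), class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: %d points, %.0f-%.0f cal BP\n",
              length(x$cal_bp), min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

#' Read an IntCal-style calibration curve file
#'
#' Accepts comma- or whitespace-separated files with three numeric columns
#' (cal BP, 14C age, 1-sigma); lines starting with `#` are comments.
#'
#' @param path Path to the curve file.
#' @return A [calibration_curve()] object.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no data lines in curve file", call. = FALSE)
  sep_comma <- grepl(",", lines[1], fixed = TRUE)
  parts <- if (sep_comma) strsplit(lines, ",") else strsplit(trimws(lines), "\\s+")
  mat <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[1:3]))
    if (anyNA(v)) stop("malformed curve line: ", paste(p, collapse = " "),
                       call. = FALSE)
    v
  }, numeric(3)))
  calibration_curve(mat[, 1], mat[, 2], mat[, 3])
}

#' Write a calibration curve in IntCal-style format
#'
#' @param curve A [calibration_curve()] object.
#' @param path Output path; three comma-separated numeric columns with a
#'   `#` comment header.
#' @return `path`, invisibly.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cal BP, 14C age BP, 1-sigma", con)
  writeLines(sprintf("%.6g,%.6g,%.6g", curve$cal_bp, curve$mu, curve$sd), con)
  invisible(path)
}
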