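# Small in-code fixtures for the I/O tests.

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

sample_csv_lines <- function() c(
  "sample_id,site,region,phase,vessel_style,vessel_form,lipid_conc,apaa_c18_E,apaa_c18_H,apaa_c20_area,phytanic_srr_pct,miliacin_present,resin_markers,d13c_16,d13c_18",
  "ASA_001,Asahi,Tokai,EarlyYayoi,Ongagawa,cooking,120.5,30,5,0,82.1,TRUE,dehydroabietic acid,-26.4,-27.9",
  "ASA_002,Asahi,Tokai,MiddleYayoi,Jokonmon,bowl,15.2,,,,ND,FALSE,,-29.1,-30.5"
)

tiny_seed_records <- function(n_sites = 4, lambda = 0.2, sherds = 200,
                              seed = 42, size = 2) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sites), function(s) {
    data.frame(site = sprintf("site%02d", s), region = "Tokai",
               phase = "EarlyYayoi", taxon = c("rice", "millet"),
               n_impressions = stats::rnbinom(2, size = size,
                                              mu = lambda * sherds),
               n_sherds = sherds, stringsAsFactors = FALSE)
  }))
}
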