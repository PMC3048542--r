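# Shared fixtures: bundled inputs loaded once, and small builders for
# user-supplied input files written into tempdirs at test time.

bundled_regions <- load_region_table("africa_gbd_2005")
bundled_params <- load_parameters("africa_gbd_2005")

east <- bundled_regions[["Sub-Saharan Africa, East"]]

# Write a minimal valid pair of CSV input files; `mutate` can tweak the
# coverage data frame before writing (e.g. to inject an invalid bound).
write_region_csvs <- function(dir = NULL, unit = "fraction",
                              mutate_coverage = identity) {
  if (is.null(dir)) {
    dir <- tempfile("regioncsv")
    dir.create(dir)
  }
  cov <- data.frame(region = c("A", "B"),
                    lower = c(0.10, 0.02),
                    value = c(0.15, 0.04),
                    upper = c(0.20, 0.06))
  cov <- mutate_coverage(cov)
  dri <- expand.grid(region = c("A", "B"),
                     sex = c("men", "women"),
                     age_band = c("15-34", "35-54", "55+"),
                     stringsAsFactors = FALSE)
  dri$value <- round(seq(0.05, 0.60, length.out = nrow(dri)), 3)
  if (unit == "percent") {
    cov[c("lower", "value", "upper")] <- cov[c("lower", "value", "upper")] * 100
    dri$value <- dri$value * 100
  }
  cov_path <- file.path(dir, "coverage.csv")
  dri_path <- file.path(dir, "drinkers.csv")
  header <- paste0("# unit: ", unit)
  writeLines(c(header, paste(names(cov), collapse = ",")), cov_path)
  utils::write.table(cov, cov_path, sep = ",", row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  writeLines(c(header, paste(names(dri), collapse = ",")), dri_path)
  utils::write.table(dri, dri_path, sep = ",", row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  c(coverage = cov_path, drinkers = dri_path)
}

# Direct transcription of the published drinker-prevalence table,
# fractions, men then women within each region, bands 15-34/35-54/55+.
published_drinkers <- list(
  "North Africa/Middle East"    = c(7.2, 12.0, 5.5, 3.5, 1.1, 0.4) / 100,
  "Sub-Saharan Africa, Central" = c(51.0, 51.9, 20.5, 32.4, 28.5, 11.9) / 100,
  "Sub-Saharan Africa, East"    = c(24.6, 38.8, 37.2, 16.1, 24.9, 21.4) / 100,
  "Sub-Saharan Africa, South"   = c(38.0, 38.0, 29.5, 12.6, 15.7, 9.8) / 100,
  "Sub-Saharan Africa, West"    = c(36.2, 50.9, 40.5, 20.8, 31.2, 27.1) / 100)

published_coverage <- list(  # lower, value, upper (fractions)
  "North Africa/Middle East"    = c(15.01, 17.36, 19.71) / 100,
  "Sub-Saharan Africa, Central" = c(3.00, 4.25, 5.50) / 100,
  "Sub-Saharan Africa, East"    = c(12.07, 14.24, 16.41) / 100,
  "Sub-Saharan Africa, South"   = c(19.11, 21.67, 24.22) / 100,
  "Sub-Saharan Africa, West"    = c(11.36, 13.47, 15.59) / 100)
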