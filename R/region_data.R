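# Regional input tables: treatment coverage and drinker prevalence by
# sex and age band, with readers for the bundled dataset and for
# user-supplied CSV/JSON files, plus population-weighted aggregation
# and results-table I/O.

BUNDLED_DATASET <- "africa_gbd_2005"
SEXES <- c("men", "women")
DEFAULT_AGE_BANDS <- c("15-34", "35-54", "55+")

drinker_key <- function(sex, age_band) paste(sex, age_band, sep = "|")

#' One population stratum's regional inputs
#'
#' A `region_record` joins a region's antiretroviral treatment coverage
#' (the proportion of people in need of therapy who receive it) with the
#' prevalence of current drinkers for every sex x age-band cell. Both
#' sexes (`"men"`, `"women"`) must carry the same set of age bands; band
#' labels are opaque strings (the bundled data uses `"15-34"`, `"35-54"`,
#' `"55+"`).
#'
#' @param region Nonempty region name.
#' @param coverage A [proportion_estimate()] of treatment coverage.
#' @param drinkers A named list of [proportion_estimate()]s keyed
#'   `"<sex>|<age_band>"`, e.g. `"men|15-34"`.
#' @return An object of class `region_record`.
#' @seealso [load_region_table()], [drinker_prevalence()]
#' @export
region_record <- function(region, coverage, drinkers) {
  if (!is.character(region) || length(region) != 1L || !nzchar(region)) {
    stop("region_record: region name must be a nonempty string",
         call. = FALSE)
  }
  if (!inherits(coverage, "proportion_estimate")) {
    stop("region_record: coverage must be a proportion_estimate (region '",
         region, "')", call. = FALSE)
  }
  if (!length(drinkers)) {
    stop("region_record: no drinker-prevalence cells for region '",
         region, "'", call. = FALSE)
  }
  ok <- vapply(drinkers, inherits, logical(1), "proportion_estimate")
  if (!all(ok)) {
    stop("region_record: drinker cells must be proportion_estimates ",
         "(region '", region, "')", call. = FALSE)
  }
  parts <- strsplit(names(drinkers), "|", fixed = TRUE)
  sexes <- vapply(parts, `[`, character(1), 1L)
  bands <- vapply(parts, function(p) paste(p[-1L], collapse = "|"),
                  character(1))
  for (s in SEXES) {
    if (!any(sexes == s)) {
      stop("region_record: region '", region, "' lacks cells for sex '",
           s, "'", call. = FALSE)
    }
  }
  band_set <- sort(unique(bands))
  for (s in SEXES) {
    have <- sort(bands[sexes == s])
    missing_bands <- setdiff(band_set, have)
    if (length(missing_bands)) {
      stop("region_record: region '", region, "', sex '", s,
           "' is missing age band(s): ",
           paste(missing_bands, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(region = region, coverage = coverage,
                 drinkers = drinkers, age_bands = band_set),
            class = "region_record")
}

#' Look up one drinker-prevalence cell
#'
#' @param record A [region_record()].
#' @param sex `"men"` or `"women"`.
#' @param age_band Age-band label, e.g. `"15-34"`.
#' @return The [proportion_estimate()] for that cell.
#' @export
drinker_prevalence <- function(record, sex, age_band) {
  stopifnot(inherits(record, "region_record"))
  key <- drinker_key(sex, age_band)
  cell <- record$drinkers[[key]]
  if (is.null(cell)) {
    stop("drinker_prevalence: region '", record$region,
         "' has no cell for sex '", sex, "', age band '", age_band, "'",
         call. = FALSE)
  }
  cell
}

#' @export
print.region_record <- function(x, ...) {
  cat(sprintf("<region_record> %s  coverage %.4f [%.4f, %.4f]  %d cells\n",
              x$region, x$coverage$value, x$coverage$lower,
              x$coverage$upper, length(x$drinkers)))
  invisible(x)
}

region_json_path <- function() {
  system.file("extdata", "regions_africa_gbd_2005.json",
              package = "aafhiv", mustWork = TRUE)
}

unit_factor <- function(unit, where) {
  unit <- unit %||% "fraction"
  if (!unit %in% c("fraction", "percent")) {
    stop("unit must be 'fraction' or 'percent' in ", where, ", got '",
         unit, "'", call. = FALSE)
  }
  if (unit == "percent") 0.01 else 1
}

check_fraction <- function(x, what, region) {
  if (!is.finite(x) || x < 0 || x > 1) {
    stop("value outside [0, 1] for ", what, " of region '", region,
         "': ", x, call. = FALSE)
  }
  x
}

#' Load a regional input table
#'
#' Reads one `region_record` per region from either the bundled dataset,
#' a single JSON document, or a pair of CSV files.
#'
#' * `source = "africa_gbd_2005"` returns the five bundled African
#'   Global Burden of Disease regions (2005 data): regional treatment
#'   coverage with lower/upper bounds and prevalence of current drinkers
#'   for men and women in age bands 15-34, 35-54 and 55+.
#' * A path to a `.json` file: the same single-document schema the
#'   bundled data ships in — top-level `unit` (`"percent"` or
#'   `"fraction"`) and a `regions` array of
#'   `{region, coverage: {lower, value, upper}, drinkers: [{sex,
#'   age_band, value[, lower, upper]}]}`.
#' * A length-2 vector `c(coverage = <path>, drinkers = <path>)` of CSV
#'   files: coverage columns `region, lower, value, upper`; drinkers
#'   columns `region, sex, age_band, value[, lower, upper]`. UTF-8,
#'   header row required, decimal point. An optional first comment line
#'   `# unit: percent` (or `fraction`, the default) declares the unit.
#'
#' Drinker prevalences without published bounds carry variance 0.
#'
#' @param source Bundled dataset name, JSON path, or named CSV path pair.
#' @param z Normal quantile the coverage bounds correspond to.
#' @return A named list of [region_record()]s.
#' @examples
#' regions <- load_region_table("africa_gbd_2005")
#' regions[["Sub-Saharan Africa, East"]]
#' @export
load_region_table <- function(source = BUNDLED_DATASET, z = default_z()) {
  if (length(source) == 2L && !is.null(names(source))) {
    return(load_region_csv(source[["coverage"]], source[["drinkers"]], z))
  }
  path <- if (identical(source, BUNDLED_DATASET)) {
    region_json_path()
  } else {
    if (!is.character(source) || length(source) != 1L ||
        !file.exists(source)) {
      stop("load_region_table: source must be '", BUNDLED_DATASET,
           "', an existing JSON file, or c(coverage=, drinkers=) CSV ",
           "paths", call. = FALSE)
    }
    source
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  f <- unit_factor(doc$unit, path)
  if (is.null(doc$regions) || !length(doc$regions)) {
    stop("load_region_table: no regions in ", path, call. = FALSE)
  }
  records <- lapply(doc$regions, function(rg) {
    region <- rg$region %||% ""
    cov <- rg$coverage
    if (is.null(cov)) stop("missing coverage for region '", region, "'",
                           call. = FALSE)
    coverage <- proportion_estimate(
      check_fraction(cov$value * f, "coverage", region),
      check_fraction(cov$lower * f, "coverage lower bound", region),
      check_fraction(cov$upper * f, "coverage upper bound", region),
      z = z)
    cells <- list()
    for (d in rg$drinkers) {
      v <- check_fraction(d$value * f,
                          paste0("drinkers (", d$sex, ", ", d$age_band, ")"),
                          region)
      lo <- if (is.null(d$lower)) v else
        check_fraction(d$lower * f, "drinkers lower bound", region)
      hi <- if (is.null(d$upper)) v else
        check_fraction(d$upper * f, "drinkers upper bound", region)
      cells[[drinker_key(d$sex, d$age_band)]] <-
        proportion_estimate(v, lo, hi, z = z)
    }
    region_record(region, coverage, cells)
  })
  names(records) <- vapply(records, `[[`, character(1), "region")
  if (anyDuplicated(names(records))) {
    stop("load_region_table: duplicate region name(s): ",
         paste(unique(names(records)[duplicated(names(records))]),
               collapse = ", "), call. = FALSE)
  }
  records
}

read_unit_csv <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  unit <- "fraction"
  m <- regmatches(first, regexec("^#\\s*unit:\\s*(\\w+)\\s*$", first))[[1]]
  if (length(m) == 2L) unit <- m[2]
  df <- utils::read.csv(path, comment.char = "#", encoding = "UTF-8",
                        stringsAsFactors = FALSE)
  list(df = df, factor = unit_factor(unit, path))
}

load_region_csv <- function(coverage_path, drinkers_path, z = default_z()) {
  for (p in c(coverage_path, drinkers_path)) {
    if (is.null(p) || !file.exists(p)) {
      stop("load_region_table: CSV file not found: ", p, call. = FALSE)
    }
  }
  cov <- read_unit_csv(coverage_path)
  dri <- read_unit_csv(drinkers_path)
  need <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("missing column(s) ", paste(miss, collapse = ", "),
                           " in ", path, call. = FALSE)
  }
  need(cov$df, c("region", "lower", "value", "upper"), coverage_path)
  need(dri$df, c("region", "sex", "age_band", "value"), drinkers_path)
  records <- lapply(unique(cov$df$region), function(region) {
    row <- cov$df[cov$df$region == region, , drop = FALSE][1, ]
    coverage <- proportion_estimate(
      check_fraction(row$value * cov$factor, "coverage", region),
      check_fraction(row$lower * cov$factor, "coverage lower bound", region),
      check_fraction(row$upper * cov$factor, "coverage upper bound", region),
      z = z)
    sub <- dri$df[dri$df$region == region, , drop = FALSE]
    if (!nrow(sub)) stop("no drinker-prevalence rows for region '", region,
                         "'", call. = FALSE)
    cells <- list()
    for (i in seq_len(nrow(sub))) {
      d <- sub[i, ]
      v <- check_fraction(d$value * dri$factor,
                          paste0("drinkers (", d$sex, ", ", d$age_band, ")"),
                          region)
      lo <- if ("lower" %in% names(sub) && is.finite(d$lower))
        check_fraction(d$lower * dri$factor, "drinkers lower bound", region)
      else v
      hi <- if ("upper" %in% names(sub) && is.finite(d$upper))
        check_fraction(d$upper * dri$factor, "drinkers upper bound", region)
      else v
      cells[[drinker_key(d$sex, d$age_band)]] <-
        proportion_estimate(v, lo, hi, z = z)
    }
    region_record(region, coverage, cells)
  })
  names(records) <- vapply(records, `[[`, character(1), "region")
  extra <- setdiff(unique(dri$df$region), names(records))
  if (length(extra)) {
    stop("drinker-prevalence rows for region(s) without coverage: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  records
}

#' Population-weighted average of coverage values
#'
#' Aggregates country-level proportions into a regional value as
#' `sum(w_i v_i) / sum(w_i)`. The result always lies within
#' `[min(values), max(values)]` and is invariant under rescaling all
#' weights by a positive constant.
#'
#' @param values Numeric vector of fractions.
#' @param weights Non-negative weights (e.g. population sizes), same
#'   length, at least one positive.
#' @return The weighted mean, a scalar.
#' @examples
#' weighted_coverage(c(0.1, 0.3), c(1, 3))  # 0.25
#' @export
weighted_coverage <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("weighted_coverage: values and weights differ in length",
         call. = FALSE)
  }
  if (!length(values)) stop("weighted_coverage: empty input", call. = FALSE)
  if (any(weights < 0)) stop("weighted_coverage: negative weight",
                             call. = FALSE)
  if (all(weights == 0)) stop("weighted_coverage: all weights are zero",
                              call. = FALSE)
  sum(weights * values) / sum(weights)
}

RESULT_COLUMNS <- c("region", "sex", "age_band", "adaf", "naaaf", "pdt",
                    "aaf", "aaf_variance", "ci_lower", "ci_upper")

#' Write a results table
#'
#' Writes the stratified AAF results produced by [compute_aaf_table()] to
#' CSV or JSON. Numeric fields are written at full double precision so
#' that reading the file back ([read_results_table()]) reproduces every
#' value exactly. CSV columns: `region, sex, age_band, adaf, naaaf, pdt,
#' aaf, aaf_variance, ci_lower, ci_upper`.
#'
#' @param results Nonempty data frame of results.
#' @param destination Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `destination`, invisibly.
#' @export
write_results_table <- function(results, destination,
                                format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || !nrow(results)) {
    stop("write_results_table: results must be a nonempty data frame",
         call. = FALSE)
  }
  if (format == "json") {
    # I(17) = 17 significant digits, enough for exact double round-trips
    jsonlite::write_json(results, destination, dataframe = "rows",
                         digits = I(17), auto_unbox = TRUE)
  } else {
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
    utils::write.csv(out, destination, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(destination)
}

#' Read back a results table
#'
#' Inverse of [write_results_table()]; the format is inferred from the
#' file extension (`.json` vs anything else = CSV).
#'
#' @param path File written by [write_results_table()].
#' @return A data frame with numeric result columns restored.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_results_table: file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
    for (col in intersect(RESULT_COLUMNS[-(1:3)], names(df))) {
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  df
}
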