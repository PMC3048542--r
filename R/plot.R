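#' Forest-style plot of stratified AAF results
#'
#' Convenience display (non-normative) of a results table from
#' [compute_aaf_table()]: point estimates with their 95% uncertainty
#' intervals, faceted by region. Requires ggplot2.
#'
#' @param results Data frame with columns `region, sex, age_band, aaf,
#'   ci_lower, ci_upper`.
#' @param percent Plot on the percent scale (default) instead of the
#'   fraction scale.
#' @return A ggplot object.
#' @export
plot_aaf <- function(results, percent = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_aaf requires the ggplot2 package", call. = FALSE)
  }
  stopifnot(all(c("region", "sex", "age_band", "aaf", "ci_lower",
                  "ci_upper") %in% names(results)))
  df <- results
  s <- if (percent) 100 else 1
  df$stratum <- paste(df$sex, df$age_band)
  df$est <- df$aaf * s
  df$lo <- df$ci_lower * s
  df$hi <- df$ci_upper * s
  ggplot2::ggplot(df, ggplot2::aes(x = est, y = stratum)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lo, xmax = hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(
      x = if (percent) "Alcohol-attributable fraction (%)"
          else "Alcohol-attributable fraction",
      y = NULL,
      title = "HIV/AIDS deaths attributable to alcohol via nonadherence",
      subtitle = "Point estimates with 95% uncertainty intervals")
}
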