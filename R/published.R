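#' Published commonness summary for French maize weed surveys
#'
#' Per-species summary statistics for the 44 most common weed taxa of
#' two national surveys of maize fields in France (175 fields in the
#' 1970s, 484 in the 2000s), as published: second-period bootstrap mean
#' frequency (percent) and mean local abundance (individuals/m2) with
#' their 95\% confidence bounds, first-period point values (\code{NA}
#' when below the 2.3\% recording floor of the first survey), the
#' published status calls, and the within-2000s Spearman trend. Used for
#' worked examples and arithmetic cross-checks; the underlying raw
#' surveys are not redistributable.
#'
#' @return Data frame with one row per taxon.
#' @export
#' @examples
#' head(published_survey_summary())
published_survey_summary <- function() {
  path <- system.file("extdata", "maize_survey_summary.csv",
                      package = "weedshift", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Between-period arithmetic on a commonness summary
#'
#' Recomputes, from the summary's printed columns, the rounded
#' percentage-point frequency differences (second minus first period),
#' the normalized change indices, and the number of taxa shared between
#' the two periods' top-k frequency lists.
#'
#' @param summary A data frame in the layout of
#'   [published_survey_summary()].
#' @param top_k Size of the top-frequency lists to compare (default 10).
#' @return List with \code{freq_diff} (named, rounded percentage
#'   points), \code{ch_freq} (named change indices), and
#'   \code{top_shared} (count of taxa in both top-k lists).
#' @export
#' @examples
#' arc <- status_change_arithmetic(published_survey_summary())
#' arc$freq_diff[["Solanum nigrum"]]  # 13
#' arc$top_shared                     # 8
status_change_arithmetic <- function(summary, top_k = 10) {
  stopifnot(all(c("species", "freq_p2", "freq_p1") %in% names(summary)))
  known <- !is.na(summary$freq_p1)
  diff <- round(summary$freq_p2[known] - summary$freq_p1[known])
  names(diff) <- summary$species[known]
  ch <- change_index(summary$freq_p1[known], summary$freq_p2[known])
  names(ch) <- summary$species[known]
  top_p2 <- summary$species[order(-summary$freq_p2)][seq_len(top_k)]
  kn <- summary[known, , drop = FALSE]
  top_p1 <- kn$species[order(-kn$freq_p1)][seq_len(min(top_k, nrow(kn)))]
  list(freq_diff = diff, ch_freq = ch,
       top_shared = length(intersect(top_p1, top_p2)))
}
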