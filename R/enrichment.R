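#' AIS enrichment ratio
#'
#' The headline statistic: the mean percent area covered by retained
#' clusters in AIS ROIs divided by the mean percent area in the congruent
#' non-AIS ROIs. The ratio of means is the reported statistic (not the mean
#' of per-pair ratios, which differs on skewed data by the Jensen gap); ROIs
#' with no retained clusters contribute a well-defined percent area of 0.
#'
#' @param ais_stats,non_ais_stats data frames of per-ROI statistics (rows
#'   from [roi_stats()]) for the AIS and non-AIS locations.
#' @param brain_area annotation copied into the result (default taken from
#'   the stats if unique).
#' @return one-row data frame with columns `brain_area`, `n_ais_rois`,
#'   `n_nonais_rois`, `mean_pct_area_ais`, `mean_pct_area_nonais`,
#'   `enrichment_ratio`. The ratio is `NA` (with a warning) when the
#'   non-AIS mean percent area is zero, a degenerate control region.
#' @export
enrichment_ratio <- function(ais_stats, non_ais_stats, brain_area = NULL) {
  if (nrow(ais_stats) == 0L || nrow(non_ais_stats) == 0L)
    stop("both location groups must be nonempty")
  if (is.null(brain_area)) {
    ba <- unique(c(ais_stats$brain_area, non_ais_stats$brain_area))
    brain_area <- if (length(ba) == 1L) ba else NA_character_
  }
  m_ais <- mean(ais_stats$percent_area)
  m_non <- mean(non_ais_stats$percent_area)
  ratio <- if (m_non > 0) m_ais / m_non else {
    warning("non-AIS mean percent area is zero; enrichment ratio undefined")
    NA_real_
  }
  data.frame(
    brain_area = brain_area,
    n_ais_rois = nrow(ais_stats),
    n_nonais_rois = nrow(non_ais_stats),
    mean_pct_area_ais = m_ais,
    mean_pct_area_nonais = m_non,
    enrichment_ratio = ratio,
    stringsAsFactors = FALSE
  )
}

#' Per-pair enrichment ratios
#'
#' Auxiliary distributional output: the percent-area ratio of each AIS ROI
#' to its own congruent control. Pairs whose non-AIS percent area is zero
#' yield `NA`. The region-level statistic remains the ratio of means from
#' [enrichment_ratio()].
#'
#' @param pair_stats data frame with one row per ROI pair and columns
#'   `pct_area_ais`, `pct_area_nonais` (plus any identifiers, carried over).
#' @return `pair_stats` with an added `pair_ratio` column.
#' @export
per_roi_enrichment <- function(pair_stats) {
  ratio <- ifelse(pair_stats$pct_area_nonais > 0,
                  pair_stats$pct_area_ais / pair_stats$pct_area_nonais,
                  NA_real_)
  pair_stats$pair_ratio <- ratio
  pair_stats
}
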