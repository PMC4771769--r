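#' ROI-restricted Pearson correlation of two channels
#'
#' Correlates raw intensities over the ROI pixels, optionally restricted to
#' pixels strictly above per-channel thresholds (as produced by
#' [costes_auto_threshold()]). Zero variance in either channel over the
#' evaluation set yields `NA` with a warning.
#'
#' @param imgA,imgB congruent [calibrated_image]s.
#' @param roi evaluation [roi].
#' @param thresholds optional numeric pair `c(threshold_a, threshold_b)` or
#'   the list returned by [costes_auto_threshold()].
#' @return list with `pearson_r` and `n_pixels` (pixels actually used).
#' @export
pearson_roi <- function(imgA, imgB, roi, thresholds = NULL) {
  if (!identical(dim(imgA$pixels), dim(imgB$pixels)))
    stop("channels are not congruent")
  a <- imgA$pixels[roi$mask]; b <- imgB$pixels[roi$mask]
  if (!is.null(thresholds)) {
    if (is.list(thresholds))
      thresholds <- c(thresholds$threshold_a, thresholds$threshold_b)
    keep <- a > thresholds[1] & b > thresholds[2]
    if (sum(keep) < 2L)
      stop("fewer than 2 pixels survive the thresholds")
    a <- a[keep]; b <- b[keep]
  }
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a channel; Pearson r undefined")
    return(list(pearson_r = NA_real_, n_pixels = length(a)))
  }
  list(pearson_r = cor(a, b), n_pixels = length(a))
}

#' Manders overlap coefficients on binarized channels
#'
#' On binary data the Manders coefficients reduce to overlap-area
#' fractions: `m1 = |A & B & roi| / |A & roi|` (fraction of channel-A signal
#' overlapped by B) and `m2 = |A & B & roi| / |B & roi|`. An empty reference
#' mask within the ROI makes the corresponding coefficient `NA`.
#'
#' @param maskA,maskB [binary_mask]s (or logical matrices).
#' @param roi evaluation [roi].
#' @return list with `m1`, `m2`, `n_pixels` (ROI size in pixels).
#' @export
manders_binary <- function(maskA, maskB, roi) {
  a <- if (inherits(maskA, "binary_mask")) maskA$pixels else maskA
  b <- if (inherits(maskB, "binary_mask")) maskB$pixels else maskB
  if (!identical(dim(a), dim(roi$mask)) || !identical(dim(b), dim(roi$mask)))
    stop("masks and roi are not congruent")
  a <- a & roi$mask; b <- b & roi$mask
  inter <- sum(a & b)
  na <- sum(a); nb <- sum(b)
  list(
    m1 = if (na > 0) inter / na else NA_real_,
    m2 = if (nb > 0) inter / nb else NA_real_,
    n_pixels = sum(roi$mask)
  )
}

#' Intensity-weighted Manders coefficients (off by default in the pipeline)
#'
#' `M1 = sum(A over A&B) / sum(A)` within the ROI, and symmetrically for
#' `M2`. Provided for completeness; the pipeline's standard coefficients
#' come from binarized channels via [manders_binary()].
#'
#' @param imgA,imgB congruent [calibrated_image]s.
#' @param maskA,maskB [binary_mask]s of the two channels.
#' @param roi evaluation [roi].
#' @return list with `m1`, `m2`.
#' @export
manders_intensity <- function(imgA, imgB, maskA, maskB, roi) {
  a <- if (inherits(maskA, "binary_mask")) maskA$pixels else maskA
  b <- if (inherits(maskB, "binary_mask")) maskB$pixels else maskB
  ia <- imgA$pixels; ib <- imgB$pixels
  both <- a & b & roi$mask
  sa <- sum(ia[a & roi$mask]); sb <- sum(ib[b & roi$mask])
  list(
    m1 = if (sa > 0) sum(ia[both]) / sa else NA_real_,
    m2 = if (sb > 0) sum(ib[both]) / sb else NA_real_
  )
}

#' Validate a candidate AIS ROI against the AnkG channel
#'
#' A delineated candidate counts as a true AIS when the fraction of
#' subunit-positive pixels inside the ROI that fall on AnkG-positive pixels
#' reaches `min_overlap_fraction`. This is the reliability check behind
#' retaining only regions whose overlap with the structural AIS marker is
#' high.
#'
#' @param subunit_mask,ankg_mask [binary_mask]s of the subunit and AnkG
#'   channels.
#' @param roi candidate [roi].
#' @param min_overlap_fraction required overlap fraction (default 0.5).
#' @return `TRUE`/`FALSE`; `FALSE` with a warning when the ROI contains no
#'   subunit-positive pixels. The observed fraction is attached as the
#'   `"overlap_fraction"` attribute.
#' @export
validate_ais_roi <- function(subunit_mask, ankg_mask, roi,
                             min_overlap_fraction = 0.5) {
  s <- if (inherits(subunit_mask, "binary_mask")) subunit_mask$pixels else subunit_mask
  g <- if (inherits(ankg_mask, "binary_mask")) ankg_mask$pixels else ankg_mask
  s <- s & roi$mask
  ns <- sum(s)
  if (ns == 0L) {
    warning("no subunit-positive pixels in ROI '", roi$label, "'")
    return(structure(FALSE, overlap_fraction = NA_real_))
  }
  frac <- sum(s & g) / ns
  structure(frac >= min_overlap_fraction, overlap_fraction = frac)
}
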