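#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image by a
#' ball-shaped (spherical cap) structuring element of the given radius and
#' subtracts it, clipping at zero. This is the classical morphological
#' interpretation of the "rolling ball" algorithm: a ball of radius
#' `radius_px` (in both the spatial and the intensity direction) is rolled
#' beneath the intensity surface and the background is the surface traced by
#' its top. No down-scaling shortcut is applied; the opening is exact.
#'
#' @param img a [calibrated_image].
#' @param radius_px ball radius in pixels (default 50, the conventional
#'   setting for ~64 nm/pixel confocal material).
#' @return A [calibrated_image] of the background-subtracted intensities;
#'   the estimated background is attached as attribute `"background"`.
#' @export
rolling_ball_subtract <- function(img, radius_px = 50) {
  stopifnot(inherits(img, "calibrated_image"))
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px > nrow(img$pixels) && radius_px > ncol(img$pixels))
    stop("ball radius exceeds both image dimensions")
  el <- ball_element(radius_px)
  er <- cpp_gray_erode(img$pixels, el$dr, el$dc, el$h)
  bg <- cpp_gray_dilate(er, el$dr, el$dc, el$h)
  out <- img$pixels - bg
  out[out < 0] <- 0
  res <- calibrated_image(out, img$pixel_size_nm, img$channel_label)
  attr(res, "background") <- bg
  res
}

# spherical-cap structuring element: height sqrt(r^2 - d^2) over a disc
ball_element <- function(radius_px) {
  off <- disc_offsets(radius_px)
  list(dr = as.integer(off$dr), dc = as.integer(off$dc),
       h = sqrt(radius_px^2 - (off$dr^2 + off$dc^2)))
}

#' Triangle-method bin selection on a histogram
#'
#' Given bin counts, draws the chord from the histogram peak to the farthest
#' non-empty bin on the longer tail and returns the 0-based index of the bin
#' maximizing perpendicular distance to that chord. Suited to histograms
#' with their maximum near one of the extremes, as is typical for sparse
#' fluorescence. When the peak is interior, the longer tail is used; on a
#' tie, the higher-intensity tail. Distance ties resolve to the lowest bin.
#'
#' @param counts numeric vector of bin counts.
#' @return 0-based index of the selected bin.
#' @export
triangle_bin <- function(counts) {
  counts <- as.numeric(counts)
  n <- length(counts)
  nz <- which(counts > 0)
  if (length(nz) == 0L) return(0L)
  peak <- which.max(counts)                 # first maximum
  lo <- min(nz); hi <- max(nz)
  left_len <- peak - lo; right_len <- hi - peak
  end <- if (right_len >= left_len) hi else lo
  if (end == peak) return(as.integer(peak - 1L))
  # perpendicular distance of (i, counts[i]) from the chord peak -> end,
  # in raw (bin index, count) coordinates
  x1 <- peak; y1 <- counts[peak]; x2 <- end; y2 <- counts[end]
  rng <- if (end > peak) seq(peak, end) else seq(end, peak)
  d <- abs((y2 - y1) * rng - (x2 - x1) * counts[rng] + x2 * y1 - y2 * x1)
  as.integer(rng[which.max(d)] - 1L)
}

#' Triangle auto-threshold of an image
#'
#' Builds a 256-bin histogram over the intensity range of the scoped pixels,
#' selects the triangle-method bin with [triangle_bin()], and binarizes the
#' image at the upper edge of that bin. "Above threshold" is strict (`>`),
#' so every true pixel of the returned mask has intensity strictly greater
#' than the threshold.
#'
#' @param img a [calibrated_image].
#' @param mask_scope optional [roi]; when given, the histogram is built from
#'   pixels inside the ROI only (the mask still spans the whole image).
#' @return A list of class `threshold_result` with elements `threshold`
#'   (intensity), `bin` (0-based selected bin), `method` and `mask`
#'   (a [binary_mask]).
#' @export
triangle_threshold <- function(img, mask_scope = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  px <- img$pixels
  scoped <- if (is.null(mask_scope)) as.vector(px) else px[mask_scope$mask]
  lo <- min(scoped); hi <- max(scoped)
  if (hi <= lo) {
    # degenerate: a single occupied bin; empty mask under strict inequality
    thr <- lo
    return(structure(list(threshold = thr, bin = 0L, method = "TRIANGLE",
                          mask = binary_mask(px > thr, "TRIANGLE", thr)),
                     class = "threshold_result"))
  }
  width <- (hi - lo) / 256
  idx <- pmin(floor((scoped - lo) / width), 255)
  counts <- tabulate(idx + 1L, nbins = 256L)
  bin <- triangle_bin(counts)
  thr <- lo + (bin + 1) * width
  structure(list(threshold = thr, bin = bin, method = "TRIANGLE",
                 mask = binary_mask(px > thr, "TRIANGLE", thr)),
            class = "threshold_result")
}

#' Costes automatic threshold for two channels
#'
#' Fits the orthogonal (total least squares) regression of channel B on
#' channel A over the ROI pixels, then lowers a candidate threshold along A
#' (with the paired B threshold taken from the regression line) until the
#' Pearson correlation of the pixels below both thresholds first drops to
#' zero or below. Pixels above the returned thresholds are the ones used
#' for thresholded intensity correlation.
#'
#' @param imgA,imgB congruent [calibrated_image]s.
#' @param roi [roi] restricting the fit.
#' @param n_steps number of candidate levels scanned (default 256).
#' @return list with elements `threshold_a`, `threshold_b`, `slope`,
#'   `intercept` and `method = "COSTES"`.
#' @export
costes_auto_threshold <- function(imgA, imgB, roi, n_steps = 256L) {
  stopifnot(inherits(imgA, "calibrated_image"),
            inherits(imgB, "calibrated_image"))
  if (!identical(dim(imgA$pixels), dim(imgB$pixels)))
    stop("channels are not congruent")
  a <- imgA$pixels[roi$mask]; b <- imgB$pixels[roi$mask]
  va <- var(a); vb <- var(b)
  if (!is.finite(va) || !is.finite(vb) || va == 0 || vb == 0)
    stop("orthogonal regression undefined: zero variance in a channel")
  cab <- cov(a, b)
  if (cab == 0) {
    slope <- 1
  } else {
    slope <- (vb - va + sqrt((vb - va)^2 + 4 * cab^2)) / (2 * cab)
  }
  intercept <- mean(b) - slope * mean(a)
  lvls <- seq(max(a), min(a), length.out = n_steps)
  thr_a <- min(a) - 1   # fallback: never dropped to <= 0 -> retain everything
  thr_b <- intercept + slope * thr_a
  for (t_a in lvls) {
    t_b <- intercept + slope * t_a
    below <- a < t_a & b < t_b
    if (sum(below) >= 3L) {
      ab <- a[below]; bb <- b[below]
      if (sd(ab) > 0 && sd(bb) > 0) {
        r <- cor(ab, bb)
        if (r <= 0) { thr_a <- t_a; thr_b <- t_b; break }
      }
    }
  }
  list(threshold_a = thr_a, threshold_b = thr_b,
       slope = slope, intercept = intercept, method = "COSTES")
}
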