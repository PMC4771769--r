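#' Calibrated single-channel image
#'
#' A single-plane grayscale intensity raster together with its physical pixel
#' size. The raster is stored as a numeric matrix; the coordinate convention
#' throughout the package is row-major with the origin at the top-left.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param pixel_size_nm physical edge length of one pixel in nanometres
#'   (confocal material in this domain is typically ~64 nm/pixel).
#' @param channel_label free-text channel name (e.g. `"alpha2"`, `"AnkG"`).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_nm, channel_label = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have positive width and height")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and non-negative")
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel_label = as.character(channel_label)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %dx%d px, %.1f nm/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              x$channel_label))
  invisible(x)
}

#' Region of interest
#'
#' A boolean mask congruent with its image, annotated with a label, a
#' location class (AIS or non-AIS) and a brain area.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param label ROI identifier (coerced to character).
#' @param location_class `"AIS"` or `"NON_AIS"`.
#' @param brain_area brain-area annotation (e.g. `"CA1"`, `"BLA"`); free text.
#' @return An object of class `roi`.
#' @export
roi <- function(mask, label, location_class = c("AIS", "NON_AIS"),
                brain_area = "NA") {
  location_class <- match.arg(location_class)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("ROI mask must not contain NA")
  if (!any(mask)) stop("ROI mask must contain at least one TRUE pixel")
  structure(
    list(mask = mask, label = as.character(label),
         location_class = location_class,
         brain_area = as.character(brain_area)),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> '%s' (%s, %s), %d px\n", x$label, x$location_class,
              x$brain_area, sum(x$mask)))
  invisible(x)
}

#' Paired AIS / non-AIS regions
#'
#' Couples an AIS region with its congruent control region. The two masks
#' must be disjoint and have equal pixel counts (up to `tolerance` pixels;
#' rasterised translated contours can differ by aliasing).
#'
#' @param ais,non_ais [roi] objects of the corresponding location class.
#' @param tolerance allowed absolute difference in pixel counts (default 0).
#' @return An object of class `roi_pair`.
#' @export
roi_pair <- function(ais, non_ais, tolerance = 0) {
  stopifnot(inherits(ais, "roi"), inherits(non_ais, "roi"))
  if (ais$location_class != "AIS" || non_ais$location_class != "NON_AIS")
    stop("roi_pair() expects an AIS roi and a NON_AIS roi, in that order")
  if (!identical(dim(ais$mask), dim(non_ais$mask)))
    stop("paired masks must have identical shape")
  da <- sum(ais$mask); dn <- sum(non_ais$mask)
  if (abs(da - dn) > tolerance)
    stop(sprintf(
      "paired masks are not congruent: %d vs %d px (tolerance %d)",
      da, dn, tolerance))
  if (any(ais$mask & non_ais$mask))
    stop(sprintf("paired masks overlap ('%s' vs '%s')", ais$label,
                 non_ais$label))
  structure(list(ais = ais, non_ais = non_ais), class = "roi_pair")
}

#' Binary mask with provenance
#'
#' @param pixels logical matrix.
#' @param method how the mask was produced (e.g. `"TRIANGLE"`).
#' @param value threshold value used, if any.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, method = "FIXED", value = NA_real_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, method = method, value = value),
            class = "binary_mask")
}

#' Read a single-plane grayscale TIFF as a calibrated image
#'
#' Integer TIFFs (8/16-bit) are read as raw integer counts with no
#' rescaling; float TIFFs are read as stored.
#'
#' @param path file path to a readable single-plane grayscale TIFF.
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param channel_label optional channel name.
#' @return A [calibrated_image].
#' @export
read_image <- function(path, pixel_size_nm, channel_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(x) != 1L)
    stop("multi-plane TIFF not supported: ", path)
  m <- x[[1]]
  if (length(dim(m)) != 2L)
    stop("RGB/multi-sample TIFF not supported: ", path)
  calibrated_image(m, pixel_size_nm, channel_label)
}

#' Write a calibrated image as a grayscale TIFF
#'
#' Integer-valued rasters are written as 8- or 16-bit integer TIFFs and
#' round-trip bit-exactly through [read_image()].
#'
#' @param img a [calibrated_image] with integer values in `[0, 65535]`.
#' @param path output path.
#' @param bits bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "calibrated_image"), bits %in% c(8L, 16L))
  px <- img$pixels
  top <- 2^bits - 1
  if (any(px != round(px)) || any(px > top))
    stop("write_image() requires integer intensities in [0, ", top, "]")
  tiff::writeTIFF(px / top, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Read an integer label mask and its sidecar annotations as ROIs
#'
#' The exchange format for regions is an integer label-mask TIFF (0 =
#' background, each positive label one ROI) plus a sidecar table giving, for
#' every label, its location class, brain area and pair id.
#'
#' @param path label-mask TIFF path.
#' @param sidecar data frame with columns `label`, `location_class`,
#'   `brain_area`, `pair_id` (as returned by [read_roi_sidecar()]), or a
#'   named character vector mapping label to location class.
#' @return A list of [roi] objects, one per positive label, with the sidecar
#'   rows attached as the `"sidecar"` attribute.
#' @export
read_roi_labels <- function(path, sidecar) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) stop("label mask must be a single-plane TIFF")
  rois_from_labels(m, sidecar)
}

#' Build ROIs from an in-memory label matrix
#'
#' @param labels integer matrix; 0 = background.
#' @param sidecar as in [read_roi_labels()].
#' @return list of [roi] objects.
#' @export
rois_from_labels <- function(labels, sidecar) {
  labels <- as.matrix(labels)
  if (is.character(sidecar) || (is.vector(sidecar) && !is.null(names(sidecar)))) {
    sidecar <- data.frame(label = names(sidecar),
                          location_class = as.character(sidecar),
                          brain_area = "NA", pair_id = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  sidecar$label <- as.character(sidecar$label)
  present <- sort(unique(labels[labels > 0]))
  if (length(present) == 0L) return(list())
  missing <- setdiff(as.character(present), sidecar$label)
  if (length(missing) > 0L)
    stop("label(s) present in mask but absent from sidecar mapping: ",
         paste(missing, collapse = ", "))
  out <- lapply(present, function(l) {
    row <- sidecar[match(as.character(l), sidecar$label), ]
    roi(labels == l, label = as.character(l),
        location_class = row$location_class,
        brain_area = row$brain_area)
  })
  attr(out, "sidecar") <- sidecar[match(as.character(present), sidecar$label), ]
  out
}

#' Read an ROI sidecar table
#'
#' @param path CSV with columns `label, location_class, brain_area, pair_id`.
#' @return data frame.
#' @export
read_roi_sidecar <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "location_class", "brain_area", "pair_id")
  if (!all(need %in% names(df)))
    stop("sidecar must have columns: ", paste(need, collapse = ", "))
  df$label <- as.character(df$label)
  df
}

#' Pair AIS ROIs with their congruent non-AIS partners
#'
#' @param rois list of [roi] objects (typically from [read_roi_labels()]).
#' @param pairing either `NULL` (use the `pair_id` column of the attached
#'   sidecar) or a named character vector mapping AIS label to non-AIS label.
#' @param tolerance allowed pixel-count difference between paired masks.
#' @return list of [roi_pair] objects.
#' @export
pair_rois <- function(rois, pairing = NULL, tolerance = 0) {
  labs <- vapply(rois, function(r) r$label, character(1))
  if (is.null(pairing)) {
    sc <- attr(rois, "sidecar")
    if (is.null(sc)) stop("no pairing given and no sidecar attached")
    ais_rows <- sc[sc$location_class == "AIS", ]
    pairing <- vapply(seq_len(nrow(ais_rows)), function(i) {
      m <- sc$label[sc$location_class == "NON_AIS" &
                    sc$pair_id == ais_rows$pair_id[i]]
      if (length(m) != 1L)
        stop("pair_id ", ais_rows$pair_id[i],
             " does not match exactly one NON_AIS label")
      m
    }, character(1))
    names(pairing) <- ais_rows$label
  }
  lapply(seq_along(pairing), function(i) {
    a <- names(pairing)[i]; n <- unname(pairing[i])
    if (!a %in% labs) stop("unknown AIS label in pairing: ", a)
    if (!n %in% labs) stop("unknown non-AIS label in pairing: ", n)
    roi_pair(rois[[match(a, labs)]], rois[[match(n, labs)]],
             tolerance = tolerance)
  })
}
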