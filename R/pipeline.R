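#' Quantify one channel over a set of ROIs
#'
#' The core measurement chain: rolling-ball background subtraction,
#' triangle binarization, connected-component labelling per ROI,
#' area/circularity gating, and per-ROI statistics.
#'
#' @param img a [calibrated_image].
#' @param rois list of [roi] objects.
#' @param rolling_ball_radius_px background-subtraction radius (default 50).
#' @param connectivity 4 or 8.
#' @param area_gate_um2,circ_gate particle gates (see [filter_clusters()]).
#' @return data frame of per-ROI statistics (one [roi_stats()] row each),
#'   with the threshold used attached as attribute `"threshold"`.
#' @export
quantify_channel <- function(img, rois, rolling_ball_radius_px = 50,
                             connectivity = 8,
                             area_gate_um2 = c(0.05, 10.00),
                             circ_gate = c(0.10, 1.00)) {
  sub <- rolling_ball_subtract(img, rolling_ball_radius_px)
  thr <- triangle_threshold(sub)
  rows <- lapply(rois, function(r) {
    cl <- label_clusters(thr$mask, r, connectivity,
                         pixel_size_nm = img$pixel_size_nm)
    cl <- filter_clusters(cl, area_gate_um2, circ_gate)
    roi_stats(cl, r, img$pixel_size_nm)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr$threshold
  out
}

resolve_inputs <- function(config) {
  if (!is.null(config$scene)) {
    sc <- config$scene
    if (!inherits(sc, "scene_config")) sc <- do.call(scene_config, sc)
    scene <- generate_scene(sc)
    rois <- rois_from_labels(scene$roi_labels, scene$sidecar)
    list(channels = scene$channels, rois = rois, sidecar = scene$sidecar,
         scene = scene, pixel_size_nm = sc$pixel_size_nm)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    sidecar <- read_roi_sidecar(inp$sidecar)
    rois <- read_roi_labels(inp$roi_mask, sidecar)
    chans <- lapply(names(inp$images), function(nm)
      read_image(inp$images[[nm]], inp$pixel_size_nm, nm))
    names(chans) <- names(inp$images)
    list(channels = chans, rois = rois, sidecar = sidecar, scene = NULL,
         pixel_size_nm = inp$pixel_size_nm)
  } else {
    stop("config must provide either $scene or $inputs")
  }
}

write_manifest <- function(config, out_dir, seed) {
  cfg <- unclass_deep(config)
  cfg$out_dir <- NULL   # volatile path; not part of the scientific record
  manifest <- list(
    package = "aispuncta",
    version = as.character(utils::packageVersion("aispuncta")),
    seed = seed,
    config = cfg
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full puncta quantification pipeline
#'
#' Orchestrates preprocessing, particle analysis, enrichment and the
#' inferential stack into one reproducible run. Outputs per-ROI statistics,
#' the region-level enrichment table, ANOVA and comparison tables as
#' deterministic CSVs plus a manifest echoing the configuration and seed.
#'
#' @param config list with components:
#'   \describe{
#'     \item{scene}{a [scene_config] (synthetic input), or}
#'     \item{inputs}{list with `images` (named list of TIFF paths),
#'       `roi_mask`, `sidecar`, `pixel_size_nm`;}
#'     \item{channel}{channel label to quantify (default: first channel);}
#'     \item{preprocess}{list: `rolling_ball_radius_px` (default 50);}
#'     \item{particles}{list: `connectivity`, `area_gate_um2`, `circ_gate`;}
#'     \item{out_dir}{output directory (optional: no files if absent);}
#'     \item{seed}{integer seed for any stochastic stage (default 1).}
#'   }
#' @return list with `roi_stats`, `enrichment`, `anova`, `comparisons`
#'   data frames (invisible file side-effects when `out_dir` is set).
#' @export
run_quantify <- function(config) {
  seed <- if (is.null(config$seed)) 1L else config$seed
  if (!is.null(config$scene) && inherits(config$scene, "scene_config"))
    config$scene$seed <- config$scene$seed # scene carries its own seed
  inp <- resolve_inputs(config)
  pp <- config$preprocess
  radius <- if (is.null(pp$rolling_ball_radius_px)) 50 else
    pp$rolling_ball_radius_px
  pt <- config$particles
  conn <- if (is.null(pt$connectivity)) 8 else pt$connectivity
  area_gate <- if (is.null(pt$area_gate_um2)) c(0.05, 10.00) else
    pt$area_gate_um2
  circ_gate <- if (is.null(pt$circ_gate)) c(0.10, 1.00) else pt$circ_gate

  ch <- if (is.null(config$channel)) names(inp$channels)[1] else config$channel
  if (!ch %in% names(inp$channels))
    stop("stage quantify: channel '", ch, "' not found among inputs")
  if (length(inp$rois) == 0L) {
    warning("stage quantify: no ROIs; emitting empty tables")
    stats_df <- data.frame()
    enr <- data.frame()
  } else {
    stats_df <- quantify_channel(inp$channels[[ch]], inp$rois, radius, conn,
                                 area_gate, circ_gate)
    enr <- do.call(rbind, lapply(split(stats_df, stats_df$brain_area),
      function(d) {
        a <- d[d$location_class == "AIS", ]
        n <- d[d$location_class == "NON_AIS", ]
        if (nrow(a) == 0L || nrow(n) == 0L) return(NULL)
        enrichment_ratio(a, n)
      }))
  }

  anova_tbl <- data.frame(); comp_tbl <- data.frame()
  if (nrow(stats_df) > 0) {
    n_area <- length(unique(stats_df$brain_area))
    n_loc <- length(unique(stats_df$location_class))
    if (n_area >= 2L && n_loc == 2L) {
      anova_tbl <- do.call(rbind, lapply(
        c("density_per_100um2", "mean_size_um2"), function(resp) {
          a <- tryCatch(two_way_anova(stats_df, resp),
                        error = function(e) NULL)
          if (is.null(a)) return(NULL)
          a$response <- resp
          a
        }))
      if (is.null(anova_tbl)) anova_tbl <- data.frame()
    }
    if (n_loc == 2L) {
      comp_tbl <- bonferroni_t_tests(
        reshape_metrics(stats_df,
                        c("density_per_100um2", "percent_area")),
        value = "value", location = "location_class", metric = "metric")
    }
  }

  out <- list(roi_stats = strip_attr(stats_df), enrichment = enr,
              anova = anova_tbl, comparisons = comp_tbl)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(out$roi_stats, file.path(config$out_dir, "roi_stats.csv"))
    write_table_csv(out$enrichment, file.path(config$out_dir, "enrichment.csv"))
    write_table_csv(out$anova, file.path(config$out_dir, "anova.csv"))
    write_table_csv(out$comparisons,
                    file.path(config$out_dir, "comparisons.csv"))
    write_manifest(config, config$out_dir, seed)
  }
  out
}

reshape_metrics <- function(df, metrics) {
  do.call(rbind, lapply(metrics, function(m)
    data.frame(metric = m, location_class = df$location_class,
               value = df[[m]], stringsAsFactors = FALSE)))
}

strip_attr <- function(df) { attr(df, "threshold") <- NULL; df }

#' Run the ROI-restricted colocalization pipeline
#'
#' For two named channels: rolling-ball subtraction on both, triangle
#' binarization for the Manders overlap fractions, Costes auto-thresholds
#' for the thresholded Pearson correlation, all restricted to each ROI,
#' followed by Bonferroni-corrected AIS versus non-AIS t-tests over the
#' coefficient family (r, M1, M2).
#'
#' @param config as in [run_quantify()], plus `channels = c(A, B)` naming
#'   the two channels (A is the subunit channel for M1's direction) and an
#'   optional `coloc` list: `pearson_thresholds` (`"costes"` (default) or
#'   `"none"`).
#' @return list with `coloc` (per-ROI table) and `tests` (comparison
#'   table); CSVs written when `out_dir` is set.
#' @export
run_coloc <- function(config) {
  inp <- resolve_inputs(config)
  chn <- config$channels
  if (is.null(chn) || length(chn) != 2L)
    stop("config$channels must name exactly two channels")
  for (nm in chn)
    if (!nm %in% names(inp$channels))
      stop("stage coloc: channel '", nm, "' not found among inputs")
  pp <- config$preprocess
  radius <- if (is.null(pp$rolling_ball_radius_px)) 50 else
    pp$rolling_ball_radius_px
  thr_mode <- if (is.null(config$coloc$pearson_thresholds)) "costes" else
    config$coloc$pearson_thresholds

  subA <- rolling_ball_subtract(inp$channels[[chn[1]]], radius)
  subB <- rolling_ball_subtract(inp$channels[[chn[2]]], radius)
  maskA <- triangle_threshold(subA)$mask
  maskB <- triangle_threshold(subB)$mask

  rows <- lapply(inp$rois, function(r) {
    thr <- NULL
    if (thr_mode == "costes") {
      thr <- tryCatch(costes_auto_threshold(subA, subB, r),
                      error = function(e) NULL)
    }
    pr <- tryCatch(pearson_roi(subA, subB, r, thresholds = thr),
                   error = function(e) list(pearson_r = NA_real_,
                                            n_pixels = 0L))
    mm <- manders_binary(maskA, maskB, r)
    data.frame(roi_label = r$label, location_class = r$location_class,
               brain_area = r$brain_area, pearson_r = pr$pearson_r,
               m1 = mm$m1, m2 = mm$m2, n_pixels = pr$n_pixels,
               stringsAsFactors = FALSE)
  })
  coloc_df <- do.call(rbind, rows)

  tests <- data.frame()
  if (length(unique(coloc_df$location_class)) == 2L) {
    long <- reshape_metrics2(coloc_df, c("pearson_r", "m1", "m2"))
    long <- long[!is.na(long$value), ]
    ok <- vapply(split(long, long$metric), function(d)
      length(unique(d$location_class)) == 2L &&
        min(table(d$location_class)) >= 2L, logical(1))
    long <- long[long$metric %in% names(ok)[ok], ]
    if (nrow(long) > 0)
      tests <- bonferroni_t_tests(long, "value", "location_class", "metric")
  }

  out <- list(coloc = coloc_df, tests = tests)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(coloc_df, file.path(config$out_dir, "coloc.csv"))
    write_table_csv(tests, file.path(config$out_dir, "coloc_tests.csv"))
    write_manifest(config, config$out_dir,
                   if (is.null(config$seed)) 1L else config$seed)
  }
  out
}

reshape_metrics2 <- function(df, metrics) {
  do.call(rbind, lapply(metrics, function(m)
    data.frame(metric = m, location_class = df$location_class,
               value = df[[m]], stringsAsFactors = FALSE)))
}
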