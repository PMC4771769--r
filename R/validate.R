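#' In-silico validation studies
#'
#' These functions encode the package's standard self-validation
#' experiments: synthetic scenes with known ground truth are generated,
#' pushed through the full measurement chain, and the recovered quantities
#' are compared with the planted ones. They are used by the test suite and
#' the reproduction script, and are exported so users can re-run them at
#' other settings.
#'
#' The validation scenes run at a coarser raster (128 nm/pixel, 640 px
#' fields) and a correspondingly scaled rolling-ball radius, which keeps a
#' full recovery study at desk scale while preserving the geometry of the
#' 64 nm material (puncta of 0.1-0.5 um radius, 1 um-wide AIS ribbons).
#'
#' @name validation-studies
NULL

# scene configuration for the ratio-recovery studies: 25 congruent ROI
# pairs per scene at 128 nm/px; two scenes give one 50-pair condition
ratio_scene_config <- function(true_ratio, seed,
                               ais_density = 24) {
  scene_config(
    image_size_px = c(640L, 640L), pixel_size_nm = 128,
    n_ais = 25L, ais_length_um = 12, ais_width_um = 1.0,
    ais_puncta_density_per_100um2 = ais_density,
    nonais_puncta_density_per_100um2 = ais_density / true_ratio,
    ambient_puncta_density_per_100um2 = 5,
    seed = seed)
}

#' Recover a planted enrichment ratio from synthetic scenes
#'
#' Generates `n_scenes` scenes (25 congruent AIS/non-AIS ROI pairs each)
#' with AIS density `ais_density` and non-AIS density
#' `ais_density / true_ratio`, quantifies the subunit channel, and returns
#' the enrichment ratio measured over the pooled ROIs.
#'
#' @param true_ratio planted AIS : non-AIS density ratio.
#' @param seed integer seed; scene seeds are derived from it.
#' @param n_scenes scenes per condition (default 2, i.e. 50 ROI pairs).
#' @param ais_density planted AIS density per 100 um^2.
#' @param rolling_ball_radius_px background-subtraction radius in pixels
#'   (default 8, i.e. ~1 um at the 128 nm validation raster — wide enough
#'   that no ball fits inside a punctum).
#' @return list with `planted` (realized truth ratio over all scenes),
#'   `measured`, and `nominal` (= `true_ratio`).
#' @export
recover_enrichment <- function(true_ratio, seed, n_scenes = 2L,
                               ais_density = 24,
                               rolling_ball_radius_px = 8) {
  stats_all <- list(); truth_all <- list()
  for (k in seq_len(n_scenes)) {
    cfg <- ratio_scene_config(true_ratio, seed + 7919L * (k - 1L),
                              ais_density)
    sc <- generate_scene(cfg)
    st <- quantify_channel(sc$channels[[cfg$subunit_label]],
                           rois_from_labels(sc$roi_labels, sc$sidecar),
                           rolling_ball_radius_px)
    stats_all[[k]] <- st
    truth_all[[k]] <- sc$truth$rois[
      sc$truth$rois$channel == cfg$subunit_label, ]
  }
  st <- do.call(rbind, stats_all)
  tr <- do.call(rbind, truth_all)
  measured <- enrichment_ratio(st[st$location_class == "AIS", ],
                               st[st$location_class == "NON_AIS", ])
  planted <- mean(tr$percent_area[tr$location_class == "AIS"]) /
    mean(tr$percent_area[tr$location_class == "NON_AIS"])
  list(nominal = true_ratio, planted = planted,
       measured = measured$enrichment_ratio)
}

#' Recover planted density and punctum size
#'
#' Equal densities are planted in AIS and non-AIS regions and the pooled
#' recovery error of per-ROI density and mean punctum size is returned.
#' `noise = "light"` disables the PSF edge, shot noise and the background
#' gradient (sharp-disc regime); `noise = "full"` uses the generator's
#' standard noise model.
#'
#' @param density planted density per 100 um^2.
#' @param seed integer seed.
#' @param noise `"light"` or `"full"`.
#' @return list with relative errors `density_err` and `size_err`
#'   (measured vs planted, pooled over all ROIs), plus the raw means.
#' @export
recover_density_size <- function(density, seed, noise = c("full", "light")) {
  noise <- match.arg(noise)
  args <- list(
    image_size_px = c(512L, 512L), pixel_size_nm = 64, n_ais = 6L,
    ais_length_um = 12, ais_puncta_density_per_100um2 = density,
    nonais_puncta_density_per_100um2 = density,
    ambient_puncta_density_per_100um2 = 5, seed = seed)
  if (noise == "light")
    args <- c(args, list(psf_sigma_um = 0, poisson_noise = FALSE,
                         gaussian_read_sd = 0,
                         background_gradient_amplitude = 0))
  cfg <- do.call(scene_config, args)
  sc <- generate_scene(cfg)
  st <- quantify_channel(sc$channels[[cfg$subunit_label]],
                         rois_from_labels(sc$roi_labels, sc$sidecar), 12)
  tr <- sc$truth$rois[sc$truth$rois$channel == cfg$subunit_label, ]
  md <- mean(st$density_per_100um2); td <- mean(tr$density_per_100um2)
  ms <- mean(st$mean_size_um2, na.rm = TRUE)
  ts <- mean(tr$mean_size_um2, na.rm = TRUE)
  list(density_err = abs(md - td) / td, size_err = abs(ms - ts) / ts,
       measured_density = md, planted_density = td,
       measured_size = ms, planted_size = ts)
}

#' Knockout scenario: channel independence
#'
#' Builds a control scene with a subunit channel and a partner channel,
#' then a knockout scene identical except that the subunit's planted puncta
#' are thinned to `residual_fraction`. Both are quantified and the relative
#' change of each channel's AIS density is returned.
#'
#' @param seed integer seed.
#' @param residual_fraction retained fraction of the knocked-out channel's
#'   puncta (default 0.05).
#' @return list with `ko_reduction` (fractional loss of the KO channel's
#'   AIS density) and `other_change` (fractional change of the untouched
#'   channel).
#' @export
ko_independence <- function(seed, residual_fraction = 0.05) {
  # 25 ROI pairs at the validation raster: ~90 planted AIS puncta, so a 5%
  # residual is resolvable against binomial thinning noise
  cfg <- scene_config(
    image_size_px = c(640L, 640L), pixel_size_nm = 128, n_ais = 25L,
    ais_length_um = 12, ais_puncta_density_per_100um2 = 30,
    nonais_puncta_density_per_100um2 = 10,
    ambient_puncta_density_per_100um2 = 5,
    coloc_fraction_geph = 0.6, seed = seed)
  ctrl <- generate_scene(cfg)
  ko <- generate_ko_scene(cfg, cfg$subunit_label, residual_fraction)
  ais_density <- function(scene, channel) {
    st <- quantify_channel(scene$channels[[channel]],
                           rois_from_labels(scene$roi_labels,
                                            scene$sidecar), 8)
    mean(st$density_per_100um2[st$location_class == "AIS"])
  }
  a0 <- ais_density(ctrl, cfg$subunit_label)
  a1 <- ais_density(ko, cfg$subunit_label)
  g0 <- ais_density(ctrl, "geph")
  g1 <- ais_density(ko, "geph")
  list(ko_reduction = (a0 - a1) / a0,
       other_change = abs(g1 - g0) / g0,
       control_density = a0, ko_density = a1)
}

#' Mean M1 at a planted colocalization fraction
#'
#' Generates one two-channel scene, binarizes both channels and returns the
#' mean binary M1 (subunit overlapped by partner) over all ROIs.
#'
#' @param coloc_fraction planted per-punctum apposition probability.
#' @param seed integer seed.
#' @return mean M1 across the scene's ROIs.
#' @export
measure_m1 <- function(coloc_fraction, seed) {
  cfg <- scene_config(
    image_size_px = c(384L, 384L), pixel_size_nm = 64, n_ais = 4L,
    ais_length_um = 8, ais_puncta_density_per_100um2 = 30,
    nonais_puncta_density_per_100um2 = 15,
    coloc_fraction_geph = coloc_fraction,
    partner_extra_density_per_100um2 = 3, seed = seed)
  sc <- generate_scene(cfg)
  maskA <- triangle_threshold(
    rolling_ball_subtract(sc$channels[[cfg$subunit_label]], 12))$mask
  maskB <- triangle_threshold(
    rolling_ball_subtract(sc$channels$geph, 12))$mask
  rois <- rois_from_labels(sc$roi_labels, sc$sidecar)
  m1 <- vapply(rois, function(r) manders_binary(maskA, maskB, r)$m1, 0)
  mean(m1, na.rm = TRUE)
}

#' Type-I error calibration of the inferential stack
#'
#' Simulates null data in the study's 2 x 6 layout (location x brain area)
#' and returns the rejection rate of each two-way ANOVA effect at alpha,
#' plus the any-pair rejection rate of Tukey-Kramer across 6 groups.
#'
#' @param n_reps simulation replicates (default 1000).
#' @param seed integer seed.
#' @param n_per_cell observations per design cell (default 10).
#' @param alpha nominal level (default 0.05).
#' @return list with `anova_rates` (named: location, brain_area,
#'   interaction) and `tukey_rate`.
#' @export
type1_calibration <- function(n_reps = 1000L, seed = 1L, n_per_cell = 10L,
                              alpha = 0.05) {
  set.seed(seed)
  layout <- expand.grid(location_class = c("AIS", "NON_AIS"),
                        brain_area = c("CA1", "CA3", "DG", "BLA", "PFC",
                                       "CTX"))
  layout <- layout[rep(seq_len(nrow(layout)), each = n_per_cell), ]
  rej <- matrix(FALSE, n_reps, 3,
                dimnames = list(NULL, c("location", "brain_area",
                                        "interaction")))
  tukey_rej <- logical(n_reps)
  g6 <- rep(letters[1:6], each = 20)
  for (i in seq_len(n_reps)) {
    layout$y <- rnorm(nrow(layout))
    a <- two_way_anova(layout, "y")
    rej[i, ] <- a$p[match(colnames(rej), a$effect)] < alpha
    d6 <- data.frame(y = rnorm(120), g = g6)
    tk <- tukey_kramer(d6, "y", "g")
    tukey_rej[i] <- any(tk$p_adjusted < alpha)
  }
  list(anova_rates = colMeans(rej), tukey_rate = mean(tukey_rej))
}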