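#' Synthetic fluorescence scene configuration
#'
#' Describes a multi-channel 2D scene emulating single-optical-section
#' confocal images of AIS-enriched receptor puncta: smooth curved AIS
#' trajectories carrying puncta in a beads-along-a-string arrangement, an
#' AnkG-like structural ribbon coextensive with each trajectory, congruent
#' translated non-AIS control regions carrying a diffuse punctum field,
#' optional partner channels (gephyrin-, vGAT-like) with controlled
#' per-punctum colocalization probability, a smooth background gradient,
#' and Poisson shot noise plus Gaussian read noise.
#'
#' Puncta are rasterized as hard discs (pixel centre within radius) with an
#' error-function edge of width `psf_sigma_um`; the rasterized footprint is
#' what the ground-truth tables record, so planted morphometry is exactly
#' defined. Placement is hard-core (minimum centre separation), so planted
#' puncta never merge. Planted counts are drawn by stochastic rounding of
#' density x area and apportioned to regions by largest remainder, which
#' keeps the planted totals tight around their expectations.
#'
#' @param image_size_px integer pair (rows, cols); default `c(1024, 1024)`.
#' @param pixel_size_nm physical pixel size (default 64, the native
#'   confocal scale for this material).
#' @param n_ais number of AIS trajectories.
#' @param ais_length_um,ais_width_um trajectory length and ribbon width.
#' @param bead_spacing_um if not `NA`, spacing of AIS beads along the
#'   trajectory (overrides the AIS density).
#' @param ais_puncta_density_per_100um2 planted AIS punctum density.
#' @param nonais_puncta_density_per_100um2 planted density inside non-AIS
#'   control regions.
#' @param ambient_puncta_density_per_100um2 punctum density in unassigned
#'   territory (scene realism; excluded from all ROIs).
#' @param puncta_radius_um_mean,puncta_radius_um_sd punctum radius
#'   distribution (normal, truncated to `puncta_radius_um_range`).
#' @param puncta_radius_um_range truncation bounds for the radius.
#' @param puncta_amplitude_mean,puncta_amplitude_sd punctum peak amplitude
#'   distribution in counts (truncated below at 50).
#' @param coloc_fraction_geph,coloc_fraction_vgat probability that a
#'   subunit punctum has an apposed partner-channel punctum; `NA` disables
#'   the channel.
#' @param partner_extra_density_per_100um2 density of partner-only puncta
#'   in ambient territory.
#' @param apposition_offset_um centre offset of apposed partner puncta;
#'   sides alternate along the trajectory (a 2D rendering of the spiralling
#'   apposition seen around the AIS).
#' @param psf_sigma_um edge softness of rendered puncta. The default keeps
#'   edges nearly sharp so that the planted footprint is recoverable by
#'   thresholding; real confocal data is blurrier (see the vignette).
#' @param ankg_amplitude intensity of the AnkG ribbon.
#' @param background_level,background_gradient_amplitude flat background
#'   and the amplitude of a random-direction linear gradient, in counts.
#' @param poisson_noise logical; Poisson shot noise on signal+background.
#' @param gaussian_read_sd additive Gaussian read noise SD in counts.
#' @param subunit_label channel label for the subunit channel.
#' @param brain_area annotation stamped on all ROIs.
#' @param seed integer; fixes all randomness of the scene.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_size_px = c(1024L, 1024L),
                         pixel_size_nm = 64,
                         n_ais = 8L,
                         ais_length_um = 15,
                         ais_width_um = 1.0,
                         bead_spacing_um = NA,
                         ais_puncta_density_per_100um2 = 30,
                         nonais_puncta_density_per_100um2 = 10,
                         ambient_puncta_density_per_100um2 = 10,
                         puncta_radius_um_mean = 0.25,
                         puncta_radius_um_sd = 0.04,
                         puncta_radius_um_range = c(0.16, 0.50),
                         puncta_amplitude_mean = 600,
                         puncta_amplitude_sd = 80,
                         coloc_fraction_geph = NA,
                         coloc_fraction_vgat = NA,
                         partner_extra_density_per_100um2 = 5,
                         apposition_offset_um = 0.10,
                         psf_sigma_um = 0.01,
                         ankg_amplitude = 500,
                         background_level = 100,
                         background_gradient_amplitude = 30,
                         poisson_noise = TRUE,
                         gaussian_read_sd = 3,
                         subunit_label = "alpha2",
                         brain_area = "BLA",
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$image_size_px > 0), cfg$pixel_size_nm > 0,
            cfg$n_ais >= 0, cfg$ais_length_um > 0, cfg$ais_width_um > 0,
            cfg$ais_puncta_density_per_100um2 >= 0,
            cfg$nonais_puncta_density_per_100um2 >= 0,
            cfg$puncta_radius_um_mean > 0)
  for (f in c("coloc_fraction_geph", "coloc_fraction_vgat"))
    if (!is.na(cfg[[f]]) && (cfg[[f]] < 0 || cfg[[f]] > 1))
      stop(f, " must lie in [0, 1]")
  class(cfg) <- "scene_config"
  cfg
}

# truncated-normal draws via inverse CDF (fixed RNG consumption: n uniforms)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# largest-remainder apportionment of total n by weights
apportion <- function(n, weights) {
  if (length(weights) == 0L || n <= 0) return(integer(length(weights)))
  w <- weights / sum(weights)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

# smooth random trajectory: spline through heading-jittered waypoints;
# returns dense samples (~0.5 px spacing), cumulative arc length, normals
sample_trajectory <- function(len_px, H, W, border) {
  step_px <- len_px / max(4L, round(len_px / 24)) # waypoint every ~1.5 um
  n_way <- round(len_px / step_px) + 1L
  start <- c(runif(1, border, H - border), runif(1, border, W - border))
  heading <- runif(1, 0, 2 * pi)
  dh <- rnorm(n_way - 1L, 0, 0.25)
  hs <- heading + cumsum(dh)
  pr <- start[1] + c(0, cumsum(step_px * sin(hs)))
  pc <- start[2] + c(0, cumsum(step_px * cos(hs)))
  if (any(pr < border | pr > H - border | pc < border | pc > W - border))
    return(NULL)
  n_dense <- max(16L, ceiling(2 * len_px))
  t0 <- seq_along(pr)
  sr <- spline(t0, pr, n = n_dense)$y
  sc <- spline(t0, pc, n = n_dense)$y
  seg <- sqrt(diff(sr)^2 + diff(sc)^2)
  cum <- c(0, cumsum(seg))
  dr <- c(diff(sr), sr[n_dense] - sr[n_dense - 1L])
  dc <- c(diff(sc), sc[n_dense] - sc[n_dense - 1L])
  nrm <- sqrt(dr^2 + dc^2); nrm[nrm == 0] <- 1
  list(r = sr, c = sc, cum = cum, len = cum[n_dense],
       normal_r = -dc / nrm, normal_c = dr / nrm)
}

# union of discs of radius `rad` stamped along path samples; stamps are
# spaced so the scallop depth between consecutive discs stays below ~0.3 px
rasterize_ribbon <- function(traj, rad, H, W) {
  n <- length(traj$r)
  spacing <- max(1, sqrt(2.4 * rad))
  keep <- unique(c(seq(1L, n, by = max(1L, floor(spacing / 0.6))), n))
  cr <- as.integer(round(traj$r[keep])); cc <- as.integer(round(traj$c[keep]))
  u <- !duplicated((cc - 1L) * H + cr)
  cr <- cr[u]; cc <- cc[u]
  off <- disc_offsets(rad)
  m <- nrow(off)
  rows <- rep(cr, each = m) + rep(as.integer(off$dr), length(cr))
  cols <- rep(cc, each = m) + rep(as.integer(off$dc), length(cc))
  ok <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
  unique((cols[ok] - 1L) * H + rows[ok])   # linear indices, column-major
}

# point on trajectory at arc length s, offset laterally by t pixels
traj_point <- function(traj, s, t) {
  i <- findInterval(s, traj$cum, all.inside = TRUE)
  w <- (s - traj$cum[i]) / pmax(traj$cum[i + 1L] - traj$cum[i], 1e-9)
  r <- traj$r[i] * (1 - w) + traj$r[i + 1L] * w + t * traj$normal_r[i]
  c <- traj$c[i] * (1 - w) + traj$c[i + 1L] * w + t * traj$normal_c[i]
  cbind(r, c)
}

# rasterized footprint of a disc punctum, clipped to the image
punctum_footprint <- function(row, col, r_px, H, W) {
  off <- disc_offsets(r_px)
  rows <- row + off$dr; cols <- col + off$dc
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  (cols[ok] - 1L) * H + rows[ok]
}

#' Generate a synthetic multi-channel scene with ground truth
#'
#' See [scene_config()] for the model. Returns the noiseless truth tables
#' (planted puncta, per-ROI morphometry, scene-level enrichment ratio) next
#' to the rendered noisy channels.
#'
#' @param config a [scene_config].
#' @return list of class `ais_scene` with elements `channels` (named list
#'   of [calibrated_image]), `roi_labels` (integer matrix), `sidecar`
#'   (label annotation data frame), `truth` (list: `puncta`, `rois`,
#'   `scalars`, `channel_sums`) and `config`.
#' @export
generate_scene <- function(config) {
  placement <- place_scene(config)
  render_scene(placement, config)
}

#' Generate a knockout scene
#'
#' Identical to [generate_scene()] at the same seed, except that the named
#' channel's planted puncta are independently retained with probability
#' `residual_fraction` before rendering — emulating the near-complete loss
#' of one subunit's immunoreactivity in a knockout while all other channels
#' are untouched.
#'
#' @param config a [scene_config].
#' @param ko_channel channel label to thin.
#' @param residual_fraction retention probability in `[0, 1]`.
#' @return An `ais_scene`.
#' @export
generate_ko_scene <- function(config, ko_channel, residual_fraction) {
  if (residual_fraction < 0 || residual_fraction > 1)
    stop("residual_fraction must lie in [0, 1]")
  placement <- place_scene(config)
  chans <- unique(placement$puncta$channel)
  if (length(chans) > 0 && !ko_channel %in% c(chans, config$subunit_label))
    stop("unknown channel label: ", ko_channel)
  sel <- placement$puncta$channel == ko_channel
  keep <- rep(TRUE, nrow(placement$puncta))
  keep[sel] <- runif(sum(sel)) < residual_fraction
  placement$puncta <- placement$puncta[keep, , drop = FALSE]
  placement$footprints <- placement$footprints[keep]
  placement <- rebuild_roi_truth(placement, config)
  render_scene(placement, config)
}

# ---- placement ------------------------------------------------------------

place_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  H <- config$image_size_px[1]; W <- config$image_size_px[2]
  px_um <- config$pixel_size_nm / 1000
  len_px <- config$ais_length_um / px_um
  half_w <- config$ais_width_um / 2 / px_um
  r_max_px <- config$puncta_radius_um_range[2] / px_um
  margin_px <- max(4, ceiling(r_max_px) + 2)
  border <- half_w + margin_px + 2

  # `blocked` separates placed structures by a small structural gap;
  # `nearroi` is the wider exclusion zone that keeps ambient puncta from
  # straddling ROI borders
  gap_struct_px <- 3
  blocked <- matrix(FALSE, H, W)
  nearroi <- matrix(FALSE, H, W)
  labels <- matrix(0L, H, W)
  trajs <- list(); ribbons <- list(); dilated <- list(); exzones <- list()

  n_ais <- config$n_ais
  # one full layout attempt; NULL when any placement is infeasible so the
  # caller can retry with the RNG advanced (keeps scenes deterministic in
  # the config seed while tolerating unlucky draws)
  attempt_layout <- function() {
    blocked <- matrix(FALSE, H, W)
    nearroi <- matrix(FALSE, H, W)
    labels <- matrix(0L, H, W)
    trajs <- list(); ribbons <- list(); dilated <- list(); exzones <- list()
    for (i in seq_len(n_ais)) {
      placed <- FALSE
      for (try in seq_len(300)) {
        tr <- sample_trajectory(len_px, H, W, border)
        if (is.null(tr)) next
        dil <- rasterize_ribbon(tr, half_w + gap_struct_px, H, W)
        if (any(blocked[dil])) next
        rib <- rasterize_ribbon(tr, half_w, H, W)
        ex <- rasterize_ribbon(tr, half_w + margin_px, H, W)
        blocked[dil] <- TRUE
        nearroi[ex] <- TRUE
        labels[rib] <- 2L * i - 1L
        trajs[[i]] <- tr; ribbons[[i]] <- rib
        dilated[[i]] <- dil; exzones[[i]] <- ex
        placed <- TRUE
        break
      }
      if (!placed) return(NULL)
    }
    # congruent non-AIS copies by translation into trajectory-free
    # territory; admissible translations found by rejection sampling with
    # an exact FFT cross-correlation fallback
    for (i in seq_len(n_ais)) {
      rib <- ribbons[[i]]
      rr <- ((rib - 1L) %% H) + 1L; cc <- ((rib - 1L) %/% H) + 1L
      sh <- sample_clear_shift_fast(blocked, dilated[[i]], H, W)
      if (is.null(sh)) sh <- sample_clear_shift(blocked, dilated[[i]], H, W)
      if (is.null(sh)) return(NULL)
      dr <- sh[1]; dc <- sh[2]
      shift_idx <- function(idx) {
        ((((idx - 1L) %/% H) + dc) * H) + ((idx - 1L) %% H) + dr + 1L
      }
      blocked[shift_idx(dilated[[i]])] <- TRUE
      ex_shift <- exzones[[i]]
      exr <- ((ex_shift - 1L) %% H) + 1L + dr
      exc <- ((ex_shift - 1L) %/% H) + 1L + dc
      ok <- exr >= 1L & exr <= H & exc >= 1L & exc <= W
      nearroi[(exc[ok] - 1L) * H + exr[ok]] <- TRUE
      labels[(cc + dc - 1L) * H + (rr + dr)] <- 2L * i
      attr(trajs[[i]], "shift") <- c(dr, dc)
    }
    list(blocked = blocked, nearroi = nearroi, labels = labels,
         trajs = trajs, ribbons = ribbons)
  }
  layout <- NULL
  if (n_ais > 0) {
    for (attempt in seq_len(5)) {
      layout <- attempt_layout()
      if (!is.null(layout)) break
    }
    if (is.null(layout))
      stop("infeasible placement: could not lay out ", n_ais,
           " AIS/non-AIS ROI pairs after bounded retries")
    blocked <- layout$blocked; nearroi <- layout$nearroi
    labels <- layout$labels
    trajs <- layout$trajs; ribbons <- layout$ribbons
  }

  sidecar <- if (n_ais > 0) data.frame(
    label = as.character(seq_len(2L * n_ais)),
    location_class = rep(c("AIS", "NON_AIS"), n_ais)[
      order(rep(seq_len(n_ais), each = 2))],
    brain_area = config$brain_area,
    pair_id = rep(seq_len(n_ais), each = 2L),
    stringsAsFactors = FALSE
  ) else data.frame(label = character(), location_class = character(),
                    brain_area = character(), pair_id = integer(),
                    stringsAsFactors = FALSE)
  # fix the interleaving: labels 2i-1 = AIS, 2i = NON_AIS
  if (n_ais > 0)
    sidecar$location_class <- ifelse(
      as.integer(sidecar$label) %% 2L == 1L, "AIS", "NON_AIS")

  puncta <- list(); footprints <- list(); next_id <- 0L
  add_punctum <- function(channel, row, col, r_px, amp, zone, roi_label,
                          partner_of = NA_integer_) {
    next_id <<- next_id + 1L
    puncta[[next_id]] <<- data.frame(
      id = next_id, channel = channel, row = row, col = col,
      radius_px = r_px, radius_um = r_px * px_um, amplitude = amp,
      zone = zone, roi_label = roi_label, partner_of = partner_of,
      stringsAsFactors = FALSE)
    footprints[[next_id]] <<- punctum_footprint(row, col, r_px, H, W)
    next_id
  }
  draw_radius <- function(n) rnorm_trunc(
    n, config$puncta_radius_um_mean, config$puncta_radius_um_sd,
    config$puncta_radius_um_range[1], config$puncta_radius_um_range[2]) / px_um
  draw_amp <- function(n) rnorm_trunc(
    n, config$puncta_amplitude_mean, config$puncta_amplitude_sd,
    50, config$puncta_amplitude_mean + 6 * config$puncta_amplitude_sd)
  gap_px <- 2
  sub <- config$subunit_label

  # AIS beads along each trajectory
  if (n_ais > 0) {
    areas_um2 <- vapply(ribbons, length, 0L) * px_um^2
    if (!is.na(config$bead_spacing_um)) {
      per_rib <- vapply(trajs, function(tr)
        max(0L, floor(tr$len * px_um / config$bead_spacing_um)), 0L)
    } else {
      n_tot <- stoch_round(config$ais_puncta_density_per_100um2 *
                             sum(areas_um2) / 100)
      per_rib <- apportion(n_tot, areas_um2)
    }
    for (i in seq_len(n_ais)) {
      n_i <- per_rib[i]
      if (n_i == 0L) next
      tr <- trajs[[i]]
      arc_margin <- r_max_px + 2
      usable <- tr$len - 2 * arc_margin
      if (usable <= 0) next
      spacing <- usable / n_i
      centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
      for (j in seq_len(n_i)) {
        r_px <- draw_radius(1)
        for (try in seq_len(10)) {
          s <- arc_margin + (j - 0.5) * spacing + rnorm(1, 0, 0.2 * spacing)
          s <- min(max(s, arc_margin), tr$len - arc_margin)
          lat_max <- max(half_w - r_px - 1, 0)
          t_off <- runif(1, -lat_max, lat_max)
          p <- traj_point(tr, s, t_off)
          row <- round(p[1]); col <- round(p[2])
          if (nrow(centers) > 0) {
            d2 <- (centers[, 1] - row)^2 + (centers[, 2] - col)^2
            if (any(d2 < (radii + r_px + gap_px)^2)) next
          }
          centers <- rbind(centers, c(row, col)); radii <- c(radii, r_px)
          add_punctum(sub, row, col, r_px, draw_amp(1), "AIS",
                      as.character(2L * i - 1L))
          break
        }
      }
    }
    # diffuse field inside the congruent non-AIS copies
    n_tot <- stoch_round(config$nonais_puncta_density_per_100um2 *
                           sum(areas_um2) / 100)
    per_rib <- apportion(n_tot, areas_um2)
    for (i in seq_len(n_ais)) {
      n_i <- per_rib[i]
      if (n_i == 0L) next
      tr <- trajs[[i]]; sh <- attr(trajs[[i]], "shift")
      arc_margin <- r_max_px + 2
      if (tr$len - 2 * arc_margin <= 0) next
      centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
      for (j in seq_len(n_i)) {
        r_px <- draw_radius(1)
        for (try in seq_len(12)) {
          s <- runif(1, arc_margin, tr$len - arc_margin)
          lat_max <- max(half_w - r_px - 1, 0)
          t_off <- runif(1, -lat_max, lat_max)
          p <- traj_point(tr, s, t_off)
          row <- round(p[1]) + sh[1]; col <- round(p[2]) + sh[2]
          if (nrow(centers) > 0) {
            d2 <- (centers[, 1] - row)^2 + (centers[, 2] - col)^2
            if (any(d2 < (radii + r_px + gap_px)^2)) next
          }
          centers <- rbind(centers, c(row, col)); radii <- c(radii, r_px)
          add_punctum(sub, row, col, r_px, draw_amp(1), "NON_AIS",
                      as.character(2L * i))
          break
        }
      }
    }
  }

  # ambient field in unassigned territory
  free <- which(!blocked & !nearroi)
  free_area_um2 <- length(free) * px_um^2
  n_amb <- stoch_round(config$ambient_puncta_density_per_100um2 *
                         free_area_um2 / 100)
  amb_centers <- place_ambient(n_amb, free, H, draw_radius, gap_px)
  if (nrow(amb_centers) > 0) {
    amps <- draw_amp(nrow(amb_centers))
    for (j in seq_len(nrow(amb_centers)))
      add_punctum(sub, amb_centers[j, 1], amb_centers[j, 2],
                  amb_centers[j, 3], amps[j], "AMBIENT", NA_character_)
  }

  # partner channels with controlled apposition
  puncta_df <- if (next_id > 0) do.call(rbind, puncta) else
    empty_puncta_df()
  offset_px <- config$apposition_offset_um / px_um
  for (pc in c("geph", "vgat")) {
    f <- config[[paste0("coloc_fraction_", pc)]]
    if (is.na(f)) next
    parents <- puncta_df[puncta_df$channel == sub, , drop = FALSE]
    if (nrow(parents) > 0) {
      take <- runif(nrow(parents)) < f
      side <- rep_len(c(1, -1), nrow(parents))   # alternating apposition side
      ang <- runif(nrow(parents), 0, 2 * pi)
      r_pp <- draw_radius(nrow(parents)) * 0.85
      a_pp <- draw_amp(nrow(parents))
      for (j in which(take)) {
        row <- round(parents$row[j] + side[j] * offset_px * sin(ang[j]))
        col <- round(parents$col[j] + side[j] * offset_px * cos(ang[j]))
        row <- min(max(row, 1L), H); col <- min(max(col, 1L), W)
        add_punctum(pc, row, col, r_pp[j], a_pp[j], parents$zone[j],
                    parents$roi_label[j], parents$id[j])
      }
    }
    n_extra <- stoch_round(config$partner_extra_density_per_100um2 *
                             free_area_um2 / 100)
    extra <- place_ambient(n_extra, free, H, draw_radius, gap_px)
    if (nrow(extra) > 0) {
      amps <- draw_amp(nrow(extra))
      for (j in seq_len(nrow(extra)))
        add_punctum(pc, extra[j, 1], extra[j, 2], extra[j, 3], amps[j],
                    "AMBIENT", NA_character_)
    }
  }
  puncta_df <- if (next_id > 0) do.call(rbind, puncta) else empty_puncta_df()

  placement <- list(
    H = H, W = W, px_um = px_um,
    labels = labels, sidecar = sidecar,
    trajs = trajs, ribbons = ribbons,
    puncta = puncta_df, footprints = footprints
  )
  rebuild_roi_truth(placement, config)
}

# rejection sampler for a clear translation: cheap subsampled hit test
# first, full test only on a pass; NULL after the retry budget
sample_clear_shift_fast <- function(blocked, shape_idx, H, W,
                                    n_try = 200L) {
  sr <- ((shape_idx - 1L) %% H) + 1L
  sc <- ((shape_idx - 1L) %/% H) + 1L
  r_lo <- 1L - min(sr); r_hi <- H - max(sr)
  c_lo <- 1L - min(sc); c_hi <- W - max(sc)
  if (r_hi < r_lo || c_hi < c_lo) return(NULL)
  probe <- shape_idx[unique(round(seq(1L, length(shape_idx),
                                      length.out = 48L)))]
  pr <- ((probe - 1L) %% H) + 1L; pc <- ((probe - 1L) %/% H) + 1L
  for (t in seq_len(n_try)) {
    dr <- r_lo + sample.int(r_hi - r_lo + 1L, 1L) - 1L
    dc <- c_lo + sample.int(c_hi - c_lo + 1L, 1L) - 1L
    if (any(blocked[(pc + dc - 1L) * H + (pr + dr)])) next
    if (any(blocked[(sc + dc - 1L) * H + (sr + dr)])) next
    return(c(dr, dc))
  }
  NULL
}

# uniform draw among all translations (dr, dc) for which the shifted shape
# stays in bounds and avoids every blocked pixel; overlap counts for every
# cyclic shift come from one FFT cross-correlation
sample_clear_shift <- function(blocked, shape_idx, H, W) {
  sr <- ((shape_idx - 1L) %% H) + 1L
  sc <- ((shape_idx - 1L) %/% H) + 1L
  S <- matrix(0, H, W); S[shape_idx] <- 1
  A <- matrix(0, H, W); A[blocked] <- 1
  ov <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(S)),
                      inverse = TRUE)) / (H * W)
  # ov[dr mod H + 1, dc mod W + 1] = overlap of shape shifted by (dr, dc)
  dr_ok <- (1L - min(sr)):(H - max(sr))
  dc_ok <- (1L - min(sc)):(W - max(sc))
  if (length(dr_ok) == 0L || length(dc_ok) == 0L) return(NULL)
  sub <- ov[dr_ok %% H + 1L, dc_ok %% W + 1L, drop = FALSE]
  clear <- which(sub < 0.5, arr.ind = TRUE)
  if (nrow(clear) == 0L) return(NULL)
  pick <- clear[sample.int(nrow(clear), 1L), ]
  c(dr_ok[pick[1]], dc_ok[pick[2]])
}

empty_puncta_df <- function() data.frame(
  id = integer(), channel = character(), row = integer(), col = integer(),
  radius_px = numeric(), radius_um = numeric(), amplitude = numeric(),
  zone = character(), roi_label = character(), partner_of = integer(),
  stringsAsFactors = FALSE)

place_ambient <- function(n, free_idx, H, draw_radius, gap_px) {
  out <- matrix(numeric(0), 0, 3)
  if (n <= 0 || length(free_idx) == 0) return(out)
  cand <- sample(free_idx, min(n * 3L, length(free_idx)))
  radii <- draw_radius(length(cand))
  for (j in seq_along(cand)) {
    row <- ((cand[j] - 1L) %% H) + 1L
    col <- ((cand[j] - 1L) %/% H) + 1L
    if (nrow(out) > 0) {
      d2 <- (out[, 1] - row)^2 + (out[, 2] - col)^2
      if (any(d2 < (out[, 3] + radii[j] + gap_px)^2)) next
    }
    out <- rbind(out, c(row, col, radii[j]))
    if (nrow(out) >= n) break
  }
  out
}

# per-ROI planted morphometry from the punctum table (noise-free truth)
rebuild_roi_truth <- function(placement, config) {
  px_um <- placement$px_um
  sidecar <- placement$sidecar
  puncta <- placement$puncta
  labels <- placement$labels
  chans <- unique(puncta$channel)
  rows <- list()
  for (ch in chans) {
    for (k in seq_len(nrow(sidecar))) {
      lab <- sidecar$label[k]
      sel <- which(puncta$channel == ch & !is.na(puncta$roi_label) &
                     puncta$roi_label == lab)
      roi_px <- sum(labels == as.integer(lab))
      fp_in <- lapply(placement$footprints[sel], function(fp)
        fp[labels[fp] == as.integer(lab)])
      sizes_px <- vapply(fp_in, length, 0L)
      covered <- length(unique(unlist(fp_in)))
      n <- length(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, roi_label = lab,
        location_class = sidecar$location_class[k],
        brain_area = sidecar$brain_area[k], pair_id = sidecar$pair_id[k],
        roi_area_um2 = roi_px * px_um^2,
        n_puncta = n,
        density_per_100um2 = n / (roi_px * px_um^2) * 100,
        mean_size_um2 = if (n == 0) NA_real_ else mean(sizes_px) * px_um^2,
        percent_area = 100 * covered / roi_px,
        stringsAsFactors = FALSE)
    }
  }
  roi_truth <- if (length(rows)) do.call(rbind, rows) else data.frame()
  scal <- list()
  if (length(rows)) {
    sub <- roi_truth[roi_truth$channel == config$subunit_label, ]
    pa <- sub$percent_area[sub$location_class == "AIS"]
    pn <- sub$percent_area[sub$location_class == "NON_AIS"]
    if (length(pa) && length(pn) && mean(pn) > 0)
      scal$true_enrichment_ratio <- mean(pa) / mean(pn)
  }
  placement$truth_rois <- roi_truth
  placement$truth_scalars <- scal
  placement
}

# ---- rendering ------------------------------------------------------------

render_scene <- function(placement, config) {
  H <- placement$H; W <- placement$W
  px_um <- placement$px_um
  sigma_px <- config$psf_sigma_um / px_um
  theta <- runif(1, 0, 2 * pi)
  gr <- matrix(rep((seq_len(H) - 1) / max(H - 1, 1), W), H, W)
  gc <- matrix(rep((seq_len(W) - 1) / max(W - 1, 1), each = H), H, W)
  field <- sin(theta) * gr + cos(theta) * gc
  field <- (field - min(field)) / max(max(field) - min(field), 1e-12)
  base <- config$background_level + config$background_gradient_amplitude * field

  chan_names <- unique(c(config$subunit_label,
                         placement$puncta$channel[
                           !is.na(placement$puncta$channel)], "AnkG"))
  chan_names <- chan_names[!is.na(chan_names)]
  channels <- list()
  for (ch in chan_names) {
    img <- base + 0
    if (ch == "AnkG") {
      for (rib in placement$ribbons) img[rib] <- img[rib] + config$ankg_amplitude
    } else {
      sel <- which(placement$puncta$channel == ch)
      pr <- placement$puncta$row[sel]; pc <- placement$puncta$col[sel]
      prad <- placement$puncta$radius_px[sel]
      pamp <- placement$puncta$amplitude[sel]
      for (j in seq_along(sel)) {
        w <- punctum_window(pr[j], pc[j], prad[j], pamp[j], sigma_px, H, W)
        img[w$rr, w$cc] <- img[w$rr, w$cc] + w$v
      }
    }
    if (config$poisson_noise) {
      img <- matrix(rpois(length(img), pmax(img, 0)), H, W)
    }
    if (config$gaussian_read_sd > 0) {
      img <- img + rnorm(length(img), 0, config$gaussian_read_sd)
    }
    img <- round(pmin(pmax(img, 0), 65535))
    channels[[ch]] <- calibrated_image(img, config$pixel_size_nm, ch)
  }
  sums <- data.frame(
    channel = names(channels),
    pixel_sum = vapply(channels, function(x) sum(x$pixels), 0),
    stringsAsFactors = FALSE)
  rownames(sums) <- NULL
  structure(list(
    channels = channels,
    roi_labels = placement$labels,
    sidecar = placement$sidecar,
    truth = list(puncta = placement$puncta,
                 rois = placement$truth_rois,
                 scalars = placement$truth_scalars,
                 channel_sums = sums),
    config = config
  ), class = "ais_scene")
}

# window of a hard disc with error-function edge of width sigma_px
punctum_window <- function(row, col, r_px, amp, sigma_px, H, W) {
  ext <- ceiling(r_px + 3 * sigma_px + 1)
  r0 <- max(1L, row - ext); r1 <- min(H, row + ext)
  c0 <- max(1L, col - ext); c1 <- min(W, col + ext)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, "+"))
  v <- if (sigma_px > 0) amp * stats::pnorm((r_px - d) / sigma_px) else
    amp * (d <= r_px)
  list(rr = rr, cc = cc, v = v)
}

#' @export
print.ais_scene <- function(x, ...) {
  cat(sprintf("<ais_scene> %dx%d px, channels: %s; %d ROIs, %d puncta\n",
              nrow(x$roi_labels), ncol(x$roi_labels),
              paste(names(x$channels), collapse = ", "),
              nrow(x$sidecar), nrow(x$truth$puncta)))
  if (!is.null(x$truth$scalars$true_enrichment_ratio))
    cat(sprintf("  planted enrichment ratio: %.3f\n",
                x$truth$scalars$true_enrichment_ratio))
  invisible(x)
}

#' Write a scene to a directory
#'
#' Channels and the ROI label mask are written as 16-bit TIFFs, the sidecar
#' and truth tables as CSV and the configuration as YAML. Re-reading with
#' [read_scene()] reproduces the rasters bit-exactly.
#'
#' @param scene an `ais_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(scene$channels))
    write_image(scene$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  lab <- scene$roi_labels
  tiff::writeTIFF(lab / 65535, file.path(dir, "roi_labels.tif"),
                  bits.per.sample = 16L, compression = "none")
  write_table_csv(scene$sidecar, file.path(dir, "roi_sidecar.csv"))
  write_table_csv(scene$truth$puncta, file.path(dir, "truth_puncta.csv"))
  write_table_csv(scene$truth$rois, file.path(dir, "truth_rois.csv"))
  write_table_csv(scene$truth$channel_sums,
                  file.path(dir, "truth_channel_sums.csv"))
  scal <- scene$truth$scalars
  scal_df <- if (length(scal) == 0) {
    data.frame(name = character(), value = numeric())
  } else {
    data.frame(name = names(scal), value = unname(unlist(scal)))
  }
  write_table_csv(scal_df, file.path(dir, "truth_scalars.csv"))
  cfg <- scene$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "scene_config.yaml"))
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir scene directory.
#' @return list with `channels`, `roi_labels`, `sidecar`, `truth` tables and
#'   the `config` list.
#' @export
read_scene <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "scene_config.yaml"))
  chans <- list()
  for (f in list.files(dir, pattern = "\\.tif$", full.names = TRUE)) {
    nm <- sub("\\.tif$", "", basename(f))
    if (nm == "roi_labels") next
    chans[[nm]] <- read_image(f, cfg$pixel_size_nm, nm)
  }
  lab <- tiff::readTIFF(file.path(dir, "roi_labels.tif"), as.is = TRUE)
  storage.mode(lab) <- "integer"
  list(
    channels = chans,
    roi_labels = lab,
    sidecar = read_roi_sidecar(file.path(dir, "roi_sidecar.csv")),
    truth = list(
      puncta = read.csv(file.path(dir, "truth_puncta.csv"),
                        stringsAsFactors = FALSE),
      rois = read.csv(file.path(dir, "truth_rois.csv"),
                      stringsAsFactors = FALSE),
      scalars = read.csv(file.path(dir, "truth_scalars.csv"),
                         stringsAsFactors = FALSE),
      channel_sums = read.csv(file.path(dir, "truth_channel_sums.csv"),
                              stringsAsFactors = FALSE)),
    config = cfg
  )
}
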