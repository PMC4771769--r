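test_that("an empty configuration yields empty channels and truth", {
  cfg <- scene_config(image_size_px = c(192L, 192L), n_ais = 2L,
                      ais_length_um = 4,
                      ais_puncta_density_per_100um2 = 0,
                      nonais_puncta_density_per_100um2 = 0,
                      ambient_puncta_density_per_100um2 = 0,
                      ankg_amplitude = 0, background_level = 0,
                      background_gradient_amplitude = 0,
                      poisson_noise = FALSE, gaussian_read_sd = 0, seed = 2L)
  sc <- generate_scene(cfg)
  for (ch in sc$channels) expect_true(all(ch$pixels == 0))
  expect_equal(nrow(sc$truth$puncta), 0)
})

test_that("scenes are pure functions of their configuration seed", {
  cfg <- test_scene_config(image_size_px = c(256L, 256L), n_ais = 3L,
                           ais_length_um = 6, seed = 77L)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$channels[[1]]$pixels, s2$channels[[1]]$pixels)
  expect_identical(s1$truth$puncta, s2$truth$puncta)

  cfg2 <- test_scene_config(image_size_px = c(256L, 256L), n_ais = 3L,
                            ais_length_um = 6, seed = 78L)
  s3 <- generate_scene(cfg2)
  expect_false(identical(s1$truth$puncta, s3$truth$puncta))
})

test_that("planted enrichment truth follows the planted densities", {
  sc <- test_scene()   # AIS 30 vs non-AIS 10 per 100 um^2, equal sizes
  expect_lt(abs(sc$truth$scalars$true_enrichment_ratio - 3) / 3, 0.25)
  tr <- sc$truth$rois[sc$truth$rois$channel == sc$config$subunit_label, ]
  # truth ratio is exactly the ratio of planted mean percent areas
  expect_equal(sc$truth$scalars$true_enrichment_ratio,
               mean(tr$percent_area[tr$location_class == "AIS"]) /
                 mean(tr$percent_area[tr$location_class == "NON_AIS"]))
})

test_that("ROI pair masks are congruent and disjoint, puncta are in bounds", {
  sc <- test_scene()
  lab <- sc$roi_labels
  for (pid in unique(sc$sidecar$pair_id)) {
    labs <- sc$sidecar$label[sc$sidecar$pair_id == pid]
    n1 <- sum(lab == as.integer(labs[1]))
    n2 <- sum(lab == as.integer(labs[2]))
    expect_equal(n1, n2)
  }
  p <- sc$truth$puncta
  expect_true(all(p$row >= 1 & p$row <= nrow(lab)))
  expect_true(all(p$col >= 1 & p$col <= ncol(lab)))
})

test_that("knockout thinning touches only the named channel", {
  cfg <- test_scene_config(image_size_px = c(320L, 320L), n_ais = 3L,
                           ais_length_um = 7, coloc_fraction_geph = 0.6,
                           seed = 23L)
  ctrl <- generate_scene(cfg)
  ko1 <- generate_ko_scene(cfg, cfg$subunit_label, 1)
  expect_identical(ctrl$truth$puncta, ko1$truth$puncta)

  ko0 <- generate_ko_scene(cfg, cfg$subunit_label, 0)
  expect_equal(sum(ko0$truth$puncta$channel == cfg$subunit_label), 0)
  # the partner channel keeps exactly its planted puncta
  expect_equal(sum(ko0$truth$puncta$channel == "geph"),
               sum(ctrl$truth$puncta$channel == "geph"))

  expect_error(generate_ko_scene(cfg, "nope", 0.5), "channel")
  expect_error(generate_ko_scene(cfg, "geph", 1.5), "residual_fraction")
})

test_that("scene write/read round trip is bit-exact and deterministic", {
  cfg <- test_scene_config(image_size_px = c(192L, 192L), n_ais = 2L,
                           ais_length_um = 5, seed = 12L)
  sc <- generate_scene(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scene(sc, d1)
  write_scene(generate_scene(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  back <- read_scene(d1)
  for (ch in names(sc$channels))
    expect_identical(back$channels[[ch]]$pixels, sc$channels[[ch]]$pixels)
  expect_identical(as.integer(back$roi_labels), as.integer(sc$roi_labels))
  # recorded channel sums match what was written
  for (i in seq_len(nrow(back$truth$channel_sums)))
    expect_equal(sum(back$channels[[back$truth$channel_sums$channel[i]]]$pixels),
                 back$truth$channel_sums$pixel_sum[i])
})

test_that("noise-light scenes recover planted density and size closely", {
  cfg <- test_scene_config(
    image_size_px = c(384L, 384L), n_ais = 4L, ais_length_um = 8,
    ais_puncta_density_per_100um2 = 25,
    nonais_puncta_density_per_100um2 = 25,
    psf_sigma_um = 0, poisson_noise = FALSE, gaussian_read_sd = 0,
    background_gradient_amplitude = 0, seed = 31L)
  sc <- generate_scene(cfg)
  res <- quantify_channel(sc$channels[[cfg$subunit_label]],
                          rois_from_labels(sc$roi_labels, sc$sidecar),
                          rolling_ball_radius_px = 12)
  tr <- sc$truth$rois[sc$truth$rois$channel == cfg$subunit_label, ]
  tr <- tr[match(res$roi_label, tr$roi_label), ]
  expect_equal(res$n_clusters, tr$n_puncta)
  expect_equal(mean(res$density_per_100um2), mean(tr$density_per_100um2),
               tolerance = 1e-8)
  expect_equal(mean(res$mean_size_um2, na.rm = TRUE),
               mean(tr$mean_size_um2, na.rm = TRUE), tolerance = 0.02)
})
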