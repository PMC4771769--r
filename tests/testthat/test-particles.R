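full_roi <- function(n) roi(matrix(TRUE, n, n), "r", "AIS")

test_that("labeling matches the definition of 4- and 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  expect_length(label_clusters(m | FALSE, full_roi(6)), 0)

  m[3, 3] <- TRUE; m[4, 4] <- TRUE   # diagonal touch
  expect_length(label_clusters(m, full_roi(6), connectivity = 4), 2)
  expect_length(label_clusters(m, full_roi(6), connectivity = 8), 1)
})

test_that("labeling equals brute-force flood fill on random masks", {
  set.seed(99)
  for (i in 1:50) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4, 8)) {
      cl <- label_clusters(m, full_roi(32), connectivity = conn)
      got <- lapply(cl, function(x)
        sort(unname((x$pixel_set[, 2] - 1L) * 32L + x$pixel_set[, 1])))
      got <- got[order(vapply(got, min, 0))]
      want <- canonical_partition(oracle_flood_fill(m, conn))
      expect_identical(got, want)
    }
  }
})

test_that("clusters are clipped to the ROI before measurement", {
  m <- matrix(FALSE, 10, 10); m[4:7, 4:7] <- TRUE
  rmask <- matrix(FALSE, 10, 10); rmask[1:5, 1:10] <- TRUE
  cl <- label_clusters(m, roi(rmask, "r", "AIS"))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_px, 8)  # 2 rows x 4 cols survive
})

test_that("single-pixel area follows the pixel calibration", {
  cl <- measure_cluster(cbind(5, 5), 64)
  expect_equal(cl$area_um2, 0.004096)
})

test_that("a rasterized disc scores circularity near 1", {
  r <- 40
  g <- expand.grid(row = -r:r + 50L, col = -r:r + 50L)
  keep <- (g$row - 50)^2 + (g$col - 50)^2 <= r^2
  px <- as.matrix(g[keep, ])
  cl <- measure_cluster(px, 64)
  expect_gte(cl$circularity, 0.95)
  expect_lte(cl$circularity, 1.0)
  # perimeter close to the analytic circumference
  expect_lt(abs(cl$perimeter_um - 2 * pi * r * 0.064), 0.1 * 2 * pi * r * 0.064)
})

test_that("chain-code perimeters match hand-computed step counts", {
  # axis-aligned rectangle: boundary through centres has 2(h-1)+2(w-1)
  # orthogonal steps
  rect <- as.matrix(expand.grid(row = 1:5, col = 1:8))
  expect_equal(measure_cluster(rect, 1000)$perimeter_um,
               0.948 * (2 * 4 + 2 * 7))
  # diagonal staircase: 2(n-1) diagonal steps
  stair <- cbind(1:6, 1:6)
  expect_equal(measure_cluster(stair, 1000)$perimeter_um,
               1.340 * 2 * 5)
  # single pixel: four orthogonal unit steps
  expect_equal(measure_cluster(cbind(3L, 3L), 1000)$perimeter_um, 0.948 * 4)
})

test_that("elongated shapes score low circularity", {
  line20 <- cbind(rep(5L, 20), 1:20 + 3L)
  line60 <- cbind(rep(5L, 60), 1:60 + 3L)
  c20 <- measure_cluster(line20, 64)$circularity
  c60 <- measure_cluster(line60, 64)$circularity
  expect_lt(c60, c20)
  expect_lt(c60, 0.10)   # excluded by the default circularity gate
  disc <- measure_cluster({
    g <- expand.grid(row = -5:5 + 10L, col = -5:5 + 10L)
    as.matrix(g[(g$row - 10)^2 + (g$col - 10)^2 <= 25, ])
  }, 64)$circularity
  expect_lt(c20, disc)
})

test_that("filtering keeps exactly the clusters inside both closed gates", {
  mk_disc <- function(r_px) {
    g <- expand.grid(row = -r_px:r_px, col = -r_px:r_px)
    px <- as.matrix(g[g$row^2 + g$col^2 <= r_px^2, ]) + r_px + 2L
    measure_cluster(px, 64)
  }
  # single pixel at 64 nm: 0.004096 um^2, below the 0.05 um^2 gate
  single <- measure_cluster(cbind(1L, 1L), 64)
  expect_length(filter_clusters(list(single)), 0)

  # planted areas straddling the gates: {~0.02, ~0.05, ~5.0, ~12.0} um^2
  discs <- lapply(c(1, 2.2, 19.7, 30.5), mk_disc)
  areas <- vapply(discs, `[[`, 0, "area_um2")
  expect_true(areas[1] < 0.05 && areas[2] >= 0.05 && areas[3] < 10 &&
                areas[4] > 10)
  kept <- filter_clusters(discs)
  expect_length(kept, 2)

  expect_error(filter_clusters(discs, area_gate_um2 = c(10, 0.05)),
               "inverted")
})

test_that("filtering is monotone in the gates", {
  set.seed(21)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  cl <- label_clusters(m, full_roi(64))
  wide <- filter_clusters(cl, c(0.001, 50), c(0.01, 1))
  narrow <- filter_clusters(cl, c(0.01, 10), c(0.10, 1))
  expect_true(length(narrow) <= length(wide))
  key <- function(x) paste(x$pixel_set[1, ], collapse = ",")
  expect_true(all(vapply(narrow, key, "") %in% vapply(wide, key, "")))
})

test_that("roi_stats implements the zero-puncta rule and the area identity", {
  r <- full_roi(20)
  s0 <- roi_stats(list(), r, 64)
  expect_equal(s0$n_clusters, 0)
  expect_equal(s0$density_per_100um2, 0)
  expect_true(is.na(s0$mean_size_um2))
  expect_equal(s0$percent_area, 0)

  # ROI of known area with clusters of known coverage
  m <- matrix(FALSE, 20, 20); m[2:5, 2:5] <- TRUE; m[10:13, 10:13] <- TRUE
  cl <- label_clusters(m, r)
  s <- roi_stats(cl, r, 64)
  expect_equal(s$n_clusters, 2)
  expect_equal(s$percent_area, 100 * 32 / 400)
  # exact identity: percent_area * roi_area / 100 = total cluster area
  expect_equal(s$percent_area * s$roi_area_um2 / 100,
               sum(vapply(cl, `[[`, 0, "area_um2")))
  expect_equal(s$density_per_100um2, 2 / (400 * 0.064^2) * 100)
})

test_that("planted per-ROI density is recovered across replicate ROIs", {
  sc <- test_scene()
  cfg <- sc$config
  res <- quantify_channel(sc$channels[[cfg$subunit_label]],
                          rois_from_labels(sc$roi_labels, sc$sidecar),
                          rolling_ball_radius_px = 12)
  ais <- res[res$location_class == "AIS", ]
  expect_lt(abs(mean(ais$density_per_100um2) -
                  cfg$ais_puncta_density_per_100um2) /
              cfg$ais_puncta_density_per_100um2, 0.15)
})
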