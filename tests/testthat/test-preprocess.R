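test_that("rolling ball removes flat and smooth backgrounds", {
  img <- calibrated_image(matrix(100, 80, 80), 64)
  out <- rolling_ball_subtract(img, 50)
  expect_true(all(out$pixels == 0))

  # isolated bright pixel survives: the ball cannot enter a 1-px spike
  m <- matrix(0, 120, 120); m[60, 60] <- 200
  out <- rolling_ball_subtract(calibrated_image(m, 64), 50)
  expect_gte(out$pixels[60, 60], 199)

  # linear ramp is background; planted narrow spots are signal
  n <- 512
  ramp <- matrix(rep(seq(0, 50, length.out = n), each = n), n, n)
  spots <- matrix(0, n, n)
  centers <- cbind(c(100, 250, 400), c(120, 300, 450))
  for (k in 1:3) {
    rr <- (centers[k, 1] - 6):(centers[k, 1] + 6)
    cc <- (centers[k, 2] - 6):(centers[k, 2] + 6)
    d2 <- outer((rr - centers[k, 1])^2, (cc - centers[k, 2])^2, "+")
    spots[rr, cc] <- spots[rr, cc] + 80 * exp(-d2 / (2 * 2.5^2))
  }
  out <- rolling_ball_subtract(calibrated_image(ramp + spots, 64), 50)
  bg_only <- out$pixels[abs(spots) < 1e-9]
  expect_lt(max(bg_only), 5)
  for (k in 1:3)
    expect_gte(out$pixels[centers[k, 1], centers[k, 2]], 0.7 * 80)
})

test_that("rolling ball equals the shift-accumulate opening oracle exactly", {
  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(runif(64 * 64, 0, 255), 64, 64)
    img <- calibrated_image(m, 64)
    out <- rolling_ball_subtract(img, 9)
    expect_identical(out$pixels, oracle_rolling_ball(m, 9))
  }
})

test_that("rolling ball output never exceeds the input", {
  set.seed(8)
  m <- matrix(rpois(96 * 96, 40), 96, 96)
  out <- rolling_ball_subtract(calibrated_image(m, 64), 15)
  expect_true(all(out$pixels <= m))
  expect_true(all(out$pixels >= 0))
  expect_error(rolling_ball_subtract(calibrated_image(matrix(1, 8, 8), 64),
                                     2000), "exceeds")
})

test_that("triangle bin matches the brute-force geometry on a known case", {
  counts <- c(1000, 900, 700, 400, 150, 40, 10, 5, 2, 1)
  expect_identical(triangle_bin(counts), oracle_triangle_bin(counts))
})

test_that("triangle bin equals the brute-force oracle on random histograms", {
  set.seed(123)
  for (i in 1:500) {
    n <- sample(8:256, 1)
    shape <- sample(c("decay", "peak_low", "peak_high", "uniform"), 1)
    counts <- switch(shape,
      decay = round(1000 * exp(-seq(0, 6, length.out = n)) *
                      runif(n, 0.5, 1.5)),
      peak_low = round(c(1000, 500, rpois(n - 2, 20)) * runif(n, 0.5, 1.5)),
      peak_high = rev(round(1000 * exp(-seq(0, 6, length.out = n)) *
                              runif(n, 0.5, 1.5))),
      uniform = rpois(n, 50))
    expect_identical(triangle_bin(counts), oracle_triangle_bin(counts))
  }
})

test_that("triangle threshold handles degenerate and sparse images", {
  img <- calibrated_image(matrix(7, 16, 16), 64)
  res <- triangle_threshold(img)
  expect_false(any(res$mask$pixels))
  expect_equal(res$threshold, 7)
})

test_that("thresholded masks satisfy the strict-inequality invariant", {
  sc <- test_scene()
  sub <- rolling_ball_subtract(sc$channels[[sc$config$subunit_label]], 12)
  res <- triangle_threshold(sub)
  expect_true(all(sub$pixels[res$mask$pixels] > res$threshold))
  # planted foreground fraction is recovered within a broad factor
  planted <- sum(sc$truth$rois$percent_area[
    sc$truth$rois$channel == sc$config$subunit_label] / 100 *
      sc$truth$rois$roi_area_um2[
        sc$truth$rois$channel == sc$config$subunit_label])
  px_um2 <- (sc$config$pixel_size_nm / 1000)^2
  measured_px <- sum(res$mask$pixels)
  planted_px <- planted / px_um2
  expect_gt(measured_px, 0.5 * planted_px)
})

test_that("Costes auto-threshold reproduces its limiting cases", {
  set.seed(31)
  m <- matrix(runif(64 * 64, 10, 200), 64, 64)
  imgA <- calibrated_image(m, 64)
  imgB <- calibrated_image(m, 64)      # B = A exactly
  r <- roi(matrix(TRUE, 64, 64), "r", "AIS")
  th <- costes_auto_threshold(imgA, imgB, r)
  expect_lte(th$threshold_a, min(m))
  expect_equal(sum(m > th$threshold_a), length(m))

  # independent noise: thresholds near the top, little retained
  retained <- replicate(20, {
    a <- matrix(runif(48 * 48, 0, 255), 48, 48)
    b <- matrix(runif(48 * 48, 0, 255), 48, 48)
    r2 <- roi(matrix(TRUE, 48, 48), "r", "AIS")
    th <- costes_auto_threshold(calibrated_image(a, 64),
                                calibrated_image(b, 64), r2)
    mean(a > th$threshold_a & b > th$threshold_b)
  })
  expect_lt(median(retained), 0.20)

  # planted colocalized spots on zero background are always retained
  a <- matrix(0, 64, 64); a[10:14, 10:14] <- 150; a[40:44, 40:44] <- 220
  a <- a + matrix(runif(64 * 64, 0, 1e-3), 64, 64)  # break zero variance
  b <- a
  r3 <- roi(matrix(TRUE, 64, 64), "r", "AIS")
  th <- costes_auto_threshold(calibrated_image(a, 64),
                              calibrated_image(b, 64), r3)
  expect_true(all(a[a > 100] > th$threshold_a))

  # degenerate: constant channel
  expect_error(costes_auto_threshold(
    calibrated_image(matrix(5, 8, 8), 64),
    calibrated_image(matrix(runif(64), 8, 8), 64),
    roi(matrix(TRUE, 8, 8), "r", "AIS")), "variance")
})
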