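test_that("contrast filtering suppresses small structures, preserves barrels", {
  # noiseless disk: filtering is (nearly) the identity up to monotone rescale
  img <- disk_image(128, list(c(64, 64)), 40)
  f <- preprocess_barrel_image(img, pixel_size = 4)
  ref <- (img - min(img)) / diff(range(img))
  expect_gt(mean(abs(f - ref) < 1e-6), 0.995)
  # dark vessel disks are suppressed >= 5x relative to the barrel contrast
  imgv <- img
  for (ctr in list(c(40, 40), c(90, 80), c(64, 60))) {
    dx2 <- (seq_len(128) - ctr[1])^2; dy2 <- (seq_len(128) - ctr[2])^2
    imgv[outer(dx2, dy2, "+") <= 2.5^2] <- 0.05
  }
  fv <- preprocess_barrel_image(imgv, pixel_size = 4)
  vessel_px <- cbind(c(40, 90, 64), c(40, 80, 60))
  barrel_contrast_before <- 0.8 - 0.4
  vessel_contrast_before <- abs(imgv[40, 40] - 0.8)
  vessel_contrast_after <- max(abs(fv[vessel_px] - fv[64, 64]))
  barrel_contrast_after <- abs(fv[64, 64] - fv[5, 5])
  expect_gt((vessel_contrast_before / barrel_contrast_before) /
              max(vessel_contrast_after / barrel_contrast_after, 1e-6), 5)
  # pure noise: variance along a line profile is reduced
  set.seed(3)
  noise <- matrix(runif(128 * 128, 0.3, 0.7), 128, 128)
  fn <- preprocess_barrel_image(noise, pixel_size = 4)
  fn_raw <- min(noise) + fn * diff(range(noise))
  expect_lt(var(fn_raw[, 64]), var(noise[, 64]))
  expect_warning(preprocess_barrel_image(matrix(0.5, 10, 10)), "constant")
})

test_that("Voronoi-confined segmentation recovers separated disks", {
  img <- disk_image(128, list(c(40, 64), c(95, 64)), c(22, 18),
                    noise = 0.03, seed = 2)
  st <- section_stack(array(rep(img, 5), c(128, 128, 5)), z = 1:5,
                      pixel_size = 4)
  seeds <- seed_set(c("C1", "C2"), x = c(39 * 4, 94 * 4),
                    y = c(63 * 4, 63 * 4))
  segs <- segment_barrels(st, seeds)
  a1 <- barrelfield:::polygon_area(segs$C1$contours[[1]])
  a2 <- barrelfield:::polygon_area(segs$C2$contours[[1]])
  expect_lt(abs(a1 / (pi * (22 * 4)^2) - 1), 0.02)
  expect_lt(abs(a2 / (pi * (18 * 4)^2) - 1), 0.02)
  # confinement: every contour stays inside its seed's Voronoi region
  co <- barrelfield:::stack_coords(st)
  vr <- barrelfield:::voronoi_regions(seeds, co$x, co$y)
  for (k in 1:2) {
    poly <- segs[[k]]$contours[[1]]
    ix <- pmin(pmax(round((poly[, 1] - co$x[1]) / 4) + 1, 1), 128)
    iy <- pmin(pmax(round((poly[, 2] - co$y[1]) / 4) + 1, 1), 128)
    expect_true(all(vr[cbind(ix, iy)] == k))
  }
})

test_that("touching disks are split at the Voronoi boundary", {
  img <- disk_image(128, list(c(52, 64), c(76, 64)), c(14, 14))
  st <- section_stack(array(img, c(128, 128, 1)), z = 1, pixel_size = 4)
  seeds <- seed_set(c("B1", "B2"), x = c(51 * 4, 75 * 4),
                    y = c(63 * 4, 63 * 4))
  segs <- segment_barrels(st, seeds, closing_radius = 2)
  # boundary between the seeds is at x = 63 * 4 = 252 um
  expect_lte(max(segs$B1$contours[[1]][, 1]), 252 + 4)
  expect_gte(min(segs$B2$contours[[1]][, 1]), 252 - 4)
})

test_that("radial ratio-of-means profiles behave as step/blur/uniform theory", {
  # ideal step-edge disk (radius 30 px = 120 um): the ratio peaks at the
  # true extent and declines beyond it
  img <- disk_image(160, list(c(80, 80)), 30)
  p <- radial_quality_profile(img, center = c(79 * 4, 79 * 4),
                              pixel_size = 4, radii = seq(40, 280, 8),
                              r_out = 300)
  expect_lt(abs(p$extent_um / 120 - 1), 0.08)
  expect_lt(p$ratio[length(p$ratio)], max(p$ratio) * 0.8)
  expect_lt(p$slope, 0)
  # blurred disk: peak estimate still close to the half-maximum radius
  blur <- EBImage::filter2(img, matrix(1 / 81, 9, 9))
  pb <- radial_quality_profile(as.matrix(blur), center = c(79 * 4, 79 * 4),
                               pixel_size = 4, radii = seq(40, 280, 4),
                               r_out = 300)
  expect_lt(abs(pb$extent_um / 120 - 1), 0.08)
  # declining branch: relative size of the true extent vs an oversized
  # segmented contour is < 1
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  big_contour <- cbind(79 * 4 + 160 * cos(th), 79 * 4 + 160 * sin(th))
  pc <- radial_quality_profile(img, contour = big_contour,
                               center = c(79 * 4, 79 * 4), pixel_size = 4,
                               radii = seq(40, 280, 8), r_out = 300)
  expect_lt(pc$relative_size, 1)
  # uniform image: ratio identically 1
  pu <- radial_quality_profile(matrix(0.5, 160, 160), center = c(316, 316),
                               pixel_size = 4, radii = seq(40, 280, 8),
                               r_out = 300)
  expect_true(all(abs(pu$ratio - 1) < 1e-9))
})

test_that("minimal-contour optimization shrinks caps and leaves mid-barrel alone", {
  # mid-barrel: sharp disk, regular contour is already optimal
  img <- disk_image(128, list(c(64, 64)), 25, noise = 0.02, seed = 4)
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  contour <- cbind(63 * 4 + 100 * cos(th), 63 * 4 + 100 * sin(th))
  out <- optimize_minimal_contour(img, contour, pixel_size = 4)
  expect_false(out$improved)
  expect_equal(out$contour, contour)
  # cap section: faint small blob inside an oversized contour
  cap <- disk_image(128, list(c(64, 64)), 10, fg = 0.62, bg = 0.4,
                    noise = 0.02, seed = 5)
  out2 <- optimize_minimal_contour(cap, contour, pixel_size = 4)
  expect_true(out2$improved)
  expect_lt(barrelfield:::polygon_area(out2$contour),
            barrelfield:::polygon_area(contour))
  # blank section
  out3 <- optimize_minimal_contour(img, NULL, pixel_size = 4)
  expect_true(out3$flagged)
  expect_null(out3$contour)
})

test_that("vertical extent is read off the diameter profile minima", {
  mk_stack <- function(d) {
    th <- seq(0, 2 * pi, length.out = 25)[-25]
    contour_stack(lapply(d / 2, function(r) cbind(r * cos(th), r * sin(th))),
                  z = seq_along(d) * 10)
  }
  # barrel spanning sections 4-11 (diameter dips at 4 and 11, maximal
  # mid-barrel) with flanking septum sections where d re-increases
  d <- c(320, 300, 270, 250, 270, 300, 330, 340, 310, 270, 250, 270, 300,
         320)
  ext <- detect_vertical_extent(mk_stack(d))
  expect_equal(ext$bt_section, 4)
  expect_equal(ext$bb_section, 11)
  expect_equal(ext$confidence, "high")
  # same stack with z increasing pia-ward
  extr <- detect_vertical_extent(mk_stack(rev(d)), pia_end = "last")
  expect_equal(extr$bt_section, length(d) - 4 + 1)
  expect_equal(extr$bb_section, length(d) - 11 + 1)
  # constant profile: endpoints, low confidence
  ext2 <- detect_vertical_extent(mk_stack(rep(200, 7)))
  expect_equal(c(ext2$bt_section, ext2$bb_section), c(1, 7))
  expect_equal(ext2$confidence, "low")
  expect_error(detect_vertical_extent(mk_stack(c(100, 200, 100))), "5")
})

test_that("macro landmarks: pia, WM and vessels from a low-resolution section", {
  n <- 200
  img <- matrix(0.9, n, n)
  dx2 <- (seq_len(n) - 100)^2
  dd <- outer(dx2, dx2, "+")
  img[dd <= 80^2] <- 0.5       # tissue
  img[dd <= 35^2] <- 0.9       # interior hole (WM boundary)
  img[96:98, 60:62] <- 0.05    # one vessel
  lm <- extract_macro_landmarks(img, pixel_size = 20)
  r_pia <- sqrt(rowSums(sweep(lm$pia, 2, c(99 * 20, 99 * 20))^2))
  expect_lt(abs(mean(r_pia) / (80 * 20) - 1), 0.02)
  expect_false(is.null(lm$wm))
  r_wm <- sqrt(rowSums(sweep(lm$wm, 2, c(99 * 20, 99 * 20))^2))
  expect_lt(abs(mean(r_wm) / (35 * 20) - 1), 0.05)
  expect_gte(nrow(lm$vessels), 1)
  expect_false(lm$clipped)
  # tissue touching the border is flagged
  img2 <- matrix(0.9, n, n)
  img2[1:120, ] <- 0.5
  lm2 <- extract_macro_landmarks(img2, pixel_size = 20)
  expect_true(lm2$clipped)
  expect_error(extract_macro_landmarks(matrix(0.9, 50, 50), pixel_size = 20),
               "tissue")
})
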