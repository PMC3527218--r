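zero_offsets <- function() {
  o <- landmark_offsets()
  o[, -1] <- 0
  o
}

test_that("global registration is exact for landmarks already in the standard frame", {
  model <- cohort_model()
  gn <- generate_neuron(model, "C2", 800, "pyramidal", seed = 31,
                        cutting_angle = 0, landmark_noise_sd = 0,
                        offsets = zero_offsets(), pia_offset = 0,
                        first_section_offset = 0)
  # undo the (translation-only) cutting transform
  g <- register_global(gn$landmarks, model)
  expect_lt(g$rotation_deg, 1e-4)
  expect_equal(g$transform$R, diag(3), tolerance = 1e-6)
})

test_that("a known cutting rotation is recovered within a degree", {
  model <- cohort_model()
  gn <- generate_neuron(model, "D2", 1100, "pyramidal", seed = 32,
                        cutting_angle = 15, landmark_noise_sd = 0)
  res <- register_neuron(gn$neuron, gn$landmarks, model)
  expect_lt(abs(res$global_rotation_deg - 15), 1)
  # with default landmark noise, still within a degree
  gn2 <- generate_neuron(model, "D2", 1100, "pyramidal", seed = 33,
                         cutting_angle = 15)
  res2 <- register_neuron(gn2$neuron, gn2$landmarks, model)
  expect_lt(abs(res2$global_rotation_deg - 15), 1)
  expect_error(register_global(
    experiment_landmarks(list(C2 = list(bc = c(0, 0, 0))), "C2",
                         c(0, 0, 0), c(0, 0, -1900)), model), "3")
})

test_that("cutting-angle ensemble statistics are recovered", {
  model <- cohort_model()
  true_ang <- rec_ang <- numeric(30)
  for (i in 1:30) {
    gn <- generate_neuron(model, "C2", 900, "pyramidal", seed = 500 + i)
    res <- register_global(gn$landmarks, model)
    true_ang[i] <- gn$truth$cutting_angle
    rec_ang[i] <- res$rotation_deg
  }
  expect_lt(mean(abs(rec_ang - true_ang)), 1.5)
  expect_lt(abs(mean(rec_ang) - 14.0), 7.6 / sqrt(30) * 3)
})

test_that("orientation refinement aligns the apical inertia axis with the field", {
  model <- cohort_model()
  gn0 <- generate_neuron(model, "C2", 900, "pyramidal", seed = 35,
                         cutting_angle = 0, landmark_noise_sd = 0,
                         offsets = zero_offsets(), pia_offset = 0,
                         first_section_offset = 0)
  # bring the scene into the model frame first (step 1; exact here)
  g0 <- register_global(gn0$landmarks, model)
  gn <- gn0
  gn$neuron <- barrelfield:::transform_neuron(gn0$neuron, g0$transform)
  r0 <- refine_orientation(gn$neuron, model)
  expect_lt(r0$rotation_deg, 2)                 # already aligned
  # apical tilted 10 degrees from the local axis
  soma <- as.numeric(gn$neuron[gn$neuron$parent == -1, c("x", "y", "z")])
  R <- rotation_about_axis(c(0, 1, 0), 10 * pi / 180)
  tilt <- barrelfield:::compose_rigid(
    rigid_transform(diag(3), soma),
    barrelfield:::compose_rigid(rigid_transform(R),
                                rigid_transform(diag(3), -soma)))
  tilted <- barrelfield:::transform_neuron(gn$neuron, tilt)
  r10 <- refine_orientation(tilted, model)
  expect_lt(abs(r10$rotation_deg - 10), 1)
  # stellate: descending-axon fallback
  gs0 <- generate_neuron(model, "C2", 900, "stellate", seed = 36,
                         cutting_angle = 0, landmark_noise_sd = 0,
                         offsets = zero_offsets(), pia_offset = 0,
                         first_section_offset = 0)
  gsg <- register_global(gs0$landmarks, model)
  sneuron <- barrelfield:::transform_neuron(gs0$neuron, gsg$transform)
  stilted <- barrelfield:::transform_neuron(sneuron, tilt)
  rs <- refine_orientation(stilted, model)
  expect_false(rs$flagged)
  expect_lt(abs(rs$rotation_deg - 10), 3)
  # neuron with neither apical nor descending axon: flagged, unchanged
  bare <- neuron_morphology(data.frame(
    id = 1:3, type = c(1, 3, 3),
    x = c(0, 50, -60), y = c(0, 10, 5), z = c(0, 0, 4),
    radius = 1, parent = c(-1, 1, 1)))
  rb <- refine_orientation(bare, c(0, 0, 1))
  expect_true(rb$flagged)
})

test_that("landmark depth correction reproduces the D2 arithmetic", {
  model <- cohort_model()
  colD2 <- barrelfield:::model_column(model, "D2")
  a <- colD2$axis
  lm <- experiment_landmarks(
    barrels = list(D2 = list(bc = colD2$bc,
                             bt = colD2$pia - a * 594,
                             bb = colD2$pia - a * 947)),
    principal = "D2",
    pia_point = colD2$pia + a * 59,
    wm_point = colD2$pia - a * 1950,
    first_section_pia = TRUE)
  corr <- correct_landmark_depths(lm, model)
  depth <- function(p) sum((colD2$pia - p) * a)
  expect_equal(depth(corr$barrels$D2$bb), 947 - 59, tolerance = 1e-9)
  expect_equal(depth(corr$barrels$D2$bt), 594 - 68, tolerance = 1e-9)
  expect_equal(depth(corr$wm_point), 1950 + 7, tolerance = 1e-9)
  expect_equal(depth(corr$pia_point), 0, tolerance = 1e-9)
  # zero offsets leave landmarks unchanged
  corr0 <- correct_landmark_depths(lm, model, offsets = zero_offsets(),
                                   pia_offset = 0, first_section_offset = 0)
  expect_equal(corr0$barrels$D2$bb, lm$barrels$D2$bb)
  expect_equal(corr0$pia_point, lm$pia_point)
  # generator round trip: +39/+20 pia bias corrected to within 2 um
  # (after the global registration step brings landmarks into the model frame)
  gn <- generate_neuron(model, "D2", 1000, "pyramidal", seed = 37,
                        cutting_angle = 0, landmark_noise_sd = 0)
  g <- register_global(gn$landmarks, model)
  lm_reg <- barrelfield:::transform_landmarks(gn$landmarks, g$transform)
  corrg <- correct_landmark_depths(lm_reg, model)
  expect_lt(abs(sum((colD2$pia - corrg$pia_point) * a)), 2)
})

test_that("stepwise scaling matches landmarks, is continuous and axial-only", {
  model <- cohort_model()
  col <- barrelfield:::model_column(model, "C2")
  a <- col$axis
  # traced intervals (400, 300, 1300) vs standard intervals
  std_int <- c(col$bt_depth, col$bb_depth - col$bt_depth,
               col$column_height - col$bb_depth)
  lm <- experiment_landmarks(
    barrels = list(C2 = list(bc = col$bc, bt = col$pia - a * 400,
                             bb = col$pia - a * 700)),
    principal = "C2",
    pia_point = col$pia, wm_point = col$pia - a * 2000)
  nodes <- data.frame(id = 1:4, type = c(1, 4, 4, 2),
                      x = 0, y = 0, z = 0, radius = 1, parent = c(-1, 1, 2, 1))
  pts <- rbind(col$pia - a * 900, col$pia - a * 400, col$pia - a * 100,
               col$pia - a * 700 + c(30, 40, 0))
  neuron <- barrelfield:::set_neuron_coords(neuron_morphology(nodes), pts)
  sc <- stepwise_scale(neuron, lm, model)
  expect_equal(unname(sc$factors),
               unname(std_int / c(400, 300, 1300)), tolerance = 1e-9)
  # landmarks map onto the standard depths
  expect_equal(sc$map(c(0, 400, 700, 2000)),
               c(0, col$bt_depth, col$bb_depth, col$column_height),
               tolerance = 1e-9)
  # continuity at the knots
  eps <- 1e-7
  expect_lt(abs(sc$map(400 - eps) - sc$map(400 + eps)), 1e-5)
  expect_lt(abs(sc$map(700 - eps) - sc$map(700 + eps)), 1e-5)
  # tangential coordinates are untouched
  rel <- sweep(barrelfield:::neuron_coords(sc$neuron), 2, col$pia)
  t_ <- as.numeric(rel %*% (-a))
  lat_after <- rel + t_ %*% t(a)
  rel0 <- sweep(pts, 2, col$pia)
  t0 <- as.numeric(rel0 %*% (-a))
  lat_before <- rel0 + t0 %*% t(a)
  expect_equal(unname(lat_after), unname(lat_before), tolerance = 1e-9)
  # degenerate traced interval errors
  bad <- lm
  bad$barrels$C2$bb <- bad$barrels$C2$bt
  expect_error(stepwise_scale(neuron, bad, model), "interval")
})

test_that("the rigid steps preserve path length; scaling acts only axially", {
  model <- cohort_model()
  gn <- generate_neuron(model, "C2", 900, "pyramidal", seed = 38,
                        cutting_angle = 12)
  len0 <- barrelfield:::neuron_path_length(gn$neuron)
  g <- register_global(gn$landmarks, model)
  n1 <- barrelfield:::transform_neuron(gn$neuron, g$transform)
  expect_equal(barrelfield:::neuron_path_length(n1) / len0, 1,
               tolerance = 1e-9)
  r <- refine_orientation(n1, model)
  expect_equal(barrelfield:::neuron_path_length(r$neuron) / len0, 1,
               tolerance = 1e-9)
})

test_that("end-to-end registration places somata within 30 um at default noise", {
  model <- cohort_model()
  errs <- vapply(1:12, function(i) {
    gn <- generate_neuron(model, "D2", 1100, "pyramidal", seed = 600 + i)
    res <- register_neuron(gn$neuron, gn$landmarks, model)
    sqrt(sum((res$soma - gn$truth$soma)^2))
  }, numeric(1))
  expect_lt(mean(errs), 30)
})

test_that("the registration report mirrors depths, factors and precision", {
  model <- cohort_model()
  gn <- generate_neuron(model, "C2", 856, "pyramidal", seed = 40,
                        cutting_angle = 10)
  res <- register_neuron(gn$neuron, gn$landmarks, model)
  rep <- registration_report(res)
  expect_equal(rep$registered_depth, res$soma_depth)
  expect_equal(rep$deviation, rep$recording_depth - rep$registered_depth)
  prec <- column_precision()
  expect_equal(rep$se, prec$se[prec$label == "C2"])
  expect_equal(rep$rmse, prec$rmse[prec$label == "C2"])
  # no recording depth: deviation empty
  gn$landmarks$recording_depth <- NA_real_
  res2 <- register_neuron(gn$neuron, gn$landmarks, model)
  expect_true(is.na(registration_report(res2)$deviation))
  # recording-depth ensemble: generator bias of -46 um is visible
  devs <- vapply(1:25, function(i) {
    g <- generate_neuron(model, "C2", 900, "pyramidal", seed = 700 + i)
    r <- register_neuron(g$neuron, g$landmarks, model)
    registration_report(r)$deviation
  }, numeric(1))
  expect_lt(abs(mean(devs) - (-46)), 3 * 102 / sqrt(25) + 10)
})
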