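random_landmarks <- function(seed = 1, n = 16) {
  set.seed(seed)
  pts <- cbind(runif(n, -1000, 1000), runif(n, -1000, 1000),
               runif(n, -900, -400))
  rownames(pts) <- paste0("p", seq_len(n))
  pts
}

test_that("GPA recovers copies under known rigid transforms", {
  base <- random_landmarks(1)
  sets <- lapply(1:4, function(i) {
    set.seed(100 + i)
    tf <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 1)),
                          runif(3, -300, 300))
    apply_rigid(tf, base)
  })
  g <- gpa_register(sets)
  expect_lt(g$state$S[length(g$state$S)], 1e-6)
  # aligned sets coincide up to global pose
  for (u in 2:4) {
    expect_equal(g$aligned[[u]], g$aligned[[1]], tolerance = 1e-6)
  }
  # transforms are rigid: pairwise distances preserved exactly
  for (u in 1:4) {
    expect_equal(as.matrix(dist(g$aligned[[u]])), as.matrix(dist(base)),
                 tolerance = 1e-6)
  }
})

test_that("GPA objective is non-increasing and converges fast when aligned", {
  base <- random_landmarks(2)
  sets <- lapply(1:3, function(i) base)
  g <- gpa_register(sets)
  expect_lte(g$state$iterations, 2)
  expect_lt(g$state$S[length(g$state$S)], 1e-9)
  # identity transforms
  for (tf in g$transforms) {
    expect_equal(tf$R, diag(3), tolerance = 1e-9)
    expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-6)
  }
  # noisy case: S non-increasing every iteration
  sets2 <- lapply(1:5, function(i) {
    set.seed(200 + i)
    tf <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 0.5)),
                          runif(3, -200, 200))
    apply_rigid(tf, base + matrix(rnorm(length(base), 0, 40), nrow(base)))
  })
  g2 <- gpa_register(sets2)
  expect_true(all(diff(g2$state$S) <= 1e-6))
  expect_error(gpa_register(sets[1]), "at least 2")
})

test_that("GPA with isotropic 30 um noise leaves ~30 um per-point scatter", {
  base <- random_landmarks(3, n = 48)
  sets <- lapply(1:12, function(i) {
    set.seed(300 + i)
    tf <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 0.4)),
                          runif(3, -200, 200))
    apply_rigid(tf, base + matrix(rnorm(length(base), 0, 30), nrow(base)))
  })
  g <- gpa_register(sets)
  resid <- simplify2array(g$aligned)               # n x 3 x 12
  percoord <- apply(resid, c(1, 2), sd)
  sd_point <- sqrt(mean(percoord^2))
  expect_lt(abs(sd_point / 30 - 1), 0.15)
})

test_that("missing barrels are handled per correspondence", {
  base <- random_landmarks(4, n = 10)
  s1 <- base
  s2 <- apply_rigid(rigid_transform(rotation_about_axis(c(0, 0, 1), 0.2),
                                    c(50, 0, 0)), base)[-c(1, 2), ]
  s3 <- base[-10, ]
  g <- gpa_register(list(s1, s2, s3))
  expect_lt(g$state$S[length(g$state$S)], 1e-6)
  expect_equal(nrow(g$aligned[[2]]), 8)
})

test_that("the standard model of a duplicated field is that field, circularized", {
  f <- cohort_fields()[[1]]
  suppressWarnings(model <- build_standard_model(list(f, f)))
  # per-label areas and depths equal the field's own
  for (l in c("C2", "D1", "E4")) {
    b <- f$barrels[[l]]
    expect_equal(model$landmarks[l, "area"], b$geometry$area)
    ax <- b$column$axis
    expect_equal(model$landmarks[l, "bt_depth"],
                 sum((b$column$pia_point - b$geometry$bt) * ax),
                 tolerance = 1e-6)
    expect_equal(model$landmarks[l, "column_height"],
                 b$column$column_height, tolerance = 1e-6)
  }
  # standard contours are circles with the mean area
  expect_equal(model$landmarks["C2", "radius"],
               sqrt(f$barrels$C2$geometry$area / pi))
})

test_that("the standard model is pose-equivariant (C2-frame invariant)", {
  fields <- cohort_registration()$fields
  m1 <- build_standard_model(fields, orientation_spacing = 200)
  tf <- rigid_transform(rotation_about_axis(c(1, 1, 0), 0.5),
                        c(300, -100, 50))
  m2 <- build_standard_model(lapply(fields, transform_field, tf = tf),
                             orientation_spacing = 200)
  expect_equal(m1$landmarks$bc.x, m2$landmarks$bc.x, tolerance = 1e-6)
  expect_equal(m1$landmarks$bt.z, m2$landmarks$bt.z, tolerance = 1e-6)
  expect_equal(m1$landmarks$orientation_deg, m2$landmarks$orientation_deg,
               tolerance = 1e-6)
})

test_that("orientation field interpolates the three nearest BC axes", {
  model <- cohort_model()
  of <- model$orientation_field
  expect_equal(of$spacing, 50)
  # at a BC the field vector matches that column's axis closely
  for (l in c("C2", "B3", "E1")) {
    col <- barrelfield:::model_column(model, l)
    v <- orientation_at(of, col$bc)
    ang <- barrelfield:::deg(barrelfield:::angle_between(v, col$axis))
    expect_lt(ang, 2)
  }
  # all axes parallel -> uniform field
  f <- toy_field(list(C2 = toy_barrel("C2", 0), C3 = toy_barrel("C3", 450),
                      D2 = toy_barrel("D2", 0)))
  suppressWarnings(mflat <- build_standard_model(list(f, f),
                                                 orientation_spacing = 200))
  vecs <- mflat$orientation_field$vectors
  expect_lt(max(abs(sweep(vecs, 2, c(0, 0, 1)))), 1e-6)
  # two axes at +-10 degrees: midpoint vector at 0 +- 0.5 degrees
  a1 <- c(sin(rad10 <- 10 * pi / 180), 0, cos(rad10))
  a2 <- c(-sin(rad10), 0, cos(rad10))
  mid <- nrm(a1 / 1 + a2 / 1)
  expect_lt(barrelfield:::deg(barrelfield:::angle_between(mid, c(0, 0, 1))),
            0.5)
})

test_that("landmark variability: zeros for identical fields, SE arithmetic", {
  f <- cohort_fields()[[2]]
  suppressWarnings(model <- build_standard_model(list(f, f, f)))
  fields <- list(f, f, f)
  v <- landmark_variability(fields, model)
  expect_lt(max(c(v$table$sd_row, v$table$sd_arc, v$table$sd_axis)), 1e-6)
  expect_equal(standard_error(35, 12), 10.1, tolerance = 0.01)
})

test_that("injected anisotropic landmark noise is recovered within 20%", {
  f0 <- cohort()[[1]]$truth$field   # unposed: x ~ row, y ~ arc direction
  noise <- c(row = 60, arc = 30, axis = 20)
  fields <- lapply(1:12, function(i) {
    set.seed(400 + i)
    f <- f0
    f$barrels <- lapply(f$barrels, function(b) {
      ax <- b$column$axis
      d_bt <- c(1, 0, 0) * rnorm(1, 0, noise["row"]) +
        c(0, 1, 0) * rnorm(1, 0, noise["arc"]) + ax * rnorm(1, 0, noise["axis"])
      d_bb <- c(1, 0, 0) * rnorm(1, 0, noise["row"]) +
        c(0, 1, 0) * rnorm(1, 0, noise["arc"]) + ax * rnorm(1, 0, noise["axis"])
      b$geometry$bt <- b$geometry$bt + d_bt
      b$geometry$bb <- b$geometry$bb + d_bb
      b$geometry$bc <- (b$geometry$bt + b$geometry$bb) / 2
      b
    })
    f
  })
  reg <- register_fields(fields)
  model <- build_standard_model(reg$fields, orientation_spacing = 200)
  v <- landmark_variability(reg$fields, model)
  rec <- colMeans(v$table[, c("sd_row", "sd_arc", "sd_axis")])
  expect_lt(abs(rec[["sd_row"]] / 60 - 1), 0.2)
  expect_lt(abs(rec[["sd_arc"]] / 30 - 1), 0.2)
  expect_lt(abs(rec[["sd_axis"]] / 20 - 1), 0.2)
})

test_that("quadrature precision combination reproduces the printed accuracies", {
  expect_equal(round(standard_error(15, 1) * 1.05), 16)
  expect_equal(round(registration_accuracy_3d(19, 14, 10)), 26)
  expect_equal(round(registration_accuracy_3d(19, 14, 28)), 37)
})
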