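# Ground-truth barrel field generator.
#
# The generator draws the measured column parameters (barrel area, BT depth,
# barrel height, pia-WM distance) per label from the per-column normal
# distributions of the printed cohort table (mean +- SD, n = 12) and places
# the columns on the somatotopic row/arc lattice underneath a curved pia.
# The pia is modeled as its osculating quadratic dome with two distinct
# curvature radii whose principal directions lie along the two diagonals of
# the map ("3-2-1" and "1-2-3" axes); this reproduces the observed diagonal
# anisotropy of the column tilts (up to ~17 deg along 3-2-1, ~3-6 deg along
# 1-2-3). Column axes are the local pia normals, so they converge towards
# the white matter; vessels run perpendicular to the pia.

#' Simulation parameters for synthetic barrel fields
#'
#' Defaults encode the study conditions: the printed cohort parameter table
#' as the per-label distribution, curvature radii of 4 mm along the 3-2-1
#' diagonal and 12 mm along the 1-2-3 diagonal (chosen to match the printed
#' column-orientation magnitudes), a 450 um row/arc lattice pitch, 50 um
#' across-animal lateral scatter of barrel centers and 8 vessels per mm^2.
#'
#' @param table per-label parameter table, defaults to [barrel_parameters()].
#' @param curvature_radius_321,curvature_radius_123 pia curvature radii (um)
#'   along the 3-2-1 and 1-2-3 diagonals; `Inf` gives a flat cortex.
#' @param arc_spacing,row_spacing lattice pitch, um.
#' @param bc_lateral_sd across-animal SD of barrel-center lattice positions
#'   in the tangential plane, um.
#' @param vessel_density vessels per mm^2 of tangential area.
#' @param vessel_angle_sd angular noise of vessel directions about the pia
#'   normal, degrees.
#' @param axis_angle_sd across-animal scatter of the column-axis
#'   orientation about the local pia normal, degrees (the observed
#'   across-animal axis variability of ~4.5 degrees combines this
#'   anatomical scatter with registration noise).
#' @param sd_scale multiplier on all table SDs (0 switches noise off).
#' @param pose `"random"` applies a random rigid pose per animal (unknown
#'   mounting/sectioning frame), `"identity"` leaves the field in the
#'   anatomical frame.
#' @return object of class `field_simulation_params`.
#' @export
field_simulation_params <- function(table = barrel_parameters(),
                                    curvature_radius_321 = 4000,
                                    curvature_radius_123 = 12000,
                                    arc_spacing = 450,
                                    row_spacing = 450,
                                    bc_lateral_sd = 50,
                                    vessel_density = 8,
                                    vessel_angle_sd = 2,
                                    axis_angle_sd = 3,
                                    sd_scale = 1,
                                    pose = c("random", "identity")) {
  pose <- match.arg(pose)
  sdcols <- grep("_sd$", names(table), value = TRUE)
  if (any(unlist(table[sdcols]) < 0)) stop("table SDs must be >= 0")
  thick <- max(table$column_height_mean)
  if (curvature_radius_321 <= thick || curvature_radius_123 <= thick)
    stop("curvature radii must exceed the cortex thickness")
  structure(list(table = table,
                 curvature_radius_321 = curvature_radius_321,
                 curvature_radius_123 = curvature_radius_123,
                 arc_spacing = arc_spacing, row_spacing = row_spacing,
                 bc_lateral_sd = bc_lateral_sd,
                 vessel_density = vessel_density,
                 vessel_angle_sd = vessel_angle_sd,
                 axis_angle_sd = axis_angle_sd,
                 sd_scale = sd_scale, pose = pose),
            class = "field_simulation_params")
}

# Pia height and unit upward normal of the quadratic dome. u/v are the
# diagonal coordinates: u along 3-2-1 (x - y), v along 1-2-3 (x + y).
pia_dome <- function(x, y, params) {
  ru <- params$curvature_radius_321; rv <- params$curvature_radius_123
  u <- (x - y) / sqrt(2); v <- (x + y) / sqrt(2)
  z <- -(u^2 / (2 * ru) + v^2 / (2 * rv))
  nx <- (u / ru + v / rv) / sqrt(2)
  ny <- (v / rv - u / ru) / sqrt(2)
  n <- cbind(nx, ny, 1)
  n <- n / sqrt(rowSums(n^2))
  list(z = z, normal = n)
}

# Regular-grid triangulation over given x/y breaks, z from function fz(x, y).
grid_mesh <- function(xs, ys, fz) {
  g <- expand.grid(x = xs, y = ys)
  z <- fz(g$x, g$y)
  nv <- length(xs)
  tri <- list()
  for (j in seq_len(length(ys) - 1)) {
    for (i in seq_len(nv - 1)) {
      a <- (j - 1) * nv + i
      tri[[length(tri) + 1]] <- c(a, a + 1, a + nv)
      tri[[length(tri) + 1]] <- c(a + 1, a + nv + 1, a + nv)
    }
  }
  surface_mesh(cbind(g$x, g$y, z), do.call(rbind, tri))
}

#' Generate one synthetic barrel field with ground truth
#'
#' Draws the per-label column parameters, constructs barrels as ellipsoidal
#' bodies of revolution about their (pia-normal) axes, builds pia/WM meshes
#' and pia-perpendicular vessels, and optionally applies a random rigid pose
#' (the per-animal mounting frame). Output is bit-reproducible for a fixed
#' seed.
#'
#' @param params a [field_simulation_params()].
#' @param seed integer random seed.
#' @param animal animal identifier stored in the field.
#' @return list with elements `field` (the posed [barrel_field()]), and
#'   `truth`: the drawn per-label parameter table (`parameters`), the
#'   unposed field (`field`), and the applied `pose` ([rigid_transform()]).
#' @export
generate_barrel_field <- function(params = field_simulation_params(),
                                  seed = 1, animal = paste0("sim", seed)) {
  stopifnot(inherits(params, "field_simulation_params"))
  set.seed(as.integer(seed))
  tab <- params$table
  s <- params$sd_scale
  n <- nrow(tab)

  drawn <- data.frame(
    label = tab$label,
    row = tab$row, arc = tab$arc,
    area = stats::rnorm(n, tab$area_mean, s * tab$area_sd),
    bt_depth = stats::rnorm(n, tab$bt_mean, s * tab$bt_sd),
    height = stats::rnorm(n, tab$height_mean, s * tab$height_sd),
    column_height = stats::rnorm(n, tab$column_height_mean,
                                 s * tab$column_height_sd),
    stringsAsFactors = FALSE
  )
  # keep draws physical
  drawn$area <- pmax(drawn$area, 2e4)
  drawn$bt_depth <- pmax(drawn$bt_depth, 200)
  drawn$height <- pmax(drawn$height, 100)
  drawn$bb_depth <- drawn$bt_depth + drawn$height
  drawn$column_height <- pmax(drawn$column_height, drawn$bb_depth + 300)
  drawn$x <- (drawn$arc - 2) * params$arc_spacing +
    stats::rnorm(n, 0, s * params$bc_lateral_sd)
  drawn$y <- (drawn$row - 2) * params$row_spacing +
    stats::rnorm(n, 0, s * params$bc_lateral_sd)
  # C2 anchors the frame: no lateral scatter there
  i2 <- which(drawn$label == "C2")
  drawn$x[i2] <- 0; drawn$y[i2] <- 0

  dome <- pia_dome(drawn$x, drawn$y, params)
  axis_c2 <- dome$normal[i2, ]

  barrels <- vector("list", n); names(barrels) <- drawn$label
  for (i in seq_len(n)) {
    p_pia <- c(drawn$x[i], drawn$y[i], dome$z[i])
    ax <- dome$normal[i, ]
    if (params$axis_angle_sd > 0 && s > 0) {
      # anatomical across-animal scatter of the axis about the pia normal
      tilt <- rad(stats::rnorm(1, 0, s * params$axis_angle_sd))
      az <- stats::runif(1, 0, 2 * pi)
      perp <- normalize(pracma_cross(ax, c(cos(az), sin(az), 0)))
      ax <- as.numeric(rotation_about_axis(perp, tilt) %*% ax)
    }
    bt <- p_pia - ax * drawn$bt_depth[i]
    bb <- p_pia - ax * drawn$bb_depth[i]
    wm <- p_pia - ax * drawn$column_height[i]
    r_max <- sqrt(drawn$area[i] / pi)
    # ellipsoidal radius profile along the axis, sections every 25 um
    depths <- seq(drawn$bt_depth[i], drawn$bb_depth[i], length.out = 15)
    half <- drawn$height[i] / 2
    mid <- (drawn$bt_depth[i] + drawn$bb_depth[i]) / 2
    e1 <- normalize(pracma_cross(ax, c(0, 1, 0)))
    e2 <- pracma_cross(ax, e1)
    theta <- seq(0, 2 * pi, length.out = 37)[-37]
    contours <- lapply(depths, function(d) {
      rr <- r_max * sqrt(pmax(1 - ((d - mid) / half)^2, 0.02))
      ctr <- p_pia - ax * d
      t(ctr + outer(e1, rr * cos(theta)) + outer(e2, rr * sin(theta)))
    })
    geom <- barrel_geometry(drawn$label[i], contours, drawn$area[i], bt, bb)
    col <- column_geometry(ax, p_pia, wm,
                           orientation_deg = deg(angle_between(ax, axis_c2)))
    barrels[[i]] <- list(geometry = geom, column = col)
  }

  ext_x <- range(drawn$x) + c(-600, 600)
  ext_y <- range(drawn$y) + c(-600, 600)
  xs <- seq(ext_x[1], ext_x[2], by = 150)
  ys <- seq(ext_y[1], ext_y[2], by = 150)
  pia_mesh <- grid_mesh(xs, ys, function(x, y) pia_dome(x, y, params)$z)

  # smooth WM surface through the per-column WM points (quadratic fit)
  wm_pts <- t(vapply(barrels, function(b) b$column$wm_point, numeric(3)))
  wfit <- stats::lm(z ~ x + y + I(x^2) + I(x * y) + I(y^2),
                    data = data.frame(x = wm_pts[, 1], y = wm_pts[, 2],
                                      z = wm_pts[, 3]))
  wm_mesh <- grid_mesh(xs, ys, function(x, y)
    stats::predict(wfit, data.frame(x = x, y = y)))

  # vessels: pia-perpendicular lines with small angular noise
  area_mm2 <- diff(ext_x) * diff(ext_y) * 1e-6
  nv <- max(1L, round(params$vessel_density * area_mm2))
  vx <- stats::runif(nv, ext_x[1], ext_x[2])
  vy <- stats::runif(nv, ext_y[1], ext_y[2])
  vd <- pia_dome(vx, vy, params)
  polylines <- lapply(seq_len(nv), function(k) {
    dir <- -vd$normal[k, ]
    if (params$vessel_angle_sd > 0 && s > 0) {
      tilt <- rad(abs(stats::rnorm(1, 0, params$vessel_angle_sd)))
      az <- stats::runif(1, 0, 2 * pi)
      perp <- normalize(pracma_cross(dir, c(cos(az), sin(az), 0)))
      dir <- as.numeric(rotation_about_axis(perp, tilt) %*% dir)
    }
    start <- c(vx[k], vy[k], vd$z[k])
    len <- stats::runif(1, 1000, 1800)
    t(start + outer(dir, seq(0, len, by = 150)))
  })

  field <- barrel_field(barrels, pia_mesh, wm_mesh, vessel_graph(polylines),
                        animal = animal)

  pose <- rigid_transform()
  if (params$pose == "random") {
    ang <- stats::runif(1, 0, rad(20))
    ax <- normalize(stats::rnorm(3))
    pose <- rigid_transform(rotation_about_axis(ax, ang),
                            stats::runif(3, -500, 500))
  }
  posed <- if (params$pose == "random") transform_field(field, pose) else field
  list(field = posed,
       truth = list(parameters = drawn, field = field, pose = pose))
}
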