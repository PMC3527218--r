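# Rendering of synthetic tangential optical-section stacks.
#
# Cytochrome-oxidase contrast is emulated as bright barrel bodies against a
# darker septum background, with dark circular blood-vessel cross sections
# and additive Gaussian intensity noise. For every rendered slice the true
# per-pixel barrel label is emitted as a ground-truth mask.

#' Parameters for rendering synthetic section images
#'
#' @param pixel_size micrometers per pixel (default 4).
#' @param section_spacing optical section spacing in micrometers (default 10).
#' @param barrel_intensity,septum_intensity mean intensities (0..1 scale) of
#'   barrel and septum tissue; their difference is the CO contrast.
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param vessel_radius range (um) of vessel cross-section radii.
#' @param margin extra in-plane margin around the barrels, um.
#' @return object of class `image_simulation_params`.
#' @export
image_simulation_params <- function(pixel_size = 4, section_spacing = 10,
                                    barrel_intensity = 0.75,
                                    septum_intensity = 0.40,
                                    noise_sd = 0.05,
                                    vessel_radius = c(4, 10),
                                    margin = 150) {
  if (pixel_size <= 0) stop("pixel size must be > 0")
  if (barrel_intensity == septum_intensity)
    stop("barrel/septum contrast must be non-zero")
  structure(list(pixel_size = pixel_size, section_spacing = section_spacing,
                 barrel_intensity = barrel_intensity,
                 septum_intensity = septum_intensity, noise_sd = noise_sd,
                 vessel_radius = vessel_radius, margin = margin),
            class = "image_simulation_params")
}

#' Image stack container
#'
#' @param data numeric array `[nx, ny, nsections]`, intensities in 0..1.
#' @param z section z positions (um), strictly increasing.
#' @param pixel_size um per pixel.
#' @param origin in-plane micrometer coordinates of the center of pixel
#'   `[1, 1]`.
#' @return object of class `section_stack`.
#' @export
section_stack <- function(data, z, pixel_size, origin = c(0, 0)) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(z))
  structure(list(data = data, z = as.numeric(z), pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("section_stack:", d[1], "x", d[2], "px,", d[3], "sections,",
      x$pixel_size, "um/px\n")
  invisible(x)
}

# Pixel-center coordinate vectors of a stack.
stack_coords <- function(stack) {
  d <- dim(stack$data)
  list(x = stack$origin[1] + (seq_len(d[1]) - 1) * stack$pixel_size,
       y = stack$origin[2] + (seq_len(d[2]) - 1) * stack$pixel_size)
}

# Radius of the ellipsoidal barrel body at depth t along its axis; NA
# outside [bt, bb].
barrel_radius_at <- function(geom, t_depth, bt_depth, bb_depth) {
  half <- (bb_depth - bt_depth) / 2
  mid <- (bt_depth + bb_depth) / 2
  w <- 1 - ((t_depth - mid) / half)^2
  ifelse(t_depth >= bt_depth & t_depth <= bb_depth,
         sqrt(geom$area / pi) * sqrt(pmax(w, 0)), NA_real_)
}

#' Render a synthetic optical-section stack from a barrel field
#'
#' Intersects every barrel body and vessel polyline with a stack of
#' tangential image planes and renders barrels as bright regions against a
#' septum background, vessels as dark disks, plus additive Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param field a [barrel_field()] (in an axis-aligned frame: image planes
#'   are planes of constant z).
#' @param params an [image_simulation_params()].
#' @param seed integer seed for the noise.
#' @param slab optional `c(zmin, zmax)`; defaults to the z-range of the
#'   barrels plus one section spacing of padding.
#' @param labels optional subset of barrel labels to render.
#' @return list with `stack` (a [section_stack()]), `masks` (integer array
#'   of per-pixel ground-truth labels, 0 = background) and `label_codes`
#'   (names of the mask integer codes).
#' @export
render_section_stack <- function(field, params = image_simulation_params(),
                                 seed = 1, slab = NULL, labels = NULL) {
  stopifnot(inherits(field, "barrel_field"),
            inherits(params, "image_simulation_params"))
  set.seed(as.integer(seed))
  barrels <- field$barrels
  if (!is.null(labels)) barrels <- barrels[intersect(names(barrels), labels)]
  if (!length(barrels)) stop("no barrels to render")

  allpts <- do.call(rbind, lapply(barrels, function(b)
    rbind(b$geometry$bt, b$geometry$bb)))
  if (is.null(slab))
    slab <- range(allpts[, 3]) + c(-1, 1) * params$section_spacing
  zs <- seq(slab[1], slab[2], by = params$section_spacing)

  ext_x <- range(allpts[, 1]) + c(-1, 1) * params$margin
  ext_y <- range(allpts[, 2]) + c(-1, 1) * params$margin
  px <- params$pixel_size
  xs <- seq(ext_x[1], ext_x[2], by = px)
  ys <- seq(ext_y[1], ext_y[2], by = px)
  nx <- length(xs); ny <- length(ys); ns <- length(zs)

  img <- array(params$septum_intensity, c(nx, ny, ns))
  masks <- array(0L, c(nx, ny, ns))
  codes <- names(barrels)

  zmax_barrel <- max(allpts[, 3]); zmin_barrel <- min(allpts[, 3])
  if (slab[2] < zmin_barrel || slab[1] > zmax_barrel) {
    warning("imaged slab does not intersect any barrel; empty stack")
  }

  for (s in seq_len(ns)) {
    for (bi in seq_along(barrels)) {
      b <- barrels[[bi]]
      ax <- b$column$axis; pp <- b$column$pia_point
      # depth at which the axis crosses the plane z = zs[s]
      if (abs(ax[3]) < 1e-6) next
      t_depth <- (pp[3] - zs[s]) / ax[3]
      bt_d <- sum((pp - b$geometry$bt) * ax)
      bb_d <- sum((pp - b$geometry$bb) * ax)
      r <- barrel_radius_at(b$geometry, t_depth, bt_d, bb_d)
      if (is.na(r) || r <= 0) next
      ctr <- pp - ax * t_depth
      ix <- which(abs(xs - ctr[1]) <= r + px)
      iy <- which(abs(ys - ctr[2]) <= r + px)
      if (!length(ix) || !length(iy)) next
      dx2 <- (xs[ix] - ctr[1])^2
      dy2 <- (ys[iy] - ctr[2])^2
      inside <- outer(dx2, dy2, "+") <= r^2
      sub <- img[ix, iy, s]
      sub[inside] <- params$barrel_intensity
      img[ix, iy, s] <- sub
      msub <- masks[ix, iy, s]
      msub[inside] <- bi
      masks[ix, iy, s] <- msub
    }
    # vessel cross sections
    for (p in field$vessels$polylines) {
      zseg <- p[, 3]
      k <- which((zseg[-nrow(p)] - zs[s]) * (zseg[-1] - zs[s]) <= 0)
      for (kk in k) {
        a <- p[kk, ]; b2 <- p[kk + 1, ]
        if (abs(b2[3] - a[3]) < 1e-9) next
        w <- (zs[s] - a[3]) / (b2[3] - a[3])
        pt <- a + w * (b2 - a)
        vr <- stats::runif(1, params$vessel_radius[1], params$vessel_radius[2])
        ix <- which(abs(xs - pt[1]) <= vr + px)
        iy <- which(abs(ys - pt[2]) <= vr + px)
        if (!length(ix) || !length(iy)) next
        inside <- outer((xs[ix] - pt[1])^2, (ys[iy] - pt[2])^2, "+") <= vr^2
        sub <- img[ix, iy, s]
        sub[inside] <- 0.05
        img[ix, iy, s] <- sub
      }
    }
  }
  if (params$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  list(stack = section_stack(img, zs, px, c(ext_x[1], ext_y[1])),
       masks = masks, label_codes = codes)
}
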