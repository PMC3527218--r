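# Assembly of 2D landmarks into 3D: vessel-based section alignment,
# z-smoothing of contour stacks, and surface reconstruction from serial
# contours via interpolated 2D distance transforms.

#' Rigid in-plane alignment of serial sections using vessel patterns
#'
#' Consecutive sections are matched by nearest-neighbor correspondence of
#' their vessel cross-section points followed by a least-squares rigid 2D
#' fit; transforms are chained so every section is expressed in the frame of
#' the first. Sections with fewer than 3 correspondences keep the identity
#' transform (with a warning).
#'
#' @param patterns list of k_i x 2 matrices of vessel points per section
#'   (micrometers).
#' @param max_dist correspondence gate: nearest neighbors farther apart
#'   than this (um) are discarded.
#' @return list of per-section transforms `list(angle, translation)`
#'   (radians / um) mapping the section into the frame of section 1.
#' @export
align_sections <- function(patterns, max_dist = 60) {
  n <- length(patterns)
  rigid2d <- function(a, b) {
    # least-squares rigid 2D mapping a -> b
    ca <- colMeans(a); cb <- colMeans(b)
    a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
    H <- crossprod(a0, b0)
    ang <- atan2(H[1, 2] - H[2, 1], H[1, 1] + H[2, 2])
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    list(angle = ang, translation = cb - as.numeric(R %*% ca), R = R)
  }
  apply2d <- function(tf, pts) sweep(pts %*% t(tf$R), 2, tf$translation, "+")
  identity2d <- list(angle = 0, translation = c(0, 0), R = diag(2))
  out <- vector("list", n)
  out[[1]] <- identity2d
  cum <- identity2d
  for (s in seq_len(n - 1)) {
    a <- patterns[[s + 1]]; b <- patterns[[s]]
    tf <- identity2d
    if (nrow(a) >= 3 && nrow(b) >= 3) {
      # iterated nearest-neighbor matching (correspondences improve once a
      # first rigid estimate is applied)
      ok <- FALSE
      cur_a <- a
      for (iter in 1:3) {
        d2 <- outer(cur_a[, 1], b[, 1], "-")^2 +
          outer(cur_a[, 2], b[, 2], "-")^2
        nn <- apply(d2, 1, which.min)
        keep <- d2[cbind(seq_len(nrow(a)), nn)] <= max_dist^2
        if (sum(keep) < 3) break
        tf <- rigid2d(a[keep, , drop = FALSE], b[nn[keep], , drop = FALSE])
        cur_a <- apply2d(tf, a)
        ok <- TRUE
      }
      if (!ok)
        warning("section ", s + 1, ": fewer than 3 vessel correspondences, ",
                "identity transform used")
    } else {
      warning("section ", s + 1, ": fewer than 3 vessels, identity used")
    }
    # cumulative: to frame of section 1
    R <- cum$R %*% tf$R
    tr <- as.numeric(cum$R %*% tf$translation) + cum$translation
    cum <- list(angle = cum$angle + tf$angle, translation = tr, R = R)
    out[[s + 1]] <- cum
  }
  out
}

# Resample a closed polygon at n equally spaced polar angles about a center.
resample_polar <- function(poly, n = 72, center = polygon_centroid(poly)) {
  rel <- sweep(poly, 2, center)
  th <- atan2(rel[, 2], rel[, 1])
  r <- sqrt(rowSums(rel^2))
  o <- order(th)
  th <- th[o]; r <- r[o]
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  r_ext <- c(r, r, r)
  tq <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
  rq <- stats::approx(th_ext, r_ext, xout = tq, rule = 2)$y
  list(theta = tq, r = rq, center = center)
}

#' Smooth a contour stack along z
#'
#' Corresponding radial samples (72 polar samples about each contour's
#' centroid) and the centroids themselves are averaged with a centered
#' 3-section window, removing single-section segmentation artifacts while
#' preserving linear tapers.
#'
#' @param contours a [contour_stack()].
#' @param n_samples number of polar samples per contour.
#' @return smoothed [contour_stack()].
#' @export
smooth_contour_stack <- function(contours, n_samples = 72) {
  stopifnot(inherits(contours, "contour_stack"))
  ns <- length(contours$z)
  if (ns < 2) return(contours)
  rs <- lapply(contours$contours, resample_polar, n = n_samples)
  rmat <- do.call(rbind, lapply(rs, `[[`, "r"))         # ns x n
  cmat <- do.call(rbind, lapply(rs, `[[`, "center"))    # ns x 2
  rsm <- apply(rmat, 2, smooth3)
  if (ns == 2) rsm <- rmat
  csm <- apply(cmat, 2, smooth3)
  th <- rs[[1]]$theta
  new_contours <- lapply(seq_len(ns), function(s) {
    cbind(csm[s, 1] + rsm[s, ] * cos(th),
          csm[s, 2] + rsm[s, ] * sin(th))
  })
  contour_stack(new_contours, contours$z, contours$pixel_size)
}

# Signed 2D distance map of a polygon on the coordinate grid xs/ys
# (negative inside).
signed_distance_map <- function(poly, xs, ys) {
  inside <- polygon_mask(poly, xs, ys)
  grid_x <- matrix(xs, length(xs), length(ys))
  grid_y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  # exact distance to the polygon edges (polygons here are small: O(n_edge))
  n <- nrow(poly)
  jn <- c(2:n, 1)
  d2 <- matrix(Inf, length(xs), length(ys))
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[jn[e], ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) next
    t_ <- ((grid_x - a[1]) * ab[1] + (grid_y - a[2]) * ab[2]) / len2
    t_ <- pmin(pmax(t_, 0), 1)
    dx <- grid_x - (a[1] + t_ * ab[1])
    dy <- grid_y - (a[2] + t_ * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2) * ifelse(inside, -1, 1)
}

#' Surface reconstruction from serial section contours
#'
#' Signed 2D distance maps are computed per section, linearly interpolated
#' between sections, and the zero level set of every (original and
#' interpolated) level is extracted and triangulated into a closed tube
#' surface. Stacked circles reproduce a cylinder and linearly shrinking
#' circles a cone to within one grid cell.
#'
#' @param contours a [contour_stack()] with >= 2 sections.
#' @param grid_spacing in-plane sampling of the distance maps, um.
#' @param z_step spacing of interpolated levels between sections, um
#'   (default: one level per `grid_spacing`).
#' @param n_ring number of vertices per level ring.
#' @return a [surface_mesh()].
#' @export
build_surface <- function(contours, grid_spacing = 10, z_step = NULL,
                          n_ring = 48) {
  stopifnot(inherits(contours, "contour_stack"))
  ns <- length(contours$z)
  if (ns < 2) stop("need at least 2 sections")
  if (is.null(z_step)) z_step <- grid_spacing
  allpts <- do.call(rbind, contours$contours)
  xs <- seq(min(allpts[, 1]) - 3 * grid_spacing,
            max(allpts[, 1]) + 3 * grid_spacing, by = grid_spacing)
  ys <- seq(min(allpts[, 2]) - 3 * grid_spacing,
            max(allpts[, 2]) + 3 * grid_spacing, by = grid_spacing)
  dmaps <- lapply(contours$contours, signed_distance_map, xs = xs, ys = ys)

  ring_at <- function(dmap) {
    cl <- grDevices::contourLines(xs, ys, dmap, levels = 0)
    if (!length(cl)) return(NULL)
    # contourLines may split a closed ring into several open pieces at
    # exact grid-node zeros: pool all pieces and resample by polar angle
    pts <- do.call(rbind, lapply(cl, function(c_) cbind(c_$x, c_$y)))
    suppressWarnings(resample_polar(pts, n = n_ring))
  }
  levels_z <- numeric(0)
  rings <- list()
  for (s in seq_len(ns - 1)) {
    z0 <- contours$z[s]; z1 <- contours$z[s + 1]
    if (z1 - z0 > 1.5 * z_step) {
      zi <- seq(z0, z1, by = z_step)
      if (zi[length(zi)] < z1) zi <- c(zi, z1)
    } else zi <- c(z0, z1)
    if (s > 1) zi <- zi[-1]
    for (z in zi) {
      a <- (z - z0) / (z1 - z0)
      a <- min(max(a, 0), 1)
      dmap <- (1 - a) * dmaps[[s]] + a * dmaps[[s + 1]]
      rg <- ring_at(dmap)
      if (is.null(rg)) {
        if (all(dmap > 0))
          stop("non-overlapping consecutive contours: empty zero level set")
        next
      }
      rings[[length(rings) + 1]] <- rg
      levels_z <- c(levels_z, z)
    }
  }
  if (length(rings) < 2) stop("surface reconstruction failed: too few rings")
  nl <- length(rings)
  verts <- do.call(rbind, lapply(seq_len(nl), function(i) {
    cbind(rings[[i]]$center[1] + rings[[i]]$r * cos(rings[[i]]$theta),
          rings[[i]]$center[2] + rings[[i]]$r * sin(rings[[i]]$theta),
          levels_z[i])
  }))
  tri <- list()
  for (i in seq_len(nl - 1)) {
    o1 <- (i - 1) * n_ring
    o2 <- i * n_ring
    for (k in seq_len(n_ring)) {
      k2 <- if (k == n_ring) 1L else k + 1L
      tri[[length(tri) + 1]] <- c(o1 + k, o1 + k2, o2 + k)
      tri[[length(tri) + 1]] <- c(o1 + k2, o2 + k2, o2 + k)
    }
  }
  surface_mesh(verts, do.call(rbind, tri))
}
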