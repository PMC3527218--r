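# Barrel contour extraction from high-resolution optical sections:
# contrast filtering, Voronoi-confined region growing, radial ratio-of-means
# contour validation and detection of the vertical barrel extent.

#' Manual seed points for barrel segmentation
#'
#' One in-plane point per barrel, placed on a reference section where all
#' barrels are visible.
#'
#' @param label barrel labels.
#' @param x,y seed coordinates in micrometers (image frame).
#' @param section index of the reference section.
#' @return object of class `seed_set`.
#' @export
seed_set <- function(label, x, y, section = 1L) {
  assert_barrel_label(label)
  if (anyDuplicated(cbind(x, y))) stop("seed points must be pairwise distinct")
  structure(data.frame(label = label, x = x, y = y,
                       section = as.integer(section),
                       stringsAsFactors = FALSE),
            class = c("seed_set", "data.frame"))
}

# Otsu threshold of an arbitrary intensity vector (256-bin histogram).
otsu_threshold <- function(vals, nbins = 256) {
  vals <- vals[is.finite(vals)]
  r <- range(vals)
  if (diff(r) < 1e-12) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((vals - r[1]) / diff(r) * nbins)),
                nbins)
  w <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # upper edge of the optimal bin: the lower class is strictly below it
  r[1] + which.max(sigma_b) / nbins * diff(r)
}

disc_brush <- function(radius_px) {
  size <- 2L * max(1L, as.integer(round(radius_px))) + 1L
  EBImage::makeBrush(size, "disc")
}

#' Contrast filtering of a barrel-field image
#'
#' Suppresses structures at small spatial scales (blood-vessel cross
#' sections, unstained somata, impulse noise) while preserving the
#' barrel/septum contrast monotonically: a small median filter, a grayscale
#' closing at the vessel scale (fills dark spots), and an optional 15x15
#' local-mean smoothing, followed by an affine rescale to 0..1.
#'
#' @param image numeric matrix, intensities in 0..1.
#' @param pixel_size micrometers per pixel.
#' @param vessel_diameter diameter (um) of the largest dark structure to
#'   suppress.
#' @param median_radius radius (px) of the median prefilter.
#' @param smooth if `TRUE` a 15x15 px local-mean filter is applied as well.
#' @return filtered matrix rescaled to 0..1.
#' @export
preprocess_barrel_image <- function(image, pixel_size = 4,
                                    vessel_diameter = 24,
                                    median_radius = 1, smooth = FALSE) {
  image <- as.matrix(image)
  if (diff(range(image)) < 1e-12) {
    warning("constant image: returned unchanged")
    return(image)
  }
  img <- (image - min(image)) / diff(range(image))
  if (median_radius > 0)
    img <- EBImage::medianFilter(img, median_radius)
  img <- EBImage::closing(img, disc_brush(vessel_diameter / 2 / pixel_size))
  if (smooth) {
    k <- matrix(1 / 225, 15, 15)
    img <- EBImage::filter2(img, k)
  }
  img <- as.matrix(img)
  (img - min(img)) / max(diff(range(img)), 1e-12)
}

#' Contrast-filter every section of a stack (joint normalization)
#'
#' Applies [preprocess_barrel_image()] slice-wise but rescales with the
#' global intensity range of the whole stack, so that signal-free sections
#' are not stretched to full contrast.
#'
#' @param stack a [section_stack()].
#' @param ... passed to [preprocess_barrel_image()].
#' @return filtered [section_stack()].
#' @export
preprocess_stack <- function(stack, ...) {
  out <- stack
  for (s in seq_along(stack$z)) {
    img <- stack$data[, , s]
    if (diff(range(img)) < 1e-12) next
    f <- preprocess_barrel_image(img, pixel_size = stack$pixel_size, ...)
    # undo the per-slice affine rescale: map back onto the slice's range
    out$data[, , s] <- min(img) + f * diff(range(img))
  }
  r <- range(out$data)
  out$data <- (out$data - r[1]) / max(diff(r), 1e-12)
  out
}

# Rasterize a polygon (n x 2, um) onto the pixel grid given by coordinate
# vectors xs/ys: even-odd ray crossing, vectorized over grid rows.
polygon_mask <- function(poly, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  mask <- matrix(FALSE, nx, ny)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  for (iy in seq_len(ny)) {
    y0 <- ys[iy]
    cross <- (py > y0) != (py[j] > y0)
    if (!any(cross)) next
    xint <- px[cross] + (y0 - py[cross]) / (py[j][cross] - py[cross]) *
      (px[j][cross] - px[cross])
    xint <- sort(xint)
    inside <- rep(FALSE, nx)
    for (k in seq(1, length(xint) - 1, by = 2)) {
      inside <- inside | (xs >= xint[k] & xs <= xint[k + 1])
    }
    mask[, iy] <- inside
  }
  mask
}

# Voronoi label of every pixel with respect to the seed points.
voronoi_regions <- function(seeds, xs, ys) {
  best <- matrix(1L, length(xs), length(ys))
  bestd <- outer((xs - seeds$x[1])^2, (ys - seeds$y[1])^2, "+")
  for (k in seq_len(nrow(seeds))[-1]) {
    d <- outer((xs - seeds$x[k])^2, (ys - seeds$y[k])^2, "+")
    upd <- d < bestd
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  best
}

# Extract the outline of a binary mask as a micrometers polygon. The
# traced boundary runs through pixel centers, which bites half a pixel off
# the enclosed area; the polygon is expanded radially by half a pixel.
mask_contour <- function(mask, xs, ys) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(NULL)
  oc <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  px <- xs[2] - xs[1]
  # ocontour returns 0-based pixel indices
  poly <- cbind(xs[1] + oc[, 1] * px, ys[1] + oc[, 2] * px)
  ctr <- colMeans(poly)
  rel <- sweep(poly, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  r[r < 1e-9] <- 1e-9
  sweep(rel * (1 + (px / 2) / r), 2, ctr, "+")
}

#' Voronoi-confined barrel segmentation of a filtered stack
#'
#' For every section and every seed, an intensity threshold (Otsu within the
#' seed's Voronoi region) segments candidate barrel pixels; the connected
#' component at the seed is kept, confined to the Voronoi region, and a
#' morphological closing merges fragments belonging to one barrel. Sections
#' whose interior/exterior intensity ratio stays below `min_ratio` are
#' treated as signal-free and yield no contour.
#'
#' @param stack a (filtered) [section_stack()].
#' @param seeds a [seed_set()] (coordinates in micrometers).
#' @param closing_radius radius (px) of the merging closing.
#' @param min_ratio minimal interior/exterior mean-intensity ratio for a
#'   contour to be accepted.
#' @param min_contrast minimal absolute interior-exterior intensity
#'   difference (on the stack's normalized scale).
#' @param min_separability minimal Otsu class-separability
#'   (between-class / total variance) of the Voronoi region's intensities;
#'   pure noise reaches ~0.64, true barrel/septum bimodality well above.
#' @param max_vr_fraction maximal fraction of the Voronoi region a barrel
#'   may cover (larger masks indicate a signal-free section).
#' @param min_area_px minimal component area in pixels.
#' @return named list (by label) of [contour_stack()] objects (possibly
#'   empty when a seed never hits signal).
#' @export
segment_barrels <- function(stack, seeds, closing_radius = 4,
                            min_ratio = 1.10, min_contrast = 0.12,
                            min_separability = 0.75,
                            max_vr_fraction = 0.5, min_area_px = 25) {
  stopifnot(inherits(stack, "section_stack"))
  co <- stack_coords(stack)
  vr <- voronoi_regions(seeds, co$x, co$y)
  seed_ix <- pmin(pmax(round((seeds$x - co$x[1]) / stack$pixel_size) + 1, 1),
                  length(co$x))
  seed_iy <- pmin(pmax(round((seeds$y - co$y[1]) / stack$pixel_size) + 1, 1),
                  length(co$y))
  ns <- length(stack$z)
  out <- stats::setNames(vector("list", nrow(seeds)), seeds$label)
  contours <- lapply(seq_len(nrow(seeds)), function(k) vector("list", ns))
  keepz <- lapply(seq_len(nrow(seeds)), function(k) logical(ns))
  brush <- disc_brush(closing_radius)

  for (s in seq_len(ns)) {
    img <- stack$data[, , s]
    for (k in seq_len(nrow(seeds))) {
      inVR <- vr == k
      vals <- img[inVR]
      thr <- otsu_threshold(vals)
      # scale-free bimodality gate: Otsu's class separability
      w1 <- mean(vals < thr)
      if (w1 > 0 && w1 < 1) {
        mu1 <- mean(vals[vals < thr]); mu2 <- mean(vals[vals >= thr])
        eta <- w1 * (1 - w1) * (mu1 - mu2)^2 / max(stats::var(vals), 1e-12)
        if (eta < min_separability) next
      } else next
      mask <- img > thr & inVR
      if (!any(mask)) next
      lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
      lab <- as.matrix(EBImage::imageData(lab))
      comp <- lab[seed_ix[k], seed_iy[k]]
      if (comp == 0) {
        # seed off signal on this section: take the largest component
        sizes <- tabulate(lab[lab > 0])
        if (!length(sizes)) next
        comp <- which.max(sizes)
      }
      m <- lab == comp
      m <- as.matrix(EBImage::closing(EBImage::Image(m * 1), brush)) > 0.5
      m <- m & inVR
      if (sum(m) < min_area_px) next
      if (sum(m) > max_vr_fraction * sum(inVR)) next
      mu_in <- mean(img[m]); mu_out <- mean(img[inVR & !m])
      if (mu_in / max(mu_out, 1e-9) < min_ratio) next
      if (mu_in - mu_out < min_contrast) next
      poly <- mask_contour(m, co$x, co$y)
      if (is.null(poly) || nrow(poly) < 3) next
      contours[[k]][[s]] <- poly
      keepz[[k]][s] <- TRUE
    }
  }
  for (k in seq_len(nrow(seeds))) {
    kp <- keepz[[k]]
    if (!any(kp)) {
      warning("no signal found for seed '", seeds$label[k], "'")
      out[[k]] <- contour_stack(list(), numeric(0), stack$pixel_size)
    } else {
      out[[k]] <- contour_stack(contours[[k]][kp], stack$z[kp],
                                stack$pixel_size)
    }
  }
  out
}

#' Radial ratio-of-means quality profile of a barrel contour
#'
#' For a growing set of test radii around the barrel center, the ratio of
#' the mean intensity inside the test circle to the mean intensity in the
#' surrounding annulus (up to `r_out`) is computed. For a real barrel the
#' ratio peaks where the test circle matches the true barrel extent and
#' declines beyond it; the interpolated peak location estimates the true
#' barrel radius (reported relative to the segmented contour's equivalent
#' radius) and the slope of the declining branch quantifies how sharply the
#' signal ends.
#'
#' @param image numeric matrix (filtered section).
#' @param contour segmented contour polygon (n x 2, um) or `NULL`.
#' @param center barrel center `c(x, y)` in micrometers.
#' @param pixel_size um/px; `origin` the um coordinates of pixel `[1, 1]`.
#' @param radii test radii in micrometers (default 40..`r_out` in 8 um
#'   steps).
#' @param r_out outer radius of the evaluation region, um.
#' @return object of class `radial_profile` with elements `radii`, `ratio`,
#'   `extent_um` (estimated true barrel radius), `slope` (of the declining
#'   branch, per um) and `relative_size` (extent / contour equivalent
#'   radius; `NA` without a contour).
#' @export
radial_quality_profile <- function(image, contour = NULL, center,
                                   pixel_size = 4, origin = c(0, 0),
                                   radii = NULL, r_out = 320) {
  xs <- origin[1] + (seq_len(nrow(image)) - 1) * pixel_size
  ys <- origin[2] + (seq_len(ncol(image)) - 1) * pixel_size
  dist2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
  if (is.null(radii)) radii <- seq(40, r_out - 20, by = 8)
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  outer_all <- dist2 <= r_out^2
  if (!any(outer_all)) stop("evaluation region outside the image")
  ratio <- vapply(radii, function(r) {
    ins <- dist2 <= r^2
    outs <- outer_all & !ins
    if (!any(outs) || !any(ins)) return(NA_real_)
    mean(image[ins]) / max(mean(image[outs]), 1e-9)
  }, numeric(1))
  ok <- is.finite(ratio)
  rr <- radii[ok]; ra <- ratio[ok]
  peak <- which.max(ra)
  tail_ <- ra[length(ra)]
  # the ratio peaks where the test circle matches the true barrel extent;
  # quadratic interpolation around the peak refines the estimate
  extent <- rr[peak]
  if (peak > 1 && peak < length(ra)) {
    y1 <- ra[peak - 1]; y2 <- ra[peak]; y3 <- ra[peak + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      delta <- max(-1, min(1, delta))
      extent <- rr[peak] + delta * (rr[min(peak + 1, length(rr))] - rr[peak])
    }
  }
  slope <- 0
  if (peak < length(ra) && max(ra) - tail_ > 1e-6) {
    decl <- peak:length(ra)
    slope <- stats::coef(stats::lm(ra[decl] ~ rr[decl]))[2]
  }
  rel <- NA_real_
  if (!is.null(contour))
    rel <- extent / sqrt(polygon_area(contour) / pi)
  structure(list(radii = radii, ratio = ratio, extent_um = extent,
                 slope = unname(slope), relative_size = rel),
            class = "radial_profile")
}

#' Optimized minimal contour near the barrel top/bottom
#'
#' Near the vertical ends of a barrel the regular segmentation tends to
#' include septum; candidate contours re-thresholded at increasing interior
#' quantiles are scored by their interior/exterior intensity ratio and the
#' best candidate replaces the regular contour only when it improves the
#' score.
#'
#' @param image filtered section (matrix).
#' @param contour regular contour polygon (n x 2, um) or `NULL` for a blank
#'   section.
#' @param pixel_size,origin image geometry as in
#'   [radial_quality_profile()].
#' @param quantiles interior-intensity quantiles defining the candidate
#'   thresholds.
#' @return list with `contour` (possibly the original), `improved` and
#'   `flagged`.
#' @export
optimize_minimal_contour <- function(image, contour, pixel_size = 4,
                                     origin = c(0, 0),
                                     quantiles = seq(0.3, 0.85, by = 0.05)) {
  if (is.null(contour)) {
    return(list(contour = NULL, improved = FALSE, flagged = TRUE))
  }
  xs <- origin[1] + (seq_len(nrow(image)) - 1) * pixel_size
  ys <- origin[2] + (seq_len(ncol(image)) - 1) * pixel_size
  inside0 <- polygon_mask(contour, xs, ys)
  if (!any(inside0)) return(list(contour = contour, improved = FALSE,
                                 flagged = TRUE))
  ctr <- polygon_centroid(contour)
  r_eq <- sqrt(polygon_area(contour) / pi)
  dist2 <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+")
  region <- dist2 <= (2 * r_eq)^2
  score_of <- function(m) {
    outs <- region & !m
    if (!any(outs) || !any(m)) return(-Inf)
    mean(image[m]) / max(mean(image[outs]), 1e-9)
  }
  best <- score_of(inside0)
  best_mask <- NULL
  vals <- image[inside0]
  brush <- disc_brush(2)
  for (q in quantiles) {
    thr <- stats::quantile(vals, q)
    m <- inside0 & image > thr
    if (sum(m) < 20) next
    lab <- as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(m * 1))))
    sizes <- tabulate(lab[lab > 0])
    if (!length(sizes)) next
    m <- lab == which.max(sizes)
    m <- as.matrix(EBImage::closing(EBImage::Image(m * 1), brush)) > 0.5
    sc <- score_of(m)
    if (sc > best * 1.02) {
      best <- sc
      best_mask <- m
    }
  }
  if (is.null(best_mask))
    return(list(contour = contour, improved = FALSE, flagged = TRUE))
  poly <- mask_contour(best_mask, xs, ys)
  list(contour = poly, improved = TRUE, flagged = FALSE)
}

# Centered 3-point moving average (ends unchanged).
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

#' Vertical barrel extent from the per-section diameter profile
#'
#' The equivalent diameter `d(z) = 2 sqrt(area/pi)` of the segmented
#' contours is smoothed with a centered 3-point moving average; the barrel
#' top is the shallowest local minimum above the global maximum of `d(z)`
#' and the barrel bottom the deepest local minimum below it (diameters
#' decrease towards the barrel ends and increase again outside). On an
#' equal-valued plateau the section closer to the global maximum is chosen
#' (conservative extent). Profiles without interior minima return the
#' endpoint sections with a low-confidence flag.
#'
#' @param contours a [contour_stack()] with at least 5 sections.
#' @param pia_end which end of the stack faces the pia: `"first"` for
#'   stacks ordered from the pia downwards (section z = depth, the usual
#'   sectioning order) or `"last"` when z increases pia-ward.
#' @return list with `bt_section`, `bb_section` (indices into the stack),
#'   `confidence` (`"high"`/`"low"`) and the smoothed diameters `d`.
#' @export
detect_vertical_extent <- function(contours, pia_end = c("first", "last")) {
  stopifnot(inherits(contours, "contour_stack"))
  pia_end <- match.arg(pia_end)
  n <- length(contours$z)
  if (n < 5) stop("need at least 5 sections with contours")
  d <- smooth3(2 * sqrt(contour_areas(contours) / pi))
  if (pia_end == "last") d <- rev(d)
  m <- which.max(d)
  # plateau-aware local-minimum runs: list of index vectors, each run an
  # interval of equal values lower than (or equal to, strictly on one side)
  # both neighbors
  minimum_runs <- function() {
    eps <- 1e-9 * max(abs(d))
    eq <- function(a, b) abs(a - b) <= eps
    lt <- function(a, b) a < b - eps
    runs <- list()
    i <- 2
    while (i <= n - 1) {
      j <- i
      while (j < n - 1 && eq(d[j + 1], d[j])) j <- j + 1
      if (!lt(d[i - 1], d[i]) && !lt(d[j + 1], d[j]) &&
          (lt(d[i], d[i - 1]) || lt(d[j], d[j + 1]))) {
        runs[[length(runs) + 1]] <- i:j
      }
      i <- j + 1
    }
    runs
  }
  runs <- minimum_runs()
  low <- FALSE
  top_runs <- Filter(function(r) max(r) < m, runs)
  if (length(top_runs)) {
    # shallowest local minimum; within an equal-valued plateau take the
    # section closest to the maximum (conservative extent)
    bt <- max(top_runs[[1]])
  } else {
    bt <- 1L; low <- TRUE
  }
  bot_runs <- Filter(function(r) min(r) > m, runs)
  if (length(bot_runs)) {
    bb <- min(bot_runs[[length(bot_runs)]])
  } else {
    bb <- n; low <- TRUE
  }
  if (pia_end == "last") {
    bt <- n + 1L - bt
    bb <- n + 1L - bb
    d <- rev(d)
  }
  list(bt_section = as.integer(bt), bb_section = as.integer(bb),
       confidence = if (low) "low" else "high", d = d)
}
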