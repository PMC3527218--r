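# Column morphometrics: overlap of neighboring cylindrical columns along
# row/arc/diagonal directions, voxelized column/septum volumes by layer,
# and tangential parameter gradients.

# Uniform cylinder description of every column of a barrel_field or
# standard_model: label, axis (pia-ward), pia/wm anchor points, radius,
# BT/BB depths, column height.
field_columns <- function(x) {
  if (inherits(x, "standard_model")) {
    labs <- rownames(x$landmarks)
    return(stats::setNames(lapply(labs, model_column, model = x), labs))
  }
  stopifnot(inherits(x, "barrel_field"))
  labs <- names(x$barrels)
  stats::setNames(lapply(labs, function(l) {
    b <- x$barrels[[l]]
    ax <- b$column$axis
    pia <- b$column$pia_point
    list(axis = ax, bc = b$geometry$bc, pia = pia, wm = b$column$wm_point,
         radius = sqrt(b$geometry$area / pi),
         bt_depth = sum((pia - b$geometry$bt) * ax),
         bb_depth = sum((pia - b$geometry$bb) * ax),
         column_height = b$column$column_height)
  }), labs)
}

# Orthonormal in-plane basis perpendicular to a unit axis.
plane_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- normalize(pracma_cross(axis, ref))
  list(e1 = e1, e2 = pracma_cross(axis, e1))
}

# Is each point (n x 3) inside the cylindrical column col?
points_in_column <- function(pts, col) {
  rel <- sweep(pts, 2, col$pia)
  t_ <- as.numeric(rel %*% (-col$axis))          # depth below pia
  lat2 <- rowSums((rel + t_ %*% t(col$axis))^2)
  t_ >= 0 & t_ <= col$column_height & lat2 <= col$radius^2
}

#' Depth-resolved overlap of neighboring barrel columns
#'
#' For every column pair one somatotopic step apart along the chosen
#' direction (`"row"`: same row, next arc, e.g. D1-D2; `"arc"`: next row,
#' same arc, e.g. C2-D2; `"321"`: the diagonal with the strongest cortical
#' curvature, e.g. C3-D2), the volume shared with the neighbor is measured
#' in 50 um depth bins along the central column's axis and reported as a
#' fraction of the central column's bin volume. Volumes are estimated on a
#' deterministic stratified grid (default 5 um) inside the central
#' cylinder.
#'
#' @param x a [barrel_field()] or `standard_model`.
#' @param direction `"row"`, `"arc"` or `"321"`.
#' @param bin_width depth bin width, um.
#' @param spacing stratified sampling grid, um.
#' @return data.frame with columns `central`, `neighbor`, `direction`,
#'   `bin_lo`, `bin_hi` (depth below pia, um) and `fraction`.
#' @export
column_overlap <- function(x, direction = c("row", "arc", "321"),
                           bin_width = 50, spacing = 5) {
  direction <- match.arg(direction)
  cols <- field_columns(x)
  out <- list()
  for (l in names(cols)) {
    nb <- neighbor_label(l, direction)
    if (is.na(nb) || is.null(cols[[nb]])) next
    cen <- cols[[l]]; ngh <- cols[[nb]]
    bas <- plane_basis(cen$axis)
    u <- seq(-cen$radius + spacing / 2, cen$radius, by = spacing)
    uu <- expand.grid(u1 = u, u2 = u)
    uu <- uu[uu$u1^2 + uu$u2^2 <= cen$radius^2, ]
    tt <- seq(spacing / 2, cen$column_height, by = spacing)
    bins <- pmin(ceiling(tt / bin_width),
                 ceiling(cen$column_height / bin_width))
    lat <- outer(uu$u1, bas$e1) + outer(uu$u2, bas$e2)   # nlat x 3
    nlat <- nrow(lat)
    frac <- numeric(max(bins))
    for (b in seq_len(max(bins))) {
      tb <- tt[bins == b]
      pts <- lat[rep(seq_len(nlat), length(tb)), , drop = FALSE] -
        rep(tb, each = nlat) %*% t(cen$axis)
      pts <- sweep(pts, 2, cen$pia, "+")
      frac[b] <- mean(points_in_column(pts, ngh))
    }
    out[[length(out) + 1]] <- data.frame(
      central = l, neighbor = nb, direction = direction,
      bin_lo = (seq_len(max(bins)) - 1) * bin_width,
      bin_hi = pmin(seq_len(max(bins)) * bin_width, cen$column_height),
      fraction = frac, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Voxelize the cortex into columns and septum with per-layer volumes
#'
#' A 10 um (default) isotropic voxel grid spans the cortex between the pia
#' and WM surfaces; every cortex voxel is assigned to the first barrel
#' column whose extrapolated cylinder contains it (voxels inside several
#' columns are counted once and flagged `multi`), remaining cortex voxels
#' to the septum. Layer boundaries are the per-column BT/BB depths; septum
#' voxels use BT/BB depths interpolated from the three laterally nearest
#' columns.
#'
#' @param x a [barrel_field()] or `standard_model`.
#' @param spacing voxel edge length, um.
#' @param margin tangential margin beyond the columns, um.
#' @return object of class `voxel_partition`: `volumes` (data.frame:
#'   compartment, layer, volume in mm^3), `totals` (named totals, mm^3),
#'   `n_multi` (voxels inside >= 2 columns), `dims`, `spacing`.
#' @export
voxelize <- function(x, spacing = 10, margin = 100) {
  cols <- field_columns(x)
  if (inherits(x, "standard_model")) {
    pia <- x$pia; wm <- x$wm
  } else {
    pia <- x$pia; wm <- x$wm
  }
  anchor <- do.call(rbind, lapply(cols, function(c_)
    rbind(c_$pia[1:2] - c_$radius, c_$pia[1:2] + c_$radius,
          c_$wm[1:2] - c_$radius, c_$wm[1:2] + c_$radius)))
  lo <- apply(anchor, 2, min) - margin
  hi <- apply(anchor, 2, max) + margin
  gx <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
  gy <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
  gxy <- as.matrix(expand.grid(x = gx, y = gy))
  pz <- mesh_height_at(pia, gxy)
  wz <- mesh_height_at(wm, gxy)
  ok <- is.finite(pz) & is.finite(wz) & pz > wz
  gxy <- gxy[ok, , drop = FALSE]; pz <- pz[ok]; wz <- wz[ok]
  zmin <- min(wz); zmax <- max(pz)
  gz <- seq(zmin + spacing / 2, zmax, by = spacing)
  # cortex voxels, built per xy-column of voxels
  nz <- length(gz)
  inz <- outer(gz, wz, ">=") & outer(gz, pz, "<=")   # nz x nxy
  idx <- which(inz)
  zi <- ((idx - 1) %% nz) + 1
  ci <- ((idx - 1) %/% nz) + 1
  pts <- cbind(gxy[ci, 1], gxy[ci, 2], gz[zi])
  depth_vert <- pz[ci] - pts[, 3]
  n <- nrow(pts)

  assigned <- integer(n)
  nmulti <- 0L
  lay <- integer(n)                      # 1 supra, 2 gran, 3 infra
  for (k in seq_along(cols)) {
    c_ <- cols[[k]]
    inside <- points_in_column(pts, c_)
    fresh <- inside & assigned == 0L
    nmulti <- nmulti + sum(inside & assigned != 0L)
    assigned[fresh] <- k
    if (any(fresh)) {
      t_ <- as.numeric(sweep(pts[fresh, , drop = FALSE], 2, c_$pia) %*%
                         (-c_$axis))
      lay[fresh] <- 1L + (t_ > c_$bt_depth) + (t_ > c_$bb_depth)
    }
  }
  sep <- assigned == 0L
  if (any(sep)) {
    # lateral distance to each column axis at the septum voxels
    spts <- pts[sep, , drop = FALSE]
    D <- vapply(cols, function(c_)
      lateral_distance(spts, c_$pia, c_$axis), numeric(nrow(spts)))
    if (is.null(dim(D))) D <- matrix(D, nrow = nrow(spts))
    ord <- t(apply(D, 1, order))[, 1:min(3, ncol(D)), drop = FALSE]
    w <- 0; btd <- 0; bbd <- 0
    for (j in seq_len(ncol(ord))) {
      dj <- D[cbind(seq_len(nrow(spts)), ord[, j])]
      wj <- 1 / pmax(dj, 1e-6)
      w <- w + wj
      btd <- btd + wj * vapply(cols, `[[`, numeric(1), "bt_depth")[ord[, j]]
      bbd <- bbd + wj * vapply(cols, `[[`, numeric(1), "bb_depth")[ord[, j]]
    }
    btd <- btd / w; bbd <- bbd / w
    dv <- depth_vert[sep]
    lay[sep] <- 1L + (dv > btd) + (dv > bbd)
  }

  vvol <- spacing^3 * 1e-9               # mm^3 per voxel
  comp <- ifelse(assigned == 0L, "septum", names(cols)[assigned])
  layer <- c("supra", "gran", "infra")[lay]
  volumes <- as.data.frame(table(compartment = comp, layer = layer),
                           stringsAsFactors = FALSE)
  volumes$volume_mm3 <- volumes$Freq * vvol
  volumes$Freq <- NULL
  totals <- c(total = n * vvol,
              column = sum(assigned != 0L) * vvol,
              septum = sum(sep) * vvol)
  structure(list(volumes = volumes, totals = totals,
                 n_multi = nmulti, n_voxels = n,
                 dims = c(length(gx), length(gy), nz), spacing = spacing),
            class = "voxel_partition")
}

#' @export
print.voxel_partition <- function(x, ...) {
  cat(sprintf("voxel_partition (%g um): total %.3f mm^3, columns %.3f (%.0f%%), septum %.3f (%.0f%%)\n",
              x$spacing, x$totals["total"], x$totals["column"],
              100 * x$totals["column"] / x$totals["total"],
              x$totals["septum"],
              100 * x$totals["septum"] / x$totals["total"]))
  invisible(x)
}

#' Tangential gradient of a column parameter over the somatotopic map
#'
#' Planar least-squares fit of the per-label parameter on (Row, Arc); the
#' fitted linear coefficients give the average gradient direction in the
#' tangential plane.
#'
#' @param x a `standard_model`, a [barrel_field()], or a named numeric
#'   vector of per-label values.
#' @param parameter one of `"bt_depth"`, `"bb_depth"`, `"area"`,
#'   `"column_height"`, `"volume"`, `"orientation"` (ignored when `x` is a
#'   plain vector).
#' @return list with `values` (named), `gradient` (`c(row, arc)`, parameter
#'   units per lattice step) and `angle_deg` (direction in the tangential
#'   plane, measured from the arc axis towards the row axis).
#' @export
gradient_map <- function(x, parameter = "bt_depth") {
  if (is.numeric(x) && !is.null(names(x))) {
    vals <- x
  } else {
    lm_ <- if (inherits(x, "standard_model")) x$landmarks else {
      cols <- field_columns(x)
      data.frame(label = names(cols),
                 bt_depth = vapply(cols, `[[`, numeric(1), "bt_depth"),
                 bb_depth = vapply(cols, `[[`, numeric(1), "bb_depth"),
                 area = pi * vapply(cols, `[[`, numeric(1), "radius")^2,
                 column_height = vapply(cols, `[[`, numeric(1),
                                        "column_height"),
                 orientation_deg = NA_real_)
    }
    vals <- switch(parameter,
                   bt_depth = lm_$bt_depth,
                   bb_depth = lm_$bb_depth,
                   area = lm_$area,
                   column_height = lm_$column_height,
                   volume = lm_$area * lm_$column_height * 1e-9,
                   orientation = lm_$orientation_deg,
                   stop("unknown parameter ", parameter))
    names(vals) <- lm_$label
  }
  ra <- numeric_row_arc(names(vals))
  fit <- stats::lm(vals ~ ra$row + ra$arc)
  g <- stats::coef(fit)[2:3]
  if (any(!is.finite(g))) g[!is.finite(g)] <- 0
  list(values = vals, gradient = c(row = unname(g[1]), arc = unname(g[2])),
       angle_deg = deg(atan2(g[1], g[2])))
}
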