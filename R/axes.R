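# Column-axis estimation: vessel filtering against the pia normal, scored
# candidate axes per pia triangle, and barrel finalization (BT/BB points,
# maximal circumference, extrapolated column).

#' Keep only vessels perpendicular to the pia
#'
#' A vessel is kept when the angle between its mean orientation and the pia
#' normal at its intersection point (or, for vessels not reaching the pia,
#' at the nearest pia triangle, flagged) is at most `max_angle` degrees.
#'
#' @param vessels a [vessel_graph()].
#' @param pia a [surface_mesh()].
#' @param max_angle angular tolerance in degrees (default 10).
#' @return filtered [vessel_graph()] with attribute `flagged` (indices of
#'   kept vessels evaluated at the nearest triangle only).
#' @export
filter_vessels <- function(vessels, pia, max_angle = 10) {
  normals <- mesh_triangle_normals(pia)
  cents <- mesh_triangle_centroids(pia)
  keep <- logical(length(vessels$polylines))
  flagged <- integer(0)
  for (i in seq_along(vessels$polylines)) {
    p <- vessels$polylines[[i]]
    o <- vessels$orientations[i, ]
    top <- p[which.max(p[, 3]), ]
    hit <- ray_mesh_intersect(top - o * 1, o, pia)
    if (is.null(hit)) {
      # not reaching the pia: nearest triangle
      d2 <- rowSums(sweep(cents, 2, top)^2)
      tri <- which.min(d2)
      flagged <- c(flagged, i)
    } else {
      d2 <- rowSums(sweep(cents, 2, hit$point)^2)
      tri <- which.min(d2)
    }
    nrm <- normals[tri, ]
    ang <- deg(acos(min(1, abs(sum(o * nrm)))))
    keep[i] <- ang <= max_angle
  }
  out <- vessel_graph(vessels$polylines[keep])
  attr(out, "flagged") <- intersect(flagged, which(keep))
  out
}

# Mean orientation of the vessels located around a barrel center: polylines
# passing laterally within (barrel radius + margin) of the BC.
local_vessel_orientation <- function(vessels, bc, radius, margin = 200) {
  if (!length(vessels$polylines)) return(NULL)
  sel <- vapply(vessels$polylines, function(p) {
    min(sqrt((p[, 1] - bc[1])^2 + (p[, 2] - bc[2])^2)) <= radius + margin
  }, logical(1))
  if (!any(sel)) return(NULL)
  normalize(colMeans(vessels$orientations[sel, , drop = FALSE]))
}

#' Column axis from scored pia-triangle candidates
#'
#' For every pia triangle within `search_radius` of the barrel center, the
#' candidate axis runs from the BC to the triangle centroid. Candidates are
#' scored as `cos(perpendicularity angle) / (length / min length)`: the
#' shorter the axis and the more perpendicular to the pia, the higher the
#' score. Among the candidates parallel (within `vessel_tolerance` degrees)
#' to the mean orientation of the vessels around the BC, the highest-scoring
#' one becomes the BC axis; without such a candidate the best overall score
#' is used and flagged. The axis is extended to the pia and WM surfaces to
#' yield the column.
#'
#' @param bc barrel center (length-3, um).
#' @param pia,wm [surface_mesh()] objects.
#' @param vessels a (filtered) [vessel_graph()].
#' @param barrel the [barrel_geometry()] (for the local vessel search
#'   radius).
#' @param search_radius candidate search radius around the BC, um.
#' @param vessel_tolerance parallelism tolerance to the local vessel
#'   orientation, degrees.
#' @return a [column_geometry()] with attribute `vessel_constrained`.
#' @export
compute_bc_axis <- function(bc, pia, wm, vessels = vessel_graph(list()),
                            barrel = NULL, search_radius = 2000,
                            vessel_tolerance = 5) {
  cents <- mesh_triangle_centroids(pia)
  normals <- mesh_triangle_normals(pia)
  rel <- sweep(cents, 2, bc)
  len <- sqrt(rowSums(rel^2))
  sel <- which(len <= search_radius & len > 1)
  if (!length(sel)) stop("no pia triangles within the search radius")
  dirs <- rel[sel, , drop = FALSE] / len[sel]
  cosperp <- abs(rowSums(dirs * normals[sel, , drop = FALSE]))
  score <- cosperp / (len[sel] / min(len[sel]))

  radius <- if (!is.null(barrel)) sqrt(barrel$area / pi) else 200
  vdir <- local_vessel_orientation(vessels, bc, radius)
  constrained <- FALSE
  cand <- seq_along(sel)
  if (!is.null(vdir)) {
    angv <- deg(acos(pmin(1, abs(dirs %*% vdir))))
    par <- which(angv <= vessel_tolerance)
    if (length(par)) {
      cand <- par
      constrained <- TRUE
    }
  }
  best <- cand[which.max(score[cand])]
  # refine below the mesh resolution: rescore sub-centroids of the
  # best-scoring candidate triangles (barycentric subdivision)
  min_len <- min(len[sel])
  top <- cand[order(-score[cand])][seq_len(min(12, length(cand)))]
  bary <- as.matrix(expand.grid(i = 0:4, j = 0:4))
  bary <- bary[rowSums(bary) <= 4, ]
  bary <- cbind(bary, 4 - rowSums(bary)) / 4
  axis <- dirs[best, ]
  best_sub <- score[best]
  v <- pia$vertices
  for (k in top) {
    trk <- pia$triangles[sel[k], ]
    pts <- bary %*% v[trk, , drop = FALSE]
    relk <- sweep(pts, 2, bc)
    lenk <- sqrt(rowSums(relk^2))
    dk <- relk / lenk
    ck <- abs(dk %*% normals[sel[k], ])
    sck <- ck / (lenk / min_len)
    if (!is.null(vdir) && constrained) {
      okv <- deg(acos(pmin(1, abs(dk %*% vdir)))) <= vessel_tolerance
      sck[!okv] <- -Inf
    }
    kbest <- which.max(sck)
    if (sck[kbest] > best_sub) {
      best_sub <- sck[kbest]
      axis <- dk[kbest, ]
    }
  }
  if (axis[3] < 0) axis <- -axis     # pia-ward

  hit_pia <- ray_mesh_intersect(bc, axis, pia)
  hit_wm <- ray_mesh_intersect(bc, -axis, wm)
  if (is.null(hit_pia) || is.null(hit_wm))
    stop("BC axis does not intersect both pia and WM surfaces")
  out <- column_geometry(axis, hit_pia$point, hit_wm$point)
  attr(out, "vessel_constrained") <- constrained
  out
}

#' Finalize a barrel: BT/BB points, area and column extrapolation
#'
#' Contour-stack centroids are projected onto the BC axis; the extremal
#' projections define the BT (pia-ward) and BB (WM-ward) points. The barrel
#' area is the maximal enclosed contour area, and the maximal circumference
#' extrapolated along the axis to the pia and WM defines the column.
#'
#' @param contours a [contour_stack()] (aligned, in the field frame).
#' @param axis unit axis direction (pia-ward) or a [column_geometry()].
#' @param pia,wm [surface_mesh()] objects.
#' @return list with `geometry` (a [barrel_geometry()]) and `column` (a
#'   [column_geometry()]).
#' @export
finalize_barrel <- function(contours, axis, pia, wm, label = "C2") {
  stopifnot(inherits(contours, "contour_stack"))
  if (length(contours$z) < 2) stop("degenerate barrel: need >= 2 sections")
  if (inherits(axis, "column_geometry")) axis <- axis$axis
  axis <- normalize(axis)
  rings <- contour_stack_to_3d(contours)
  centroids <- t(vapply(rings, colMeans, numeric(3)))
  areas <- contour_areas(contours)
  ref <- colMeans(centroids)
  proj <- as.numeric(sweep(centroids, 2, ref) %*% axis)
  bt <- ref + axis * max(proj)
  bb <- ref + axis * min(proj)
  area <- max(areas)
  bc <- (bt + bb) / 2
  hit_pia <- ray_mesh_intersect(bc, axis, pia)
  hit_wm <- ray_mesh_intersect(bc, -axis, wm)
  if (is.null(hit_pia) || is.null(hit_wm))
    stop("axis does not intersect both surfaces")
  geom <- barrel_geometry(label, rings, area, bt, bb, bc)
  col <- column_geometry(axis, hit_pia$point, hit_wm$point)
  list(geometry = geom, column = col)
}
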