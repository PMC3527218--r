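# The standardized average barrel cortex: average landmarks, circular
# standard columns, triangulated standard pia/WM, orientation vector field,
# and the across-animal variability report.

# Fixed triangulation of the somatotopic lattice: integer-arc grid (rows
# A-E x arcs 1-4) plus a stitched strip connecting the greek arc.
lattice_triangulation <- function(labels) {
  ra <- numeric_row_arc(labels)
  idx <- function(lab) match(lab, labels)
  tri <- list()
  add <- function(a, b, c_) {
    if (!anyNA(c(a, b, c_))) tri[[length(tri) + 1]] <<- c(a, b, c_)
    invisible(NULL)
  }
  for (r in 0:3) for (a in 1:3) {
    p00 <- idx(ra$label[ra$row == r & ra$arc == a])
    p01 <- idx(ra$label[ra$row == r & ra$arc == a + 1])
    p10 <- idx(ra$label[ra$row == r + 1 & ra$arc == a])
    p11 <- idx(ra$label[ra$row == r + 1 & ra$arc == a + 1])
    if (length(p00) && length(p01) && length(p10))
      add(p00[1], p01[1], p10[1])
    if (length(p01) && length(p11) && length(p10))
      add(p01[1], p11[1], p10[1])
  }
  greek <- c("alpha", "beta", "gamma", "delta")
  arc1 <- c("A1", "B1", "C1", "D1", "E1")
  for (k in 1:4) {
    g <- idx(greek[k])
    lo <- idx(arc1[k]); hi <- idx(arc1[k + 1])
    if (!anyNA(c(g, lo, hi))) add(g, lo, hi)
    if (k < 4) {
      g2 <- idx(greek[k + 1])
      if (!anyNA(c(g, g2, hi))) add(g, hi, g2)
    }
  }
  do.call(rbind, tri)
}

#' Build the standardized average model from aligned barrel fields
#'
#' Standard BT and BB points are the per-label centroids of the aligned
#' fields (labels present in fewer than `min_fields` fields are excluded
#' with a warning); the standard barrel contour is a circle with the mean
#' cross-sectional area; standard columns extrapolate these circles along
#' the average BC axes by the mean pia and WM distances; the column
#' top/bottom points are triangulated into the standard pia and WM. The
#' model is re-expressed in its own C2 frame so that it is independent of
#' the arbitrary registration pose.
#'
#' @param fields list of aligned [barrel_field()] objects (see
#'   [register_fields()]).
#' @param min_fields minimal number of fields a label must appear in.
#' @param orientation_spacing voxel size of the orientation field, um.
#' @return object of class `standard_model`: `landmarks` (per-label table
#'   with BT/BB/BC points, axes, depths, areas, radii, orientation), `pia`,
#'   `wm` ([surface_mesh()]), `orientation_field`, `n_fields`.
#' @export
build_standard_model <- function(fields, min_fields = 2,
                                 orientation_spacing = 50) {
  labs <- Reduce(union, lapply(fields, function(f) names(f$barrels)))
  count <- vapply(labs, function(l)
    sum(vapply(fields, function(f) !is.null(f$barrels[[l]]), logical(1))),
    numeric(1))
  drop <- labs[count < min_fields]
  if (length(drop))
    warning("labels excluded (present in < ", min_fields, " fields): ",
            paste(drop, collapse = ", "))
  labs <- labs[count >= min_fields]
  ord <- order(match(labs, barrel_labels()))
  labs <- labs[ord]

  per_label <- lapply(labs, function(l) {
    per <- lapply(fields, function(f) f$barrels[[l]])
    per <- per[!vapply(per, is.null, logical(1))]
    bt <- colMeans(do.call(rbind, lapply(per, function(b) b$geometry$bt)))
    bb <- colMeans(do.call(rbind, lapply(per, function(b) b$geometry$bb)))
    area <- mean(vapply(per, function(b) b$geometry$area, numeric(1)))
    depths <- vapply(per, function(b) {
      ax <- b$column$axis
      c(sum((b$column$pia_point - b$geometry$bt) * ax),
        sum((b$column$pia_point - b$geometry$bb) * ax),
        b$column$column_height)
    }, numeric(3))
    list(label = l, bt = bt, bb = bb, bc = (bt + bb) / 2,
         axis = normalize(bt - bb), area = area,
         bt_depth = mean(depths[1, ]), bb_depth = mean(depths[2, ]),
         column_height = mean(depths[3, ]), n = length(per))
  })
  names(per_label) <- labs

  # re-express in the model's own C2 frame
  if (!all(c("C2", "C3") %in% labs))
    stop("standard model requires the C2 and C3 barrels")
  c2 <- per_label[["C2"]]; c3 <- per_label[["C3"]]
  ez <- c2$axis
  dx <- c3$bc - c2$bc
  ex <- normalize(dx - sum(dx * ez) * ez)
  frame <- coordinate_frame(c2$bc, ex, pracma_cross(ez, ex), ez)
  tf <- frame_to_rigid(frame)
  per_label <- lapply(per_label, function(p) {
    p$bt <- apply_rigid(tf, p$bt); p$bb <- apply_rigid(tf, p$bb)
    p$bc <- apply_rigid(tf, p$bc)
    p$axis <- as.numeric(tf$R %*% p$axis)
    p
  })

  axis_c2 <- per_label[["C2"]]$axis
  lm_tab <- do.call(rbind, lapply(per_label, function(p) {
    ra <- numeric_row_arc(p$label)
    data.frame(label = p$label, row = ra$row, arc = ra$arc,
               bt.x = p$bt[1], bt.y = p$bt[2], bt.z = p$bt[3],
               bb.x = p$bb[1], bb.y = p$bb[2], bb.z = p$bb[3],
               bc.x = p$bc[1], bc.y = p$bc[2], bc.z = p$bc[3],
               axis.x = p$axis[1], axis.y = p$axis[2], axis.z = p$axis[3],
               area = p$area, radius = sqrt(p$area / pi),
               bt_depth = p$bt_depth, bb_depth = p$bb_depth,
               column_height = p$column_height,
               orientation_deg = deg(angle_between(p$axis, axis_c2)),
               n = p$n, stringsAsFactors = FALSE)
  }))
  rownames(lm_tab) <- lm_tab$label

  col_points <- lapply(per_label, function(p) {
    bc_depth <- (p$bt_depth + p$bb_depth) / 2
    pia_pt <- p$bc + p$axis * bc_depth
    wm_pt <- pia_pt - p$axis * p$column_height
    list(pia = pia_pt, wm = wm_pt)
  })
  tri <- lattice_triangulation(labs)
  pia_mesh <- surface_mesh(do.call(rbind, lapply(col_points, `[[`, "pia")),
                           tri)
  wm_mesh <- surface_mesh(do.call(rbind, lapply(col_points, `[[`, "wm")),
                          tri)
  model <- structure(list(landmarks = lm_tab, pia = pia_mesh, wm = wm_mesh,
                          frame = coordinate_frame(c(0, 0, 0), c(1, 0, 0),
                                                   c(0, 1, 0), c(0, 0, 1)),
                          to_model = tf,
                          columns = col_points,
                          orientation_field = NULL,
                          n_fields = length(fields)),
                     class = "standard_model")
  model$orientation_field <- build_orientation_field(
    model, spacing = orientation_spacing)
  model
}

#' @export
print.standard_model <- function(x, ...) {
  cat("standard_model:", nrow(x$landmarks), "barrels averaged over",
      x$n_fields, "fields\n")
  invisible(x)
}

# pia/wm axis anchor points of a model column.
model_column <- function(model, label) {
  lm <- model$landmarks[label, ]
  list(axis = c(lm$axis.x, lm$axis.y, lm$axis.z),
       bc = c(lm$bc.x, lm$bc.y, lm$bc.z),
       pia = model$columns[[label]]$pia,
       wm = model$columns[[label]]$wm,
       radius = lm$radius,
       bt_depth = lm$bt_depth, bb_depth = lm$bb_depth,
       column_height = lm$column_height)
}

#' Local orientation field of the standard model
#'
#' A voxel grid (default 50 um isotropic) spanning the standard cortex; the
#' vector of each voxel is the inverse-distance-weighted interpolation of
#' the three nearest BC axes, normalized. Voxels farther than `far` um from
#' every axis fall back to the nearest axis and are flagged.
#'
#' @param model a `standard_model`.
#' @param spacing voxel edge length, um.
#' @param far fallback distance, um.
#' @return list with `origin`, `spacing`, `dims`, `vectors` (nvox x 3,
#'   voxel-major x fastest) and `flagged` (logical).
#' @export
build_orientation_field <- function(model, spacing = 50, far = 600) {
  anchors <- lapply(rownames(model$landmarks), function(l)
    model_column(model, l))
  pts <- rbind(do.call(rbind, lapply(anchors, `[[`, "pia")),
               do.call(rbind, lapply(anchors, `[[`, "wm")))
  lo <- apply(pts, 2, min) - spacing
  hi <- apply(pts, 2, max) + spacing
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)))
  gx <- lo[1] + (seq_len(dims[1]) - 0.5) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 0.5) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 0.5) * spacing
  g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  na <- length(anchors)
  D <- matrix(Inf, nrow(g), na)
  for (k in seq_len(na)) {
    a <- anchors[[k]]
    seg <- a$pia - a$wm
    len2 <- sum(seg^2)
    rel <- sweep(g, 2, a$wm)
    t_ <- pmin(pmax((rel %*% seg) / len2, 0), 1)
    D[, k] <- sqrt(rowSums((rel - t_ %*% t(seg))^2))
  }
  axes <- do.call(rbind, lapply(anchors, `[[`, "axis"))
  ord <- t(apply(D, 1, order))[, 1:3, drop = FALSE]
  d1 <- D[cbind(seq_len(nrow(g)), ord[, 1])]
  vec <- matrix(0, nrow(g), 3)
  w_of <- function(d) 1 / pmax(d, 1e-6)
  for (j in 1:3) {
    dk <- D[cbind(seq_len(nrow(g)), ord[, j])]
    vec <- vec + w_of(dk) * axes[ord[, j], , drop = FALSE]
  }
  flagged <- d1 > far
  if (any(flagged)) vec[flagged, ] <- axes[ord[flagged, 1], , drop = FALSE]
  vec <- vec / sqrt(rowSums(vec^2))
  list(origin = lo, spacing = spacing, dims = dims, vectors = vec,
       flagged = flagged)
}

#' Orientation-field vector nearest to a point
#'
#' @param field an orientation field from [build_orientation_field()].
#' @param point length-3 position, um.
#' @return unit length-3 vector.
#' @export
orientation_at <- function(field, point) {
  ijk <- pmin(pmax(floor((point - field$origin) / field$spacing) + 1, 1),
              field$dims)
  row <- (ijk[3] - 1) * field$dims[1] * field$dims[2] +
    (ijk[2] - 1) * field$dims[1] + ijk[1]
  field$vectors[row, ]
}

#' Across-animal landmark variability of the aligned fields
#'
#' Per label, the covariance matrix of the aligned BT (and BB) positions is
#' diagonalized; the square roots of the eigenvalues are reported along the
#' row / arc / column-axis directions (each eigenvector is attributed to the
#' frame direction it is most parallel to). SE = SD / sqrt(n). The
#' variability of the BC axes is the SD of per-field axis angles to the
#' standard axis, averaged over labels.
#'
#' @param fields aligned [barrel_field()] list (same frame as `model`).
#' @param model the corresponding `standard_model`.
#' @param min_fields minimal per-label sample size.
#' @return list with `table` (per label and landmark type: sd/se along row,
#'   arc, axis) and `axis_orientation_sd` (degrees).
#' @export
landmark_variability <- function(fields, model, min_fields = 3) {
  # bring the aligned fields into the model's own (C2) frame
  if (!is.null(model$to_model))
    fields <- lapply(fields, transform_field, tf = model$to_model)
  ex <- model$frame$ex; ey <- model$frame$ey
  rows <- list()
  axis_sds <- numeric(0)
  for (l in rownames(model$landmarks)) {
    col <- model_column(model, l)
    per <- lapply(fields, function(f) f$barrels[[l]])
    per <- per[!vapply(per, is.null, logical(1))]
    n <- length(per)
    if (n < min_fields) next
    for (type in c("bt", "bb")) {
      pts <- do.call(rbind, lapply(per, function(b) b$geometry[[type]]))
      cv <- stats::cov(pts)
      eg <- eigen(cv, symmetric = TRUE)
      sds <- sqrt(pmax(eg$values, 0))
      dirs <- rbind(row = ex, arc = ey, axis = col$axis)
      # attribute each eigenvector to its most parallel frame direction
      ali <- abs(dirs %*% eg$vectors)     # 3 directions x 3 eigenvectors
      assign <- rep(NA_integer_, 3)
      for (k in order(-sds)) {
        cand <- setdiff(order(-ali[, k]), assign)
        assign[k] <- cand[1]
      }
      out <- numeric(3)
      out[assign] <- sds
      rows[[length(rows) + 1]] <- data.frame(
        label = l, type = type, n = n,
        sd_row = out[1], sd_arc = out[2], sd_axis = out[3],
        se_row = out[1] / sqrt(n), se_arc = out[2] / sqrt(n),
        se_axis = out[3] / sqrt(n), stringsAsFactors = FALSE)
    }
    angles <- vapply(per, function(b)
      deg(angle_between(b$geometry$bt - b$geometry$bb, col$axis)),
      numeric(1))
    axis_sds <- c(axis_sds, stats::sd(angles))
  }
  list(table = do.call(rbind, rows),
       axis_orientation_sd = mean(axis_sds, na.rm = TRUE))
}

#' Standard error of a mean
#'
#' @param sd sample standard deviation.
#' @param n sample size.
#' @return `sd / sqrt(n)`.
#' @export
standard_error <- function(sd, n) sd / sqrt(n)

#' Combined 3D registration accuracy from per-axis standard errors
#'
#' Quadrature combination `sqrt(se_row^2 + se_arc^2 + se_z^2)` of the
#' tangential and vertical precisions into a single 3D accuracy.
#'
#' @param se_row,se_arc,se_z per-axis standard errors, um.
#' @return combined accuracy, um.
#' @export
registration_accuracy_3d <- function(se_row, se_arc, se_z) {
  sqrt(se_row^2 + se_arc^2 + se_z^2)
}
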