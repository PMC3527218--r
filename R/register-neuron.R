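# Four-step registration of a neuron morphology into the standard model:
# (1) rigid global registration of the traced barrel centers with the
# principal BC matched exactly, (2) orientation refinement from the
# smallest moment of inertia of the apical dendrite against the local
# orientation field, (3) correction of the traced landmark depths by the
# manual-vs-standard offsets, (4) stepwise linear scaling along the column
# axis matching pia/BT/BB/WM.

#' Step 1: global rigid registration of the traced barrel field
#'
#' The traced principal BC is aligned exactly to its standard counterpart;
#' the rotation about that point minimizes the squared distances of the
#' remaining traced BCs to their standard BCs (SVD solution, proper
#' rotation enforced). The principal-column residual is zero by
#' construction.
#'
#' @param landmarks an [experiment_landmarks()].
#' @param model a `standard_model`.
#' @return list with `transform` ([rigid_transform()]) and `rotation_deg`.
#' @export
register_global <- function(landmarks, model) {
  labs <- intersect(names(landmarks$barrels), rownames(model$landmarks))
  if (length(labs) < 3) stop("need at least 3 traced barrel centers")
  p <- do.call(rbind, lapply(landmarks$barrels[labs], `[[`, "bc"))
  q <- as.matrix(model$landmarks[labs, c("bc.x", "bc.y", "bc.z")])
  pr <- landmarks$principal
  ip <- which(labs == pr)
  p_pr <- p[ip, ]; q_pr <- q[ip, ]
  p0 <- sweep(p, 2, p_pr)
  q0 <- sweep(q, 2, q_pr)
  rot <- kabsch(p0, q0, translate = FALSE)
  tf <- rigid_transform(rot$R, as.numeric(q_pr - rot$R %*% p_pr))
  list(transform = tf, rotation_deg = deg(rotation_angle(rot$R)))
}

# Length-weighted segment midpoints of a subset of neuron nodes.
segment_midpoints <- function(neuron, types) {
  pi_ <- match(neuron$parent, neuron$id)
  sel <- which(neuron$type %in% types & !is.na(pi_))
  if (!length(sel)) return(NULL)
  xyz <- neuron_coords(neuron)
  a <- xyz[sel, , drop = FALSE]
  b <- xyz[pi_[sel], , drop = FALSE]
  list(mid = (a + b) / 2, w = sqrt(rowSums((a - b)^2)))
}

#' Step 2: orientation refinement against the local column axis
#'
#' The principal axis of smallest moment of inertia of the apical dendrite
#' (length-weighted segment midpoints) defines the neuron's vertical
#' orientation; the neuron is rotated about its soma so that this axis
#' matches the orientation-field vector nearest the soma. Neurons without
#' an apical dendrite fall back to the main descending axon, provided it
#' leaves the soma within 30 degrees of the local axis; otherwise the step
#' is skipped and flagged.
#'
#' @param neuron a [neuron_morphology()] (already globally registered).
#' @param model a `standard_model` (its orientation field is used), or a
#'   unit vector giving the local axis directly.
#' @return list with `neuron` (rotated), `rotation_deg`, `flagged`.
#' @export
refine_orientation <- function(neuron, model) {
  soma <- as.numeric(neuron[neuron$parent == -1, c("x", "y", "z")])
  v <- if (is.numeric(model)) normalize(model) else
    orientation_at(model$orientation_field, soma)
  seg <- segment_midpoints(neuron, 4)
  if (is.null(seg)) {
    seg <- segment_midpoints(neuron, 2)
    if (is.null(seg))
      return(list(neuron = neuron, rotation_deg = NA_real_, flagged = TRUE))
    # main axon must leave the soma roughly along the (downward) axis
    near <- sqrt(rowSums(sweep(seg$mid, 2, soma)^2)) < 250
    if (!any(near))
      return(list(neuron = neuron, rotation_deg = NA_real_, flagged = TRUE))
    dir0 <- normalize(soma - colSums(seg$mid[near, , drop = FALSE] *
                                       seg$w[near]) / sum(seg$w[near]))
    if (deg(angle_between(dir0, v)) > 30)
      return(list(neuron = neuron, rotation_deg = NA_real_, flagged = TRUE))
    seg$mid <- seg$mid[near, , drop = FALSE]
    seg$w <- seg$w[near]
    w_axis <- dir0
  } else {
    ctr <- colSums(seg$mid * seg$w) / sum(seg$w)
    rel <- sweep(seg$mid, 2, ctr)
    M <- crossprod(rel * seg$w, rel) / sum(seg$w)
    eg <- eigen(M, symmetric = TRUE)
    w_axis <- eg$vectors[, 1]          # largest spread = smallest inertia
    if (sum(w_axis * v) < 0) w_axis <- -w_axis
  }
  R <- rotation_between(w_axis, v)
  tf <- compose_rigid(rigid_transform(diag(3), soma),
                      compose_rigid(rigid_transform(R),
                                    rigid_transform(diag(3), -soma)))
  list(neuron = transform_neuron(neuron, tf),
       rotation_deg = deg(angle_between(w_axis, v)), flagged = FALSE)
}

# Depth of a point below the standard pia along the principal axis.
axis_depth <- function(point, col) sum((col$pia - point) * col$axis)

#' Step 3: correct traced landmark depths by manual-vs-standard offsets
#'
#' Shifts the principal column's BT, BB and WM landmarks along the local
#' axis by the mean manual-minus-standard depth offsets of that column, and
#' the traced pia by the tuft-to-pia calibration (+39 um) plus the
#' first-section thickness error (+20 um) where applicable. Columns absent
#' from the offset table get zero offsets with a warning.
#'
#' @param landmarks registered [experiment_landmarks()] (model frame).
#' @param model a `standard_model`.
#' @param offsets offset table, see [landmark_offsets()].
#' @param pia_offset,first_section_offset pia corrections, um.
#' @return corrected [experiment_landmarks()].
#' @export
correct_landmark_depths <- function(landmarks, model,
                                    offsets = landmark_offsets(),
                                    pia_offset = 39,
                                    first_section_offset = 20) {
  pr <- landmarks$principal
  col <- model_column(model, pr)
  a <- col$axis
  i <- match(pr, offsets$label)
  if (is.na(i)) {
    warning("no offsets for column ", pr, "; zero used")
    off <- c(bt = 0, bb = 0, wm = 0)
  } else {
    off <- c(bt = offsets$bt_offset[i], bb = offsets$bb_offset[i],
             wm = offsets$wm_offset[i])
  }
  # corrected depth = traced depth - (manual - standard); moving a point to
  # a smaller depth means shifting it pia-ward along the axis
  landmarks$barrels[[pr]]$bt <- landmarks$barrels[[pr]]$bt + a * off["bt"]
  landmarks$barrels[[pr]]$bb <- landmarks$barrels[[pr]]$bb + a * off["bb"]
  landmarks$wm_point <- landmarks$wm_point + a * off["wm"]
  shift <- pia_offset +
    if (isTRUE(landmarks$first_section_pia)) first_section_offset else 0
  landmarks$pia_point <- landmarks$pia_point - a * shift
  landmarks
}

#' Step 4: stepwise linear scaling along the column axis
#'
#' A continuous piecewise-linear map of the axial coordinate sends the
#' traced (pia, BT, BB, WM) depths of the principal column onto the
#' standard depths; the three factors are the ratios standard interval /
#' traced interval for the supragranular, granular and infragranular
#' compartments. Tangential coordinates are not scaled; points above the
#' pia or below the WM are extended with the boundary factor.
#'
#' @param neuron a registered [neuron_morphology()] (model frame).
#' @param landmarks corrected [experiment_landmarks()] (model frame).
#' @param model a `standard_model`.
#' @return list with `neuron` (scaled), `factors` (`c(supra, gran,
#'   infra)`), and `map` (the axial map as a function).
#' @export
stepwise_scale <- function(neuron, landmarks, model) {
  pr <- landmarks$principal
  col <- model_column(model, pr)
  t_traced <- c(axis_depth(landmarks$pia_point, col),
                axis_depth(landmarks$barrels[[pr]]$bt, col),
                axis_depth(landmarks$barrels[[pr]]$bb, col),
                axis_depth(landmarks$wm_point, col))
  t_std <- c(0, col$bt_depth, col$bb_depth, col$column_height)
  dtr <- diff(t_traced)
  if (any(dtr <= 0)) stop("non-positive traced interval: landmarks out of order")
  factors <- diff(t_std) / dtr
  axial_map <- function(t_) {
    out <- numeric(length(t_))
    below <- t_ < t_traced[1]
    out[below] <- t_std[1] + (t_[below] - t_traced[1]) * factors[1]
    above <- t_ >= t_traced[4]
    out[above] <- t_std[4] + (t_[above] - t_traced[4]) * factors[3]
    mid <- !below & !above
    if (any(mid)) {
      seg <- findInterval(t_[mid], t_traced, rightmost.closed = TRUE)
      seg <- pmin(pmax(seg, 1), 3)
      out[mid] <- t_std[seg] + (t_[mid] - t_traced[seg]) * factors[seg]
    }
    out
  }
  xyz <- neuron_coords(neuron)
  rel <- sweep(xyz, 2, col$pia)
  t_ <- as.numeric(rel %*% (-col$axis))
  lat <- rel + t_ %*% t(col$axis)
  t_new <- axial_map(t_)
  xyz_new <- sweep(lat - t_new %*% t(col$axis), 2, col$pia, "+")
  list(neuron = set_neuron_coords(neuron, xyz_new),
       factors = stats::setNames(factors, c("supra", "gran", "infra")),
       map = axial_map)
}

#' Register a neuron morphology into the standard model (all 4 steps)
#'
#' Runs [register_global()], [refine_orientation()],
#' [correct_landmark_depths()] and [stepwise_scale()] in sequence.
#'
#' @param neuron a [neuron_morphology()] (experiment frame).
#' @param landmarks the matching [experiment_landmarks()].
#' @param model a `standard_model`.
#' @param offsets per-column offset table for step 3.
#' @param refine run the orientation-refinement step.
#' @return object of class `registration_result`: registered `neuron` and
#'   `landmarks`, `global_rotation_deg`, `orientation_rotation_deg`,
#'   `factors`, `soma_depth` (registered, um), `precision` (per-column SE /
#'   SD / RMSE row) and the step-1 `transform`.
#' @export
register_neuron <- function(neuron, landmarks, model,
                            offsets = landmark_offsets(), refine = TRUE) {
  g <- register_global(landmarks, model)
  neuron1 <- transform_neuron(neuron, g$transform)
  lm1 <- transform_landmarks(landmarks, g$transform)
  rot2 <- NA_real_
  if (refine) {
    r <- refine_orientation(neuron1, model)
    neuron1 <- r$neuron
    rot2 <- r$rotation_deg
  }
  lm2 <- correct_landmark_depths(lm1, model, offsets)
  sc <- stepwise_scale(neuron1, lm2, model)
  col <- model_column(model, landmarks$principal)
  soma <- as.numeric(sc$neuron[sc$neuron$parent == -1, c("x", "y", "z")])
  prec <- column_precision()
  prec <- prec[prec$label == landmarks$principal, ]
  structure(list(neuron = sc$neuron, landmarks = lm2,
                 global_rotation_deg = g$rotation_deg,
                 orientation_rotation_deg = rot2,
                 factors = sc$factors,
                 soma_depth = axis_depth(soma, col),
                 soma = soma,
                 recording_depth = landmarks$recording_depth,
                 precision = prec, transform = g$transform,
                 principal = landmarks$principal),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: principal %s, global rotation %.1f deg, soma depth %.0f um\n",
    x$principal, x$global_rotation_deg, x$soma_depth))
  invisible(x)
}

#' Summary report of a neuron registration
#'
#' @param result a `registration_result`.
#' @return data.frame with the registered soma depth, the recording depth,
#'   their deviation (recording - registered; negative when the
#'   unregistered neuron appeared deeper), the scaling factors and the
#'   per-column precision measures (SE within the principal column, SD for
#'   surrounding columns, leave-one-out RMSE).
#' @export
registration_report <- function(result) {
  rec <- result$recording_depth %||% NA_real_
  data.frame(principal = result$principal,
             registered_depth = result$soma_depth,
             recording_depth = rec,
             deviation = rec - result$soma_depth,
             s_supra = result$factors["supra"],
             s_gran = result$factors["gran"],
             s_infra = result$factors["infra"],
             se = result$precision$se, sd = result$precision$sd,
             rmse = result$precision$rmse,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
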