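# Synthetic neuron morphologies with experiment-frame landmark sets.
#
# A neuron is generated at a known ground-truth location inside a barrel
# field / standard model; the whole scene (neuron + manually-traceable
# landmarks) is then re-expressed in a "cutting frame" rotated by the
# sectioning-angle mismatch and contaminated with the manual-tracing biases
# (deep-shifted principal landmarks, pia traced too high by 39 um plus a
# 20 um first-section thickness error) and landmark noise.

#' SWC-style neuron morphology container
#'
#' @param nodes data.frame with SWC semantics: `id`, `type` (1 soma,
#'   2 axon, 3 basal dendrite, 4 apical dendrite), `x`, `y`, `z` (um),
#'   `radius`, `parent` (-1 for the root).
#' @return object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(nodes) {
  stopifnot(all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(nodes)))
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) stop("need exactly one root node")
  if (nodes$type[roots] != 1) stop("root must be the soma")
  ord <- match(nodes$parent, nodes$id)
  if (any(is.na(ord) & nodes$parent != -1))
    stop("orphan node: parent id not found")
  structure(nodes, class = c("neuron_morphology", "data.frame"))
}

#' @export
print.neuron_morphology <- function(x, ...) {
  cat("neuron_morphology:", nrow(x), "nodes;",
      paste(names(table(x$type)), table(x$type), collapse = ", "), "\n")
  invisible(x)
}

neuron_coords <- function(neuron) as.matrix(neuron[, c("x", "y", "z")])

set_neuron_coords <- function(neuron, xyz) {
  neuron$x <- xyz[, 1]; neuron$y <- xyz[, 2]; neuron$z <- xyz[, 3]
  neuron
}

# Total path length (sum of parent-child segment lengths), um.
neuron_path_length <- function(neuron) {
  pi_ <- match(neuron$parent, neuron$id)
  ok <- !is.na(pi_)
  xyz <- neuron_coords(neuron)
  sum(sqrt(rowSums((xyz[ok, , drop = FALSE] -
                      xyz[pi_[ok], , drop = FALSE])^2)))
}

#' Experiment-frame landmark set accompanying a neuron tracing
#'
#' @param barrels named list (label -> `list(bc, bt, bb)` length-3 points).
#' @param principal label of the column containing the soma.
#' @param pia_point,wm_point traced pia/WM points on the principal axis.
#' @param section_thickness vibratome section thickness, um.
#' @param recording_depth pipette penetration depth, um (or `NA`).
#' @param first_section_pia whether the pia location stems from the first
#'   section (subject to the first-section thickness error).
#' @return object of class `experiment_landmarks`.
#' @export
experiment_landmarks <- function(barrels, principal, pia_point, wm_point,
                                 section_thickness = 100,
                                 recording_depth = NA_real_,
                                 first_section_pia = TRUE) {
  assert_barrel_label(names(barrels))
  if (!principal %in% names(barrels)) stop("principal column not in barrels")
  structure(list(barrels = barrels, principal = principal,
                 pia_point = as.numeric(pia_point),
                 wm_point = as.numeric(wm_point),
                 section_thickness = section_thickness,
                 recording_depth = recording_depth,
                 first_section_pia = first_section_pia),
            class = "experiment_landmarks")
}

transform_landmarks <- function(landmarks, tf) {
  landmarks$barrels <- lapply(landmarks$barrels, function(b)
    lapply(b, function(p) apply_rigid(tf, p)))
  landmarks$pia_point <- apply_rigid(tf, landmarks$pia_point)
  landmarks$wm_point <- apply_rigid(tf, landmarks$wm_point)
  landmarks
}

transform_neuron <- function(neuron, tf) {
  set_neuron_coords(neuron, apply_rigid(tf, neuron_coords(neuron)))
}

#' Generate a synthetic neuron with landmarks in a cutting frame
#'
#' Builds a pyramidal (apical dendrite elongated along the true local
#' column axis, tuft reaching the pia) or spiny-stellate (descending main
#' axon) morphology at a known soma depth, together with the manually
#' traceable landmark set (barrel BC/BT/BB points, pia and WM points of the
#' principal column). The scene is rotated into a cutting frame (angle
#' drawn from the observed sectioning mismatch, 14.0 +- 7.6 degrees, unless
#' given) and the landmarks carry the manual-tracing biases and Gaussian
#' noise.
#'
#' @param x a `standard_model` or [barrel_field()].
#' @param label principal column label.
#' @param soma_depth soma depth below the pia along the column axis, um.
#' @param kind `"pyramidal"` or `"stellate"`.
#' @param seed integer seed.
#' @param cutting_angle sectioning mismatch in degrees; `NULL` draws from
#'   `N(14, 7.6^2)` (truncated at 0).
#' @param cutting_translation translation of the cutting frame, um; `NULL`
#'   draws uniformly from +-200 per axis.
#' @param landmark_noise_sd isotropic noise on traced landmark points, um.
#' @param offsets per-column manual-minus-standard depth offsets, see
#'   [landmark_offsets()].
#' @param pia_offset,first_section_offset pia tracing biases, um (traced
#'   pia lies above the true pia by their sum).
#' @param recording_depth_bias,recording_depth_sd distribution of the
#'   recorded pipette depth around the true soma depth, um.
#' @return list with `neuron` ([neuron_morphology()]), `landmarks`
#'   ([experiment_landmarks()]), both in the cutting frame, and `truth`
#'   (true soma position/depth in the model frame, the cutting transform
#'   and angle).
#' @export
generate_neuron <- function(x, label, soma_depth, kind = c("pyramidal",
                                                           "stellate"),
                            seed = 1, cutting_angle = NULL,
                            cutting_translation = NULL,
                            landmark_noise_sd = 15,
                            offsets = landmark_offsets(),
                            pia_offset = 39, first_section_offset = 20,
                            recording_depth_bias = -46,
                            recording_depth_sd = 102) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  cols <- field_columns(x)
  assert_barrel_label(label)
  if (is.null(cols[[label]])) stop("label not present in the field/model")
  col <- cols[[label]]
  if (soma_depth < 0 || soma_depth > col$column_height)
    stop("soma depth outside the column")
  a <- col$axis
  soma <- col$pia - a * soma_depth
  bas <- plane_basis(a)

  nodes <- data.frame(id = 1, type = 1, x = soma[1], y = soma[2],
                      z = soma[3], radius = 8, parent = -1)
  addn <- function(pos, type, parent, radius = 0.8) {
    id <- nrow(nodes) + 1
    nodes[id, ] <<- c(id, type, pos, radius, parent)
    id
  }
  jitter3 <- function(sd = 3)
    as.numeric(bas$e1 * stats::rnorm(1, 0, sd) +
                 bas$e2 * stats::rnorm(1, 0, sd))

  if (kind == "pyramidal") {
    # apical trunk straight towards the pia, tuft reaching it
    par <- 1
    for (t_ in seq(soma_depth - 20, 60, by = -20)) {
      par <- addn(col$pia - a * t_ + jitter3(), 4, par, 1.5)
    }
    trunk_top <- par
    for (br in 1:2) {
      side <- (if (br == 1) 1 else -1) * bas$e1
      par <- trunk_top
      for (s_ in seq(15, 60, by = 15)) {
        t_ <- max(60 - s_, 0)
        par <- addn(col$pia - a * t_ + side * s_ + jitter3(2), 4, par, 1)
      }
    }
  }
  # basal dendrites
  nb <- if (kind == "pyramidal") 4 else 6
  for (br in seq_len(nb)) {
    az <- 2 * pi * br / nb
    dir <- normalize(cos(az) * bas$e1 + sin(az) * bas$e2 - 0.3 * a)
    par <- 1
    for (s_ in seq(30, 120, by = 30)) {
      par <- addn(soma + dir * s_ + jitter3(2), 3, par, 1)
    }
  }
  # main axon descending towards the WM
  par <- 1
  for (t_ in seq(soma_depth + 30, min(soma_depth + 600,
                                      col$column_height - 50), by = 30)) {
    sdj <- if (kind == "stellate") 1 else 3
    par <- addn(col$pia - a * t_ + jitter3(sdj), 2, par, 0.6)
  }
  neuron <- neuron_morphology(nodes)

  # true landmark set (model frame)
  true_barrels <- lapply(cols, function(c_) {
    list(bc = c_$bc, bt = c_$pia - c_$axis * c_$bt_depth,
         bb = c_$pia - c_$axis * c_$bb_depth)
  })
  off <- offsets[match(label, offsets$label), ]
  if (anyNA(off)) off <- data.frame(bt_offset = 0, bb_offset = 0,
                                    wm_offset = 0)
  traced <- true_barrels
  # principal-column landmarks deviate by the manual-minus-standard offsets
  traced[[label]]$bt <- col$pia - a * (col$bt_depth + off$bt_offset)
  traced[[label]]$bb <- col$pia - a * (col$bb_depth + off$bb_offset)
  pia_traced <- col$pia + a * (pia_offset + first_section_offset)
  wm_traced <- col$pia - a * (col$column_height + off$wm_offset)
  noise <- function(p) p + stats::rnorm(3, 0, landmark_noise_sd)
  if (landmark_noise_sd > 0) {
    traced <- lapply(traced, function(b) lapply(b, noise))
    pia_traced <- noise(pia_traced); wm_traced <- noise(wm_traced)
  }

  ang <- if (is.null(cutting_angle))
    abs(stats::rnorm(1, 14.0, 7.6)) else cutting_angle
  az <- stats::runif(1, 0, 2 * pi)
  horiz <- normalize(c(cos(az), sin(az), 0))
  if (is.null(cutting_translation))
    cutting_translation <- stats::runif(3, -200, 200)
  cut <- rigid_transform(rotation_about_axis(horiz, rad(ang)),
                         cutting_translation)
  # rotate about the soma, then translate
  cut <- compose_rigid(cut, rigid_transform(diag(3), -soma))
  cut <- compose_rigid(rigid_transform(diag(3), soma), cut)

  rec <- soma_depth + recording_depth_bias +
    stats::rnorm(1, 0, recording_depth_sd)
  lm <- experiment_landmarks(traced, label, pia_traced, wm_traced,
                             recording_depth = rec)
  list(neuron = transform_neuron(neuron, cut),
       landmarks = transform_landmarks(lm, cut),
       truth = list(soma = soma, soma_depth = soma_depth,
                    axis = a, cutting = cut, cutting_angle = ang))
}
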