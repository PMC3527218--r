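# Generalized Procrustes registration of corresponding landmark sets.
#
# The objective S is the sum over corresponding points i and over all pairs
# of reconstructions (u, v) of the squared distances between the matched
# points; only translations and rotations are used ("no scaling"), rotations
# coming from the SVD of the cross-covariance of corresponding points.

#' Generalized Procrustes registration (rigid, no scaling)
#'
#' Iterative scheme: an arbitrary reference (the first set) is chosen; each
#' point set is aligned to the reference by the optimal translation
#' (centroid match over shared points) and rotation (SVD of the
#' cross-covariance, reflections corrected to proper rotations); the
#' per-point centroids over all sets then become the reference of the next
#' iteration, until the maximum point displacement falls below `tol`
#' micrometers. Point sets may miss individual labels; correspondences are
#' formed per rowname.
#'
#' @param point_sets list of matrices (k_i x 3) with label rownames.
#' @param tol convergence threshold on the maximum point displacement, um.
#' @param max_iter iteration cap.
#' @return list with `transforms` (list of [rigid_transform()] per set),
#'   `aligned` (transformed point sets), `mean_shape` (per-label centroid
#'   matrix) and `state`: objective trajectory `S` (um^2), `iterations`,
#'   and `max_displacement` of the last iteration.
#' @export
gpa_register <- function(point_sets, tol = 1, max_iter = 50) {
  m <- length(point_sets)
  if (m < 2) stop("need at least 2 point sets")
  for (ps in point_sets) {
    if (is.null(rownames(ps))) stop("point sets need label rownames")
    if (nrow(ps) < 3) stop("need at least 3 labeled points per set")
  }
  all_names <- Reduce(union, lapply(point_sets, rownames))

  expand <- function(ps) {
    out <- matrix(NA_real_, length(all_names), 3,
                  dimnames = list(all_names, NULL))
    out[rownames(ps), ] <- ps
    out
  }
  cur <- lapply(point_sets, expand)
  tfs <- replicate(m, rigid_transform(), simplify = FALSE)

  mean_shape <- function(sets) {
    acc <- matrix(0, length(all_names), 3)
    cnt <- numeric(length(all_names))
    for (ps in sets) {
      ok <- stats::complete.cases(ps)
      acc[ok, ] <- acc[ok, ] + ps[ok, ]
      cnt[ok] <- cnt[ok] + 1
    }
    out <- acc / cnt
    rownames(out) <- all_names
    out
  }
  objective <- function(sets) {
    S <- 0
    for (u in seq_len(m - 1)) for (v in seq(u + 1, m)) {
      ok <- stats::complete.cases(sets[[u]]) & stats::complete.cases(sets[[v]])
      if (any(ok)) S <- S + sum((sets[[u]][ok, ] - sets[[v]][ok, ])^2)
    }
    S
  }

  ref <- cur[[1]]
  S_path <- objective(cur)
  max_disp <- Inf
  it <- 0
  while (it < max_iter && max_disp >= tol) {
    it <- it + 1
    prev <- cur
    for (u in seq_len(m)) {
      ok <- stats::complete.cases(cur[[u]]) & stats::complete.cases(ref)
      if (sum(ok) < 3) stop("fewer than 3 shared landmarks for set ", u)
      tf <- kabsch(cur[[u]][ok, , drop = FALSE], ref[ok, , drop = FALSE])
      cur[[u]][stats::complete.cases(cur[[u]]), ] <-
        apply_rigid(tf, cur[[u]][stats::complete.cases(cur[[u]]), ,
                                 drop = FALSE])
      tfs[[u]] <- compose_rigid(tf, tfs[[u]])
    }
    ref <- mean_shape(cur)
    S_path <- c(S_path, objective(cur))
    max_disp <- max(vapply(seq_len(m), function(u) {
      ok <- stats::complete.cases(cur[[u]]) & stats::complete.cases(prev[[u]])
      if (!any(ok)) return(0)
      max(sqrt(rowSums((cur[[u]][ok, , drop = FALSE] -
                          prev[[u]][ok, , drop = FALSE])^2)))
    }, numeric(1)))
  }
  aligned <- lapply(seq_len(m), function(u) {
    ok <- stats::complete.cases(cur[[u]])
    cur[[u]][ok, , drop = FALSE]
  })
  list(transforms = tfs, aligned = aligned, mean_shape = ref,
       state = list(S = S_path, iterations = it, max_displacement = max_disp))
}

#' Rigidly co-register several barrel fields
#'
#' Convenience wrapper: extracts the BT/BB landmark matrices of each field,
#' runs [gpa_register()] and returns the transformed fields together with
#' the registration state.
#'
#' @param fields list of [barrel_field()] objects.
#' @param ... passed to [gpa_register()].
#' @return list with `fields` (aligned), `gpa` (full [gpa_register()]
#'   output).
#' @export
register_fields <- function(fields, ...) {
  sets <- lapply(fields, field_landmarks)
  g <- gpa_register(sets, ...)
  aligned <- Map(function(f, tf) transform_field(f, tf), fields, g$transforms)
  list(fields = aligned, gpa = g)
}
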