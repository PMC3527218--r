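# Low-level 3D geometry: vectors, rigid transforms, meshes, ray casting.
# All lengths are in micrometers; all rotation matrices are proper (det +1).

vec_norm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

angle_between <- function(u, v) {
  cu <- normalize(u); cv <- normalize(v)
  d <- sum(cu * cv)
  acos(max(-1, min(1, d)))
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for the proper rotation by `angle` radians about the
#' (not necessarily unit) axis `axis`.
#'
#' @param axis length-3 numeric, rotation axis.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- normalize(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation taking direction u onto direction v.
rotation_between <- function(u, v) {
  u <- normalize(u); v <- normalize(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- normalize(pracma_cross(u, ref))
    return(rotation_about_axis(axis, pi))
  }
  axis <- pracma_cross(u, v)
  rotation_about_axis(axis, acos(max(-1, min(1, c_))))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Rigid 3D transform
#'
#' A proper rigid-body motion `x -> R x + t`. No scaling or reflection is
#' permitted: `R` must be orthonormal with determinant +1.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (micrometers).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("R is not orthonormal")
  if (det(R) < 0)
    stop("R is a reflection, not a proper rotation")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: rotation", format(deg(rotation_angle(x$R)), digits = 4),
      "deg, translation", format(vec_norm(x$t), digits = 4), "um\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param points length-3 vector or n x 3 matrix of points.
#' @return transformed points with the same shape.
#' @export
apply_rigid <- function(tf, points) {
  if (is.null(dim(points))) {
    as.numeric(tf$R %*% points + tf$t)
  } else {
    sweep(points %*% t(tf$R), 2, tf$t, "+")
  }
}

# b(a(x)): compose two rigid transforms.
compose_rigid <- function(b, a) {
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

invert_rigid <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Optimal rigid alignment of two corresponding point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum_i |R a_i + t - b_i|^2`. The reflection case of the SVD solution is
#' corrected by flipping the sign of the smallest singular vector, so the
#' result is always a proper rotation.
#'
#' @param a,b n x 3 matrices of corresponding points (n >= 3).
#' @param translate if `FALSE` the centroids are assumed already matched and
#'   only a rotation about the origin is fitted.
#' @return a [rigid_transform()].
#' @export
kabsch <- function(a, b, translate = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  if (nrow(a) < 3) stop("need at least 3 corresponding points")
  if (translate) {
    ca <- colMeans(a); cb <- colMeans(b)
    a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  } else {
    ca <- cb <- c(0, 0, 0)
    a0 <- a; b0 <- b
  }
  H <- crossprod(a0, b0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cb - as.numeric(R %*% ca))
}

#' Triangulated surface
#'
#' @param vertices n x 3 matrix of vertex positions (micrometers).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle index out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

mesh_triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

mesh_triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

#' Ray / mesh intersection
#'
#' Moeller-Trumbore intersection of the ray `origin + s * direction`
#' (`s > 0`) with every triangle; the nearest hit is returned.
#'
#' @param origin,direction length-3 numeric vectors.
#' @param mesh a [surface_mesh()].
#' @return list with `point` (length-3) and `distance`, or `NULL` when the
#'   ray misses the mesh.
#' @export
ray_mesh_intersect <- function(origin, direction, mesh) {
  d <- normalize(direction)
  v <- mesh$vertices; tr <- mesh$triangles
  p0 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - p0
  e2 <- v[tr[, 3], , drop = FALSE] - p0
  # h = d x e2
  h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  if (!any(ok)) return(NULL)
  f <- ifelse(ok, 1 / a, NA_real_)
  s <- sweep(-p0, 2, origin, "+")           # origin - p0
  u <- f * rowSums(s * h)
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- f * (q %*% d)[, 1]
  tt <- f * rowSums(e2 * q)
  hit <- ok & !is.na(u) & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 &
    tt > 1e-9
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.min(tt[hit])]
  list(point = origin + tt[i] * d, distance = tt[i])
}

# Distance from points (n x 3) to the infinite line through p0 along unit u.
lateral_distance <- function(points, p0, u) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  rel <- sweep(points, 2, p0)
  t_ <- rel %*% u
  perp <- rel - t_ %*% t(u)
  sqrt(rowSums(perp^2))
}

# Signed area of a closed planar polygon (shoelace; vertices not repeated).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(xy) {
  colMeans(xy)
}

# Interpolate mesh height z(x, y) for query points (k x 2) by barycentric
# interpolation on the triangle whose xy-projection contains the query.
mesh_height_at <- function(mesh, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, 1)
  v <- mesh$vertices; tr <- mesh$triangles
  out <- rep(NA_real_, nrow(xy))
  for (i in seq_len(nrow(tr))) {
    a <- v[tr[i, 1], ]; b <- v[tr[i, 2], ]; c_ <- v[tr[i, 3], ]
    det_ <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(det_) < 1e-12) next
    todo <- which(is.na(out))
    if (!length(todo)) break
    px <- xy[todo, 1]; py <- xy[todo, 2]
    l1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / det_
    l2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / det_
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(inside)) {
      idx <- todo[inside]
      out[idx] <- l1[inside] * a[3] + l2[inside] * b[3] + l3[inside] * c_[3]
    }
  }
  out
}
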