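# Domain containers and closed-form derived quantities.
#
# Conventions used throughout the package:
#   * all lengths in micrometers; volumes converted to mm^3 only on output;
#   * z increases towards the pia; depth below the pia is positive and is
#     measured along the local column axis;
#   * column axis unit vectors point from the white matter towards the pia.

#' Contour stack (serial planar outlines)
#'
#' Ordered closed outlines of one structure across optical/physical sections.
#' Contours are stored as n x 2 matrices of in-plane micrometer coordinates
#' (vertices not repeated); section z-positions must strictly increase.
#'
#' @param contours list of n_i x 2 numeric matrices.
#' @param z numeric vector of section z positions (micrometers).
#' @param pixel_size original pixel size in micrometers per pixel (or `NA`).
#' @return object of class `contour_stack`.
#' @export
contour_stack <- function(contours, z, pixel_size = NA_real_) {
  stopifnot(is.list(contours), length(contours) == length(z))
  if (length(z) > 1 && any(diff(z) <= 0))
    stop("section z positions must be strictly increasing")
  contours <- lapply(contours, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 3) stop("each contour needs >= 3 xy points")
    m
  })
  structure(list(contours = contours, z = as.numeric(z),
                 pixel_size = pixel_size),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat("contour_stack:", length(x$z), "sections, z in [",
      min(x$z), ",", max(x$z), "] um\n")
  invisible(x)
}

contour_areas <- function(stack) {
  vapply(stack$contours, polygon_area, numeric(1))
}

# 3D point rings (list of n x 3 matrices) from a contour stack.
contour_stack_to_3d <- function(stack) {
  Map(function(m, z) cbind(m, z), stack$contours, stack$z)
}

#' One barrel's geometry
#'
#' @param label barrel label (see [barrel_labels()]).
#' @param contours list of n x 3 matrices: closed outline rings in 3D.
#' @param area maximal tangential cross-section area, um^2.
#' @param bt,bb,bc barrel top / bottom / center points (length-3, um).
#' @return object of class `barrel_geometry`; `height` is |bt - bb|.
#' @export
barrel_geometry <- function(label, contours, area, bt, bb, bc = (bt + bb) / 2) {
  assert_barrel_label(label)
  if (!is.finite(area) || area <= 0) stop("barrel area must be > 0")
  height <- vec_norm(bt - bb)
  if (height <= 0) stop("barrel height must be > 0")
  structure(list(label = label, contours = contours, area = area,
                 bt = as.numeric(bt), bb = as.numeric(bb),
                 bc = as.numeric(bc), height = height),
            class = "barrel_geometry")
}

#' One column's geometry
#'
#' @param axis unit vector of the BC axis, pointing pia-ward.
#' @param pia_point,wm_point intersections of the axis with pia and WM.
#' @param orientation_deg tilt with respect to the C2 axis (C2 itself is 0).
#' @return object of class `column_geometry`; `column_height` is the pia-WM
#'   distance along the axis.
#' @export
column_geometry <- function(axis, pia_point, wm_point,
                            orientation_deg = NA_real_) {
  axis <- normalize(unname(as.numeric(axis)))
  column_height <- vec_norm(pia_point - wm_point)
  if (column_height <= 0) stop("column height must be > 0")
  structure(list(axis = axis, pia_point = as.numeric(pia_point),
                 wm_point = as.numeric(wm_point),
                 column_height = column_height,
                 orientation_deg = orientation_deg),
            class = "column_geometry")
}

#' Blood vessel traces
#'
#' @param polylines list of k_i x 3 matrices (k_i >= 2), micrometers.
#' @return object of class `vessel_graph` with per-vessel mean orientation
#'   unit vectors (pointing towards larger z, i.e. pia-ward).
#' @export
vessel_graph <- function(polylines) {
  stopifnot(is.list(polylines))
  ok <- vapply(polylines, function(p) is.matrix(p) && nrow(p) >= 2 &&
                 ncol(p) == 3, logical(1))
  if (length(polylines) && !all(ok)) stop("each vessel polyline needs >= 2 3D points")
  orientations <- t(vapply(polylines, function(p) {
    d <- p[nrow(p), ] - p[1, ]
    d <- normalize(d)
    if (d[3] < 0) d <- -d
    d
  }, numeric(3)))
  if (!length(polylines)) orientations <- matrix(numeric(0), 0, 3)
  structure(list(polylines = polylines, orientations = orientations),
            class = "vessel_graph")
}

#' Per-animal barrel field
#'
#' The complete set of labeled barrels, columns, pia/WM surfaces and vessel
#' traces of one animal, all expressed in one coordinate frame.
#'
#' @param barrels named list (by label) of `list(geometry = , column = )`.
#' @param pia,wm [surface_mesh()] objects.
#' @param vessels a [vessel_graph()].
#' @param animal animal identifier.
#' @return object of class `barrel_field`.
#' @export
barrel_field <- function(barrels, pia, wm, vessels = vessel_graph(list()),
                         animal = "unknown") {
  assert_barrel_label(names(barrels))
  if (length(barrels) > 24) stop("more than 24 barrels")
  for (b in barrels) {
    stopifnot(inherits(b$geometry, "barrel_geometry"),
              inherits(b$column, "column_geometry"))
    if (b$column$column_height < b$geometry$height - 1e-6)
      stop("column height below barrel height for ", b$geometry$label)
  }
  structure(list(barrels = barrels, pia = pia, wm = wm, vessels = vessels,
                 animal = animal),
            class = "barrel_field")
}

#' @export
print.barrel_field <- function(x, ...) {
  cat("barrel_field '", x$animal, "': ", length(x$barrels), " barrels, ",
      length(x$vessels$polylines), " vessels\n", sep = "")
  invisible(x)
}

#' Column diameter from the circular approximation of the barrel area
#'
#' @param area barrel area in um^2 (maximal tangential cross-section).
#' @return diameter of the circle with the same area, um: `2 * sqrt(area/pi)`.
#' @examples
#' column_diameter(10.30e4)  # C2: ~362 um
#' @export
column_diameter <- function(area) {
  if (any(!is.finite(area) | area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' Barrel and column volumes (cylindrical model)
#'
#' @param area barrel area, um^2.
#' @param barrel_height barrel (BT-BB) height, um.
#' @param column_height pia-WM distance, um.
#' @return list with `barrel_volume` and `column_volume` in mm^3.
#' @export
derived_volumes <- function(area, barrel_height, column_height) {
  if (any(!is.finite(c(area, barrel_height, column_height))) ||
      any(c(area, barrel_height, column_height) <= 0))
    stop("area and heights must be positive")
  if (any(column_height < barrel_height))
    stop("column height must be >= barrel height")
  list(barrel_volume = area * barrel_height * 1e-9,
       column_volume = area * column_height * 1e-9)
}

#' Supragranular / granular / infragranular layer profile
#'
#' Layer boundaries are taken at the BT and BB depths: the supragranular
#' compartment spans pia to BT, the granular compartment is the barrel
#' itself, the infragranular compartment spans BB to WM.
#'
#' @param bt_depth,bb_depth depths of BT and BB below the pia, um.
#' @param column_height pia-WM distance, um.
#' @return object of class `layer_profile` with thicknesses (um) and
#'   percentage fractions that sum to 100 within rounding.
#' @export
layer_profile <- function(bt_depth, bb_depth, column_height) {
  if (!(bt_depth > 0 && bb_depth > bt_depth && column_height > bb_depth))
    stop("require 0 < bt_depth < bb_depth < column_height")
  thick <- c(supra = bt_depth, gran = bb_depth - bt_depth,
             infra = column_height - bb_depth)
  structure(list(supra = thick[["supra"]], gran = thick[["gran"]],
                 infra = thick[["infra"]],
                 fractions = 100 * thick / column_height),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("layers s-g-i: %.0f-%.0f-%.0f um (%d%%-%d%%-%d%%)\n",
              x$supra, x$gran, x$infra,
              round(x$fractions[1]), round(x$fractions[2]),
              round(x$fractions[3])))
  invisible(x)
}

#' Orthonormal coordinate frame
#'
#' @param origin frame origin (length-3).
#' @param ex,ey,ez right-handed orthonormal basis vectors.
#' @return object of class `coordinate_frame`.
#' @export
coordinate_frame <- function(origin, ex, ey, ez) {
  B <- rbind(ex, ey, ez)
  if (max(abs(B %*% t(B) - diag(3))) > 1e-9)
    stop("basis is not orthonormal")
  if (det(B) < 0) stop("frame is not right-handed")
  structure(list(origin = as.numeric(origin), ex = as.numeric(ex),
                 ey = as.numeric(ey), ez = as.numeric(ez)),
            class = "coordinate_frame")
}

# World -> frame coordinates as a rigid transform.
frame_to_rigid <- function(frame) {
  B <- rbind(frame$ex, frame$ey, frame$ez)
  rigid_transform(B, as.numeric(-B %*% frame$origin))
}

#' Barrel-field coordinate frame anchored at the C2 column
#'
#' The frame origin is the C2 barrel center; `ez` is the C2 column axis
#' (pointing pia-ward), `ex` is the projection of the C2-to-C3 barrel-center
#' direction onto the plane perpendicular to `ez` (approximately along the
#' whisker row), and `ey = ez x ex` points approximately along the arc.
#'
#' @param field a [barrel_field()] containing C2 and C3.
#' @return a [coordinate_frame()].
#' @export
build_c2_frame <- function(field) {
  if (is.null(field$barrels[["C2"]]) || is.null(field$barrels[["C3"]]))
    stop("field must contain the C2 and C3 barrels")
  c2 <- field$barrels[["C2"]]; c3 <- field$barrels[["C3"]]
  origin <- c2$geometry$bc
  ez <- normalize(c2$column$axis)
  dx <- c3$geometry$bc - origin
  dx_perp <- dx - sum(dx * ez) * ez
  if (vec_norm(dx_perp) < 1e-6 * max(vec_norm(dx), 1))
    stop("degenerate frame: C3 displaced only along the C2 axis")
  ex <- normalize(dx_perp)
  ey <- pracma_cross(ez, ex)
  coordinate_frame(origin, ex, ey, ez)
}

# Landmark matrix (rownames "<label>.bt"/"<label>.bb") of a field, used for
# generalized Procrustes registration.
field_landmarks <- function(field) {
  labs <- names(field$barrels)
  pts <- do.call(rbind, lapply(labs, function(l) {
    b <- field$barrels[[l]]
    rbind(b$geometry$bt, b$geometry$bb)
  }))
  rownames(pts) <- as.vector(rbind(paste0(labs, ".bt"), paste0(labs, ".bb")))
  pts
}

#' Apply a rigid transform to a whole barrel field
#'
#' Transforms every stored point, axis, mesh vertex and vessel polyline.
#'
#' @param field a [barrel_field()].
#' @param tf a [rigid_transform()].
#' @return the transformed field.
#' @export
transform_field <- function(field, tf) {
  rot <- function(v) as.numeric(tf$R %*% v)
  field$barrels <- lapply(field$barrels, function(b) {
    g <- b$geometry
    g$bt <- apply_rigid(tf, g$bt); g$bb <- apply_rigid(tf, g$bb)
    g$bc <- apply_rigid(tf, g$bc)
    g$contours <- lapply(g$contours, function(m) apply_rigid(tf, m))
    cl <- b$column
    cl$axis <- rot(cl$axis)
    cl$pia_point <- apply_rigid(tf, cl$pia_point)
    cl$wm_point <- apply_rigid(tf, cl$wm_point)
    list(geometry = g, column = cl)
  })
  for (m in c("pia", "wm")) {
    field[[m]]$vertices <- apply_rigid(tf, field[[m]]$vertices)
  }
  field$vessels$polylines <- lapply(field$vessels$polylines,
                                    function(p) apply_rigid(tf, p))
  if (length(field$vessels$polylines))
    field$vessels <- vessel_graph(field$vessels$polylines)
  field
}
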