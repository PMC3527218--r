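# File formats: SWC neuron morphologies, ASCII PLY meshes, landmark and
# contour CSV/JSON, TIFF stacks, YAML run configuration.

#' Read a neuron morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), '#' comments
#' allowed. Parse errors (orphan nodes, missing root, cycles) report the
#' offending line.
#'
#' @param path file path.
#' @return a [neuron_morphology()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 7)
  if (length(bad))
    stop("SWC parse error at line ", ln[bad[1]], ": expected 7 columns")
  m <- do.call(rbind, lapply(fields, as.numeric))
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  orphan <- which(nodes$parent != -1 & !(nodes$parent %in% nodes$id))
  if (length(orphan))
    stop("SWC parse error at line ", ln[orphan[1]], ": orphan node ",
         nodes$id[orphan[1]])
  # cycle check by walking to the root from every node
  pidx <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0); j <- i
    while (!is.na(pidx[j])) {
      if (j %in% seen) stop("SWC parse error at line ", ln[i],
                            ": cyclic parent chain")
      seen <- c(seen, j)
      j <- pidx[j]
    }
  }
  neuron_morphology(nodes)
}

#' Write a neuron morphology as SWC
#'
#' @param neuron a [neuron_morphology()].
#' @param path output path.
#' @export
write_swc <- function(neuron, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC exported by barrelfield", con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     as.integer(neuron$id), as.integer(neuron$type),
                     neuron$x, neuron$y, neuron$z, neuron$radius,
                     as.integer(neuron$parent)), con)
  invisible(path)
}

#' Write / read a triangulated surface as ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  he <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  verts <- do.call(rbind, lapply(strsplit(lines[he + seq_len(nv)], " "),
                                 as.numeric))
  faces <- do.call(rbind, lapply(strsplit(lines[he + nv + seq_len(nf)], " "),
                                 as.integer))
  if (any(faces[, 1] != 3)) stop("only triangle faces supported")
  surface_mesh(verts[, 1:3, drop = FALSE], faces[, 2:4, drop = FALSE] + 1L)
}

#' Write / read a contour stack as CSV
#'
#' Long format: `section, z, vertex, x, y` with micrometer coordinates;
#' coordinates round-trip bit-exactly through the decimal representation.
#'
#' @param stack a [contour_stack()].
#' @param path file path.
#' @export
write_contours_csv <- function(stack, path) {
  rows <- do.call(rbind, lapply(seq_along(stack$z), function(s) {
    m <- stack$contours[[s]]
    data.frame(section = s, z = stack$z[s], vertex = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2])
  }))
  utils::write.csv(format(rows, digits = 17, scientific = FALSE,
                          trim = TRUE), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  d <- utils::read.csv(path)
  secs <- sort(unique(d$section))
  contours <- lapply(secs, function(s) {
    m <- d[d$section == s, ]
    as.matrix(m[order(m$vertex), c("x", "y")])
  })
  z <- vapply(secs, function(s) d$z[d$section == s][1], numeric(1))
  contour_stack(lapply(contours, unname), z)
}

#' Serialize barrel-field landmarks to JSON
#'
#' Writes per-barrel BT/BB/BC points, axes, areas and column heights with a
#' frame tag; 6-decimal micrometer precision (sub-nanometer).
#'
#' @param field a [barrel_field()].
#' @param path file path.
#' @param frame frame tag stored in the file.
#' @export
write_field_json <- function(field, path, frame = "experiment") {
  barrels <- lapply(field$barrels, function(b) {
    list(bt = round(b$geometry$bt, 6), bb = round(b$geometry$bb, 6),
         bc = round(b$geometry$bc, 6), area = round(b$geometry$area, 6),
         axis = round(b$column$axis, 9),
         pia_point = round(b$column$pia_point, 6),
         wm_point = round(b$column$wm_point, 6),
         orientation_deg = round(b$column$orientation_deg, 6))
  })
  jsonlite::write_json(list(animal = field$animal, frame = frame,
                            barrels = barrels),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a grayscale image stack as (multi-page) TIFF
#'
#' @param stack a [section_stack()].
#' @param path file path.
#' @param bits bits per sample (16 preserves the intensity range).
#' @export
write_stack_tiff <- function(stack, path, bits = 16) {
  imgs <- lapply(seq_along(stack$z), function(s) t(stack$data[, , s]))
  tiff::writeTIFF(imgs, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param z section z positions to attach on reading.
#' @param pixel_size um per pixel.
#' @param origin um position of pixel `[1, 1]`.
#' @export
read_stack_tiff <- function(path, z = NULL, pixel_size = 1,
                            origin = c(0, 0)) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  arr <- array(0, c(ncol(imgs[[1]]), nrow(imgs[[1]]), length(imgs)))
  for (s in seq_along(imgs)) arr[, , s] <- t(imgs[[s]])
  if (is.null(z)) z <- seq_along(imgs)
  section_stack(arr, z, pixel_size, origin)
}

# default run configuration (all tunable thresholds of the pipeline)
default_config <- function() {
  list(seed = 1,
       pixel_size = 4, section_spacing = 10,
       closing_radius = 4, min_ratio = 1.10,
       vessel_max_angle = 10, vessel_tolerance = 5,
       axis_search_radius = 2000,
       gpa_tolerance = 1,
       orientation_spacing = 50,
       overlap_bin = 50, overlap_spacing = 5,
       voxel_spacing = 10,
       pia_offset = 39, first_section_offset = 20)
}

#' Read a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys are filled with the package
#' defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}
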