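# Shared fixtures, built in code. Heavy objects (the 12-field simulated
# cohort and its standard model) are cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

nrm <- function(v) v / sqrt(sum(v^2))

# flat-cortex, noise-free simulation parameters
flat_params <- function(vessel_density = 3, ...) {
  field_simulation_params(curvature_radius_321 = Inf,
                          curvature_radius_123 = Inf,
                          sd_scale = 0, pose = "identity",
                          vessel_density = vessel_density, ...)
}

# large flat pia/WM meshes at given z levels
flat_mesh <- function(z, half = 2500) {
  surface_mesh(rbind(c(-half, -half, z), c(half, -half, z),
                     c(-half, half, z), c(half, half, z)),
               rbind(c(1, 2, 3), c(2, 4, 3)))
}

# minimal barrel entry: cylinder of radius r at tangential position x,
# tilted by `tilt` radians in the xz-plane
toy_barrel <- function(label, x, tilt = 0, r = 200, bt = 500, bb = 800,
                       height_col = 1900) {
  ax <- nrm(c(sin(tilt), 0, cos(tilt)))
  pia <- c(x, 0, 0)
  geom <- barrel_geometry(label, list(), pi * r^2, pia - ax * bt,
                          pia - ax * bb)
  col <- column_geometry(ax, pia, pia - ax * height_col)
  list(geometry = geom, column = col)
}

toy_field <- function(barrels) {
  barrel_field(barrels, flat_mesh(5), flat_mesh(-1950), animal = "toy")
}

# simulated 12-animal cohort under the default (printed-table) conditions
cohort <- function() {
  cached("cohort", lapply(1:12, function(s) generate_barrel_field(seed = s)))
}

cohort_fields <- function() lapply(cohort(), `[[`, "field")

cohort_registration <- function() {
  cached("registration", register_fields(cohort_fields()))
}

cohort_model <- function() {
  cached("model", build_standard_model(cohort_registration()$fields))
}

# disk image: bright disk(s) on darker background, optional noise
disk_image <- function(n = 128, centers, radii, fg = 0.8, bg = 0.4,
                       noise = 0, seed = 1) {
  set.seed(seed)
  img <- matrix(bg, n, n)
  for (k in seq_along(radii)) {
    dx2 <- (seq_len(n) - centers[[k]][1])^2
    dy2 <- (seq_len(n) - centers[[k]][2])^2
    img[outer(dx2, dy2, "+") <= radii[k]^2] <- fg
  }
  if (noise > 0) img <- img + matrix(rnorm(n * n, 0, noise), n, n)
  pmin(pmax(img, 0), 1)
}
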