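# Synthetic data: geometric phantoms with analytically known volumes,
# analytic dose fields sampled at voxel centres, and template-conformant
# synthetic patient records / cohorts. Everything is reproducible from an
# explicit seed; the global RNG state is never disturbed.

with_rtqa_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# derive a child seed below 2^31 from a parent seed and a label
derive_seed <- function(seed, label) {
  h <- digest::digest(paste(seed, label, sep = "/"), algo = "sha256",
                      serialize = FALSE)
  strtoi(substr(h, 1, 7), 16L)
}

#' Phantom specification
#'
#' @param shape "BOX", "CYLINDER" or "SPHERE"
#' @param center (x, y, z) centre in mm
#' @param dimensions BOX: (lx, ly, lz); CYLINDER: (radius, height);
#'   SPHERE: radius — all in mm, all > 0
#' @param slice_thickness contour plane spacing in mm
#' @param polygon_vertices circle discretization (>= 8)
#' @return object of class `rt_phantom_spec`
#' @export
phantom_spec <- function(shape, center = c(0, 0, 0), dimensions,
                         slice_thickness = 2, polygon_vertices = 64L) {
  shape <- toupper(shape)
  stopifnot(shape %in% c("BOX", "CYLINDER", "SPHERE"))
  if (any(dimensions <= 0)) rtqa_error("dimensions must be > 0", "rtqa_bad_spec")
  if (polygon_vertices < 8L) rtqa_error("polygon_vertices must be >= 8", "rtqa_bad_spec")
  extent_z <- switch(shape, BOX = dimensions[3], CYLINDER = dimensions[2],
                     SPHERE = 2 * dimensions[1])
  if (slice_thickness > extent_z)
    rtqa_error("slice_thickness exceeds the solid's z extent",
               "rtqa_degenerate_phantom")
  structure(list(shape = shape, center = as.numeric(center),
                 dimensions = as.numeric(dimensions),
                 slice_thickness = as.numeric(slice_thickness),
                 polygon_vertices = as.integer(polygon_vertices)),
            class = "rt_phantom_spec")
}

.regular_polygon <- function(cx, cy, r, n, z) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th), z)
}

#' Generate a phantom structure from a spec
#'
#' Slice planes are placed at the centres of `slice_thickness`-thick slabs
#' spanning the solid's z extent. The analytic volume of the ideal solid is
#' attached as `analytic_volume_mm3`.
#'
#' @param spec an [phantom_spec()]
#' @param name structure name
#' @param roi_number ROI identifier
#' @return an [rt_structure()]
#' @export
make_structure <- function(spec, name = tolower(spec$shape), roi_number = 1L) {
  cx <- spec$center[1]; cy <- spec$center[2]; cz <- spec$center[3]
  st <- spec$slice_thickness
  if (spec$shape == "BOX") {
    lx <- spec$dimensions[1]; ly <- spec$dimensions[2]; lz <- spec$dimensions[3]
    nslice <- max(1L, round(lz / st))
    zs <- cz - lz / 2 + (seq_len(nslice) - 0.5) * (lz / nslice)
    contours <- lapply(zs, function(z)
      cbind(cx + c(-1, 1, 1, -1) * lx / 2, cy + c(-1, -1, 1, 1) * ly / 2, z))
    vol <- lx * ly * lz
  } else if (spec$shape == "CYLINDER") {
    r <- spec$dimensions[1]; h <- spec$dimensions[2]
    nslice <- max(1L, round(h / st))
    zs <- cz - h / 2 + (seq_len(nslice) - 0.5) * (h / nslice)
    contours <- lapply(zs, function(z)
      .regular_polygon(cx, cy, r, spec$polygon_vertices, z))
    vol <- pi * r^2 * h
  } else { # SPHERE
    r <- spec$dimensions[1]
    nslice <- max(1L, round(2 * r / st))
    zs <- cz - r + (seq_len(nslice) - 0.5) * (2 * r / nslice)
    contours <- lapply(zs, function(z) {
      rz <- sqrt(max(0, r^2 - (z - cz)^2))
      .regular_polygon(cx, cy, rz, spec$polygon_vertices, z)
    })
    vol <- 4 / 3 * pi * r^3
  }
  rt_structure(name, roi_number, contours,
               analytic_volume_mm3 = vol)
}

#' Dose-field specification
#'
#' @param kind "UNIFORM" (parameters: level Gy), "LINEAR_X" (gradient
#'   Gy/mm, intercept Gy at x = 0) or "SPHERICAL_FALLOFF" (center mm,
#'   peak Gy, radius mm: linear falloff from peak at the centre to 0 at
#'   `radius`, 0 outside)
#' @param ... kind-specific parameters (see above)
#' @return object of class `rt_dose_field_spec`
#' @export
dose_field_spec <- function(kind, ...) {
  kind <- toupper(kind)
  stopifnot(kind %in% c("UNIFORM", "LINEAR_X", "SPHERICAL_FALLOFF"))
  p <- list(...)
  defaults <- switch(kind,
    UNIFORM = list(level = 20),
    LINEAR_X = list(gradient = 0.1, intercept = 0),
    SPHERICAL_FALLOFF = list(center = c(0, 0, 0), peak = 70, radius = 50))
  p <- utils::modifyList(defaults, p)
  structure(c(list(kind = kind), p), class = "rt_dose_field_spec")
}

.dose_field_at <- function(spec, x, y, z) {
  switch(spec$kind,
    UNIFORM = rep(spec$level, length(x)),
    LINEAR_X = pmax(0, spec$intercept + spec$gradient * x),
    SPHERICAL_FALLOFF = {
      r <- sqrt((x - spec$center[1])^2 + (y - spec$center[2])^2 +
                (z - spec$center[3])^2)
      pmax(0, spec$peak * (1 - r / spec$radius))
    })
}

#' Sample an analytic dose field onto a grid
#'
#' @param spec an [dose_field_spec()]
#' @param origin (x, y, z) mm of the first voxel centre
#' @param spacing (dx, dy, dz) mm
#' @param shape (nx, ny, nz) voxel counts
#' @param frame_of_reference frame-of-reference UID
#' @return an [rt_dose_grid()] with values sampled at voxel centres
#' @export
make_dose_grid <- function(spec, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                           shape = c(50, 50, 25),
                           frame_of_reference = rtqa_uid("FOR")) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xs <- origin[1] + (seq_len(nx) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(ny) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(nz) - 1) * spacing[3]
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)
  vals <- array(.dose_field_at(spec, px, py, pz), dim = c(nx, ny, nz))
  rt_dose_grid(origin = origin, spacing = spacing[1:2],
               z_offsets = (seq_len(nz) - 1) * spacing[3],
               values = vals, dose_units = "GY",
               frame_of_reference = frame_of_reference)
}
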