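# DVH engine: rasterize structures onto the dose grid, build cumulative
# dose-volume histograms, evaluate standard metrics.
#
# Conventions (stated, tested):
#  - rasterization happens on the dose grid; the dose is never resampled
#  - membership is decided at voxel centres (supersample 1) or at s x s
#    sub-centres averaged (supersample s)
#  - polygons on one plane combine by the even-odd rule (holes subtract);
#    points exactly on a polygon boundary count as inside
#  - each contour is assigned to the nearest grid plane within half the
#    median plane spacing

# Even-odd point-in-polygon with boundary-inclusive convention.
# px, py: point coordinates; polys: list of n x 2 matrices.
.pip_evenodd <- function(px, py, polys, eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (poly in polys) {
    n <- nrow(poly)
    x1 <- poly[, 1]; y1 <- poly[, 2]
    x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
    crossings <- rep(FALSE, length(px))
    for (e in seq_len(n)) {
      ax <- x1[e]; ay <- y1[e]; bx <- x2[e]; by <- y2[e]
      straddles <- (ay > py) != (by > py)
      if (any(straddles)) {
        xint <- ax + (py[straddles] - ay) * (bx - ax) / (by - ay)
        hit <- straddles
        hit[straddles] <- px[straddles] < xint
        crossings <- xor(crossings, hit)
      }
      # boundary test: point within eps of segment [a, b]
      dx <- bx - ax; dy <- by - ay
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- ((px - ax) * dx + (py - ay) * dy) / len2
        t <- pmin(1, pmax(0, t))
        qx <- ax + t * dx; qy <- ay + t * dy
        on_edge <- on_edge | ((px - qx)^2 + (py - qy)^2 <= eps^2)
      }
    }
    inside <- xor(inside, crossings)
  }
  inside | on_edge
}

#' Rasterize a structure onto a dose grid
#'
#' Each contour plane defines a slab of the structure's slice thickness
#' (the median spacing of its distinct contour z positions; the grid plane
#' spacing if there is only one contour plane). A grid plane adopts the
#' polygons of its nearest contour plane when it lies within half a slab;
#' a grid plane sitting exactly on an outer face (half a slab beyond the
#' first/last contour) contributes with weight 1/2. In-plane membership is
#' decided
#' at voxel centres (supersample 1) or averaged over s x s sub-centres;
#' polygons on one plane combine by the even-odd rule and boundary points
#' count as inside.
#'
#' @param structure an [rt_structure()]
#' @param grid an [rt_dose_grid()] sharing the structure's frame of reference
#' @param supersample integer >= 1; membership is averaged over an s x s
#'   grid of sub-centres per voxel
#' @return object of class `rt_structure_mask`: occupancy array (fractions
#'   in \[0,1\], same dim as the grid), voxel_volume (mm^3), structure_name
#' @export
rasterize_structure <- function(structure, grid, supersample = 1L) {
  stopifnot(supersample >= 1L)
  if (!is.null(structure$frame_of_reference) &&
      !is.null(grid$frame_of_reference) &&
      !is.null(attr(structure, "frame_of_reference")) &&
      !identical(attr(structure, "frame_of_reference"), grid$frame_of_reference))
    rtqa_error("structure and grid frames of reference differ", "rtqa_wiring_error")
  d <- dim(grid$values)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dx <- grid$spacing[1]; dy <- grid$spacing[2]
  pz <- grid_plane_z(grid)
  gz <- if (nz > 1L) stats::median(diff(pz)) else 1
  eps <- 1e-6

  # group polygons by distinct contour plane
  czs_all <- vapply(structure$contours, function(m) m[1, 3], numeric(1))
  czs <- sort(unique(czs_all))
  slab <- if (length(czs) > 1L) stats::median(diff(czs)) else gz
  polys_by_cz <- lapply(czs, function(z) {
    idx <- which(abs(czs_all - z) < eps)
    lapply(structure$contours[idx], function(m) m[, 1:2, drop = FALSE])
  })

  # every contour must be reachable from the grid
  tol_grid <- if (nz > 1L) 0.5 * stats::median(diff(pz)) else Inf
  for (zc in czs) {
    if (min(abs(pz - zc)) > tol_grid + eps)
      rtqa_error(sprintf("contour at z=%.3f mm is farther than %.3f mm from every grid plane",
                         zc, tol_grid), "rtqa_out_of_grid")
  }

  # assign each grid plane to its nearest contour plane within half a slab;
  # a plane beyond the outer contours at exactly half a slab sits on the
  # solid's face and contributes with weight 1/2 (midpoint rule at the jump)
  by_plane <- vector("list", nz)
  plane_weight <- numeric(nz)
  for (iz in seq_len(nz)) {
    z <- pz[iz]
    i <- which.min(abs(czs - z))
    dist <- abs(czs[i] - z)
    outside <- z < czs[1] - eps || z > czs[length(czs)] + eps
    w <- if (dist < slab / 2 - eps) 1
         else if (dist <= slab / 2 + eps) (if (outside) 0.5 else 1)
         else 0
    if (w > 0) {
      by_plane[[iz]] <- polys_by_cz[[i]]
      plane_weight[iz] <- w
    }
  }

  s <- as.integer(supersample)
  sub <- (seq_len(s) - 0.5) / s - 0.5   # sub-centre offsets in voxel units
  xs <- grid$origin[1] + (seq_len(nx) - 1L) * dx
  ys <- grid$origin[2] + (seq_len(ny) - 1L) * dy
  occ <- array(0, dim = d)

  for (iz in seq_len(nz)) {
    polys <- by_plane[[iz]]
    if (is.null(polys)) next
    allxy <- do.call(rbind, polys)
    pad <- 1.0
    ixr <- which(xs >= min(allxy[, 1]) - dx * pad & xs <= max(allxy[, 1]) + dx * pad)
    iyr <- which(ys >= min(allxy[, 2]) - dy * pad & ys <= max(allxy[, 2]) + dy * pad)
    if (!length(ixr) || !length(iyr)) next
    acc <- matrix(0, nrow = length(ixr), ncol = length(iyr))
    for (ox in sub) for (oy in sub) {
      px <- rep(xs[ixr] + ox * dx, times = length(iyr))
      py <- rep(ys[iyr] + oy * dy, each = length(ixr))
      ins <- .pip_evenodd(px, py, polys)
      acc <- acc + matrix(as.numeric(ins), nrow = length(ixr))
    }
    occ[ixr, iyr, iz] <- occ[ixr, iyr, iz] + plane_weight[iz] * acc / (s * s)
  }
  occ[occ > 1] <- 1
  if (sum(occ) == 0)
    rtqa_error(sprintf("structure %s has zero occupancy on this grid",
                       structure$name), "rtqa_degenerate_structure")
  structure(list(occupancy = occ, voxel_volume = dx * dy * gz,
                 structure_name = structure$name,
                 frame_of_reference = grid$frame_of_reference),
            class = "rt_structure_mask")
}

#' Total masked volume in mm^3
#' @param mask an `rt_structure_mask`
#' @return volume in mm^3
#' @export
mask_volume <- function(mask) sum(mask$occupancy) * mask$voxel_volume

#' Compute a cumulative DVH
#'
#' The exported curve is binned at `bin_width`; the exact occupancy-weighted
#' voxel doses are retained on the object and all metrics are evaluated on
#' them, never on the bins.
#'
#' @param mask an `rt_structure_mask` built on `grid`
#' @param grid the [rt_dose_grid()] the mask was built on
#' @param bin_width curve bin width in Gy
#' @return object of class `rt_dvh` with fields structure_name, dose_edges,
#'   cum_volume_pct, total_volume_cc, doses, weights
#' @export
compute_dvh <- function(mask, grid, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  sel <- mask$occupancy > 0
  if (!any(sel))
    rtqa_error("empty mask", "rtqa_degenerate_structure")
  d <- grid$values[sel]
  w <- mask$occupancy[sel] * mask$voxel_volume
  ord <- order(d)
  ds <- d[ord]; ws <- w[ord]
  total <- sum(ws)
  maxd <- ds[length(ds)]
  edges <- bin_width * (0:(floor(maxd / bin_width) + 1L))
  below <- c(0, cumsum(ws))[findInterval(edges, ds, left.open = TRUE) + 1L]
  vpct <- 100 * (total - below) / total
  structure(list(structure_name = mask$structure_name,
                 dose_edges = edges, cum_volume_pct = vpct,
                 total_volume_cc = total / 1000,
                 doses = ds, weights = ws),
            class = "rt_dvh")
}

#' @export
print.rt_dvh <- function(x, ...) {
  cat(sprintf("<rt_dvh> %s: %.2f cc, Dmean %.2f Gy, Dmax %.2f Gy\n",
              x$structure_name, x$total_volume_cc,
              evaluate_metric(x, metric_spec("DMEAN")),
              evaluate_metric(x, metric_spec("DMAX"))))
  invisible(x)
}

#' @export
plot.rt_dvh <- function(x, ...) {
  graphics::plot(x$dose_edges, x$cum_volume_pct, type = "s",
                 xlab = "Dose (Gy)", ylab = "Volume (%)",
                 main = x$structure_name, ylim = c(0, 100), ...)
  invisible(x)
}

#' Construct a DVH metric specification
#'
#' @param kind one of "D_PCT", "D_CC", "V_GY", "DMEAN", "DMAX", "DMIN"
#' @param argument x in Dx% / Dx cc / Vx Gy; ignored for DMEAN/DMAX/DMIN
#' @param unit_out "GY", "PCT" or "CC" (only V_GY admits PCT/CC choice)
#' @return object of class `rt_metric_spec`
#' @export
metric_spec <- function(kind, argument = NA_real_, unit_out = NULL) {
  kind <- toupper(kind)
  kinds <- c("D_PCT", "D_CC", "V_GY", "DMEAN", "DMAX", "DMIN")
  if (!kind %in% kinds) rtqa_error(paste("unknown metric kind", kind),
                                   "rtqa_bad_metric")
  if (kind %in% c("D_PCT", "D_CC", "V_GY") && is.na(argument))
    rtqa_error(paste(kind, "requires an argument"), "rtqa_bad_metric")
  if (kind == "D_PCT" && (argument <= 0 || argument > 100))
    rtqa_error("Dx% argument must lie in (0, 100]", "rtqa_bad_metric")
  if (is.null(unit_out))
    unit_out <- switch(kind, V_GY = "PCT", "GY")
  structure(list(kind = kind, argument = as.numeric(argument),
                 unit_out = unit_out), class = "rt_metric_spec")
}

#' Parse a metric string ("D2%", "D0.1cc", "V70Gy", "Dmean", "Dmax", "Dmin")
#' @param s metric string
#' @return an [metric_spec()]
#' @export
parse_metric <- function(s) {
  s0 <- trimws(s)
  sl <- tolower(s0)
  if (sl == "dmean") return(metric_spec("DMEAN"))
  if (sl == "dmax") return(metric_spec("DMAX"))
  if (sl == "dmin") return(metric_spec("DMIN"))
  m <- regmatches(s0, regexec("^[Dd]([0-9.]+)%$", s0))[[1]]
  if (length(m)) return(metric_spec("D_PCT", as.numeric(m[2])))
  m <- regmatches(s0, regexec("^[Dd]([0-9.]+) ?cc$", s0))[[1]]
  if (length(m)) return(metric_spec("D_CC", as.numeric(m[2])))
  m <- regmatches(s0, regexec("^[Vv]([0-9.]+) ?[Gg]y(\\[cc\\])?$", s0))[[1]]
  if (length(m)) return(metric_spec("V_GY", as.numeric(m[2]),
                                    unit_out = if (nzchar(m[3])) "CC" else "PCT"))
  rtqa_error(paste("cannot parse metric:", s), "rtqa_bad_metric")
}

# Dx%: dose to the hottest x% of the volume. On the descending-sorted
# weighted dose atoms with cumulative volume c_i, D(x) = d_1 for x <= c_1
# and linear interpolation between (c_i, d_i) and (c_{i+1}, d_{i+1})
# otherwise, so D at an atom boundary equals that atom's dose.
.dvh_d_pct <- function(curve, x) {
  dd <- rev(curve$doses); wd <- rev(curve$weights)
  total <- sum(wd)
  cp <- 100 * cumsum(wd) / total
  cp[length(cp)] <- 100
  if (x <= cp[1]) return(dd[1])
  stats::approx(cp, dd, xout = x, rule = 2, ties = "ordered")$y
}

#' Evaluate a DVH metric exactly (weighted voxel doses, no binning)
#'
#' @param curve an `rt_dvh`
#' @param spec an [metric_spec()] or metric string
#' @return numeric value with a "unit" attribute ("GY", "PCT" or "CC")
#' @export
evaluate_metric <- function(curve, spec) {
  if (is.character(spec)) spec <- parse_metric(spec)
  ds <- curve$doses; ws <- curve$weights
  total <- sum(ws)
  val <- switch(spec$kind,
    DMAX = max(ds),
    DMIN = min(ds),
    DMEAN = sum(ds * ws) / total,
    D_PCT = .dvh_d_pct(curve, spec$argument),
    D_CC = {
      if (spec$argument > curve$total_volume_cc)
        rtqa_error(sprintf("D_CC argument %.3g cc exceeds structure volume %.3g cc",
                           spec$argument, curve$total_volume_cc),
                   "rtqa_domain_error")
      .dvh_d_pct(curve, 100 * spec$argument / curve$total_volume_cc)
    },
    V_GY = {
      pct <- 100 * sum(ws[ds >= spec$argument]) / total
      if (identical(spec$unit_out, "CC")) curve$total_volume_cc * pct / 100 else pct
    })
  attr(val, "unit") <- spec$unit_out
  val
}
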