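# Independent oracles: deliberately naive, loop-based implementations that
# share no code with the package internals.

# -- dynamic-programming Levenshtein distance --------------------------------
oracle_edit_distance <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in 1:na) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in 1:nb) {
      cost <- if (av[i] == bv[j]) 0 else 1
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1]
}

# -- scalar point-in-polygon (even-odd, boundary inclusive) ------------------
oracle_point_inside <- function(x, y, polys, eps = 1e-9) {
  inside <- FALSE
  for (poly in polys) {
    n <- nrow(poly)
    cross <- FALSE
    for (e in 1:n) {
      ax <- poly[e, 1]; ay <- poly[e, 2]
      f <- if (e == n) 1 else e + 1
      bx <- poly[f, 1]; by <- poly[f, 2]
      # boundary
      dx <- bx - ax; dy <- by - ay
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- ((x - ax) * dx + (y - ay) * dy) / len2
        t <- min(1, max(0, t))
        qx <- ax + t * dx; qy <- ay + t * dy
        if ((x - qx)^2 + (y - qy)^2 <= eps^2) return(TRUE)
      }
      if ((ay > y) != (by > y)) {
        xint <- ax + (y - ay) * (bx - ax) / (by - ay)
        if (x < xint) cross <- !cross
      }
    }
    inside <- xor(inside, cross)
  }
  inside
}

# -- brute-force rasterization + DVH -----------------------------------------
# Same declared conventions as the engine (nearest contour plane within half
# a slab, half-weight outer faces, voxel-centre membership), coded with
# explicit loops over planes and voxels.
oracle_voxel_weights <- function(struct, grid) {
  d <- dim(grid$values)
  dx <- grid$spacing[1]; dy <- grid$spacing[2]
  pz <- grid$origin[3] + grid$z_offsets
  gz <- if (d[3] > 1) median(diff(pz)) else 1
  eps <- 1e-6
  czs_all <- sapply(struct$contours, function(m) m[1, 3])
  czs <- sort(unique(czs_all))
  slab <- if (length(czs) > 1) median(diff(czs)) else gz
  w <- array(0, dim = d)
  for (iz in 1:d[3]) {
    z <- pz[iz]
    best <- 1
    for (i in seq_along(czs)) if (abs(czs[i] - z) < abs(czs[best] - z)) best <- i
    dist <- abs(czs[best] - z)
    outside <- z < czs[1] - eps || z > czs[length(czs)] + eps
    pw <- if (dist < slab / 2 - eps) 1
          else if (dist <= slab / 2 + eps) { if (outside) 0.5 else 1 }
          else 0
    if (pw == 0) next
    polys <- list()
    for (k in seq_along(struct$contours))
      if (abs(czs_all[k] - czs[best]) < eps)
        polys[[length(polys) + 1]] <- struct$contours[[k]][, 1:2, drop = FALSE]
    for (iy in 1:d[2]) {
      y <- grid$origin[2] + (iy - 1) * dy
      for (ix in 1:d[1]) {
        x <- grid$origin[1] + (ix - 1) * dx
        if (oracle_point_inside(x, y, polys))
          w[ix, iy, iz] <- pw * dx * dy * gz
      }
    }
  }
  w
}

# V(d) at given dose points, by direct counting
oracle_dvh_curve <- function(weights, grid, dose_points) {
  sel <- weights > 0
  total <- sum(weights[sel])
  vapply(dose_points, function(d0) {
    s <- 0
    dsel <- grid$values[sel]; wsel <- weights[sel]
    for (i in seq_along(dsel)) if (dsel[i] >= d0) s <- s + wsel[i]
    100 * s / total
  }, numeric(1))
}

# -- recursive decision-tree evaluator ---------------------------------------
oracle_tree_eval <- function(measure, features) {
  walk <- function(id) {
    node <- measure$nodes[[id]]
    if (!is.null(node$result)) return(node$result)
    v <- features[[node$field]]
    if (node$op == "EXISTS") {
      out <- !is.null(v)
    } else {
      if (is.null(v)) return("NOT_EVALUABLE")
      lit <- unlist(node$value)
      out <- switch(node$op,
        EQ = as.character(v) == as.character(lit)[1] ||
             (is.numeric(v) && is.numeric(lit) && v == lit),
        NE = !(as.character(v) == as.character(lit)[1] ||
               (is.numeric(v) && is.numeric(lit) && v == lit)),
        LT = as.numeric(v) < as.numeric(lit),
        LE = as.numeric(v) <= as.numeric(lit),
        GT = as.numeric(v) > as.numeric(lit),
        GE = as.numeric(v) >= as.numeric(lit),
        IN = as.character(v) %in% as.character(lit))
    }
    walk(if (isTRUE(out)) node$true else node$false)
  }
  walk(measure$root)
}

# -- hand-coded NCCN three-tier table ----------------------------------------
# Independent encoding of the published clinically-localized risk grouping.
oracle_nccn <- function(t_stage, gp, gs, psa) {
  t_rank <- match(t_stage,
                  c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4"))
  gsum <- gp + gs
  if (t_rank >= 7 || gsum >= 8 || psa > 20) return("HIGH")
  if (t_rank <= 4 && gsum <= 6 && psa < 10) return("LOW")
  "INTERMEDIATE"
}
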