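#' Occluder device specification
#'
#' Idealized parametric occluder models: a plug-type device is a single
#' capped cylinder (lobe) seated in the appendage neck; a pacifier-type
#' device adds a distally offset sealing disk wider than the lobe. Struts,
#' anchors, hubs and the catheter tip are omitted, mirroring the usual
#' CAD simplifications in LAAO flow modelling.
#'
#' @param device_type `"plug"` or `"pacifier"`.
#' @param size nominal (lobe) diameter, mm; must be positive.
#' @param lobe_length lobe length, mm.
#' @param disk_diameter sealing-disk diameter, mm (pacifier only; must be
#'   at least `size`).
#' @param disk_thickness disk thickness, mm (pacifier only).
#' @param disk_offset gap between the disk and the lobe proximal face, mm.
#' @return an object of class `device_spec`.
#' @export
device_spec <- function(device_type = c("plug", "pacifier"), size,
                        lobe_length = 0.75 * size, disk_diameter = NULL,
                        disk_thickness = 3, disk_offset = 4) {
  device_type <- match.arg(device_type)
  if (!is.numeric(size) || !is.finite(size) || size <= 0) {
    stop("invalid device_spec: 'size' must be positive")
  }
  if (lobe_length <= 0) stop("invalid device_spec: 'lobe_length' must be positive")
  if (device_type == "pacifier") {
    if (is.null(disk_diameter)) {
      stop("invalid device_spec: pacifier requires 'disk_diameter'")
    }
    if (disk_diameter < size) {
      stop("invalid device_spec: 'disk_diameter' must be >= 'size'")
    }
  } else {
    disk_diameter <- NULL
  }
  structure(list(device_type = device_type, size = size,
                 lobe_length = lobe_length, disk_diameter = disk_diameter,
                 disk_thickness = disk_thickness, disk_offset = disk_offset),
            class = "device_spec")
}

# closed capped cylinder along +z from z0 to z1, labelled per-part
capped_cylinder <- function(radius, z0, z1, n_circ, label) {
  body <- tube_mesh(rbind(c(0, 0, z0), c(0, 0, z1)), rep(radius, 2),
                    n_circ, label)
  cap0 <- disk_mesh(c(0, 0, z0), c(0, 0, -1), radius, n_circ, label)
  cap1 <- disk_mesh(c(0, 0, z1), c(0, 0, 1), radius, n_circ, label)
  merge_meshes(body, cap0, cap1)
}

#' Build an occluder surface mesh in canonical pose
#'
#' The device is built with its axis along +z and its proximal (atrial-side)
#' face in the z = 0 plane, extending distally into +z. The proximal face is
#' sealed (closed surface). A pacifier lobe sits distal to the disk.
#'
#' @param spec a [device_spec()].
#' @param edge_length target triangle edge length, mm.
#' @return a [surface_mesh()] with labels `device_lobe` (and `device_disk`
#'   for pacifiers), plus a `proximal_face` attribute
#'   (`list(center, normal, radius)` with the normal pointing proximally,
#'   i.e. -z) and a `device_spec` attribute.
#' @export
build_device <- function(spec, edge_length = 1.5) {
  if (!inherits(spec, "device_spec")) stop("spec must be a device_spec")
  r <- spec$size / 2
  n_circ <- max(24L, ceiling(pi * spec$size / edge_length))
  if (spec$device_type == "plug") {
    m <- capped_cylinder(r, 0, spec$lobe_length, n_circ, "device_lobe")
    face_r <- r
  } else {
    rd <- spec$disk_diameter / 2
    disk <- capped_cylinder(rd, 0, spec$disk_thickness, n_circ, "device_disk")
    lobe <- capped_cylinder(r, spec$disk_thickness + spec$disk_offset,
                            spec$disk_thickness + spec$disk_offset +
                              spec$lobe_length, n_circ, "device_lobe")
    m <- merge_meshes(disk, lobe)
    face_r <- rd
  }
  attr(m, "proximal_face") <- list(center = c(0, 0, 0),
                                   normal = c(0, 0, -1), radius = face_r)
  attr(m, "device_spec") <- spec
  attr(m, "axis") <- c(0, 0, 1)
  m
}

#' Appendage centerline
#'
#' Polyline of appendage cross-section centroids at fixed arc steps from the
#' ostium centroid towards the apex, computed from the `laa_wall` vertices.
#'
#' @param mesh atrium mesh from [generate_atrium()].
#' @param step arc step, mm.
#' @return matrix of centerline points (mm), first row on the ostium plane.
#' @export
laa_centerline <- function(mesh, step = 1) {
  oc <- attr(mesh, "ostium_center")
  ax <- attr(mesh, "laa_axis")
  L <- attr(mesh, "laa_length")
  if (is.null(oc) || is.null(ax) || is.null(L)) {
    stop("mesh lacks appendage descriptors")
  }
  wall_v <- unique(as.vector(mesh$faces[mesh$labels == "laa_wall", ]))
  V <- mesh$vertices[wall_v, , drop = FALSE]
  lf <- laa_frame(mesh, V)
  svals <- seq(0, L, by = step)
  out <- matrix(0, length(svals), 3)
  for (i in seq_along(svals)) {
    # epsilon keeps vertex rings lying exactly on the window edge intact
    sel <- abs(lf$s - svals[i]) <= max(step, 1.5) + 1e-6
    out[i, ] <- if (any(sel)) colMeans(V[sel, , drop = FALSE]) else
      oc + svals[i] * ax
  }
  # first point anchored to the ostium centroid
  out[1, ] <- oc
  out
}

#' Deploy a device along the appendage centerline
#'
#' Aligns the device axis with the local centerline tangent and places the
#' proximal face at signed distance `depth` from the ostium plane (negative
#' depths sit proximal of the ostium, covering the pulmonary ridge). The
#' placement is rigid; wall penetration is reported, not resolved.
#'
#' @param device canonical device mesh from [build_device()].
#' @param mesh atrium mesh from [generate_atrium()].
#' @param depth signed distance from the ostium plane, mm; must not exceed
#'   the appendage length.
#' @return the transformed device mesh; attributes `proximal_face` (moved
#'   with the device), `depth`, and `penetration_mm` (maximum radial
#'   protrusion of device vertices beyond the local appendage wall).
#' @export
place_device <- function(device, mesh, depth = 0) {
  L <- attr(mesh, "laa_length")
  if (depth > L) {
    stop("placement error: depth ", depth, " mm exceeds appendage length ",
         L, " mm")
  }
  cl <- laa_centerline(mesh)
  oc <- attr(mesh, "ostium_center")
  ax <- attr(mesh, "laa_axis")
  # local tangent at the target arc position
  s_tgt <- max(min(depth, L - 1e-6), 0)
  seg <- max(2L, min(nrow(cl), 1L + ceiling(s_tgt)))
  j0 <- max(1L, seg - 3L); j1 <- min(nrow(cl), seg + 2L)
  tangent <- cl[j1, ] - cl[j0, ]
  nt <- sqrt(sum(tangent^2))
  # coincident centroids can occur at coarse mesh resolution
  if (!is.finite(nt) || nt < 1e-6) tangent <- ax else tangent <- tangent / nt
  rot <- rotation_between(c(0, 0, 1), tangent)
  anchor <- oc + depth * ax
  placed <- transform_mesh(device, rot, anchor)
  pf <- attr(device, "proximal_face")
  attr(placed, "proximal_face") <- list(
    center = drop(rot %*% pf$center) + anchor,
    normal = drop(rot %*% pf$normal),
    radius = pf$radius)
  attr(placed, "axis") <- tangent
  attr(placed, "depth") <- depth
  # penetration: device vertices radially outside the local wall
  lf <- laa_frame(mesh, placed$vertices)
  inside_span <- lf$s >= 0 & lf$s <= L
  pen <- 0
  if (any(inside_span)) {
    overshoot <- lf$r[inside_span] - laa_radius_at(mesh, lf$s[inside_span])
    pen <- max(0, overshoot)
  }
  attr(placed, "penetration_mm") <- pen
  placed
}

# Planar-contour helpers ------------------------------------------------------

# Fit plane through contour (centroid + dominant SVD directions); returns the
# contour projected to 2D in-plane coordinates plus planarity residual.
contour_plane <- function(contour, tol = NULL) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("geometry error: contour needs >= 3 points")
  ctr <- colMeans(contour)
  d <- sweep(contour, 2, ctr, `-`)
  sv <- svd(d)
  xy <- d %*% sv$v[, 1:2, drop = FALSE]
  resid <- max(abs(d %*% sv$v[, 3]))
  if (!is.null(tol) && resid > tol) {
    stop("geometry error: contour not planar within tolerance (residual ",
         signif(resid, 3), " mm)")
  }
  list(center = ctr, xy = xy, normal = sv$v[, 3], residual = resid)
}

polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && s > 1e-9 && s < 1 - 1e-9
  }
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (seg_int(xy[idx[i, 1], ], xy[idx[i, 2], ],
                  xy[idx[j, 1], ], xy[idx[j, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Area and perimeter of a planar closed contour
#'
#' Area by the planar polygon (shoelace) formula on the plane fitted through
#' the points; perimeter by arc length of the closed polyline.
#'
#' @param contour n x 3 matrix of ordered contour points (mm); the closing
#'   edge from the last to the first point is implicit.
#' @param planar_tol maximum out-of-plane residual accepted, mm.
#' @return an object of class `ostium_metrics`: list with `area` (mm^2) and
#'   `perimeter` (mm); satisfies `perimeter^2 >= 4 * pi * area`.
#' @export
ostium_metrics <- function(contour, planar_tol = 0.5) {
  cp <- contour_plane(contour, tol = planar_tol)
  xy <- cp$xy
  if (polygon_self_intersects(xy)) {
    stop("geometry error: self-intersecting contour")
  }
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1], 1L)
  area <- abs(sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2])) / 2
  peri <- sum(sqrt(rowSums((xy[nxt, ] - xy)^2)))
  structure(list(area = area, perimeter = peri), class = "ostium_metrics")
}

#' Landing-zone diagonals of a planar contour
#'
#' Maximum diagonal (largest point-pair distance in the fitted plane),
#' minimum diagonal (minimum caliper width of the convex hull), and their
#' average, the sizing diameter used by manufacturer charts.
#'
#' @inheritParams ostium_metrics
#' @return an object of class `landing_zone`: list with `contour`, `d_max`,
#'   `d_min`, `d_mean` (mm); `d_min <= d_mean <= d_max`.
#' @export
landing_zone_diagonals <- function(contour, planar_tol = 0.5) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("geometry error: need >= 3 contour points")
  cp <- contour_plane(contour, tol = planar_tol)
  xy <- cp$xy
  hull <- grDevices::chull(xy)
  h <- xy[hull, , drop = FALSE]
  d_max <- max(stats::dist(h))
  # rotating-caliper width: min over hull edge directions of the projected extent
  nh <- nrow(h)
  nxt <- c(seq_len(nh)[-1], 1L)
  edges <- h[nxt, , drop = FALSE] - h
  len <- sqrt(rowSums(edges^2))
  keep <- len > 1e-12
  d_min <- min(vapply(which(keep), function(i) {
    nrm <- c(-edges[i, 2], edges[i, 1]) / len[i]
    pr <- h %*% nrm
    max(pr) - min(pr)
  }, 0))
  structure(list(contour = contour, d_max = d_max, d_min = d_min,
                 d_mean = (d_max + d_min) / 2),
            class = "landing_zone")
}

# distance from a point to a triangle (exact projection onto the triangle)
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

# minimum distance from point p to any face of the mesh
point_mesh_distance <- function(p, mesh) {
  fc <- face_corners(mesh)
  # prune with centroid distances first
  cen <- face_centroids(mesh)
  d0 <- sqrt(colSums((t(cen) - p)^2))
  # triangles whose centroid is within (min + largest edge) are candidates
  edge_max <- sqrt(max(rowSums((fc$a - fc$b)^2), rowSums((fc$b - fc$c)^2),
                       rowSums((fc$c - fc$a)^2)))
  cand <- which(d0 <= min(d0) + edge_max)
  min(vapply(cand, function(i) {
    point_triangle_distance(p, fc$a[i, ], fc$b[i, ], fc$c[i, ])
  }, 0))
}

#' Pulmonary-ridge coverage classification
#'
#' A device pose covers the pulmonary ridge when the Euclidean distance from
#' the LSPV endpoint (the ridge fold) to the device surface is at most
#' `threshold_mm`; strictly greater distances expose an uncovered wall
#' region between the ostium plane and the device proximal face, whose area
#' is reported. The 10 mm default follows the uncovered-ridge criterion used
#' clinically (uncovered requires a distance strictly greater than 10 mm, so
#' exactly 10 mm counts as covered).
#'
#' @param mesh atrium mesh (provides the appendage wall and, by default, the
#'   `lspv_endpoint` attribute).
#' @param device placed device mesh with faces labelled `device_*`.
#' @param lspv_endpoint optional 3-vector overriding the mesh attribute.
#' @param threshold_mm coverage threshold, mm.
#' @return an object of class `pr_coverage`: list with `lspv_endpoint`,
#'   `min_distance_to_device` (mm), `uncovered_region_area` (mm^2),
#'   `covered`.
#' @export
pr_coverage <- function(mesh, device, lspv_endpoint = NULL,
                        threshold_mm = 10) {
  if (is.null(device) || !any(grepl("^device", device$labels))) {
    stop("configuration error: missing device label")
  }
  if (is.null(lspv_endpoint)) lspv_endpoint <- attr(mesh, "lspv_endpoint")
  if (is.null(lspv_endpoint)) {
    stop("configuration error: no lspv_endpoint available")
  }
  dmin <- point_mesh_distance(lspv_endpoint, device)
  pf <- attr(device, "proximal_face")
  oc <- attr(mesh, "ostium_center")
  ax <- attr(mesh, "laa_axis")
  depth <- if (!is.null(pf) && !is.null(oc)) sum((pf$center - oc) * ax) else 0
  area <- 0
  if (!is.null(oc) && depth > 0) {
    cen <- face_centroids(mesh)
    lf <- laa_frame(mesh, cen)
    band <- mesh$labels == "laa_wall" & lf$s > 0 & lf$s < depth
    area <- sum(face_areas(mesh)[band])
  }
  structure(list(lspv_endpoint = lspv_endpoint,
                 min_distance_to_device = dmin,
                 uncovered_region_area = area,
                 covered = dmin <= threshold_mm),
            class = "pr_coverage")
}

#' Default device sizing table
#'
#' Maps landing-zone mean-diagonal intervals to nominal device sizes, one
#' row per interval, per device type. This is a documented package default
#' in the spirit of manufacturer sizing charts (which are not reproduced
#' verbatim); supply your own table to match a specific device generation.
#'
#' @return data.frame with columns `device_type`, `d_lo`, `d_hi` (mm,
#'   interval `[d_lo, d_hi)`), `size` (mm).
#' @export
default_sizing_table <- function() {
  rbind(
    data.frame(device_type = "plug",
               d_lo = c(14, 17, 20, 23, 26, 29),
               d_hi = c(17, 20, 23, 26, 29, 32),
               size = c(21, 24, 27, 30, 33, 35)),
    data.frame(device_type = "pacifier",
               d_lo = c(11, 13, 15, 17, 19, 21, 23, 25, 28),
               d_hi = c(13, 15, 17, 19, 21, 23, 25, 28, 31),
               size = c(16, 18, 20, 22, 25, 28, 30, 32, 34))
  )
}

#' Recommend a device size from landing-zone measurements
#'
#' Looks up the sizing-table interval containing the landing-zone mean
#' diagonal; a value on an interval boundary resolves to the larger size.
#'
#' @param zone a [landing_zone_diagonals()] result (or list with `d_mean`).
#' @param device_type `"plug"` or `"pacifier"`.
#' @param sizing_table table as from [default_sizing_table()].
#' @return nominal size, mm.
#' @export
recommend_size <- function(zone, device_type = c("plug", "pacifier"),
                           sizing_table = default_sizing_table()) {
  device_type <- match.arg(device_type)
  tab <- sizing_table[sizing_table$device_type == device_type, , drop = FALSE]
  if (nrow(tab) == 0L) stop("empty sizing table for device type ", device_type)
  d <- zone$d_mean
  lo <- min(tab$d_lo); hi <- max(tab$d_hi)
  if (d < lo || d > hi) {
    stop("out-of-range error: d_mean ", signif(d, 4),
         " mm outside sizing range [", lo, ", ", hi, "] mm")
  }
  # [d_lo, d_hi) intervals; boundary values fall into the upper interval,
  # i.e. ties break toward the larger size; d == max(d_hi) maps to the top row
  tab <- tab[order(tab$d_lo), , drop = FALSE]
  hit <- which(d >= tab$d_lo & d < tab$d_hi)
  if (length(hit) == 0L) hit <- nrow(tab)
  max(tab$size[hit])
}
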