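#' Labeled triangulated surface mesh
#'
#' Light-weight container for a triangulated surface with named regions.
#' Vertices are in millimetres; faces index into the vertex array; every face
#' carries a region label (e.g. `"chamber"`, `"laa_wall"`, `"device"`,
#' `"pv_inlet_1"`, `"mv_outlet"`).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param labels character vector of length m, one region label per face.
#' @param ... named attributes attached to the mesh (e.g. `ostium_contour`,
#'   `ostium_center`, `laa_axis`, `lspv_endpoint`).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, labels, ...) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (length(labels) != nrow(faces)) {
    stop("labels must have one entry per face")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  m <- structure(
    list(vertices = vertices, faces = faces, labels = as.character(labels)),
    class = "surface_mesh"
  )
  extra <- list(...)
  for (nm in names(extra)) attr(m, nm) <- extra[[nm]]
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  tb <- table(x$labels)
  cat("regions:", paste0(names(tb), " (", tb, ")", collapse = ", "), "\n")
  invisible(x)
}

# Per-face geometry -----------------------------------------------------------

face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

row_norms <- function(x) sqrt(rowSums(x * x))

#' Face centroids, normals and areas
#'
#' @param mesh a [surface_mesh()].
#' @return `face_centroids`: m x 3 matrix (mm); `face_normals`: m x 3 matrix of
#'   unit normals; `face_areas`: numeric vector (mm^2).
#' @export
face_centroids <- function(mesh) {
  fc <- face_corners(mesh)
  (fc$a + fc$b + fc$c) / 3
}

#' @rdname face_centroids
#' @export
face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- row_norms(n)
  len[len == 0] <- 1
  n / len
}

#' @rdname face_centroids
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  0.5 * row_norms(cross3(fc$b - fc$a, fc$c - fc$a))
}

#' Total surface area of a mesh or of one region
#'
#' @param mesh a [surface_mesh()].
#' @param label optional region label; if given, only faces with that label
#'   contribute.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh, label = NULL) {
  a <- face_areas(mesh)
  if (!is.null(label)) a <- a[mesh$labels %in% label]
  sum(a)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#'
#' @param mesh a closed, consistently oriented [surface_mesh()].
#' @return volume in mm^3 (absolute value).
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  abs(sum(rowSums(fc$a * cross3(fc$b, fc$c)))) / 6
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return the transformed mesh; labels and attributes are preserved, and any
#'   point-valued attributes listed in `point_attrs` are transformed too.
#' @param point_attrs character vector of attribute names holding 3-vectors or
#'   n x 3 matrices of points that must move with the mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           point_attrs = character()) {
  out <- mesh
  out$vertices <- sweep(mesh$vertices %*% t(rotation), 2, translation, `+`)
  for (nm in point_attrs) {
    p <- attr(mesh, nm)
    if (is.null(p)) next
    if (is.matrix(p)) {
      attr(out, nm) <- sweep(p %*% t(rotation), 2, translation, `+`)
    } else {
      attr(out, nm) <- drop(rotation %*% p) + translation
    }
  }
  out
}

#' Merge meshes, keeping labels
#'
#' @param ... surface_mesh objects.
#' @return a single [surface_mesh()]; attributes of the first argument win.
#' @export
merge_meshes <- function(...) {
  parts <- list(...)
  offs <- 0L
  verts <- list(); fcs <- list(); labs <- list()
  for (p in parts) {
    verts[[length(verts) + 1L]] <- p$vertices
    fcs[[length(fcs) + 1L]] <- p$faces + offs
    labs[[length(labs) + 1L]] <- p$labels
    offs <- offs + nrow(p$vertices)
  }
  m <- surface_mesh(do.call(rbind, verts), do.call(rbind, fcs),
                    unlist(labs))
  for (nm in setdiff(names(attributes(parts[[1]])), c("names", "class"))) {
    attr(m, nm) <- attr(parts[[1]], nm)
  }
  m
}

# Rotation taking unit vector a to unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# Primitive builders ----------------------------------------------------------

# Open tube along +z through the given section centres/radii. Returns rings of
# n_circ vertices per section; caller closes/caps as needed.
tube_mesh <- function(centers, radii, n_circ, label) {
  ns <- nrow(centers)
  th <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  # local frame: axis from consecutive centres
  verts <- matrix(0, ns * n_circ, 3)
  axis <- centers[min(2L, ns), ] - centers[1L, ]
  axis <- axis / sqrt(sum(axis^2))
  e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  for (i in seq_len(ns)) {
    ring <- outer(cos(th), e1) * radii[i] + outer(sin(th), e2) * radii[i]
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <-
      sweep(ring, 2, centers[i, ], `+`)
  }
  fcs <- list()
  for (i in seq_len(ns - 1L)) {
    b0 <- (i - 1L) * n_circ
    j <- seq_len(n_circ)
    jn <- c(seq_len(n_circ)[-1L], 1L)
    fcs[[i]] <- rbind(cbind(b0 + j, b0 + jn, b0 + n_circ + j),
                      cbind(b0 + jn, b0 + n_circ + jn, b0 + n_circ + j))
  }
  faces <- do.call(rbind, fcs)
  surface_mesh(verts, faces, rep(label, nrow(faces)))
}

# Triangle-fan disk: ring of n points about center in plane with normal nrm.
disk_mesh <- function(center, normal, radius, n_circ, label) {
  normal <- normal / sqrt(sum(normal^2))
  e1 <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  ring <- sweep(outer(cos(th), e1) * radius + outer(sin(th), e2) * radius,
                2, center, `+`)
  verts <- rbind(center, ring)
  j <- seq_len(n_circ) + 1L
  jn <- c(j[-1L], 2L)
  faces <- cbind(1L, j, jn)
  surface_mesh(verts, faces, rep(label, nrow(faces)))
}

# Icosphere scaled to an ellipsoid with the given semi-axes; subdivision level
# chosen so the typical edge length is close to edge_length (mm).
ellipsoid_mesh <- function(semi_axes, edge_length, label = "chamber",
                           max_level = 6L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mean_r <- mean(semi_axes)
  # icosahedron edge on unit sphere ~ 1.05; halves per subdivision
  lvl <- max(0L, min(max_level,
                     ceiling(log2(1.05 * mean_r / edge_length))))
  for (s in seq_len(lvl)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- !duplicated(key)
    mid_idx <- match(key, key[uk]) + nrow(v)
    mids <- (v[edges[uk, 1], ] + v[edges[uk, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m31 <- mid_idx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- sweep(v, 2, semi_axes, `*`)
  surface_mesh(v, f, rep(label, nrow(f)))
}
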