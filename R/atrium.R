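#' Specification of an idealized left atrium with appendage
#'
#' Parametric stand-in for a patient-specific atrial surface: an ellipsoidal
#' chamber, 4-6 pulmonary-vein (PV) tubes with planar inlet caps, a mitral
#' valve (MV) outlet disk, and a tapering tubular left atrial appendage (LAA)
#' whose circular ostium sits on the chamber surface. Default chamber
#' semi-axes give an LA volume close to the typical control-group mean
#' (~164 mL); the default surface resolution targets an average edge length
#' of 0.68 mm, matching clinical-grade surface reconstructions.
#'
#' @param chamber_semi_axes length-3 numeric, ellipsoid semi-axes (mm).
#' @param pv_count number of pulmonary veins, one of 4, 5, 6.
#' @param pv_radius PV tube radius (mm).
#' @param pv_length PV tube length (mm).
#' @param laa_length appendage length from ostium to apex (mm).
#' @param laa_ostium_diameter ostium diameter (mm).
#' @param laa_taper_ratio apex radius / ostium radius, in (0, 1].
#' @param lspv_fold_point optional 3-vector (mm): pulmonary-ridge fold point
#'   (endpoint of the left superior PV at the chamber). Computed from the
#'   geometry when `NULL`.
#' @param device_depth signed distance (mm) from the ostium plane to the
#'   device proximal face; <= 0 means a proximal, ridge-covering pose.
#' @param mesh_edge_length target triangle edge length (mm).
#' @param seed integer seed; generators are pure functions of (spec, seed).
#' @return an object of class `atrium_spec`.
#' @export
atrium_spec <- function(chamber_semi_axes = c(42, 36, 26),
                        pv_count = 4L,
                        pv_radius = 6,
                        pv_length = 20,
                        laa_length = 30,
                        laa_ostium_diameter = 25.6,
                        laa_taper_ratio = 0.35,
                        lspv_fold_point = NULL,
                        device_depth = 0,
                        mesh_edge_length = 0.68,
                        seed = 1L) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop("invalid atrium_spec: field '", nm, "' must be positive and finite")
    }
  }
  chk_pos(chamber_semi_axes, "chamber_semi_axes")
  if (length(chamber_semi_axes) != 3L) {
    stop("invalid atrium_spec: field 'chamber_semi_axes' needs 3 values")
  }
  if (!pv_count %in% c(4L, 5L, 6L)) {
    stop("invalid atrium_spec: field 'pv_count' must be 4, 5 or 6")
  }
  chk_pos(pv_radius, "pv_radius"); chk_pos(pv_length, "pv_length")
  chk_pos(laa_length, "laa_length")
  chk_pos(laa_ostium_diameter, "laa_ostium_diameter")
  if (!is.numeric(laa_taper_ratio) || laa_taper_ratio <= 0 ||
      laa_taper_ratio > 1) {
    stop("invalid atrium_spec: field 'laa_taper_ratio' must be in (0, 1]")
  }
  chk_pos(mesh_edge_length, "mesh_edge_length")
  structure(list(chamber_semi_axes = as.numeric(chamber_semi_axes),
                 pv_count = as.integer(pv_count),
                 pv_radius = pv_radius, pv_length = pv_length,
                 laa_length = laa_length,
                 laa_ostium_diameter = laa_ostium_diameter,
                 laa_taper_ratio = laa_taper_ratio,
                 lspv_fold_point = lspv_fold_point,
                 device_depth = device_depth,
                 mesh_edge_length = mesh_edge_length,
                 seed = as.integer(seed)),
            class = "atrium_spec")
}

# Point on the ellipsoid surface in direction d (from the origin).
ellipsoid_point <- function(semi_axes, d) {
  d <- d / sqrt(sum(d^2))
  t <- 1 / sqrt(sum((d / semi_axes)^2))
  t * d
}

# Outward surface normal of the ellipsoid at point p.
ellipsoid_normal <- function(semi_axes, p) {
  n <- p / semi_axes^2
  n / sqrt(sum(n^2))
}

#' Generate an idealized labeled atrium surface
#'
#' Builds the chamber, PV tubes with inlet caps (`pv_inlet_1` ...), the MV
#' outlet disk (`mv_outlet`), and the tapering appendage (`laa_wall`).
#' Components are joined at shared boundary rings on the chamber surface; the
#' chamber ellipsoid itself is kept intact (holes are not cut), an
#' idealization documented in the methods vignette. The ostium contour is a
#' planar circle stored as the `ostium_contour` attribute, along with
#' `ostium_center`, `laa_axis` (unit, pointing into the LAA),
#' `lspv_endpoint`, per-PV cap descriptors (`pv_caps`), the MV descriptor
#' (`mv_cap`) and the chamber semi-axes.
#'
#' @param spec an [atrium_spec()].
#' @return a [surface_mesh()] with labels
#'   `{chamber, laa_wall, pv_inlet_i, mv_outlet}`; the ostium contour is a
#'   polyline attribute rather than a face label.
#' @export
generate_atrium <- function(spec) {
  if (!inherits(spec, "atrium_spec")) spec <- do.call(atrium_spec, spec)
  ax <- spec$chamber_semi_axes
  edge <- spec$mesh_edge_length
  chamber <- ellipsoid_mesh(ax, edge, "chamber")

  n_circ <- function(r) max(12L, ceiling(2 * pi * r / edge))

  # LAA on the left-anterior-superior aspect
  laa_dir <- c(1, 0.35, 0.45)
  laa_dir <- laa_dir / sqrt(sum(laa_dir^2))
  ost_center <- ellipsoid_point(ax, laa_dir)
  laa_axis <- ellipsoid_normal(ax, ost_center)
  r0 <- spec$laa_ostium_diameter / 2
  r1 <- r0 * spec$laa_taper_ratio
  ns <- max(4L, ceiling(spec$laa_length / edge) + 1L)
  s <- seq(0, spec$laa_length, length.out = ns)
  centers <- sweep(outer(s, laa_axis), 2, ost_center, `+`)
  radii <- r0 + (r1 - r0) * s / spec$laa_length
  nc_laa <- n_circ(r0)
  laa <- tube_mesh(centers, radii, nc_laa, "laa_wall")
  apex_center <- centers[ns, ]
  apex <- disk_mesh(apex_center + 1e-9 * laa_axis, laa_axis, r1, nc_laa,
                    "laa_wall")
  ostium_contour <- laa$vertices[seq_len(nc_laa), , drop = FALSE]

  # Pulmonary veins: LSPV first, immediately adjacent to the LAA (the
  # pulmonary ridge is the fold between them); others spread posteriorly
  pv_dirs <- list(c(0.62, 0.65, 0.58),  # LSPV, superior-left, by the ridge
                  c(0.5, 0.75, -0.5),   # LIPV
                  c(-0.7, 0.55, 0.5),   # RSPV
                  c(-0.7, 0.55, -0.5),  # RIPV
                  c(-0.1, 0.9, 0.1),    # accessory
                  c(0.1, 0.9, -0.3))    # accessory
  pv_caps <- vector("list", spec$pv_count)
  pv_parts <- vector("list", spec$pv_count)
  nc_pv <- n_circ(spec$pv_radius)
  for (i in seq_len(spec$pv_count)) {
    d <- pv_dirs[[i]]; d <- d / sqrt(sum(d^2))
    base <- ellipsoid_point(ax, d)
    nrm <- ellipsoid_normal(ax, base)
    tip <- base + spec$pv_length * nrm
    tube <- tube_mesh(rbind(base, tip), rep(spec$pv_radius, 2), nc_pv,
                      paste0("pv_tube_", i))
    cap <- disk_mesh(tip, nrm, spec$pv_radius, nc_pv, paste0("pv_inlet_", i))
    pv_parts[[i]] <- merge_meshes(tube, cap)
    pv_caps[[i]] <- list(center = tip, normal = nrm,  # outward (inflow = -normal)
                         radius = spec$pv_radius, base = base,
                         label = paste0("pv_inlet_", i))
  }

  # MV outlet: disk at the inferior pole
  mv_radius <- 13
  mv_center <- c(0, -0.15 * ax[2], -ax[3] * 0.97)
  mv_normal <- c(0, 0, -1)
  mv <- disk_mesh(mv_center, mv_normal, mv_radius, n_circ(mv_radius),
                  "mv_outlet")

  lspv <- spec$lspv_fold_point
  if (is.null(lspv)) {
    # ridge fold: chamber point midway between the LSPV base and the ostium rim
    lspv <- ellipsoid_point(ax, 0.5 * (pv_caps[[1]]$base + ost_center))
  }

  mesh <- do.call(merge_meshes, c(list(chamber, laa, apex),
                                  pv_parts, list(mv)))
  attr(mesh, "ostium_contour") <- ostium_contour
  attr(mesh, "ostium_center") <- ost_center
  attr(mesh, "ostium_radius") <- r0
  attr(mesh, "laa_axis") <- laa_axis
  attr(mesh, "laa_length") <- spec$laa_length
  attr(mesh, "laa_taper_ratio") <- spec$laa_taper_ratio
  attr(mesh, "laa_apex") <- apex_center
  attr(mesh, "lspv_endpoint") <- lspv
  attr(mesh, "pv_caps") <- pv_caps
  attr(mesh, "mv_cap") <- list(center = mv_center, normal = mv_normal,
                               radius = mv_radius)
  attr(mesh, "chamber_semi_axes") <- ax
  attr(mesh, "device_depth") <- spec$device_depth
  attr(mesh, "spec") <- spec
  mesh
}

# Local LAA radius at axial coordinate s (mm from the ostium plane).
laa_radius_at <- function(mesh, s) {
  r0 <- attr(mesh, "ostium_radius")
  L <- attr(mesh, "laa_length")
  tr <- attr(mesh, "laa_taper_ratio")
  r0 + (r0 * tr - r0) * pmin(pmax(s, 0), L) / L
}

# LAA-frame coordinates: s along the axis from the ostium plane (positive
# into the appendage), r radial distance from the axis.
laa_frame <- function(mesh, x) {
  oc <- attr(mesh, "ostium_center")
  axs <- attr(mesh, "laa_axis")
  d <- sweep(x, 2, oc, `-`)
  s <- drop(d %*% axs)
  perp <- d - outer(s, axs)
  list(s = s, r = row_norms(perp), perp = perp)
}
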