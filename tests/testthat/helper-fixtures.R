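# Shared fixtures, built once per test run. The "demo" scale (3 mm mesh
# edge, 24^3 flow grid) is the resolution used for transport experiments;
# geometry-only tests use a coarser, faster atrium.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

fix_atrium <- function() {
  memo("atrium4", function() generate_atrium(atrium_spec(mesh_edge_length = 4)))
}

fix_atrium_demo <- function() {
  memo("atrium3", function() generate_atrium(atrium_spec(mesh_edge_length = 3)))
}

fix_waveforms <- function() memo("wf", waveform_set)

demo_flow <- function(depth, seed = 1L, stasis = 1) {
  key <- paste0("flow_", depth, "_", seed, "_", stasis)
  memo(key, function() {
    m <- fix_atrium_demo()
    attr(m, "device_depth") <- depth
    generate_flow(m, fix_waveforms(), seed = seed, grid_n = 24L,
                  stasis = stasis)
  })
}

demo_plan <- function() {
  memo("plan", function() {
    m <- fix_atrium_demo()
    semi <- attr(m, "chamber_semi_axes")
    plan_injection(vol_la = (4 / 3) * pi * prod(semi) / 1000,
                   n_inj = nrow(inlet_facets(m)$centroids),
                   dt = fix_waveforms()$dt)
  })
}

# Constant-in-space velocity series on a small grid.
uniform_series <- function(u0, times = seq(0, 0.2, by = 0.01), lim = 60) {
  ax <- seq(-lim, lim, length.out = 5)
  grid <- list(x = ax, y = ax, z = ax)
  u <- array(0, c(5, 5, 5, length(times), 3))
  for (c3 in 1:3) u[, , , , c3] <- u0[c3]
  velocity_series(u, grid, times)
}

# Simple shear u_x = gamma * y (SI), sampled on a grid in mm.
shear_series <- function(gamma, times = c(0, 0.01), lim = 60) {
  ax <- seq(-lim, lim, length.out = 5)
  grid <- list(x = ax, y = ax, z = ax)
  u <- array(0, c(5, 5, 5, length(times), 3))
  for (iy in seq_along(ax)) u[, iy, , , 1] <- gamma * ax[iy] / 1000
  velocity_series(u, grid, times)
}

# Velocity series from a function f(X_mm, t) -> n x 3 (m/s).
series_from_fun <- function(f, times, lim = 60, n = 7) {
  ax <- seq(-lim, lim, length.out = n)
  grid <- list(x = ax, y = ax, z = ax)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  u <- array(0, c(n, n, n, length(times), 3))
  for (k in seq_along(times)) {
    uk <- f(pts, times[k])
    for (c3 in 1:3) u[, , , k, c3] <- array(uk[, c3], c(n, n, n))
  }
  velocity_series(u, grid, times)
}

# Square wall patch in the x = x0 plane (two triangles), labelled.
wall_patch <- function(x0 = 5, half = 20, label = "laa_wall") {
  v <- rbind(c(x0, -half, -half), c(x0, half, -half),
             c(x0, half, half), c(x0, -half, half))
  surface_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)), rep(label, 2))
}

# Circle contour in 3D (n points, radius r, plane z = 0).
circle_contour <- function(r, n = 256, center = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th), center[3])
}

ellipse_contour <- function(a, b, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th), 0)
}

# Minimal free-space "atrium" for transport limit cases: one inlet facet
# high above an outlet plane, no walls, effectively unbounded chamber.
free_fall_mesh <- function(inlet_z = 30) {
  tri <- rbind(c(-2, -2, inlet_z), c(2, -2, inlet_z), c(0, 3, inlet_z))
  m <- surface_mesh(tri, matrix(1:3, 1), "pv_inlet_1")
  attr(m, "pv_caps") <- list(list(center = c(0, 0, inlet_z),
                                  normal = c(0, 0, 1), radius = 5,
                                  base = c(0, 0, inlet_z - 5),
                                  label = "pv_inlet_1"))
  attr(m, "mv_cap") <- list(center = c(0, 0, 0), normal = c(0, 0, -1),
                            radius = 100)
  attr(m, "chamber_semi_axes") <- c(1000, 1000, 1000)
  attr(m, "ostium_center") <- c(900, 0, 0)
  attr(m, "ostium_radius") <- 5
  attr(m, "laa_axis") <- c(1, 0, 0)
  attr(m, "laa_length") <- 10
  attr(m, "laa_taper_ratio") <- 1
  m
}

# Inlet facet facing a wall 1 mm away (for the stagnant worst case).
wall_target_mesh <- function() {
  tri <- rbind(c(0, -2, -2), c(0, 2, -2), c(0, 0, 3))
  inlet <- surface_mesh(tri, matrix(1:3, 1), "pv_inlet_1")
  wall <- wall_patch(x0 = 1, half = 30)
  m <- merge_meshes(inlet, wall)
  attr(m, "pv_caps") <- list(list(center = c(0, 0, 0),
                                  normal = c(-1, 0, 0), radius = 5,
                                  base = c(5, 0, 0), label = "pv_inlet_1"))
  attr(m, "mv_cap") <- list(center = c(0, 0, -1000),
                            normal = c(0, 0, -1), radius = 10)
  attr(m, "chamber_semi_axes") <- c(1000, 1000, 1000)
  attr(m, "ostium_center") <- c(900, 0, 0)
  attr(m, "ostium_radius") <- 5
  attr(m, "laa_axis") <- c(1, 0, 0)
  attr(m, "laa_length") <- 10
  attr(m, "laa_taper_ratio") <- 1
  m
}
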