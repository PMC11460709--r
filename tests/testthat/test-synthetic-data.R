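# Idealized atrium ------------------------------------------------------------

test_that("generated atrium carries the expected labelled regions", {
  m <- fix_atrium()
  labs <- unique(m$labels)
  expect_length(grep("^pv_inlet_", labs), 4L)
  expect_true("mv_outlet" %in% labs)
  expect_true(all(c("chamber", "laa_wall") %in% labs))
  m5 <- generate_atrium(atrium_spec(pv_count = 5L, mesh_edge_length = 5))
  expect_length(grep("^pv_inlet_", unique(m5$labels)), 5L)
})

test_that("circular ostium contour reproduces pi r^2 at default resolution", {
  m <- generate_atrium(atrium_spec())  # 0.68 mm edges
  om <- ostium_metrics(attr(m, "ostium_contour"))
  expect_equal(om$area, pi * 12.8^2, tolerance = 0.01)
  expect_equal(om$perimeter, 2 * pi * 12.8, tolerance = 0.01)
})

test_that("atrium generation is deterministic and validates its spec", {
  s <- atrium_spec(mesh_edge_length = 5, seed = 3L)
  expect_identical(generate_atrium(s)$vertices, generate_atrium(s)$vertices)
  expect_error(atrium_spec(pv_radius = -1), "pv_radius")
  expect_error(atrium_spec(laa_taper_ratio = 1.2), "laa_taper_ratio")
  expect_error(atrium_spec(pv_count = 3), "pv_count")
})

# Waveforms --------------------------------------------------------------------

test_that("waveform invariants hold and bad grids are rejected", {
  wf <- fix_waveforms()
  expect_equal(wf$steps_per_beat * wf$dt, wf$beat_period, tolerance = 1e-9)
  expect_length(wf$mv_velocity, wf$steps_per_beat)
  expect_gt(mean(wf$mv_velocity), 0)
  expect_error(waveform_set(beat_period = 0.9), "must equal")
  expect_error(waveform_set(mv_velocity = rep(-0.1, 88)), "net inflow")
  # two peaks: E and A wave present in the default profile
  dv <- diff(wf$mv_velocity)
  peaks <- which(head(dv, -1) > 0 & tail(dv, -1) <= 0)
  expect_gte(length(peaks), 2L)
})

# Flow generation --------------------------------------------------------------

test_that("imposed outlet waveform is recovered at the outlet cap", {
  m <- fix_atrium()
  wfc <- waveform_set(mv_velocity = rep(0.3, 88))
  vs <- generate_flow(m, wfc, seed = 1, grid_n = 16L)
  mv <- attr(m, "mv_cap")
  ks <- seq(89L, 176L)
  speeds <- vapply(ks, function(k) {
    sqrt(sum(sample_flow(vs, mv$center, vs$times[k])$u^2))
  }, 0)
  expect_equal(mean(speeds), 0.3, tolerance = 0.01)
})

test_that("null transmitral forcing produces a null field", {
  m <- fix_atrium()
  wf0 <- waveform_set(mv_velocity = rep(0, 88))
  vs <- generate_flow(m, wf0, seed = 1, grid_n = 8L)
  expect_equal(max(abs(vs$u)), 0)
})

test_that("seeds differ only through the bounded stochastic perturbation", {
  m <- fix_atrium()
  wf <- fix_waveforms()
  v1 <- generate_flow(m, wf, seed = 1, grid_n = 8L)
  v2 <- generate_flow(m, wf, seed = 2, grid_n = 8L)
  amp <- attr(v1, "params")$perturb_amplitude * max(wf$mv_velocity)
  expect_gt(max(abs(v1$u - v2$u)), 0)
  expect_lte(max(abs(v1$u - v2$u)), 2 * amp + 1e-12)
  v0 <- generate_flow(m, wf, seed = 1, grid_n = 8L, perturb_amplitude = 0)
  v0b <- generate_flow(m, wf, seed = 99, grid_n = 8L, perturb_amplitude = 0)
  expect_identical(v0$u, v0b$u)
})

test_that("flow generation rejects a mesh without an outlet", {
  m <- fix_atrium()
  attr(m, "mv_cap") <- NULL
  expect_error(generate_flow(m, fix_waveforms()), "outlet")
})

# Wall shear from the field ----------------------------------------------------

test_that("Newtonian wall shear recovers mu * gamma on a flat patch", {
  gam <- 120  # 1/s
  vs <- shear_series(gam, times = seq(0, 1.75, by = 0.01))
  patch <- wall_patch(x0 = 0)  # plane x = 0; field varies with y only
  # rotate the patch into the z-x plane at y = 0 so its normal is +/- y
  v <- patch$vertices[, c(2, 1, 3)]
  patch2 <- surface_mesh(v, patch$faces, patch$labels)
  wss <- generate_wss(vs, patch2, mu = 0.0035, delta = 0.5)
  mag <- sqrt(apply(wss$tau^2, c(1, 2), sum))
  expect_equal(mean(mag), 0.0035 * gam, tolerance = 1e-6)
  # tangency: no component along the wall normal (y)
  expect_lt(max(abs(wss$tau[, , 2])), 1e-10)
})

test_that("zero velocity field yields zero wall shear", {
  vs <- uniform_series(c(0, 0, 0), times = seq(0, 1.75, by = 0.01))
  wss <- generate_wss(vs, wall_patch(x0 = 5))
  expect_equal(max(abs(wss$tau)), 0)
})

test_that("wall shear vectors are tangent on the curved appendage wall", {
  m <- fix_atrium()
  vs <- demo_flow_small <- generate_flow(m, fix_waveforms(), seed = 1,
                                         grid_n = 12L)
  wss <- generate_wss(vs, m, labels = "laa_wall")
  nrm <- face_normals(m)[wss$element_ids, , drop = FALSE]
  k <- sample(dim(wss$tau)[2], 3)
  for (j in k) {
    dots <- rowSums(wss$tau[, j, ] * nrm)
    rel <- abs(dots) / pmax(sqrt(rowSums(wss$tau[, j, ]^2)), 1e-12)
    expect_lt(max(rel[sqrt(rowSums(wss$tau[, j, ]^2)) > 1e-9]), 1e-6)
  }
})

# Cohort fixture ---------------------------------------------------------------

test_that("synthetic cohort reproduces its stratum means at large n", {
  cf <- generate_cohort_fixture(10000, 0, seed = 11L)
  expect_equal(mean(cf$la_volume), 163.6, tolerance = 1 / 163.6)
  expect_true(all(cf$la_volume > 0))
  expect_true(all(cf$ostium_perimeter^2 >= 4 * pi * cf$ostium_area))
})

test_that("synthetic cohort is deterministic and handles empty strata", {
  a <- generate_cohort_fixture(5, 5, seed = 2L)
  b <- generate_cohort_fixture(5, 5, seed = 2L)
  expect_identical(a, b)
  d <- generate_cohort_fixture(4, 0, seed = 1L)
  expect_equal(sum(d$outcome == "DRT"), 0L)
  expect_error(generate_cohort_fixture(-1, 2), "non-negative")
})
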