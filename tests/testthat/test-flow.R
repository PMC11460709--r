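test_that("sampling a uniform field returns it exactly with zero gradient", {
  vs <- uniform_series(c(0.2, -0.1, 0.05))
  s <- sample_flow(vs, c(13.7, -22.1, 5.0), 0.013)
  expect_equal(s$u, c(0.2, -0.1, 0.05))
  expect_equal(max(abs(s$grad_u)), 0)
  expect_equal(s$shear_magnitude, 0)
})

test_that("simple shear yields the analytic gradient and shear magnitude", {
  gam <- 80
  vs <- shear_series(gam)
  s <- sample_flow(vs, c(3, 7, -11), 0.005)
  expect_equal(s$grad_u[1, 2], gam, tolerance = 1e-9)
  expect_equal(sum(abs(s$grad_u)) - abs(s$grad_u[1, 2]), 0, tolerance = 1e-9)
  expect_equal(s$d_ij[1, 2], gam / 2)
  expect_equal(s$shear_magnitude, gam / sqrt(2), tolerance = 1e-9)
})

test_that("sampling is exact at stored nodes and steps", {
  vs <- demo_flow(0)
  g <- vs$grid
  i <- c(5L, 9L, 13L); k <- 40L
  x <- c(g$x[i[1]], g$y[i[2]], g$z[i[3]])
  s <- sample_flow(vs, x, vs$times[k])
  expect_identical(s$u, vs$u[i[1], i[2], i[3], k, ])
  expect_error(sample_flow(vs, c(1e4, 0, 0), vs$times[k]), "out of domain")
  expect_error(sample_flow(vs, x, 99), "outside series span")
})

test_that("phase windows partition the beat and weight the full-cycle mean", {
  vs <- demo_flow(0)
  ks_sys <- laaoflow:::window_steps(vs, phase_window("systole"), 2L)
  ks_dia <- laaoflow:::window_steps(vs, phase_window("diastole"), 2L)
  ks_all <- laaoflow:::window_steps(vs, phase_window("full_cycle"), 2L)
  expect_length(ks_sys, 31L)
  expect_length(ks_dia, 57L)
  expect_setequal(c(ks_sys, ks_dia), ks_all)
  m <- fix_atrium_demo()
  pts <- face_centroids(m)[m$labels == "laa_wall", ][1:20, ]
  v_s <- phase_average_speed(vs, pts, phase_window("systole"))
  v_d <- phase_average_speed(vs, pts, phase_window("diastole"))
  v_f <- phase_average_speed(vs, pts, phase_window("full_cycle"))
  expect_equal(v_f$mean, (31 * v_s$mean + 57 * v_d$mean) / 88,
               tolerance = 1e-12)
})

test_that("phase averages match closed forms on constructed fields", {
  tt <- seq(0, 1.75, by = 0.01)
  vs_const <- uniform_series(c(0.25, 0, 0), times = tt)
  ps <- phase_average_speed(vs_const, matrix(c(0, 0, 0), 1),
                            phase_window("full_cycle"))
  expect_equal(ps$mean, 0.25)
  expect_equal(ps$sd, 0)
  # |u|(t) = A |sin(pi t / T)|: full-cycle mean 2 A / pi
  A <- 0.4; Tb <- 0.88
  f <- function(X, t) {
    cbind(rep(A * abs(sin(pi * (t %% Tb) / Tb)), nrow(X)), 0, 0)
  }
  vs_sin <- series_from_fun(f, tt)
  pm <- phase_average_speed(vs_sin, matrix(c(0, 0, 0), 1),
                            phase_window("full_cycle"))
  expect_equal(pm$mean, 2 * A / pi, tolerance = 0.01)
  expect_error(phase_average_speed(vs_const, matrix(0, 0, 3)), "empty region")
})

test_that("recirculation score separates steady from reversing flow", {
  tt <- seq(0, 1.75, by = 0.01)
  pts <- matrix(c(0, 0, 0, 5, 5, 5), 2, 3, byrow = TRUE)
  steady <- uniform_series(c(0.3, 0, 0), times = tt)
  r1 <- recirculation_index(steady, pts)
  expect_equal(r1$score, 0, tolerance = 1e-12)
  expect_false(r1$flag)
  # reversal: +v first half of the beat, -v second half
  f <- function(X, t) {
    v <- if ((t %% 0.88) < 0.44) 0.15 else -0.15
    cbind(rep(v, nrow(X)), 0, 0)
  }
  rev <- series_from_fun(f, tt)
  r2 <- recirculation_index(rev, pts)
  expect_equal(r2$score, 1, tolerance = 1e-6)
  expect_true(r2$flag)
  # slow but steady flow is not flagged
  slow <- uniform_series(c(0.1, 0, 0), times = tt)
  r3 <- recirculation_index(slow, pts)
  expect_equal(r3$score, 0, tolerance = 1e-12)
  expect_false(r3$flag)
  # degenerate zero flow: score 1 with a warning
  expect_warning(r4 <- recirculation_index(uniform_series(c(0, 0, 0),
                                                          times = tt), pts),
                 "degenerate")
  expect_equal(r4$score, 1)
})

test_that("recirculation score is invariant under rigid rotation", {
  tt <- seq(0, 1.75, by = 0.01)
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  f <- function(X, t) {
    v <- 0.1 * sin(2 * pi * t / 0.88) + 0.05
    cbind(rep(v, nrow(X)), rep(0.3 * v, nrow(X)), 0)
  }
  frot <- function(X, t) f(X, t) %*% t(rot)
  pts <- matrix(c(3, -4, 6, -2, 8, 1), 2, 3, byrow = TRUE)
  r_a <- recirculation_index(series_from_fun(f, tt), pts)
  r_b <- recirculation_index(series_from_fun(frot, tt),
                             pts %*% t(rot))
  expect_equal(r_a$score, r_b$score, tolerance = 1e-9)
})

test_that("device region collapses, measures slab volume, and is stable", {
  m <- generate_atrium(atrium_spec(laa_ostium_diameter = 20,
                                   laa_taper_ratio = 1,
                                   mesh_edge_length = 4))
  oc <- attr(m, "ostium_center")
  attr(m, "lspv_endpoint") <- oc  # fold on the ostium plane
  dev <- build_device(device_spec("plug", 18))
  # depth 0: no band, device surface only
  p0 <- place_device(dev, m, 0)
  r0 <- device_region(m, p0)
  expect_equal(r0$volume_mm3, 0)
  expect_equal(nrow(r0$points), sum(laaoflow:::laa_frame(
    m, face_centroids(p0))$s <= 0.5))
  # straight tube radius 10, depth 12: slab volume pi 10^2 12 within 5%
  p12 <- place_device(dev, m, 12)
  r12 <- device_region(m, p12)
  expect_equal(r12$volume_mm3, pi * 100 * 12, tolerance = 0.05)
  # deterministic membership
  r12b <- device_region(m, p12)
  expect_identical(r12$points, r12b$points)
})
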