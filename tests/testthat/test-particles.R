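test_that("injection plan reproduces the worked parameter example", {
  plan <- plan_injection(c_p = 2e8, vol_la = 100, n_inj = 1000, n_ts = 10)
  expect_equal(plan$n_ppc, 2e6)
  expect_equal(plan$d_p, 2e6^(1 / 3) * 3e-6, tolerance = 1e-12)
  expect_equal(plan$d_p * 1e6, 378.0, tolerance = 1e-3)
  expect_equal(plan$t_inj, 0.1)
  expect_equal(plan$q, plan$m_t / plan$t_inj)
  expect_equal(plan$m_t,
               2e8 * 100 * 1550 * (4 / 3) * pi * (1.5e-6)^3,
               tolerance = 1e-12)
})

test_that("cluster diameter identity holds over randomized inputs", {
  set.seed(42)
  for (i in 1:50) {
    cp <- runif(1, 1e7, 1e9)
    vol <- runif(1, 20, 300)
    ninj <- sample(50:5000, 1)
    nts <- sample(5:20, 1)
    plan <- plan_injection(cp, vol, ninj, nts)
    # volume route (cluster volume then sphere diameter) vs direct cube root
    expect_equal(plan$d_p, plan$n_ppc^(1 / 3) * 3e-6,
                 tolerance = 1e-9)
    expect_equal((6 * plan$v_part / pi)^(1 / 3), plan$d_p, tolerance = 1e-12)
  }
  expect_error(plan_injection(2e8, 100, 0, 10), "division error")
})

test_that("single-platelet cluster collapses to the platelet diameter", {
  props <- particle_properties()
  # n_ppc = 1 when c_p vol = n_inj n_ts
  plan <- plan_injection(c_p = 10, vol_la = 1, n_inj = 1, n_ts = 10)
  expect_equal(plan$n_ppc, 1)
  expect_equal(plan$d_p, props$d_plat)
  plan2 <- plan_injection(c_p = 1e4, vol_la = 1, n_inj = 1, n_ts = 10)
  expect_equal(plan2$n_ppc, 1000)
  expect_equal(plan2$d_p, 10 * props$d_plat, tolerance = 1e-12)
})

test_that("injection seeds one cluster per facet per step per beat", {
  inl <- list(centroids = cbind(seq(0, 9), 0, 0),
              normals = matrix(rep(c(0, 0, -1), 10), 10, 3, byrow = TRUE),
              labels = rep("pv_inlet_1", 10))
  plan <- plan_injection(vol_la = 100, n_inj = 10, n_ts = 10)
  ens <- inject(plan, inl, beats = 2L)
  expect_length(ens$id, 10 * 10 * 2)
  expect_equal(unname(row_norms_test <- sqrt(rowSums(ens$vel^2))),
               rep(0.01, 200))
  expect_equal(max(abs(ens$pos[, 3])), 0, tolerance = 1e-9)
  # second-beat copies are born one period later, at identical positions
  first <- ens$birth_time < 0.88
  expect_equal(sum(first), 100)
  expect_equal(ens$pos[first, ], ens$pos[!first, ])
  expect_equal(ens$birth_time[!first] - ens$birth_time[first],
               rep(0.88, 100))
})

test_that("drag-only relaxation matches the closed-form exponential", {
  u0 <- c(0.3, 0, 0)
  vs <- uniform_series(u0, times = seq(0, 0.2, by = 0.01))
  props <- particle_properties(C_vm = 1e-12)
  tau <- 0.02
  st <- list(position = c(0, 0, 0), velocity = c(0, 0, 0), tau_r = tau,
             diameter = 1e-4, status = "suspended")
  nstep <- 10L
  for (k in seq_len(nstep)) {
    st <- step_particle(st, vs, fluid_properties(), props,
                        t = (k - 1) * 0.01, dt = 0.01, n_sub = 10L)
  }
  t_end <- nstep * 0.01
  expect_lt(max(abs(st$velocity - u0 * (1 - exp(-t_end / tau)))),
            1e-3 * sqrt(sum(u0^2)))
})

test_that("matched particle in uniform flow feels no net force", {
  u0 <- c(0.15, -0.05, 0.2)
  vs <- uniform_series(u0)
  st <- list(position = c(1, 2, 3), velocity = u0, tau_r = 0.01,
             diameter = 1e-4, status = "suspended")
  st2 <- step_particle(st, vs, t = 0, dt = 0.01)
  expect_equal(st2$velocity, u0, tolerance = 1e-12)
  expect_equal(st2$position, st$position + 0.01 * u0 * 1000,
               tolerance = 1e-9)
  # no flow, no velocity: nothing moves
  null <- uniform_series(c(0, 0, 0))
  st0 <- list(position = c(1, 1, 1), velocity = c(0, 0, 0), tau_r = 0.01,
              diameter = 1e-4, status = "suspended")
  st0b <- step_particle(st0, null, t = 0, dt = 0.01)
  expect_equal(st0b$position, c(1, 1, 1))
})

test_that("wall-film rule attaches any wall-crossing segment", {
  mesh <- wall_patch(x0 = 5)
  st <- list(prev_position = c(0, 0, 0), position = c(10, 0, 0),
             velocity = c(0.003, 0, 0), diameter = 1e-4,
             status = "suspended", attach_element = NA_integer_)
  out <- wall_interaction(st, mesh)
  expect_equal(out$status, "attached")
  expect_equal(out$position[1], 5, tolerance = 1e-9)
  expect_equal(out$attach_speed, 0.003)
  # interior segment: unchanged
  st2 <- st; st2$position <- c(2, 1, 1)
  expect_equal(wall_interaction(st2, mesh)$status, "suspended")
  # zero-length segment is a no-op
  st3 <- st; st3$position <- st3$prev_position
  expect_equal(wall_interaction(st3, mesh)$status, "suspended")
})

test_that("Weber criterion rolls an attached particle in strong cross-flow", {
  mesh <- wall_patch(x0 = 5)
  props <- particle_properties()
  d_p <- 1e-3
  # tangential speed giving We = 4 We_crit
  vt <- sqrt(4 * props$we_crit * props$sigma_p / (props$rho_p * d_p))
  vs <- uniform_series(c(0, vt, 0))
  st <- list(position = c(5, 0, 0), velocity = c(0, 0, 0), diameter = d_p,
             status = "attached", attach_element = 1L)
  out <- wall_interaction(st, mesh, props, series = vs, t = 0, dt = 0.01)
  expect_equal(out$status, "rolling")
  disp <- out$position - c(5, 0, 0)
  expect_equal(disp[1], 0, tolerance = 1e-9)        # stays on the wall plane
  expect_gt(disp[2], 0)                             # moved with the flow
  expect_lte(sqrt(sum(out$velocity^2)), props$roll_cap + 1e-12)
  # weak cross-flow: stays attached
  slow <- uniform_series(c(0, 0.001, 0))
  st2 <- st
  out2 <- wall_interaction(st2, mesh, props, series = slow, t = 0, dt = 0.01)
  expect_equal(out2$status, "attached")
})

test_that("pure outflow exits every cluster through the mitral plane", {
  mesh <- free_fall_mesh()
  vs <- uniform_series(c(0, 0, -0.2), times = seq(0, 1.75, by = 0.01),
                       lim = 200)
  plan <- plan_injection(vol_la = 100, n_inj = 1, n_ts = 10)
  res <- run_transport(vs, mesh, plan, seed = 1)
  expect_equal(res$pct_attached, 0)
  expect_equal(unname(res$counts[["exited"]]), res$n_injected)
  expect_equal(res$n_injected, 20L)
})

test_that("stagnant field with wall-directed injection attaches everything", {
  mesh <- wall_target_mesh()
  vs <- uniform_series(c(0, 0, 0), times = seq(0, 1.75, by = 0.01),
                       lim = 200)
  plan <- plan_injection(vol_la = 100, n_inj = 1, n_ts = 10)
  res <- run_transport(vs, mesh, plan, seed = 1)
  expect_equal(res$pct_attached, 100)
  expect_equal(unname(res$counts[["attached"]]), res$n_injected)
})

test_that("fields are inputs: transport leaves the series untouched", {
  mesh <- wall_target_mesh()
  vs <- uniform_series(c(0, 0, 0), times = seq(0, 1.75, by = 0.01),
                       lim = 200)
  u_before <- vs$u
  plan <- plan_injection(vol_la = 100, n_inj = 1, n_ts = 10)
  invisible(run_transport(vs, mesh, plan, seed = 1))
  expect_identical(vs$u, u_before)
})
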