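#' Carrier-fluid properties
#'
#' Blood treated as an incompressible Newtonian fluid; gravity is neglected
#' by default.
#'
#' @param rho density, kg/m^3 (default 1060).
#' @param mu dynamic viscosity, kg/(m s) (default 0.0035).
#' @param gravity_enabled include the buoyant-weight term of the force
#'   balance (default FALSE).
#' @param g gravity vector, m/s^2 (used only when enabled).
#' @return an object of class `fluid_properties`; `nu = mu / rho`.
#' @export
fluid_properties <- function(rho = 1060, mu = 0.0035,
                             gravity_enabled = FALSE, g = c(0, 0, -9.81)) {
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  structure(list(rho = rho, mu = mu, nu = mu / rho,
                 gravity_enabled = isTRUE(gravity_enabled), g = g),
            class = "fluid_properties")
}

#' Platelet-cluster particle properties
#'
#' Physical constants of the discrete phase: platelet diameter and density,
#' surface tension and molecular viscosity governing the wall roll/detach
#' criterion, the virtual-mass factor, the Saffman lift constant, the
#' physiological platelet concentration, and the injection speed. The
#' roll/detach knobs (`we_crit`, `roll_floor`, `roll_cap`,
#' `detach_we_factor`) parameterize this package's Weber-number substitute
#' for droplet-separation models; they are configuration values reported
#' with every run.
#'
#' @param rho_p particle density, kg/m^3 (default 1550).
#' @param d_plat platelet diameter, m (default 3e-6).
#' @param sigma_p surface tension, N/m (default 0.03).
#' @param mu_p molecular viscosity, kg/(m s) (default 0.0025).
#' @param C_vm virtual-mass factor (default 0.5).
#' @param K_saffman Saffman lift constant (default 2.954).
#' @param c_p platelet concentration, 1/mL (default 2e8).
#' @param injection_speed initial particle speed, m/s (default 0.01).
#' @param we_crit Weber number above which an attached particle starts
#'   rolling (default 1).
#' @param roll_floor minimum tangential fluid speed for rolling, m/s.
#' @param roll_cap rolling speed cap, m/s (default 0.2).
#' @param detach_we_factor multiple of `we_crit` above which a rolling
#'   particle re-suspends (default 16).
#' @param shear_eps shear magnitude (1/s) below which the Saffman term is
#'   dropped.
#' @return an object of class `particle_properties`.
#' @export
particle_properties <- function(rho_p = 1550, d_plat = 3e-6, sigma_p = 0.03,
                                mu_p = 0.0025, C_vm = 0.5, K_saffman = 2.954,
                                c_p = 2e8, injection_speed = 0.01,
                                we_crit = 1, roll_floor = 0.01,
                                roll_cap = 0.2, detach_we_factor = 16,
                                shear_eps = 1e-8) {
  vals <- c(rho_p = rho_p, d_plat = d_plat, sigma_p = sigma_p, mu_p = mu_p,
            C_vm = C_vm, K_saffman = K_saffman, c_p = c_p,
            injection_speed = injection_speed)
  if (any(vals <= 0)) {
    stop("particle properties must be strictly positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  structure(list(rho_p = rho_p, d_plat = d_plat, sigma_p = sigma_p,
                 mu_p = mu_p, C_vm = C_vm, K_saffman = K_saffman, c_p = c_p,
                 injection_speed = injection_speed, we_crit = we_crit,
                 roll_floor = roll_floor, roll_cap = roll_cap,
                 detach_we_factor = detach_we_factor, shear_eps = shear_eps),
            class = "particle_properties")
}

#' Plan a platelet-cluster injection
#'
#' Personalizes the injection to the analysed anatomy so that the
#' physiological platelet count `c_p * Vol_LA` is represented by one cluster
#' per inlet facet per injection step: platelets per cluster
#' `n_ppc = c_p * Vol_LA / (n_inj * n_ts)`; cluster volume
#' `V_part = n_ppc * (4/3) pi (d_plat/2)^3`; cluster diameter
#' `d_p = (6 V_part / pi)^(1/3) = n_ppc^(1/3) * d_plat`; total injected mass
#' `m_T = n_plat * rho_p * (4/3) pi (d_plat/2)^3`; injection time
#' `t_inj = n_ts * dt`; mass flow rate `Q = m_T / t_inj`.
#'
#' @param c_p platelet concentration, 1/mL.
#' @param vol_la left-atrial volume, mL.
#' @param n_inj number of inlet facets.
#' @param n_ts number of injection time steps (default 10).
#' @param dt time step, s (default 0.01).
#' @param props a [particle_properties()].
#' @return an object of class `injection_plan` with fields `n_ppc`, `d_p`
#'   (m), `v_part` (m^3), `m_p` (cluster mass, kg), `tau_r` (Stokes
#'   relaxation time, s, for blood viscosity 0.0035), `q` (kg/s), `m_t`
#'   (kg), `t_inj` (s), `n_ts`, `n_inj`, `vol_la`, `n_plat`.
#' @export
plan_injection <- function(c_p = 2e8, vol_la, n_inj, n_ts = 10L, dt = 0.01,
                           props = particle_properties()) {
  if (any(c(c_p, vol_la, dt) <= 0)) {
    stop("c_p, vol_la and dt must be positive")
  }
  if (n_inj < 1 || n_ts < 1) {
    stop("division error: n_inj and n_ts must be at least 1")
  }
  n_ppc <- c_p * vol_la / (n_inj * n_ts)
  v_part <- n_ppc * (4 / 3) * pi * (props$d_plat / 2)^3
  d_p <- (6 * v_part / pi)^(1 / 3)
  n_plat <- c_p * vol_la
  m_t <- n_plat * props$rho_p * (4 / 3) * pi * (props$d_plat / 2)^3
  t_inj <- n_ts * dt
  structure(list(n_ppc = n_ppc, d_p = d_p, v_part = v_part,
                 m_p = props$rho_p * v_part,
                 tau_r = props$rho_p * d_p^2 / (18 * 0.0035),
                 q = m_t / t_inj, m_t = m_t, t_inj = t_inj,
                 n_ts = as.integer(n_ts), n_inj = as.integer(n_inj),
                 vol_la = vol_la, n_plat = n_plat, dt = dt,
                 c_p = c_p),
            class = "injection_plan")
}

#' Inlet facets of a labeled mesh
#'
#' Centroids and inward-pointing unit normals of all faces whose label
#' matches `pattern` (pulmonary-vein inlet caps by default). Inward normals
#' come from the stored PV cap descriptors when present, else face normals
#' flipped towards the mesh centroid.
#'
#' @param mesh a [surface_mesh()].
#' @param pattern regular expression for inlet labels.
#' @return list with `centroids` (n x 3, mm), `normals` (n x 3, inward
#'   unit), `labels`.
#' @export
inlet_facets <- function(mesh, pattern = "^pv_inlet_") {
  sel <- grepl(pattern, mesh$labels)
  if (!any(sel)) stop("no inlet facets match ", pattern)
  cen <- face_centroids(mesh)[sel, , drop = FALSE]
  labs <- mesh$labels[sel]
  pv_caps <- attr(mesh, "pv_caps")
  nrm <- matrix(0, nrow(cen), 3)
  if (!is.null(pv_caps)) {
    caps <- stats::setNames(pv_caps,
                            vapply(pv_caps, function(p) p$label, ""))
    for (i in seq_len(nrow(cen))) {
      nrm[i, ] <- -caps[[labs[i]]]$normal
    }
  } else {
    fn <- face_normals(mesh)[sel, , drop = FALSE]
    ctr <- colMeans(mesh$vertices)
    toin <- sweep(-cen, 2, -ctr, `+`)
    flip <- rowSums(fn * toin) < 0
    fn[flip, ] <- -fn[flip, , drop = FALSE]
    nrm <- fn
  }
  # verify planarity per inlet label
  for (lb in unique(labs)) {
    pts <- cen[labs == lb, , drop = FALSE]
    if (nrow(pts) >= 3L && contour_plane(pts)$residual > 0.5) {
      stop("geometry error: inlet ", lb, " is not planar")
    }
  }
  list(centroids = cen, normals = nrm, labels = labs)
}

#' Seed platelet clusters at the inlets
#'
#' One cluster per inlet facet per injection step, born at the facet
#' centroid with speed `injection_speed` directed inward along the facet
#' normal; the injection is repeated identically at the start of every
#' simulated beat.
#'
#' @param plan an [injection_plan()].
#' @param inlets result of [inlet_facets()] (or a mesh, from which inlets
#'   are derived).
#' @param props a [particle_properties()].
#' @param beats number of beats receiving an injection (default 2).
#' @param beat_period beat length, s.
#' @return a `particle_ensemble`: list of parallel vectors `id`, `pos`
#'   (n x 3 mm), `vel` (n x 3 m/s), `mass` (kg), `diameter` (m), `tau_r`
#'   (s), `status`, `birth_time` (s), `attach_time`, `attach_speed`,
#'   `attach_element`, `reflections`.
#' @export
inject <- function(plan, inlets, props = particle_properties(), beats = 2L,
                   beat_period = 0.88) {
  if (inherits(inlets, "surface_mesh")) inlets <- inlet_facets(inlets)
  nf <- nrow(inlets$centroids)
  n <- nf * plan$n_ts * beats
  rep_f <- rep(seq_len(nf), times = plan$n_ts * beats)
  step_of <- rep(rep(seq_len(plan$n_ts), each = nf), times = beats)
  beat_of <- rep(seq_len(beats), each = nf * plan$n_ts)
  pos <- inlets$centroids[rep_f, , drop = FALSE]
  vel <- props$injection_speed * inlets$normals[rep_f, , drop = FALSE]
  structure(list(
    id = seq_len(n),
    pos = pos, vel = vel,
    mass = rep(plan$m_p, n), diameter = rep(plan$d_p, n),
    tau_r = rep(plan$tau_r, n),
    status = rep("unborn", n),
    birth_time = (beat_of - 1L) * beat_period + (step_of - 1L) * plan$dt,
    facet = rep_f,
    attach_time = rep(NA_real_, n), attach_speed = rep(NA_real_, n),
    attach_element = rep(NA_integer_, n),
    reflections = rep(0L, n)),
    class = "particle_ensemble")
}

# Force-balance sub-stepped update for a batch of suspended particles.
# pos (mm), vel (m/s). The linear drag term is integrated exactly per
# sub-step (exponential integrator); pressure-gradient, virtual-mass
# convective and Saffman terms are held constant across the sub-step.
advance_particles <- function(pos, vel, tau_r, diameter, series, fluid,
                              props, t0, dt, n_sub = 10L) {
  h <- dt / n_sub
  beta <- props$C_vm * fluid$rho / props$rho_p
  for (k in seq_len(n_sub)) {
    t <- t0 + (k - 1) * h
    s <- sample_many(series, pos, t)
    u <- s$u
    g <- s$grad
    # (a . grad) u for a = u and a = u_p
    conv <- function(a) {
      cbind(g[, 1, 1] * a[, 1] + g[, 1, 2] * a[, 2] + g[, 1, 3] * a[, 3],
            g[, 2, 1] * a[, 1] + g[, 2, 2] * a[, 2] + g[, 2, 3] * a[, 3],
            g[, 3, 1] * a[, 1] + g[, 3, 2] * a[, 2] + g[, 3, 3] * a[, 3])
    }
    acc <- (fluid$rho / props$rho_p) * conv(u) + beta * conv(vel)
    # Saffman lift: (2 K nu^1/2 rho / (rho_p d_p)) d_ij (u - u_p) / (dd)^(1/4)
    d11 <- g[, 1, 1]; d22 <- g[, 2, 2]; d33 <- g[, 3, 3]
    d12 <- 0.5 * (g[, 1, 2] + g[, 2, 1])
    d13 <- 0.5 * (g[, 1, 3] + g[, 3, 1])
    d23 <- 0.5 * (g[, 2, 3] + g[, 3, 2])
    dd <- d11^2 + d22^2 + d33^2 + 2 * (d12^2 + d13^2 + d23^2)
    shear <- sqrt(dd)
    rel <- u - vel
    coef <- ifelse(shear >= props$shear_eps,
                   2 * props$K_saffman * sqrt(fluid$nu) * fluid$rho /
                     (props$rho_p * diameter * pmax(dd, 1e-300)^0.25),
                   0)
    a_saff <- cbind(
      coef * (d11 * rel[, 1] + d12 * rel[, 2] + d13 * rel[, 3]),
      coef * (d12 * rel[, 1] + d22 * rel[, 2] + d23 * rel[, 3]),
      coef * (d13 * rel[, 1] + d23 * rel[, 2] + d33 * rel[, 3]))
    acc <- acc + a_saff
    if (fluid$gravity_enabled) {
      acc <- acc + matrix((props$rho_p - fluid$rho) / props$rho_p * fluid$g,
                          nrow(pos), 3, byrow = TRUE)
    }
    acc <- acc / (1 + beta)
    tau_eff <- tau_r * (1 + beta)
    u_eq <- u + tau_eff * acc
    decay <- exp(-h / tau_eff)
    vel <- u_eq + (vel - u_eq) * decay
    pos <- pos + h * vel * 1000  # m/s over s -> mm
  }
  list(pos = pos, vel = vel)
}

#' Advance one suspended platelet cluster over a time step
#'
#' Integrates the particle force balance — Stokes drag
#' `m_p (u - u_p) / tau_r`, pressure-gradient force
#' `m_p (rho/rho_p) (u . grad) u`, virtual-mass force
#' `C_vm m_p (rho/rho_p) ((u_p . grad) u - du_p/dt)` and shear-induced
#' (Saffman) lift with constant `K`, gravity optional — with fixed
#' sub-stepping; the stiff linear drag term is integrated exactly within
#' each sub-step. The Saffman term is dropped below a shear floor.
#'
#' @param state a single-particle state: list with `position` (mm),
#'   `velocity` (m/s), `tau_r` (s), `diameter` (m), `status`.
#' @param series a [velocity_series()].
#' @param fluid a [fluid_properties()].
#' @param props a [particle_properties()].
#' @param t current time, s.
#' @param dt step, s (default 0.01).
#' @param n_sub sub-steps (default 10).
#' @return the updated state (suspended particles only; other states pass
#'   through unchanged).
#' @export
step_particle <- function(state, series, fluid = fluid_properties(),
                          props = particle_properties(), t = 0, dt = 0.01,
                          n_sub = 10L) {
  if (!identical(state$status, "suspended")) return(state)
  out <- advance_particles(matrix(state$position, 1, 3),
                           matrix(state$velocity, 1, 3),
                           state$tau_r, state$diameter,
                           series, fluid, props, t, dt, n_sub)
  state$position <- drop(out$pos)
  state$velocity <- drop(out$vel)
  state
}

# Spatial hash of wall triangles ---------------------------------------------

build_tri_hash <- function(mesh, labels, cell = 5) {
  sel <- which(mesh$labels %in% labels)
  if (length(sel) == 0L) return(NULL)
  fc <- face_corners(mesh)
  a <- fc$a[sel, , drop = FALSE]
  b <- fc$b[sel, , drop = FALSE]
  cc <- fc$c[sel, , drop = FALSE]
  lo <- pmin(a, b, cc) - 1e-9
  hi <- pmax(a, b, cc) + 1e-9
  origin <- apply(lo, 2, min)
  key_of <- function(i, j, k) paste(i, j, k)
  keys <- character(0); tri <- integer(0)
  for (f in seq_along(sel)) {
    il <- floor((lo[f, ] - origin) / cell)
    ih <- floor((hi[f, ] - origin) / cell)
    gx <- il[1]:ih[1]; gy <- il[2]:ih[2]; gz <- il[3]:ih[3]
    grid <- expand.grid(gx, gy, gz)
    keys <- c(keys, key_of(grid[, 1], grid[, 2], grid[, 3]))
    tri <- c(tri, rep(f, nrow(grid)))
  }
  list(map = split(tri, keys), origin = origin, cell = cell,
       a = a, b = b, c = cc, face_index = sel,
       labels = mesh$labels[sel])
}

# candidate triangle rows for segments p0 -> p1 (matrix rows)
hash_candidates <- function(hash, p0, p1) {
  lo <- pmin(p0, p1); hi <- pmax(p0, p1)
  il <- floor(sweep(lo, 2, hash$origin, `-`) / hash$cell)
  ih <- floor(sweep(hi, 2, hash$origin, `-`) / hash$cell)
  lapply(seq_len(nrow(p0)), function(i) {
    gx <- il[i, 1]:ih[i, 1]; gy <- il[i, 2]:ih[i, 2]; gz <- il[i, 3]:ih[i, 3]
    grid <- expand.grid(gx, gy, gz)
    ks <- paste(grid[, 1], grid[, 2], grid[, 3])
    unique(unlist(hash$map[ks], use.names = FALSE))
  })
}

# vectorized segment-triangle intersection (Moeller-Trumbore) over pairs
segment_tri_hits <- function(hash, seg_id, tri_id, p0, p1) {
  O <- p0[seg_id, , drop = FALSE]
  D <- p1[seg_id, , drop = FALSE] - O
  A <- hash$a[tri_id, , drop = FALSE]
  B <- hash$b[tri_id, , drop = FALSE]
  C <- hash$c[tri_id, , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  pv <- cross3(D, e2)
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  inv <- ifelse(ok, 1 / det, 0)
  tv <- O - A
  uu <- rowSums(tv * pv) * inv
  qv <- cross3(tv, e1)
  vv <- rowSums(D * qv) * inv
  tt <- rowSums(e2 * qv) * inv
  hit <- ok & uu >= -1e-9 & vv >= -1e-9 & (uu + vv) <= 1 + 1e-9 &
    tt >= 0 & tt <= 1
  list(hit = hit, t = tt)
}

#' Wall interaction of one particle over its last trajectory segment
#'
#' Worst-case wall-film adhesion: a trajectory segment crossing the
#' appendage wall or the device surface attaches the cluster at the impact
#' point, regardless of impact speed, recording the impact speed; particles
#' crossing the mitral outlet exit. Attached particles are re-evaluated
#' each step with a Weber-number criterion
#' `We = rho_p d_p v_t^2 / sigma_p`: `We > we_crit` with tangential fluid
#' speed above the rolling floor sets the particle rolling along the
#' surface tangent at the (capped) local tangential fluid speed; a rolling
#' particle above `detach_we_factor * we_crit` re-suspends; below the floor
#' it re-attaches.
#'
#' @param state particle state list with `position`, `prev_position`,
#'   `velocity`, `diameter`, `status`.
#' @param mesh a [surface_mesh()] whose `laa_wall` / `device*` faces form
#'   the wall and whose `mv_outlet` faces form the exit.
#' @param props a [particle_properties()].
#' @param series optional [velocity_series()] (needed for the roll/detach
#'   evaluation of already-attached particles).
#' @param t current time, s.
#' @param dt step, s.
#' @return the updated state.
#' @export
wall_interaction <- function(state, mesh, props = particle_properties(),
                             series = NULL, t = 0, dt = 0.01) {
  wall_labels <- unique(grep("^laa_wall$|^device", mesh$labels, value = TRUE))
  if (state$status == "suspended") {
    p0 <- matrix(state$prev_position, 1, 3)
    p1 <- matrix(state$position, 1, 3)
    if (sum((p1 - p0)^2) == 0) return(state)
    hash <- build_tri_hash(mesh, c(wall_labels, "mv_outlet"))
    if (is.null(hash)) return(state)
    cand <- hash_candidates(hash, p0, p1)[[1]]
    if (length(cand)) {
      hits <- segment_tri_hits(hash, rep(1L, length(cand)), cand, p0, p1)
      if (any(hits$hit)) {
        first <- cand[hits$hit][which.min(hits$t[hits$hit])]
        tfirst <- min(hits$t[hits$hit])
        xhit <- p0 + tfirst * (p1 - p0)
        if (hash$labels[first] == "mv_outlet") {
          state$status <- "exited"
          state$position <- drop(xhit)
        } else {
          state$status <- "attached"
          state$position <- drop(xhit)
          state$attach_speed <- sqrt(sum(state$velocity^2))
          state$attach_time <- t
          state$attach_element <- hash$face_index[first]
        }
      }
    }
    return(state)
  }
  if (state$status %in% c("attached", "rolling") && !is.null(series)) {
    s <- sample_many(series, matrix(state$position, 1, 3), t)
    u <- drop(s$u)
    el <- state$attach_element
    nrm <- if (!is.na(el)) face_normals(mesh)[el, ] else c(0, 0, 1)
    ut <- u - sum(u * nrm) * nrm
    vt <- sqrt(sum(ut^2))
    we <- props$rho_p * state$diameter * vt^2 / props$sigma_p
    if (we > props$detach_we_factor * props$we_crit &&
        state$status == "rolling") {
      state$status <- "suspended"
      state$velocity <- ut
    } else if (we > props$we_crit && vt > props$roll_floor) {
      state$status <- "rolling"
      speed <- min(vt, props$roll_cap)
      state$velocity <- ut / vt * speed
      state$position <- state$position + state$velocity * dt * 1000
    } else {
      state$status <- "attached"
      state$velocity <- c(0, 0, 0)
    }
  }
  state
}

#' Run a full platelet-transport episode
#'
#' Injects clusters at the pulmonary-vein inlet caps during the first
#' `n_ts` steps of each beat, advances all suspended clusters under the
#' particle force balance, applies worst-case wall-film adhesion with the
#' Weber-number roll/detach criterion, removes clusters through the mitral
#' outlet, and summarizes adhesion at the end of the final beat (late
#' diastole of the second beat by default). Particles leaving the domain
#' other than through the outlet are reflected once at the chamber surface
#' and frozen on a repeat offence (counted in the summary). Count
#' conservation (injected = suspended + attached + rolling + exited) holds
#' at every step. The seed only shuffles injection ordering; the physics is
#' deterministic.
#'
#' @param series a [velocity_series()] spanning the episode.
#' @param mesh atrium mesh from [generate_atrium()].
#' @param plan an [injection_plan()].
#' @param fluid a [fluid_properties()].
#' @param props a [particle_properties()].
#' @param seed integer seed (injection ordering only).
#' @param device optional placed device mesh merged into the wall.
#' @param beats number of beats (default 2).
#' @param n_sub integration sub-steps per dt (default 10).
#' @return an object of class `adhesion_summary`: list with `pct_attached`
#'   (% of injected clusters adhered — attached or rolling — at evaluation
#'   time), `mean_attach_speed` (m/s), `counts` (status tallies),
#'   `attachment_map` (per-element counts), `attached_fraction` (time
#'   series), `n_injected`, `n_frozen`, `ensemble`.
#' @export
run_transport <- function(series, mesh, plan, fluid = fluid_properties(),
                          props = particle_properties(), seed = 1L,
                          device = NULL, beats = 2L, n_sub = 10L) {
  wf <- attr(series, "waveforms")
  period <- if (!is.null(wf)) wf$beat_period else 0.88
  wall_mesh <- if (!is.null(device)) merge_meshes(mesh, device) else mesh
  wall_labels <- unique(grep("^laa_wall$|^device", wall_mesh$labels,
                             value = TRUE))
  hash <- build_tri_hash(wall_mesh, wall_labels,
                         cell = max(5, attr(mesh, "ostium_radius") %||% 5))
  ens <- inject(plan, mesh, props, beats = beats, beat_period = period)
  # seed shuffles injection ordering (ids), not physics
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ens$id <- sample(ens$id)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  mv <- attr(mesh, "mv_cap")
  semi <- attr(mesh, "chamber_semi_axes")
  tt <- series$times
  nt <- length(tt)
  n <- length(ens$status)
  frozen <- rep(FALSE, n)
  attached_fraction <- numeric(nt)

  for (k in seq_len(nt)) {
    t <- tt[k]
    dt <- if (k < nt) tt[k + 1L] - tt[k] else diff(tt[(nt - 1):nt])
    ens$status[ens$status == "unborn" & ens$birth_time <= t + 1e-9] <-
      "suspended"
    live <- which(ens$status == "suspended" & !frozen)
    if (length(live)) {
      p0 <- ens$pos[live, , drop = FALSE]
      adv <- advance_particles(p0, ens$vel[live, , drop = FALSE],
                               ens$tau_r[live], ens$diameter[live],
                               series, fluid, props, t, dt, n_sub)
      p1 <- adv$pos
      ens$vel[live, ] <- adv$vel
      # wall / device / outlet crossings
      cand <- if (is.null(hash)) vector("list", length(live)) else
        hash_candidates(hash, p0, p1)
      ncand <- lengths(cand)
      if (any(ncand > 0)) {
        seg_id <- rep(seq_along(live)[ncand > 0], ncand[ncand > 0])
        tri_id <- unlist(cand[ncand > 0], use.names = FALSE)
        hits <- segment_tri_hits(hash, seg_id, tri_id, p0, p1)
        if (any(hits$hit)) {
          hseg <- seg_id[hits$hit]; htri <- tri_id[hits$hit]
          htt <- hits$t[hits$hit]
          ord <- order(hseg, htt)
          firsts <- !duplicated(hseg[ord])
          for (w in which(firsts)) {
            i <- hseg[ord][w]; tri <- htri[ord][w]; tf <- htt[ord][w]
            gi <- live[i]
            xhit <- p0[i, ] + tf * (p1[i, ] - p0[i, ])
            ens$pos[gi, ] <- xhit
            ens$status[gi] <- "attached"
            ens$attach_speed[gi] <- sqrt(sum(ens$vel[gi, ]^2))
            ens$attach_time[gi] <- t + tf * dt
            ens$attach_element[gi] <- hash$face_index[tri]
            p1[i, ] <- xhit
          }
        }
      }
      moved <- which(ens$status[live] == "suspended")
      if (length(moved)) {
        ens$pos[live[moved], ] <- p1[moved, , drop = FALSE]
        # mitral outlet: crossing the outlet plane within the annulus exits
        if (!is.null(mv)) {
          d <- sweep(ens$pos[live[moved], , drop = FALSE], 2, mv$center, `-`)
          sn <- drop(d %*% mv$normal)
          rr <- row_norms(d - outer(sn, mv$normal))
          out <- sn > 0 & rr < 1.5 * mv$radius
          ens$status[live[moved][out]] <- "exited"
        }
        # chamber containment: reflect once, then freeze
        if (!is.null(semi)) {
          still <- which(ens$status[live] == "suspended")
          if (length(still)) {
            gi <- live[still]
            X <- ens$pos[gi, , drop = FALSE]
            q <- rowSums(sweep(X, 2, semi, `/`)^2)
            lf <- laa_frame(mesh, X)
            in_laa <- lf$s > -4 & lf$s < attr(mesh, "laa_length") &
              lf$r < laa_radius_at(mesh, pmax(lf$s, 0)) + 2
            in_pv <- rep(FALSE, length(gi))
            for (p in attr(mesh, "pv_caps") %||% list()) {
              dd <- sweep(X, 2, p$base, `-`)
              sp <- drop(dd %*% p$normal)
              rp <- row_norms(dd - outer(sp, p$normal))
              in_pv <- in_pv | (sp > -1 & sp < 1.05 *
                                  sqrt(sum((p$center - p$base)^2)) &
                                  rp < p$radius + 0.5)
            }
            # tolerance band: particles skimming the chamber surface are not
            # escapes; only clear departures reflect (once) or freeze
            escape <- q > 1.1 & !in_laa & !in_pv
            if (any(escape)) {
              ei <- gi[escape]
              nvec <- sweep(X[escape, , drop = FALSE], 2, semi^2, `/`)
              nvec <- nvec / row_norms(nvec)
              vn <- rowSums(ens$vel[ei, , drop = FALSE] * nvec)
              ens$vel[ei, ] <- ens$vel[ei, , drop = FALSE] -
                2 * vn * nvec
              # pull back inside the chamber surface
              scl <- 0.995 / sqrt(q[escape])
              ens$pos[ei, ] <- X[escape, , drop = FALSE] * scl
              reoffend <- ens$reflections[ei] >= 1L
              frozen[ei[reoffend]] <- TRUE
              ens$reflections[ei] <- ens$reflections[ei] + 1L
            }
          }
        }
      }
    }
    # roll / detach evaluation for adhered particles
    adh <- which(ens$status %in% c("attached", "rolling"))
    if (length(adh)) {
      s <- sample_many(series, ens$pos[adh, , drop = FALSE], t)
      fn <- face_normals(wall_mesh)
      for (ii in seq_along(adh)) {
        gi <- adh[ii]
        el <- ens$attach_element[gi]
        nrm <- if (!is.na(el)) fn[el, ] else c(0, 0, 1)
        u <- s$u[ii, ]
        ut <- u - sum(u * nrm) * nrm
        vt <- sqrt(sum(ut^2))
        we <- props$rho_p * ens$diameter[gi] * vt^2 / props$sigma_p
        if (ens$status[gi] == "rolling" &&
            we > props$detach_we_factor * props$we_crit) {
          ens$status[gi] <- "suspended"
          ens$vel[gi, ] <- ut
        } else if (we > props$we_crit && vt > props$roll_floor) {
          ens$status[gi] <- "rolling"
          speed <- min(vt, props$roll_cap)
          ens$vel[gi, ] <- ut / vt * speed
          ens$pos[gi, ] <- ens$pos[gi, ] + ens$vel[gi, ] * dt * 1000
        } else {
          ens$status[gi] <- "attached"
          ens$vel[gi, ] <- 0
        }
      }
    }
    born <- ens$status != "unborn"
    attached_fraction[k] <- if (any(born)) {
      mean(ens$status[born] %in% c("attached", "rolling"))
    } else 0
    # count conservation check
    stopifnot(sum(ens$status %in%
                    c("unborn", "suspended", "attached", "rolling",
                      "exited")) == n)
  }
  counts <- table(factor(ens$status,
                         levels = c("suspended", "attached", "rolling",
                                    "exited", "unborn")))
  n_inj_total <- sum(ens$status != "unborn")
  adhered <- sum(ens$status %in% c("attached", "rolling"))
  amap <- table(ens$attach_element[!is.na(ens$attach_element)])
  structure(list(
    pct_attached = 100 * adhered / max(n_inj_total, 1L),
    mean_attach_speed = mean(ens$attach_speed, na.rm = TRUE),
    counts = counts,
    attachment_map = amap,
    attached_fraction = attached_fraction,
    n_injected = n_inj_total,
    n_frozen = sum(frozen),
    ensemble = ens),
    class = "adhesion_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adhesion_summary <- function(x, ...) {
  cat(sprintf("adhesion_summary: %d injected, %.1f%% adhered (mean attach speed %.3f m/s)\n",
              x$n_injected, x$pct_attached, x$mean_attach_speed))
  print(x$counts)
  invisible(x)
}
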