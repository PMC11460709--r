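#' Time-resolved velocity-field series on a regular grid
#'
#' Container for a pulsatile velocity field sampled on a regular Cartesian
#' grid (mm) at the simulation time steps (s). Space-time sampling is linear
#' (trilinear in space, linear in time) and exact at stored nodes/steps;
#' velocity gradients are the analytic derivatives of the trilinear
#' interpolant within each cell, converted to SI (1/s).
#'
#' @param u numeric array `c(nx, ny, nz, nt, 3)`, velocities in m/s.
#' @param grid list with numeric vectors `x`, `y`, `z` (mm, strictly
#'   increasing, uniform spacing).
#' @param times numeric vector of length `nt` (s), strictly increasing.
#' @return an object of class `velocity_series`.
#' @export
velocity_series <- function(u, grid, times) {
  stopifnot(length(dim(u)) == 5L, dim(u)[5] == 3L)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  if (any(!is.finite(u))) stop("velocity samples must all be finite")
  structure(list(u = u, grid = grid, times = times,
                 interpolation = "linear"),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$u)
  cat("velocity_series:", d[1], "x", d[2], "x", d[3], "grid,",
      d[4], "steps, t in [", min(x$times), ",", max(x$times), "] s\n")
  invisible(x)
}

# Vectorized space-time sampling. X: n x 3 positions (mm); t scalar (s).
# Returns u (n x 3), grad (n x 3 x 3 with grad[,i,j] = d u_i / d x_j, 1/s)
# and `inside` flags. Positions outside the grid are clamped for evaluation.
sample_many <- function(series, X, t) {
  g <- series$grid
  d <- dim(series$u)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nt <- d[4]
  X <- matrix(X, ncol = 3)
  n <- nrow(X)

  tt <- series$times
  kt <- findInterval(t, tt, rightmost.closed = TRUE)
  kt <- min(max(kt, 1L), nt - 1L)
  if (nt == 1L) { kt <- 1L; wt <- 0 } else {
    wt <- (t - tt[kt]) / (tt[kt + 1L] - tt[kt])
    wt <- min(max(wt, 0), 1)
  }

  axis_locate <- function(p, gr) {
    ng <- length(gr)
    i <- findInterval(p, gr, rightmost.closed = TRUE)
    inside <- p >= gr[1] & p <= gr[ng]
    i <- pmin(pmax(i, 1L), ng - 1L)
    f <- (p - gr[i]) / (gr[i + 1L] - gr[i])
    list(i = i, f = pmin(pmax(f, 0), 1), inside = inside,
         h = gr[2] - gr[1])
  }
  lx <- axis_locate(X[, 1], g$x)
  ly <- axis_locate(X[, 2], g$y)
  lz <- axis_locate(X[, 3], g$z)
  inside <- lx$inside & ly$inside & lz$inside

  # linear indices of the 8 cell corners for each point, per component/time
  base_idx <- function(ix, iy, iz) {
    (ix - 1L) + nx * ((iy - 1L) + ny * (iz - 1L)) + 1L
  }
  corner <- function(dx, dy, dz) base_idx(lx$i + dx, ly$i + dy, lz$i + dz)
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)

  nspace <- nx * ny * nz
  uu <- matrix(0, n, 3)
  grad <- array(0, c(n, 3, 3))
  fx <- lx$f; fy <- ly$f; fz <- lz$f
  for (comp in 1:3) {
    slab <- function(k) {
      off <- nspace * ((k - 1L) + nt * (comp - 1L))
      uv <- series$u  # flat single-bracket indexing: no copy
      v000 <- uv[off + c000]; v100 <- uv[off + c100]
      v010 <- uv[off + c010]; v110 <- uv[off + c110]
      v001 <- uv[off + c001]; v101 <- uv[off + c101]
      v011 <- uv[off + c011]; v111 <- uv[off + c111]
      # interpolate in z then y, keeping x-pairs for the derivative
      a00 <- v000 * (1 - fz) + v001 * fz
      a10 <- v100 * (1 - fz) + v101 * fz
      a01 <- v010 * (1 - fz) + v011 * fz
      a11 <- v110 * (1 - fz) + v111 * fz
      b0 <- a00 * (1 - fy) + a01 * fy
      b1 <- a10 * (1 - fy) + a11 * fy
      val <- b0 * (1 - fx) + b1 * fx
      ddx <- (b1 - b0) / lx$h
      # d/dy: interpolate x first
      cx0 <- a00 * (1 - fx) + a10 * fx
      cx1 <- a01 * (1 - fx) + a11 * fx
      ddy <- (cx1 - cx0) / ly$h
      # d/dz
      e00 <- v000 * (1 - fy) + v010 * fy
      e10 <- v100 * (1 - fy) + v110 * fy
      e01 <- v001 * (1 - fy) + v011 * fy
      e11 <- v101 * (1 - fy) + v111 * fy
      z0 <- e00 * (1 - fx) + e10 * fx
      z1 <- e01 * (1 - fx) + e11 * fx
      ddz <- (z1 - z0) / lz$h
      list(val = val, ddx = ddx, ddy = ddy, ddz = ddz)
    }
    s0 <- slab(kt)
    if (wt > 0 && nt > 1L) {
      s1 <- slab(kt + 1L)
      mix <- function(a, b) a * (1 - wt) + b * wt
      val <- mix(s0$val, s1$val)
      ddx <- mix(s0$ddx, s1$ddx); ddy <- mix(s0$ddy, s1$ddy)
      ddz <- mix(s0$ddz, s1$ddz)
    } else {
      val <- s0$val; ddx <- s0$ddx; ddy <- s0$ddy; ddz <- s0$ddz
    }
    uu[, comp] <- val
    # grid is mm, velocity m/s: convert spatial derivative to 1/s
    grad[, comp, 1] <- ddx * 1000
    grad[, comp, 2] <- ddy * 1000
    grad[, comp, 3] <- ddz * 1000
  }
  list(u = uu, grad = grad, inside = inside)
}

#' Sample the velocity field at one position and time
#'
#' Linear interpolation in space and time; exact at grid nodes and stored
#' steps. Also returns the velocity-gradient tensor, its symmetric part (the
#' deformation tensor) and the shear magnitude `sqrt(d_lk d_kl)`.
#'
#' @param series a [velocity_series()].
#' @param x position (mm), length-3.
#' @param t time (s) within the series span.
#' @return list with `u` (m/s), `grad_u` (3 x 3, 1/s, `grad_u[i, j]` =
#'   du_i/dx_j), `d_ij` (symmetric part), `shear_magnitude` (1/s).
#' @export
sample_flow <- function(series, x, t) {
  if (t < min(series$times) - 1e-12 || t > max(series$times) + 1e-12) {
    stop("time ", t, " outside series span")
  }
  s <- sample_many(series, matrix(x, 1, 3), t)
  if (!s$inside) stop("position outside the field support (out of domain)")
  grad <- matrix(s$grad[1, , ], 3, 3)
  dij <- 0.5 * (grad + t(grad))
  list(u = drop(s$u), grad_u = grad, d_ij = dij,
       shear_magnitude = sqrt(sum(dij * dij)))
}

#' Generate an analytic pulsatile flow field on an idealized atrium
#'
#' Superposes (i) an ambient chamber component — a hemispherical sink at the
#' mitral outlet plus an interior drift vanishing at the chamber wall —
#' blended into a uniform plug near the outlet cap so the imposed outlet
#' velocity is recovered exactly there; (ii) a chamber vortex about the
#' outlet axis; (iii) pulmonary-vein inlet jets with parabolic profiles
#' scaled to balance the outlet flow; (iv) an intra-appendage
#' sign-reversing recirculation cell whose amplitude scales with the
#' exposed ostium-to-device gap, with ambient flow decaying exponentially
#' with depth into the appendage (decay length `8 / stasis` mm) — so
#' proximal, ridge-covering device poses see faster device-surface flow
#' than deep poses by construction; and (v) an optional additive
#' divergence-free stochastic perturbation (random transverse Fourier
#' modes) with amplitude a fixed fraction of the peak transmitral speed.
#'
#' @param mesh an atrium from [generate_atrium()] (device pose read from its
#'   `device_depth` attribute).
#' @param waveforms a [waveform_set()].
#' @param seed integer seed for the stochastic perturbation.
#' @param stasis dimensionless stasis parameter (>= 0); larger values shorten
#'   the ambient decay length inside the appendage, slowing intra-LAA flow.
#' @param vortex_strength chamber swirl speed per unit transmitral speed at
#'   30 mm radius (dimensionless, default 0.5).
#' @param recirc_speed peak appendage recirculation speed (m/s) at full
#'   ostium exposure (default 0.15).
#' @param perturb_amplitude perturbation amplitude as a fraction of the peak
#'   transmitral speed (default 0.05; 0 disables).
#' @param grid_n grid nodes per axis (length 1 or 3).
#' @return a [velocity_series()] covering `n_beats` beats.
#' @export
generate_flow <- function(mesh, waveforms, seed = 1L, stasis = 1,
                          vortex_strength = 0.5, recirc_speed = 0.15,
                          perturb_amplitude = 0.05, grid_n = 20L) {
  mv_cap <- attr(mesh, "mv_cap")
  if (is.null(mv_cap)) stop("mesh has no outlet (mv_outlet) label/descriptor")
  pv_caps <- attr(mesh, "pv_caps")
  f <- flow_field_function(mesh, waveforms, seed, stasis, vortex_strength,
                           recirc_speed, perturb_amplitude)
  if (length(grid_n) == 1L) grid_n <- rep(grid_n, 3L)
  lo <- apply(mesh$vertices, 2, min) - 2
  hi <- apply(mesh$vertices, 2, max) + 2
  grid <- list(x = seq(lo[1], hi[1], length.out = grid_n[1]),
               y = seq(lo[2], hi[2], length.out = grid_n[2]),
               z = seq(lo[3], hi[3], length.out = grid_n[3]))
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  nt <- waveforms$n_beats * waveforms$steps_per_beat
  times <- (seq_len(nt) - 1L) * waveforms$dt
  u <- array(0, c(grid_n, nt, 3))
  npts <- nrow(pts)
  for (k in seq_len(nt)) {
    uk <- f(pts, times[k])
    u[, , , k, 1] <- array(uk[, 1], grid_n)
    u[, , , k, 2] <- array(uk[, 2], grid_n)
    u[, , , k, 3] <- array(uk[, 3], grid_n)
  }
  vs <- velocity_series(u, grid, times)
  attr(vs, "field_fun") <- f
  attr(vs, "params") <- list(seed = seed, stasis = stasis,
                             vortex_strength = vortex_strength,
                             recirc_speed = recirc_speed,
                             perturb_amplitude = perturb_amplitude)
  attr(vs, "waveforms") <- waveforms
  vs
}

# The analytic field as a closure: f(X, t) with X in mm, result m/s.
flow_field_function <- function(mesh, waveforms, seed, stasis,
                                vortex_strength, recirc_speed,
                                perturb_amplitude) {
  mv_cap <- attr(mesh, "mv_cap")
  pv_caps <- attr(mesh, "pv_caps")
  e_mv <- mv_cap$normal / sqrt(sum(mv_cap$normal^2))
  mv_peak <- max(waveforms$mv_velocity)
  depth <- attr(mesh, "device_depth")
  if (is.null(depth)) depth <- 0
  L <- attr(mesh, "laa_length")
  gap <- min(max(depth, 0), L)
  gap_frac <- gap / L + 0.02
  lambda <- 5

  # mass balance factor for PV jets
  a_mv <- pi * mv_cap$radius^2
  a_pv <- sum(vapply(pv_caps, function(p) pi * p$radius^2, 0))

  # seeded divergence-free perturbation modes (transverse plane waves)
  modes <- NULL
  if (perturb_amplitude > 0 && mv_peak > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    nm <- 4L
    kdir <- matrix(stats::rnorm(3 * nm), nm, 3)
    kdir <- kdir / row_norms(kdir)
    adir <- matrix(stats::rnorm(3 * nm), nm, 3)
    adir <- adir - kdir * rowSums(adir * kdir)
    adir <- adir / row_norms(adir)
    modes <- list(k = kdir, a = adir,
                  lambda_mm = stats::runif(nm, 15, 40),
                  phase = stats::runif(nm, 0, 2 * pi),
                  amp = perturb_amplitude * mv_peak / nm)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else {
      rm(".Random.seed", envir = globalenv())
    }
  }

  semi <- attr(mesh, "chamber_semi_axes")

  function(X, t) {
    X <- matrix(X, ncol = 3)
    n <- nrow(X)
    vmv <- waveform_mv_at(waveforms, t)

    # ambient chamber flow: hemispherical sink at the mitral outlet plus an
    # interior drift that vanishes at the chamber wall (keeps particles off
    # the wall), blended into a uniform plug within one annulus diameter of
    # the outlet cap so the imposed outlet velocity is matched exactly
    to_mv <- sweep(-X, 2, mv_cap$center, `+`)   # mv_center - x
    dist <- pmax(row_norms(to_mv), 1e-9)
    dirm <- to_mv / dist
    u_sink <- (vmv * mv_cap$radius^2 / (2 * pmax(dist, mv_cap$radius)^2)) *
      dirm
    q <- if (!is.null(semi)) rowSums(sweep(X, 2, semi, `/`)^2) else
      rep(0, n)
    wall_fac <- pmax(1 - q, 0)
    u_drift <- outer(0.8 * vmv * wall_fac, e_mv)
    amb <- u_sink + u_drift
    # plateau of one annulus radius around the cap, then linear falloff, so
    # grid interpolation at the cap still recovers the imposed waveform
    w_cap <- pmin(pmax((2.5 * mv_cap$radius - dist) / (1.5 * mv_cap$radius),
                       0), 1)
    u <- outer(w_cap * vmv, e_mv) + (1 - w_cap) * amb

    # chamber vortex about the outlet axis through the origin; tapered to
    # zero near the outlet plane so the imposed outlet velocity is clean
    r_perp <- X - outer(drop(X %*% e_mv), e_mv)
    swirl <- cross3(matrix(e_mv, n, 3, byrow = TRUE), r_perp) / 30
    d_out <- abs(drop(sweep(X, 2, mv_cap$center, `-`) %*% e_mv))
    taper <- pmin(pmax((d_out - 5) / 10, 0), 1)
    u <- u + vortex_strength * vmv * swirl * taper

    # pulmonary-vein jets (parabolic profile, inward = -cap normal)
    for (p in pv_caps) {
      d <- sweep(X, 2, p$base, `-`)
      s <- drop(d %*% p$normal)
      rp <- row_norms(d - outer(s, p$normal))
      inj <- s > -2 & s <= (sqrt(sum((p$center - p$base)^2)) + 1) &
        rp < p$radius
      if (any(inj)) {
        vj <- vmv * (a_mv / a_pv) * 2 * (1 - (rp[inj] / p$radius)^2)
        u[inj, ] <- u[inj, , drop = FALSE] -
          outer(vj, p$normal)
      }
    }

    # appendage: ambient decay inside the cone + gap-scaled sign-reversing
    # filling/emptying cell, extended into a short entrainment zone in front
    # of the mouth so the exposed appendage actually exchanges particles
    # with the chamber; a covered pose (gap ~ 0) suppresses the cell
    lf <- laa_frame(mesh, X)
    in_cone <- lf$s > 0 & lf$r < laa_radius_at(mesh, lf$s) + 1
    if (any(in_cone)) {
      s_in <- lf$s[in_cone]
      damp <- exp(-s_in / lambda)
      # seal behind the device face
      damp <- damp * ifelse(s_in > gap, exp(-(s_in - gap) / 3), 1)
      u[in_cone, ] <- u[in_cone, , drop = FALSE] * damp
    }
    # stasis damps the ambient sweep in the mouth vestibule: under impaired
    # emptying, near-ostium blood is not washed back into the chamber
    if (stasis > 1) {
      in_vest <- lf$s > -10 & lf$s <= 0 &
        lf$r < laa_radius_at(mesh, 0) + 2
      if (any(in_vest)) {
        w_v <- 1 + lf$s[in_vest] / 10
        scale <- 1 - w_v * (1 - 1 / stasis)
        u[in_vest, ] <- u[in_vest, , drop = FALSE] * scale
      }
    }
    in_cell <- lf$s > -15 & lf$r < laa_radius_at(mesh, pmax(lf$s, 0)) + 2
    if (any(in_cell)) {
      s_c <- lf$s[in_cell]
      R <- laa_radius_at(mesh, pmax(s_c, 0))
      # breathing (filling/emptying) profile of a compliant sac; strictly
      # positive core so the oscillation survives coarse grid sampling
      prof <- 1 - (pmin(lf$r[in_cell] / (R + 2), 1))^2
      period <- waveforms$beat_period
      osc <- sin(2 * pi * t / period)
      # impaired emptying under stasis: the outflow half-phase is attenuated
      # by the stasis parameter, so slower appendage flow retains particles
      if (osc < 0) osc <- osc / max(stasis, 1e-6)
      # cell strength follows the transmitral forcing (0.45 m/s reference
      # E-peak); a null forcing yields a null field
      amp <- recirc_speed * osc * gap_frac * mv_peak / 0.45
      axial_fac <- ifelse(s_c >= 0, exp(-s_c / 12), exp(s_c / 6))
      axial_fac <- axial_fac * ifelse(s_c > gap, exp(-(s_c - gap) / 3), 1)
      ax <- attr(mesh, "laa_axis")
      u[in_cell, ] <- u[in_cell, , drop = FALSE] +
        outer(amp * prof * axial_fac, ax)
    }
    # no-penetration surrogate at the device proximal face: the axial flow
    # component is removed in a thin layer in front of the face, so flow
    # washes across a covered face instead of impinging on it
    if (!is.null(depth)) {
      ax <- attr(mesh, "laa_axis")
      face_r <- laa_radius_at(mesh, gap) + 3
      in_face <- lf$s <= gap & lf$s > gap - 6 & lf$r < face_r
      if (any(in_face)) {
        w <- exp(-(gap - lf$s[in_face]) / 2)
        uax <- drop(u[in_face, , drop = FALSE] %*% ax)
        u[in_face, ] <- u[in_face, , drop = FALSE] - outer(w * uax, ax)
      }
    }

    if (!is.null(modes)) {
      for (j in seq_len(nrow(modes$k))) {
        ph <- 2 * pi * drop(X %*% modes$k[j, ]) / modes$lambda_mm[j] +
          modes$phase[j]
        u <- u + outer(modes$amp * cos(ph) * taper * vmv /
                         max(mv_peak, 1e-12), modes$a[j, ])
      }
    }
    u
  }
}

# Phase windows ---------------------------------------------------------------

#' Cardiac phase window
#'
#' Beat-local analysis windows: systole `[0, 0.30]` s, diastole
#' `[0.31, 0.88]` s, full cycle `[0, 0.88]` s by default; windows are closed
#' on the sample grid with the beat-period end mapping to the last stored
#' step, so systole and diastole partition the default 88-step beat exactly
#' (31 + 57 samples). Statistics are evaluated on the second beat by default.
#'
#' @param name one of `"systole"`, `"diastole"`, `"full_cycle"`.
#' @param beat_period beat length (s).
#' @param t_start,t_end optional overrides (s, beat-local).
#' @return an object of class `phase_window`.
#' @export
phase_window <- function(name = c("full_cycle", "systole", "diastole"),
                         beat_period = 0.88, t_start = NULL, t_end = NULL) {
  name <- match.arg(name)
  def <- switch(name,
                systole = c(0, 0.30),
                diastole = c(0.31, beat_period),
                full_cycle = c(0, beat_period))
  structure(list(name = name,
                 t_start = if (is.null(t_start)) def[1] else t_start,
                 t_end = if (is.null(t_end)) def[2] else t_end,
                 beat_period = beat_period),
            class = "phase_window")
}

# indices of series steps inside the window on the given beat
window_steps <- function(series, window, beat = 2L) {
  tt <- series$times
  t0 <- (beat - 1L) * window$beat_period
  tb <- tt - t0
  eps <- 1e-9
  in_beat <- tb >= -eps & tb < window$beat_period - eps
  hi <- if (window$t_end >= window$beat_period - eps) {
    window$beat_period  # include through the final stored step
  } else window$t_end
  which(in_beat & tb >= window$t_start - eps & tb <= hi + eps)
}

# Regions ---------------------------------------------------------------------

#' Device-neighbourhood measurement region
#'
#' The region between the ostium-side plane through the pulmonary-ridge
#' (LSPV) fold and the device proximal face, plus the device surface itself.
#' Sample points are device-surface face centroids and appendage-wall face
#' centroids inside the band; statistics over the region weight each sample
#' point equally (node-count weighting).
#'
#' @param mesh atrium mesh with `lspv_endpoint`, `ostium_center`, `laa_axis`
#'   attributes.
#' @param device placed device mesh ([place_device()]); `NULL` uses only the
#'   wall band.
#' @param tol signed-distance tolerance for band membership (mm).
#' @return an object of class `flow_region` with `points`, the two bounding
#'   planes, and an approximate band `volume_mm3`.
#' @export
device_region <- function(mesh, device = NULL, tol = 1e-6) {
  oc <- attr(mesh, "ostium_center")
  ax <- attr(mesh, "laa_axis")
  if (is.null(oc) || is.null(ax)) stop("mesh lacks ostium/axis labels")
  lspv <- attr(mesh, "lspv_endpoint")
  if (is.null(lspv)) stop("mesh lacks the lspv_endpoint label")
  # fold plane: through the LSPV fold point, normal = LAA axis; band runs
  # from that plane (clamped to the ostium plane) to the device face
  s_fold <- min(max(sum((lspv - oc) * ax), 0), attr(mesh, "laa_length"))
  depth <- if (!is.null(device)) {
    pf <- attr(device, "proximal_face")
    if (is.null(pf)) stop("device mesh lacks a proximal_face descriptor")
    sum((pf$center - oc) * ax)
  } else {
    d <- attr(mesh, "device_depth"); if (is.null(d)) 0 else max(d, 0)
  }
  depth <- max(depth, 0)
  cent <- face_centroids(mesh)
  wall <- mesh$labels == "laa_wall"
  lf <- laa_frame(mesh, cent)
  band <- wall & lf$s > s_fold + tol & lf$s < depth - tol
  pts <- cent[band, , drop = FALSE]
  if (!is.null(device)) {
    # only the exposed (proximal) device surface is in fluid contact; faces
    # distal to the proximal-face plane sit in the sealed appendage
    dc <- face_centroids(device)
    sd_dev <- laa_frame(mesh, dc)$s
    pts <- rbind(pts, dc[sd_dev <= depth + 0.5, , drop = FALSE])
  }
  if (nrow(pts) == 0L) stop("empty region: no device surface and no band")
  # band volume: slab integral of the local circular cross-section
  vol <- 0
  if (depth > s_fold) {
    sgrid <- seq(s_fold, depth, length.out = 64L)
    vol <- sum(pi * laa_radius_at(mesh, sgrid)^2) * diff(sgrid[1:2])
  }
  structure(list(points = pts,
                 plane_fold = list(point = oc + s_fold * ax, normal = ax),
                 plane_device = list(point = oc + depth * ax, normal = ax),
                 s_fold = s_fold, s_device = depth,
                 volume_mm3 = vol),
            class = "flow_region")
}

#' Phase-resolved mean speed over a region
#'
#' Mean and standard deviation of the velocity magnitude over all region
#' sample points and all stored steps inside the phase window (node-count
#' weighting, sample sd).
#'
#' @param series a [velocity_series()].
#' @param region a [flow_region()] from [device_region()], or an n x 3 matrix
#'   of sample points (mm).
#' @param window a [phase_window()].
#' @param beat beat index to analyse (default 2, the converged beat).
#' @return list with `mean`, `sd` (m/s) and `n` samples.
#' @export
phase_average_speed <- function(series, region,
                                window = phase_window("full_cycle"),
                                beat = 2L) {
  pts <- if (inherits(region, "flow_region")) region$points else
    matrix(region, ncol = 3)
  if (nrow(pts) == 0L) stop("empty region")
  ks <- window_steps(series, window, beat)
  if (length(ks) == 0L) stop("window contains no stored steps")
  speeds <- unlist(lapply(ks, function(k) {
    row_norms(sample_many(series, pts, series$times[k])$u)
  }))
  list(mean = mean(speeds),
       sd = if (length(speeds) > 1L) stats::sd(speeds) else 0,
       n = length(speeds))
}

#' Recirculation score of a region
#'
#' Quantifies flow reversal as `1 - |time-mean velocity| / time-mean speed`
#' averaged over region points: 0 for steady unidirectional flow, 1 for
#' fully reversing flow. The companion flag requires both a score at or
#' above `threshold` and a mean speed below `speed_limit` — a steady but
#' slow flow is not flagged. This score is this package's quantification of
#' the streamline-based visual judgement used in clinical CFD reports; the
#' 0.5 default threshold is a documented configuration value.
#'
#' @inheritParams phase_average_speed
#' @param threshold score threshold for the flag (default 0.5).
#' @param speed_limit stasis speed threshold in m/s (default 0.2).
#' @return list with `score` in `[0, 1]`, `flag`, `mean_speed`, and
#'   `degenerate` (TRUE when the flow vanished everywhere).
#' @export
recirculation_index <- function(series, region,
                                window = phase_window("full_cycle"),
                                beat = 2L, threshold = 0.5,
                                speed_limit = 0.2) {
  pts <- if (inherits(region, "flow_region")) region$points else
    matrix(region, ncol = 3)
  if (nrow(pts) == 0L) stop("empty region")
  ks <- window_steps(series, window, beat)
  np <- nrow(pts)
  usum <- matrix(0, np, 3)
  spsum <- numeric(np)
  for (k in ks) {
    uk <- sample_many(series, pts, series$times[k])$u
    usum <- usum + uk
    spsum <- spsum + row_norms(uk)
  }
  mean_vec <- usum / length(ks)
  mean_speed <- spsum / length(ks)
  degenerate <- all(mean_speed <= 0)
  ratio <- ifelse(mean_speed > 0, row_norms(mean_vec) / mean_speed, 0)
  score <- mean(1 - ratio)
  if (degenerate) {
    warning("degenerate flow: zero mean speed everywhere; score set to 1")
    score <- 1
  }
  ms <- mean(mean_speed)
  list(score = score, flag = (score >= threshold) && (ms < speed_limit),
       mean_speed = ms, degenerate = degenerate)
}
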