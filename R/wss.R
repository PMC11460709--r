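#' Wall-shear-stress series on a surface
#'
#' Per-element shear-stress vector time series over one analysis beat,
#' stored as an array `tau[element, step, component]` in Pa with the step
#' size `dt`.
#'
#' @param tau numeric array `c(n_elements, n_steps, 3)`, Pa.
#' @param dt time step, s.
#' @param element_ids optional element identifiers.
#' @param areas optional element areas, mm^2 (used for area weighting).
#' @return an object of class `wss_series`.
#' @export
wss_series <- function(tau, dt, element_ids = NULL, areas = NULL) {
  stopifnot(length(dim(tau)) == 3L, dim(tau)[3] == 3L)
  if (any(!is.finite(tau))) stop("WSS values must be finite")
  if (is.null(element_ids)) element_ids <- seq_len(dim(tau)[1])
  structure(list(tau = tau, dt = dt, element_ids = element_ids,
                 areas = areas),
            class = "wss_series")
}

#' Derive wall shear stress from a velocity field
#'
#' Newtonian near-wall estimate: the fluid velocity is sampled one probe
#' length `delta` inside the wall-adjacent fluid along the inward normal at
#' each face centroid; its wall-tangential component divided by the probe
#' length, times the dynamic viscosity, is the shear-stress vector. The
#' result is tangent to the surface by construction. One beat of steps is
#' extracted (the second beat by default).
#'
#' @param series a [velocity_series()].
#' @param mesh a [surface_mesh()]; faces selected by `labels` contribute.
#' @param labels face labels forming the wall (default: appendage wall and
#'   any device region).
#' @param mu dynamic viscosity, kg/(m s) (blood default 0.0035).
#' @param delta probe length, mm.
#' @param beat beat index to extract (default 2).
#' @param inward optional n x 3 matrix of inward unit normals; defaults to
#'   the face normals flipped to point away from the sampling side.
#' @return a [wss_series()] with element areas attached.
#' @export
generate_wss <- function(series, mesh,
                         labels = c("laa_wall", "device_lobe", "device_disk",
                                    "device"),
                         mu = 0.0035, delta = 0.5, beat = 2L,
                         inward = NULL) {
  sel <- which(mesh$labels %in% labels)
  if (length(sel) == 0L) stop("no faces match the requested labels")
  cen <- face_centroids(mesh)[sel, , drop = FALSE]
  nrm <- face_normals(mesh)[sel, , drop = FALSE]
  if (!is.null(inward)) {
    nrm <- -matrix(inward, ncol = 3)  # stored as outward below
  }
  # probe on the fluid side: for the tubular appendage wall the fluid is on
  # the axis side; orient normals outward relative to the appendage axis when
  # available, else keep mesh orientation
  oc <- attr(mesh, "ostium_center")
  if (!is.null(oc) && is.null(inward)) {
    lf <- laa_frame(mesh, cen)
    radial <- lf$perp
    rn <- row_norms(radial)
    ok <- rn > 1e-9
    flip <- rowSums(nrm * radial) < 0
    nrm[ok & flip, ] <- -nrm[ok & flip, , drop = FALSE]
  }
  probe <- cen - delta * nrm
  wf <- attr(series, "waveforms")
  period <- if (!is.null(wf)) wf$beat_period else 0.88
  win <- phase_window("full_cycle", beat_period = period)
  ks <- window_steps(series, win, beat = beat)
  if (length(ks) == 0L) {
    stop("coverage error: series does not span the requested beat")
  }
  span_lo <- apply(mesh$vertices, 2, min); span_hi <- apply(mesh$vertices, 2, max)
  glo <- c(series$grid$x[1], series$grid$y[1], series$grid$z[1])
  ghi <- c(max(series$grid$x), max(series$grid$y), max(series$grid$z))
  if (any(span_lo < glo - 1e-6) || any(span_hi > ghi + 1e-6)) {
    stop("consistency error: mesh extends outside the field support")
  }
  nel <- nrow(probe)
  tau <- array(0, c(nel, length(ks), 3))
  delta_m <- delta / 1000
  for (j in seq_along(ks)) {
    u <- sample_many(series, probe, series$times[ks[j]])$u
    ut <- u - nrm * rowSums(u * nrm)   # tangential projection
    tau[, j, ] <- mu * ut / delta_m
  }
  dt <- diff(series$times[1:2])
  wss_series(tau, dt, element_ids = sel, areas = face_areas(mesh)[sel])
}
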