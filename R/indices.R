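#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) * sum_i |tau(t_i)| * dt` over the analysis beat, per
#' surface element.
#'
#' @param series a [wss_series()] covering one full beat.
#' @return numeric vector, Pa, one value per element.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  mag <- sqrt(apply(series$tau^2, c(1, 2), sum))
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = dim(series$tau)[1])
  rowMeans(mag)
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |sum tau dt| / sum |tau| dt)` per element, using the
#' vector-valued time integral: 0 marks unidirectional shear, 0.5 fully
#' reversing shear. Elements with identically zero shear are assigned 0.
#'
#' @inheritParams tawss
#' @return numeric vector in `[0, 0.5]`, one value per element.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  vint <- sqrt(rowSums(apply(series$tau, c(1, 3), sum)^2))
  mint <- rowSums(sqrt(apply(series$tau^2, c(1, 2), sum)))
  out <- numeric(length(mint))
  pos <- mint > 0
  out[pos] <- 0.5 * (1 - vint[pos] / mint[pos])
  pmin(pmax(out, 0), 0.5)
}

#' Endothelial cell activation potential (ECAP)
#'
#' `ECAP = OSI / TAWSS` per element (1/Pa): high values mark slow,
#' oscillatory, thrombus-prone wall regions. Elements whose TAWSS falls
#' below `eps` are flagged undefined (`NA`) and excluded from summaries;
#' their count is attached as the `n_undefined` attribute.
#'
#' @inheritParams tawss
#' @param eps TAWSS floor below which the ratio is undefined, Pa.
#' @return numeric vector, 1/Pa, `NA` where undefined.
#' @export
ecap <- function(series, eps = 1e-9) {
  ta <- tawss(series)
  os <- osi(series)
  out <- ifelse(ta > eps, os / ta, NA_real_)
  attr(out, "n_undefined") <- sum(ta <= eps)
  out
}

#' Region summary of an index map
#'
#' Max and mean +/- sd of a per-element index, area-weighted when element
#' areas are available (wall-shear indices are element fields); undefined
#' elements are dropped and counted.
#'
#' @param values per-element index values (possibly `NA`).
#' @param areas optional element areas for weighting.
#' @return list with `max`, `mean`, `sd`, `n`, `n_undefined`.
#' @export
index_summary <- function(values, areas = NULL) {
  und <- sum(is.na(values))
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) == 0L) {
    return(list(max = NA_real_, mean = NA_real_, sd = NA_real_,
                n = 0L, n_undefined = und))
  }
  if (is.null(areas)) {
    m <- mean(v); s <- if (length(v) > 1) stats::sd(v) else 0
  } else {
    w <- areas[ok] / sum(areas[ok])
    m <- sum(w * v)
    s <- sqrt(sum(w * (v - m)^2) * length(v) / max(length(v) - 1, 1))
  }
  list(max = max(v), mean = m, sd = s, n = length(v), n_undefined = und)
}

#' Threshold classification of region summaries
#'
#' Applies the standard DRT risk thresholds: low velocity when the
#' full-cycle mean speed is strictly below `velocity_ms` (default 0.2 m/s),
#' high ECAP when the region maximum exceeds `ecap_pa_inv` (default
#' 0.5 1/Pa). The mean-ECAP exceedance is reported alongside.
#'
#' @param ecap_summary list from [index_summary()] on the ECAP map.
#' @param velocity_summary list with `mean` full-cycle speed (m/s), as from
#'   [phase_average_speed()].
#' @param velocity_ms,ecap_pa_inv thresholds.
#' @return list of booleans `low_velocity`, `high_ecap`, `high_mean_ecap`.
#' @export
classify_thresholds <- function(ecap_summary, velocity_summary,
                                velocity_ms = 0.2, ecap_pa_inv = 0.5) {
  list(low_velocity = isTRUE(velocity_summary$mean < velocity_ms),
       high_ecap = isTRUE(ecap_summary$max > ecap_pa_inv),
       high_mean_ecap = isTRUE(ecap_summary$mean > ecap_pa_inv))
}
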