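# Wall shear indices from a per-vertex traction time series over one cardiac
# cycle. All integrals use periodic trapezoidal quadrature: the series spans
# exactly one period, so the first sample is reused to close the cycle,
# which for uniform sampling reduces to the plain sample mean.

# periodic trapezoidal time average of x(t): x is n_vertices x n_times (or
# n_times vector); times span [0, T).
periodic_time_average <- function(x, times, period) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nt <- length(times)
  w <- diff(c(times, period))
  wt <- c(w[1] / 2 + w[nt] / 2, (w[-nt] + w[-1]) / 2)
  as.numeric(x %*% wt) / period
}

#' Compute the wall shear stress indices from a traction series
#'
#' Computes, per vertex: TAWSS, the cycle average of the traction magnitude;
#' OSI, `0.5 * (1 - ||mean vector|| / TAWSS)` where the mean vector is the
#' time-averaged traction (dimensionless, in `[0, 0.5]`); ECAP = OSI/TAWSS;
#' RRT, the reciprocal of the mean-vector magnitude; HOLMES =
#' `TAWSS * (0.5 - OSI)`; and the unit flow direction `g` of the
#' time-averaged traction. Vertices with TAWSS = 0 get OSI = 0 and are
#' flagged undefined for ECAP and RRT; vertices whose mean vector vanishes
#' get RRT = Inf with `rrt_defined = FALSE` (excluded, not capped, by
#' downstream statistics).
#'
#' @param series a [traction_series()] with at least 8 samples over one
#'   period.
#' @return object of class `shear_index_set`: list of numeric vectors
#'   `tawss` (Pa), `osi`, `ecap` (1/Pa), `rrt` (1/Pa), `holmes` (Pa),
#'   logical masks `ecap_defined`, `rrt_defined`, and matrix `g` (unit
#'   mean-traction directions).
#' @export
compute_shear_indices <- function(series) {
  stopifnot(inherits(series, "traction_series"))
  if (any(diff(series$times) <= 0)) stop("non-monotone time samples")
  tau <- series$traction
  n <- dim(tau)[1]; nt <- dim(tau)[3]
  mag <- sqrt(tau[, 1, ]^2 + tau[, 2, ]^2 + tau[, 3, ]^2)
  if (n == 1L) mag <- matrix(mag, nrow = 1)
  tawss <- periodic_time_average(mag, series$times, series$period)
  mean_vec <- vapply(1:3, function(ax) {
    m <- tau[, ax, ]
    if (n == 1L) m <- matrix(m, nrow = 1)
    periodic_time_average(m, series$times, series$period)
  }, numeric(n))
  if (n == 1L) mean_vec <- matrix(mean_vec, nrow = 1)
  mv_norm <- sqrt(rowSums(mean_vec^2))
  osi <- ifelse(tawss > 0, 0.5 * (1 - mv_norm / tawss), 0)
  osi <- pmin(pmax(osi, 0), 0.5)
  ecap_defined <- tawss > 0
  ecap <- ifelse(ecap_defined, osi / tawss, NA_real_)
  rrt_defined <- mv_norm > 0
  rrt <- ifelse(rrt_defined, 1 / mv_norm, Inf)
  holmes <- tawss * (0.5 - osi)
  g <- mean_vec / ifelse(mv_norm > 0, mv_norm, 1)
  structure(list(tawss = tawss, osi = osi, ecap = ecap, rrt = rrt,
                 holmes = holmes, g = g,
                 ecap_defined = ecap_defined, rrt_defined = rrt_defined),
            class = "shear_index_set")
}

#' @exportS3Method base::print
print.shear_index_set <- function(x, ...) {
  cat(sprintf(
    "shear_index_set: %d vertices | TAWSS [%.3g, %.3g] Pa | OSI [%.3g, %.3g]\n",
    length(x$tawss), min(x$tawss), max(x$tawss), min(x$osi), max(x$osi)))
  invisible(x)
}

#' Surface gradient of a per-vertex scalar field
#'
#' Per-face gradient of the linear interpolant (tangent to each face),
#' averaged to vertices with face-area weights. Zero-area faces are skipped.
#'
#' @param mesh a [surface_mesh()].
#' @param field numeric vector or [scalar_field()] on the vertices.
#' @return n x 3 matrix of gradient vectors (field units per mm).
#' @export
surface_scalar_gradient <- function(mesh, field) {
  f <- as.numeric(field)
  v <- mesh$vertices; tr <- mesh$triangles
  stopifnot(length(f) == nrow(v))
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)      # 2A * unit normal
  a2 <- sqrt(rowSums(nrm^2))           # 2A
  ok <- a2 > 1e-14
  nhat <- nrm / ifelse(ok, a2, 1)
  # grad f = (f1 (p3-p2) + f2 (p1-p3) + f3 (p2-p1)) rotated by n / (2A)
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
  gsum <- f[tr[, 1]] * cross3(nhat, e1) +
          f[tr[, 2]] * cross3(nhat, e2) +
          f[tr[, 3]] * cross3(nhat, e3)
  gface <- gsum / ifelse(ok, a2, 1)
  gface[!ok, ] <- 0
  area <- a2 / 2
  gv <- matrix(0, nrow(v), 3L)
  wv <- numeric(nrow(v))
  for (c in 1:3) {
    idx <- tr[, c]
    for (ax in 1:3) {
      acc <- tapply(gface[, ax] * area * ok, idx, sum)
      gv[as.integer(names(acc)), ax] <-
        gv[as.integer(names(acc)), ax] + acc
    }
    accw <- tapply(area * ok, idx, sum)
    wv[as.integer(names(accw))] <- wv[as.integer(names(accw))] + accw
  }
  gv / ifelse(wv > 0, wv, 1)
}

#' Time-averaged wall shear stress gradient along the flow direction
#'
#' At each time sample the surface gradient of the traction magnitude is
#' projected onto the unit traction direction; the projection is
#' time-averaged over the period (periodic trapezoid). Samples with zero
#' traction magnitude at a vertex contribute zero there (occurrences are
#' counted in the `"n_zero_mag"` attribute). `direction = "mean"` projects
#' instead onto the fixed time-averaged traction direction.
#'
#' @param series a [traction_series()].
#' @param mesh the [surface_mesh()] carrying the series.
#' @param direction `"instantaneous"` (default) or `"mean"`.
#' @return [scalar_field()] of WSSG in Pa/mm.
#' @export
compute_wssg <- function(series, mesh,
                         direction = c("instantaneous", "mean")) {
  direction <- match.arg(direction)
  tau <- series$traction
  n <- dim(tau)[1]; nt <- dim(tau)[3]
  stopifnot(n == nrow(mesh$vertices))
  g_mean <- NULL
  if (direction == "mean") {
    idx <- compute_shear_indices(series)
    g_mean <- idx$g
  }
  proj <- matrix(0, n, nt)
  n_zero <- 0L
  for (k in seq_len(nt)) {
    tk <- tau[, , k, drop = FALSE]
    dim(tk) <- c(n, 3L)
    mag <- sqrt(rowSums(tk^2))
    grad <- surface_scalar_gradient(mesh, mag)
    if (direction == "instantaneous") {
      dirk <- tk / ifelse(mag > 0, mag, 1)
      p <- rowSums(grad * dirk)
      p[mag == 0] <- 0
      n_zero <- n_zero + sum(mag == 0)
    } else {
      p <- rowSums(grad * g_mean)
    }
    proj[, k] <- p
  }
  out <- periodic_time_average(proj, series$times, series$period)
  res <- scalar_field(out, "WSSG", "Pa/mm")
  attr(res, "n_zero_mag") <- n_zero
  res
}
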