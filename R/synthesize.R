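# Synthetic stand-ins for the clinical inputs: bipolar-voltage and
# image-intensity-ratio wall fields with prescribed rank correlation to
# TAWSS, an electroanatomical point cloud with a known rigid pose, and
# per-vertex wall-traction time series with prescribed TAWSS/OSI.

#' Synthesize correlated bipolar-voltage and image-intensity-ratio fields
#'
#' Gaussian-copula construction: the TAWSS field is converted to normal
#' scores through its ranks; each output field blends those scores with a
#' spatially smooth Gaussian random field (random Fourier features with
#' correlation length `noise_length_mm`, emulating the patchy spatial
#' structure of fibrosis and scar rather than vertex-wise white noise) at
#' the prescribed correlation. The noise component is orthogonalized
#' against the scores in-sample, so before range mapping the realized
#' Pearson correlation with the scores equals `rho` exactly. Values are
#' mapped linearly into the requested range (and clipped at the range
#' ends). At `rho = +/-1` the field is an exact linear (sign-matching)
#' transform of TAWSS. This emulates the clinical observation that bipolar
#' voltage falls and image intensity ratio rises with wall shear.
#'
#' @param mesh a [surface_mesh()].
#' @param tawss [scalar_field()] of TAWSS values (Pa) on the mesh.
#' @param rho_bv target Pearson correlation of BV with TAWSS (typically < 0).
#' @param rho_iir target Pearson correlation of IIR with TAWSS (> 0).
#' @param bv_range ordered pair, mV; values are mapped into this range.
#' @param iir_range ordered pair, dimensionless.
#' @param noise_length_mm correlation length of the noise field, mm
#'   (default 8, a typical fibrotic patch scale).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list with `scalar_field`s `bv` (mV) and `iir` (dimensionless).
#' @export
synthesize_wall_fields <- function(mesh, tawss, rho_bv = -0.4,
                                   rho_iir = 0.3,
                                   bv_range = c(0, 2.6),
                                   iir_range = c(0.5, 1.7),
                                   noise_length_mm = 8,
                                   seed = 1L) {
  if (abs(rho_bv) > 1 || abs(rho_iir) > 1)
    stop("correlations must lie in [-1, 1]")
  stopifnot(bv_range[1] < bv_range[2], iir_range[1] < iir_range[2])
  n <- nrow(mesh$vertices)
  stopifnot(length(tawss) == n)
  rng <- seeded_rng(seed, "wall-fields")
  z_t <- stats::qnorm((rank(as.numeric(tawss), ties.method = "first") - 0.5) / n)
  z_t <- (z_t - mean(z_t)) / stats::sd(z_t)
  one <- function(rho, range) {
    if (abs(rho) == 1) {
      # exact comonotone/antimonotone limit: map the TAWSS range onto the
      # target range linearly so no value is clipped and |r| = 1 exactly
      tvals <- as.numeric(tawss)
      u <- (tvals - min(tvals)) / max(max(tvals) - min(tvals), 1e-300)
      if (rho < 0) u <- 1 - u
      return(range[1] + diff(range) * u)
    } else {
      eps <- smooth_random_field(mesh$vertices, noise_length_mm, rng)
      # project out both the scores and the raw TAWSS values (smooth noise
      # has few independent patches, so its chance correlation with a
      # smooth TAWSS field is non-negligible); after this, cor(x, z_t) ==
      # rho and cor(x, tawss) == rho * cor(tawss, z_t) exactly in-sample
      tv <- scale(as.numeric(tawss))[, 1]
      eps <- eps - mean(eps)
      eps <- eps - sum(eps * z_t) / sum(z_t^2) * z_t
      tvr <- tv - sum(tv * z_t) / sum(z_t^2) * z_t  # tawss residual off z_t
      if (sum(tvr^2) > 1e-12)
        eps <- eps - sum(eps * tvr) / sum(tvr^2) * tvr
      eps <- eps / stats::sd(eps)
      x <- rho * z_t + sqrt(1 - rho^2) * eps
    }
    mid <- mean(range); half <- diff(range) / 2
    pmin(range[2], pmax(range[1], mid + half / 2.5 * x))
  }
  list(bv = scalar_field(one(rho_bv, bv_range), "BV", "mV"),
       iir = scalar_field(one(rho_iir, iir_range), "IIR", ""))
}

# stationary Gaussian random field with squared-exponential covariance of
# length scale `ell`, by random Fourier features (K cosines)
smooth_random_field <- function(points, ell, rng, K = 256L) {
  omega <- matrix(rng$norm(3L * K, sd = 1 / ell), K, 3L)
  phase <- rng$unif(K, 0, 2 * pi)
  z <- sqrt(2 / K) * rowSums(cos(points %*% t(omega) +
                                   matrix(phase, nrow(points), K,
                                          byrow = TRUE)))
  z
}

#' Synthesize an electroanatomical point cloud with a known rigid pose
#'
#' Samples points on the mesh surface (area-weighted triangles, uniform
#' barycentric coordinates), attaches the local BV value (barycentric
#' interpolation), perturbs the points with isotropic Gaussian jitter, and
#' moves the cloud by a stored ground-truth rigid transform. The transform
#' is retained so registration tests can verify recovery.
#'
#' @param mesh a [surface_mesh()].
#' @param bv [scalar_field()] of bipolar voltage on the mesh vertices.
#' @param n_points number of points (>= 10).
#' @param transform a [rigid_transform()] applied to the jittered points
#'   (default identity).
#' @param jitter_sd isotropic jitter standard deviation, mm.
#' @param seed integer seed.
#' @return list with `points` (n x 3 matrix, mm), `bv` (numeric), and
#'   `true_transform`.
#' @export
synthesize_emap_cloud <- function(mesh, bv, n_points = 2000L,
                                  transform = rigid_transform(),
                                  jitter_sd = 0.5, seed = 1L) {
  stopifnot(n_points >= 10)
  rng <- seeded_rng(seed, "emap-cloud")
  areas <- triangle_areas(mesh)
  # area-weighted triangle choice via inverse CDF on uniform draws
  cdf <- cumsum(areas) / sum(areas)
  u <- rng$unif(n_points)
  tri <- findInterval(u, cdf) + 1L
  tri[tri > length(areas)] <- length(areas)
  r1 <- sqrt(rng$unif(n_points)); r2 <- rng$unif(n_points)
  b1 <- 1 - r1; b2 <- r1 * (1 - r2); b3 <- r1 * r2
  tr <- mesh$triangles[tri, , drop = FALSE]
  v <- mesh$vertices
  pts <- b1 * v[tr[, 1], , drop = FALSE] +
         b2 * v[tr[, 2], , drop = FALSE] +
         b3 * v[tr[, 3], , drop = FALSE]
  bvv <- as.numeric(bv)
  bv_pts <- b1 * bvv[tr[, 1]] + b2 * bvv[tr[, 2]] + b3 * bvv[tr[, 3]]
  if (jitter_sd > 0)
    pts <- pts + matrix(rng$norm(3L * n_points, sd = jitter_sd), n_points, 3L)
  pts <- apply_rigid(transform, pts)
  list(points = pts, bv = bv_pts, true_transform = transform,
       triangle = tri)
}

#' Construct a traction series on an object
#'
#' @param times sample times, s, spanning one period `[0, T)`.
#' @param traction array n_vertices x 3 x n_times of wall shear stress
#'   vectors, Pa.
#' @param period period T, s.
#' @return object of class `traction_series`.
#' @export
traction_series <- function(times, traction, period) {
  stopifnot(length(dim(traction)) == 3, dim(traction)[2] == 3,
            dim(traction)[3] == length(times), length(times) >= 8,
            all(diff(times) > 0), times[1] >= 0,
            times[length(times)] < period, all(is.finite(traction)))
  structure(list(times = as.numeric(times), traction = traction,
                 period = as.numeric(period)),
            class = "traction_series")
}

#' @exportS3Method base::print
print.traction_series <- function(x, ...) {
  cat(sprintf("traction_series: %d vertices, %d samples over T = %.3f s\n",
              dim(x$traction)[1], dim(x$traction)[3], x$period))
  invisible(x)
}

#' Synthesize a wall-traction time series with prescribed TAWSS and OSI
#'
#' Per vertex, the traction is a tangential vector of fixed magnitude equal
#' to the prescribed mean (so TAWSS is reproduced exactly by the cycle
#' average of the magnitude) whose direction reverses for a fraction of the
#' cycle chosen so the oscillatory shear index equals `oscillation / 2`
#' (up to the time discretization). The vectors are exactly tangent to the
#' wall.
#'
#' @param mesh a [surface_mesh()].
#' @param mean_magnitude [scalar_field()] of target TAWSS, Pa.
#' @param oscillation per-vertex (or scalar) value in `[0, 1]`; the
#'   resulting OSI is `oscillation / 2`.
#' @param n_samples time samples per period (>= 8).
#' @param period cycle period, s.
#' @param seed integer seed for the per-vertex tangent orientation.
#' @return a [traction_series()].
#' @export
synthesize_traction_series <- function(mesh, mean_magnitude,
                                       oscillation = 0,
                                       n_samples = 32L, period = 1.0,
                                       seed = 1L) {
  n <- nrow(mesh$vertices)
  mag <- as.numeric(mean_magnitude)
  stopifnot(length(mag) == n, all(mag >= 0))
  osc <- rep_len(as.numeric(oscillation), n)
  if (any(osc < 0 | osc > 1)) stop("oscillation must lie in [0, 1]")
  stopifnot(n_samples >= 8)
  rng <- seeded_rng(seed, "traction")
  nrm <- vertex_normals(mesh)
  # a seeded tangent direction per vertex
  ref <- matrix(rng$norm(3L * n), n, 3L)
  tang <- ref - rowSums(ref * nrm) * nrm
  tl <- sqrt(rowSums(tang^2))
  fix <- tl < 1e-8
  if (any(fix)) {
    alt <- cbind(-nrm[fix, 2], nrm[fix, 1], 0)
    tang[fix, ] <- alt
    tl[fix] <- sqrt(rowSums(alt^2))
  }
  tang <- tang / tl
  times <- seq(0, period, length.out = n_samples + 1L)[1:n_samples]
  # reversed fraction q = oscillation / 2 gives OSI = oscillation / 2
  q <- osc / 2
  n_rev <- round(q * n_samples)
  tau <- array(0, dim = c(n, 3L, n_samples))
  for (k in seq_len(n_samples)) {
    sgn <- ifelse(k <= n_samples - n_rev, 1, -1)
    tau[, , k] <- (sgn * mag) * tang
  }
  traction_series(times, tau, period)
}
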