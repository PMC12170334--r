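# Rigid alignment of clinical point sets to the hemodynamic mesh and
# scattered-data transfer of the measured fields: point-to-point ICP with an
# SVD (Kabsch) rigid fit, and radial basis function interpolation with an
# affine polynomial term.

#' Rigid transform
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(transform, points) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Compose two rigid transforms (`a` then `b`)
#' @param a,b [rigid_transform()] objects.
#' @return the composition as a [rigid_transform()].
#' @export
compose_rigid <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_rigid <- function(transform) {
  rigid_transform(t(transform$rotation),
                  as.numeric(-t(transform$rotation) %*% transform$translation))
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# brute-force nearest neighbour (compiled): for each row of `query`, the
# index of the nearest row of `ref`
nearest_neighbour <- function(query, ref) {
  .nn_bruteforce(query, ref)
}

# Kabsch: least-squares rigid fit mapping x onto y (paired rows)
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  H <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cy - as.numeric(R %*% cx))
}

#' Iterative closest point rigid alignment
#'
#' Alternates nearest-neighbour correspondence and SVD-based rigid fitting
#' until the relative change in RMS distance falls below `rel_tol` or
#' `max_iter` is reached. The RMS distance is non-increasing across
#' iterations.
#'
#' @param source n x 3 point matrix to be moved.
#' @param target m x 3 point matrix (or a [surface_mesh()], whose vertices
#'   are used).
#' @param max_iter maximum iterations (default 100).
#' @param rel_tol relative RMS-change stopping tolerance (default 1e-6).
#' @return list with `transform` (mapping source onto target), `rms` (final
#'   RMS nearest-point distance, mm), `iterations`, `converged`, and the
#'   per-iteration `rms_trace`.
#' @export
icp_align <- function(source, target, max_iter = 100L, rel_tol = 1e-6) {
  if (inherits(target, "surface_mesh")) target <- target$vertices
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) >= 3, nrow(target) >= 3)
  if (point_rank(source) < 2L || point_rank(target) < 2L)
    stop("rank-deficient point set: at least 3 non-collinear points required")
  cur <- rigid_transform()
  moved <- source
  rms_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nn <- nearest_neighbour(moved, target)
    corr <- target[nn, , drop = FALSE]
    step <- kabsch(moved, corr)
    cur <- compose_rigid(step, cur)
    moved <- apply_rigid(cur, source)
    nn2 <- nearest_neighbour(moved, target)
    rms <- sqrt(mean(rowSums((moved - target[nn2, , drop = FALSE])^2)))
    trace <- c(trace, rms)
    if (is.finite(rms_prev) &&
        abs(rms_prev - rms) <= rel_tol * max(rms_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  list(transform = cur, rms = trace[length(trace)], iterations = it,
       converged = converged || it < max_iter, rms_trace = trace)
}

point_rank <- function(x, tol = 1e-9) {
  s <- svd(sweep(x, 2, colMeans(x)))$d
  sum(s > tol * max(s, 1))
}

rbf_kernel <- function(r, kernel) {
  switch(kernel,
         "thin-plate" = ifelse(r > 0, r^2 * log(r), 0),
         "linear" = r,
         "gaussian" = exp(-(r^2)),
         stop("unknown kernel: ", kernel))
}

#' Radial basis function interpolation in 3D
#'
#' Solves the RBF system with an affine (degree-1 polynomial) term, so
#' linear fields are reproduced exactly by every kernel. With `smoothing =
#' 0` the interpolant passes through the site values. If the number of
#' sites exceeds `max_sites`, a seeded uniform subsample is used (reported
#' via the `"n_sites_used"` attribute).
#'
#' @param sites n x 3 matrix of data locations, mm.
#' @param values numeric vector at the sites.
#' @param queries m x 3 matrix of evaluation points.
#' @param kernel `"thin-plate"` (default), `"linear"` or `"gaussian"`.
#' @param smoothing ridge parameter lambda >= 0 on the kernel block.
#' @param max_sites site budget before seeded subsampling (default 4000).
#' @param scale length scale, mm, used to normalize radii (default: median
#'   inter-site distance of a 200-site probe; fixes the gaussian width and
#'   conditions the polyharmonic system).
#' @param seed seed for subsampling.
#' @return numeric vector of interpolated values at `queries`.
#' @export
rbf_interpolate <- function(sites, values, queries,
                            kernel = c("thin-plate", "linear", "gaussian"),
                            smoothing = 0, max_sites = 4000L, scale = NULL,
                            seed = 1L) {
  kernel <- match.arg(kernel)
  sites <- as.matrix(sites); queries <- as.matrix(queries)
  stopifnot(length(values) == nrow(sites), smoothing >= 0)
  if (nrow(sites) < 4 || point_rank(sites) < 3L)
    stop("at least 4 non-coplanar sites required")
  if (nrow(sites) > max_sites) {
    n_orig <- nrow(sites)
    rng <- seeded_rng(seed, "rbf-subsample")
    keep <- sort(rng$sample_int(n_orig, max_sites))
    sites <- sites[keep, , drop = FALSE]
    values <- values[keep]
    message("rbf_interpolate: subsampled ", max_sites, " of ", n_orig,
            " sites")
  }
  n <- nrow(sites)
  D <- as.matrix(stats::dist(sites))
  if (smoothing == 0 && any(D[upper.tri(D)] < 1e-12))
    stop("duplicate sites with smoothing = 0 make the system singular; ",
         "set smoothing > 0")
  if (is.null(scale)) {
    probe <- D[seq_len(min(200L, n)), seq_len(min(200L, n))]
    scale <- stats::median(probe[upper.tri(probe)])
    if (!is.finite(scale) || scale <= 0) scale <- 1
  }
  K <- rbf_kernel(D / scale, kernel)
  P <- cbind(1, sites)
  A <- rbind(cbind(K + smoothing * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(values, numeric(4))
  coef <- solve(A, rhs)
  w <- coef[1:n]; beta <- coef[(n + 1):(n + 4)]
  out <- numeric(nrow(queries))
  chunk <- 2000L
  for (s in seq(1L, nrow(queries), by = chunk)) {
    e <- min(nrow(queries), s + chunk - 1L)
    q <- queries[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(sites^2), `+`) - 2 * tcrossprod(q, sites)
    d2[d2 < 0] <- 0
    Kq <- rbf_kernel(sqrt(d2) / scale, kernel)
    out[s:e] <- as.numeric(Kq %*% w) + beta[1] +
      as.numeric(q %*% beta[2:4])
  }
  attr(out, "n_sites_used") <- n
  out
}

#' Map measured fields onto the hemodynamic mesh
#'
#' Reproduces the clinical transfer step: each measured source (an
#' electroanatomical cloud carrying bipolar voltage, and/or a second surface
#' carrying the image intensity ratio) is rigidly aligned to the
#' hemodynamic ("CFD") mesh with ICP, then its values are interpolated onto
#' the mesh vertices by 3D RBF interpolation. The hemodynamic mesh is the
#' basis of the transform: sources are moved onto it.
#'
#' @param cfd_mesh the target [surface_mesh()].
#' @param emap_cloud list with `points` (n x 3 mm) and `bv` (mV), as from
#'   [synthesize_emap_cloud()]; NULL to skip.
#' @param cmr_mesh a [surface_mesh()] with `iir` values attached as a list
#'   `list(mesh =, iir =)`; NULL to skip.
#' @param kernel,smoothing,max_sites,seed passed to [rbf_interpolate()].
#' @return list with `scalar_field`s `bv` and/or `iir` on `cfd_mesh`
#'   vertices; each carries a `"provenance"` attribute (ICP transform and
#'   RMS, kernel, smoothing, site count).
#' @export
map_fields_to_mesh <- function(cfd_mesh, emap_cloud = NULL, cmr_mesh = NULL,
                               kernel = "thin-plate", smoothing = 1e-8,
                               max_sites = 4000L, seed = 1L) {
  out <- list()
  transfer <- function(points, values, name, units) {
    if (nrow(points) < 50)
      warning("sparse source (", nrow(points), " points) for ", name)
    icp <- icp_align(points, cfd_mesh$vertices)
    aligned <- apply_rigid(icp$transform, points)
    vals <- rbf_interpolate(aligned, values, cfd_mesh$vertices,
                            kernel = kernel, smoothing = smoothing,
                            max_sites = max_sites, seed = seed)
    f <- scalar_field(as.numeric(vals), name, units)
    attr(f, "provenance") <- list(transform = icp$transform, rms = icp$rms,
                                  kernel = kernel, smoothing = smoothing,
                                  n_sites = attr(vals, "n_sites_used"))
    f
  }
  if (!is.null(emap_cloud))
    out$bv <- transfer(emap_cloud$points, emap_cloud$bv, "BV", "mV")
  if (!is.null(cmr_mesh))
    out$iir <- transfer(cmr_mesh$mesh$vertices, as.numeric(cmr_mesh$iir),
                        "IIR", "")
  out
}
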