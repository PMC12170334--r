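# Quasi-static potential-flow surrogate and blood-age transport. At each
# instant the face velocities solve a discrete Laplace problem with flux
# boundary conditions (divergence-free by construction); the waveform only
# rescales the unit solution, so one sparse solve serves the whole cycle.
# Blood age obeys da/dt + u . grad a = D lap a + 1 with age 0 at the inlets,
# zero-gradient outflow at the mitral outlet and no-flux walls.

#' Interior faces of a voxel domain
#' @param domain a [voxel_domain()].
#' @return data frame with interior cell ids `c1`, `c2` (`c2` is the +axis
#'   neighbour of `c1`) and `axis`.
#' @export
interior_faces <- function(domain) {
  d <- dim(domain$mask)
  idx <- domain$index
  w <- which(domain$mask, arr.ind = TRUE)
  out <- list()
  for (axis in 1:3) {
    nb <- w
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= d[axis]
    ok[ok] <- domain$mask[nb[ok, , drop = FALSE]]
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        c1 = idx[w[ok, , drop = FALSE]],
        c2 = idx[nb[ok, , drop = FALSE]],
        axis = axis)
  }
  do.call(rbind, out)
}

#' Prescribe waveform-driven potential flow on a voxel domain
#'
#' Solves one discrete Laplace problem with flux boundary conditions: the
#' outlet (mitral) faces carry the unit outlet velocity, each pulmonary-vein
#' inlet carries the prescribed fraction of the total volumetric flux, and
#' walls are impermeable. The time-dependent field is the unit solution
#' scaled by the mitral waveform, so total inlet and outlet fluxes balance
#' identically at every instant and every interior cell is divergence-free
#' to solver precision.
#'
#' @param domain a [voxel_domain()] with labeled inlet/outlet faces.
#' @param waveform a [velocity_waveform()] (m/s at the outlet).
#' @param split flux fraction per inlet label (named, or in the order the
#'   inlet labels appear); must sum to 1.
#' @return the domain with a `flow` element (unit face velocities in mm/s
#'   per mm/s of outlet speed, plus the waveform).
#' @export
prescribe_flow <- function(domain, waveform,
                           split = c(LSPV = 0.25, LIPV = 0.25,
                                     RSPV = 0.25, RIPV = 0.25)) {
  bf <- domain$boundary_faces
  h <- domain$spacing
  inlet_labels <- setdiff(unique(bf$label), c("wall", "mitral"))
  n_out <- sum(bf$label == "mitral")
  if (n_out == 0L) stop("configuration error: domain has no mitral outlet")
  if (length(inlet_labels) == 0L)
    stop("configuration error: domain has no inlet faces")
  if (is.null(names(split))) {
    stopifnot(length(split) == length(inlet_labels))
    names(split) <- inlet_labels
  }
  split <- split[inlet_labels]
  if (abs(sum(split) - 1) > 1e-9) stop("inlet split must sum to 1")

  area <- h^2
  q_total <- n_out * area            # unit outlet speed 1 mm/s
  b_out <- numeric(nrow(bf))         # outward velocity per boundary face
  b_out[bf$label == "mitral"] <- 1
  for (p in inlet_labels) {
    sel <- bf$label == p
    if (!any(sel)) stop("configuration error: no faces for inlet ", p)
    b_out[sel] <- -split[[p]] * q_total / (sum(sel) * area)
  }

  ifc <- interior_faces(domain)
  n <- domain$n_cells
  ii <- c(ifc$c1, ifc$c1, ifc$c2, ifc$c2)
  jj <- c(ifc$c1, ifc$c2, ifc$c2, ifc$c1)
  xx <- rep(c(h, -h, h, -h), each = nrow(ifc))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  rhs <- numeric(n)
  flx <- -b_out * area               # inward flux adds as source
  for (r in seq_len(nrow(bf))) rhs[bf$cell[r]] <- rhs[bf$cell[r]] + flx[r]
  # pin the potential in one cell (compatible singular system)
  A[1, ] <- 0; A[1, 1] <- 1; rhs[1] <- 0
  phi <- as.numeric(Matrix::solve(A, rhs))
  u_unit <- (phi[ifc$c1] - phi[ifc$c2]) / h

  # divergence check on the unit field
  div <- numeric(n)
  ffl <- u_unit * area
  for (r in seq_len(nrow(ifc))) {
    div[ifc$c1[r]] <- div[ifc$c1[r]] + ffl[r]
    div[ifc$c2[r]] <- div[ifc$c2[r]] - ffl[r]
  }
  div <- div + tapply(b_out * area, factor(bf$cell, levels = seq_len(n)),
                      sum, default = 0)
  div[1] <- 0  # pinned row replaced its balance equation
  mean_speed <- mean(abs(c(u_unit, b_out)))
  if (mean_speed > 0 && max(abs(div)) / (mean_speed * area) > 1e-8)
    warning("interior divergence above tolerance: ",
            format(max(abs(div)) / (mean_speed * area)))

  domain$flow <- list(iface = ifc, u_unit = u_unit, b_out_unit = b_out,
                      waveform = waveform, unit_scale = 1000)
  domain
}

# advection operator (per unit flow factor) and diffusion Laplacian
transport_operators <- function(domain) {
  n <- domain$n_cells
  h <- domain$spacing
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  di <- integer(0); dj <- integer(0); dx <- numeric(0)
  if (!is.null(domain$flow)) {
    ifc <- domain$flow$iface
    u <- domain$flow$u_unit
    pos <- u >= 0
    # upwind: donor cell loses u/h, receiver gains
    ti <- c(ifc$c1[pos], ifc$c2[pos], ifc$c2[!pos], ifc$c1[!pos])
    tj <- c(ifc$c1[pos], ifc$c1[pos], ifc$c2[!pos], ifc$c2[!pos])
    tx <- c(u[pos], -u[pos], -u[!pos], u[!pos]) / h
    bf <- domain$boundary_faces
    bo <- domain$flow$b_out_unit
    outfl <- bo > 0       # outflow faces: upwind donor is the interior cell
    if (any(outfl)) {
      ti <- c(ti, bf$cell[outfl]); tj <- c(tj, bf$cell[outfl])
      tx <- c(tx, bo[outfl] / h)
    }
    # inflow faces carry ghost age 0: no matrix term
  }
  ifc_all <- interior_faces(domain)
  di <- c(ifc_all$c1, ifc_all$c1, ifc_all$c2, ifc_all$c2)
  dj <- c(ifc_all$c1, ifc_all$c2, ifc_all$c2, ifc_all$c1)
  dx <- rep(c(-1, 1, -1, 1), each = nrow(ifc_all)) / h^2
  # Dirichlet (age 0) ghost at inlet faces
  if (!is.null(domain$flow)) {
    bf <- domain$boundary_faces
    inl <- domain$flow$b_out_unit < 0
    if (any(inl)) {
      di <- c(di, bf$cell[inl]); dj <- c(dj, bf$cell[inl])
      dx <- c(dx, rep(-2 / h^2, sum(inl)))
    }
  }
  list(
    adv = Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n)),
    lap = Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(n, n))
  )
}

#' Solve the blood-age transport equation
#'
#' Transient solve of `da/dt + u . grad a = D lap a + 1` (unit volumetric
#' source: age accrues at one second per second) with zero initial
#' condition, age 0 at the inlets, zero-gradient outflow at the outlet and
#' no-flux walls. Advection is first-order upwind, diffusion central;
#' backward Euler (default) is unconditionally stable; the explicit scheme
#' sub-steps automatically (with a warning) when the CFL bound is violated.
#'
#' @param domain a [voxel_domain()], normally after [prescribe_flow()]; a
#'   domain without flow is treated as closed and quiescent.
#' @param n_cycles number of cardiac cycles to integrate (default 6).
#' @param dt time step, s (default 0.25 ms, rounded so a cycle is a whole
#'   number of steps).
#' @param diffusivity blood-age diffusivity D, mm^2/s (default 1; not a
#'   measured quantity - a numerical regularization, set as a parameter).
#' @param period cycle period, s; only used when the domain has no flow.
#' @param scheme `"implicit"` or `"explicit"`.
#' @return object of class `age_field`: `values` (s, per interior cell),
#'   `elapsed` (s), `n_cycles`, and the domain.
#' @export
solve_blood_age <- function(domain, n_cycles = 6L, dt = 0.00025,
                            diffusivity = 1.0, period = 1.0,
                            scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  stopifnot(n_cycles >= 1, dt > 0, diffusivity >= 0)
  has_flow <- !is.null(domain$flow)
  T_ <- if (has_flow) domain$flow$waveform$period else period
  n_steps <- max(1L, round(T_ / dt))
  dt_eff <- T_ / n_steps
  n <- domain$n_cells
  ops <- transport_operators(domain)
  a <- numeric(n)
  Id <- Matrix::Diagonal(n)
  factors <- if (has_flow)
    domain$flow$waveform$fun(seq_len(n_steps) * dt_eff) *
      domain$flow$unit_scale
  else rep(0, n_steps)
  if (any(factors < 0))
    stop("negative waveform values: flow reversal is not supported")
  # quantize the flow factor to a 1e-4 relative grid so repeated levels
  # (e.g. the long diastasis of an A-wave-removed waveform) share one
  # factorization
  fmax <- max(factors)
  if (fmax > 0) factors <- round(factors / (fmax * 1e-4)) * (fmax * 1e-4)
  lu_cache <- new.env(parent = emptyenv())
  if (scheme == "explicit") {
    umax <- if (has_flow)
      max(abs(c(domain$flow$u_unit, domain$flow$b_out_unit))) * max(factors)
    else 0
    dt_cfl <- min(if (umax > 0) domain$spacing / umax else Inf,
                  if (diffusivity > 0) domain$spacing^2 / (6 * diffusivity)
                  else Inf)
    sub <- max(1L, ceiling(dt_eff / (0.9 * dt_cfl)))
    if (sub > 1L)
      warning("explicit CFL violated; sub-stepping each step ", sub, " times")
  }
  for (cyc in seq_len(n_cycles)) {
    for (k in seq_len(n_steps)) {
      if (scheme == "implicit") {
        key <- sprintf("f%.8g", factors[k])
        if (is.null(lu_cache[[key]])) {
          L <- factors[k] * ops$adv - diffusivity * ops$lap
          lu_cache[[key]] <- Matrix::lu(Id / dt_eff + L)
        }
        a <- as.numeric(Matrix::solve(lu_cache[[key]], a / dt_eff + 1))
      } else {
        L <- factors[k] * ops$adv - diffusivity * ops$lap
        dts <- dt_eff / sub
        for (s in seq_len(sub))
          a <- a + dts * (1 - as.numeric(L %*% a))
      }
    }
  }
  structure(list(values = a, elapsed = n_cycles * T_,
                 n_cycles = n_cycles, domain = domain),
            class = "age_field")
}

#' @exportS3Method base::print
print.age_field <- function(x, ...) {
  cat(sprintf(
    "age_field: %d cells, %d cycle(s), elapsed %.3f s, range [%.3f, %.3f] s\n",
    length(x$values), x$n_cycles, x$elapsed, min(x$values), max(x$values)))
  invisible(x)
}

# trilinear interpolation of an interior-cell field at points (n x 3, mm);
# points whose 8-cell stencil leaves the interior fall back to the nearest
# interior cell value. Returns list(values, n_fallback).
grid_interpolate <- function(domain, values, pts) {
  d <- dim(domain$mask)
  full <- array(NA_real_, d)
  full[domain$mask] <- values
  g <- sweep(pts, 2, domain$origin) / domain$spacing - 0.5
  i0 <- floor(g)
  fr <- g - i0
  i0 <- i0 + 1L  # cell index of the lower corner
  out <- numeric(nrow(pts))
  fell <- logical(nrow(pts))
  cc <- NULL
  for (p in seq_len(nrow(pts))) {
    ok <- TRUE
    acc <- 0
    for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
      ci <- i0[p, 1] + bx; cj <- i0[p, 2] + by; ck <- i0[p, 3] + bz
      if (ci < 1 || cj < 1 || ck < 1 || ci > d[1] || cj > d[2] || ck > d[3] ||
          is.na(full[ci, cj, ck])) { ok <- FALSE; break }
      w <- (if (bx) fr[p, 1] else 1 - fr[p, 1]) *
           (if (by) fr[p, 2] else 1 - fr[p, 2]) *
           (if (bz) fr[p, 3] else 1 - fr[p, 3])
      acc <- acc + w * full[ci, cj, ck]
    }
    if (ok) out[p] <- acc else fell[p] <- TRUE
  }
  if (any(fell)) {
    if (is.null(cc)) cc <- cell_centres(domain)
    for (p in which(fell)) {
      d2 <- (cc[, 1] - pts[p, 1])^2 + (cc[, 2] - pts[p, 2])^2 +
            (cc[, 3] - pts[p, 3])^2
      out[p] <- values[which.min(d2)]
    }
  }
  list(values = out, n_fallback = sum(fell))
}

#' Sample the blood-age field near the wall
#'
#' Trilinear interpolation of blood age at `vertex - offset * outward
#' normal` for every mesh vertex; sampling away from the wall avoids the
#' wall boundary layer of the transport solution. Points whose interpolation
#' stencil leaves the interior fall back to the nearest interior voxel (the
#' count is recorded in the `"n_fallback"` attribute).
#'
#' @param age an `age_field` from [solve_blood_age()].
#' @param mesh the wall [surface_mesh()].
#' @param offset inward sampling distance, mm (default 1).
#' @return [scalar_field()] of blood age, s, per vertex.
#' @export
sample_near_wall <- function(age, mesh, offset = 1.0) {
  nrm <- vertex_normals(mesh)
  pts <- mesh$vertices - offset * nrm
  gi <- grid_interpolate(age$domain, age$values, pts)
  out <- scalar_field(gi$values, "BA", "s")
  attr(out, "n_fallback") <- gi$n_fallback
  out
}

# cell-centered unit velocity vectors (mm/s per unit outlet speed)
cell_velocity_unit <- function(domain) {
  n <- domain$n_cells
  acc <- matrix(0, n, 3L)
  cnt <- matrix(0, n, 3L)
  if (!is.null(domain$flow)) {
    ifc <- domain$flow$iface
    u <- domain$flow$u_unit
    for (axis in 1:3) {
      sel <- ifc$axis == axis
      s1 <- tapply(u[sel], factor(ifc$c1[sel], levels = seq_len(n)), sum,
                   default = 0)
      s2 <- tapply(u[sel], factor(ifc$c2[sel], levels = seq_len(n)), sum,
                   default = 0)
      k1 <- tapply(rep(1, sum(sel)), factor(ifc$c1[sel], levels = seq_len(n)),
                   sum, default = 0)
      k2 <- tapply(rep(1, sum(sel)), factor(ifc$c2[sel], levels = seq_len(n)),
                   sum, default = 0)
      acc[, axis] <- acc[, axis] + s1 + s2
      cnt[, axis] <- cnt[, axis] + k1 + k2
    }
    bf <- domain$boundary_faces
    bo <- domain$flow$b_out_unit
    for (r in seq_len(nrow(bf))) {
      ua <- bf$side[r] * bo[r]  # velocity component along +axis
      acc[bf$cell[r], bf$axis[r]] <- acc[bf$cell[r], bf$axis[r]] + ua
      cnt[bf$cell[r], bf$axis[r]] <- cnt[bf$cell[r], bf$axis[r]] + 1
    }
  }
  acc / pmax(cnt, 1)
}

#' Estimate wall traction from the near-wall velocity field
#'
#' A finite-difference surrogate: the tangential velocity sampled at
#' `offset` from the wall, divided by the offset and scaled by the dynamic
#' viscosity, gives an approximate wall shear vector per vertex and time
#' sample. This is a near-wall velocity-gradient estimate on the voxel
#' field, not a Navier-Stokes traction.
#'
#' @param domain a [voxel_domain()] after [prescribe_flow()].
#' @param mesh the wall [surface_mesh()].
#' @param viscosity dynamic viscosity, Pa s (default 0.0035, blood).
#' @param offset near-wall sampling distance, mm; must be at least the
#'   voxel spacing.
#' @return a [traction_series()] (Pa) on the waveform's time samples.
#' @export
estimate_wall_traction <- function(domain, mesh, viscosity = 0.0035,
                                   offset = NULL) {
  if (is.null(domain$flow)) stop("prescribe_flow() must be called first")
  if (is.null(offset)) offset <- domain$spacing
  if (offset < domain$spacing)
    stop("offset (", offset, " mm) below voxel spacing (", domain$spacing,
         " mm)")
  wf <- domain$flow$waveform
  nrm <- vertex_normals(mesh)
  pts <- mesh$vertices - offset * nrm
  uc <- cell_velocity_unit(domain)
  u_at <- vapply(1:3, function(ax)
    grid_interpolate(domain, uc[, ax], pts)$values, numeric(nrow(pts)))
  # tangential projection of the unit field
  u_t <- u_at - rowSums(u_at * nrm) * nrm
  n <- nrow(pts); nt <- length(wf$times)
  tau <- array(0, c(n, 3L, nt))
  for (k in seq_len(nt)) {
    f <- wf$velocity[k] * domain$flow$unit_scale
    tau[, , k] <- viscosity * f * u_t / offset
  }
  traction_series(wf$times, tau, wf$period)
}
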