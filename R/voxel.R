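# Voxelized interior of a capped atrial surface, the substrate for the
# potential-flow surrogate and the blood-age transport solve. Geometry in
# mm; velocities held in mm/s internally.

#' Construct a voxel domain directly
#'
#' Low-level constructor, chiefly for analytic test domains. `voxelize()`
#' builds one from a surface mesh.
#'
#' @param mask logical 3D array: interior cells.
#' @param spacing cell size, mm.
#' @param origin coordinates of the corner of cell (1,1,1), mm (cell centers
#'   sit at `origin + (i - 1/2) * spacing`).
#' @param boundary_faces data frame with columns `cell` (interior cell id),
#'   `i, j, k`, `axis` (1-3), `side` (+1/-1) and `label` (`"wall"`, a PV
#'   name, or `"mitral"`). When NULL every boundary face is a wall.
#' @return object of class `voxel_domain`.
#' @export
voxel_domain <- function(mask, spacing, origin = c(0, 0, 0),
                         boundary_faces = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, spacing > 0)
  idx <- array(0L, dim(mask))
  idx[mask] <- seq_len(sum(mask))
  if (is.null(boundary_faces)) boundary_faces <- find_boundary_faces(mask, idx)
  structure(list(mask = mask, spacing = spacing, origin = as.numeric(origin),
                 index = idx, n_cells = sum(mask),
                 boundary_faces = boundary_faces, flow = NULL),
            class = "voxel_domain")
}

#' @exportS3Method base::print
print.voxel_domain <- function(x, ...) {
  labs <- table(x$boundary_faces$label)
  cat(sprintf("voxel_domain: %d interior cells, spacing %.3g mm, dims %s\n",
              x$n_cells, x$spacing, paste(dim(x$mask), collapse = "x")))
  cat("boundary faces:",
      paste(sprintf("%s=%d", names(labs), labs), collapse = " "), "\n")
  invisible(x)
}

# Enumerate boundary faces (interior cell with exterior/out-of-grid
# neighbour), all labeled wall.
find_boundary_faces <- function(mask, idx) {
  d <- dim(mask)
  out <- list()
  which3 <- which(mask, arr.ind = TRUE)
  for (axis in 1:3) {
    for (side in c(-1L, 1L)) {
      nb <- which3
      nb[, axis] <- nb[, axis] + side
      inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
             nb[, 2] >= 1 & nb[, 2] <= d[2] &
             nb[, 3] >= 1 & nb[, 3] <= d[3]
      ext <- !inb
      ext[inb] <- !mask[nb[inb, , drop = FALSE]]
      if (any(ext)) {
        w <- which3[ext, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          cell = idx[w], i = w[, 1], j = w[, 2], k = w[, 3],
          axis = axis, side = side, label = "wall",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# cell centers of interior cells, n x 3
cell_centres <- function(domain) {
  w <- which(domain$mask, arr.ind = TRUE)
  sweep((w - 0.5) * domain$spacing, 2, domain$origin, `+`)
}

#' Voxelize a surface mesh interior
#'
#' Caps every open boundary loop with a triangle fan, then classifies cell
#' centers by x-ray parity against the closed surface. The largest
#' connected interior component is kept. Boundary faces lying on an orifice
#' cap inherit the orifice label (PV name or `"mitral"`); the rest are
#' walls.
#'
#' @param mesh a [surface_mesh()] whose open loops are the 4 PV inlets and
#'   the mitral outlet.
#' @param spacing voxel size, mm. An error is raised if a PV orifice is
#'   resolved by fewer than 3 cells across its equivalent diameter.
#' @return a [voxel_domain()].
#' @export
voxelize <- function(mesh, spacing) {
  stopifnot(spacing > 0)
  loops <- boundary_loops(mesh)
  v <- mesh$vertices
  tris <- mesh$triangles
  caps <- list()
  for (loop in loops) {
    lab_tab <- table(mesh$labels[loop])
    lab <- names(lab_tab)[which.max(lab_tab)]
    if (lab == "mitral_rim") lab <- "mitral"
    pts <- v[loop, , drop = FALSE]
    pl <- loop_plane(pts, colMeans(v))
    d_eq <- sqrt(4 * pl$area / pi)
    if (lab != "mitral" && d_eq < 3 * spacing)
      stop("spacing too coarse: orifice ", lab, " resolved by < 3 voxels")
    ctr_idx <- nrow(v) + length(caps) + 1L
    caps[[length(caps) + 1L]] <- list(label = lab, centre = pl$centre,
                                      normal = pl$normal,
                                      radius = sqrt(pl$area / pi),
                                      centre_idx = ctr_idx, loop = loop)
  }
  # closed triangle soup: mesh + fans
  v_all <- rbind(v, t(vapply(caps, `[[`, numeric(3), "centre")))
  tr_all <- tris
  for (cp in caps) {
    k <- length(cp$loop)
    ip1 <- c(2:k, 1L)
    tr_all <- rbind(tr_all, cbind(cp$loop[ip1], cp$loop, cp$centre_idx))
  }

  lo <- apply(v_all, 2, min) - 1.5 * spacing
  hi <- apply(v_all, 2, max) + 1.5 * spacing
  # irrational sub-cell shift avoids rays through vertices/edges
  origin <- lo - spacing * c(sqrt(2) - 1.4, sqrt(3) - 1.7, sqrt(5) - 2.2) / 97
  dims <- pmax(2L, ceiling((hi - origin) / spacing))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  yc <- origin[2] + (seq_len(ny) - 0.5) * spacing
  zc <- origin[3] + (seq_len(nz) - 0.5) * spacing

  # per (j,k) column: x-coordinates where the +x ray crosses the surface
  crossings <- vector("list", ny * nz)
  p1 <- v_all[tr_all[, 1], , drop = FALSE]
  p2 <- v_all[tr_all[, 2], , drop = FALSE]
  p3 <- v_all[tr_all[, 3], , drop = FALSE]
  for (t in seq_len(nrow(tr_all))) {
    a <- p1[t, ]; b <- p2[t, ]; c_ <- p3[t, ]
    jr <- range(c(a[2], b[2], c_[2])); kr <- range(c(a[3], b[3], c_[3]))
    js <- which(yc >= jr[1] & yc <= jr[2])
    ks <- which(zc >= kr[1] & zc <= kr[2])
    if (!length(js) || !length(ks)) next
    d1 <- c(b[2] - a[2], b[3] - a[3])
    d2 <- c(c_[2] - a[2], c_[3] - a[3])
    det <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(det) < 1e-14) next
    gj <- rep(js, times = length(ks))
    gk <- rep(ks, each = length(js))
    py <- yc[gj] - a[2]; pz <- zc[gk] - a[3]
    s <- (py * d2[2] - pz * d2[1]) / det
    u <- (pz * d1[1] - py * d1[2]) / det
    hit <- s >= 0 & u >= 0 & s + u <= 1
    if (any(hit)) {
      xh <- a[1] + s[hit] * (b[1] - a[1]) + u[hit] * (c_[1] - a[1])
      cols <- (gk[hit] - 1L) * ny + gj[hit]
      for (q in seq_along(cols))
        crossings[[cols[q]]] <- c(crossings[[cols[q]]], xh[q])
    }
  }
  mask <- array(FALSE, dims)
  xc <- origin[1] + (seq_len(nx) - 0.5) * spacing
  for (kk in seq_len(nz)) for (jj in seq_len(ny)) {
    xs <- crossings[[(kk - 1L) * ny + jj]]
    if (is.null(xs) || length(xs) < 2L) next
    xs <- sort(xs)
    for (m in seq(1L, length(xs) - 1L, by = 2L)) {
      inside <- xc > xs[m] & xc < xs[m + 1L]
      mask[inside, jj, kk] <- TRUE
    }
  }
  mask <- largest_component(mask)
  idx <- array(0L, dims)
  idx[mask] <- seq_len(sum(mask))
  bf <- find_boundary_faces(mask, idx)
  # label faces on orifice caps
  fc <- cbind(origin[1] + (bf$i - 0.5) * spacing,
              origin[2] + (bf$j - 0.5) * spacing,
              origin[3] + (bf$k - 0.5) * spacing)
  for (r in seq_len(nrow(bf))) fc[r, bf$axis[r]] <-
    fc[r, bf$axis[r]] + bf$side[r] * spacing / 2
  for (cp in caps) {
    rel <- sweep(fc, 2, cp$centre)
    dn <- abs(rel %*% cp$normal)
    dr <- sqrt(rowSums(rel^2) - (rel %*% cp$normal)^2)
    hit <- dn < 0.75 * spacing & dr <= cp$radius + 0.75 * spacing
    bf$label[hit] <- cp$label
  }
  voxel_domain(mask, spacing, origin, boundary_faces = bf)
}

# keep the largest 6-connected component of a logical array
largest_component <- function(mask) {
  d <- dim(mask)
  idx <- array(0L, d)
  idx[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0L) return(mask)
  w <- which(mask, arr.ind = TRUE)
  edges <- NULL
  for (axis in 1:3) {
    nb <- w
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= d[axis]
    ok[ok] <- mask[nb[ok, , drop = FALSE]]
    if (any(ok))
      edges <- rbind(edges, cbind(idx[w[ok, , drop = FALSE]],
                                  idx[nb[ok, , drop = FALSE]]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, sum(mask) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep_comp <- which.max(comp$csize)
  keep <- comp$membership == keep_comp
  out <- array(FALSE, d)
  out[mask] <- keep[idx[mask]]
  out
}
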