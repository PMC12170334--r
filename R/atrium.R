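# Idealized left-atrial geometry: ellipsoid body, four pulmonary-vein tubes,
# a bent capped appendage pouch and an open mitral orifice, built from a
# subdivided icosphere with feature caps cut out and tubes bridged onto the
# resulting rims.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, t, 0,   1, t, 0,  -1, -t, 0,   1, -t, 0,
                 0, -1, t,  0, 1, t,   0, -1, -t,  0, 1, -t,
                 t, 0, -1,  t, 0, 1,  -t, 0, -1,  -t, 0, 1),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
              ncol = 3, byrow = TRUE)
  # enforce outward winding (positive enclosed volume)
  vol <- signed_volume(v, f)
  if (vol < 0) f <- f[, c(1L, 3L, 2L)]
  list(vertices = v, faces = f)
}

signed_volume <- function(v, f) {
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

# One loop subdivision step on the unit sphere: split every triangle in 4,
# new vertices at normalized edge midpoints.
icosphere <- function(subdivisions) {
  ico <- icosahedron()
  v <- ico$vertices; f <- ico$faces
  for (s in seq_len(subdivisions)) {
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
    key <- paste(a, b)
    uk <- !duplicated(key)
    mid <- (v[a[uk], , drop = FALSE] + v[b[uk], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    idx <- nrow(v) + seq_len(sum(uk))
    names(idx) <- key[uk]
    v <- rbind(v, mid)
    m12 <- idx[paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2]))]
    m23 <- idx[paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3]))]
    m31 <- idx[paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  list(vertices = v, faces = unname(f))
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s * K + (1 - c_) * tcrossprod(a)
}

# Feature directions on the unit sphere (x: septal +, lateral -; y:
# posterior +, anterior -; z: superior +).
atrium_features <- function(body_semi_axes, pv_radius, pv_length,
                            appendage_scale) {
  s_bar <- mean(body_semi_axes)
  norm1 <- function(d) d / sqrt(sum(d^2))
  list(
    list(name = "LSPV", dir = norm1(c(-0.60, 0.55, 0.60)), radius = pv_radius,
         type = "tube_open", length = pv_length),
    list(name = "LIPV", dir = norm1(c(-0.74, 0.60, -0.32)), radius = pv_radius,
         type = "tube_open", length = pv_length),
    list(name = "RSPV", dir = norm1(c(0.60, 0.55, 0.60)), radius = pv_radius,
         type = "tube_open", length = pv_length),
    list(name = "RIPV", dir = norm1(c(0.74, 0.60, -0.32)), radius = pv_radius,
         type = "tube_open", length = pv_length),
    list(name = "appendage", dir = norm1(c(-0.62, -0.72, 0.32)),
         radius = appendage_scale * s_bar, type = "tube_closed",
         length = 1.6 * appendage_scale * s_bar),
    list(name = "mitral_rim", dir = c(0, 0, -1), radius = 0.45 * s_bar,
         type = "rim_only", length = 0)
  )
}

#' Build an idealized labeled left-atrial surface mesh
#'
#' Constructs a closed genus-0 atrial body from a subdivided icosphere scaled
#' to an ellipsoid, with four open pulmonary-vein tubes, a closed bent
#' appendage pouch and an open (roughly circular) mitral orifice. Anatomical
#' wall sectors (roof, posterior, anterior, lateral, septal, floor) are
#' labeled by direction on the generating sphere. A small seeded smooth
#' radial perturbation breaks exact symmetry.
#'
#' @param body_semi_axes ellipsoid semi-axes in mm (x, y, z).
#' @param pv_radius pulmonary-vein tube radius, mm.
#' @param pv_length pulmonary-vein tube length from ostium to distal rim, mm.
#' @param appendage_scale appendage neck radius as a fraction of the mean
#'   body semi-axis; must be > 0.
#' @param resolution target mesh edge length, mm; must be finer than
#'   `pv_radius`.
#' @param seed integer seed for the radial perturbation.
#'
#' @return a [surface_mesh()] with 5 boundary loops (4 distal PV rims and
#'   the mitral orifice) and Euler characteristic -3.
#' @export
build_idealized_atrium <- function(body_semi_axes = c(35, 30, 28),
                                   pv_radius = 5.5,
                                   pv_length = 40,
                                   appendage_scale = 0.32,
                                   resolution = 2.0,
                                   seed = 1L) {
  stopifnot(length(body_semi_axes) == 3, all(body_semi_axes > 0),
            pv_radius > 0, pv_length > 0, resolution > 0)
  if (appendage_scale <= 0)
    stop("appendage_scale must be > 0: an empty appendage is degenerate")
  if (resolution >= pv_radius)
    stop("degenerate geometry: resolution (", resolution,
         " mm) must be finer than pv_radius (", pv_radius, " mm)")
  s_bar <- mean(body_semi_axes)
  level <- max(2L, ceiling(log2(1.05 * s_bar / resolution)))
  ico <- icosphere(level)
  sph <- ico$vertices

  # seeded smooth radial perturbation (a few random quadratic lobes)
  rng <- seeded_rng(seed, "atrium-perturbation")
  ndirs <- 5L
  dirs <- matrix(rng$norm(3L * ndirs), ndirs, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coef <- rng$unif(ndirs, -1, 1)
  proj <- sph %*% t(dirs)
  bump <- 1 + 0.03 * as.numeric((proj^2) %*% coef)

  verts <- sph * bump * rep(body_semi_axes, each = nrow(sph))
  faces <- ico$faces

  feats <- atrium_features(body_semi_axes, pv_radius, pv_length,
                           appendage_scale)
  # cap angular radius on the unit sphere for each feature
  for (k in seq_along(feats)) {
    rho <- sqrt(sum((feats[[k]]$dir * body_semi_axes)^2))
    feats[[k]]$cap_angle <- asin(min(0.95, feats[[k]]$radius / rho))
    feats[[k]]$axis <- {
      a <- feats[[k]]$dir * body_semi_axes; a / sqrt(sum(a^2))
    }
  }

  # body sector labels from sphere directions
  labels <- rep("body", nrow(sph))
  z <- sph[, 3]; x <- sph[, 1]; y <- sph[, 2]
  labels[y > 0.62 & abs(z) <= 0.62] <- "posterior"
  labels[y < -0.62 & abs(z) <= 0.62] <- "anterior"
  labels[x < -0.62 & abs(z) <= 0.62 & abs(y) <= 0.62] <- "lateral"
  labels[x > 0.62 & abs(z) <= 0.62 & abs(y) <= 0.62] <- "septal"
  labels[z > 0.62] <- "roof"
  labels[z < -0.62] <- "floor"

  # remove triangles whose centroid falls inside any feature cap
  cent <- (sph[faces[, 1], ] + sph[faces[, 2], ] + sph[faces[, 3], ]) / 3
  cent <- cent / sqrt(rowSums(cent^2))
  drop <- rep(FALSE, nrow(faces))
  for (f in feats)
    drop <- drop | (cent %*% f$dir > cos(f$cap_angle))
  mesh <- surface_mesh(verts, faces[!drop, , drop = FALSE], labels,
                       validate = FALSE)
  mesh <- submesh(mesh, sort(unique(as.integer(mesh$triangles))))

  # bridge each cap rim to a circular ring, then extrude the tubes
  loops <- boundary_loops(mesh)
  loop_dirs <- t(vapply(loops, function(l) {
    c_ <- colMeans(mesh$vertices[l, , drop = FALSE])
    c_ / sqrt(sum(c_^2))
  }, numeric(3)))
  for (f in feats) {
    li <- which.max(loop_dirs %*% f$dir)
    mesh <- attach_tube(mesh, loops[[li]], f, resolution)
    loops <- boundary_loops(mesh)
    loop_dirs <- t(vapply(loops, function(l) {
      c_ <- colMeans(mesh$vertices[l, , drop = FALSE])
      c_ / sqrt(sum(c_^2))
    }, numeric(3)))
  }

  mesh <- surface_mesh(mesh$vertices, mesh$triangles, mesh$labels)
  present <- unique(mesh$labels)
  missing <- setdiff(LABEL_LEVELS, present)
  if (length(missing))
    stop("label class(es) empty after construction: ",
         paste(missing, collapse = ", "))
  nb <- length(boundary_loops(mesh))
  if (nb != 5L)
    stop("expected 5 boundary loops, got ", nb)
  mesh
}

# Bridge an ordered boundary loop to a circular ring along the feature axis
# and extrude. The directed loop order (from boundary_loops) fixes the
# winding of the new triangles.
attach_tube <- function(mesh, loop, feat, resolution) {
  v <- mesh$vertices
  pts <- v[loop, , drop = FALSE]
  ctr <- colMeans(pts)
  a <- feat$axis
  # in-plane frame
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  k <- length(loop)
  rel <- sweep(pts, 2, ctr)
  phi0 <- atan2(sum(rel[1, ] * e2), sum(rel[1, ] * e1))
  # winding direction of the directed loop about the axis
  ang <- atan2(rel %*% e2, rel %*% e1)
  dphi <- diff(c(ang, ang[1]))
  dphi <- (dphi + pi) %% (2 * pi) - pi
  dir <- ifelse(sum(dphi) >= 0, 1, -1)
  phis <- phi0 + dir * 2 * pi * (seq_len(k) - 1) / k

  step <- max(resolution, 1e-6)
  n_r <- if (feat$type == "rim_only") 1L else max(2L, round(feat$length / step))
  seg <- if (feat$type == "rim_only") 0.75 * step else feat$length / n_r

  # bend frame for the appendage pouch
  bend_total <- if (feat$type == "tube_closed") 70 * pi / 180 else 0
  bend_axis <- e1

  verts_new <- NULL
  ring_prev <- loop
  centre <- ctr
  axis_k <- a
  tris_new <- NULL
  nv <- nrow(v)
  for (r in seq_len(n_r)) {
    if (bend_total > 0) {
      R <- rotation_about_axis(bend_axis, bend_total / n_r)
      axis_k <- as.numeric(R %*% axis_k)
    }
    centre <- centre + seg * axis_k
    f1 <- e1; f2 <- e2
    if (bend_total > 0) {
      Rtot <- rotation_about_axis(bend_axis, bend_total * r / n_r)
      f1 <- as.numeric(Rtot %*% e1); f2 <- as.numeric(Rtot %*% e2)
    }
    ring_xyz <- t(vapply(phis, function(p)
      centre + feat$radius * (cos(p) * f1 + sin(p) * f2), numeric(3)))
    idx <- nv + nrow(if (is.null(verts_new)) matrix(0, 0, 3) else verts_new) +
      seq_len(k)
    verts_new <- rbind(verts_new, ring_xyz)
    ip1 <- c(2:k, 1L)
    tris_new <- rbind(tris_new,
                      cbind(ring_prev[ip1], ring_prev, idx),
                      cbind(ring_prev[ip1], idx, idx[ip1]))
    ring_prev <- idx
  }
  lab_new <- rep(feat$name, nrow(verts_new))
  if (feat$type == "tube_closed") {
    apex <- colMeans(verts_new[(nrow(verts_new) - k + 1):nrow(verts_new), ,
                               drop = FALSE]) +
      0.5 * feat$radius * axis_k
    apex_idx <- nv + nrow(verts_new) + 1L
    verts_new <- rbind(verts_new, apex)
    lab_new <- c(lab_new, feat$name)
    ip1 <- c(2:k, 1L)
    tris_new <- rbind(tris_new, cbind(ring_prev[ip1], ring_prev, apex_idx))
  }
  surface_mesh(rbind(v, verts_new),
               rbind(mesh$triangles, tris_new),
               c(mesh$labels, lab_new), validate = FALSE)
}

# Best-fit plane of a boundary loop: centroid, unit normal (oriented away
# from a reference point), projected 2D coordinates and polygon area.
loop_plane <- function(pts, away_from) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  n <- s$v[, 3]
  if (sum(n * (ctr - away_from)) < 0) n <- -n
  u <- s$v[, 1]; w <- s$v[, 2]
  rel <- sweep(pts, 2, ctr)
  xy <- cbind(rel %*% u, rel %*% w)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1L)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  oop <- sqrt(mean((rel %*% n)^2))
  list(centre = ctr, normal = n, area = area, out_of_plane = oop)
}

#' Add straight flow extensions to every open orifice
#'
#' Each open boundary loop is extruded along its outward mean normal by a
#' straight tube of length `factor` times the orifice equivalent diameter
#' \eqn{d_{eq} = \sqrt{4A/\pi}}, where A is the loop area on its best-fit
#' plane. Extension vertices inherit the parent orifice label.
#'
#' @param mesh a [surface_mesh()] with at least one open boundary loop.
#' @param factor extension length in equivalent diameters (default 10);
#'   0 returns the mesh unchanged.
#' @return the extended mesh, with attribute `"extensions"` recording, per
#'   orifice, the added vertex indices, the equivalent diameter and the
#'   extension length, and `"n_vertices_original"`.
#' @export
add_flow_extensions <- function(mesh, factor = 10) {
  stopifnot(factor >= 0)
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L) stop("mesh has no open boundary loop to extend")
  if (factor == 0) return(mesh)
  mesh_ctr <- colMeans(mesh$vertices)
  ext_info <- list()
  for (loop in loops) {
    pts <- mesh$vertices[loop, , drop = FALSE]
    pl <- loop_plane(pts, mesh_ctr)
    if (pl$out_of_plane > 0.1 * sqrt(pl$area))
      warning("non-planar orifice beyond tolerance; projected-plane area used")
    d_eq <- sqrt(4 * pl$area / pi)
    len <- factor * d_eq
    seglen <- sqrt(rowSums((pts[c(2:nrow(pts), 1L), ] - pts)^2))
    step <- stats::median(seglen)
    n_r <- max(1L, ceiling(len / step))
    seg <- len / n_r
    lab_tab <- table(mesh$labels[loop])
    parent_label <- names(lab_tab)[which.max(lab_tab)]
    if (parent_label == "mitral_rim") parent_label <- "mitral_rim"
    k <- length(loop)
    nv0 <- nrow(mesh$vertices)
    ring_prev <- loop
    verts_new <- NULL; tris_new <- NULL
    for (r in seq_len(n_r)) {
      ring_xyz <- sweep(pts, 2, r * seg * pl$normal, `+`)
      idx <- nv0 + (r - 1L) * k + seq_len(k)
      verts_new <- rbind(verts_new, ring_xyz)
      ip1 <- c(2:k, 1L)
      tris_new <- rbind(tris_new,
                        cbind(ring_prev[ip1], ring_prev, idx),
                        cbind(ring_prev[ip1], idx, idx[ip1]))
      ring_prev <- idx
    }
    added <- nv0 + seq_len(n_r * k)
    mesh <- surface_mesh(rbind(mesh$vertices, verts_new),
                         rbind(mesh$triangles, tris_new),
                         c(mesh$labels, rep(parent_label, length(added))),
                         validate = FALSE)
    ext_info[[length(ext_info) + 1L]] <-
      list(vertices = added, label = parent_label, d_eq = d_eq, length = len)
  }
  attr(mesh, "extensions") <- ext_info
  attr(mesh, "n_vertices_original") <-
    nrow(mesh$vertices) - sum(lengths(lapply(ext_info, `[[`, "vertices")))
  mesh
}

#' Remove previously added flow extensions
#' @param mesh a mesh returned by [add_flow_extensions()].
#' @return the mesh restricted to its original vertices.
#' @export
remove_flow_extensions <- function(mesh) {
  ext <- attr(mesh, "extensions")
  if (is.null(ext)) return(mesh)
  drop <- unlist(lapply(ext, `[[`, "vertices"))
  m <- submesh(mesh, setdiff(seq_len(nrow(mesh$vertices)), drop))
  attr(m, "index_map") <- NULL
  m
}

#' Clip the pulmonary veins to a fixed residual length
#'
#' Truncates each labeled pulmonary-vein tube so that the geodesic distance
#' (shortest path along mesh edges) from the ostium curve to the new rim is
#' `residual_length`, the standardization applied before 2D unfolding.
#'
#' @param mesh a [surface_mesh()] with PV labels.
#' @param residual_length residual vein length in mm (default 10).
#' @return the clipped mesh. Veins shorter than `residual_length` are left
#'   intact with a warning.
#' @export
clip_pulmonary_veins <- function(mesh, residual_length = 10) {
  stopifnot(residual_length > 0)
  pv_labels <- c("LSPV", "LIPV", "RSPV", "RIPV")
  if (!any(mesh$labels %in% pv_labels)) stop("no pulmonary-vein labels present")
  ed <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[ed[, 1], ] - mesh$vertices[ed[, 2], ])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- w
  drop <- integer(0)
  adj <- lapply(seq_len(nrow(mesh$vertices)), function(i) integer(0))
  for (r in seq_len(nrow(ed))) {
    adj[[ed[r, 1]]] <- c(adj[[ed[r, 1]]], ed[r, 2])
    adj[[ed[r, 2]]] <- c(adj[[ed[r, 2]]], ed[r, 1])
  }
  for (pv in pv_labels) {
    vids <- which(mesh$labels == pv)
    if (!length(vids)) next
    seeds <- vids[vapply(vids, function(i)
      any(mesh$labels[adj[[i]]] != pv), logical(1))]
    if (!length(seeds)) next
    d <- igraph::distances(g, v = seeds, to = vids)
    dmin <- apply(d, 2, min)
    if (max(dmin) <= residual_length) {
      warning("PV ", pv, " shorter than residual_length; left intact")
      next
    }
    drop <- c(drop, vids[dmin > residual_length])
  }
  if (!length(drop)) return(mesh)
  m <- submesh(mesh, setdiff(seq_len(nrow(mesh$vertices)), drop))
  attr(m, "index_map") <- NULL
  m
}
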