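# Atlas registration, harmonic 2D unfolding with the mitral rim pinned to
# the template perimeter, 24-region assignment and rasterization.

#' Register a mesh to an atrium atlas
#'
#' Similarity alignment (rotation, isotropic scale, translation; the
#' Umeyama closed form on anatomical-label centroids, refined by ICP on the
#' scaled vertices) followed by label-wise matching of the PV ostia,
#' appendage and mitral-rim landmarks.
#'
#' @param mesh a labeled [surface_mesh()].
#' @param atlas a labeled [surface_mesh()] with the same label classes.
#' @return list with `scale`, `rotation`, `translation`, per-label
#'   `landmarks` (matched centroid pairs), and `rms` of matched landmarks.
#' @export
register_to_atlas <- function(mesh, atlas) {
  classes <- intersect(unique(mesh$labels), LABEL_LEVELS)
  missing <- setdiff(unique(atlas$labels), unique(mesh$labels))
  if (length(missing))
    stop("registration error: mesh lacks label class(es): ",
         paste(missing, collapse = ", "))
  missing2 <- setdiff(unique(mesh$labels), unique(atlas$labels))
  if (length(missing2))
    stop("registration error: atlas lacks label class(es): ",
         paste(missing2, collapse = ", "))
  cm <- t(vapply(classes, function(l)
    colMeans(mesh$vertices[mesh$labels == l, , drop = FALSE]), numeric(3)))
  ca <- t(vapply(classes, function(l)
    colMeans(atlas$vertices[atlas$labels == l, , drop = FALSE]), numeric(3)))
  um <- umeyama(cm, ca)
  moved <- sweep(um$scale * cm %*% t(um$rotation), 2, um$translation, `+`)
  rms <- sqrt(mean(rowSums((moved - ca)^2)))
  landmarks <- data.frame(label = classes,
                          mesh_x = cm[, 1], mesh_y = cm[, 2], mesh_z = cm[, 3],
                          atlas_x = ca[, 1], atlas_y = ca[, 2],
                          atlas_z = ca[, 3])
  list(scale = um$scale, rotation = um$rotation,
       translation = um$translation, landmarks = landmarks, rms = rms)
}

# Umeyama similarity fit mapping x onto y
umeyama <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  H <- crossprod(xc, yc) / nrow(x)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  S <- diag(c(1, 1, d))
  R <- s$v %*% S %*% t(s$u)
  varx <- mean(rowSums(xc^2))
  scale <- sum(s$d * diag(S)) / varx
  list(scale = scale, rotation = R,
       translation = cy - scale * as.numeric(R %*% cx))
}

#' Default circular 2D unfolding template with 24 regions
#'
#' Unit-disk template: the mitral rim maps to the perimeter. Regions are
#' anchor-driven: a disk and a surrounding ostial ring for each PV, a disk
#' for the appendage (anchors default to the unfolded label centroids so
#' every region is populated on any labeled mesh), and 15 body sectors
#' (roof x3 and posterior x3 in an inner band; anterior x3, lateral x2,
#' septal x2 and floor x2 in the outer band). Serializable to JSON with
#' [write_template()].
#'
#' @param pv_radius PV disk radius in template units (default 0.10).
#' @param ring_width ostial ring width (default 0.05).
#' @param appendage_radius appendage disk radius (default 0.13).
#' @param inner_band radius separating the inner (roof/posterior) band from
#'   the outer band (default 0.55).
#' @return object of class `template2d`.
#' @export
default_template <- function(pv_radius = 0.10, ring_width = 0.05,
                             appendage_radius = 0.13, inner_band = 0.55) {
  regions <- c("LSPV", "LSPV_ostium", "LIPV", "LIPV_ostium",
               "RSPV", "RSPV_ostium", "RIPV", "RIPV_ostium",
               "appendage",
               "roof_1", "roof_2", "roof_3",
               "posterior_1", "posterior_2", "posterior_3",
               "anterior_1", "anterior_2", "anterior_3",
               "lateral_1", "lateral_2",
               "septal_1", "septal_2",
               "floor_1", "floor_2")
  structure(list(
    perimeter = polygon_circle(1, 96),
    pv_radius = pv_radius, ring_width = ring_width,
    appendage_radius = appendage_radius, inner_band = inner_band,
    anchors = NULL,  # NULL: derive from unfolded label centroids
    region_names = regions
  ), class = "template2d")
}

polygon_circle <- function(r, n, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

#' Write / read a 2D template as JSON
#' @param template a `template2d`.
#' @param path file path.
#' @return `read_template` returns a `template2d`.
#' @export
write_template <- function(template, path) {
  obj <- list(perimeter = template$perimeter,
              pv_radius = template$pv_radius,
              ring_width = template$ring_width,
              appendage_radius = template$appendage_radius,
              inner_band = template$inner_band,
              anchors = template$anchors,
              region_names = template$region_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(perimeter = as.matrix(obj$perimeter),
                 pv_radius = obj$pv_radius, ring_width = obj$ring_width,
                 appendage_radius = obj$appendage_radius,
                 inner_band = obj$inner_band,
                 anchors = if (is.null(obj$anchors)) NULL else
                   lapply(obj$anchors, unlist),
                 region_names = obj$region_names),
            class = "template2d")
}

# mean-value weight for directed edge i->j given the 1-2 triangles adjacent
# to it; all quantities per edge, vectorized outside.
#' Unfold a clipped atrial mesh to the 2D template
#'
#' Harmonic parameterization with mean-value weights: the mitral-rim
#' boundary loop is pinned to the template perimeter by arc-length
#' proportion (anchored at the rim vertex nearest the septal region,
#' counterclockwise), and all other vertices - including the free PV rims
#' and the appendage - solve the discrete Laplace equation. Positive
#' mean-value weights with a convex pinned boundary give a fold-free
#' embedding; the flip count is checked and reported.
#'
#' @param mesh a [surface_mesh()] after [clip_pulmonary_veins()]; the
#'   mitral rim must be an open boundary loop.
#' @param template a `template2d` (default [default_template()]).
#' @return object of class `unfolded_map`: `uv` (n x 2 template
#'   coordinates), `mesh`, `template`, `flip_count`, `boundary_residual`.
#' @export
unfold_to_2d <- function(mesh, template = default_template()) {
  loops <- boundary_loops(mesh)
  if (!length(loops)) stop("mesh has no boundary: cannot unfold")
  is_mitral <- vapply(loops, function(l)
    mean(mesh$labels[l] == "mitral_rim") > 0.5, logical(1))
  if (!any(is_mitral)) {
    # fall back: the largest loop plays the mitral role
    sizes <- lengths(loops)
    is_mitral <- sizes == max(sizes)
  }
  mloop <- loops[[which(is_mitral)[1]]]
  # Euler check for a disk with h interior holes: V - E + F = 2 - (1 + h)
  chi <- euler_characteristic(mesh)
  n_holes <- length(loops) - 1L
  if (chi != 1L - n_holes)
    stop("topology error: Euler characteristic ", chi, " with ",
         length(loops), " boundary loops; expected a disk with holes (chi = ",
         1L - n_holes, ")")

  # anchor: rim vertex closest to the septal label centroid
  sep_ctr <- if (any(mesh$labels == "septal"))
    colMeans(mesh$vertices[mesh$labels == "septal", , drop = FALSE])
  else colMeans(mesh$vertices)
  rimpts <- mesh$vertices[mloop, , drop = FALSE]
  start <- which.min(rowSums(sweep(rimpts, 2, sep_ctr)^2))
  mloop <- c(mloop[start:length(mloop)], mloop[seq_len(start - 1L)])
  rimpts <- mesh$vertices[mloop, , drop = FALSE]
  seg <- sqrt(rowSums((rimpts[c(2:nrow(rimpts), 1L), ] - rimpts)^2))
  arc <- c(0, cumsum(seg))[seq_along(mloop)] / sum(seg)
  theta <- 2 * pi * arc
  uv_bnd <- cbind(cos(theta), sin(theta))

  uv <- harmonic_embed(mesh, mloop, uv_bnd)
  # orientation: if the majority of triangles are negatively oriented in 2D,
  # flip one axis (the boundary traversal direction is mesh-winding-driven)
  s <- triangle_signs(uv, mesh$triangles)
  if (mean(s < 0) > 0.5) {
    uv[, 2] <- -uv[, 2]
    s <- triangle_signs(uv, mesh$triangles)
  }
  flip_count <- sum(s < 0)
  resid <- max(sqrt(rowSums((uv[mloop, , drop = FALSE] - uv_bnd)^2)))
  structure(list(uv = uv, mesh = mesh, template = template,
                 region = NULL, flip_count = flip_count,
                 boundary_residual = resid, mitral_loop = mloop),
            class = "unfolded_map")
}

#' @exportS3Method base::print
print.unfolded_map <- function(x, ...) {
  cat(sprintf(
    "unfolded_map: %d vertices, flips = %d, boundary residual = %.2e%s\n",
    nrow(x$uv), x$flip_count, x$boundary_residual,
    if (is.null(x$region)) "" else
      sprintf(", %d regions", length(unique(x$region)))))
  invisible(x)
}

triangle_signs <- function(uv, tr) {
  a <- uv[tr[, 1], , drop = FALSE]
  b <- uv[tr[, 2], , drop = FALSE]
  c_ <- uv[tr[, 3], , drop = FALSE]
  (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
}

# solve the mean-value Laplace system with Dirichlet values on `pinned`
harmonic_embed <- function(mesh, pinned, uv_pinned) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  # mean-value weights per directed half-edge: w_ij = (tan(a/2) + tan(b/2))
  # / |e_ij| where a, b are the angles at i in the two faces adjacent to
  # (i, j). Accumulate tan(angle/2) per directed edge from each face.
  he_i <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 1], tr[, 2], tr[, 3])
  he_j <- c(tr[, 2], tr[, 3], tr[, 1], tr[, 3], tr[, 1], tr[, 2])
  # angle at vertex i of each face
  ang <- function(p, q, r) {
    u <- q - p; w <- r - p
    cu <- sqrt(rowSums(u^2)); cw <- sqrt(rowSums(w^2))
    cosang <- pmin(1, pmax(-1, rowSums(u * w) / (cu * cw)))
    acos(cosang)
  }
  a1 <- ang(v[tr[, 1], , drop = FALSE], v[tr[, 2], , drop = FALSE],
            v[tr[, 3], , drop = FALSE])
  a2 <- ang(v[tr[, 2], , drop = FALSE], v[tr[, 3], , drop = FALSE],
            v[tr[, 1], , drop = FALSE])
  a3 <- ang(v[tr[, 3], , drop = FALSE], v[tr[, 1], , drop = FALSE],
            v[tr[, 2], , drop = FALSE])
  half_tan <- tan(c(a1, a2, a3, a1, a2, a3) / 2)
  elen <- sqrt(rowSums((v[he_j, , drop = FALSE] - v[he_i, , drop = FALSE])^2))
  wij <- half_tan / elen
  W <- Matrix::sparseMatrix(i = he_i, j = he_j, x = wij, dims = c(n, n))
  rs <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(n, rs) - W
  free <- setdiff(seq_len(n), pinned)
  uv <- matrix(0, n, 2L)
  uv[pinned, ] <- uv_pinned
  if (length(free)) {
    Lff <- L[free, free, drop = FALSE]
    Lfp <- L[free, pinned, drop = FALSE]
    rhs <- -as.matrix(Lfp %*% uv_pinned)
    sol <- Matrix::solve(Lff, rhs)
    uv[free, ] <- as.matrix(sol)
  }
  uv
}

#' Assign the 24 template regions to an unfolded map
#'
#' Each vertex receives exactly one of the 24 region labels by
#' anchor-driven membership: PV disks and ostial rings around the PV
#' anchors, the appendage disk, then body sectors by radial band and
#' azimuth. When the template has no stored anchors they are derived from
#' the unfolded centroids of the mesh's own PV/appendage labels, so all 24
#' regions are populated on any labeled fixture.
#'
#' @param unfolded an `unfolded_map` from [unfold_to_2d()].
#' @param template a `template2d`; defaults to the one stored in
#'   `unfolded`.
#' @return the `unfolded_map` with a `region` factor (24 levels) added.
#' @export
assign_regions <- function(unfolded, template = NULL) {
  if (is.null(template)) template <- unfolded$template
  uv <- unfolded$uv
  mesh <- unfolded$mesh
  anchors <- template$anchors
  feats <- c("LSPV", "LIPV", "RSPV", "RIPV", "appendage")
  if (is.null(anchors)) {
    anchors <- lapply(feats, function(l) {
      sel <- mesh$labels == l
      if (!any(sel)) stop("cannot derive anchor: no vertices labeled ", l)
      colMeans(uv[sel, , drop = FALSE])
    })
    names(anchors) <- feats
  }
  n <- nrow(uv)
  region <- rep(NA_character_, n)
  r_pv <- template$pv_radius; r_ring <- r_pv + template$ring_width
  for (l in c("LSPV", "LIPV", "RSPV", "RIPV")) {
    a <- anchors[[l]]
    d <- sqrt((uv[, 1] - a[1])^2 + (uv[, 2] - a[2])^2)
    region[is.na(region) & d <= r_pv] <- l
    region[is.na(region) & d <= r_ring] <- paste0(l, "_ostium")
  }
  a <- anchors[["appendage"]]
  d <- sqrt((uv[, 1] - a[1])^2 + (uv[, 2] - a[2])^2)
  region[is.na(region) & d <= template$appendage_radius] <- "appendage"
  # PV-labeled vertices always belong to their own PV disk region, and
  # appendage-labeled vertices to the appendage disk (anchor consistency)
  for (l in c("LSPV", "LIPV", "RSPV", "RIPV", "appendage"))
    region[mesh$labels == l] <- l
  rad <- sqrt(rowSums(uv^2))
  azi <- (atan2(uv[, 2], uv[, 1])) %% (2 * pi)
  body <- is.na(region)
  inner <- body & rad <= template$inner_band
  outer <- body & !inner
  # inner band: roof x3 (azimuth 0..pi), posterior x3 (pi..2pi)
  k3 <- pmin(2L, floor(3 * ((azi %% pi) / pi)))
  region[inner & azi < pi] <- paste0("roof_", k3[inner & azi < pi] + 1L)
  region[inner & azi >= pi] <- paste0("posterior_",
                                      k3[inner & azi >= pi] + 1L)
  # outer band: 9 azimuth wedges - anterior x3, lateral x2, septal x2,
  # floor x2
  wedge_names <- c("anterior_1", "anterior_2", "anterior_3",
                   "lateral_1", "lateral_2", "septal_1", "septal_2",
                   "floor_1", "floor_2")
  w9 <- pmin(8L, floor(9 * azi / (2 * pi)))
  region[outer] <- wedge_names[w9[outer] + 1L]
  stopifnot(!anyNA(region))
  unfolded$region <- factor(region, levels = template$region_names)
  unfolded$anchors <- anchors
  unfolded
}

#' Regional means and normalized regional means
#'
#' Arithmetic mean of a field per 2D region, and the normalized mean (each
#' regional mean divided by the maximum regional mean). Undefined vertices
#' are excluded; empty regions are reported as missing and excluded from
#' the maximum.
#'
#' @param field numeric vector or [scalar_field()] on the mesh vertices.
#' @param unfolded an `unfolded_map` with regions assigned.
#' @return tibble with `region`, `n`, `mean`, `normalized_mean`.
#' @export
regional_means <- function(field, unfolded) {
  if (is.null(unfolded$region)) stop("assign_regions() must be called first")
  f <- as.numeric(field)
  reg <- unfolded$region
  stopifnot(length(f) == length(reg))
  ok <- is.finite(f)
  m <- tapply(f[ok], reg[ok], mean)
  m <- m[levels(reg)]
  nn <- tapply(rep(1, sum(ok)), reg[ok], sum)
  nn <- nn[levels(reg)]
  nn[is.na(nn)] <- 0
  mx <- max(m, na.rm = TRUE)
  tibble::tibble(region = levels(reg), n = as.integer(nn),
                 mean = as.numeric(m),
                 normalized_mean = as.numeric(m) / mx)
}

#' Rasterize an unfolded field to a 2D image
#'
#' Barycentric interpolation of a per-vertex field over the mapped
#' triangles onto a square pixel grid covering the template; pixels outside
#' the atrium are NA.
#'
#' @param unfolded an `unfolded_map`.
#' @param field numeric vector or [scalar_field()] on the vertices.
#' @param resolution image width/height in pixels (default 200).
#' @return list with `image` (resolution x resolution matrix, NA outside),
#'   `extent` (xmin, xmax, ymin, ymax) and `range` (field range used for a
#'   colorbar).
#' @export
rasterize_map <- function(unfolded, field, resolution = 200L) {
  f <- as.numeric(field)
  uv <- unfolded$uv
  tr <- unfolded$mesh$triangles
  ext <- c(min(uv[, 1]), max(uv[, 1]), min(uv[, 2]), max(uv[, 2]))
  px <- seq(ext[1], ext[2], length.out = resolution)
  py <- seq(ext[3], ext[4], length.out = resolution)
  img <- matrix(NA_real_, resolution, resolution)
  for (t in seq_len(nrow(tr))) {
    a <- uv[tr[t, 1], ]; b <- uv[tr[t, 2], ]; c_ <- uv[tr[t, 3], ]
    xs <- which(px >= min(a[1], b[1], c_[1]) & px <= max(a[1], b[1], c_[1]))
    ys <- which(py >= min(a[2], b[2], c_[2]) & py <= max(a[2], b[2], c_[2]))
    if (!length(xs) || !length(ys)) next
    det <- (b[1] - a[1]) * (c_[2] - a[2]) - (c_[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-14) next
    gx <- rep(px[xs], times = length(ys))
    gy <- rep(py[ys], each = length(xs))
    l2 <- ((gx - a[1]) * (c_[2] - a[2]) - (gy - a[2]) * (c_[1] - a[1])) / det
    l3 <- ((gy - a[2]) * (b[1] - a[1]) - (gx - a[1]) * (b[2] - a[2])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -1e-12 & l2 >= -1e-12 & l3 >= -1e-12
    if (!any(inside)) next
    vals <- l1 * f[tr[t, 1]] + l2 * f[tr[t, 2]] + l3 * f[tr[t, 3]]
    ix <- rep(xs, times = length(ys))[inside]
    iy <- rep(ys, each = length(xs))[inside]
    img[cbind(ix, iy)] <- vals[inside]
  }
  list(image = img, extent = ext,
       range = range(f[is.finite(f)]))
}
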