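#' @keywords internal
#' @useDynLib lashear, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Canonical anatomical label set shared by all meshes in the package.
LABEL_LEVELS <- c("body", "roof", "posterior", "anterior", "lateral",
                  "septal", "floor", "appendage",
                  "LSPV", "LIPV", "RSPV", "RIPV", "mitral_rim")

#' Construct a labeled triangulated surface mesh
#'
#' The common geometric substrate of the package: a triangulated atrial wall
#' with per-vertex anatomical labels. Coordinates are in millimetres.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param triangles integer matrix, m x 3, 1-based vertex indices with
#'   consistent (outward, counterclockwise) winding.
#' @param labels character or factor of length n with levels from the
#'   anatomical label set (`body`, `roof`, `posterior`, `anterior`,
#'   `lateral`, `septal`, `floor`, `appendage`, `LSPV`, `LIPV`, `RSPV`,
#'   `RIPV`, `mitral_rim`). Defaults to `body` everywhere.
#' @param validate check manifoldness and index bounds.
#'
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `labels`.
#' @export
surface_mesh <- function(vertices, triangles, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  n <- nrow(vertices)
  if (is.null(labels)) labels <- rep("body", n)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have one entry per vertex")
  bad <- setdiff(unique(labels), LABEL_LEVELS)
  if (length(bad))
    stop("unknown vertex labels: ", paste(bad, collapse = ", "))
  if (validate) {
    if (any(triangles < 1L) || any(triangles > n))
      stop("triangle indices out of range")
    ec <- edge_face_count(triangles)
    if (any(ec > 2L))
      stop("non-manifold edge: shared by more than two triangles")
    if (any(!is.finite(vertices)))
      stop("non-finite vertex coordinates")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 labels = labels),
            class = "surface_mesh")
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  bl <- boundary_loops(x)
  cat(sprintf("surface_mesh: %d vertices, %d triangles, %d boundary loop(s)\n",
              nrow(x$vertices), nrow(x$triangles), length(bl)))
  tab <- table(factor(x$labels, levels = LABEL_LEVELS))
  tab <- tab[tab > 0]
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

# Undirected edge keys (i < j) for all triangle edges; one row per half-edge.
mesh_half_edges <- function(triangles) {
  rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
}

edge_key <- function(e) {
  a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
  paste(a, b)
}

edge_face_count <- function(triangles) {
  table(edge_key(mesh_half_edges(triangles)))
}

#' Unique undirected edges of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer matrix, one row per edge (i < j).
#' @export
mesh_edges <- function(mesh) {
  he <- mesh_half_edges(mesh$triangles)
  a <- pmin(he[, 1L], he[, 2L]); b <- pmax(he[, 1L], he[, 2L])
  unique(cbind(a, b))
}

#' Euler characteristic V - E + F
#' @param mesh a `surface_mesh`.
#' @return integer. For a genus-0 surface with `b` boundary loops this is
#'   `2 - b`.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

# Directed boundary half-edges: edges that appear exactly once. For a mesh
# with consistent winding these traverse each boundary loop in a consistent
# direction.
boundary_half_edges <- function(triangles) {
  he <- mesh_half_edges(triangles)
  k <- edge_key(he)
  cnt <- table(k)
  he[cnt[k] == 1L, , drop = FALSE]
}

#' Ordered boundary loops of an open mesh
#'
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors, each an ordered closed polyline of vertex
#'   indices (first vertex not repeated at the end); empty list for a closed
#'   mesh.
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_half_edges(mesh$triangles)
  if (nrow(be) == 0L) return(list())
  nxt <- integer(0)
  nxt[be[, 1L]] <- be[, 2L]
  todo <- rep(TRUE, nrow(be))
  names(todo) <- be[, 1L]
  starts <- be[, 1L]
  seen <- logical(max(be))
  loops <- list()
  for (s in starts) {
    if (seen[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      seen[v] <- TRUE
      v <- nxt[v]
      if (is.na(v)) stop("open boundary chain: mesh boundary is not closed")
      if (v == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], ] - v[tr[, 1L], ]
  e2 <- v[tr[, 3L], ] - v[tr[, 1L], ]
  cx <- cross3(e1, e2)
  0.5 * sqrt(rowSums(cx^2))
}

# Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Area-weighted outward vertex normals
#' @param mesh a `surface_mesh` with consistent outward winding.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], ] - v[tr[, 1L], ]
  e2 <- v[tr[, 3L], ] - v[tr[, 1L], ]
  fn <- cross3(e1, e2)  # length = 2 * area, so already area-weighted
  n <- matrix(0, nrow(v), 3L)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- tapply(fn[, ax], tr[, c], sum)
      idx <- as.integer(names(acc))
      n[idx, ax] <- n[idx, ax] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Keep a vertex subset; drops triangles touching removed vertices and
# remaps indices. Returns the submesh plus the index map (old -> new).
submesh <- function(mesh, keep) {
  if (is.logical(keep)) keep <- which(keep)
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  tr <- mesh$triangles
  ok <- map[tr[, 1L]] > 0L & map[tr[, 2L]] > 0L & map[tr[, 3L]] > 0L
  tr2 <- cbind(map[tr[ok, 1L]], map[tr[ok, 2L]], map[tr[ok, 3L]])
  m <- surface_mesh(mesh$vertices[keep, , drop = FALSE], tr2,
                    mesh$labels[keep], validate = FALSE)
  attr(m, "index_map") <- map
  m
}

#' Per-vertex scalar field
#'
#' @param values numeric vector, one value per mesh vertex (NA marks missing).
#' @param name field name (e.g. `"BV"`, `"IIR"`, `"TAWSS"`, `"BA"`).
#' @param units unit string (`"mV"`, `"Pa"`, `"s"`, `""`).
#' @return object of class `scalar_field` (a numeric vector with metadata).
#' @export
scalar_field <- function(values, name = "field", units = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values) & !is.na(values)))
    stop("scalar_field values must be finite or NA")
  structure(values, name = name, units = units, class = "scalar_field")
}

#' @exportS3Method base::print
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field '%s' [%s]: n=%d, range [%.4g, %.4g], %d missing\n",
              attr(x, "name"), attr(x, "units"), length(x),
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)), sum(is.na(x))))
  invisible(x)
}
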