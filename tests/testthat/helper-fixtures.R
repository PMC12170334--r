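# Shared fixtures, built in code and cached per test file.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_atrium <- function() {
  cached("tiny_atrium", function()
    build_idealized_atrium(resolution = 3, seed = 11L))
}

clipped_atrium <- function() {
  cached("clipped_atrium", function()
    clip_pulmonary_veins(tiny_atrium(), 10))
}

# axis-aligned box surface mesh [0,L1]x[0,L2]x[0,L3], 12 triangles,
# outward winding
box_mesh <- function(l = c(10, 10, 10)) {
  v <- as.matrix(expand.grid(x = c(0, l[1]), y = c(0, l[2]),
                             z = c(0, l[3])))
  # vertices: 1:(0,0,0) 2:(L,0,0) 3:(0,L,0) 4:(L,L,0) 5:(0,0,L) 6:(L,0,L)
  # 7:(0,L,L) 8:(L,L,L)
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = L (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = L (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = L (+x)
  surface_mesh(v, tr)
}

# flat triangulated square patch in z = 0, (n+1)^2 vertices over [0,L]^2
flat_patch <- function(n = 10, L = 10) {
  xs <- seq(0, L, length.out = n + 1)
  v <- cbind(rep(xs, n + 1), rep(xs, each = n + 1), 0)
  tri <- NULL
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    a <- j * (n + 1) + i + 1; b <- a + 1
    c_ <- a + (n + 1); d <- c_ + 1
    tri <- rbind(tri, c(a, b, d), c(a, d, c_))
  }
  surface_mesh(v, tri)
}

# unit icosphere as a surface_mesh (closed)
sphere_mesh <- function(level = 3, radius = 1) {
  ico <- lashear:::icosphere(level)
  surface_mesh(ico$vertices * radius, ico$faces)
}

# 1D channel voxel domain with labeled end faces
channel_domain <- function(n = 50, spacing = 1, inlet = "LSPV",
                           outlet = "mitral") {
  mask <- array(TRUE, c(n, 1, 1))
  idx <- array(0L, dim(mask)); idx[mask] <- seq_len(n)
  bf <- lashear:::find_boundary_faces(mask, idx)
  bf$label[bf$axis == 1 & bf$side == -1] <- inlet
  bf$label[bf$axis == 1 & bf$side == 1] <- outlet
  voxel_domain(mask, spacing, boundary_faces = bf)
}

constant_waveform <- function(u = 0.01, period = 1) {
  velocity_waveform(seq(0, period * 0.9, length.out = 10),
                    rep(u, 10), period, fun = function(t) rep(u, length(t)))
}

# independent Dijkstra oracle (binary-heap-free, O(V^2), fine at test sizes)
dijkstra_oracle <- function(vertices, edges, weights, sources) {
  n <- nrow(vertices)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  visited <- rep(FALSE, n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[r]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[r]))
  }
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        alt <- dist[u] + nb[r, 2]
        if (alt < dist[nb[r, 1]]) dist[nb[r, 1]] <- alt
      }
    }
  }
  dist
}

# smooth analytic traction series used for quadrature checks: per-vertex
# random low-order Fourier coefficients; returns a closure tau(t) -> n x 3
fourier_traction <- function(n_vertices, seed) {
  rng <- lashear:::seeded_rng(seed, "fourier-traction")
  a0 <- matrix(rng$norm(3 * n_vertices), n_vertices, 3)
  a1 <- matrix(rng$norm(3 * n_vertices, sd = 0.5), n_vertices, 3)
  b1 <- matrix(rng$norm(3 * n_vertices, sd = 0.5), n_vertices, 3)
  a2 <- matrix(rng$norm(3 * n_vertices, sd = 0.25), n_vertices, 3)
  function(t) {
    w <- 2 * pi * t
    a0 + a1 * cos(w) + b1 * sin(w) + a2 * cos(2 * w)
  }
}

# sample a closure traction into a traction_series with n samples over [0,1)
sample_traction <- function(tau_fun, n_samples) {
  times <- seq(0, 1, length.out = n_samples + 1)[1:n_samples]
  nv <- nrow(tau_fun(0))
  arr <- array(0, c(nv, 3, n_samples))
  for (k in seq_len(n_samples)) arr[, , k] <- tau_fun(times[k])
  traction_series(times, arr, 1)
}

# composite Simpson quadrature oracle over one period for f(t) (vectorized
# scalar function), m intervals (even)
simpson_period <- function(f, m = 1024) {
  h <- 1 / m
  t <- seq(0, 1, length.out = m + 1)
  w <- c(1, rep(c(4, 2), length.out = m - 1), 1)
  sum(w * f(t)) * h / 3
}
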