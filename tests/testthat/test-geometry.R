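test_that("idealized atrium has 5 boundary loops, chi = -3, full labels", {
  m <- tiny_atrium()
  expect_length(boundary_loops(m), 5L)
  expect_equal(euler_characteristic(m), -3L)
  expect_setequal(unique(m$labels), lashear:::LABEL_LEVELS)
  # area agrees with an independent per-triangle oracle
  oracle <- sum(vapply(seq_len(nrow(m$triangles)), function(t) {
    p <- m$vertices[m$triangles[t, ], ]
    u <- p[2, ] - p[1, ]; w <- p[3, ] - p[1, ]
    0.5 * sqrt(sum(c(u[2] * w[3] - u[3] * w[2],
                     u[3] * w[1] - u[1] * w[3],
                     u[1] * w[2] - u[2] * w[1])^2))
  }, numeric(1)))
  expect_lt(abs(mesh_area(m) - oracle) / oracle, 0.02)
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(build_idealized_atrium(appendage_scale = 0), "appendage")
  expect_error(build_idealized_atrium(pv_radius = 2, resolution = 3),
               "degenerate")
})

test_that("flow extensions have length factor x equivalent diameter", {
  m <- tiny_atrium()
  ext <- add_flow_extensions(m, factor = 10)
  info <- attr(ext, "extensions")
  expect_length(info, 5L)
  loops0 <- boundary_loops(m)
  for (k in seq_along(info)) {
    # oracle: projected shoelace area of the original loop
    loop <- loops0[[k]]
    pts <- m$vertices[loop, , drop = FALSE]
    ctr <- colMeans(pts)
    s <- svd(sweep(pts, 2, ctr))
    xy <- sweep(pts, 2, ctr) %*% s$v[, 1:2]
    j <- c(2:nrow(xy), 1)
    area <- abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
    d_eq <- sqrt(4 * area / pi)
    expect_equal(info[[k]]$d_eq, d_eq, tolerance = 1e-9)
    # realized extension length: distance from loop plane to the new rim
    added <- ext$vertices[info[[k]]$vertices, , drop = FALSE]
    nrml <- s$v[, 3]
    reach <- max(abs(sweep(added, 2, ctr) %*% nrml))
    edge <- stats::median(sqrt(rowSums((pts[j, ] - pts)^2)))
    expect_lt(abs(reach - 10 * d_eq), edge + 1e-9)
  }
})

test_that("zero-factor extension is a no-op and removal restores the mesh", {
  m <- tiny_atrium()
  expect_identical(nrow(add_flow_extensions(m, 0)$vertices),
                   nrow(m$vertices))
  ext <- add_flow_extensions(m, 10)
  back <- remove_flow_extensions(ext)
  expect_identical(nrow(back$vertices), nrow(m$vertices))
  expect_identical(nrow(back$triangles), nrow(m$triangles))
})

test_that("elliptic orifice extension follows the hydraulic diameter", {
  # open elliptic cylinder: one elliptical rim (4 x 9 mm semi-axes)
  k <- 48
  th <- seq(0, 2 * pi, length.out = k + 1)[1:k]
  rim <- cbind(4 * cos(th), 9 * sin(th), 0)
  base <- cbind(4.4 * cos(th), 9.9 * sin(th), -5)
  v <- rbind(rim, base, c(0, 0, -7))
  ip1 <- c(2:k, 1)
  tr <- rbind(cbind(ip1, seq_len(k), k + seq_len(k)),
              cbind(ip1, k + seq_len(k), k + ip1),
              cbind(k + seq_len(k), 2 * k + 1, k + ip1))
  tube <- surface_mesh(v, tr)
  expect_length(boundary_loops(tube), 1L)
  ext <- add_flow_extensions(tube, factor = 10)
  info <- attr(ext, "extensions")[[1]]
  area_oracle <- pi * 4 * 9  # shoelace limit of the ellipse
  expect_equal(info$d_eq, sqrt(4 * area_oracle / pi), tolerance = 0.01)
  expect_equal(info$length, 10 * info$d_eq, tolerance = 1e-12)
})

test_that("pulmonary veins are clipped to 10 mm geodesic length", {
  m <- tiny_atrium()
  cl <- clipped_atrium()
  expect_length(boundary_loops(cl), 5L)
  ed <- mesh_edges(cl)
  w <- sqrt(rowSums((cl$vertices[ed[, 1], ] - cl$vertices[ed[, 2], ])^2))
  h <- stats::median(w)
  for (pv in c("LSPV", "LIPV", "RSPV", "RIPV")) {
    vids <- which(cl$labels == pv)
    # ostium seeds: PV vertices adjacent to non-PV vertices
    touch <- unique(c(ed[cl$labels[ed[, 2]] == pv & cl$labels[ed[, 1]] != pv, 2],
                      ed[cl$labels[ed[, 1]] == pv & cl$labels[ed[, 2]] != pv, 1]))
    d <- dijkstra_oracle(cl$vertices, ed, w, touch)
    expect_lt(max(d[vids]), 10 + h + 1e-9)
  }
  # and the un-clipped veins genuinely reach further than 10 mm
  ed0 <- mesh_edges(m)
  w0 <- sqrt(rowSums((m$vertices[ed0[, 1], ] - m$vertices[ed0[, 2], ])^2))
  touch0 <- unique(c(ed0[m$labels[ed0[, 2]] == "LSPV" &
                           m$labels[ed0[, 1]] != "LSPV", 2],
                     ed0[m$labels[ed0[, 1]] == "LSPV" &
                           m$labels[ed0[, 2]] != "LSPV", 1]))
  d0 <- dijkstra_oracle(m$vertices, ed0, w0, touch0)
  expect_gt(max(d0[m$labels == "LSPV"]), 30)
})

test_that("clipping a vein shorter than the residual is a warned no-op", {
  cl <- clipped_atrium()
  ws <- capture_warnings(cl2 <- clip_pulmonary_veins(cl, 10))
  expect_true(all(grepl("left intact", ws)) && length(ws) == 4L)
  expect_identical(nrow(cl2$vertices), nrow(cl$vertices))
})
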