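test_that("atlas registration recovers identity and similarity scale", {
  m <- tiny_atrium()
  reg <- register_to_atlas(m, m)
  expect_equal(reg$scale, 1, tolerance = 1e-9)
  expect_lt(reg$rms, 1e-9)
  atlas <- m
  atlas$vertices <- m$vertices * 1.3
  reg2 <- register_to_atlas(m, atlas)
  expect_equal(reg2$scale, 1.3, tolerance = 1e-6)
  # missing label class is named in the error
  m2 <- m
  m2$labels[m2$labels == "LIPV"] <- "body"
  expect_error(register_to_atlas(m2, m), "LIPV")
})

test_that("a flat disk unfolds to itself up to rotation and scale", {
  # planar fan disk with circular boundary
  k <- 64
  th <- seq(0, 2 * pi, length.out = k + 1)[1:k]
  rings <- list(c(0, 0))
  v <- rbind(c(0, 0, 0),
             cbind(0.5 * cos(th), 0.5 * sin(th), 0),
             cbind(cos(th), sin(th), 0))
  ip1 <- c(2:k, 1)
  inner <- 1 + seq_len(k); outer <- 1 + k + seq_len(k)
  tr <- rbind(cbind(1, inner, inner[ip1]),
              cbind(inner, outer, outer[ip1]),
              cbind(inner, outer[ip1], inner[ip1]))
  lab <- c("body", rep("body", k), rep("mitral_rim", k))
  disk <- surface_mesh(v, tr, lab)
  um <- unfold_to_2d(disk)
  expect_equal(um$flip_count, 0L)
  expect_lt(um$boundary_residual, 1e-6)
  # harmonic map of a flat disk: radius preserved up to small distortion
  r3 <- sqrt(rowSums(v[, 1:2]^2))
  r2 <- sqrt(rowSums(um$uv^2))
  expect_lt(max(abs(r2 - r3)), 0.08)
})

test_that("the clipped atrium unfolds fold-free with the rim on the circle", {
  um <- cached("unfolded", function() assign_regions(unfold_to_2d(clipped_atrium())))
  expect_equal(um$flip_count, 0L)
  expect_lt(um$boundary_residual, 1e-6)
  rim <- um$mitral_loop
  expect_equal(sqrt(rowSums(um$uv[rim, ]^2)),
               rep(1, length(rim)), tolerance = 1e-9)
})

test_that("region assignment partitions vertices into 24 labeled regions", {
  um <- cached("unfolded", function() assign_regions(unfold_to_2d(clipped_atrium())))
  expect_length(levels(um$region), 24L)
  tab <- table(um$region)
  expect_true(all(tab > 0))
  expect_identical(sum(tab), nrow(um$uv))
  expect_false(anyNA(um$region))
  # PV rim vertices land in their designated PV region
  cl <- um$mesh
  for (pv in c("LSPV", "LIPV", "RSPV", "RIPV"))
    expect_true(all(um$region[cl$labels == pv] == pv))
})

test_that("non-disk topology is reported with the Euler characteristic", {
  expect_error(unfold_to_2d(sphere_mesh(2)), "no boundary")
})

test_that("matching the template scale to the rim length lowers distortion", {
  um <- cached("unfolded", function() assign_regions(unfold_to_2d(clipped_atrium())))
  cl <- um$mesh
  a3 <- lashear:::triangle_areas(cl)
  a2 <- abs(lashear:::triangle_signs(um$uv, cl$triangles)) / 2
  rim_len <- {
    pts <- cl$vertices[um$mitral_loop, ]
    sum(sqrt(rowSums((pts[c(2:nrow(pts), 1), ] - pts)^2)))
  }
  distortion <- function(s)
    mean(abs(log((s^2 * a2[a3 > 0]) / a3[a3 > 0])))
  s_match <- rim_len / (2 * pi)     # template perimeter = rim length
  expect_lt(distortion(s_match), distortion(1))
})

test_that("regional means equal a group-by oracle and normalize correctly", {
  um <- cached("unfolded", function() assign_regions(unfold_to_2d(clipped_atrium())))
  n <- nrow(um$uv)
  # constant field: all means equal, all normalized means 1
  rc <- regional_means(rep(2.5, n), um)
  expect_equal(rc$mean, rep(2.5, 24))
  expect_equal(rc$normalized_mean, rep(1, 24))
  # random field vs brute-force split oracle
  f <- lashear:::seeded_rng(2, "rm")$norm(n)
  rm1 <- regional_means(f, um)
  oracle <- sapply(split(f, um$region), mean)
  expect_equal(rm1$mean, unname(oracle[rm1$region]), tolerance = 1e-12)
  expect_equal(max(rm1$normalized_mean), 1)
  # permutation invariance of the (region, mean) relation
  perm <- lashear:::seeded_rng(3, "perm")$sample_int(n)
  um2 <- um; um2$uv <- um$uv[perm, ]; um2$region <- um$region[perm]
  rm2 <- regional_means(f[perm], um2)
  expect_equal(rm2$mean, rm1$mean, tolerance = 1e-12)
})

test_that("rasterization is exact for linear fields and stable in coverage", {
  um <- cached("unfolded", function() assign_regions(unfold_to_2d(clipped_atrium())))
  n <- nrow(um$uv)
  img_c <- rasterize_map(um, rep(7, n), resolution = 100)
  vals_c <- stats::na.omit(as.numeric(img_c$image))
  expect_equal(range(vals_c), c(7, 7), tolerance = 1e-12)
  # linear-in-2D field reproduced to 1e-6 by barycentric interpolation
  f <- 3 * um$uv[, 1] - 2 * um$uv[, 2] + 0.5
  img_l <- rasterize_map(um, f, resolution = 100)
  px <- seq(img_l$extent[1], img_l$extent[2], length.out = 100)
  py <- seq(img_l$extent[3], img_l$extent[4], length.out = 100)
  want <- outer(3 * px, -2 * py, `+`) + 0.5
  ok <- !is.na(img_l$image)
  expect_lt(max(abs(img_l$image[ok] - want[ok])), 1e-6)
  # pixel coverage fraction stable under 2x resolution
  cov1 <- mean(!is.na(img_l$image))
  img_2 <- rasterize_map(um, f, resolution = 200)
  cov2 <- mean(!is.na(img_2$image))
  expect_lt(abs(cov1 - cov2), 0.02)
})

test_that("templates round-trip through JSON", {
  tpl <- default_template()
  path <- tempfile(fileext = ".json")
  write_template(tpl, path)
  tpl2 <- read_template(path)
  expect_equal(tpl2$region_names, tpl$region_names)
  expect_equal(tpl2$pv_radius, tpl$pv_radius)
  expect_equal(dim(tpl2$perimeter), dim(tpl$perimeter))
})
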