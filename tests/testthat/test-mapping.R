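test_that("rigid transforms are orthonormal and distance preserving", {
  R <- lashear:::rotation_about_axis(c(1, 1, 0), 0.7)
  tf <- rigid_transform(R, c(4, -2, 1))
  pts <- matrix(lashear:::seeded_rng(1, "p")$norm(60), 20, 3) * 10
  moved <- apply_rigid(tf, pts)
  expect_equal(as.matrix(dist(moved)), as.matrix(dist(pts)),
               tolerance = 1e-9)
  expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-10)
  inv <- invert_rigid(tf)
  expect_equal(apply_rigid(inv, moved), pts, tolerance = 1e-10)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("ICP recovers a known rigid transform on exact point sets", {
  rng <- lashear:::seeded_rng(7, "icp")
  pts <- matrix(rng$norm(900), 300, 3) * 15
  # identity case
  fit0 <- icp_align(pts, pts)
  expect_lt(fit0$rms, 1e-10)
  # 20 degrees about z plus translation (5, -3, 2)
  R <- lashear:::rotation_about_axis(c(0, 0, 1), 20 * pi / 180)
  truth <- rigid_transform(R, c(5, -3, 2))
  src <- apply_rigid(invert_rigid(truth), pts)  # source maps onto pts by truth
  fit <- icp_align(src, pts)
  comp <- compose_rigid(fit$transform, invert_rigid(truth))
  probe <- matrix(rng$norm(300), 100, 3) * 20
  rms <- sqrt(mean(rowSums((apply_rigid(comp, probe) - probe)^2)))
  expect_lt(rms, 1e-6)
  # RMS trace is non-increasing
  expect_true(all(diff(fit$rms_trace) <= 1e-12))
})

test_that("ICP rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(icp_align(line, line), "collinear|rank")
})

test_that("RBF interpolation reproduces sites, linears and constants", {
  rng <- lashear:::seeded_rng(3, "rbf")
  sites <- matrix(rng$unif(600, -10, 10), 200, 3)
  vals <- sin(sites[, 1] / 3) + 0.1 * sites[, 2]
  out <- rbf_interpolate(sites, vals, sites, smoothing = 0)
  expect_equal(out, vals, tolerance = 1e-8, ignore_attr = TRUE)
  lin <- 2 * sites[, 1] - sites[, 2] + 3
  q <- matrix(rng$unif(90, -8, 8), 30, 3)
  for (kn in c("thin-plate", "linear", "gaussian")) {
    got <- rbf_interpolate(sites, lin, q, kernel = kn)
    expect_equal(as.numeric(got), 2 * q[, 1] - q[, 2] + 3,
                 tolerance = 1e-6)
  }
  cst <- rbf_interpolate(sites, rep(4.2, 200), q)
  expect_equal(as.numeric(cst), rep(4.2, 30), tolerance = 1e-9)
  # duplicate sites are singular without smoothing
  dup <- rbind(sites, sites[1, , drop = FALSE])
  expect_error(rbf_interpolate(dup, c(vals, vals[1]), q, smoothing = 0),
               "smoothing")
  # seeded subsampling kicks in over the site budget
  expect_message(rbf_interpolate(sites, lin, q, max_sites = 100L),
                 "subsampled")
})

test_that("field mapping transfers values onto the mesh basis", {
  m <- tiny_atrium()
  rng <- lashear:::seeded_rng(5, "fields")
  tw <- scalar_field(pmax(0.01, 1.5 +
                            lashear:::smooth_random_field(m$vertices, 12,
                                                          rng)))
  truth <- synthesize_wall_fields(m, tw, -0.4, 0.3, seed = 7)
  # self-mapping: cloud sampled from the mesh's own BV field, identity pose
  cloud <- synthesize_emap_cloud(m, truth$bv, 2500, jitter_sd = 0, seed = 2)
  mapped <- map_fields_to_mesh(m, emap_cloud = cloud)
  expect_gt(stats::cor(as.numeric(mapped$bv), as.numeric(truth$bv)), 0.99)
  prov <- attr(mapped$bv, "provenance")
  expect_s3_class(prov$transform, "rigid_transform")
  # known displacement is recovered by the ICP stage
  R <- lashear:::rotation_about_axis(c(0, 1, 0), 8 * pi / 180)
  tf <- rigid_transform(R, c(3, 2, -4))
  cloud2 <- synthesize_emap_cloud(m, truth$bv, 2500, transform = tf,
                                  jitter_sd = 0, seed = 2)
  mapped2 <- map_fields_to_mesh(m, emap_cloud = cloud2)
  expect_gt(stats::cor(as.numeric(mapped2$bv), as.numeric(truth$bv)), 0.98)
  # sparse source warns
  tiny_cloud <- synthesize_emap_cloud(m, truth$bv, 10, jitter_sd = 0,
                                      seed = 2)
  expect_warning(map_fields_to_mesh(m, emap_cloud = tiny_cloud), "sparse")
})

test_that("injected correlation structure survives mapping", {
  m <- tiny_atrium()
  rng <- lashear:::seeded_rng(6, "fields2")
  tw <- scalar_field(pmax(0.01, 1.5 + 0.8 *
                            lashear:::smooth_random_field(m$vertices, 12,
                                                          rng)))
  truth <- synthesize_wall_fields(m, tw, -0.4, 0.3, seed = 9)
  cloud <- synthesize_emap_cloud(m, truth$bv, 3000, jitter_sd = 0.5,
                                 seed = 4)
  mapped <- map_fields_to_mesh(m, emap_cloud = cloud,
                               cmr_mesh = list(mesh = m, iir = truth$iir))
  r_before <- stats::cor(as.numeric(tw), as.numeric(truth$bv))
  r_after <- stats::cor(as.numeric(tw), as.numeric(mapped$bv))
  expect_lt(abs(r_after - r_before), 0.05)
  r_iir_after <- stats::cor(as.numeric(tw), as.numeric(mapped$iir))
  expect_lt(abs(r_iir_after - 0.3), 0.05)
})
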