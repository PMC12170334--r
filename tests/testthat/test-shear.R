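test_that("constant traction gives the closed-form index values", {
  tau <- array(0, c(1, 3, 16))
  for (k in 1:16) tau[1, , k] <- c(3, 4, 0)
  ts <- sample_traction(function(t) matrix(c(3, 4, 0), 1), 16)
  si <- compute_shear_indices(ts)
  expect_equal(si$tawss, 5)
  expect_equal(si$osi, 0)
  expect_equal(si$rrt, 0.2)
  expect_equal(si$holmes, 2.5)
  expect_equal(si$ecap, 0)
  expect_equal(as.numeric(si$g), c(3, 4, 0) / 5)
})

test_that("fully reversing traction maxes out OSI and undefines RRT", {
  tau <- array(0, c(1, 3, 16))
  tau[1, 1, 1:8] <- 1; tau[1, 1, 9:16] <- -1
  ts <- traction_series(seq(0, 1, length.out = 17)[1:16], tau, 1)
  si <- compute_shear_indices(ts)
  expect_equal(si$tawss, 1)
  expect_equal(si$osi, 0.5)
  expect_equal(si$holmes, 0)
  expect_false(si$rrt_defined)
  expect_identical(si$rrt, Inf)
})

test_that("indices match a fine Simpson quadrature oracle on smooth series", {
  nv <- 40
  tau_fun <- fourier_traction(nv, seed = 8)
  ts <- sample_traction(tau_fun, 64)
  si <- compute_shear_indices(ts)
  for (v in seq_len(5)) {
    tawss_o <- simpson_period(function(t)
      vapply(t, function(tt) sqrt(sum(tau_fun(tt)[v, ]^2)), numeric(1)))
    mv_o <- vapply(1:3, function(ax) simpson_period(function(t)
      vapply(t, function(tt) tau_fun(tt)[v, ax], numeric(1))), numeric(1))
    osi_o <- 0.5 * (1 - sqrt(sum(mv_o^2)) / tawss_o)
    expect_equal(si$tawss[v], tawss_o, tolerance = 1e-3)
    expect_equal(si$osi[v], osi_o, tolerance = 1e-3)
    expect_equal(si$rrt[v], 1 / sqrt(sum(mv_o^2)), tolerance = 1e-3)
    expect_equal(si$holmes[v], tawss_o * (0.5 - osi_o), tolerance = 1e-3)
    expect_equal(si$ecap[v], osi_o / tawss_o, tolerance = 1e-3)
  }
})

test_that("index identities and bounds hold on random series", {
  tau_fun <- fourier_traction(300, seed = 21)
  si <- compute_shear_indices(sample_traction(tau_fun, 48))
  expect_true(all(si$tawss >= 0))
  expect_true(all(si$osi >= 0 & si$osi <= 0.5))
  expect_equal(si$holmes, si$tawss * (0.5 - si$osi), tolerance = 1e-12)
  ok <- si$ecap_defined
  expect_equal(si$ecap[ok] * si$tawss[ok], si$osi[ok], tolerance = 1e-12)
  okr <- si$rrt_defined
  expect_equal(si$rrt[okr] * si$tawss[okr] * (1 - 2 * si$osi[okr]),
               rep(1, sum(okr)), tolerance = 1e-9)
})

test_that("OSI is rotation invariant; TAWSS is phase-shift invariant; scaling behaves", {
  tau_fun <- fourier_traction(50, seed = 3)
  ts <- sample_traction(tau_fun, 64)
  si <- compute_shear_indices(ts)
  R <- lashear:::rotation_about_axis(c(1, 2, 3), 1.1)
  tsr <- ts
  for (k in seq_along(ts$times))
    tsr$traction[, , k] <- ts$traction[, , k] %*% t(R)
  sir <- compute_shear_indices(tsr)
  expect_equal(sir$osi, si$osi, tolerance = 1e-12)
  expect_equal(sir$tawss, si$tawss, tolerance = 1e-12)
  # cyclic phase shift of a uniformly sampled periodic signal
  shift <- 17
  tss <- ts
  tss$traction <- ts$traction[, , c((shift + 1):64, 1:shift), drop = FALSE]
  sis <- compute_shear_indices(tss)
  expect_equal(sis$tawss, si$tawss, tolerance = 1e-12)
  # doubling magnitudes
  ts2 <- ts; ts2$traction <- 2 * ts$traction
  si2 <- compute_shear_indices(ts2)
  expect_equal(si2$tawss, 2 * si$tawss, tolerance = 1e-12)
  expect_equal(si2$holmes, 2 * si$holmes, tolerance = 1e-12)
  expect_equal(si2$osi, si$osi, tolerance = 1e-12)
  ok <- si$rrt_defined
  expect_equal(si2$rrt[ok], si$rrt[ok] / 2, tolerance = 1e-12)
  expect_equal(si2$ecap[ok], si$ecap[ok] / 2, tolerance = 1e-12)
})

test_that("surface gradient is exact for linear fields and convergent", {
  patch <- flat_patch(10, 10)
  g <- surface_scalar_gradient(patch, 2 * patch$vertices[, 1])
  expect_lt(max(abs(sweep(g, 2, c(2, 0, 0)))), 1e-10)
  g0 <- surface_scalar_gradient(patch, rep(3.3, nrow(patch$vertices)))
  expect_lt(max(abs(g0)), 1e-12)
  # quadratic field on a refining sphere: tangential gradient error shrinks
  # with at least first-order rate
  err <- vapply(c(2, 3, 4), function(lv) {
    s <- sphere_mesh(lv)
    f <- s$vertices[, 3]^2
    g <- surface_scalar_gradient(s, f)
    # analytic tangential gradient of z^2 on the unit sphere
    z <- s$vertices[, 3]
    gt <- 2 * z * (cbind(0, 0, 1) [rep(1, nrow(s$vertices)), ] -
                     z * s$vertices)
    sqrt(mean(rowSums((g - gt)^2)))
  }, numeric(1))
  expect_gt(log2(err[1] / err[2]), 0.9)
  expect_gt(log2(err[2] / err[3]), 0.9)
})

test_that("WSSG projects the magnitude gradient on the flow direction", {
  patch <- flat_patch(10, 10)
  nv <- nrow(patch$vertices)
  interior <- patch$vertices[, 1] > 0 & patch$vertices[, 1] < 10 &
    patch$vertices[, 2] > 0 & patch$vertices[, 2] < 10
  # uniform magnitude: zero gradient
  ts_u <- sample_traction(function(t) matrix(c(2, 0, 0), nv, 3,
                                             byrow = TRUE), 8)
  expect_lt(max(abs(as.numeric(compute_wssg(ts_u, patch)))), 1e-12)
  # |tau| = x, direction +x: WSSG = 1 Pa/mm
  ts_x <- sample_traction(function(t)
    cbind(patch$vertices[, 1], 0, 0), 8)
  w <- as.numeric(compute_wssg(ts_x, patch))
  expect_equal(w[interior], rep(1, sum(interior)), tolerance = 1e-10)
  # direction orthogonal to the gradient: zero
  # |tau| = x but direction +y
  ts_y <- sample_traction(function(t) cbind(0, patch$vertices[, 1], 0), 8)
  w2 <- as.numeric(compute_wssg(ts_y, patch))
  expect_lt(max(abs(w2[interior])), 1e-10)
  # the mean-direction variant agrees for steady series
  w3 <- as.numeric(compute_wssg(ts_x, patch, direction = "mean"))
  expect_equal(w3[interior], rep(1, sum(interior)), tolerance = 1e-10)
})
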