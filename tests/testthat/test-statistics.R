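rng_stats <- function(label, seed = 1) lashear:::seeded_rng(seed, label)

test_that("per-case correlations match closed forms and a covariance oracle", {
  x <- seq(0.1, 5, length.out = 200)
  tb <- data.frame(tawss = x, bv = -x)
  res <- per_case_correlations(tb)
  row <- res[res$var1 == "tawss" & res$var2 == "bv", ]
  expect_equal(row$r, -1, tolerance = 1e-12)
  expect_lt(row$p, 1e-10)
  # null case at N = 20,000
  rng <- rng_stats("null")
  tb0 <- data.frame(tawss = rng$norm(20000), bv = rng$norm(20000))
  r0 <- per_case_correlations(tb0)
  expect_lt(abs(r0$r[1]), 0.03)
  # rho = -0.4 fixture, against the direct covariance-formula oracle
  rng2 <- rng_stats("rho")
  z <- rng2$norm(20000)
  bv <- -0.4 * z + sqrt(1 - 0.16) * rng2$norm(20000)
  tbr <- data.frame(tawss = z, bv = bv)
  rr <- per_case_correlations(tbr)$r[1]
  expect_true(rr > -0.43 && rr < -0.37)
  oracle <- {
    mx <- mean(z); my <- mean(bv)
    sum((z - mx) * (bv - my)) /
      sqrt(sum((z - mx)^2) * sum((bv - my)^2))
  }
  expect_equal(rr, oracle, tolerance = 1e-12)
  # pairwise deletion and degenerate variance
  tbna <- data.frame(tawss = c(z[1:50], NA), bv = c(bv[1:50], 1))
  expect_equal(per_case_correlations(tbna)$n_excluded[1], 1L)
  tbcst <- data.frame(tawss = rep(1, 20), bv = rnorm(20))
  expect_match(per_case_correlations(tbcst)$note[1], "zero variance")
})

test_that("quartile assignment reproduces the exact small case and ties rule", {
  q <- assign_quartiles(1:8)
  expect_equal(q, rep(1:4, each = 2))
  # invariant to adding a constant
  expect_equal(assign_quartiles(1:8 + 100), q)
  # boundary values fall in the lower quartile
  x <- c(1, 2, 2, 2, 3, 4, 5, 6)
  qx <- assign_quartiles(x)
  expect_equal(qx[x == 2], rep(1L, 3))  # 2 is the 25th percentile here
})

test_that("quartile analysis summarizes and tests against a rank oracle", {
  # identical response across quartiles: KW statistic ~ 0, p ~ 1
  tb <- data.frame(tawss = 1:100, bv = rep(c(1, 2), 50))
  qa <- quartile_analysis(tb, responses = "bv")
  expect_gt(qa$tests$p, 0.9)
  # monotone response: strictly decreasing quartile means, oracle-matched KW
  rng <- rng_stats("kw")
  tawss <- rng$unif(400, 0, 4)
  bv <- 3 - 0.6 * tawss + rng$norm(400, sd = 0.2)
  tb2 <- data.frame(tawss = tawss, bv = bv)
  qa2 <- quartile_analysis(tb2, responses = "bv")
  mu <- qa2$summary$mean
  expect_true(all(diff(mu) < 0))
  # brute-force Kruskal-Wallis statistic from ranks
  g <- assign_quartiles(tawss)
  r <- rank(bv)
  n <- length(bv)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  # tie correction
  ties <- table(bv)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(unname(qa2$tests$statistic), H, tolerance = 1e-9)
})

test_that("fibrosis and scar thresholds are inclusive/strict as defined", {
  iir <- c(1.19, 1.2, 1.21)
  bv <- c(0.49, 0.5, 0.51)
  cls <- classify_fibrosis(iir, bv)
  expect_identical(cls$fibrosis, c(FALSE, TRUE, TRUE))
  expect_identical(cls$scar, c(TRUE, FALSE, FALSE))
  cls0 <- classify_fibrosis(rep(1.0, 10), rep(1, 10))
  expect_identical(unname(cls0$counts["fibrosis"]), 0L)
})

test_that("pooled chi-square matches the direct O/E formula oracle", {
  # contingency [[90,10],[80,20],[60,40],[30,70]] rebuilt from vectors
  counts <- rbind(c(90, 10), c(80, 20), c(60, 40), c(30, 70))
  quart <- rep(1:4, times = rowSums(counts))
  flags <- unlist(lapply(1:4, function(q)
    rep(c(FALSE, TRUE), counts[q, ])))
  res <- pooled_quartile_chisq(flags, quart)
  oracle <- {
    tot <- sum(counts)
    e <- outer(rowSums(counts), colSums(counts)) / tot
    sum((counts - e)^2 / e)
  }
  expect_equal(res$statistic, oracle, tolerance = 1e-9)
  expect_equal(res$df, 3)
  expect_equal(res$prevalence, counts[, 2] / rowSums(counts))
  expect_true(all(diff(res$prevalence) > 0))
  # equal prevalence: statistic ~ 0, p ~ 1
  res0 <- pooled_quartile_chisq(rep(c(TRUE, FALSE), 200),
                                rep(1:4, each = 100))
  expect_lt(res0$statistic, 1e-9)
  expect_gt(res0$p, 0.999)
  expect_error(pooled_quartile_chisq(flags[quart != 4], quart[quart != 4]),
               "empty quartile")
})

test_that("Fisher-z comparison uses atanh and behaves at the null", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  same <- c(0.3, 0.4, 0.5, 0.35)
  res <- compare_correlations_fisher(same, same)
  expect_equal(res$p, 1, tolerance = 1e-9)
  expect_error(compare_correlations_fisher(c(0.2, 1), c(0.3, 0.4)),
               "overflow")
  diffr <- compare_correlations_fisher(c(0.7, 0.72, 0.69, 0.71),
                                       c(0.1, 0.12, 0.08, 0.11))
  expect_lt(diffr$p, 0.001)
})

test_that("test selection follows the normality/variance decision tree", {
  rng <- rng_stats("select")
  g_norm <- list(rng$norm(200), rng$norm(200, mean = 0.1))
  expect_identical(auto_test_selection(g_norm)$test, "anova")
  # heavy-tailed samples route to Kruskal-Wallis
  u <- rng$unif(400)
  g_cauchy <- list(tan(pi * (u[1:200] - 0.5)), tan(pi * (u[201:400] - 0.5)))
  expect_identical(auto_test_selection(g_cauchy)$test, "kruskal-wallis")
  # normal but heteroscedastic samples route to Welch
  g_het <- list(rng$norm(200, sd = 1), rng$norm(200, sd = 10))
  expect_identical(auto_test_selection(g_het)$test, "welch")
  trail <- auto_test_selection(g_het)$decision_trail
  expect_true(any(grepl("welch", trail$decision)))
})

test_that("correlation is affine invariant and the case table is coherent", {
  rng <- rng_stats("affine")
  x <- rng$norm(500); y <- 0.5 * x + rng$norm(500)
  r1 <- per_case_correlations(data.frame(tawss = x, bv = y))$r[1]
  r2 <- per_case_correlations(data.frame(tawss = 3 * x + 7,
                                         bv = -2 * y + 1))$r[1]
  expect_equal(r2, -r1, tolerance = 1e-12)
  # case_vertex_table masks undefined RRT/ECAP and assigns quartiles
  ts <- sample_traction(fourier_traction(100, 5), 16)
  si <- compute_shear_indices(ts)
  tb <- case_vertex_table(si)
  expect_identical(nrow(tb), 100L)
  expect_true(all(tb$quartile %in% 1:4))
  expect_true(all(is.na(tb$rrt[!si$rrt_defined])))
})
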