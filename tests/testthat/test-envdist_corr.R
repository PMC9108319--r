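test_that("environmental distance is garden minus origin", {
  expect_equal(env_distance(origin_value = 54, garden_value = 2852), 2798)
  expect_equal(env_distance(2852, 54), -2798)
  expect_equal(env_distance(100, 100), 0)
  expect_true(is.na(env_distance(NA, 100)))
})

test_that("a noiseless parabola gives R2 = 1 and a negative quadratic term", {
  dist <- seq(-3, 3, length.out = 60)
  fitness <- 2 - 0.5 * dist^2 + 0.1 * dist
  r <- quadratic_residual_test(fitness, dist)
  expect_equal(r$r2, 1, tolerance = 1e-10)
  expect_equal(r$quad_coef, -0.5, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-12)
  expect_lt(abs(sum(r$residuals)), 1e-8)  # stage 1 centres the residuals
})

test_that("the test is invariant to constant fitness shifts", {
  set.seed(5)
  dist <- runif(80, -2, 2)
  y <- rnorm(80) - 0.3 * dist^2
  r1 <- quadratic_residual_test(y, dist)
  r2 <- quadratic_residual_test(y + 100, dist)
  expect_equal(r1$quad_coef, r2$quad_coef, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  expect_error(quadratic_residual_test(1:3, 1:3), "at least 4")
  expect_error(quadratic_residual_test(rnorm(10), rep(1, 10)), "degenerate")
  # two distinct distances: quadratic aliased with linear
  expect_error(quadratic_residual_test(rnorm(10), rep(c(-1, 1), 5)), "aliased")
})

test_that("null quadratic p-values are approximately uniform", {
  set.seed(99)
  dist <- runif(60, -2, 2)
  pvals <- replicate(400, quadratic_residual_test(rnorm(60), dist)$p_value)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the per-variable scan runs on simulated data and orders variables", {
  sim <- default_sim()
  fit <- fitness_by_accession_garden(sim$pheno)
  oe <- sim$env$env[sim$env$env$location_id %in% sim$env$passports$accession_id, ]
  names(oe)[names(oe) == "location_id"] <- "accession_id"
  res <- env_distance_scan(fit, oe, sim$env$sites,
                           variables = c("elevation", "annual_mean_temp"),
                           p_adjust = "bonferroni")
  expect_equal(res$variable, c("elevation", "annual_mean_temp"))
  expect_true(all(res$quad_coef < 0))   # simulated decay penalises distance
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_error(env_distance_scan(fit, oe, sim$env$sites, variables = "bogus"),
               "bogus")
})

test_that("garden correlations agree with cor.test and handle edge cases", {
  set.seed(303)
  n <- 200
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, sqrt(0.75)); z <- rnorm(n)
  ph <- data.frame(site_id = "HighSite", X = x, Y = y, Z = z, C = 1)
  gc <- garden_correlations(ph, c("X", "Y", "Z", "C"), garden = "HighSite")
  expect_equal(diag(gc$r)[c("X", "Y", "Z")], c(X = 1, Y = 1, Z = 1))
  expect_true(isSymmetric(gc$r))
  ct <- cor.test(x, y)
  expect_equal(gc$r["X", "Y"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(gc$p["X", "Y"], ct$p.value, tolerance = 1e-12)
  expect_lt(abs(gc$r["X", "Y"] - 0.5), 0.1)
  expect_lt(gc$p["X", "Y"], 0.001)
  # zero-variance trait: correlations undefined
  expect_true(all(is.na(gc$r["C", ])))

  gz <- garden_correlations(ph, c("X", "Y"), method = "z")
  z_stat <- atanh(gc$r["X", "Y"]) * sqrt(n - 3)
  expect_equal(gz$p["X", "Y"], 2 * pnorm(-abs(z_stat)), tolerance = 1e-12)

  stars <- correlation_stars(gc$p)
  expect_equal(stars["X", "Y"], "***")
})

test_that("correlation differences subtract lowland from highland", {
  r_high <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  r_low <- matrix(c(1, -0.4, -0.4, 1), 2, dimnames = dimnames(r_high))
  d <- correlation_difference(r_high, r_low)
  expect_equal(d["a", "b"], 1.0)
  expect_equal(correlation_difference(r_high, r_high),
               matrix(0, 2, 2, dimnames = dimnames(r_high)))
  expect_equal(correlation_difference(r_low, r_high), -d)
  r_other <- r_low; dimnames(r_other) <- list(c("a", "c"), c("a", "c"))
  expect_error(correlation_difference(r_high, r_other), "different trait sets")
})

test_that("trait clustering recovers planted correlation blocks", {
  block_cor <- function(sizes, r_within) {
    k <- sum(sizes)
    m <- matrix(0, k, k)
    stop_at <- cumsum(sizes); start_at <- c(1, utils::head(stop_at, -1) + 1)
    for (b in seq_along(sizes)) {
      idx <- start_at[b]:stop_at[b]
      m[idx, idx] <- r_within
    }
    diag(m) <- 1
    dimnames(m) <- list(paste0("t", 1:k), paste0("t", 1:k))
    m
  }
  m2 <- block_cor(c(3, 3), 1)
  cl2 <- cluster_traits(m2, k = 2)
  expect_equal(as.integer(cl2), rep(1:2, each = 3))

  m3 <- block_cor(c(3, 4, 2), 0.8)
  cl3 <- cluster_traits(m3, k = 3)
  expect_equal(length(unique(cl3)), 3L)
  grp <- rep(1:3, c(3, 4, 2))
  expect_equal(as.integer(table(paste(as.integer(cl3), grp))), c(3L, 4L, 2L))

  cl_all <- cluster_traits(m3, k = 9)
  expect_equal(length(unique(cl_all)), 9L)
  expect_error(cluster_traits(m3, k = 10), "exceeds")
  m_na <- m3; m_na[1, 2] <- NA
  expect_error(cluster_traits(m_na, k = 2), "complete")
})
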