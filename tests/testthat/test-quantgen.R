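## direct evaluation of the restricted log-likelihood for a one-way
## random-intercept model; independent oracle for the REML fit
reml_loglik_oneway <- function(y, group, s2b, s2e) {
  Z <- outer(group, sort(unique(group)), `==`) * 1
  n <- length(y)
  V <- s2b * tcrossprod(Z) + s2e * diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * ((n - ncol(X)) * log(2 * pi) + determinant(V)$modulus +
            determinant(XtViX)$modulus + t(y) %*% P %*% y)[1]
}

test_that("REML matches the balanced one-way ANOVA method-of-moments estimator", {
  set.seed(101)
  k <- 10; n0 <- 8
  d <- data.frame(g = rep(sprintf("g%02d", 1:k), each = n0))
  d$y <- rep(rnorm(k, 0, sqrt(3)), each = n0) + rnorm(k * n0)
  f <- fit_lmm_reml("y", d, random_terms = "g")
  a <- anova(aov(y ~ g, data = d))
  mom <- (a["g", "Mean Sq"] - a["Residuals", "Mean Sq"]) / n0
  expect_gt(mom, 0)  # informative only when the MoM estimate is interior
  expect_lt(abs(f$sigma2[["g"]] - mom), 1e-6)
  expect_lt(abs(f$sigma2[["resid"]] - a["Residuals", "Mean Sq"]), 1e-4)
  expect_true(f$converged)
})

test_that("zero between-group signal estimates land on the boundary", {
  set.seed(55)
  d <- data.frame(g = rep(sprintf("g%02d", 1:6), each = 4))
  # group means forced exactly equal: no between-group variance at all
  d$y <- as.vector(replicate(6, scale(rnorm(4), scale = FALSE)))
  f <- fit_lmm_reml("y", d, random_terms = "g")
  expect_equal(unname(f$sigma2[["g"]]), 0, tolerance = 1e-8)
})

test_that("REML estimates maximize the directly-evaluated restricted likelihood", {
  set.seed(303)
  k <- 4; n0 <- 5
  d <- data.frame(g = rep(letters[1:k], each = n0))
  d$y <- rep(rnorm(k, 0, 1.5), each = n0) + rnorm(k * n0)
  f <- fit_lmm_reml("y", d, random_terms = "g")
  s2b <- f$sigma2[["g"]]; s2e <- f$sigma2[["resid"]]
  ll_hat <- reml_loglik_oneway(d$y, d$g, s2b, s2e)
  expect_equal(ll_hat, f$loglik_reml, tolerance = 1e-4)
  for (fb in c(0.8, 0.9, 1.1, 1.25)) for (fe in c(0.8, 0.9, 1.1, 1.25)) {
    expect_lte(reml_loglik_oneway(d$y, d$g, s2b * fb, s2e * fe),
               ll_hat + 1e-8)
  }
})

test_that("model-spec plumbing rejects bad inputs", {
  d <- data.frame(y = rnorm(10), g = rep(c("a", "b"), 5))
  expect_error(fit_lmm_reml("y", d, random_terms = "nope"), "nope")
  expect_error(fit_lmm_reml("y", data.frame(y = rnorm(4), g = "a"),
                            random_terms = "g"), ">= 2 levels")
  expect_error(fit_lmm_reml("y", d, random_terms = c("g", "g")), "duplicate")
})

test_that("Q_ST closed forms and monotonicity hold", {
  expect_equal(compute_qst(0, 1), 0)
  expect_equal(compute_qst(1, 0), 1)
  expect_equal(compute_qst(1, 1), 1 / 3)
  expect_equal(compute_qst(2, 1), 0.5)
  expect_warning(q0 <- compute_qst(0, 0), "undefined")
  expect_true(is.na(q0))

  gb <- seq(0.1, 5, length.out = 20)
  q_gb <- compute_qst(gb, 1)
  expect_true(all(diff(q_gb) > 0))          # increasing in sigma2_GB
  q_gw <- compute_qst(1, gb)
  expect_true(all(diff(q_gw) < 0))          # decreasing in sigma2_GW
  expect_true(all(q_gb >= 0 & q_gb <= 1))
})

test_that("contrast groups map labels to the right accession sets", {
  pp <- toy_passports(3)
  hl <- qst_contrast_groups(pp, "High:Low")
  expect_equal(length(hl$group1), 6L)
  expect_true(all(grepl("High", hl$group1)))
  ms <- qst_contrast_groups(pp, "Mex:SA")
  expect_true(all(grepl("^Mex", ms$group1)))
  mm <- qst_contrast_groups(pp, "MexHigh:MexLow")
  expect_setequal(mm$group1, pp$accession_id[pp$population == "MexHigh"])
  expect_error(qst_contrast_groups(pp, "High:Low:Extra"), "A:B")
})

test_that("qst_test returns a coherent row and skips degenerate traits", {
  set.seed(17)
  d <- simulate_qst_dataset(n_pops = 2, n_lines_per_pop = 20,
                            sigma2_pop = 2, sigma2_line = 1, seed = 17)
  cfg <- sim_config(n_pops = 2, n_lines_per_pop = 20, n_markers = 200,
                    fst_target = 0.05, seed = 17)
  g <- simulate_genotypes(cfg)
  g1 <- unique(d$accession_id[d$population == "Pop1"])
  g2 <- unique(d$accession_id[d$population == "Pop2"])
  r <- qst_test(d, g, g1, g2, label = "Pop1:Pop2")
  expect_equal(r$qst, compute_qst(r$sigma2_GB, r$sigma2_GW))
  expect_equal(r$threshold, r$mean_fst + 2 * r$sd_fst)
  expect_identical(r$significant, r$qst > r$threshold)

  d0 <- d; d0$value <- 1
  expect_warning(r0 <- qst_test(d0, g, g1, g2), "constant")
  expect_null(r0)
  d1 <- d[d$accession_id %in% c(g1[1], g2[1:5]), ]
  expect_warning(r1 <- qst_test(d1, g, g1[1], g2[1:5]), "fewer than 2 lines")
  expect_null(r1)
})

test_that("the trait x contrast scan runs on a synthetic experiment", {
  sim <- default_sim()
  scan <- suppressWarnings(
    qst_fst_scan(sim$pheno, sim$env$passports, sim$geno,
                 traits = c("FITplantveg", "PH")))
  expect_s3_class(scan, "qst_fst_scan")
  expect_equal(nrow(scan), 8L)  # 2 traits x 4 contrasts
  expect_true(all(scan$qst >= 0 & scan$qst <= 1, na.rm = TRUE))
  expect_equal(scan$significant, scan$qst > scan$threshold)
  # the flag is recomputable from the stored fields
  expect_equal(scan$threshold, scan$mean_fst + 2 * scan$sd_fst)
})
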