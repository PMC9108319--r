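## balanced factorial phenotype/passport pair with *zero* latitude-pair
## signal, so the mixed model collapses onto ordinary least squares
ols_fixture <- function(seed = 1, n_pairs = 4, reps = 4) {
  set.seed(seed)
  pp <- toy_passports(n_pairs)
  rows <- expand.grid(accession_id = pp$accession_id, block = 1:2,
                      site_id = GARDENS, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  i <- match(rows$accession_id, pp$accession_id)
  eff <- with(rows, 0.5 * (site_id == "HighSite") +
                0.3 * (pp$continent[i] == "SA") +
                0.8 * (site_id == "HighSite") * (pp$elev_class[i] == "High"))
  pheno <- data.frame(accession_id = rows$accession_id, site_id = rows$site_id,
                      block = rows$block, row_id = seq_len(nrow(rows)),
                      plant_id = NA, level = "plant",
                      Y = eff + rnorm(nrow(rows)))
  list(pheno = pheno, passports = pp)
}

test_that("with zero random variance the fit reproduces OLS fixed effects", {
  fx <- ols_fixture(seed = 2)
  fit <- suppressMessages(fit_gxe_model("Y", fx$pheno, fx$passports))
  d <- build_gxe_data(fx$pheno, fx$passports, "Y")
  ols <- lm(value ~ GARDEN * CONTINENT * ELEVATION + GARDEN:BLOCK, data = d)
  # latitude pairs carry no signal; REML puts their variance at ~0
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_lt(sum(vc$vcov[vc$grp != "Residual"]), 0.05)
  common <- intersect(names(coef(ols)), names(lme4::fixef(fit)))
  expect_gt(length(common), 8)
  expect_equal(lme4::fixef(fit)[common], coef(ols)[common], tolerance = 1e-3)
})

test_that("contrast t-ratios equal the pooled two-sample t when variances vanish", {
  set.seed(11)
  n <- 40
  d <- data.frame(GROUP = rep(c("a", "b"), each = n),
                  NOISE = rep(sprintf("n%02d", 1:8), times = 10))
  ## residuals centred within every NOISE level so the random-intercept
  ## variance is exactly zero (boundary fit), collapsing the model onto the
  ## two-sample problem
  e <- rnorm(2 * n)
  e <- e - ave(e, d$NOISE)
  d$y <- 0.7 * (d$GROUP == "b") + e
  fit <- suppressMessages(
    lmerTest::lmer(y ~ GROUP + (1 | NOISE), data = d))
  pc <- pairwise_contrast(fit, "GROUP")
  tt <- t.test(y ~ GROUP, data = d, var.equal = TRUE)
  expect_lt(abs(abs(pc$t_ratio) - abs(tt$statistic)), 1e-6)
  expect_lt(abs(pc$df - (2 * n - 2)), 1)
  expect_lt(abs(pc$p_value - tt$p.value), 1e-6)
})

test_that("marginal means equal sample means on balanced designs", {
  set.seed(21)
  d <- data.frame(GROUP = rep(c("a", "b"), each = 30),
                  NOISE = rep(sprintf("n%02d", 1:6), times = 10))
  d$y <- rnorm(60, mean = c(2, 5)[as.integer(factor(d$GROUP))])
  fit <- suppressMessages(lmerTest::lmer(y ~ GROUP + (1 | NOISE), data = d))
  mm <- marginal_means(fit, specs = ~ GROUP)
  sm <- tapply(d$y, d$GROUP, mean)
  expect_equal(mm$emmean, as.numeric(sm[as.character(mm$GROUP)]),
               tolerance = 1e-8)

  # intercept-only grid: grand mean
  mm1 <- marginal_means(fit, specs = ~ 1)
  expect_equal(mm1$emmean, mean(sm), tolerance = 1e-6)
})

test_that("the twelve contrast families are well-formed on synthetic data", {
  sim <- default_sim()
  fit <- fit_gxe_model("FITplantveg", sim$pheno, sim$env$passports)
  ct <- contrast_tratios(fit)
  expect_equal(nrow(ct), 12L)
  expect_equal(as.integer(table(ct$family)[c("garden", "continent", "elevation")]),
               c(4L, 4L, 4L))
  # t * se = estimate, Bonferroni flag is pure in p, df within bounds
  expect_equal(ct$t_ratio * ct$se, ct$estimate, tolerance = 1e-8)
  expect_identical(ct$significant_bonferroni, ct$p_value < 0.0125)
  n_obs <- sum(!is.na(sim$pheno$FITplantveg))
  expect_true(all(ct$df >= 1 & ct$df <= n_obs))
  # strong simulated home-site advantage: garden contrasts have opposite
  # signs for High and Low populations
  g <- setNames(ct$estimate, ct$contrast_id)
  expect_gt(g[["garden|Mex.High"]], 0)
  expect_lt(g[["garden|Mex.Low"]], 0)
})

test_that("an additive (no G x E) truth gives a null three-way interaction", {
  ## fixed effects additive in garden and elevation; interaction estimates
  ## should scatter around zero across replicates
  est <- vapply(1:8, function(r) {
    fx <- ols_fixture(seed = 100 + r)
    d <- build_gxe_data(fx$pheno, fx$passports, "Y")
    i <- match(fx$pheno$accession_id, fx$passports$accession_id)
    fx$pheno$Y <- 0.5 * (fx$pheno$site_id == "HighSite") +
      0.4 * (fx$passports$elev_class[i] == "High") + rnorm(nrow(fx$pheno))
    fit <- suppressMessages(fit_gxe_model("Y", fx$pheno, fx$passports))
    unname(lme4::fixef(fit)[["GARDENHighSite:CONTINENTSA:ELEVATIONHigh"]])
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)) + 0.05)
})

test_that("reaction norms match direct cell averages and flag crossing", {
  sim <- default_sim()
  rn <- reaction_norms(sim$pheno, sim$env$passports,
                       traits = c("FITplantveg", "PH"))
  cc <- rn$cells[rn$cells$trait == "PH" & rn$cells$population == "MexHigh" &
                   rn$cells$site_id == "HighSite", ]
  i <- match(sim$pheno$accession_id, sim$env$passports$accession_id)
  direct <- sim$pheno$PH[sim$env$passports$population[i] == "MexHigh" &
                           sim$pheno$site_id == "HighSite"]
  expect_equal(cc$mean, mean(direct, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(cc$sd, sd(direct[!is.na(direct)]), tolerance = 1e-12)

  # constant trait: no crossing anywhere
  ph2 <- sim$pheno
  ph2$CONST <- ifelse(ph2$level == "plant", 1, NA)
  rn2 <- reaction_norms(ph2, sim$env$passports, traits = "CONST")
  expect_false(any(rn2$crossing$crossing))
})

test_that("Bonferroni helper gives the 0.05/4 per-test level", {
  expect_identical(bonferroni_alpha(), 0.0125)
  expect_identical(bonferroni_alpha(0.05, 4), 0.05 / 4)
})
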