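test_that("simulated design matches the field layout", {
  sim <- default_sim()
  pp <- sim$env$passports
  expect_equal(nrow(pp), 120L)
  expect_equal(sum(pp$elev_class == "High" & pp$elevation > 2000), 60L)
  expect_equal(sum(pp$elev_class == "Low" & pp$elevation < 1000), 60L)
  pair_tab <- table(pp$latitude_pair_id, pp$elev_class)
  expect_true(all(pair_tab == 1L))  # one High and one Low per pair
  expect_equal(sort(unique(pp$population)), sort(POPULATIONS))

  sites <- sim$env$sites
  expect_equal(sort(sites$elevation), c(54, 2852))
  expect_true(all(c("annual_mean_temp", "annual_precip") %in% names(sites)))

  expect_equal(dim(sim$geno$dosages), c(120L, 500L))
  # row records: gardens x blocks x accessions; two tagged plants per row
  expect_equal(sum(sim$pheno$level == "row"), 2L * 2L * 120L)
  expect_equal(sum(sim$pheno$level == "plant"), 2L * 2L * 120L * 2L)
})

test_that("identical (config, seed) reproduce byte-identical files", {
  cfg <- sim_config(seed = 5, n_markers = 40)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_experiment(cfg, d1)
  s2 <- simulate_experiment(cfg, d2)
  for (k in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[k]]), readLines(s2$paths[[k]]),
                     info = k)
  }
  # and a different seed changes the data
  s3 <- simulate_experiment(sim_config(seed = 6, n_markers = 40),
                            withr::local_tempdir())
  expect_false(identical(readLines(s1$paths$phenotypes),
                         readLines(s3$paths$phenotypes)))
})

test_that("Balding-Nichols genotypes realize the target differentiation", {
  mean_fst <- function(seed, f) {
    cfg <- sim_config(n_pops = 2, n_lines_per_pop = 100, n_markers = 500,
                      fst_target = f, seed = seed, missing_rate = 0)
    g <- simulate_genotypes(cfg)
    pops <- substr(g$accession_ids, 1, 4)
    snps <- hudson_fst_per_snp(g, g$accession_ids[pops == "Pop1"],
                               g$accession_ids[pops == "Pop2"])
    mean(snps$fst, na.rm = TRUE)
  }
  expect_lt(abs(mean_fst(21, f = 0)), 0.01)
  ## per-SNP averaging sits slightly below the Balding-Nichols parameter
  ## (mean-of-ratios vs ratio-of-averages); average three draws so the test
  ## reflects the estimator's distribution rather than one tail realization
  expect_lt(abs(mean(vapply(22:24, mean_fst, numeric(1), f = 0.10)) - 0.10),
            0.02)
})

test_that("configured G x E cell offsets reproduce the crossing pattern", {
  gxe <- matrix(c(-2, 2,  2, -2, -2, 2,  2, -2), nrow = 4, byrow = TRUE,
                dimnames = list(POPULATIONS, GARDENS))
  cfg <- sim_config(seed = 9, n_markers = 10, gxe_matrix = gxe)
  env <- simulate_environment(cfg)
  ph <- simulate_phenotypes(cfg, env$passports, env$sites)
  d <- derive_traits(ph$pheno)
  rn <- reaction_norms(d, env$passports, traits = "FITplantveg")
  cells <- rn$cells
  m <- tapply(cells$mean, list(cells$population, cells$site_id), mean)
  # populations favoured at HighSite beat the others there, and vice versa
  expect_gt(m["MexHigh", "HighSite"], m["MexLow", "HighSite"])
  expect_gt(m["MexLow", "LowSite"], m["MexHigh", "LowSite"])
  cr <- rn$crossing
  expect_true(cr$crossing[cr$pop1 == "MexHigh" & cr$pop2 == "MexLow"])
})

test_that("negative env_decay lowers fitness at larger elevational distance", {
  cfg <- sim_config(seed = 13, n_markers = 10, env_decay = -0.04)
  env <- simulate_environment(cfg)
  ph <- simulate_phenotypes(cfg, env$passports, env$sites)
  d <- derive_traits(ph$pheno)
  fit <- fitness_by_accession_garden(d)
  ge <- setNames(env$sites$elevation, env$sites$site_id)
  oe <- setNames(env$passports$elevation, env$passports$accession_id)
  dist2 <- ((ge[fit$site_id] - oe[fit$accession_id]) / 1000)^2
  expect_lt(cor(dist2, fit$fitness, method = "spearman"), -0.3)
})

test_that("zero variances and zero G x E make traits cell-deterministic", {
  cfg <- sim_config(seed = 3, n_markers = 10,
                    variance_spec = list(pop = 0, line = 0, lat = 0,
                                         latgarden = 0, block = 0, resid = 0),
                    gxe_matrix = matrix(0, 4, 2,
                                        dimnames = list(POPULATIONS, GARDENS)),
                    env_decay = 0)
  env <- simulate_environment(cfg)
  ph <- simulate_phenotypes(cfg, env$passports, env$sites)
  pl <- ph$pheno[ph$pheno$level == "plant", ]
  pop <- env$passports$population[match(pl$accession_id,
                                        env$passports$accession_id)]
  for (tr in c("PH", "delta13C")) {
    spread <- tapply(pl[[tr]], paste(pop, pl$site_id),
                     function(x) diff(range(x, na.rm = TRUE)))
    expect_true(all(spread == 0), info = tr)
  }
})

test_that("variance-partition generator recovers configured components", {
  ## replicate-based recovery: mean estimate within 3 Monte-Carlo SEs
  n_rep <- 20
  est <- t(vapply(seq_len(n_rep), function(r) {
    d <- simulate_qst_dataset(sigma2_pop = 2, sigma2_line = 1,
                              sigma2_resid = 1, seed = 100 + r)
    d$GB <- paste(d$site_id, d$block)
    f <- fit_lmm_reml("value", d,
                      random_terms = c("population", "accession_id",
                                      "site_id", "GB"))
    c(pop = unname(f$sigma2[["population"]]),
      line = unname(f$sigma2[["accession_id"]]),
      resid = unname(f$sigma2[["resid"]]))
  }, numeric(3)))
  for (k in c("pop", "line", "resid")) {
    truth <- c(pop = 2, line = 1, resid = 1)[[k]]
    se <- sd(est[, k]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, k]) - truth), 3 * se + 1e-8, label = k)
  }
})
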