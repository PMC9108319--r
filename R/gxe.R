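#' Assemble the modelling frame for the G x E analysis of one trait
#'
#' Joins phenotype records with passports and builds the factors of the full
#' model: GARDEN (LowSite/HighSite), CONTINENT (Mex/SA), ELEVATION (Low/High
#' population class), BLOCK, and LATPAIR (the 1-degree latitude pair
#' identifier used as the accession grouping). Records with a missing trait
#' value are dropped.
#'
#' @param pheno phenotype table (derived traits included as needed).
#' @param passports passport table.
#' @param trait trait column name.
#' @return data.frame with `value` and the model factors.
#' @export
build_gxe_data <- function(pheno, passports, trait) {
  stopifnot(trait %in% names(pheno))
  d <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  i <- match(d$accession_id, passports$accession_id)
  if (anyNA(i)) stop("phenotype records reference accessions absent from passports")
  data.frame(
    value = d[[trait]],
    GARDEN = factor(d$site_id, levels = GARDENS),
    CONTINENT = factor(passports$continent[i], levels = c("Mex", "SA")),
    ELEVATION = factor(passports$elev_class[i], levels = c("Low", "High")),
    BLOCK = factor(d$block),
    LATPAIR = factor(passports$latitude_pair_id[i]),
    accession_id = d$accession_id,
    stringsAsFactors = FALSE)
}

#' Fit the full G x E mixed model for one trait
#'
#' REML fit of
#' `TRAIT ~ GARDEN * CONTINENT * ELEVATION + GARDEN:BLOCK +
#'  (1|LATPAIR) + (1|LATPAIR:GARDEN)`:
#' all three treatment factors and their interactions as fixed effects,
#' block nested in garden, and random intercepts for the latitude pair and
#' its interaction with garden.
#'
#' @param trait trait column name.
#' @param pheno phenotype table.
#' @param passports passport table.
#' @return a `lmerModLmerTest` fit with attribute `"trait"`.
#' @export
fit_gxe_model <- function(trait, pheno, passports) {
  d <- build_gxe_data(pheno, passports, trait)
  for (f in c("GARDEN", "CONTINENT", "ELEVATION")) {
    if (nlevels(droplevels(d[[f]])) < 2) {
      stop(sprintf("factor %s does not have both levels in the data", f))
    }
  }
  if (nlevels(droplevels(d$LATPAIR)) < 2) stop("need >= 2 latitude pairs")
  fit <- lmerTest::lmer(
    value ~ GARDEN * CONTINENT * ELEVATION + GARDEN:BLOCK +
      (1 | LATPAIR) + (1 | LATPAIR:GARDEN),
    data = d, REML = TRUE)
  attr(fit, "trait") <- trait
  fit
}

#' Estimated marginal means over the treatment grid
#'
#' Model-based cell means for the GARDEN x CONTINENT x ELEVATION grid,
#' averaging over BLOCK within GARDEN with equal weights (the usual
#' least-squares-means semantics), with standard errors from the
#' fixed-effect covariance and Satterthwaite degrees of freedom.
#'
#' @param fit a fit from [fit_gxe_model()] (or any lmer fit with factors).
#' @param cell optional named list of factor levels to select a single cell,
#'   e.g. `list(GARDEN = "HighSite", CONTINENT = "Mex", ELEVATION = "High")`.
#' @param specs emmeans specification when `fit` is not a G x E fit.
#' @return data.frame of cell means with `emmean`, `SE`, `df`.
#' @export
marginal_means <- function(fit, cell = NULL, specs = ~ GARDEN * CONTINENT * ELEVATION) {
  em <- emmeans::emmeans(fit, specs, lmer.df = "satterthwaite")
  out <- as.data.frame(summary(em))
  if (!is.null(cell)) {
    for (f in names(cell)) out <- out[out[[f]] == cell[[f]], , drop = FALSE]
  }
  out
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha familywise error rate.
#' @param m number of comparisons in the family (4: the tests of each trait
#'   within each contrast family).
#' @return per-test alpha (0.05/4 = 0.0125 at the defaults).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 4) alpha / m

## The twelve contrast columns: garden effect within each population,
## continent effect within garden x elevation, elevation effect within
## garden x continent. Signs: HighSite - LowSite, Mex - SA, High - Low.
gxe_contrast_table <- function() {
  grid <- expand.grid(GARDEN = GARDENS, CONTINENT = c("Mex", "SA"),
                      ELEVATION = c("Low", "High"), stringsAsFactors = FALSE)
  cells <- paste(grid$GARDEN, grid$CONTINENT, grid$ELEVATION, sep = ".")
  cvec <- function(plus, minus) {
    v <- setNames(rep(0, nrow(grid)), cells)
    v[plus] <- 1; v[minus] <- -1
    v
  }
  out <- list()
  for (co in c("Mex", "SA")) for (el in c("High", "Low")) {
    out[[sprintf("garden|%s.%s", co, el)]] <- list(
      family = "garden",
      w = cvec(paste("HighSite", co, el, sep = "."),
               paste("LowSite", co, el, sep = ".")))
  }
  for (ga in GARDENS) for (el in c("High", "Low")) {
    out[[sprintf("continent|%s.%s", ga, el)]] <- list(
      family = "continent",
      w = cvec(paste(ga, "Mex", el, sep = "."),
               paste(ga, "SA", el, sep = ".")))
  }
  for (ga in GARDENS) for (co in c("Mex", "SA")) {
    out[[sprintf("elevation|%s.%s", ga, co)]] <- list(
      family = "elevation",
      w = cvec(paste(ga, co, "High", sep = "."),
               paste(ga, co, "Low", sep = ".")))
  }
  out
}

#' Treatment-effect t-ratios for the reaction-norm contrast families
#'
#' Computes, per trait, the twelve cell contrasts of the reciprocal
#' transplant: between-garden within each population, between-continent
#' within garden and elevation, and between-population (elevation) within
#' garden and continent. Estimates are differences of estimated marginal
#' means; t-ratios are estimate/SE with Satterthwaite degrees of freedom,
#' and the Bonferroni flag applies the per-test level 0.05/4 = 0.0125
#' (four tests of each trait within each contrast family).
#'
#' @param fit a fit from [fit_gxe_model()].
#' @param alpha familywise error rate before correction.
#' @param family_size comparisons per family for the Bonferroni correction.
#' @return data.frame with `trait`, `family`, `contrast_id`, `estimate`,
#'   `se`, `df`, `t_ratio`, `p_value`, `significant_bonferroni`.
#' @export
contrast_tratios <- function(fit, alpha = 0.05, family_size = 4) {
  em <- emmeans::emmeans(fit, ~ GARDEN * CONTINENT * ELEVATION,
                         lmer.df = "satterthwaite")
  grid <- as.data.frame(em)[, c("GARDEN", "CONTINENT", "ELEVATION")]
  key <- paste(grid$GARDEN, grid$CONTINENT, grid$ELEVATION, sep = ".")
  ctab <- gxe_contrast_table()
  meth <- lapply(ctab, function(x) unname(x$w[key]))
  cs <- summary(emmeans::contrast(em, method = meth), adjust = "none")
  data.frame(
    trait = attr(fit, "trait") %||% NA_character_,
    family = vapply(ctab, `[[`, "", "family"),
    contrast_id = names(ctab),
    estimate = cs$estimate, se = cs$SE, df = cs$df,
    t_ratio = cs$t.ratio, p_value = cs$p.value,
    significant_bonferroni = cs$p.value < bonferroni_alpha(alpha, family_size),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-level pairwise contrast for a simple mixed model
#'
#' Convenience wrapper giving the estimated difference, Satterthwaite t and
#' p for a single two-level factor in any lmer fit (used e.g. to check the
#' contrast machinery against the pooled two-sample t-statistic).
#'
#' @param fit an lmer fit.
#' @param factor_name name of a two-level factor in the model.
#' @return one-row data.frame with `estimate`, `se`, `df`, `t_ratio`,
#'   `p_value`.
#' @export
pairwise_contrast <- function(fit, factor_name) {
  em <- emmeans::emmeans(fit, reformulate(factor_name),
                         lmer.df = "satterthwaite")
  cs <- summary(emmeans::contrast(em, "pairwise"), adjust = "none")
  data.frame(estimate = cs$estimate[1], se = cs$SE[1], df = cs$df[1],
             t_ratio = cs$t.ratio[1], p_value = cs$p.value[1])
}

#' Population x garden reaction norms
#'
#' Cell means and standard deviations per trait for the population x garden
#' grid, plus a crossing indicator per population pair: TRUE when the sign
#' of the between-population difference changes between the two gardens
#' (the reaction norms cross, the graphical signature of local adaptation
#' when shown by fitness traits).
#'
#' @param pheno phenotype table processed by [derive_traits()].
#' @param passports passport table.
#' @param traits trait columns to summarise.
#' @return list with `cells` (trait x population x garden means/SDs/n) and
#'   `crossing` (trait x population pair indicator).
#' @export
reaction_norms <- function(pheno, passports,
                           traits = c("FITplant", "FITplantveg")) {
  i <- match(pheno$accession_id, passports$accession_id)
  pop <- passports$population[i]
  cells <- list(); crossing <- list()
  pops <- sort(unique(pop))
  for (tr in traits) {
    ok <- !is.na(pheno[[tr]])
    if (!any(ok)) { warning(sprintf("trait %s has no data", tr)); next }
    d <- data.frame(value = pheno[[tr]][ok], population = pop[ok],
                    site_id = pheno$site_id[ok])
    agg <- aggregate(value ~ population + site_id, data = d,
                     FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
    cc <- data.frame(trait = tr, population = agg$population,
                     site_id = agg$site_id,
                     mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                     n = agg$value[, "n"], stringsAsFactors = FALSE)
    cells[[tr]] <- cc
    m <- tapply(cc$mean, list(cc$population, cc$site_id), mean)
    if (ncol(m) == 2 && !anyNA(m)) {
      prs <- utils::combn(pops, 2)
      crossing[[tr]] <- data.frame(
        trait = tr, pop1 = prs[1, ], pop2 = prs[2, ],
        crossing = apply(prs, 2, function(p) {
          d1 <- m[p[1], 1] - m[p[2], 1]
          d2 <- m[p[1], 2] - m[p[2], 2]
          is.finite(d1) && is.finite(d2) && d1 * d2 < 0
        }), stringsAsFactors = FALSE)
    }
  }
  list(cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
       crossing = do.call(rbind, c(crossing, list(make.row.names = FALSE))))
}
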