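#' REML variance components for a random-intercept mixed model
#'
#' Fits `response ~ fixed_terms + (1|g)` for each grouping factor `g` in
#' `random_terms` by restricted maximum likelihood (lme4 backend; variance
#' estimates are bounded below by zero at the boundary). Interaction
#' groupings may be written `"A:B"`. Boundary (singular) fits are
#' converged fits with a zero variance component, not failures.
#'
#' @param response name of the (numeric) response column.
#' @param data model data.frame.
#' @param random_terms character vector of grouping factors, each fitted as
#'   an independent random intercept.
#' @param fixed_terms optional character vector of fixed-effect terms
#'   (default intercept only).
#' @return list of class `lmm_varcomp` with `sigma2` (named vector of
#'   variance components including `resid`), `se` (NA; use replicate-based
#'   standard errors for recovery checks), `fixef`, `vcov_fixef`,
#'   `loglik_reml`, `converged` and the underlying `fit`.
#' @export
fit_lmm_reml <- function(response, data, random_terms,
                         fixed_terms = character(0)) {
  stopifnot(length(random_terms) >= 1, response %in% names(data))
  if (anyDuplicated(c(fixed_terms, random_terms))) stop("duplicate model terms")
  for (g in unique(unlist(strsplit(random_terms, ":", fixed = TRUE)))) {
    if (!g %in% names(data)) stop(sprintf("grouping factor '%s' not in data", g))
    if (length(unique(na.omit(data[[g]]))) < 2) {
      stop(sprintf("grouping factor '%s' needs >= 2 levels", g))
    }
  }
  rhs <- c(if (length(fixed_terms)) fixed_terms else "1",
           paste0("(1|", random_terms, ")"))
  form <- reformulate(rhs, response = response)
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "resid", vc$grp))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(list(sigma2 = sigma2,
                 se = setNames(rep(NA_real_, length(sigma2)), names(sigma2)),
                 fixef = lme4::fixef(fit),
                 vcov_fixef = as.matrix(vcov(fit)),
                 loglik_reml = as.numeric(stats::logLik(fit)),
                 converged = conv, fit = fit),
            class = "lmm_varcomp")
}

#' @export
print.lmm_varcomp <- function(x, ...) {
  cat("<lmm_varcomp> REML variance components\n")
  print(round(x$sigma2, 6))
  cat(sprintf("  REML logLik %.3f, converged: %s\n", x$loglik_reml, x$converged))
  invisible(x)
}

#' Quantitative trait differentiation Q_ST
#'
#' `Q_ST = sigma2_GB / (sigma2_GB + 2 * sigma2_GW)` where `sigma2_GB` is the
#' between-population and `sigma2_GW` the within-population (accession line)
#' genetic variance component. The line variance is used directly
#' (broad-sense, heritability 1); `h2` rescales it if a heritability
#' correction is wanted.
#'
#' @param sigma2_GB between-population variance component (>= 0).
#' @param sigma2_GW within-population line variance component (>= 0).
#' @param h2 heritability scaling applied to `sigma2_GW` (default 1, i.e.
#'   none).
#' @return Q_ST in \[0, 1\], or NA with a warning when both components are 0.
#' @export
compute_qst <- function(sigma2_GB, sigma2_GW, h2 = 1) {
  stopifnot(all(sigma2_GB >= 0, na.rm = TRUE), all(sigma2_GW >= 0, na.rm = TRUE),
            h2 > 0)
  both0 <- !is.na(sigma2_GB) & !is.na(sigma2_GW) & sigma2_GB == 0 & sigma2_GW == 0
  if (any(both0)) warning("Q_ST undefined where both variance components are 0")
  out <- sigma2_GB / (sigma2_GB + 2 * sigma2_GW / h2)
  out[both0] <- NA_real_
  out
}

#' Accession groups for the four population contrasts
#'
#' Maps a contrast label to the two accession sets it compares: pooled
#' highland vs lowland, pooled Mexican vs South American, or the
#' within-continent highland/lowland pairs.
#'
#' @param passports passport table.
#' @param contrast one of `"High:Low"`, `"Mex:SA"`, `"MexHigh:MexLow"`,
#'   `"SAHigh:SALow"`.
#' @return list with `group1`, `group2` (accession ids) and `label`.
#' @export
qst_contrast_groups <- function(passports, contrast) {
  side_ids <- function(side) {
    switch(side,
      High = passports$accession_id[passports$elev_class == "High"],
      Low = passports$accession_id[passports$elev_class == "Low"],
      Mex = passports$accession_id[passports$continent == "Mex"],
      SA = passports$accession_id[passports$continent == "SA"],
      passports$accession_id[passports$population == side])
  }
  sides <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("contrast must be 'A:B'")
  g1 <- side_ids(sides[1]); g2 <- side_ids(sides[2])
  if (!length(g1) || !length(g2)) stop(sprintf("contrast '%s' selects no accessions", contrast))
  list(group1 = g1, group2 = g2, label = contrast)
}

#' Q_ST vs F_ST for one trait and one contrast
#'
#' Fits the variance-partition model
#' `value ~ 1 + (1|POPULATION) + (1|LINE) + (1|GARDEN) + (1|GARDEN:BLOCK)`
#' on the observations belonging to the two contrast groups (the contrast
#' side is the POPULATION grouping), computes Q_ST from the
#' between-population and line components, computes the per-SNP Hudson F_ST
#' summary between the same two accession sets, and flags significance by
#' the point rule `Q_ST > mean F_ST + 2 SD(F_ST)`.
#'
#' @param df data.frame with columns `value`, `accession_id`, `site_id`,
#'   `block` (one row per observation).
#' @param geno a [genotype_matrix()], or NULL to skip the F_ST side.
#' @param group1,group2 accession id sets defining the contrast.
#' @param label contrast label for the output.
#' @return one-row data.frame with qst, variance components, F_ST summary
#'   fields and the significance flag, or NULL when the model is not
#'   estimable (constant trait or too few lines per side).
#' @export
qst_test <- function(df, geno, group1, group2, label = "custom") {
  df <- df[!is.na(df$value) & df$accession_id %in% c(group1, group2), , drop = FALSE]
  df$SIDE <- ifelse(df$accession_id %in% group1, "g1", "g2")
  df$LINE <- df$accession_id
  df$GB <- paste(df$site_id, df$block, sep = ":")
  n_lines <- tapply(df$LINE, df$SIDE, function(x) length(unique(x)))
  if (length(n_lines) < 2 || any(n_lines < 2)) {
    warning(sprintf("contrast %s: fewer than 2 lines per side; skipped", label))
    return(NULL)
  }
  if (var(df$value) == 0) {
    warning(sprintf("contrast %s: constant trait; skipped", label))
    return(NULL)
  }
  vcfit <- tryCatch(
    fit_lmm_reml("value", df,
                 random_terms = c("SIDE", "LINE", "site_id", "GB")),
    error = function(e) {
      warning(sprintf("contrast %s: model fit failed (%s)", label,
                      conditionMessage(e)))
      NULL
    })
  if (is.null(vcfit)) return(NULL)
  s2 <- vcfit$sigma2
  qst <- suppressWarnings(compute_qst(s2[["SIDE"]], s2[["LINE"]]))

  fs <- NULL
  if (!is.null(geno)) {
    snps <- hudson_fst_per_snp(geno,
                               intersect(group1, geno$accession_ids),
                               intersect(group2, geno$accession_ids))
    fs <- fst_summary(snps)
  }
  data.frame(contrast = label, qst = unname(qst),
             sigma2_GB = unname(s2[["SIDE"]]), sigma2_GW = unname(s2[["LINE"]]),
             mean_fst = fs$mean_fst %||% NA_real_,
             sd_fst = fs$sd_fst %||% NA_real_,
             threshold = fs$threshold %||% NA_real_,
             n_snps_used = fs$n_snps_used %||% NA_integer_,
             significant = if (is.null(fs) || is.na(qst)) NA else qst > fs$threshold,
             stringsAsFactors = FALSE)
}

#' Q_ST vs F_ST scan over traits and population contrasts
#'
#' Runs [qst_test()] for every trait x contrast combination. Trait values
#' are taken at their native measurement level; traits with no variation or
#' too few lines in a contrast are skipped with a warning.
#'
#' @param pheno phenotype table processed by [derive_traits()].
#' @param passports passport table.
#' @param geno a [genotype_matrix()] (or NULL: Q_ST only, no significance).
#' @param traits character vector of trait columns to scan.
#' @param contrasts contrast labels understood by [qst_contrast_groups()].
#' @return data.frame of class `qst_fst_scan`, one row per trait x contrast.
#' @export
qst_fst_scan <- function(pheno, passports, geno = NULL,
                         traits = c("FITplantveg", "PH", "DTS", "delta13C"),
                         contrasts = c("High:Low", "Mex:SA",
                                       "MexHigh:MexLow", "SAHigh:SALow")) {
  ## F_ST summaries depend only on the contrast; compute once
  grp <- lapply(contrasts, qst_contrast_groups, passports = passports)
  names(grp) <- contrasts
  out <- list()
  for (tr in traits) {
    if (!tr %in% names(pheno)) {
      warning(sprintf("trait %s not in phenotype table; skipped", tr))
      next
    }
    d <- pheno[!is.na(pheno[[tr]]),
               c("accession_id", "site_id", "block", tr), drop = FALSE]
    names(d)[4] <- "value"
    for (ct in contrasts) {
      res <- qst_test(d, geno, grp[[ct]]$group1, grp[[ct]]$group2, label = ct)
      if (!is.null(res)) {
        res <- cbind(data.frame(trait = tr, stringsAsFactors = FALSE), res)
        out[[length(out) + 1L]] <- res
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("qst_fst_scan", class(res))
  res
}
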