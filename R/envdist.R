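#' Environmental distance between a garden and an accession origin
#'
#' `DISTANCE = Value_GARDEN - Value_ORIGIN`, per environmental variable.
#' Missing values propagate.
#'
#' @param origin_value environmental value at the accession origin.
#' @param garden_value environmental value at the common-garden site.
#' @return signed distance in the variable's units.
#' @export
env_distance <- function(origin_value, garden_value) garden_value - origin_value

#' Quadratic fitness-decay test against environmental distance
#'
#' Two-stage regression: (1) fitness is regressed linearly on distance,
#' absorbing unequal mean fitness between gardens; (2) the stage-1 residuals
#' `e` are fitted with the quadratic model `e ~ DISTANCE + DISTANCE^2`. A
#' significantly negative quadratic coefficient (two-sided t-test) indicates
#' fitness decaying as transplant distance grows in either direction; `r2`
#' is the proportion of residual variance explained by the quadratic model.
#'
#' @param fitness numeric fitness values (one per accession x garden).
#' @param distance environmental distances, same length.
#' @return list of class `envdist_result` with `quad_coef`, `t_value`,
#'   `p_value`, `r2`, `n`, the stage-1 `residuals` and the stage-2 fit.
#' @export
quadratic_residual_test <- function(fitness, distance) {
  ok <- complete.cases(fitness, distance)
  fitness <- fitness[ok]; distance <- distance[ok]
  if (length(fitness) < 4) stop("need at least 4 complete observations")
  if (var(distance) == 0) stop("distances are degenerate (all equal)")
  stage1 <- lm(fitness ~ distance)
  e <- resid(stage1)
  d2 <- distance^2
  if (length(unique(round(d2, 12))) < 2 ||
      qr(cbind(1, distance, d2))$rank < 3) {
    stop("quadratic term is aliased; test inestimable")
  }
  stage2 <- lm(e ~ distance + d2)
  sm <- summary(stage2)
  co <- coef(sm)["d2", ]
  structure(list(quad_coef = unname(co["Estimate"]),
                 t_value = unname(co["t value"]),
                 p_value = unname(co["Pr(>|t|)"]),
                 r2 = sm$r.squared, n = length(fitness),
                 residuals = e, fit = stage2),
            class = "envdist_result")
}

#' @export
print.envdist_result <- function(x, ...) {
  cat(sprintf(
    "<envdist_result> quadratic coef %.4g (t = %.3f, p = %.3g), R2 = %.3f, n = %d\n",
    x$quad_coef, x$t_value, x$p_value, x$r2, x$n))
  invisible(x)
}

#' Fitness-decay scan over environmental variables
#'
#' Builds, for every accession x garden combination, the distance between
#' the garden's value and the origin's value of each environmental variable,
#' and runs [quadratic_residual_test()] per variable against mean vegetative
#' fitness. Variables are tested independently; no multiplicity correction
#' is applied by default (p-values are reported per variable), but
#' `p_adjust` passes a method to [stats::p.adjust()].
#'
#' @param fitness data.frame from [fitness_by_accession_garden()].
#' @param origin_env per-accession environment table (column `accession_id`
#'   plus variables).
#' @param sites garden-site table (column `site_id` plus variables).
#' @param variables environmental variables to scan; defaults to all
#'   variables shared by the two tables.
#' @param p_adjust optional multiple-testing correction method.
#' @return data.frame with one row per variable: `variable`, `quad_coef`,
#'   `t_value`, `p_value`, `r2`, `n`.
#' @export
env_distance_scan <- function(fitness, origin_env, sites, variables = NULL,
                              p_adjust = NULL) {
  shared <- intersect(names(origin_env), names(sites))
  shared <- setdiff(shared, c("accession_id", "site_id", "location_id", "year"))
  variables <- variables %||% shared
  miss <- setdiff(variables, shared)
  if (length(miss)) stop(sprintf("variables not in both tables: %s",
                                 paste(miss, collapse = ", ")))
  io <- match(fitness$accession_id, origin_env$accession_id)
  ig <- match(fitness$site_id, sites$site_id)
  out <- lapply(variables, function(v) {
    dist <- env_distance(origin_env[[v]][io], sites[[v]][ig])
    r <- quadratic_residual_test(fitness$fitness, dist)
    data.frame(variable = v, quad_coef = r$quad_coef, t_value = r$t_value,
               p_value = r$p_value, r2 = r$r2, n = r$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(p_adjust)) res$p_adjusted <- stats::p.adjust(res$p_value, p_adjust)
  res
}
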