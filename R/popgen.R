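#' Per-SNP Hudson F_ST between two accession groups
#'
#' For each marker, with sample alternate-allele frequencies p1, p2 and
#' allele counts n1, n2 (twice the genotyped individuals; missing calls are
#' excluded per marker), the Hudson estimator with finite-sample correction
#' is
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}.}
#' Per-SNP estimates may be negative and are retained; markers monomorphic
#' across both groups (zero denominator) or with fewer than two genotyped
#' individuals in either group are reported as NA. The estimator is
#' symmetric in the two groups and invariant to swapping reference and
#' alternate allele labels. No minor-allele-frequency filter is applied by
#' default.
#'
#' @param geno a [genotype_matrix()].
#' @param group1,group2 disjoint character vectors of accession ids.
#' @return data.frame with columns `marker_id`, `p1`, `p2`, `n1`, `n2`, `fst`.
#' @export
hudson_fst_per_snp <- function(geno, group1, group2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  i1 <- match(group1, geno$accession_ids)
  i2 <- match(group2, geno$accession_ids)
  if (anyNA(i1) || anyNA(i2)) stop("unknown accession id in group")

  freq <- function(idx) {
    d <- geno$dosages[idx, , drop = FALSE]
    n <- 2 * colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / n
    list(p = p, n = n)
  }
  f1 <- freq(i1); f2 <- freq(i2)
  usable <- f1$n >= 4 & f2$n >= 4
  if (!any(usable)) warning("no marker has >= 2 genotyped individuals in both groups")

  num <- (f1$p - f2$p)^2 - f1$p * (1 - f1$p) / (f1$n - 1) -
    f2$p * (1 - f2$p) / (f2$n - 1)
  den <- f1$p * (1 - f2$p) + f2$p * (1 - f1$p)
  fst <- num / den
  fst[!usable | den == 0] <- NA_real_
  data.frame(marker_id = geno$marker_ids, p1 = unname(f1$p), p2 = unname(f2$p),
             n1 = unname(f1$n), n2 = unname(f2$n), fst = unname(fst))
}

#' Summarise the per-SNP F_ST distribution for the 2-SD rule
#'
#' Mean and sample standard deviation over defined per-SNP values (negative
#' estimates retained), plus the significance threshold mean + 2 SD against
#' which Q_ST values are compared.
#'
#' @param snps output of [hudson_fst_per_snp()] (or any data.frame with an
#'   `fst` column, or a bare numeric vector).
#' @return list of class `fst_summary` with `mean_fst`, `sd_fst`,
#'   `threshold` and `n_snps_used`.
#' @export
fst_summary <- function(snps) {
  x <- if (is.data.frame(snps)) snps$fst else as.numeric(snps)
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least two defined per-SNP F_ST values")
  m <- mean(x); s <- sd(x)
  structure(list(mean_fst = m, sd_fst = s, threshold = m + 2 * s,
                 n_snps_used = length(x)),
            class = "fst_summary")
}

#' @export
print.fst_summary <- function(x, ...) {
  cat(sprintf("<fst_summary> mean %.4f, SD %.4f, mean+2SD %.4f (%d SNPs)\n",
              x$mean_fst, x$sd_fst, x$threshold, x$n_snps_used))
  invisible(x)
}

#' Principal components analysis of the dosage matrix
#'
#' Markers with missing calls are mean-imputed per marker; the matrix is
#' centered (and optionally unit-scaled) and decomposed by singular value
#' decomposition. Percent variance per component comes from the squared
#' singular values.
#'
#' @param geno a [genotype_matrix()].
#' @param n_components number of components to return (clipped with a
#'   warning if larger than the matrix rank allows).
#' @param scale. unit-variance scaling of markers (off by default, the usual
#'   dosage-PCA practice).
#' @return list of class `pca_result` with `scores` (accessions x
#'   components) and `pct_var`.
#' @export
genotype_pca <- function(geno, n_components = 10, scale. = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  x <- geno$dosages
  if (nrow(x) < 2) stop("need at least two accessions")
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  keep <- apply(x, 2, var) > 0 | !scale.
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  kmax <- ncol(pc$x)
  if (n_components > kmax) {
    warning(sprintf("n_components clipped from %d to %d", n_components, kmax))
    n_components <- kmax
  }
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 pct_var = 100 * pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_result")
}
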