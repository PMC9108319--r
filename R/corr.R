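#' Garden-specific Pearson trait correlations
#'
#' Pearson correlations between trait columns, computed on pairwise-complete
#' observations within one common garden. Significance uses the t-test on r,
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom (the test
#' `cor.test` performs); `method = "z"` instead uses the normal test on
#' Fisher's z-transformation with standard error `1/sqrt(n-3)`. delta13C is
#' conventionally excluded from garden-wide correlation analyses because of
#' its restricted sampling; exclude it via `traits`.
#'
#' @param pheno phenotype table (derived traits included as needed).
#' @param traits character vector of trait columns to correlate.
#' @param garden optional `site_id` to subset to one garden.
#' @param method significance method: `"t"` (default) or `"z"`.
#' @return list of class `garden_correlation` with matrices `r`, `p`, `n`
#'   and the `garden` label.
#' @export
garden_correlations <- function(pheno, traits, garden = NULL,
                                method = c("t", "z")) {
  method <- match.arg(method)
  stopifnot(all(traits %in% names(pheno)))
  d <- if (is.null(garden)) pheno else pheno[pheno$site_id == garden, , drop = FALSE]
  x <- as.matrix(d[, traits, drop = FALSE])
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- r
  n <- matrix(0L, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- complete.cases(x[, i], x[, j])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (i == j) {
      r[i, j] <- if (nij > 0 && var(x[ok, i]) > 0) 1 else NA_real_
      p[i, j] <- NA_real_
      next
    }
    if (nij < 4 || var(x[ok, i]) == 0 || var(x[ok, j]) == 0) next
    rij <- cor(x[ok, i], x[ok, j])
    r[i, j] <- r[j, i] <- rij
    pij <- if (abs(rij) >= 1) {
      0
    } else if (method == "t") {
      tt <- rij * sqrt((nij - 2) / (1 - rij^2))
      2 * pt(-abs(tt), df = nij - 2)
    } else {
      z <- atanh(rij) * sqrt(nij - 3)
      2 * pnorm(-abs(z))
    }
    p[i, j] <- p[j, i] <- pij
  }
  structure(list(r = r, p = p, n = n, garden = garden %||% "all",
                 method = method),
            class = "garden_correlation")
}

#' @export
print.garden_correlation <- function(x, ...) {
  cat(sprintf("<garden_correlation> garden %s, %d traits (%s-test)\n",
              x$garden, ncol(x$r), x$method))
  print(round(x$r, 3))
  invisible(x)
}

#' Significance stars for a correlation p-value matrix
#'
#' @param p p-value matrix.
#' @return character matrix with `***` (< 0.001), `**` (< 0.01), `*` (< 0.05).
#' @export
correlation_stars <- function(p) {
  s <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  s[!is.na(p) & p < 0.05] <- "*"
  s[!is.na(p) & p < 0.01] <- "**"
  s[!is.na(p) & p < 0.001] <- "***"
  s
}

#' Between-garden difference of correlation matrices
#'
#' Elementwise `r_High - r_Low`; positive entries mean the trait pair is
#' more positively correlated in the highland garden. Antisymmetric under
#' swapping the gardens.
#'
#' @param high correlation result (or matrix) from the highland garden.
#' @param low correlation result (or matrix) from the lowland garden.
#' @return difference matrix.
#' @export
correlation_difference <- function(high, low) {
  rh <- if (inherits(high, "garden_correlation")) high$r else as.matrix(high)
  rl <- if (inherits(low, "garden_correlation")) low$r else as.matrix(low)
  if (!identical(dimnames(rh), dimnames(rl))) {
    stop("correlation matrices cover different trait sets")
  }
  rh - rl
}

#' Cluster traits by their correlation structure
#'
#' Hierarchical agglomerative clustering (average linkage) on the
#' dissimilarity `1 - r`, cut into `k` clusters; used to identify the top
#' clusters of correlated traits within each garden. Deterministic given
#' the input matrix.
#'
#' @param r complete correlation matrix.
#' @param k number of clusters.
#' @return named integer vector of cluster assignments, with the `hclust`
#'   tree as attribute `"tree"`.
#' @export
cluster_traits <- function(r, k = 5) {
  r <- if (inherits(r, "garden_correlation")) r$r else as.matrix(r)
  if (k > ncol(r)) stop("k exceeds the number of traits")
  if (anyNA(r)) stop("correlation matrix must be complete")
  hc <- hclust(as.dist(1 - r), method = "average")
  out <- cutree(hc, k = k)
  attr(out, "tree") <- hc
  out
}
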