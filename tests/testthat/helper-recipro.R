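## Shared fixtures, all built in code.

## genotype matrix with exact group allele frequencies:
## group sizes 10/10, dosage sums chosen per marker.
geno_from_freqs <- function(sum1, sum2, n_per_group = 10) {
  stopifnot(length(sum1) == length(sum2))
  fill <- function(s) {
    # dosage vector of length n_per_group summing to s (0 <= s <= 2n)
    d <- rep(0, n_per_group)
    d[seq_len(s %/% 2)] <- 2
    if (s %% 2 == 1) d[s %/% 2 + 1] <- 1
    d
  }
  d1 <- sapply(sum1, fill)
  d2 <- sapply(sum2, fill)
  ids <- c(sprintf("A%02d", 1:n_per_group), sprintf("B%02d", 1:n_per_group))
  genotype_matrix(rbind(d1, d2), accession_ids = ids,
                  marker_ids = sprintf("M%03d", seq_along(sum1)))
}

group_a <- function(g) grep("^A", g$accession_ids, value = TRUE)
group_b <- function(g) grep("^B", g$accession_ids, value = TRUE)

## literal one-marker evaluation of the Hudson estimator, kept deliberately
## naive and independent of the package implementation
hudson_oracle <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- 2 * length(d1); n2 <- 2 * length(d2)
  p1 <- sum(d1) / n1; p2 <- sum(d2) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) NA_real_ else num / den
}

## minimal valid passport table: n_pairs latitude pairs per continent
toy_passports <- function(n_pairs = 2) {
  out <- list()
  for (cont in c("Mex", "SA")) for (p in seq_len(n_pairs)) {
    for (cls in c("High", "Low")) {
      out[[length(out) + 1L]] <- data.frame(
        accession_id = sprintf("%s%s%02d", cont, cls, p),
        latitude = ifelse(cont == "Mex", 20, -10) + p,
        longitude = ifelse(cont == "Mex", -100, -70),
        elevation = ifelse(cls == "High", 2500, 500),
        continent = cont, elev_class = cls,
        population = paste0(cont, cls),
        latitude_pair_id = sprintf("%s_P%02d", cont, p))
    }
  }
  do.call(rbind, out)
}

## cached default synthetic experiment shared across test files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_markers = 500)
      env <- simulate_environment(cfg)
      geno <- simulate_genotypes(cfg, env$passports)
      ph <- simulate_phenotypes(cfg, env$passports, env$sites)
      cache <<- list(config = cfg, env = env, geno = geno,
                     pheno = derive_traits(ph$pheno), truth = ph$truth)
    }
    cache
  }
})
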