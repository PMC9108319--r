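#' Construct a genotype matrix object
#'
#' Accession x biallelic-SNP matrix of alternate-allele dosages (0, 1, 2 or
#' NA for missing calls). Markers are columns, accessions rows; internal
#' indexing is 0/1/2 dosage with 1-based VCF coordinates preserved only in
#' marker identifiers.
#'
#' @param dosages numeric matrix of dosages in \{0, 1, 2, NA\}.
#' @param accession_ids character vector, one per row.
#' @param marker_ids character vector, one per column.
#' @return an object of class `genotype_matrix` with elements
#'   `accession_ids`, `marker_ids` and `dosages`.
#' @export
genotype_matrix <- function(dosages,
                            accession_ids = rownames(dosages),
                            marker_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(accession_ids)) accession_ids <- paste0("ACC", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(dosages)))
  stopifnot(length(accession_ids) == nrow(dosages),
            length(marker_ids) == ncol(dosages))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(accession_ids, marker_ids)
  structure(list(accession_ids = as.character(accession_ids),
                 marker_ids = as.character(marker_ids),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("<genotype_matrix> %d accessions x %d markers (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Assemble a dataset object from its component tables
#'
#' @param pheno phenotype record table (see [read_phenotypes()]).
#' @param passports accession passport table.
#' @param geno optional [genotype_matrix()].
#' @param sites garden-site environment table.
#' @param origin_env optional per-accession origin environment table
#'   (same environmental columns as `sites`).
#' @return a list of class `recipro_dataset`.
#' @export
recipro_dataset <- function(pheno, passports, geno = NULL, sites,
                            origin_env = NULL) {
  structure(list(pheno = pheno, passports = passports, geno = geno,
                 sites = sites, origin_env = origin_env),
            class = "recipro_dataset")
}

#' @export
print.recipro_dataset <- function(x, ...) {
  cat(sprintf("<recipro_dataset> %d phenotype records, %d accessions, %d sites",
              nrow(x$pheno), nrow(x$passports), nrow(x$sites)))
  if (!is.null(x$geno)) cat(sprintf(", %d markers", ncol(x$geno$dosages)))
  cat("\n")
  invisible(x)
}
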