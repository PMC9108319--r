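#' Read a complete experiment dataset from disk
#'
#' Reads the phenotype, passport and environment tables (CSV or TSV with a
#' header row; trait columns named by their standard codes) and, optionally,
#' genotypes from a VCF file or a TSV dosage matrix. Missing phenotype values
#' may be encoded as empty cells or `"NA"`.
#'
#' The environment table is keyed by `location_id` and covers both common
#' garden sites and accession origin locations: rows whose `location_id`
#' matches a garden `site_id` become the garden-site table, rows matching an
#' accession become the origin-environment table used for environmental
#' distances.
#'
#' @param pheno_path path to the phenotype table.
#' @param passport_path path to the accession passport table.
#' @param geno_path optional path to a VCF (`.vcf`) or dosage TSV.
#' @param env_path path to the environment table.
#' @return a [recipro_dataset()].
#' @export
read_dataset <- function(pheno_path, passport_path, geno_path = NULL, env_path) {
  pheno <- read_phenotypes(pheno_path)
  passports <- read_passports(passport_path)
  env <- read_env_table(env_path)
  geno <- if (!is.null(geno_path)) read_genotypes(geno_path) else NULL

  site_ids <- unique(as.character(pheno$site_id))
  sites <- env[env$location_id %in% site_ids, , drop = FALSE]
  names(sites)[names(sites) == "location_id"] <- "site_id"
  origin_env <- env[env$location_id %in% passports$accession_id, , drop = FALSE]
  names(origin_env)[names(origin_env) == "location_id"] <- "accession_id"

  recipro_dataset(pheno, passports, geno, sites, origin_env)
}

#' @rdname read_dataset
#' @export
read_phenotypes <- function(pheno_path) {
  df <- read_table_auto(pheno_path)
  require_columns(df, c("accession_id", "site_id", "block", "row_id", "level"),
                  "phenotype table")
  df$block <- as.integer(df$block)
  for (tr in intersect(names(TRAIT_LEVELS), names(df))) {
    df[[tr]] <- as.numeric(df[[tr]])
  }
  df
}

#' @rdname read_dataset
#' @export
read_passports <- function(passport_path) {
  df <- read_table_auto(passport_path)
  require_columns(df, c("accession_id", "latitude", "longitude", "elevation",
                        "continent", "elev_class", "population",
                        "latitude_pair_id"), "passport table")
  df$accession_id <- as.character(df$accession_id)
  df
}

#' @rdname read_dataset
#' @export
read_env_table <- function(env_path) {
  df <- read_table_auto(env_path)
  require_columns(df, c("location_id", "elevation", "annual_mean_temp",
                        "annual_precip"), "environment table")
  df$location_id <- as.character(df$location_id)
  df
}

#' Read genotypes from VCF or a TSV dosage matrix
#'
#' VCF records are converted to alternate-allele dosages; only biallelic SNP
#' records are retained (others are skipped with a warning giving the count).
#' A TSV matrix must have accessions in the first column (`accession_id`) and
#' one column per marker.
#'
#' @param geno_path path to a `.vcf` file or dosage TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(geno_path) {
  if (grepl("\\.vcf(\\.gz)?$", geno_path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(geno_path, verbose = FALSE)
    bi <- vcfR::is.biallelic(vcf)
    n_skip <- sum(!bi)
    if (n_skip > 0) {
      warning(sprintf("skipped %d non-biallelic VCF record(s)", n_skip))
      vcf <- vcf[bi, ]
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- vcfR::getID(vcf)
    if (anyNA(ids)) ids <- paste0(vcfR::getCHROM(vcf), "_", vcfR::getPOS(vcf))
    dos <- apply(gt, 2, function(g) {
      g <- gsub("\\|", "/", g)
      out <- rep(NA_real_, length(g))
      out[g == "0/0"] <- 0
      out[g %in% c("0/1", "1/0")] <- 1
      out[g == "1/1"] <- 2
      out
    })
    dos <- t(dos)  # accessions x markers
    genotype_matrix(dos, accession_ids = colnames(gt), marker_ids = ids)
  } else {
    df <- read_table_auto(geno_path)
    require_columns(df, "accession_id", "genotype matrix")
    ids <- as.character(df$accession_id)
    m <- as.matrix(df[, setdiff(names(df), "accession_id"), drop = FALSE])
    mode(m) <- "numeric"
    genotype_matrix(m, accession_ids = ids)
  }
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Minimal VCFv4.2 writer (GT field only, arbitrary A/T alleles, one marker
#' per record) producing uncompressed text readable by standard VCF tools.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n_mark <- length(geno$marker_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recipro",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$accession_ids), collapse = "\t"))
  body <- vapply(seq_len(n_mark), function(j) {
    g <- geno$dosages[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c("1", j, geno$marker_ids[j], "A", "T", ".", "PASS", ".", "GT",
            calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write analysis results as TSV + JSON
#'
#' Each data.frame in `results` is written as `<name>.tsv`; the whole list is
#' additionally serialised to `results.json`. Names are written in sorted
#' order so outputs are byte-identical across re-runs on the same inputs.
#'
#' @param results named list of data.frames (or scalar summaries).
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- results[order(names(results))]
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_tsv_file(x, f)
      files <- c(files, f)
    }
  }
  jf <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, jf, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(files, jf))
}
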