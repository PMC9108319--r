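#' Validate a dataset against the design invariants
#'
#' Checks every type invariant of the experimental design and reports
#' violations as data (never exceptions): accession elevation classes must
#' respect the below-1000 m / above-2000 m selection rule, each latitude pair
#' must contain exactly one highland and one lowland accession, counts must
#' satisfy 0 <= PE <= STD <= seeds_per_row, ordinal scores must lie on the 0-4
#' scale, pigment-extent scores on \{0, 25, 50, 75, 100\}, and genotype
#' dosages in \{0, 1, 2, NA\}. Validation is pure: repeated calls on the same
#' dataset yield identical reports.
#'
#' @param dataset a [recipro_dataset()] (or a list with the same elements).
#' @param seeds_per_row seeds planted per row (upper bound for STD).
#' @param max_marker_missingness warn about markers whose missingness exceeds
#'   this fraction.
#' @return a `validation_report` list with `errors`, `warnings` and counts.
#' @export
validate_dataset <- function(dataset, seeds_per_row = 15,
                             max_marker_missingness = 0.2) {
  errors <- character(0)
  warnings <- character(0)
  pheno <- dataset$pheno
  pp <- dataset$passports
  geno <- dataset$geno
  sites <- dataset$sites

  ## --- passports ---
  bad_hi <- pp$elev_class == "High" & !(pp$elevation > 2000)
  bad_lo <- pp$elev_class == "Low" & !(pp$elevation < 1000)
  for (i in which(bad_hi | bad_lo)) {
    errors <- c(errors, sprintf(
      "passport %s: elevation %.0f m violates the <1000 m (Low) / >2000 m (High) class rule",
      pp$accession_id[i], pp$elevation[i]))
  }
  bad_class <- !pp$elev_class %in% c("High", "Low")
  for (i in which(bad_class)) {
    errors <- c(errors, sprintf("passport %s: unknown elev_class '%s'",
                                pp$accession_id[i], pp$elev_class[i]))
  }
  if (any(!pp$continent %in% c("Mex", "SA"))) {
    errors <- c(errors, "passport: continent must be 'Mex' or 'SA'")
  }
  for (pid in unique(pp$latitude_pair_id)) {
    cls <- sort(pp$elev_class[pp$latitude_pair_id == pid])
    if (!identical(cls, c("High", "Low"))) {
      errors <- c(errors, sprintf(
        "latitude pair %s: must contain exactly one High and one Low accession", pid))
    }
  }

  ## --- phenotype records ---
  if (!is.null(pheno) && nrow(pheno)) {
    rowlev <- pheno$level == "row"
    if (all(c("STD", "PE") %in% names(pheno))) {
      std <- pheno$STD; pe <- pheno$PE
      bad <- rowlev & !is.na(std) & !is.na(pe) &
        !(pe >= 0 & pe <= std & std <= seeds_per_row)
      for (i in which(bad)) {
        errors <- c(errors, sprintf(
          "record %s/%s block %s row %s: requires 0 <= PE (%s) <= STD (%s) <= %d",
          pheno$accession_id[i], pheno$site_id[i], pheno$block[i],
          pheno$row_id[i], pe[i], std[i], seeds_per_row))
      }
    }
    for (tr in intersect(ORDINAL_TRAITS, names(pheno))) {
      v <- pheno[[tr]]
      bad <- !is.na(v) & !(v %in% 0:4)
      for (i in which(bad)) {
        errors <- c(errors, sprintf(
          "record %s/%s row %s: %s = %s outside the 0-4 scale",
          pheno$accession_id[i], pheno$site_id[i], pheno$row_id[i], tr, v[i]))
      }
    }
    for (tr in intersect(PERCENT_TRAITS, names(pheno))) {
      v <- pheno[[tr]]
      bad <- !is.na(v) & !(v %in% c(0, 25, 50, 75, 100))
      for (i in which(bad)) {
        errors <- c(errors, sprintf(
          "record %s/%s row %s: %s = %s not on the 25%% interval scale",
          pheno$accession_id[i], pheno$site_id[i], pheno$row_id[i], tr, v[i]))
      }
    }
    for (tr in intersect(c("STD", "PE", "EN", "TBN", "KPR", "DTA", "DTS"),
                         names(pheno))) {
      v <- pheno[[tr]]
      bad <- !is.na(v) & (v < 0 | v != round(v))
      for (i in which(bad)) {
        errors <- c(errors, sprintf(
          "record %s/%s row %s: %s = %s is not a non-negative integer",
          pheno$accession_id[i], pheno$site_id[i], pheno$row_id[i], tr, v[i]))
      }
    }
    unknown <- setdiff(unique(pheno$accession_id), pp$accession_id)
    if (length(unknown)) {
      errors <- c(errors, sprintf(
        "phenotype records reference %d accession(s) absent from passports: %s",
        length(unknown), paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }

  ## --- sites ---
  if (!is.null(sites)) {
    need <- c("elevation", "annual_mean_temp", "annual_precip")
    miss <- setdiff(need, names(sites))
    if (length(miss)) {
      errors <- c(errors, sprintf("site table missing environment variable(s): %s",
                                  paste(miss, collapse = ", ")))
    }
  }

  ## --- genotypes ---
  n_markers <- 0L
  if (!is.null(geno)) {
    n_markers <- ncol(geno$dosages)
    miss_rate <- colMeans(is.na(geno$dosages))
    n_bad <- sum(miss_rate > max_marker_missingness)
    if (n_bad > 0) {
      warnings <- c(warnings, sprintf(
        "%d marker(s) exceed %.0f%% missingness", n_bad,
        100 * max_marker_missingness))
    }
    if (!setequal(intersect(geno$accession_ids, pp$accession_id),
                  geno$accession_ids)) {
      warnings <- c(warnings,
                    "genotype matrix contains accessions absent from passports")
    }
  }

  structure(list(errors = errors, warnings = warnings,
                 n_accessions = nrow(pp), n_markers = n_markers,
                 n_records = if (is.null(pheno)) 0L else nrow(pheno)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d records, %d accessions, %d markers\n",
              x$n_records, x$n_accessions, x$n_markers))
  cat(sprintf("  errors: %d, warnings: %d\n", length(x$errors), length(x$warnings)))
  for (e in utils::head(x$errors, 10)) cat("  E:", e, "\n")
  for (w in utils::head(x$warnings, 10)) cat("  W:", w, "\n")
  invisible(x)
}
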