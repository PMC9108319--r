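#' Adjusted plant fitness metrics
#'
#' Agronomic plant fitness multiplies the fraction of planted seeds that
#' produced ears (PE / seeds_per_row) by the square-root-transformed ear
#' number (diminishing returns of later ears) and primary ear weight:
#' `FITplant = PE/seeds_per_row * sqrt(EN) * EW`. Vegetative plant fitness
#' drops the ear-weight factor so that plants without harvested ears still
#' carry a fitness value: `FITplantveg = PE/seeds_per_row * sqrt(EN)`.
#' PE is a row-level count while EN and EW come from the tagged plant.
#'
#' @param PE ear-producing stand count of the row (0..seeds_per_row).
#' @param EN ear number of the plant (>= 0).
#' @param EW primary ear weight in grams (may be NA).
#' @param seeds_per_row seeds planted per row.
#' @return a data.frame with columns `FITplant` and `FITplantveg`.
#' @examples
#' compute_fitness(PE = 9, EN = 4, EW = 80)  # FITplant 96, FITplantveg 1.2
#' @export
compute_fitness <- function(PE, EN, EW = NA_real_, seeds_per_row = 15) {
  if (any(!is.na(PE) & (PE < 0 | PE > seeds_per_row))) {
    stop(sprintf("PE must lie in [0, %d]", seeds_per_row))
  }
  if (any(!is.na(EN) & EN < 0)) stop("EN must be non-negative")
  fitveg <- PE / seeds_per_row * sqrt(EN)
  data.frame(FITplant = fitveg * EW, FITplantveg = fitveg)
}

#' Barrenness: fraction of surviving plants with no ears
#'
#' `BRN = 1 - PE/STD`; undefined (NA, with a warning) when the stand count
#' is zero.
#'
#' @param STD stand count (plants surviving to maturity).
#' @param PE ear-producing stand count (0 <= PE <= STD).
#' @return numeric vector of barrenness values in \[0, 1\].
#' @export
compute_barrenness <- function(STD, PE) {
  if (any(!is.na(STD) & !is.na(PE) & (PE < 0 | PE > STD))) {
    stop("requires 0 <= PE <= STD")
  }
  zero <- !is.na(STD) & STD == 0
  if (any(zero)) warning(sprintf("BRN undefined for %d row(s) with STD = 0", sum(zero)))
  out <- 1 - PE / STD
  out[zero] <- NA_real_
  out
}

#' Anthesis-silking interval
#'
#' `ASI = DTS - DTA`, in days. Negative values (silking before anthesis)
#' are permitted and preserved; NA in either input propagates.
#'
#' @param DTA days to anthesis.
#' @param DTS days to silking.
#' @return numeric vector of intervals.
#' @export
compute_asi <- function(DTA, DTS) DTS - DTA

#' Carbon isotope composition relative to Vienna Pee Dee Belemnite
#'
#' `delta13C = (R_sample / R_standard - 1) * 1000`, in per mil, where each R
#' is a 13C:12C ratio and the standard is Vienna Pee Dee Belemnite. In C4
#' plants delta13C is inversely related to water use efficiency.
#'
#' @param ratio_sample 13C:12C ratio of the sample (> 0).
#' @param ratio_standard 13C:12C ratio of the standard (> 0).
#' @return delta 13C in per mil.
#' @export
compute_delta13c <- function(ratio_sample, ratio_standard) {
  if (any(!is.na(ratio_sample) & ratio_sample <= 0) ||
      any(!is.na(ratio_standard) & ratio_standard <= 0)) {
    stop("isotope ratios must be positive")
  }
  (ratio_sample / ratio_standard - 1) * 1000
}

#' Add derived traits to a phenotype table
#'
#' Adds `BRN` and `ASI` to row-level records and `FITplant` / `FITplantveg`
#' to plant-level records. Per-plant fitness combines the row's PE (matched
#' by site, block and row) with the tagged plant's EN and EW; missing EW
#' leaves FITplant missing while FITplantveg is always defined where PE and
#' EN are.
#'
#' @param pheno phenotype table as returned by [read_phenotypes()] or
#'   [simulate_phenotypes()].
#' @param seeds_per_row seeds planted per row.
#' @return the table with derived-trait columns appended.
#' @export
derive_traits <- function(pheno, seeds_per_row = 15) {
  is_row <- pheno$level == "row"
  pheno$BRN <- NA_real_
  pheno$ASI <- NA_real_
  ok <- is_row & !is.na(pheno$STD)
  pheno$BRN[ok] <- suppressWarnings(
    compute_barrenness(pheno$STD[ok], pheno$PE[ok]))
  pheno$ASI[is_row] <- compute_asi(pheno$DTA[is_row], pheno$DTS[is_row])

  key <- function(d) paste(d$site_id, d$block, d$row_id, sep = "\r")
  row_pe <- setNames(pheno$PE[is_row], key(pheno[is_row, ]))
  pheno$FITplant <- NA_real_
  pheno$FITplantveg <- NA_real_
  ip <- which(!is_row)
  if (length(ip)) {
    pe <- unname(row_pe[key(pheno[ip, ])])
    fit <- compute_fitness(pe, pheno$EN[ip], pheno$EW[ip], seeds_per_row)
    pheno$FITplant[ip] <- fit$FITplant
    pheno$FITplantveg[ip] <- fit$FITplantveg
  }
  pheno
}

#' Mean vegetative fitness per accession and garden
#'
#' Environmental-distance regressions operate on one fitness value per
#' accession x garden; this helper averages plant-level FITplantveg
#' (missing values dropped).
#'
#' @param pheno a phenotype table processed by [derive_traits()].
#' @param trait fitness column to aggregate.
#' @return data.frame with `accession_id`, `site_id` and `fitness`.
#' @export
fitness_by_accession_garden <- function(pheno, trait = "FITplantveg") {
  d <- pheno[!is.na(pheno[[trait]]), c("accession_id", "site_id", trait)]
  out <- aggregate(d[[trait]],
                   by = list(accession_id = d$accession_id, site_id = d$site_id),
                   FUN = mean)
  names(out)[3] <- "fitness"
  out
}
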