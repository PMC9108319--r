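#' Configuration for a synthetic reciprocal-transplant experiment
#'
#' Defaults emulate the field design: 4 populations (continent x elevation)
#' of 30 latitude-paired accessions, two common gardens (54 m and 2852 m)
#' each with 2 complete blocks of one 15-seed row per accession, two tagged
#' plants per row, and biallelic markers simulated under the Balding-Nichols
#' model at the target differentiation `fst_target`. The marker count is
#' scaled down from the genotyping platform's ~67k by default.
#'
#' `variance_spec` gives variance components in units of each trait's
#' nominal residual variance: population, line (accession), latitude pair,
#' latitude-pair x garden, block-within-garden, and a `resid` multiplier for
#' the residual itself (0 makes continuous traits deterministic functions of
#' their cell). `gxe_matrix`
#' (populations x gardens, residual-SD units) shifts the latent fitness
#' surface (survival and ear probabilities, ear number and ear weight
#' locations) and controls reaction-norm crossing; the default encodes
#' moderate home-site advantage with a Mexican edge in Mexican gardens.
#' `env_decay` is the change in survival probability per squared kilometre
#' of elevational transplant distance (negative values penalise foreign
#' elevations quadratically).
#'
#' @param n_pops number of populations (4 gives the full continent x
#'   elevation design; other values give generic populations usable for
#'   genotype and variance-partition simulations).
#' @param n_lines_per_pop accessions per population.
#' @param n_markers biallelic markers to simulate.
#' @param fst_target Balding-Nichols differentiation parameter in \[0, 1).
#' @param n_gardens,n_blocks,seeds_per_row,plants_per_row design constants.
#' @param seed integer RNG seed; all draws derive from named sub-streams of it.
#' @param variance_spec named list of relative variance components
#'   (`pop`, `line`, `lat`, `latgarden`, `block`; residual variance is 1).
#' @param gxe_matrix numeric matrix `n_pops x n_gardens` of cell-mean offsets
#'   in residual-SD units, rows named by population, columns
#'   `c("LowSite", "HighSite")`.
#' @param env_decay survival-probability decay per (km elevation distance)^2.
#' @param missing_rate per-call genotype missingness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 4, n_lines_per_pop = 30, n_markers = 2000,
                       fst_target = 0.1, n_gardens = 2, n_blocks = 2,
                       seeds_per_row = 15, plants_per_row = 2, seed = 1,
                       variance_spec = list(pop = 0, line = 1, lat = 0.5,
                                            latgarden = 0.25, block = 0.25,
                                            resid = 1),
                       gxe_matrix = NULL, env_decay = -0.04,
                       missing_rate = 0.02) {
  stopifnot(fst_target >= 0, fst_target < 1, n_pops >= 2,
            all(unlist(variance_spec) >= 0))
  if (is.null(gxe_matrix)) {
    gxe_matrix <- if (n_pops == 4) {
      matrix(c(-1.0,  1.0,
                1.0, -1.0,
               -1.5,  0.5,
                0.5, -1.5),
             nrow = 4, byrow = TRUE,
             dimnames = list(POPULATIONS, GARDENS))
    } else {
      matrix(0, n_pops, n_gardens,
             dimnames = list(paste0("Pop", seq_len(n_pops)), GARDENS[seq_len(n_gardens)]))
    }
  }
  stopifnot(nrow(gxe_matrix) == n_pops, ncol(gxe_matrix) == n_gardens)
  structure(list(n_pops = n_pops, n_lines_per_pop = n_lines_per_pop,
                 n_markers = n_markers, fst_target = fst_target,
                 n_gardens = n_gardens, n_blocks = n_blocks,
                 seeds_per_row = seeds_per_row, plants_per_row = plants_per_row,
                 seed = seed, variance_spec = variance_spec,
                 gxe_matrix = gxe_matrix, env_decay = env_decay,
                 missing_rate = missing_rate),
            class = "sim_config")
}

sim_pop_labels <- function(config) {
  if (config$n_pops == 4) POPULATIONS else paste0("Pop", seq_len(config$n_pops))
}

## Shared elevation -> climate mapping (rough Mexican-transect lapse rates).
## Bioclim-style variables beyond temperature and precipitation are affine in
## elevation plus noise, mimicking the collinearity of real bioclim layers.
env_from_elevation <- function(elev, noise = TRUE) {
  n <- length(elev)
  z <- elev / 1000
  jitter <- function(s) if (noise) rnorm(n, 0, s) else 0
  out <- data.frame(
    elevation = elev,
    annual_mean_temp = 27 - 6.2 * z + jitter(0.6),
    annual_precip = pmax(100, 1500 - 300 * z + jitter(80))
  )
  bio_slopes <- c(bio02 = 0.8, bio03 = 2.0, bio04 = 30, bio05 = -6.0,
                  bio06 = -6.5, bio07 = 1.0, bio08 = -6.0, bio09 = -6.3,
                  bio10 = -6.1, bio11 = -6.4, bio13 = -40, bio14 = -4,
                  bio15 = 3, bio16 = -100, bio17 = -15, bio18 = -80,
                  bio19 = -20)
  bio_base <- c(bio02 = 12, bio03 = 60, bio04 = 150, bio05 = 33, bio06 = 12,
                bio07 = 20, bio08 = 26, bio09 = 25, bio10 = 27, bio11 = 24,
                bio13 = 300, bio14 = 10, bio15 = 70, bio16 = 750, bio17 = 60,
                bio18 = 600, bio19 = 120)
  for (k in names(bio_slopes)) {
    out[[k]] <- bio_base[[k]] + bio_slopes[[k]] * z +
      jitter(0.05 * abs(bio_base[[k]]) + 0.1)
  }
  out
}

#' Simulate common-garden sites and accession passports
#'
#' Two gardens with the contrasting elevations of the field experiment
#' (54 m lowland, 2852 m highland) and, for the four-population design,
#' latitude-paired highland (>2000 m) and lowland (<1000 m) accession
#' origins on each continent. Environmental variables at every location are
#' derived from elevation plus noise.
#'
#' @param config a [sim_config()] with `n_pops = 4`.
#' @return list with `sites` (garden table), `passports`, and `env`
#'   (location-keyed environment table covering gardens and origins).
#' @export
simulate_environment <- function(config) {
  if (config$n_pops != 4) {
    stop("environment simulation assumes the four continent x elevation populations")
  }
  set.seed(substream_seed(config$seed, "environment"))
  n_pairs <- config$n_lines_per_pop

  garden_env <- env_from_elevation(c(54, 2852), noise = FALSE)
  sites <- cbind(data.frame(location_id = GARDENS,
                            year = c(2017L, 2016L)), garden_env)

  pp <- list()
  for (cont in c("Mex", "SA")) {
    lat_bins <- if (cont == "Mex") sample(14:24, n_pairs, replace = TRUE)
                else sample(-20:-4, n_pairs, replace = TRUE)
    lon_rng <- if (cont == "Mex") c(-106, -92) else c(-78, -58)
    for (p in seq_len(n_pairs)) {
      pair_id <- sprintf("%s_P%02d", cont, p)
      for (cls in c("High", "Low")) {
        elev <- if (cls == "High") runif(1, 2050, 2950) else runif(1, 60, 950)
        pop <- paste0(cont, cls)
        pp[[length(pp) + 1L]] <- data.frame(
          accession_id = sprintf("%s%02d", pop, p),
          latitude = lat_bins[p] + runif(1),
          longitude = runif(1, lon_rng[1], lon_rng[2]),
          elevation = elev, continent = cont, elev_class = cls,
          population = pop, latitude_pair_id = pair_id)
      }
    }
  }
  passports <- do.call(rbind, pp)
  passports <- passports[order(match(passports$population, POPULATIONS),
                               passports$accession_id), ]
  rownames(passports) <- NULL

  origin_env <- cbind(data.frame(location_id = passports$accession_id,
                                 year = NA_integer_),
                      env_from_elevation(passports$elevation))
  env <- rbind(sites, origin_env)
  names(sites)[names(sites) == "location_id"] <- "site_id"
  list(sites = sites, passports = passports, env = env)
}

#' Simulate biallelic genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); each
#' population's frequency is Beta-distributed around the ancestral value
#' with differentiation parameter F = `fst_target` (F = 0 degenerates to the
#' ancestral frequency), and dosages are Binomial(2, p) Hardy-Weinberg
#' draws. Expected pairwise Hudson F_ST between populations is approximately
#' F.
#'
#' @param config a [sim_config()].
#' @param passports optional passport table whose `accession_id` /
#'   `population` columns fix sample identity; defaults to generic labels.
#' @return a [genotype_matrix()] of shape
#'   `(n_pops * n_lines_per_pop) x n_markers`.
#' @export
simulate_genotypes <- function(config, passports = NULL) {
  set.seed(substream_seed(config$seed, "genotypes"))
  M <- config$n_markers
  f <- config$fst_target
  pops <- sim_pop_labels(config)
  if (is.null(passports)) {
    ids <- unlist(lapply(pops, function(p)
      sprintf("%s%02d", p, seq_len(config$n_lines_per_pop))))
    pop_of <- rep(pops, each = config$n_lines_per_pop)
  } else {
    ids <- passports$accession_id
    pop_of <- passports$population
  }

  p_anc <- runif(M, 0.05, 0.95)
  dos <- matrix(NA_real_, length(ids), M, dimnames = list(ids, NULL))
  for (pop in unique(pop_of)) {
    p_pop <- if (f == 0) p_anc else {
      rbeta(M, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
    rows <- which(pop_of == pop)
    n <- length(rows)
    dos[rows, ] <- matrix(rbinom(n * M, 2, rep(p_pop, each = n)), n, M)
  }
  if (config$missing_rate > 0) {
    mask <- runif(length(dos)) < config$missing_rate
    dos[mask] <- NA_real_
  }
  genotype_matrix(dos, accession_ids = ids,
                  marker_ids = sprintf("M%05d", seq_len(M)))
}

## internal: per-trait mean structure defaults (trait units).
## pop offsets ordered MexHigh, MexLow, SAHigh, SALow.
trait_mean_table <- function() {
  list(
    DTA      = list(mu = 70,   garden_hi = 18,  pop = c(-2, 2, 0, 4),    sd = 3,    round = TRUE,  min = 40),
    ASI      = list(mu = 2,    garden_hi = -1,  pop = c(0, 0, -0.5, 0.5), sd = 1.5, round = TRUE,  min = -Inf),
    PH       = list(mu = 210,  garden_hi = -35, pop = c(-10, 15, -5, 12), sd = 15,  round = FALSE, min = 30),
    EH       = list(mu = 110,  garden_hi = -22, pop = c(-8, 10, -4, 8),   sd = 12,  round = FALSE, min = 10),
    TL       = list(mu = 34,   garden_hi = -3,  pop = c(-2, 2, -1, 2),    sd = 4,   round = FALSE, min = 5),
    TBN      = list(mu = 17,   garden_hi = -1,  pop = c(-2, 2, 1, 4),     sd = 3,   round = TRUE,  min = 1),
    EL       = list(mu = 14,   garden_hi = -1,  pop = c(-0.5, 0.5, -0.5, 0.5), sd = 2, round = FALSE, min = 2),
    KPR      = list(mu = 28,   garden_hi = -2,  pop = c(-1, 1, -1, 1),    sd = 4,   round = TRUE,  min = 2),
    ED       = list(mu = 4.4,  garden_hi = 0.1, pop = c(-0.1, 0.1, -0.1, 0.1), sd = 0.5, round = FALSE, min = 1),
    delta13C = list(mu = -12.3, garden_hi = -0.4, pop = c(-0.5, 0.2, -0.3, 0.2), sd = 0.35, round = FALSE, min = -Inf),
    ## latent scales for ordinal / percent scores (unit residual SD)
    P_INTsolid = list(mu = 0, garden_hi = 0.8, pop = c(0.3, -0.3, 0.6, -0.6), sd = 1, round = FALSE, min = -Inf),
    P_INTspot  = list(mu = 0, garden_hi = 0.6, pop = c(0.2, -0.2, 0.3, -0.3), sd = 1, round = FALSE, min = -Inf),
    P_EXTsolid = list(mu = 0, garden_hi = 0.8, pop = c(0.3, -0.3, 0.5, -0.5), sd = 1, round = FALSE, min = -Inf),
    P_EXTspot  = list(mu = 0, garden_hi = 0.7, pop = c(0.2, -0.2, 0.3, -0.3), sd = 1, round = FALSE, min = -Inf),
    M_DENsolid = list(mu = 0, garden_hi = 0.1, pop = c(1.2, -0.4, -0.4, -0.4), sd = 1, round = FALSE, min = -Inf),
    M_DENmarg  = list(mu = 0, garden_hi = 0.0, pop = c(0.3, -0.1, -0.1, -0.1), sd = 1, round = FALSE, min = -Inf)
  )
}

#' Simulate phenotype records for a reciprocal-transplant design
#'
#' Continuous traits follow
#' `y = mu + pop x garden cell mean + block + latitude + latitude x garden +
#' line + residual`, all Gaussian with configured relative variances
#' (group-level effects are rescaled so their realized sample variance equals
#' the configured value exactly). Stand count is Binomial(seeds_per_row,
#' survival probability) and ear-producing stand count Binomial(STD, ear
#' probability); both probabilities carry the `gxe_matrix` offsets and an
#' `env_decay` x (elevational distance in km)^2 penalty, clipped to \[0, 1\]
#' with a warning if exceeded. Ear number is 1 + Poisson, ear weight
#' log-normal with site x population location, and ordinal scores threshold a
#' latent Gaussian at its \{0.2, 0.4, 0.6, 0.8\} quantiles. Ear traits (EW,
#' EL, KPR, ED) are missing for rows with no ear-producing plants, and
#' flowering dates are missing for rows with no surviving plants.
#'
#' @param config a [sim_config()].
#' @param passports passport table from [simulate_environment()].
#' @param sites garden-site table from [simulate_environment()].
#' @return list with `pheno` (row- and plant-level records) and `truth`
#'   (realized latent effects and parameters, reproducible from
#'   `(config, seed)`).
#' @export
simulate_phenotypes <- function(config, passports, sites) {
  pops <- sim_pop_labels(config)
  vs <- config$variance_spec
  n_acc <- nrow(passports)
  gardens <- sites$site_id
  pairs <- unique(passports$latitude_pair_id)

  ## design frame: one row per garden x block x accession
  rows <- expand.grid(accession_idx = seq_len(n_acc),
                      block = seq_len(config$n_blocks),
                      site_id = gardens, stringsAsFactors = FALSE)
  rows$accession_id <- passports$accession_id[rows$accession_idx]
  rows$population <- passports$population[rows$accession_idx]
  rows$pair_id <- passports$latitude_pair_id[rows$accession_idx]
  rows$row_id <- ave(seq_len(nrow(rows)),
                     paste(rows$site_id, rows$block), FUN = seq_along)

  ## elevational transplant distance (km), garden minus origin
  garden_elev <- setNames(sites$elevation, sites$site_id)
  dist_km <- (garden_elev[rows$site_id] - passports$elevation[rows$accession_idx]) / 1000

  gxe <- config$gxe_matrix
  cell_of <- function(scale = 1) scale * gxe[cbind(match(rows$population, rownames(gxe)),
                                                   match(rows$site_id, colnames(gxe)))]

  ## named-substream effect draws for one trait family
  draw_effects <- function(trait_key, sd_resid) {
    set.seed(substream_seed(config$seed, paste0("pheno_", trait_key)))
    line <- scale_to_variance(rnorm(n_acc), vs$line * sd_resid^2)
    lat <- scale_to_variance(rnorm(length(pairs)), vs$lat * sd_resid^2)
    latg <- matrix(0, length(pairs), length(gardens))
    if (vs$latgarden > 0) {
      latg <- matrix(scale_to_variance(rnorm(length(pairs) * length(gardens)),
                                       vs$latgarden * sd_resid^2),
                     length(pairs), length(gardens))
    }
    blockg <- matrix(0, config$n_blocks, length(gardens))
    if (vs$block > 0) {
      blockg <- matrix(scale_to_variance(rnorm(config$n_blocks * length(gardens)),
                                         vs$block * sd_resid^2),
                       config$n_blocks, length(gardens))
    }
    pop_eff <- rep(0, length(pops))
    if (vs$pop > 0) pop_eff <- scale_to_variance(rnorm(length(pops)), vs$pop * sd_resid^2)
    list(line = line, lat = lat, latg = latg, blockg = blockg, pop = pop_eff)
  }

  linpred <- function(eff) {
    i_pair <- match(rows$pair_id, pairs)
    i_gard <- match(rows$site_id, gardens)
    eff$line[rows$accession_idx] + eff$lat[i_pair] +
      eff$latg[cbind(i_pair, i_gard)] + eff$blockg[cbind(rows$block, i_gard)] +
      eff$pop[match(rows$population, pops)]
  }

  truth <- list(gxe_matrix = gxe, env_decay = config$env_decay,
                variance_spec = vs, cell_means = list())

  ## ---- survival cascade (row level) ----
  eff_s <- draw_effects("surv", 1)
  set.seed(substream_seed(config$seed, "pheno_surv_draws"))
  p_surv <- plogis(qlogis(0.85) + 0.5 * cell_of() + 0.25 * linpred(eff_s)) +
    config$env_decay * dist_km^2
  p_ear_base <- plogis(qlogis(0.80) + 0.4 * cell_of() + 0.25 * linpred(eff_s)) +
    0.5 * config$env_decay * dist_km^2
  n_clip <- sum(p_surv < 0 | p_surv > 1 | p_ear_base < 0 | p_ear_base > 1)
  if (n_clip > 0) {
    warning(sprintf("%d survival/ear probabilities outside [0, 1] after decay; clipped",
                    n_clip))
  }
  p_surv <- pmin(pmax(p_surv, 0), 1)
  p_ear <- pmin(pmax(p_ear_base, 0), 1)
  STD <- rbinom(nrow(rows), config$seeds_per_row, p_surv)
  PE <- rbinom(nrow(rows), STD, p_ear)
  truth$p_surv <- data.frame(accession_id = rows$accession_id,
                             site_id = rows$site_id, block = rows$block,
                             p_surv = p_surv, p_ear = p_ear)

  ## ---- continuous / latent traits ----
  tmt <- trait_mean_table()
  trait_cols <- list()
  n_plants <- config$plants_per_row
  plant_idx <- rep(seq_len(nrow(rows)), each = n_plants)

  sim_cont <- function(trait, level) {
    sp <- tmt[[trait]]
    eff <- draw_effects(trait, sp$sd)
    set.seed(substream_seed(config$seed, paste0("pheno_resid_", trait)))
    base <- sp$mu + sp$garden_hi * (rows$site_id == "HighSite") +
      (if (config$n_pops == 4) sp$pop[match(rows$population, POPULATIONS)] else 0) +
      linpred(eff)
    truth$cell_means[[trait]] <<- aggregate(base,
      list(population = rows$population, site_id = rows$site_id), mean)
    sd_res <- sp$sd * sqrt(vs$resid %||% 1)
    if (level == "row") {
      y <- base + rnorm(nrow(rows), 0, sd_res)
    } else {
      y <- base[plant_idx] + rnorm(length(plant_idx), 0, sd_res)
    }
    if (sp$round) y <- round(y)
    pmax(y, sp$min)
  }

  DTA <- sim_cont("DTA", "row")
  ASI <- sim_cont("ASI", "row")
  DTS <- DTA + ASI
  DTA[STD == 0] <- NA; DTS[STD == 0] <- NA

  plant_cont <- c("PH", "EH", "TL", "EL", "KPR", "ED", "delta13C", "TBN")
  for (tr in plant_cont) trait_cols[[tr]] <- sim_cont(tr, "plant")

  ## ear number / weight with site x pop location shifts
  set.seed(substream_seed(config$seed, "pheno_EN"))
  lam <- exp(log(0.6) + 0.15 * cell_of())[plant_idx]
  EN <- 1 + rpois(length(plant_idx), lam)
  eff_ew <- draw_effects("EW", 0.25)
  set.seed(substream_seed(config$seed, "pheno_EW_draws"))
  EW <- rlnorm(length(plant_idx),
               meanlog = (log(75) + 0.12 * cell_of() - 0.1 * (rows$site_id == "HighSite") +
                          linpred(eff_ew))[plant_idx],
               sdlog = 0.25 * sqrt(vs$resid %||% 1))
  trait_cols$EN <- EN
  trait_cols$EW <- EW

  ## ordinal / percent scores from latent Gaussians
  for (tr in c(ORDINAL_TRAITS, PERCENT_TRAITS)) {
    z <- sim_cont(tr, "plant")
    thr <- quantile(z, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
    score <- findInterval(z, thr)          # 0..4
    if (tr %in% PERCENT_TRAITS) score <- score * 25
    trait_cols[[tr]] <- score
  }

  ## rows with no surviving / ear-producing plants lose plant measurements
  row_STD <- STD[plant_idx]; row_PE <- PE[plant_idx]
  for (tr in names(trait_cols)) trait_cols[[tr]][row_STD == 0] <- NA
  for (tr in c("EW", "EL", "KPR", "ED")) trait_cols[[tr]][row_PE == 0] <- NA

  ## ---- assemble record tables ----
  row_records <- data.frame(
    accession_id = rows$accession_id, site_id = rows$site_id,
    block = rows$block, row_id = rows$row_id, plant_id = NA_character_,
    level = "row", STD = STD, PE = PE, DTA = DTA, DTS = DTS,
    stringsAsFactors = FALSE)

  plant_records <- data.frame(
    accession_id = rows$accession_id[plant_idx],
    site_id = rows$site_id[plant_idx], block = rows$block[plant_idx],
    row_id = rows$row_id[plant_idx],
    plant_id = paste0("P", rep(seq_len(n_plants), times = nrow(rows))),
    level = "plant", stringsAsFactors = FALSE)
  for (tr in names(TRAIT_LEVELS)[TRAIT_LEVELS == "plant"]) {
    plant_records[[tr]] <- trait_cols[[tr]]
  }

  all_traits <- names(TRAIT_LEVELS)
  for (tr in setdiff(all_traits, names(row_records))) row_records[[tr]] <- NA_real_
  for (tr in setdiff(all_traits, names(plant_records))) plant_records[[tr]] <- NA_real_
  ord <- c("accession_id", "site_id", "block", "row_id", "plant_id", "level", all_traits)
  pheno <- rbind(row_records[, ord], plant_records[, ord])
  rownames(pheno) <- NULL

  list(pheno = pheno, truth = truth)
}

#' Simulate a complete experiment and write it to disk
#'
#' Runs [simulate_environment()], [simulate_genotypes()] and
#' [simulate_phenotypes()] and writes `phenotypes.tsv`, `passports.tsv`,
#' `environment.tsv`, `genotypes.vcf` and `truth.json` into `out_dir`, in a
#' layout loadable by [read_dataset()]. Identical `(config, seed)` produce
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param with_genotypes set FALSE to omit the genotype stage (no VCF is
#'   written and downstream F_ST/Q_ST stages are skipped).
#' @return invisibly, a list with the file paths, the truth record and the
#'   in-memory dataset.
#' @export
simulate_experiment <- function(config = sim_config(), out_dir,
                                with_genotypes = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  env <- simulate_environment(config)
  geno <- if (with_genotypes) simulate_genotypes(config, env$passports) else NULL
  ph <- simulate_phenotypes(config, env$passports, env$sites)

  paths <- list(
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    passports = file.path(out_dir, "passports.tsv"),
    environment = file.path(out_dir, "environment.tsv"),
    genotypes = if (with_genotypes) file.path(out_dir, "genotypes.vcf") else NULL,
    truth = file.path(out_dir, "truth.json"))

  write_tsv_file(ph$pheno, paths$phenotypes)
  write_tsv_file(env$passports, paths$passports)
  write_tsv_file(env$env, paths$environment)
  if (with_genotypes) write_genotypes_vcf(geno, paths$genotypes)
  truth <- ph$truth
  truth$seed <- config$seed
  truth$fst_target <- config$fst_target
  jsonlite::write_json(truth, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth,
                 dataset = recipro_dataset(ph$pheno, env$passports, geno,
                                           env$sites)))
}

#' Simulate a single trait under the Q_ST variance-partition model
#'
#' Generates one observation per line x garden x block with independent
#' population, line, garden, block-within-garden and residual effects —
#' the generative mirror of the variance-partition model
#' `TRAIT ~ 1 + (1|POPULATION) + (1|LINE) + (1|GARDEN/BLOCK)`. Population
#' and line effects are rescaled to realize their configured variances
#' exactly; `pop_means` overrides random population effects with fixed
#' values (e.g. a divergent-selection shift).
#'
#' @param n_pops,n_lines_per_pop,n_gardens,n_blocks design sizes.
#' @param sigma2_pop,sigma2_line,sigma2_garden,sigma2_block,sigma2_resid
#'   variance components (trait units squared).
#' @param pop_means optional fixed population means replacing random
#'   population effects.
#' @param seed RNG seed.
#' @return data.frame with columns `value`, `accession_id`, `population`,
#'   `site_id`, `block`, plus attribute `"effects"` holding the realized
#'   latent effects.
#' @export
simulate_qst_dataset <- function(n_pops = 4, n_lines_per_pop = 30,
                                 n_gardens = 2, n_blocks = 2,
                                 sigma2_pop = 1, sigma2_line = 1,
                                 sigma2_garden = 0.25, sigma2_block = 0.25,
                                 sigma2_resid = 1, pop_means = NULL,
                                 seed = 1) {
  set.seed(seed)
  pops <- if (n_pops == 4) POPULATIONS else paste0("Pop", seq_len(n_pops))
  gardens <- GARDENS[seq_len(n_gardens)]
  pop_eff <- if (!is.null(pop_means)) {
    stopifnot(length(pop_means) == n_pops)
    as.numeric(pop_means)
  } else {
    scale_to_variance(rnorm(n_pops), sigma2_pop)
  }
  n_lines <- n_pops * n_lines_per_pop
  line_eff <- scale_to_variance(rnorm(n_lines), sigma2_line)
  gard_eff <- if (sigma2_garden > 0) scale_to_variance(rnorm(n_gardens), sigma2_garden) else rep(0, n_gardens)
  block_eff <- if (sigma2_block > 0) {
    matrix(scale_to_variance(rnorm(n_gardens * n_blocks), sigma2_block),
           n_blocks, n_gardens)
  } else matrix(0, n_blocks, n_gardens)

  d <- expand.grid(line = seq_len(n_lines), block = seq_len(n_blocks),
                   garden = seq_len(n_gardens))
  pop_of_line <- rep(seq_len(n_pops), each = n_lines_per_pop)
  d$value <- pop_eff[pop_of_line[d$line]] + line_eff[d$line] +
    gard_eff[d$garden] + block_eff[cbind(d$block, d$garden)] +
    rnorm(nrow(d), 0, sqrt(sigma2_resid))
  out <- data.frame(
    value = d$value,
    accession_id = sprintf("%s%02d", pops[pop_of_line[d$line]],
                           ((d$line - 1L) %% n_lines_per_pop) + 1L),
    population = pops[pop_of_line[d$line]],
    site_id = gardens[d$garden],
    block = d$block, stringsAsFactors = FALSE)
  attr(out, "effects") <- list(pop = pop_eff, line = line_eff,
                               garden = gard_eff, block = block_eff)
  out
}
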