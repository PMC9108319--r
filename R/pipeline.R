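#' Run the full analysis pipeline on a synthetic experiment
#'
#' Orchestrates the six pipeline stages in dependency order:
#' `simulate` (write the synthetic experiment), `validate` (reload from disk
#' and check invariants), `traits` (derived fitness metrics), `fst_qst`
#' (genotype PCA, per-contrast Hudson F_ST summaries and the Q_ST scan),
#' `gxe` (reaction norms and the twelve contrast families per trait) and
#' `envdist_corr` (environmental-distance fitness decay and garden-specific
#' correlations). Results are written as TSV + JSON via [write_results()],
#' and a manifest with the configuration, seed, package versions and MD5
#' checksums of every stage file is returned and written alongside. A
#' failing stage stops the run with prior stage outputs intact; identical
#' `(config, seed)` reproduce identical checksums.
#'
#' @param config a [sim_config()], or the path to a YAML file whose keys are
#'   [sim_config()] arguments.
#' @param out_dir output directory.
#' @param gxe_traits traits for the G x E contrast stage.
#' @param qst_traits traits for the Q_ST/F_ST scan.
#' @param corr_traits traits for the garden correlation stage (delta13C
#'   excluded by convention).
#' @param with_genotypes set FALSE to run without genotypes; the F_ST/Q_ST
#'   stage is then skipped with an explicit manifest note.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         gxe_traits = c("FITplant", "FITplantveg", "DTA",
                                        "DTS", "PH", "M_DENsolid"),
                         qst_traits = c("FITplantveg", "PH", "DTS",
                                        "delta13C", "M_DENsolid"),
                         corr_traits = c("FITplantveg", "PH", "EH", "TL",
                                         "P_INTsolid", "P_EXTsolid",
                                         "M_DENsolid", "M_DENmarg"),
                         with_genotypes = TRUE) {
  if (is.character(config)) config <- do.call(sim_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config), "gxe_matrix")],
                   versions = list(R = as.character(getRversion()),
                                   recipro = as.character(packageVersion("recipro"))),
                   stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  ## 1. simulate
  sim <- stage("simulate",
               simulate_experiment(config, data_dir, with_genotypes))
  manifest$stages$simulate$files <- lapply(
    Filter(Negate(is.null), sim$paths), function(p) unname(tools::md5sum(p)))

  ## 2. validate
  ds <- stage("validate", {
    ds <- read_dataset(sim$paths$phenotypes, sim$paths$passports,
                       sim$paths$genotypes, sim$paths$environment)
    rep <- validate_dataset(ds, seeds_per_row = config$seeds_per_row)
    if (length(rep$errors)) {
      stop(sprintf("dataset invalid: %s", rep$errors[1]))
    }
    ds
  })

  ## 3. derived traits
  pheno <- stage("traits", derive_traits(ds$pheno, config$seeds_per_row))
  write_tsv_file(pheno, file.path(out_dir, "derived_traits.tsv"))

  results <- list()
  ## 4. popgen + quantgen
  if (!is.null(ds$geno)) {
    stage("fst_qst", {
      pca <- genotype_pca(ds$geno, n_components = 4)
      results$pca_pct_var <- data.frame(component = seq_along(pca$pct_var[1:4]),
                                         pct_var = pca$pct_var[1:4])
      scan <- suppressWarnings(
        qst_fst_scan(pheno, ds$passports, ds$geno, traits = qst_traits))
      results$qst_fst <- as.data.frame(scan)
      invisible(NULL)
    })
  } else {
    manifest$stages$fst_qst <- list(
      status = "skipped", note = "no genotypes in configuration")
  }

  ## 5. gxe
  stage("gxe", {
    ct <- lapply(gxe_traits, function(tr)
      contrast_tratios(fit_gxe_model(tr, pheno, ds$passports)))
    results$gxe_contrasts <- do.call(rbind, ct)
    rn <- reaction_norms(pheno, ds$passports, traits = gxe_traits)
    results$reaction_norm_cells <- rn$cells
    results$reaction_norm_crossing <- rn$crossing
    invisible(NULL)
  })

  ## 6. envdist + correlations
  stage("envdist_corr", {
    fit <- fitness_by_accession_garden(pheno)
    results$env_distance <- env_distance_scan(
      fit, ds$origin_env, ds$sites,
      variables = c("elevation", "annual_mean_temp", "annual_precip"))
    ch <- garden_correlations(pheno, corr_traits, garden = "HighSite")
    cl <- garden_correlations(pheno, corr_traits, garden = "LowSite")
    dm <- correlation_difference(ch, cl)
    results$correlation_difference <- data.frame(
      trait1 = rep(rownames(dm), times = ncol(dm)),
      trait2 = rep(colnames(dm), each = nrow(dm)),
      r_high_minus_r_low = as.vector(dm))
    invisible(NULL)
  })

  files <- write_results(results, res_dir)
  manifest$result_checksums <- as.list(tools::md5sum(sort(files)))
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest_path <- file.path(out_dir, "manifest.json")
  ## checksums (not timings) define reproducibility; keep elapsed out of the file
  m_out <- manifest[setdiff(names(manifest), "elapsed_s")]
  jsonlite::write_json(m_out, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
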