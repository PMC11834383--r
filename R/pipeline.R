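# End-to-end orchestration: records -> summaries -> covariates -> mixed
# models -> synchrony (raw and covariate-adjusted) -> output bundle.

#' Run the full analysis pipeline
#'
#' Stages: (1) summarise breeding records into filtered annual descriptors;
#' (2) assemble covariates when climate/nest/mast inputs are given; (3) fit
#' the per-covariate random-slope regressions; (4) fit the correlogram to
#' the chosen descriptor and bootstrap it; (5) refit after adjusting for
#' each requested covariate; (6) write all outputs plus a machine-readable
#' manifest. All randomness flows from `config$seed`.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `inputs` (paths: `records`, `sites`, optionally `climate`, `nests`,
#'   `mast`), `output_dir`, and optionally `descriptor` (default
#'   `"prop_subadult"`), `senescent_age_threshold`, `running_mean_window`,
#'   `min_n`, `min_aged_fraction`, `years` (e.g. `c(2000, 2022)`), `B`
#'   (bootstrap replicates, default 2000), `seed`,
#'   `reference_distances`, `adjust_covariates` (character vector),
#'   `covariate_names` (subset for the mixed models).
#' @return Invisibly, a list with the in-memory results (`summaries`,
#'   `covariates`, `mixed_models`, `fit`, `boot`, `adjusted`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs %||% stop_demosync("config$inputs missing")
  out_dir <- config$output_dir %||% stop_demosync("config$output_dir missing")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  descriptor <- config$descriptor %||% "prop_subadult"
  seed <- config$seed %||% 1L
  B <- config$B %||% 2000L
  ref_d <- config$reference_distances %||% c(100, 500, 1000, 2500)
  years <- if (!is.null(config$years))
    seq(config$years[1], config$years[2]) else NULL
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    message("[demosync] ", line)
    log_lines <<- c(log_lines, line)
  }

  note("stage ingest: reading ", inputs$records)
  records <- read_breeding_records(inputs$records)
  summaries <- summarise_structure(
    records,
    senescent_age_threshold = config$senescent_age_threshold %||% 4L,
    min_n = config$min_n %||% 20L,
    min_aged_fraction = config$min_aged_fraction %||% 0.25,
    window = config$running_mean_window %||% 5L)
  note("stage ingest: ", nrow(records), " records -> ", nrow(summaries),
       " population-years (", sum(summaries$passes_filters),
       " pass filters)")
  write.csv(summaries, file.path(out_dir, "summaries.csv"),
            row.names = FALSE, na = "")

  sites <- read_sites(inputs$sites)
  geometry <- haversine_matrix(sites)

  covariates <- NULL
  mixed_models <- NULL
  if (!is.null(inputs$nests)) {
    note("stage covariates")
    daily <- if (!is.null(inputs$climate)) read_daily_climate(inputs$climate)
             else data.frame(population_id = character(), date = as.Date(character()),
                             tmean = numeric(), tmin = numeric(),
                             tmax = numeric(), precip = numeric())
    mast <- if (!is.null(inputs$mast)) read_mast(inputs$mast)
            else data.frame(site_id = character(), lat = numeric(),
                            lon = numeric(), year = integer(),
                            mast_value = numeric())
    nests <- read_clutches(inputs$nests)
    covariates <- suppressWarnings(
      build_covariates(summaries, daily, nests, mast, sites))
    write.csv(covariates, file.path(out_dir, "covariates.csv"),
              row.names = FALSE, na = "")
    note("stage mixed models")
    mixed_models <- fit_all_covariates(
      summaries, covariates, response = descriptor,
      covariate_names = config$covariate_names)
    write.csv(mixed_models, file.path(out_dir, "mixed_models.csv"),
              row.names = FALSE, na = "")
  }

  note("stage synchrony: descriptor ", descriptor)
  panel <- build_panel(summaries, descriptor = descriptor, years = years)
  fit <- fit_synchrony(panel, geometry, seed = seed)
  boot <- synchrony_bootstrap(fit, B = B, reference_distances = ref_d,
                              seed = seed + 1L)
  note(sprintf("stage synchrony: rho0=%.3f l=%.0f km over %d years",
               fit$params$rho0, fit$params$l, fit$n_years_used))
  write_fit_report(fit, boot, file.path(out_dir, "synchrony_fit.json"))
  write.csv(boot$replicates,
            file.path(out_dir, "bootstrap_replicates.csv"),
            row.names = FALSE)
  write.csv(synchrony_curve(boot),
            file.path(out_dir, "synchrony_curve.csv"), row.names = FALSE)
  write.csv(pairwise_synchrony(panel, geometry),
            file.path(out_dir, "pairwise_correlations.csv"),
            row.names = FALSE)

  adjusted <- list()
  for (nm in config$adjust_covariates %||% character()) {
    if (is.null(covariates)) break
    note("stage adjusted synchrony: ", nm)
    adj <- tryCatch(
      adjust_for_covariate(summaries, covariates, nm,
                           descriptor = descriptor),
      error = function(e) { note("  skipped: ", conditionMessage(e)); NULL })
    if (is.null(adj)) next
    apanel <- build_panel(adj, descriptor = "value", years = years,
                          apply_filters = FALSE)
    afit <- fit_synchrony(apanel, geometry, seed = seed)
    aboot <- synchrony_bootstrap(afit, B = B, reference_distances = ref_d,
                                 seed = seed + 1L)
    write_fit_report(afit, aboot,
                     file.path(out_dir, paste0("synchrony_adjusted_", nm,
                                               ".json")))
    adjusted[[nm]] <- list(fit = afit, boot = aboot)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("demosync")),
    seed = seed, B = B, descriptor = descriptor,
    years = years %||% "all",
    n_populations = fit$n_populations,
    n_years_used = fit$n_years_used,
    reference_distances = ref_d,
    config = config[setdiff(names(config), "inputs")],
    inputs = inputs,
    config_hash = fnv1a_hash(config),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summaries = summaries, covariates = covariates,
                 mixed_models = mixed_models, fit = fit, boot = boot,
                 adjusted = adjusted, manifest = manifest))
}

write_fit_report <- function(fit, boot, path) {
  report <- list(
    point = list(rho0 = fit$params$rho0, rho_inf = fit$params$rho_inf,
                 l = fit$params$l, loglik = fit$loglik,
                 boundary = fit$boundary),
    plugin_rho = as.list(boot$plugin),
    bootstrap = list(B = boot$B, n_dropped = boot$n_dropped,
                     seed = boot$seed),
    summary = split(boot$summary[c("median", "lower", "upper")],
                    seq_len(nrow(boot$summary))) |>
      setNames(boot$summary$quantity) |>
      lapply(as.list),
    n_years_used = fit$n_years_used,
    n_populations = fit$n_populations)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
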