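# Seeded synthetic study generator: latent spatially correlated descriptor
# fields with known truth, individual-level records consistent with them,
# and covariate fields with known effects.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the shape of a continental nest-box study: 32
#' populations scattered over a roughly 3500 km extent (35-65 deg N,
#' 4 deg W - 33 deg E), years 1956-2022 with staggered multi-decade
#' observation windows (about a fifth of populations monitored 45-67
#' years, the rest 8-35), true correlogram (rho0, rho_inf, l) =
#' (0.35, 0, 650 km), a logistic link from the latent field to the
#' subadult proportion, lognormal breeder counts floored at 25, an aged
#' fraction uniform on (0.30, 0.85), adult ages 2 + Geometric(0.5) capped
#' at 9 (annual adult mortality above 50%), and clutch sizes around 8.5
#' eggs linked to the next year's latent value.
#'
#' @param n_populations Number of populations.
#' @param lat_range,lon_range Coordinate box (decimal degrees), used when
#'   `coords` is `NULL`.
#' @param coords Optional explicit data frame `population_id,lat,lon`.
#' @param years Study years.
#' @param window_lengths Optional integer vector of per-population series
#'   lengths (recycled); `NULL` draws the staggered default.
#' @param params True [synchrony_params()].
#' @param mu,sigma Latent logit-scale mean and sd of the subadult
#'   proportion.
#' @param n_breeders_meanlog,n_breeders_sdlog,n_breeders_min Lognormal
#'   breeder-count distribution and floor.
#' @param aged_fraction_range Uniform range of the aged fraction.
#' @param adult_survival Geometric survival rate for adult ages.
#' @param max_age Cap on generated ages.
#' @param clutch_mean,clutch_sd,clutch_link Clutch-size location, spread,
#'   and link (eggs per latent-sd unit of next year's field).
#' @param seed Top-level seed; all generator randomness flows from it.
#' @return Object of class `sim_config` (a list).
#' @export
simulation_config <- function(n_populations = 32L,
                              lat_range = c(35, 65),
                              lon_range = c(-4, 33),
                              coords = NULL,
                              years = 1956:2022,
                              window_lengths = NULL,
                              params = synchrony_params(0.35, 0, 650),
                              mu = 0, sigma = 0.8,
                              n_breeders_meanlog = log(140),
                              n_breeders_sdlog = 0.7,
                              n_breeders_min = 25L,
                              aged_fraction_range = c(0.30, 0.85),
                              adult_survival = 0.5,
                              max_age = 9L,
                              clutch_mean = 8.5,
                              clutch_sd = 1.5,
                              clutch_link = 0.5,
                              seed = 1L) {
  stopifnot(inherits(params, "synchrony_params"), sigma >= 0,
            n_populations >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

# coordinates and observation windows are drawn first so that every later
# stage conditions on the same design given one seed
simulate_design <- function(config) {
  ids <- sprintf("pop%02d", seq_len(config$n_populations))
  if (is.null(config$coords)) {
    coords <- data.frame(
      population_id = ids,
      lat = runif(config$n_populations, config$lat_range[1],
                  config$lat_range[2]),
      lon = runif(config$n_populations, config$lon_range[1],
                  config$lon_range[2]),
      stringsAsFactors = FALSE)
  } else {
    coords <- config$coords
    ids <- as.character(coords$population_id)
  }
  n_years <- length(config$years)
  if (is.null(config$window_lengths)) {
    long <- runif(length(ids)) < 0.2
    len <- ifelse(long,
                  round(runif(length(ids), 45, 67)),
                  round(runif(length(ids), 8, 35)))
    len <- pmin(len, n_years)
  } else {
    len <- pmin(rep_len(config$window_lengths, length(ids)), n_years)
  }
  start <- vapply(len, function(k) {
    sample.int(n_years - k + 1L, 1L)
  }, integer(1))
  windows <- lapply(seq_along(ids), function(i) {
    config$years[start[i]:(start[i] + len[i] - 1L)]
  })
  names(windows) <- ids
  list(ids = ids, coords = coords, windows = windows)
}

#' Simulate the latent spatially correlated descriptor field
#'
#' Draws, for every year, the observed populations' latent values from a
#' multivariate normal distribution with unit variances and correlations
#' given by the true correlogram; years are independent. Returns both the
#' raw draws and the per-population-normalised panel, plus the truth.
#'
#' @param config A [simulation_config()].
#' @return List with `values` (`population_id,year,value`, raw draws),
#'   `panel` (a `sync_panel` of the per-population z-normalised series),
#'   `geometry`, `windows`, `truth`, `config`.
#' @export
simulate_latent_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed)
  design <- simulate_design(config)
  geometry <- haversine_matrix(design$coords)
  obs <- do.call(rbind, lapply(design$ids, function(p) {
    data.frame(population_id = p, year = design$windows[[p]],
               stringsAsFactors = FALSE)
  }))
  # group years by observed set and draw via Cholesky
  by_year <- split(obs, obs$year)
  vals <- lapply(by_year, function(d) {
    idx <- match(d$population_id, geometry$ids)
    o <- order(idx)
    d <- d[o, , drop = FALSE]
    if (nrow(d) == 1L) {
      d$value <- rnorm(1)
    } else {
      S <- build_sigma(d$population_id, geometry, config$params)
      d$value <- as.numeric(t(chol(S)) %*% rnorm(nrow(d)))
    }
    d
  })
  values <- do.call(rbind, vals)
  rownames(values) <- NULL
  values <- values[order(values$population_id, values$year), , drop = FALSE]
  panel <- suppressMessages(
    build_panel(values, descriptor = "value", apply_filters = FALSE))
  list(values = values, panel = panel, geometry = geometry,
       windows = design$windows,
       truth = config$params, config = config)
}

#' Expand a latent field into individual breeding records and clutches
#'
#' Maps the latent value to a subadult proportion through an inverse-logit
#' link, draws the realised number of subadults among aged breeders as a
#' binomial, and emits one capture record per breeder: aged individuals
#' carry their hatch year (subadults hatched the previous year; adults get
#' ages from a geometric survival tail and a chick-marked history), while
#' the remaining breeders are unidentified rows. Clutch sizes are drawn
#' around `clutch_mean` plus `clutch_link` times the next year's latent
#' value, so that large clutch years precede young breeding populations.
#' Summarising the emitted records recovers the realised subadult fraction
#' exactly.
#'
#' @param field Output of [simulate_latent_field()].
#' @param config The same [simulation_config()].
#' @return List with `records`, `clutches`, `expected` (per
#'   population-year: latent value, link-scale proportion `p`, realised
#'   `prop_subadult`, `n_breeders`, `n_aged`).
#' @export
latent_to_records <- function(field, config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed + 1L)
  v <- field$values
  recs <- vector("list", nrow(v))
  clutch <- vector("list", nrow(v))
  expected <- vector("list", nrow(v))
  lat_by_key <- setNames(v$value, paste(v$population_id, v$year))
  for (i in seq_len(nrow(v))) {
    p_id <- v$population_id[i]
    yr <- v$year[i]
    p <- plogis(config$mu + config$sigma * v$value[i])
    n_breeders <- max(config$n_breeders_min,
                      round(rlnorm(1, config$n_breeders_meanlog,
                                   config$n_breeders_sdlog)))
    n_aged <- max(2L, round(runif(1, config$aged_fraction_range[1],
                                  config$aged_fraction_range[2]) *
                              n_breeders))
    n_sub <- rbinom(1, n_aged, p)
    n_ad <- n_aged - n_sub
    ad_ages <- if (n_ad > 0)
      pmin(2L + rgeom(n_ad, config$adult_survival), config$max_age)
    else integer()
    ages <- c(rep(1L, n_sub), ad_ages)
    ids <- sprintf("%s_%d_i%04d", p_id, yr, seq_len(n_breeders))
    n_unident <- n_breeders - n_aged
    recs[[i]] <- data.frame(
      population_id = p_id, year = yr,
      individual_id = c(ids[seq_len(n_aged)],
                        rep(NA_character_, n_unident)),
      hatch_year = c(yr - ages, rep(NA_integer_, n_unident)),
      first_capture_age_class = c(ifelse(ages == 1L, "subadult", "chick"),
                                  rep(NA_character_, n_unident)),
      sex = sample(c("F", "M"), n_breeders, replace = TRUE),
      stringsAsFactors = FALSE)
    n_nests <- max(1L, n_breeders %/% 2L)
    y_next <- lat_by_key[paste(p_id, yr + 1L)]
    if (is.na(y_next)) y_next <- 0
    clutch[[i]] <- data.frame(
      population_id = p_id, year = yr,
      nest_id = sprintf("%s_%d_n%04d", p_id, yr, seq_len(n_nests)),
      clutch_size = pmax(1L, round(rnorm(n_nests,
                                         config$clutch_mean +
                                           config$clutch_link * y_next,
                                         config$clutch_sd))),
      stringsAsFactors = FALSE)
    expected[[i]] <- data.frame(
      population_id = p_id, year = yr, latent = v$value[i], p = p,
      prop_subadult = n_sub / n_aged, n_breeders = n_breeders,
      n_aged = n_aged, stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs),
       clutches = do.call(rbind, clutch),
       expected = do.call(rbind, expected))
}

#' Simulate a covariate field with a known effect on the descriptor
#'
#' Draws a covariate from its own spatially correlated field (or a single
#' shared series when `synchronous`), then constructs the latent descriptor
#' as `beta * covariate + residual field`, where the residual field has the
#' configuration's true correlogram. The output records both truths, so a
#' covariate-adjusted synchrony fit can be compared against the residual
#' field's parameters.
#'
#' @param config A [simulation_config()]; its `params` are the residual
#'   field's truth.
#' @param name Covariate name used in the output table.
#' @param beta Effect size (latent-sd units per covariate-sd unit).
#' @param cov_params [synchrony_params()] of the covariate field (ignored
#'   when `synchronous`).
#' @param synchronous If `TRUE` the covariate is identical across sites
#'   each year (perfect synchrony).
#' @return List with `covariates` (long table), `values` (combined latent
#'   descriptor), `panel`, `geometry`, `truth_residual`, `truth_covariate`,
#'   `beta`.
#' @export
simulate_covariate_field <- function(config, name = "covariate",
                                     beta = 1,
                                     cov_params = synchrony_params(0.9, 0,
                                                                   1000),
                                     synchronous = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  resid_field <- simulate_latent_field(config)
  local_seed(config$seed + 2L)
  obs <- resid_field$values
  geometry <- resid_field$geometry
  by_year <- split(obs, obs$year)
  cov_vals <- lapply(by_year, function(d) {
    idx <- match(d$population_id, geometry$ids)
    d <- d[order(idx), , drop = FALSE]
    n <- nrow(d)
    if (synchronous) {
      d$cov <- rep(rnorm(1), n)
    } else if (n == 1L) {
      d$cov <- rnorm(1)
    } else {
      S <- build_sigma(d$population_id, geometry, cov_params)
      d$cov <- as.numeric(t(chol(S)) %*% rnorm(n))
    }
    d
  })
  cov_df <- do.call(rbind, cov_vals)
  rownames(cov_df) <- NULL
  combined <- data.frame(population_id = cov_df$population_id,
                         year = cov_df$year,
                         value = beta * cov_df$cov + cov_df$value,
                         stringsAsFactors = FALSE)
  combined <- combined[order(combined$population_id, combined$year), ,
                       drop = FALSE]
  panel <- suppressMessages(
    build_panel(combined, descriptor = "value", apply_filters = FALSE))
  covariates <- data.frame(population_id = cov_df$population_id,
                           year = cov_df$year, name = name,
                           value = cov_df$cov,
                           meta_distance_km = NA_real_,
                           stringsAsFactors = FALSE)
  list(covariates = covariates, values = combined, panel = panel,
       geometry = geometry, truth_residual = config$params,
       truth_covariate = if (synchronous) NULL else cov_params,
       beta = beta)
}

#' Simulate a complete synthetic study
#'
#' Latent field, individual records, clutch table, site table, and daily
#' climate / mast tables in the CSV dialects the ingest and covariate
#' modules consume.
#'
#' @param config A [simulation_config()].
#' @return List with `records`, `clutches`, `sites`, `field`, `expected`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  field <- simulate_latent_field(config)
  tabs <- latent_to_records(field, config)
  sites <- field$geometry
  sites_df <- data.frame(population_id = sites$ids,
                         lat = unname(sites$lat),
                         lon = unname(sites$lon),
                         beech_flag = TRUE,
                         stringsAsFactors = FALSE)
  list(records = tabs$records, clutches = tabs$clutches,
       sites = sites_df, field = field, expected = tabs$expected,
       truth = config$params, config = config)
}

#' Write a synthetic bundle to disk
#'
#' Emits `records.csv`, `clutches.csv`, `sites.csv` and `truth.json` in the
#' dialects consumed by the readers; byte-identical for a given config.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  paths <- list(records = file.path(dir, "records.csv"),
                clutches = file.path(dir, "clutches.csv"),
                sites = file.path(dir, "sites.csv"),
                truth = file.path(dir, "truth.json"))
  write.csv(study$records, paths$records, row.names = FALSE, na = "")
  write.csv(study$clutches, paths$clutches, row.names = FALSE, na = "")
  write.csv(study$sites, paths$sites, row.names = FALSE, na = "")
  truth <- list(rho0 = study$truth$rho0, rho_inf = study$truth$rho_inf,
                l = study$truth$l, seed = config$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
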