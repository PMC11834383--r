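# programmatic fixtures shared across tests

# a one-population breeding-records table from explicit ages
records_from_ages <- function(ages, population_id = "A", year = 2000,
                              n_unidentified = 0L) {
  n <- length(ages)
  rec <- data.frame(
    population_id = population_id, year = year,
    individual_id = sprintf("%s_%d_%03d", population_id, year, seq_len(n)),
    hatch_year = year - ages,
    first_capture_age_class = ifelse(ages == 1L, "subadult", "chick"),
    sex = "F", stringsAsFactors = FALSE)
  if (n_unidentified > 0L) {
    unk <- data.frame(
      population_id = population_id, year = year,
      individual_id = NA_character_, hatch_year = NA_integer_,
      first_capture_age_class = NA_character_, sex = "M",
      stringsAsFactors = FALSE)
    rec <- rbind(rec, unk[rep(1L, n_unidentified), ])
  }
  rownames(rec) <- NULL
  rec
}

# random site geometry inside the study's coordinate box
random_geometry <- function(n, seed = 1) {
  set.seed(seed)
  haversine_matrix(data.frame(
    population_id = sprintf("p%02d", seq_len(n)),
    lat = runif(n, 35, 65), lon = runif(n, -4, 33),
    stringsAsFactors = FALSE))
}

# small rectangular panel (every population observed every year) drawn from
# the model, via the synthetic generator with explicit design
small_field <- function(n_pops = 10, n_years = 40, seed = 1,
                        params = synchrony_params(0.35, 0, 650)) {
  cfg <- simulation_config(n_populations = n_pops,
                           years = seq_len(n_years) + 1950L,
                           window_lengths = n_years,
                           params = params, seed = seed)
  simulate_latent_field(cfg)
}

# independent R-side MVN log-density via explicit matrix inverse
mvn_loglik_explicit <- function(y, S) {
  n <- length(y)
  Sinv <- solve(S)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                       t(y) %*% Sinv %*% y))
}

# spherical law of cosines distance, an independent oracle for haversine
slc_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  acos(pmin(1, pmax(-1,
    sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)))) * 6371
}
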