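# Per-population-year explanatory variables: lagged clutch size, seasonal
# climate, extreme-event counts, and nearest-site beech mast.

COVARIATE_NAMES <- c("clutch_size_lag1",
                     "temp_summer", "temp_autumn", "temp_winter",
                     "temp_spring",
                     "precip_summer", "precip_autumn", "precip_winter",
                     "precip_spring",
                     "n_cold_ece", "n_hot_ece",
                     "mast_lag1", "mast_lag1_local")

#' Read per-population daily climate
#'
#' Header: `population_id,date,tmean,tmin,tmax,precip` (date `YYYY-MM-DD`,
#' temperatures in degrees C, precipitation in mm).
#' @param path CSV path.
#' @return Data frame with `date` parsed as `Date`.
#' @export
read_daily_climate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(population_id = "character"))
  need <- c("population_id", "date", "tmean", "tmin", "tmax", "precip")
  if (!all(need %in% names(df)))
    stop_demosync("daily climate missing columns: ",
                  paste(setdiff(need, names(df)), collapse = ", "))
  df$date <- as.Date(df$date)
  df
}

#' Read a clutch table (`population_id,year,nest_id,clutch_size`)
#' @param path CSV path.
#' @return Data frame.
#' @export
read_clutches <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(population_id = "character"))
}

#' Read mast records (`site_id,lat,lon,year,mast_value`)
#' @param path CSV path.
#' @return Data frame.
#' @export
read_mast <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read site metadata (`population_id,lat,lon,beech_flag`)
#' @param path CSV path.
#' @return Data frame with logical `beech_flag`.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(population_id = "character"))
  df$beech_flag <- as.logical(df$beech_flag)
  df
}

# season of a date relative to a focal breeding year, or NA outside the
# June(year-1)-May(year) window
season_of <- function(date, breeding_year) {
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  s <- rep(NA_character_, length(date))
  s[y == breeding_year - 1L & m %in% 6:8] <- "summer"
  s[y == breeding_year - 1L & m %in% 9:11] <- "autumn"
  s[(y == breeding_year - 1L & m == 12L) |
      (y == breeding_year & m %in% 1:2)] <- "winter"
  s[y == breeding_year & m %in% 3:5] <- "spring"
  s
}

# calendar day counts of each season preceding a given breeding year
season_lengths <- function(breeding_year) {
  from <- as.Date(sprintf("%d-06-01", breeding_year - 1L))
  to <- as.Date(sprintf("%d-05-31", breeding_year))
  days <- seq(from, to, by = "day")
  table(factor(season_of(days, breeding_year),
               levels = c("summer", "autumn", "winter", "spring")))
}

#' Seasonal climate means preceding a breeding season
#'
#' Averages daily mean temperature and daily precipitation over the four
#' seasons preceding breeding in `breeding_year`: summer (Jun-Aug of the
#' previous year), autumn (Sep-Nov), winter (Dec-Feb) and spring (Mar-May of
#' the breeding year). A seasonal value is set to missing, with a warning,
#' when more than `max_missing_frac` of the season's calendar days lack data.
#'
#' @param daily Daily climate data frame (see [read_daily_climate()]).
#' @param population_id Focal population.
#' @param breeding_year Focal breeding year.
#' @param max_missing_frac Tolerated fraction of missing days; default 0.1.
#' @return Named list with `temp_summer` ... `precip_spring` (8 values).
#' @export
seasonal_aggregate <- function(daily, population_id, breeding_year,
                               max_missing_frac = 0.1) {
  d <- daily[daily$population_id == population_id, , drop = FALSE]
  s <- season_of(d$date, breeding_year)
  keep <- !is.na(s)
  d <- d[keep, , drop = FALSE]
  s <- s[keep]
  expected <- season_lengths(breeding_year)
  out <- list()
  for (season in c("summer", "autumn", "winter", "spring")) {
    for (var in c("tmean", "precip")) {
      x <- d[[var]][s == season]
      x <- x[!is.na(x)]
      nm <- paste0(if (var == "tmean") "temp_" else "precip_", season)
      n_exp <- as.integer(expected[[season]])
      if (length(x) < (1 - max_missing_frac) * n_exp) {
        warning(sprintf("%s %d %s: %d/%d days present, value set missing",
                        population_id, breeding_year, nm, length(x), n_exp),
                call. = FALSE)
        out[[nm]] <- NA_real_
      } else {
        out[[nm]] <- mean(x)
      }
    }
  }
  out
}

#' Count extreme climatic events in the year preceding breeding
#'
#' Thresholds are the empirical 5th percentile of daily minimum temperature
#' and 95th percentile of daily maximum temperature over the population's
#' full record (linear-interpolation quantiles). A cold event is a day with
#' `tmin` strictly below the lower threshold, a hot event a day with `tmax`
#' strictly above the upper one; days are counted in the 12-month window
#' June 1 (year-1) to May 31 (year).
#'
#' @param daily Daily climate for one population over the full study period.
#' @param breeding_year Focal breeding year.
#' @param probs Lower/upper tail probabilities; default `c(0.05, 0.95)`.
#' @return Named list `n_cold_ece`, `n_hot_ece` (integer or `NA` when the
#'   count window has no data).
#' @export
count_eces <- function(daily, breeding_year, probs = c(0.05, 0.95)) {
  if (!nrow(daily) || all(is.na(daily$tmin)) || all(is.na(daily$tmax)))
    return(list(n_cold_ece = NA_integer_, n_hot_ece = NA_integer_))
  lo <- quantile(daily$tmin, probs[1], na.rm = TRUE, names = FALSE, type = 7)
  hi <- quantile(daily$tmax, probs[2], na.rm = TRUE, names = FALSE, type = 7)
  from <- as.Date(sprintf("%d-06-01", breeding_year - 1L))
  to <- as.Date(sprintf("%d-05-31", breeding_year))
  win <- daily[daily$date >= from & daily$date <= to, , drop = FALSE]
  if (!nrow(win)) return(list(n_cold_ece = NA_integer_,
                              n_hot_ece = NA_integer_))
  list(n_cold_ece = sum(win$tmin < lo, na.rm = TRUE),
       n_hot_ece = sum(win$tmax > hi, na.rm = TRUE))
}

#' Mean clutch size in the year preceding breeding
#'
#' The mean number of eggs per breeding attempt in `breeding_year - 1`;
#' all attempts (including second clutches) count by default. Non-positive
#' clutch sizes are rejected with a warning.
#'
#' @param nests Clutch table (`population_id,year,nest_id,clutch_size`).
#' @param population_id Focal population.
#' @param breeding_year Focal breeding year (the lag is applied internally).
#' @param first_clutches_only If `TRUE` and the table has an `attempt`
#'   column, keep only `attempt == 1`.
#' @return Mean clutch size, or `NA` when no attempts were recorded.
#' @export
mean_clutch_size_lag <- function(nests, population_id, breeding_year,
                                 first_clutches_only = FALSE) {
  sub <- nests[nests$population_id == population_id &
                 nests$year == breeding_year - 1L, , drop = FALSE]
  if (first_clutches_only && "attempt" %in% names(sub))
    sub <- sub[sub$attempt == 1L, , drop = FALSE]
  bad <- !is.na(sub$clutch_size) & sub$clutch_size <= 0
  if (any(bad)) {
    warning(sum(bad), " clutch row(s) with non-positive size rejected",
            call. = FALSE)
    sub <- sub[!bad, , drop = FALSE]
  }
  x <- sub$clutch_size[!is.na(sub$clutch_size)]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' Match the nearest beech-mast record to a population
#'
#' Selects, among mast sites with a record in `breeding_year - 1`, the one
#' nearest to the population by great-circle distance. The value is missing
#' when the nearest such site lies farther than `max_km`. A match is "local"
#' when the distance is at most `local_km` and the population lies within
#' the beech distribution (`beech_flag`). Distance ties resolve to the
#' lowest site index (input order), with a message.
#'
#' @param site_lat,site_lon Population coordinates (decimal degrees).
#' @param beech_flag Logical: population within the beech distribution.
#' @param mast Mast records (`site_id,lat,lon,year,mast_value`).
#' @param breeding_year Focal breeding year.
#' @param max_km Maximum usable distance; default 1500.
#' @param local_km Distance defining a local match; default 100.
#' @return List `mast_lag1`, `distance_km`, `is_local`, `site_id`.
#' @export
match_mast <- function(site_lat, site_lon, beech_flag, mast, breeding_year,
                       max_km = 1500, local_km = 100) {
  cand <- mast[mast$year == breeding_year - 1L &
                 !is.na(mast$mast_value), , drop = FALSE]
  if (!nrow(cand))
    return(list(mast_lag1 = NA_real_, distance_km = NA_real_,
                is_local = FALSE, site_id = NA))
  d <- haversine_km(site_lat, site_lon, cand$lat, cand$lon)
  best <- which(d == min(d))
  if (length(best) > 1L)
    message("mast distance tie at ", round(min(d), 3),
            " km; lowest site index used")
  best <- best[1L]
  if (d[best] > max_km)
    return(list(mast_lag1 = NA_real_, distance_km = d[best],
                is_local = FALSE, site_id = cand$site_id[best]))
  list(mast_lag1 = cand$mast_value[best],
       distance_km = d[best],
       is_local = isTRUE(beech_flag) && d[best] <= local_km,
       site_id = cand$site_id[best])
}

#' Assemble the full covariate table
#'
#' Builds, for every population-year in `summaries`, the 13 explanatory
#' variables: previous-year mean clutch size; four seasonal temperature and
#' four seasonal precipitation means; cold and hot extreme-event counts;
#' nearest-site beech mast (previous year); and the same mast value
#' restricted to local matches within the beech distribution.
#'
#' @param summaries Annual summaries (defines the population-years).
#' @param daily Daily climate table covering all populations.
#' @param nests Clutch table.
#' @param mast Mast records.
#' @param sites Site metadata (`population_id,lat,lon,beech_flag`).
#' @param max_km,local_km Mast matching distances (km).
#' @return Long-format data frame
#'   `population_id,year,name,value,meta_distance_km`.
#' @export
build_covariates <- function(summaries, daily, nests, mast, sites,
                             max_km = 1500, local_km = 100) {
  rows <- list()
  daily_by_pop <- split(daily, daily$population_id)
  for (i in seq_len(nrow(summaries))) {
    p <- summaries$population_id[i]
    y <- summaries$year[i]
    site <- sites[sites$population_id == p, , drop = FALSE]
    if (!nrow(site))
      stop_demosync("population ", p, " missing from sites table")
    vals <- list()
    metas <- list()

    vals$clutch_size_lag1 <- mean_clutch_size_lag(nests, p, y)
    dpop <- daily_by_pop[[p]]
    if (!is.null(dpop)) {
      vals <- c(vals, seasonal_aggregate(dpop, p, y))
      vals <- c(vals, count_eces(dpop, y))
    } else {
      for (nm in COVARIATE_NAMES[2:11]) vals[[nm]] <- NA_real_
    }
    m <- match_mast(site$lat[1], site$lon[1], site$beech_flag[1],
                    mast, y, max_km = max_km, local_km = local_km)
    vals$mast_lag1 <- m$mast_lag1
    vals$mast_lag1_local <- if (m$is_local) m$mast_lag1 else NA_real_
    metas$mast_lag1 <- m$distance_km
    metas$mast_lag1_local <- m$distance_km

    for (nm in COVARIATE_NAMES) {
      rows[[length(rows) + 1L]] <- data.frame(
        population_id = p, year = y, name = nm,
        value = as.numeric(vals[[nm]] %||% NA_real_),
        meta_distance_km = as.numeric(metas[[nm]] %||% NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
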