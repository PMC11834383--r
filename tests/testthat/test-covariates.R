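make_daily <- function(from, to, tmean = 5, tmin = NULL, tmax = NULL,
                       precip = 1, population_id = "A") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  n <- length(dates)
  data.frame(population_id = population_id, date = dates,
             tmean = rep_len(tmean, n),
             tmin = rep_len(tmin %||% (tmean - 5), n),
             tmax = rep_len(tmax %||% (tmean + 5), n),
             precip = rep_len(precip, n), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("seasonal means reproduce constant and window-disjoint inputs", {
  d <- make_daily("1999-06-01", "2000-05-31")
  s <- seasonal_aggregate(d, "A", 2000)
  expect_equal(unname(unlist(s[paste0("temp_", c("summer", "autumn",
                                                 "winter", "spring"))])),
               rep(5, 4))
  d2 <- d
  d2$tmean <- ifelse(format(d2$date, "%m") %in% c("06", "07", "08") &
                       format(d2$date, "%Y") == "1999", 10, 0)
  s2 <- seasonal_aggregate(d2, "A", 2000)
  expect_equal(s2$temp_summer, 10)
  expect_equal(s2$temp_winter, 0)
})

test_that("seasonal windows partition the year and match a calendar oracle", {
  days <- seq(as.Date("1999-06-01"), as.Date("2000-05-31"), by = "day")
  season <- demosync:::season_of(days, 2000)
  expect_false(anyNA(season))  # every day in exactly one season
  expect_equal(sum(table(season)), length(days))

  set.seed(3)
  d <- make_daily("1999-06-01", "2000-05-31")
  d$tmean <- rnorm(nrow(d))
  d$precip <- rexp(nrow(d))
  s <- seasonal_aggregate(d, "A", 2000)
  in_window <- function(from, to) d$date >= as.Date(from) &
    d$date <= as.Date(to)
  expect_equal(s$temp_autumn,
               mean(d$tmean[in_window("1999-09-01", "1999-11-30")]))
  expect_equal(s$precip_winter,
               mean(d$precip[in_window("1999-12-01", "2000-02-29")]))
  expect_equal(s$temp_spring,
               mean(d$tmean[in_window("2000-03-01", "2000-05-31")]))
})

test_that("seasonal means go missing past the missing-day tolerance", {
  d <- make_daily("1999-06-01", "2000-05-31")
  d <- d[!(d$date >= as.Date("1999-06-01") &
             d$date <= as.Date("1999-06-15")), ]  # 15/92 summer days gone
  w <- capture_warnings(s <- seasonal_aggregate(d, "A", 2000))
  expect_true(any(grepl("temp_summer", w)))
  expect_true(is.na(s$temp_summer))
  expect_false(is.na(s$temp_autumn))
})

test_that("extreme-event counts use full-record thresholds and strict tails", {
  # degenerate distribution: thresholds equal the constant, strict
  # inequalities never met
  d <- make_daily("1999-06-01", "2000-05-31", tmin = 0, tmax = 10)
  e <- count_eces(d, 2000)
  expect_equal(e$n_cold_ece, 0L)
  expect_equal(e$n_hot_ece, 0L)

  # 20-day toy record with one clearly extreme cold day
  d2 <- make_daily("1999-06-01", "1999-06-20")
  d2$tmin <- c(-20, rep(0:3, 5)[-1])
  d2$tmax <- rep(10, 20)
  lo <- quantile(d2$tmin, 0.05, type = 7, names = FALSE)
  expect_equal(count_eces(d2, 2000)$n_cold_ece, sum(d2$tmin < lo))
  expect_equal(count_eces(d2, 2000)$n_cold_ece, 1L)

  # i.i.d. record spanning exactly the count window: expect ~5% of days
  set.seed(5)
  d3 <- make_daily("1999-06-01", "2000-05-31")
  d3$tmin <- rnorm(nrow(d3))
  d3$tmax <- rnorm(nrow(d3), 20)
  e3 <- count_eces(d3, 2000)
  n <- nrow(d3)
  expect_lt(abs(e3$n_cold_ece - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95) + 1)
  expect_lt(abs(e3$n_hot_ece - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95) + 1)
})

test_that("extreme-event counts are invariant to joint monotone transforms", {
  set.seed(9)
  d <- make_daily("1998-06-01", "2001-05-31")
  d$tmin <- rnorm(nrow(d), 0, 4)
  d$tmax <- rnorm(nrow(d), 15, 4)
  base <- count_eces(d, 2000)
  d2 <- d
  d2$tmin <- exp(d$tmin / 4)          # strictly increasing
  d2$tmax <- -1 / (1 + exp(d$tmax))   # strictly increasing
  expect_equal(count_eces(d2, 2000), base)
})

test_that("lagged clutch means follow the arithmetic and reject bad rows", {
  nests <- data.frame(population_id = "A", year = 1999L,
                      nest_id = c("n1", "n2", "n3"),
                      clutch_size = c(8L, 10L, 9L), stringsAsFactors = FALSE)
  expect_equal(mean_clutch_size_lag(nests, "A", 2000), 9)
  expect_true(is.na(mean_clutch_size_lag(nests, "A", 1999)))
  expect_warning(
    bad <- mean_clutch_size_lag(
      rbind(nests, data.frame(population_id = "A", year = 1999L,
                              nest_id = "n4", clutch_size = 0L)),
      "A", 2000),
    "non-positive")
  expect_equal(bad, 9)

  set.seed(13)
  sizes <- sample(4:14, 50, replace = TRUE)
  many <- data.frame(population_id = "A", year = 1999L,
                     nest_id = sprintf("n%02d", 1:50), clutch_size = sizes)
  expect_equal(mean_clutch_size_lag(many, "A", 2000), sum(sizes) / 50)
})

test_that("mast matching picks the nearest in-year site within range", {
  mast <- data.frame(site_id = 1:3,
                     lat = c(50, 51, 60), lon = c(0, 0, 10),
                     year = 1999L, mast_value = c(1.5, 2.5, 3.5))
  m <- match_mast(50, 0, TRUE, mast, 2000)
  expect_equal(m$mast_lag1, 1.5)
  expect_equal(m$distance_km, 0)
  expect_true(m$is_local)
  # beyond the usable range: value missing
  far <- data.frame(site_id = 1, lat = 50, lon = 0, year = 1999L,
                    mast_value = 9)
  m2 <- match_mast(35.5, 0, TRUE, far, 2000)  # ~1612 km away
  expect_gt(m2$distance_km, 1500)
  expect_true(is.na(m2$mast_lag1))
  # no records in the lag year
  expect_true(is.na(match_mast(50, 0, TRUE, far, 1999)$mast_lag1))
})

test_that("mast matching agrees with an exhaustive distance oracle", {
  set.seed(17)
  for (i in 1:10) {
    mast <- data.frame(site_id = 1:3, lat = runif(3, 35, 65),
                       lon = runif(3, -4, 33), year = 1999L,
                       mast_value = rnorm(3))
    plat <- runif(1, 35, 65); plon <- runif(1, -4, 33)
    d <- slc_km(plat, plon, mast$lat, mast$lon)
    m <- match_mast(plat, plon, TRUE, mast, 2000, max_km = Inf)
    expect_equal(m$site_id, mast$site_id[which.min(d)])
    expect_equal(m$distance_km, min(d), tolerance = 1 / min(d))
  }
})

test_that("great-circle distances behave and match the alternate formula", {
  expect_equal(haversine_km(51, 4, 51, 4), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  set.seed(19)
  lat1 <- runif(20, -80, 80); lon1 <- runif(20, -170, 170)
  lat2 <- runif(20, -80, 80); lon2 <- runif(20, -170, 170)
  expect_lt(max(abs(haversine_km(lat1, lon1, lat2, lon2) -
                      slc_km(lat1, lon1, lat2, lon2))), 1)
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  # distance matrix: symmetric, zero diagonal
  g <- random_geometry(6, seed = 2)
  expect_equal(g$dist_km, t(g$dist_km))
  expect_equal(diag(g$dist_km), setNames(rep(0, 6), g$ids))
  expect_true(all(g$dist_km[upper.tri(g$dist_km)] > 0))
})

test_that("the assembled covariate table is complete and long-format", {
  rec <- records_from_ages(c(1, 1, 2, 3, 4), year = 2000)
  summaries <- summarise_structure(rec)
  daily <- make_daily("1998-06-01", "2000-05-31")
  nests <- data.frame(population_id = "A", year = 1999L, nest_id = "n1",
                      clutch_size = 9L)
  mast <- data.frame(site_id = 1L, lat = 50, lon = 0, year = 1999L,
                     mast_value = 2)
  sites <- data.frame(population_id = "A", lat = 50, lon = 0,
                      beech_flag = TRUE)
  cv <- build_covariates(summaries, daily, nests, mast, sites)
  expect_equal(nrow(cv), 13L)
  expect_setequal(cv$name, demosync:::COVARIATE_NAMES)
  expect_equal(cv$value[cv$name == "clutch_size_lag1"], 9)
  expect_equal(cv$value[cv$name == "mast_lag1"], 2)
  expect_equal(cv$value[cv$name == "mast_lag1_local"], 2)
  expect_equal(cv$value[cv$name == "temp_winter"], 5)
})
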