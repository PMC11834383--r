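test_that("the correlogram interpolates between its limits monotonically", {
  p <- synchrony_params(0.5, 0.1, 650)
  expect_equal(synchrony_rho(0, p), 0.5)
  expect_equal(synchrony_rho(1e7, p), 0.1)
  d <- seq(0, 5000, by = 10)
  r <- synchrony_rho(d, p)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= 0.1 & r <= 0.5))
  # plug-in values at the reported parameter scale
  tab <- synchrony_params(0.344, 0, 641)
  expect_equal(round(synchrony_rho(500, tab), 4), 0.2538)
  expect_error(synchrony_params(1, 0, 650), "rho0")
  expect_error(synchrony_params(0.3, 0.4, 650), "rho_inf")
  expect_error(synchrony_params(0.3, 0.1, 0), "positive")
})

test_that("yearly correlation matrices match element-wise evaluation", {
  g <- random_geometry(5, seed = 4)
  p0 <- synchrony_params(0, 0, 650)
  expect_equal(unname(build_sigma(g$ids, g, p0)), diag(5))
  p <- synchrony_params(0.4, 0.05, 800)
  S <- build_sigma(g$ids, g, p)
  for (i in 1:5) for (j in 1:5) {
    expected <- if (i == j) 1 else synchrony_rho(g$dist_km[i, j], p)
    expect_equal(unname(S[i, j]), expected)
  }
  # two populations: off-diagonal is rho(d)
  g2 <- random_geometry(2, seed = 5)
  S2 <- build_sigma(g2$ids, g2, p)
  expect_equal(S2[1, 2], synchrony_rho(g2$dist_km[1, 2], p),
               ignore_attr = TRUE)
})

test_that("the summed annual log-likelihood matches closed forms", {
  # single year, two independent populations, values at the origin
  g2 <- random_geometry(2, seed = 6)
  panel0 <- suppressMessages(build_panel(
    data.frame(population_id = rep(g2$ids, each = 3),
               year = rep(2000:2002, 2),
               value = rep(c(-1, 0, 1), 2)),
    descriptor = "value", apply_filters = FALSE))
  p0 <- synchrony_params(0, 0, 650)
  # three years of a standard bivariate normal at (-1,-1),(0,0),(1,1)
  expect_equal(log_likelihood(p0, panel0, g2),
               sum(dnorm(c(-1, 0, 1, -1, 0, 1), log = TRUE)))
  # correlated closed form: bivariate normal density
  p <- synchrony_params(0.6, 0.2, 900)
  r <- synchrony_rho(g2$dist_km[1, 2], p)
  y <- cbind(c(-1, 0, 1), c(-1, 0, 1))
  closed <- sum(vapply(1:3, function(t) {
    q <- (y[t, 1]^2 - 2 * r * y[t, 1] * y[t, 2] + y[t, 2]^2) / (1 - r^2)
    -log(2 * pi) - 0.5 * log(1 - r^2) - 0.5 * q
  }, numeric(1)))
  expect_equal(log_likelihood(p, panel0, g2), closed, tolerance = 1e-10)
})

test_that("the likelihood agrees with an explicit-inverse quadratic form", {
  set.seed(21)
  for (trial in 1:5) {
    n <- sample(3:5, 1)
    g <- random_geometry(n, seed = 21 + trial)
    vals <- do.call(rbind, lapply(g$ids, function(id) {
      data.frame(population_id = id, year = 2000:2002, value = rnorm(3))
    }))
    panel <- suppressMessages(build_panel(vals, descriptor = "value",
                                          apply_filters = FALSE))
    p <- synchrony_params(runif(1, 0.1, 0.7), runif(1, 0, 0.1),
                          runif(1, 200, 1500))
    S <- build_sigma(g$ids, g, p)
    oracle <- sum(vapply(2000:2002, function(yr) {
      d <- panel$data[panel$data$year == yr, ]
      d <- d[order(match(d$population_id, g$ids)), ]
      mvn_loglik_explicit(d$value, S)
    }, numeric(1)))
    expect_equal(log_likelihood(p, panel, g), oracle, tolerance = 1e-8)
  }
})

test_that("years with fewer than two observed populations are dropped", {
  g <- random_geometry(3, seed = 8)
  vals <- rbind(
    data.frame(population_id = g$ids[1], year = 1996:2002,
               value = rnorm(7)),
    data.frame(population_id = g$ids[2], year = 2000:2006,
               value = rnorm(7)))
  panel <- suppressMessages(build_panel(vals, descriptor = "value",
                                        apply_filters = FALSE))
  pg <- demosync:::panel_groups(panel, g)
  expect_equal(pg$n_years, 3L)  # only 2000:2002 are shared
  expect_equal(sort(unique(unlist(lapply(pg$groups, `[[`, "years")))),
               2000:2002)
})

test_that("the fit is invariant to relabelling and unobserved populations", {
  f <- small_field(8, 35, seed = 31)
  fit1 <- fit_synchrony(f$panel, f$geometry, seed = 1)
  # append an unobserved population to the geometry
  coords <- data.frame(population_id = c(f$geometry$ids, "ghost"),
                       lat = c(unname(f$geometry$lat), 48),
                       lon = c(unname(f$geometry$lon), 10))
  fit2 <- fit_synchrony(f$panel, haversine_matrix(coords), seed = 1)
  expect_equal(fit2$params$rho0, fit1$params$rho0, tolerance = 1e-6)
  expect_equal(fit2$params$l, fit1$params$l, tolerance = 1e-4)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
  # relabel populations (consistently in panel and geometry)
  relab <- function(x) paste0("site_", x)
  panel3 <- f$panel
  panel3$data$population_id <- relab(panel3$data$population_id)
  panel3$populations <- sort(unique(panel3$data$population_id))
  coords3 <- data.frame(population_id = relab(f$geometry$ids),
                        lat = unname(f$geometry$lat),
                        lon = unname(f$geometry$lon))
  fit3 <- fit_synchrony(panel3, haversine_matrix(coords3), seed = 1)
  expect_equal(fit3$params$rho0, fit1$params$rho0, tolerance = 1e-6)
  expect_equal(fit3$loglik, fit1$loglik, tolerance = 1e-8)
})

test_that("independent series yield near-zero synchrony", {
  f <- small_field(10, 50, seed = 33, params = synchrony_params(0, 0, 650))
  fit <- fit_synchrony(f$panel, f$geometry, seed = 2)
  expect_lt(fit$params$rho0, 0.12)
})

test_that("perfectly shared series drive the fit to the upper boundary", {
  g <- random_geometry(5, seed = 9)
  set.seed(10)
  shared <- rnorm(30)
  vals <- do.call(rbind, lapply(g$ids, function(id) {
    data.frame(population_id = id, year = 1990:2019, value = shared)
  }))
  panel <- suppressMessages(build_panel(vals, descriptor = "value",
                                        apply_filters = FALSE))
  fit <- fit_synchrony(panel, g, seed = 3, n_starts = 4)
  expect_gt(fit$params$rho0, 0.95)
  expect_true(fit$boundary)
})

test_that("fits are reproducible given a seed", {
  f <- small_field(6, 30, seed = 35)
  fit1 <- fit_synchrony(f$panel, f$geometry, seed = 11)
  fit2 <- fit_synchrony(f$panel, f$geometry, seed = 11)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$loglik, fit2$loglik)
})
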