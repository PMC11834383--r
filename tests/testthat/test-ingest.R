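test_that("ages follow hatch year when known and the adult-at-2 rule otherwise", {
  rec <- data.frame(
    population_id = "A",
    year = c(2000L, 2000L, 2002L, 2005L),
    individual_id = c("hatch98", "adfirst", "adfirst", "subfirst"),
    hatch_year = c(1998L, NA, NA, NA),
    first_capture_age_class = c("chick", "adult", "adult", "subadult"),
    sex = "F", stringsAsFactors = FALSE)
  aged <- assign_ages(rec)
  a <- function(id, yr) aged$age[aged$individual_id == id & aged$year == yr]
  k <- function(id, yr) aged$age_known_exactly[aged$individual_id == id &
                                                 aged$year == yr]
  expect_equal(a("hatch98", 2000), 2L)
  expect_true(k("hatch98", 2000))
  # first captured as adult in 2000: age 2 then, 4 two years later
  expect_equal(a("adfirst", 2000), 2L)
  expect_equal(a("adfirst", 2002), 4L)
  expect_false(k("adfirst", 2002))
  # first captured as subadult implies hatched the year before
  expect_equal(a("subfirst", 2005), 1L)
  expect_true(k("subfirst", 2005))
})

test_that("inconsistent and impossible ages are flagged", {
  rec <- data.frame(
    population_id = "A", year = 2000L,
    individual_id = c("bad", "early"),
    hatch_year = c(1995L, 2001L),
    first_capture_age_class = c("adult", "chick"),
    sex = "F", stringsAsFactors = FALSE)
  expect_warning(expect_warning(aged <- assign_ages(rec),
                                "first captured as adult"),
                 "age < 1")
  # hatch year preferred over the adult class
  expect_equal(aged$age[aged$individual_id == "bad"], 5L)
  # age would be -1: rejected
  expect_false("early" %in% aged$individual_id)
})

test_that("population summaries compute the three descriptors", {
  ages <- c(1, 1, 1, 2, 2, 3, 3, 4, 5, 5)
  aged <- data.frame(individual_id = as.character(seq_along(ages)),
                     age = ages)
  s <- summarise_population(aged, 30, "A", 2000,
                            senescent_age_threshold = 4)
  expect_equal(s$prop_subadult, 0.3)
  expect_equal(s$mean_age, 2.7)
  expect_equal(s$prop_senescent, 0.3)
  expect_equal(s$n_aged, 10L)
})

test_that("inclusion filters exclude boundary cases", {
  aged19 <- data.frame(individual_id = as.character(1:19),
                       age = rep(1:19 %% 4 + 1))
  expect_false(summarise_population(aged19, 19, "A", 2000)$passes_filters)
  # aged fraction exactly 0.25 must fail the strict inequality
  aged25 <- data.frame(individual_id = as.character(1:25),
                       age = rep(1:25 %% 4 + 1))
  expect_false(summarise_population(aged25, 100, "A", 2000)$passes_filters)
  expect_true(summarise_population(aged25, 99, "A", 2000)$passes_filters)
  # no aged individuals: missing descriptors, excluded
  s0 <- summarise_population(aged25[0, ], 50, "A", 2000)
  expect_true(is.na(s0$prop_subadult))
  expect_false(s0$passes_filters)
})

test_that("descriptors ignore record order and duplicated capture rows", {
  rec <- records_from_ages(c(1, 1, 2, 3, 4, 5, 2, 2, 1, 6),
                           n_unidentified = 12L)
  base <- summarise_structure(rec)
  shuffled <- summarise_structure(rec[sample(nrow(rec)), ])
  duplicated <- summarise_structure(rbind(rec, rec[1:3, ]))
  for (v in c("n_breeders", "n_aged", "prop_subadult", "mean_age",
              "prop_senescent")) {
    expect_equal(shuffled[[v]], base[[v]])
    expect_equal(duplicated[[v]], base[[v]])
  }
  # subadult and adult proportions partition the aged individuals
  expect_equal(base$prop_subadult + 7 / 10, 1)
  expect_equal(base$n_breeders, 10L + 12L)
  expect_equal(base$n_aged, 10L)
})

test_that("filter pass-rate is monotone in both thresholds", {
  set.seed(7)
  recs <- do.call(rbind, lapply(1:15, function(i) {
    n_aged <- sample(5:60, 1)
    records_from_ages(sample(1:6, n_aged, replace = TRUE),
                      population_id = sprintf("P%02d", i),
                      n_unidentified = sample(0:80, 1))
  }))
  rate <- function(min_n, min_frac) {
    mean(summarise_structure(recs, min_n = min_n,
                             min_aged_fraction = min_frac)$passes_filters)
  }
  r_n <- vapply(c(5, 20, 40, 80), rate, numeric(1), min_frac = 0.25)
  expect_true(all(diff(r_n) <= 0))
  r_f <- vapply(c(0.1, 0.25, 0.5, 0.9), rate, numeric(1), min_n = 20)
  expect_true(all(diff(r_f) <= 0))
})

test_that("running-mean deltas match examples and a brute-force oracle", {
  mk <- function(x) data.frame(population_id = "A",
                               year = seq_along(x) + 1999L,
                               prop_subadult = x, mean_age = x,
                               prop_senescent = x)
  d1 <- running_mean_deltas(mk(c(0.4, 0.4, 0.4, 0.4)), window = 5)
  expect_equal(d1$delta_prop_subadult, c(NA, NA, 0, 0))
  d2 <- running_mean_deltas(mk(c(0.2, 0.4, 0.6)), window = 5)
  expect_equal(d2$delta_prop_subadult[3], 0.6 - 0.3)

  set.seed(11)
  x <- runif(20)
  d3 <- running_mean_deltas(mk(x), window = 3)
  oracle <- rep(NA_real_, 20)
  for (t in 3:20) oracle[t] <- x[t] - mean(x[max(1, t - 3):(t - 1)])
  expect_equal(d3$delta_prop_subadult, oracle)
})
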