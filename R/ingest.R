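# From individual breeding captures to filtered annual
# demographic-structure descriptors.

#' Read a breeding-records CSV
#'
#' Expected header:
#' `population_id,year,individual_id,hatch_year,first_capture_age_class,sex`.
#' Empty fields are missing. `first_capture_age_class` is one of
#' `chick`, `subadult`, `adult`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of breeding records.
#' @export
read_breeding_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(population_id = "character",
                                individual_id = "character"))
  need <- c("population_id", "year", "individual_id", "hatch_year",
            "first_capture_age_class", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_demosync("breeding records missing columns: ",
                  paste(missing_cols, collapse = ", "))
  df$individual_id[df$individual_id == ""] <- NA_character_
  df$first_capture_age_class[df$first_capture_age_class == ""] <- NA_character_
  df
}

#' Assign breeding ages to identified individuals
#'
#' Individuals with a known hatch year (typically first marked as chicks or
#' subadults) get `age = year - hatch_year` and are flagged as exactly aged.
#' An individual first captured breeding as an adult is assumed to be in its
#' second year at that first capture: it gets age 2 in its first capture year
#' and `2 + (year - first_year)` thereafter, flagged as not exactly known.
#' A record carrying both an adult first-capture class and a hatch year is
#' inconsistent; the hatch year takes precedence and a warning is issued.
#' Records whose computed age would be below 1 are rejected with a warning.
#'
#' Records without an `individual_id` cannot be aged and are ignored here
#' (they still count towards the breeder total in [summarise_structure()]).
#'
#' @param records Data frame of breeding records (see
#'   [read_breeding_records()] for the schema).
#' @return Data frame with columns `population_id`, `year`, `individual_id`,
#'   `age`, `age_known_exactly`.
#' @export
assign_ages <- function(records) {
  stopifnot(all(c("population_id", "year", "individual_id",
                  "first_capture_age_class") %in% names(records)))
  if (!"hatch_year" %in% names(records)) records$hatch_year <- NA_integer_
  rec <- records[!is.na(records$individual_id), , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(population_id = character(), year = integer(),
                      individual_id = character(), age = integer(),
                      age_known_exactly = logical()))
  }

  # hatch year per individual: explicit if given anywhere, else implied by a
  # first capture as chick (hatched that year) or subadult (hatched year-1)
  key <- rec$individual_id
  first_year <- tapply(rec$year, key, min)
  hatch <- tapply(rec$hatch_year, key, function(h) {
    h <- h[!is.na(h)]
    if (length(h)) h[1] else NA_integer_
  })
  first_class <- mapply(function(id, y0) {
    cls <- rec$first_capture_age_class[rec$individual_id == id &
                                         rec$year == y0]
    cls <- cls[!is.na(cls)]
    if (length(cls)) cls[1] else NA_character_
  }, names(first_year), first_year)

  inconsistent <- !is.na(hatch) & !is.na(first_class) & first_class == "adult"
  if (any(inconsistent)) {
    warning(sum(inconsistent), " individual(s) first captured as adult but ",
            "carrying a hatch year; hatch year used", call. = FALSE)
  }
  implied <- is.na(hatch) & !is.na(first_class) & first_class != "adult"
  hatch[implied] <- ifelse(first_class[implied] == "chick",
                           first_year[implied], first_year[implied] - 1L)

  idx <- match(rec$individual_id, names(first_year))
  known <- !is.na(hatch[idx])
  age <- ifelse(known,
                rec$year - hatch[idx],
                2L + (rec$year - first_year[idx]))
  bad <- age < 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with computed age < 1 rejected",
            call. = FALSE)
  }
  out <- data.frame(population_id = rec$population_id,
                    year = rec$year,
                    individual_id = rec$individual_id,
                    age = as.integer(age),
                    age_known_exactly = as.logical(known),
                    stringsAsFactors = FALSE)
  out[!bad, , drop = FALSE]
}

#' Summarise one population-year of aged breeders
#'
#' Computes the demographic-structure descriptors over aged individuals:
#' the proportion of subadults (age 1), the mean age, and the proportion of
#' senescent breeders (age at or above `senescent_age_threshold`). Each
#' individual is counted once per population-year. The summary passes the
#' inclusion filters when the breeding population has at least `min_n`
#' parents and strictly more than `min_aged_fraction` of them were aged.
#'
#' @param aged Data frame of aged records for one population-year
#'   (columns `individual_id`, `age`); may have zero rows.
#' @param all_parents_count Total number of breeding parents (with at least
#'   one egg laid), aged or not.
#' @param population_id,year Identifiers for the summary row.
#' @param senescent_age_threshold Age (years) from which a breeder is
#'   considered senescent; default 4.
#' @param min_n Minimum breeders for inclusion; default 20.
#' @param min_aged_fraction Aged fraction must strictly exceed this;
#'   default 0.25.
#' @return One-row data frame (an annual population summary).
#' @export
summarise_population <- function(aged, all_parents_count, population_id, year,
                                 senescent_age_threshold = 4L,
                                 min_n = 20L, min_aged_fraction = 0.25) {
  if (nrow(aged)) {
    aged <- aged[!duplicated(aged$individual_id), , drop = FALSE]
  }
  n_aged <- nrow(aged)
  if (all_parents_count < n_aged)
    stop_demosync("all_parents_count smaller than number of aged individuals")
  if (n_aged > 0) {
    prop_subadult <- mean(aged$age == 1)
    mean_age <- mean(aged$age)
    prop_senescent <- mean(aged$age >= senescent_age_threshold)
  } else {
    prop_subadult <- mean_age <- prop_senescent <- NA_real_
  }
  passes <- n_aged > 0 &&
    all_parents_count >= min_n &&
    (n_aged / all_parents_count) > min_aged_fraction
  data.frame(population_id = population_id, year = as.integer(year),
             n_breeders = as.integer(all_parents_count),
             n_aged = as.integer(n_aged),
             prop_subadult = prop_subadult,
             mean_age = mean_age,
             prop_senescent = prop_senescent,
             delta_prop_subadult = NA_real_,
             delta_mean_age = NA_real_,
             delta_prop_senescent = NA_real_,
             passes_filters = passes,
             stringsAsFactors = FALSE)
}

#' Build annual demographic-structure summaries from breeding records
#'
#' Runs [assign_ages()] and [summarise_population()] over every
#' population-year in `records`, then fills the running-mean deltas with
#' [running_mean_deltas()]. Parents without identity contribute to
#' `n_breeders` but never to `n_aged`.
#'
#' @param records Breeding-records data frame.
#' @param senescent_age_threshold,min_n,min_aged_fraction Passed to
#'   [summarise_population()].
#' @param window Running-mean window (observed years) for the deltas.
#' @return Data frame with one row per population-year, ordered by
#'   population and year.
#' @export
summarise_structure <- function(records, senescent_age_threshold = 4L,
                                min_n = 20L, min_aged_fraction = 0.25,
                                window = 5L) {
  aged <- assign_ages(records)
  # breeder count: unique identified parents + unidentified capture rows
  py <- unique(records[c("population_id", "year")])
  py <- py[order(py$population_id, py$year), , drop = FALSE]
  rows <- lapply(seq_len(nrow(py)), function(i) {
    p <- py$population_id[i]; y <- py$year[i]
    sub <- records[records$population_id == p & records$year == y, ,
                   drop = FALSE]
    ided <- sub[!is.na(sub$individual_id), , drop = FALSE]
    n_breeders <- length(unique(ided$individual_id)) +
      sum(is.na(sub$individual_id))
    a <- aged[aged$population_id == p & aged$year == y, , drop = FALSE]
    summarise_population(a, n_breeders, p, y,
                         senescent_age_threshold = senescent_age_threshold,
                         min_n = min_n,
                         min_aged_fraction = min_aged_fraction)
  })
  out <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(out, out$population_id),
                               running_mean_deltas, window = window))
  rownames(out) <- NULL
  out[order(out$population_id, out$year), , drop = FALSE]
}

#' Change in descriptors relative to a trailing running mean
#'
#' For each descriptor x, `delta_x(t) = x(t) - mean(x over the previous
#' `window` observed years)`; the delta is missing when fewer than two prior
#' observed values exist. "Observed" counts rows present in the series (with
#' a non-missing descriptor), not calendar years, so gaps do not shrink the
#' window.
#'
#' @param summaries Annual summaries for a single population.
#' @param window Number of previous observed years in the mean; default 5.
#' @return `summaries` with `delta_prop_subadult`, `delta_mean_age`,
#'   `delta_prop_senescent` filled.
#' @export
running_mean_deltas <- function(summaries, window = 5L) {
  stopifnot(window >= 1)
  if (length(unique(summaries$population_id)) > 1)
    stop_demosync("running_mean_deltas expects a single population")
  summaries <- summaries[order(summaries$year), , drop = FALSE]
  for (v in c("prop_subadult", "mean_age", "prop_senescent")) {
    x <- summaries[[v]]
    d <- rep(NA_real_, length(x))
    for (t in seq_along(x)) {
      prev <- x[seq_len(t - 1L)]
      prev <- prev[!is.na(prev)]
      if (length(prev) >= 2L) {
        tail_prev <- prev[max(1L, length(prev) - window + 1L):length(prev)]
        d[t] <- x[t] - mean(tail_prev)
      }
    }
    summaries[[paste0("delta_", v)]] <- d
  }
  summaries
}
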