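# Normalised descriptor panels: per-population series with staggered
# observation windows, grouped by yearly observation pattern for the
# multivariate-normal likelihood.

#' Build a normalised descriptor panel from annual summaries
#'
#' Extracts one descriptor series per population and z-normalises it within
#' population (mean 0, sd 1 over that population's observed years), the
#' margin scaling required by a unit-diagonal yearly covariance matrix.
#' Populations with too few observed years, or a constant series, are
#' dropped with a message.
#'
#' @param summaries Data frame with `population_id`, `year` and the
#'   descriptor column (annual summaries, or any compatible table such as
#'   the output of [adjust_for_covariate()]).
#' @param descriptor Name of the descriptor column; default
#'   `"prop_subadult"`.
#' @param years Optional year filter (e.g. `2000:2022`).
#' @param apply_filters Use only rows with `passes_filters` (when present).
#' @param min_years Minimum observed years per population; default 3.
#' @return An object of class `sync_panel`: list with `data`
#'   (`population_id`, `year`, `value`), `populations`, `n_obs`.
#' @export
build_panel <- function(summaries, descriptor = "prop_subadult",
                        years = NULL, apply_filters = TRUE,
                        min_years = 3L) {
  stopifnot(descriptor %in% names(summaries))
  df <- summaries
  if (apply_filters && "passes_filters" %in% names(df))
    df <- df[df$passes_filters, , drop = FALSE]
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  df <- data.frame(population_id = as.character(df$population_id),
                   year = as.integer(df$year),
                   value = df[[descriptor]], stringsAsFactors = FALSE)
  df <- df[!is.na(df$value), , drop = FALSE]
  if (anyDuplicated(df[c("population_id", "year")]))
    stop_demosync("duplicate population-year rows in summaries")
  keep <- vapply(split(df$value, df$population_id), function(v) {
    length(v) >= min_years && sd(v) > 0
  }, logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped),
            " population(s) with short or constant series: ",
            paste(dropped, collapse = ", "))
  df <- df[df$population_id %in% names(keep)[keep], , drop = FALSE]
  if (!nrow(df)) stop_demosync("no usable population series")
  df <- df[order(df$population_id, df$year), , drop = FALSE]
  df$value <- unsplit(lapply(split(df$value, df$population_id), z_normalise),
                      df$population_id)
  structure(list(data = df,
                 populations = sort(unique(df$population_id)),
                 n_obs = nrow(df)),
            class = "sync_panel")
}

#' @export
print.sync_panel <- function(x, ...) {
  cat("sync_panel:", length(x$populations), "populations,",
      x$n_obs, "population-years,",
      length(unique(x$data$year)), "years\n")
  invisible(x)
}

# Group panel years by identical observed-population sets. Years observed in
# fewer than two populations carry no information about cross-correlation
# and are dropped. Returns the structure consumed by the likelihood kernel:
# for each group an index vector into the geometry's site order and a
# matrix of observed value vectors (columns = years).
panel_groups <- function(panel, geometry) {
  stopifnot(inherits(panel, "sync_panel"), inherits(geometry, "site_geometry"))
  missing_ids <- setdiff(panel$populations, geometry$ids)
  if (length(missing_ids))
    stop_demosync("panel populations missing from geometry: ",
                  paste(missing_ids, collapse = ", "))
  df <- panel$data
  df$idx <- match(df$population_id, geometry$ids)
  by_year <- split(df, df$year)
  by_year <- Filter(function(d) nrow(d) >= 2L, by_year)
  if (!length(by_year)) stop_demosync("no years with >= 2 observed populations")
  keys <- vapply(by_year, function(d) paste(sort(d$idx), collapse = ","),
                 character(1))
  groups <- lapply(split(by_year, keys), function(year_list) {
    idx <- sort(year_list[[1]]$idx)
    Y <- vapply(year_list, function(d) d$value[order(d$idx)],
                numeric(length(idx)))
    Y <- matrix(Y, nrow = length(idx))
    list(idx = idx, Y = Y,
         years = as.integer(names(year_list)))
  })
  names(groups) <- NULL
  list(groups = groups,
       n_years = length(by_year),
       n_populations = length(unique(df$idx)))
}

#' Pairwise synchrony scatter with overlap weights
#'
#' Pearson correlation of the normalised descriptor for every population
#' pair over their overlapping years, with the overlap length as plotting
#' weight (pairs sharing more years informed the likelihood more).
#'
#' @param panel A `sync_panel`.
#' @param geometry Matching `site_geometry`.
#' @param min_overlap Minimum overlapping years per pair; default 3.
#' @return Data frame `pop_i, pop_j, distance_km, correlation, n_overlap`.
#' @export
pairwise_synchrony <- function(panel, geometry, min_overlap = 3L) {
  df <- panel$data
  pops <- panel$populations
  out <- list()
  for (i in seq_along(pops)) {
    xi <- df[df$population_id == pops[i], ]
    for (j in seq_len(i - 1L)) {
      xj <- df[df$population_id == pops[j], ]
      yrs <- intersect(xi$year, xj$year)
      if (length(yrs) < min_overlap) next
      r <- suppressWarnings(
        cor(xi$value[match(yrs, xi$year)], xj$value[match(yrs, xj$year)]))
      if (!is.finite(r)) next
      out[[length(out) + 1L]] <- data.frame(
        pop_i = pops[j], pop_j = pops[i],
        distance_km = geometry$dist_km[pops[j], pops[i]],
        correlation = r, n_overlap = length(yrs),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pop_i = character(), pop_j = character(),
                      distance_km = numeric(), correlation = numeric(),
                      n_overlap = integer()))
  do.call(rbind, out)
}
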