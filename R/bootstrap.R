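# Parametric bootstrap of the correlogram fit and covariate-adjusted
# re-estimation.

# Simulate one panel realisation from the fitted correlogram, preserving
# which populations are observed in which years. `chols` holds the upper
# Cholesky factor per observation-pattern group.
simulate_panel_values <- function(pg, chols) {
  dfs <- vector("list", length(pg$groups))
  for (g in seq_along(pg$groups)) {
    grp <- pg$groups[[g]]
    n <- length(grp$idx)
    Tg <- length(grp$years)
    Z <- matrix(rnorm(n * Tg), n, Tg)
    V <- t(chols[[g]]) %*% Z  # cov = t(U) U = Sigma
    dfs[[g]] <- data.frame(idx = rep(grp$idx, Tg),
                           year = rep(grp$years, each = n),
                           value = as.numeric(V))
  }
  do.call(rbind, dfs)
}

#' Parametric bootstrap of a synchrony fit
#'
#' For each replicate, simulates the normalised descriptor panel from the
#' fitted multivariate-normal model -- independently across years, keeping
#' the data's yearly sets of observed populations -- re-normalises each
#' population's simulated series, and refits the correlogram (starting from
#' the point estimate plus one jittered start). Reports, per replicate, the
#' parameters and the synchrony at reference distances, and summarises them
#' as medians with 95% percentile intervals. Replicates whose refit fails
#' are dropped and counted; a warning is raised past 5% drops.
#'
#' @param fit A [fit_synchrony()] result.
#' @param B Number of bootstrap replicates; default 2000.
#' @param reference_distances Distances (km) at which synchrony is reported;
#'   default `c(100, 500, 1000, 2500)`.
#' @param seed Seed making the whole bootstrap reproducible.
#' @param maxit Nelder-Mead cap per refit start; default 400.
#' @return Object of class `synchrony_boot`: `point`, `plugin` (synchrony
#'   at the reference distances evaluated at the point estimate),
#'   `replicates` (one row per kept replicate), `summary` (median, 2.5% and
#'   97.5% quantiles per quantity), `B`, `n_dropped`, `seed`.
#' @export
synchrony_bootstrap <- function(fit, B = 2000L,
                                reference_distances = c(100, 500, 1000, 2500),
                                seed = NULL, maxit = 400L) {
  stopifnot(inherits(fit, "synchrony_fit"), B >= 1L)
  pg <- panel_groups(fit$panel, fit$geometry)
  dist_km <- fit$geometry$dist_km
  point <- fit$params
  l_bounds <- fit$l_bounds %||% c(1, 20000)

  chols <- lapply(pg$groups, function(grp) {
    ids <- fit$geometry$ids[grp$idx]
    chol(build_sigma(ids, fit$geometry, point))
  })
  # replicate group skeleton reused for refits; only Y changes
  year_of <- lapply(pg$groups, `[[`, "years")
  idx_of <- lapply(pg$groups, `[[`, "idx")

  objective_factory <- function(groups_Y) {
    idx_list <- idx_of
    function(par) {
      if (any(!is.finite(par)) || any(abs(par[1:2]) > 30)) return(1e10)
      l <- exp(par[3])
      if (l < l_bounds[1] || l > l_bounds[2]) return(1e10)
      ll <- panel_loglik_cpp(idx_list, groups_Y, dist_km,
                             plogis(par[1]),
                             plogis(par[1]) * plogis(par[2]),
                             l)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }

  start_point <- params_to_par(point)
  ref_names <- paste0("rho", reference_distances)
  local_seed(seed)
  reps <- vector("list", B)
  n_dropped <- 0L
  for (b in seq_len(B)) {
    sim <- simulate_panel_values(pg, chols)
    # per-population re-normalisation over the population's observed years
    ok <- TRUE
    sim$value <- tryCatch(
      unsplit(lapply(split(sim$value, sim$idx), z_normalise), sim$idx),
      error = function(e) { ok <<- FALSE; sim$value })
    if (!ok) { n_dropped <- n_dropped + 1L; next }
    groups_Y <- mapply(function(idx, yrs) {
      sub <- sim[sim$year %in% yrs & sim$idx %in% idx, ]
      matrix(sub$value[order(sub$year, sub$idx)], nrow = length(idx))
    }, idx_of, year_of, SIMPLIFY = FALSE)
    obj <- objective_factory(groups_Y)
    starts <- list(start_point, start_point + rnorm(3, 0, 0.3))
    best <- NULL
    for (s in starts) {
      res <- tryCatch(
        optim(s, obj, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-8)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best) || best$value >= 1e10) {
      n_dropped <- n_dropped + 1L
      next
    }
    p <- par_to_params(best$par)
    row <- data.frame(replicate = b, rho0 = p$rho0, rho_inf = p$rho_inf,
                      l = p$l, loglik = -best$value)
    for (k in seq_along(reference_distances))
      row[[ref_names[k]]] <- synchrony_rho(reference_distances[k], p)
    reps[[b]] <- row
  }
  replicates <- do.call(rbind, reps)
  if (is.null(replicates) || !nrow(replicates))
    stop_demosync("all bootstrap replicates failed")
  if (n_dropped > 0.05 * B)
    warning(sprintf("%d of %d bootstrap replicates dropped", n_dropped, B),
            call. = FALSE)

  qty <- c("rho0", "rho_inf", "l", ref_names)
  summ <- do.call(rbind, lapply(qty, function(q) {
    v <- replicates[[q]]
    data.frame(quantity = q,
               median = median(v),
               lower = quantile(v, 0.025, names = FALSE),
               upper = quantile(v, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  plugin <- setNames(synchrony_rho(reference_distances, point), ref_names)
  structure(list(point = point, plugin = plugin, replicates = replicates,
                 summary = summ, B = B, n_dropped = n_dropped,
                 reference_distances = reference_distances, seed = seed),
            class = "synchrony_boot")
}

#' @export
print.synchrony_boot <- function(x, ...) {
  cat(sprintf("synchrony_boot: %d replicates (%d dropped)\n",
              x$B, x$n_dropped))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s median %7.3f  [%7.3f, %7.3f]\n", s$quantity[i],
                s$median[i], s$lower[i], s$upper[i]))
  }
  invisible(x)
}

#' Median synchrony-distance curve with a 95% bootstrap band
#'
#' Evaluates the correlogram of every bootstrap replicate on a distance
#' grid and returns the pointwise median and 2.5/97.5 percentiles.
#'
#' @param boot A [synchrony_bootstrap()] result.
#' @param distances Distance grid in km; default `seq(0, 3000, by = 25)`.
#' @return Data frame `distance_km, median, lower, upper`.
#' @export
synchrony_curve <- function(boot, distances = seq(0, 3000, by = 25)) {
  stopifnot(inherits(boot, "synchrony_boot"))
  r <- boot$replicates
  vals <- vapply(seq_len(nrow(r)), function(i) {
    p <- synchrony_params(r$rho0[i], min(r$rho_inf[i], r$rho0[i]), r$l[i])
    synchrony_rho(distances, p)
  }, numeric(length(distances)))
  vals <- matrix(vals, nrow = length(distances))
  data.frame(distance_km = distances,
             median = apply(vals, 1, median),
             lower = apply(vals, 1, quantile, 0.025, names = FALSE),
             upper = apply(vals, 1, quantile, 0.975, names = FALSE))
}

#' Residualise a descriptor against a covariate, per population
#'
#' For each population, regresses the descriptor on the covariate by
#' ordinary least squares (intercept and slope) over the years where both
#' are observed, z-normalises the residuals within population, and returns
#' them as the adjusted series. Fitting the correlogram to this output
#' estimates the synchrony remaining once the covariate's contribution is
#' removed. Populations with a constant covariate pass through unadjusted
#' (flagged); populations whose residuals are numerically zero (descriptor
#' collinear with covariate) are dropped (flagged).
#'
#' @param summaries Annual summaries (filtered rows are used when
#'   `apply_filters` and a `passes_filters` column are present).
#' @param covariates Long covariate table (`population_id,year,name,value`).
#' @param covariate_name Which covariate to adjust for.
#' @param descriptor Descriptor column; default `"prop_subadult"`.
#' @param min_obs Minimum joint observations per population; default 3.
#' @param apply_filters Respect `passes_filters`; default `TRUE`.
#' @return Data frame `population_id, year, value` (normalised residuals)
#'   with attributes `unadjusted` and `dropped` listing flagged
#'   populations.
#' @export
adjust_for_covariate <- function(summaries, covariates, covariate_name,
                                 descriptor = "prop_subadult",
                                 min_obs = 3L, apply_filters = TRUE) {
  df <- summaries
  if (apply_filters && "passes_filters" %in% names(df))
    df <- df[df$passes_filters, , drop = FALSE]
  cov <- covariates[covariates$name == covariate_name,
                    c("population_id", "year", "value")]
  names(cov)[3] <- ".cov"
  dat <- merge(df[c("population_id", "year", descriptor)], cov,
               by = c("population_id", "year"))
  dat <- dat[complete.cases(dat[c(descriptor, ".cov")]), , drop = FALSE]
  unadjusted <- character()
  droppedp <- character()
  out <- lapply(split(dat, dat$population_id), function(d) {
    if (nrow(d) < min_obs) {
      droppedp <<- c(droppedp, d$population_id[1]); return(NULL)
    }
    if (sd(d$.cov) == 0) {
      unadjusted <<- c(unadjusted, d$population_id[1])
      res <- d[[descriptor]]
    } else {
      res <- residuals(lm(d[[descriptor]] ~ d$.cov))
    }
    if (sd(res) < 1e-10) {
      droppedp <<- c(droppedp, d$population_id[1]); return(NULL)
    }
    data.frame(population_id = d$population_id, year = d$year,
               value = as.numeric(z_normalise(res)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    stop_demosync("no populations left after covariate adjustment")
  rownames(out) <- NULL
  attr(out, "unadjusted") <- unadjusted
  attr(out, "dropped") <- droppedp
  out
}
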