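# Random-slope hierarchical regression of demographic structure on one
# covariate at a time.

#' z-normalise a numeric series
#'
#' Centres to mean 0 and scales to sample standard deviation 1 over all
#' non-missing values; missing values stay missing.
#'
#' @param x Numeric vector (at least two non-missing, non-constant values).
#' @return Normalised vector.
#' @export
z_normalise <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop_demosync("need >= 2 non-missing values")
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0) stop_demosync("degenerate covariate")
  (x - mean(x[ok])) / s
}

#' Fit a random-intercept + random-slope regression for one covariate
#'
#' Fits, by maximum likelihood, the Gaussian hierarchical model
#' \deqn{y_{ij} = \beta_{int} + u_{int,i} + (\beta_{expl} + u_{expl,i})
#'   Z_{ij} + \epsilon_{ij}}
#' where i indexes populations and j years; random intercepts and random
#' slopes are normal with mean zero and are uncorrelated by default. The
#' response and covariate are z-normalised globally (pooled over all
#' population-years) before fitting, so slopes are comparable across
#' covariates. Returns the fixed slope with a Wald 95% interval, variance
#' components, and per-population slopes
#' \eqn{\beta_{expl} + u_{expl,i}}.
#'
#' @param data Data frame with one row per population-year.
#' @param response,covariate Names of the response and covariate columns.
#' @param population Name of the population-id column.
#' @param allow_correlation If `TRUE`, estimate the intercept-slope
#'   correlation instead of forcing independence.
#' @return An object of class `mixed_model_fit` (a list with `beta_int`,
#'   `beta_expl`, `slope_interval`, `sigma_u_int`, `sigma_u_expl`,
#'   `sigma_resid`, `per_population_slopes`, `n_obs`, `n_populations`,
#'   `singular`, and the `lme4` fit in `$model`).
#' @export
fit_random_slope <- function(data, response, covariate,
                             population = "population_id",
                             allow_correlation = FALSE) {
  stopifnot(all(c(response, covariate, population) %in% names(data)))
  df <- data.frame(y = data[[response]], z = data[[covariate]],
                   pop = factor(data[[population]]))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) stop_demosync("need >= 10 complete rows")
  if (nlevels(droplevels(df$pop)) < 2L)
    stop_demosync("need >= 2 populations")
  df$pop <- droplevels(df$pop)
  df$y <- z_normalise(df$y)
  df$z <- z_normalise(df$z)

  form <- if (allow_correlation) y ~ z + (1 + z | pop)
          else y ~ z + (1 | pop) + (0 + z | pop)
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(var) {
    i <- which(vc$var1 == var & is.na(vc$var2))
    if (length(i)) vc$sdcor[i[1]] else 0
  }
  re <- lme4::ranef(fit)
  slope_re <- rep(0, nlevels(df$pop))
  names(slope_re) <- levels(df$pop)
  for (blk in re) {
    if ("z" %in% colnames(blk)) {
      slope_re[rownames(blk)] <- slope_re[rownames(blk)] + blk[, "z"]
    }
  }
  ci <- unname(fe["z"] + qnorm(c(0.025, 0.975)) * se["z"])
  structure(list(
    beta_int = unname(fe["(Intercept)"]),
    beta_expl = unname(fe["z"]),
    slope_se = unname(se["z"]),
    slope_interval = ci,
    sigma_u_int = sd_of("(Intercept)"),
    sigma_u_expl = sd_of("z"),
    sigma_resid = stats::sigma(fit),
    per_population_slopes = unname(fe["z"]) + slope_re,
    n_obs = nrow(df),
    n_populations = nlevels(df$pop),
    singular = lme4::isSingular(fit),
    response = response, covariate = covariate,
    model = fit), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("random-slope fit: %s ~ %s\n", x$response, x$covariate))
  cat(sprintf("  slope %.3f [%.3f, %.3f]%s\n", x$beta_expl,
              x$slope_interval[1], x$slope_interval[2],
              if (x$singular) " (singular fit)" else ""))
  cat(sprintf("  sd(u_int) %.3f  sd(u_slope) %.3f  sd(resid) %.3f  n=%d\n",
              x$sigma_u_int, x$sigma_u_expl, x$sigma_resid, x$n_obs))
  invisible(x)
}

#' Fit the per-covariate regression for every covariate in a long table
#'
#' Joins each covariate series to the filtered summaries and fits
#' [fit_random_slope()] once per covariate (rows with a missing covariate
#' drop from that covariate's model only).
#'
#' @param summaries Annual summaries; only rows passing filters are used.
#' @param covariates Long covariate table from [build_covariates()].
#' @param response Descriptor column in `summaries`; default
#'   `"prop_subadult"`.
#' @param covariate_names Subset of covariate names; default all present.
#' @return Data frame with one row per covariate: slope, interval bounds,
#'   variance components, `n_obs`, `n_populations`, `singular`.
#' @export
fit_all_covariates <- function(summaries, covariates,
                               response = "prop_subadult",
                               covariate_names = NULL) {
  use <- summaries[summaries$passes_filters, , drop = FALSE]
  covariate_names <- covariate_names %||% unique(covariates$name)
  rows <- lapply(covariate_names, function(nm) {
    cov <- covariates[covariates$name == nm,
                      c("population_id", "year", "value")]
    dat <- merge(use, cov, by = c("population_id", "year"))
    fit <- tryCatch(
      fit_random_slope(dat, response, "value"),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(covariate = nm, beta_expl = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        sigma_u_int = NA_real_, sigma_u_expl = NA_real_,
                        sigma_resid = NA_real_, n_obs = nrow(dat),
                        n_populations = NA_integer_, singular = NA,
                        stringsAsFactors = FALSE))
    }
    data.frame(covariate = nm, beta_expl = fit$beta_expl,
               lower = fit$slope_interval[1], upper = fit$slope_interval[2],
               sigma_u_int = fit$sigma_u_int,
               sigma_u_expl = fit$sigma_u_expl,
               sigma_resid = fit$sigma_resid, n_obs = fit$n_obs,
               n_populations = fit$n_populations, singular = fit$singular,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
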