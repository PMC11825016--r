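#' Fit the cyclic-seasonal Bernoulli presence model
#'
#' Penalized binomial GAM for daily detection/non-detection:
#' `logit p = b0 + f_cyc(month) + survey-year factor + site intercept`,
#' with `f_cyc` a cyclic spline over calendar month (period 12, continuous
#' across the December–January boundary by construction) and site entering
#' as a random-effect smooth. Missing days are excluded. Serial dependence
#' of daily observations is accommodated by an AR1 working-correlation
#' adjustment: the lag-1 autocorrelation of within-site working residuals
#' on consecutive days estimates `rho`, and standard errors are inflated
#' by `sqrt((1 + rho) / (1 - rho))` (never deflated).
#'
#' With a single site the random effect is dropped; with a single survey
#' year the year factor is dropped (the model reduces to a cyclic logistic
#' regression).
#'
#' @param table Daily presence tibble (`site_id`, `date`, `state`; one
#'   species).
#' @param k Cyclic basis dimension.
#' @param ar1 Apply the AR1 working-correlation adjustment.
#' @param method Smoothing-penalty selection criterion passed to
#'   [mgcv::gam()] (`"REML"` default; `"GCV.Cp"` for generalized
#'   cross-validation).
#' @param origin Survey-year origin date (Year 1 starts here); default the
#'   earliest date in `table`.
#' @return A `presence_fit` object wrapping the [mgcv::gam] fit plus
#'   `rho`, the SE inflation factor, and bookkeeping.
#' @export
#' @examples
#' d <- simulate_presence_dataset(presence_sim_params(), sites = 4,
#'                                days = 2 * 365, seed = 2)
#' f <- fit_presence_gam(d)
#' glance(f)
fit_presence_gam <- function(table, k = 8, ar1 = TRUE, method = "REML",
                             origin = NULL) {
  df <- filter(table, .data$state != "missing") |>
    mutate(y = as.integer(.data$state == "detected"),
           month = lubridate::month(.data$date))
  if (nrow(df) == 0) abort("no recorded days")
  if (all(df$y == 0) || all(df$y == 1))
    abort("degenerate response: all days ", if (all(df$y == 1)) "detected" else "non-detected")
  origin <- origin %||% min(df$date)
  df$year <- factor(paste("Year", survey_year_index(df$date, origin)))
  df$site <- factor(df$site_id)
  n_year <- length(levels(df$year)); n_site <- length(levels(df$site))
  rhs <- c("s(month, bs = \"cc\", k = k)",
           if (n_year > 1) "year",
           if (n_site > 1) "s(site, bs = \"re\")")
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  g <- mgcv::gam(form, family = stats::binomial(), data = df,
                 knots = list(month = c(0.5, 12.5)), method = method)
  rho <- 0
  if (ar1) rho <- working_lag1_rho(g, df)
  infl <- if (rho > 0) sqrt((1 + rho) / (1 - rho)) else 1
  structure(list(gam = g, data = df, rho = rho, se_inflation = infl,
                 ar1 = ar1, k = k, method = method, origin = origin,
                 years = levels(df$year), sites = levels(df$site),
                 converged = g$converged),
            class = "presence_fit")
}

# pooled lag-1 autocorrelation of working residuals over consecutive days
# within each site series
working_lag1_rho <- function(g, df) {
  r <- stats::residuals(g, type = "working")
  d <- tibble(site = df$site, date = df$date, r = r) |>
    arrange(.data$site, .data$date) |>
    group_by(.data$site) |>
    mutate(r_lag = lag(.data$r),
           consec = .data$date - lag(.data$date) == 1) |>
    ungroup() |>
    filter(!is.na(.data$r_lag), .data$consec)
  if (nrow(d) < 10) return(0)
  suppressWarnings(cor(d$r, d$r_lag))
}

#' @export
print.presence_fit <- function(x, ...) {
  cat(sprintf("<presence_fit> %d obs, %d site(s), %s; edf %.1f; rho %.3f (SE x %.2f)\n",
              nrow(x$data), length(x$sites),
              paste(x$years, collapse = "/"),
              sum(x$gam$edf), x$rho, x$se_inflation))
  invisible(x)
}

# prediction-grid lpmatrix with the site random effect zeroed out
year_grid_lp <- function(fit) {
  grid <- tidyr::expand_grid(year = factor(fit$years, levels = fit$years),
                             month = 1:12)
  grid$site <- factor(fit$sites[1], levels = fit$sites)
  X <- predict(fit$gam, newdata = grid, type = "lpmatrix")
  X[, grepl("s(site)", colnames(X), fixed = TRUE)] <- 0
  list(grid = grid, X = X)
}

#' Estimated marginal means per survey year
#'
#' For each year, the predicted logit is averaged over the month grid
#' (1–12) at the population level (site random effect excluded), then
#' back-transformed to the response scale. Standard errors use the delta
#' method and carry the AR1 inflation.
#'
#' @param fit A [fit_presence_gam()] result.
#' @return Tibble with `year`, `emm` (probability), `se`, `logit`,
#'   `logit_se`, `df`.
#' @export
estimated_marginal_means <- function(fit) {
  stopifnot(inherits(fit, "presence_fit"))
  if (!fit$converged) abort("model did not converge")
  gl <- year_grid_lp(fit)
  V <- stats::vcov(fit$gam)
  b <- coef(fit$gam)
  rows <- map(fit$years, function(yr) {
    Xi <- colMeans(gl$X[gl$grid$year == yr, , drop = FALSE])
    lo <- sum(Xi * b)
    se_l <- sqrt(drop(t(Xi) %*% V %*% Xi)) * fit$se_inflation
    p <- plogis(lo)
    tibble(year = yr, emm = p, se = se_l * p * (1 - p),
           logit = lo, logit_se = se_l,
           df = fit$gam$df.residual)
  })
  list_rbind(rows)
}

#' Pairwise survey-year contrasts (Tukey-adjusted)
#'
#' Differences of the per-year average logits (log odds ratios), with
#' AR1-inflated standard errors, studentized statistics and family-wise
#' adjusted p values from the studentized-range (Tukey) distribution over
#' the number of years.
#'
#' @param fit A [fit_presence_gam()] result with at least two years.
#' @return Tibble with `contrast`, `estimate` (log odds ratio), `se`,
#'   `statistic`, `df`, `p_adj`.
#' @export
pairwise_year_contrasts <- function(fit) {
  stopifnot(inherits(fit, "presence_fit"))
  yrs <- fit$years
  if (length(yrs) < 2) abort("need at least two survey years for contrasts")
  gl <- year_grid_lp(fit)
  V <- stats::vcov(fit$gam)
  b <- coef(fit$gam)
  Xm <- do.call(rbind, map(yrs, function(yr)
    colMeans(gl$X[gl$grid$year == yr, , drop = FALSE])))
  pairs <- utils::combn(seq_along(yrs), 2)
  df_res <- fit$gam$df.residual
  out <- map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- Xm[i1, ] - Xm[i2, ]
    est <- sum(d * b)
    se <- sqrt(drop(t(d) %*% V %*% d)) * fit$se_inflation
    stat <- est / se
    tibble(contrast = paste(yrs[i1], "-", yrs[i2]),
           estimate = est, se = se, statistic = stat, df = df_res,
           p_adj = ptukey(sqrt(2) * abs(stat), nmeans = length(yrs),
                          df = df_res, lower.tail = FALSE))
  })
  list_rbind(out)
}

#' Evaluate the fitted cyclic seasonal curve
#'
#' The cyclic smooth's contribution to the logit at integer months 1–12
#' (centred, as fitted).
#'
#' @param fit A [fit_presence_gam()] result.
#' @param months Months at which to evaluate.
#' @return Tibble with `month`, `f` (logit contribution), `se`.
#' @export
seasonal_curve <- function(fit, months = 1:12) {
  nd <- tibble(month = months,
               year = factor(fit$years[1], levels = fit$years),
               site = factor(fit$sites[1], levels = fit$sites))
  pt <- predict(fit$gam, newdata = nd, type = "terms", se.fit = TRUE)
  cl <- grep("s(month)", colnames(pt$fit), fixed = TRUE)
  tibble(month = months, f = pt$fit[, cl],
         se = pt$se.fit[, cl] * fit$se_inflation)
}

#' Working-likelihood AIC comparison of two presence fits
#'
#' `AIC = -2 logLik / c + 2 edf`, where `c` is the AR1 variance-inflation
#' factor `(1 + rho) / (1 - rho)` for an AR1-adjusted fit and 1 otherwise
#' (a quasi-likelihood-style correction: positive serial correlation
#' reduces the effective information in the likelihood). The lower-AIC
#' model is selected only when the difference exceeds `delta`; otherwise
#' the fits are reported as equivalent.
#'
#' @param fit_a,fit_b Two [fit_presence_gam()] results on identical data.
#' @param delta Minimum AIC difference for selection.
#' @return List with `aic_a`, `aic_b`, `delta_aic`, and `selected`
#'   (`"a"`, `"b"` or `"equivalent"`).
#' @export
compare_models_aic <- function(fit_a, fit_b, delta = 2) {
  same <- nrow(fit_a$data) == nrow(fit_b$data) &&
    all(fit_a$data$y == fit_b$data$y)
  if (!same) abort("fits are not on identical data")
  aic1 <- working_aic(fit_a); aic2 <- working_aic(fit_b)
  d <- aic1 - aic2
  list(aic_a = aic1, aic_b = aic2, delta_aic = d,
       selected = if (abs(d) <= delta) "equivalent" else if (d < 0) "a" else "b")
}

working_aic <- function(fit) {
  ll <- logLik(fit$gam)
  edf <- attr(ll, "df")
  cc <- if (fit$ar1 && fit$rho > 0) (1 + fit$rho) / (1 - fit$rho) else 1
  -2 * as.numeric(ll) / cc + 2 * edf
}

#' @export
tidy.presence_fit <- function(x, ...) {
  sm <- summary(x$gam)
  p <- sm$p.table
  tibble(term = rownames(p),
         estimate = p[, "Estimate"],
         std_error = p[, "Std. Error"] * x$se_inflation,
         statistic = p[, "Estimate"] / (p[, "Std. Error"] * x$se_inflation))
}

#' @export
glance.presence_fit <- function(x, ...) {
  tibble(n = nrow(x$data), n_sites = length(x$sites),
         n_years = length(x$years), edf = sum(x$gam$edf),
         log_lik = as.numeric(logLik(x$gam)), aic = working_aic(x),
         rho = x$rho, se_inflation = x$se_inflation,
         converged = x$converged)
}

#' Plot the fitted seasonal presence curve
#' @param object A `presence_fit`.
#' @param ... Unused.
#' @return A ggplot of the cyclic smooth with a 95% band.
#' @export
autoplot.presence_fit <- function(object, ...) {
  sc <- seasonal_curve(object, months = seq(1, 12, by = 0.25))
  ggplot(sc, aes(.data$month, .data$f)) +
    geom_ribbon(aes(ymin = .data$f - 1.96 * .data$se,
                    ymax = .data$f + 1.96 * .data$se), alpha = 0.2) +
    geom_line() +
    labs(x = "Month", y = "Seasonal effect (logit)") +
    theme_minimal()
}
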