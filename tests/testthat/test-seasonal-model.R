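test_that("null data yield a flat smooth and non-significant contrasts", {
  d <- simulate_presence_dataset(
    presence_sim_params(seasonal_amplitude = 0, year_effects = c(0, 0, 0),
                        site_sd = 0.3, ar1_rho = 0),
    sites = 6, days = 1095, seed = 21)
  fit <- fit_presence_gam(d)
  sc <- seasonal_curve(fit)
  expect_lt(max(abs(sc$f)), 0.4)
  ct <- pairwise_year_contrasts(fit)
  expect_equal(nrow(ct), 3)
  expect_true(all(abs(ct$estimate) < 0.3))
})

test_that("simulated seasonal structure and year effects are recovered", {
  d <- simulate_presence_dataset(
    presence_sim_params(seasonal_amplitude = 1.5, year_effects = c(0, 0, -1),
                        site_sd = 0.5, ar1_rho = 0.3),
    sites = 8, days = 1095, seed = 22)
  fit <- fit_presence_gam(d)
  expect_true(fit$converged)
  truth <- 1.5 * cos(2 * pi * (1:12 - 3) / 12)
  expect_gt(cor(seasonal_curve(fit)$f, truth), 0.9)
  y3 <- tidy(fit)$estimate[tidy(fit)$term == "yearYear 3"]
  expect_lt(abs(y3 - (-1)), 0.3)
  # EMM ordering matches the simulated year ordering
  em <- estimated_marginal_means(fit)
  expect_lt(em$emm[3], min(em$emm[1:2]))
  expect_true(all(em$emm > 0 & em$emm < 1))
})

test_that("the cyclic smooth is continuous across the December-January boundary", {
  d <- simulate_presence_dataset(presence_sim_params(), sites = 4,
                                 days = 730, seed = 23)
  fit <- fit_presence_gam(d)
  f_lo <- seasonal_curve(fit, months = 0.5)$f
  f_hi <- seasonal_curve(fit, months = 12.5)$f
  expect_equal(f_lo, f_hi, tolerance = 1e-8)
})

test_that("single-site single-year data reduce to a cyclic logistic regression", {
  d <- simulate_presence_dataset(
    presence_sim_params(seasonal_amplitude = 1, year_effects = 0,
                        site_sd = 0, ar1_rho = 0),
    sites = 1, days = 365, seed = 24)
  fit <- fit_presence_gam(d)
  expect_length(fit$sites, 1)
  expect_length(fit$years, 1)
  truth <- cos(2 * pi * (1:12 - 3) / 12)
  expect_gt(cor(seasonal_curve(fit)$f, truth), 0.8)
  expect_error(pairwise_year_contrasts(fit), "two survey years")
})

test_that("degenerate responses are signalled", {
  d <- simulate_presence_dataset(presence_sim_params(baseline = 30,
                                                     latent_sd = 0,
                                                     site_sd = 0),
                                 sites = 2, days = 50, seed = 25)
  expect_error(fit_presence_gam(d), "degenerate")
})

test_that("marginal means follow the inverse-logit closed form", {
  # flat simulation at baseline 0: EMM ~ 0.5; at -2.197: EMM ~ 0.1
  for (cfg in list(list(b = 0, p = 0.5), list(b = qlogis(0.1), p = 0.1))) {
    d <- simulate_presence_dataset(
      presence_sim_params(baseline = cfg$b, seasonal_amplitude = 0,
                          year_effects = 0, site_sd = 0, ar1_rho = 0,
                          latent_sd = 0),
      sites = 6, days = 1000, seed = 26)
    fit <- fit_presence_gam(d, ar1 = FALSE)
    em <- estimated_marginal_means(fit)
    expect_equal(mean(em$emm), cfg$p, tolerance = 0.03)
  }
})

test_that("package EMMs and Tukey contrasts agree with emmeans", {
  d <- simulate_presence_dataset(presence_sim_params(ar1_rho = 0),
                                 sites = 4, days = 1095, seed = 7)
  fit <- fit_presence_gam(d, ar1 = FALSE)
  em <- estimated_marginal_means(fit)
  ct <- pairwise_year_contrasts(fit)
  ref <- emmeans::emmeans(fit$gam, ~year, at = list(month = 1:12),
                          type = "response", data = fit$data)
  ref_df <- as.data.frame(ref)
  expect_equal(em$emm, ref_df$prob, tolerance = 1e-6)
  expect_equal(em$se, ref_df$SE, tolerance = 1e-5)
  ref_ct <- as.data.frame(graphics::pairs(
    emmeans::emmeans(fit$gam, ~year, at = list(month = 1:12),
                     data = fit$data), adjust = "tukey"))
  expect_equal(ct$estimate, ref_ct$estimate, tolerance = 1e-6)
  expect_equal(ct$p_adj, ref_ct$p.value, tolerance = 1e-5)
})

test_that("AIC comparison reports equivalence and prefers AR1 handling on AR1 data", {
  d <- simulate_presence_dataset(presence_sim_params(), sites = 4,
                                 days = 730, seed = 27)
  f1 <- fit_presence_gam(d, ar1 = FALSE)
  f2 <- fit_presence_gam(d, ar1 = FALSE)
  cmp <- compare_models_aic(f1, f2)
  expect_equal(cmp$delta_aic, 0)
  expect_equal(cmp$selected, "equivalent")

  picks <- vapply(1:8, function(i) {
    di <- simulate_presence_dataset(
      presence_sim_params(ar1_rho = 0.6, seasonal_amplitude = 1),
      sites = 4, days = 730, seed = 300 + i)
    compare_models_aic(fit_presence_gam(di, ar1 = TRUE),
                       fit_presence_gam(di, ar1 = FALSE))$selected
  }, character(1))
  expect_gte(mean(picks == "a"), 0.85)

  d2 <- simulate_presence_dataset(presence_sim_params(), sites = 3,
                                  days = 365, seed = 28)
  expect_error(compare_models_aic(f1, fit_presence_gam(d2, ar1 = FALSE)),
               "identical data")
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- simulate_presence_dataset(presence_sim_params(), sites = 3,
                                 days = 730, seed = 29)
  fit <- fit_presence_gam(d)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, sum(d$state != "missing"))
  expect_true(gl$converged)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
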