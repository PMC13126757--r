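test_that("representative ages are interval midpoints, open top group aside", {
  g <- zi_age_groups()
  expect_equal(representative_ages(g),
               c(12.5, 30, 40, 50, 60, 70, 80, 91))
  expect_equal(representative_ages(g, top_age = 95)[8], 95)
  bad <- data.frame(age_lo = c(0, 20), age_hi = c(24, 34))
  expect_error(representative_ages(bad), "overlap")
})

test_that("aggregated prevalence container validates its schema", {
  df <- data.frame(sex = "male", year = 2013, age_lo = c(0, 25),
                   age_hi = c(24, 34), prev = c(0.01, 0.05), denom = 1e6)
  obs <- aggregated_prevalence(df)
  expect_s3_class(obs, "aggregated_prevalence")
  expect_equal(obs$group, c("0-24", "25-34"))
  df2 <- df; df2$age_lo <- c(0, 20)
  expect_error(aggregated_prevalence(df2), "overlapping")
  df3 <- df; df3$prev <- c(-0.1, 0.5)
  expect_error(aggregated_prevalence(df3), "\\[0, 1\\]")
})

test_that("prevalence CSV round-trips", {
  obs <- noiseless_world()$prevalence
  path <- withr::local_tempfile(fileext = ".csv")
  write_prevalence(obs, path)
  back <- read_prevalence(path)
  expect_equal(back$prev, obs$prev, tolerance = 1e-15)
  expect_identical(back$age_lo, obs$age_lo)
})

test_that("curve aggregation: constant and linear curves reduce to closed forms", {
  ages <- seq(0, 110, by = 0.05)
  const <- structure(data.frame(age = ages, p = rep(0.2, length(ages))),
                     class = c("prevalence_curve", "data.frame"), t_ref = 2013.5)
  g <- zi_age_groups()
  gz <- german_gompertz()
  expect_equal(previnc:::aggregate_prevalence_curve(const, g), rep(0.2, 8))
  expect_equal(previnc:::aggregate_prevalence_curve(const, g, hazard = gz,
                                                    aggregate = "weighted"),
               rep(0.2, 8), tolerance = 1e-12)
  lin <- structure(data.frame(age = ages, p = 0.001 * ages),
                   class = c("prevalence_curve", "data.frame"), t_ref = 2013.5)
  expect_equal(previnc:::aggregate_prevalence_curve(lin, g),
               0.001 * representative_ages(g))
})

test_that("model group prevalence is strictly increasing at published truths", {
  pred <- model_group_prevalence(published_inc("male"), published_mrr("male"),
                                 german_gompertz(), zi_age_groups())
  expect_length(pred, 8)
  expect_true(all(diff(pred) > 0))
  expect_true(all(pred > 0 & pred < 1))
})

test_that("objective is zero at the generating truth and larger off it", {
  w <- noiseless_world()
  obs <- sex_obs(w, "male")
  hz <- world_hazard(w, "male")
  truth <- c(0.076334, 25.33680, 0.408, -0.0171)
  expect_lt(prevalence_objective(truth, 87.5, obs, hz), 1e-12)
  bumped <- truth * c(1.1, 1, 1, 1)
  expect_gt(prevalence_objective(bumped, 87.5, obs, hz),
            prevalence_objective(truth, 87.5, obs, hz))
  # all-zero observations with positive beta1 leave residual
  zero <- obs; zero$prev <- 0
  expect_gt(prevalence_objective(truth, 87.5, zero, hz), 0)
  # out-of-bounds parameters: large finite penalty, not an error
  pen <- prevalence_objective(c(-0.01, 25, 0.4, 0), 87.5, obs, hz)
  expect_true(is.finite(pen) && pen >= 1e6)
})

test_that("noiseless synthetic data round-trips through the fit", {
  fit <- noiseless_fit("male")
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[1]), 0.076334, tolerance = 1e-3)
  expect_equal(unname(fit$theta[2]), 25.33680, tolerance = 1e-3)
  expect_lt(abs(fit$theta[3] - 0.408), 5e-3)
  expect_lt(abs(fit$theta[4] - (-0.0171)), 5e-3)
  expect_lt(fit$objective, 1e-12)
})

test_that("fit is equivariant to relabelling the sex strata", {
  w <- noiseless_world()
  obs <- sex_obs(w, "male")
  relab <- as.data.frame(obs); relab$sex <- "female"
  fit_m <- noiseless_fit("male")
  fit_f <- fit_incidence(aggregated_prevalence(relab),
                         world_hazard(w, "male"), seed = 1L)
  expect_equal(fit_f$theta, fit_m$theta, tolerance = 1e-12)
})

test_that("midpoint and weighted aggregation give close incidence parameters", {
  w <- noiseless_world()
  obs <- sex_obs(w, "male")
  hz <- world_hazard(w, "male")
  f_mid <- fit_incidence(obs, hz, seed = 1L, age_step = 0.1)
  f_wt <- fit_incidence(obs, hz, seed = 1L, age_step = 0.1,
                        aggregate = "weighted")
  expect_true(f_wt$converged)
  # structural sensitivity of the aggregation convention: the incidence
  # parameters move by a few percent; the weakly identified MRR parameters
  # absorb the rest of the misspecification and are not compared
  expect_lt(abs(f_wt$theta[1] / f_mid$theta[1] - 1), 0.05)
  expect_lt(abs(f_wt$theta[2] / f_mid$theta[2] - 1), 0.05)
})

test_that("trajectory and derivative objectives agree where differencing is valid", {
  # eight coarse claims groups are too wide for finite differences, so the
  # agreement regime is a 5-year grouping of the same noiseless world
  lo <- seq(0, 105, by = 5)
  groups <- data.frame(age_lo = lo, age_hi = lo + 4)
  cfg <- synthetic_config(groups = groups,
                          group_denoms = list(male = rep(2e6, 22),
                                              female = rep(2e6, 22)),
                          noise = "none", top_age = 107.5)
  w <- generate_truth(cfg)
  obs <- sex_obs(w, "male")
  hz <- world_hazard(w, "male")
  f_tr <- fit_incidence(obs, hz, seed = 1L, age_step = 0.1, top_age = 107.5)
  f_dv <- fit_incidence(obs, hz, seed = 1L, top_age = 107.5,
                        mode = "derivative")
  expect_true(f_dv$converged)
  a <- seq(30, 95, by = 2.5)
  ratio <- incidence_rate(a, f_dv$params$inc) / incidence_rate(a, f_tr$params$inc)
  expect_lt(max(abs(ratio - 1)), 0.05)
})

test_that("degenerate inputs are flagged instead of silently fitted", {
  w <- noiseless_world()
  hz <- world_hazard(w, "male")
  zero <- as.data.frame(sex_obs(w, "male")); zero$prev <- 0
  fit <- fit_incidence(aggregated_prevalence(zero), hz, seed = 1L,
                       n_restarts = 0L, maxit = 300L, age_step = 0.1)
  expect_true(!fit$converged || fit$boundary)
  few <- aggregated_prevalence(as.data.frame(sex_obs(w, "male"))[1:3, ])
  expect_error(fit_incidence(few, hz), "at least 4")
  both <- aggregated_prevalence(as.data.frame(w$prevalence))
  expect_error(fit_incidence(both, hz), "single-sex")
})

test_that("fit results serialise to JSON with full precision", {
  fit <- noiseless_fit("male")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$beta1, unname(fit$theta[1]), tolerance = 1e-15)
  expect_equal(back$fixed_beta2, 87.5)
  expect_true(back$converged)
})
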