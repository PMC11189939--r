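test_that("configuration and truth objects validate their invariants", {
  expect_error(sim_config(n_individuals = 0), "counts")
  expect_error(sim_config(readings_per_day = 0), "counts")
  expect_error(sim_config(covariates = modifyList(
    formals(sim_config)$covariates |> eval(),
    list(parasite_prevalence = 1.4))), "prevalence")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(true_parameters("t_sel", re_cor = bad),
               "re_cor \\(t_sel\\).*positive semi-definite")
  expect_error(true_parameters("x", sd_intercept = -1), "SDs")
  expect_silent(true_parameters("x", re_cor = diag(3)))
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- sim_config(seed = 21)
  tr <- default_truth()
  a <- simulate_trait_table(cfg, tr$t_sel)
  b <- simulate_trait_table(cfg, tr$t_sel)
  expect_identical(a, b)
  ra <- simulate_raw_dataset(cfg)
  rb <- simulate_raw_dataset(cfg)
  expect_identical(ra$thermal_log, rb$thermal_log)
  expect_identical(ra$behaviour_log, rb$behaviour_log)
  expect_identical(ra$covariates, rb$covariates)
  pre <- syndrome_preset()
  ma <- simulate_multitrait_table(cfg, pre$sigma_b, pre$sigma_w,
                                  design = "interleaved")
  mb <- simulate_multitrait_table(cfg, pre$sigma_b, pre$sigma_w,
                                  design = "interleaved")
  expect_identical(ma, mb)
  # a different seed must change the numbers but not the schema
  mc <- simulate_trait_table(sim_config(seed = 22), tr$t_sel)
  expect_identical(names(a), names(mc))
  expect_false(identical(a$y, mc$y))
})

test_that("degenerate truth gives exchangeable standard-normal responses", {
  cfg <- sim_config(n_individuals = 2000, seed = 1)
  tt <- simulate_trait_table(cfg, true_parameters("x", beta0 = 0.3),
                             n_occasions = 4)
  expect_lt(abs(mean(tt$y) - 0.3), 0.035)   # 3 x MC standard error
  expect_equal(sd(tt$y), 1, tolerance = 0.02)
})

test_that("generated moments recover the generating variance components", {
  set.seed(1)
  cfg <- sim_config(n_individuals = 10000, seed = 1)
  truth <- true_parameters("t_sel", sd_intercept = 0.68, gamma0 = -0.48)
  tt <- simulate_trait_table(cfg, truth, n_occasions = 6)
  ind_mean <- tapply(tt$y, tt$individual, mean)
  ind_var <- tapply(tt$y, tt$individual, var)
  # between-individual variance: variance of individual means minus the
  # within-individual sampling contribution
  v_between <- var(ind_mean) - mean(ind_var) / 6
  expect_equal(v_between, 0.68^2, tolerance = 0.025)
  expect_equal(sqrt(mean(ind_var)), exp(-0.48), tolerance = 0.01)
})

test_that("multi-trait generator hits its covariance targets", {
  cfg <- sim_config(n_individuals = 500, seed = 2)
  sb <- matrix(c(1, 0.8, 0.8, 1), 2)
  d <- simulate_multitrait_table(cfg, sb, diag(2) * 1e-12, n_occasions = 4)
  m1 <- tapply(d$V1, d$individual, mean)
  m2 <- tapply(d$V2, d$individual, mean)
  expect_equal(cor(m1, m2), 0.8, tolerance = 0.04)

  d0 <- simulate_multitrait_table(cfg, matrix(0, 2, 2), diag(2),
                                  n_occasions = 4, seed = 3)
  m1 <- tapply(d0$V1, d0$individual, mean)
  m2 <- tapply(d0$V2, d0$individual, mean)
  expect_lt(abs(cor(m1, m2)), 3 / sqrt(500))

  # generated phenotypic covariance = between + within covariance
  pre <- syndrome_preset()
  big <- simulate_multitrait_table(sim_config(n_individuals = 2000, seed = 4),
                                   pre$sigma_b, pre$sigma_w, n_occasions = 4)
  emp <- cov(as.matrix(big[pre$traits]))
  expect_equal(emp, pre$sigma_b + pre$sigma_w, tolerance = 0.06,
               ignore_attr = TRUE)

  expect_error(simulate_multitrait_table(cfg, sb, diag(3)), "dimension")
  expect_error(simulate_multitrait_table(cfg, sb, diag(2), mu = 1:3),
               "mu length")
})

test_that("interleaved design reproduces the alternating assay layout", {
  cfg <- sim_config(seed = 5)
  pre <- syndrome_preset()
  d <- simulate_multitrait_table(cfg, pre$sigma_b, pre$sigma_w,
                                 design = "interleaved")
  expect_equal(nrow(d), 36 * 11)
  th <- d[d$occasion %% 2 == 1, ]
  bh <- d[d$occasion %% 2 == 0, ]
  expect_true(all(!is.na(th$t_sel)) && all(is.na(th$activity)))
  expect_true(all(is.na(bh$t_sel)) && all(!is.na(bh$activity)))
  expect_equal(length(unique(th$occasion)), 6)
  expect_equal(length(unique(bh$occasion)), 5)
})

test_that("raw generator respects physical invariants and the design", {
  cfg <- sim_config(seed = 1)
  raw <- simulate_raw_dataset(cfg)
  expect_equal(nrow(raw$thermal_log), 36 * 6 * 22)
  expect_equal(nrow(raw$behaviour_log), 36 * 5)
  expect_true(all(raw$thermal_log$body_temp_c >= 23 &
                    raw$thermal_log$body_temp_c <= 60))
  with(raw$behaviour_log, {
    expect_true(all(sheltering_s >= 0 & sheltering_s <= 3600))
    expect_true(all(time_outside_s >= 0 & time_outside_s <= 3600))
    expect_true(all(risk_latency_s >= 0 & risk_latency_s <= 3600))
    expect_true(all(transitions == round(transitions) & transitions >= 0))
  })
  # every individual-day pair complete
  counts <- table(raw$thermal_log$individual, raw$thermal_log$day)
  expect_true(all(counts == 22))
  expect_error(simulate_raw_dataset(sim_config(readings_per_day = 3)),
               "quartiles")
})

test_that("round trip generator -> derivation stays within the stated noise", {
  raw <- simulate_raw_dataset(sim_config(seed = 9))
  tg <- attr(raw, "targets")
  tab <- derive_trait_table(raw)
  th <- tab[tab$assay == "thermal", ]
  err <- abs(th$t_sel - tg$t_sel)
  # medians of m-1 truncated-normal readings: tolerance is the generator's
  # stated sampling SE of the day median
  expect_lt(median(err / tg$median_se), 1.5)
  expect_true(mean(err < 4 * tg$median_se) > 0.98)
  # the day's maximum is the generating peak wherever no clamping occurred
  unclamped <- tg$t_vmax <= 60 & tg$t_vmax >= 23
  expect_equal(th$t_vmax[unclamped], tg$t_vmax[unclamped], tolerance = 1e-12)
})

test_that("default calibration lands on the study's descriptive statistics", {
  raw <- simulate_raw_dataset(sim_config(seed = 1))
  tab <- derive_trait_table(raw)
  expect_equal(mean(tab$t_sel, na.rm = TRUE), 32.22, tolerance = 0.02)
  expect_equal(mean(tab$t_set, na.rm = TRUE), 4.49, tolerance = 0.15)
  expect_equal(mean(tab$t_vmax, na.rm = TRUE), 39.73, tolerance = 0.03)
  ind_sel <- tapply(tab$t_sel, tab$individual, mean, na.rm = TRUE)
  expect_gt(min(ind_sel), 28.5)
  expect_lt(max(ind_sel), 35.5)
  expect_gt(diff(range(ind_sel)), 2)      # clear personality spread
  expect_equal(mean(tab$activity, na.rm = TRUE), 6.84, tolerance = 0.2)
  shel_s <- mean(expm1(tab$sheltering), na.rm = TRUE)
  risk_s <- mean(expm1(tab$risk_taking), na.rm = TRUE)
  expect_gt(shel_s, 35); expect_lt(shel_s, 170)
  expect_gt(risk_s, 85); expect_lt(risk_s, 450)
})

test_that("no-heterogeneity thermal truth gives exchangeable day summaries", {
  tr <- default_truth()
  flat <- function(t) {
    t$sd_intercept <- 0; t$sd_time <- 0; t$omega <- 0
    t$beta_time <- 0; t$re_cor <- diag(3)
    t
  }
  raw <- simulate_raw_dataset(sim_config(seed = 13), lapply(tr, flat))
  tab <- derive_trait_table(raw)
  th <- tab[tab$assay == "thermal", ]
  # all individual-day series share one generating law up to residual and
  # within-day noise: spread of day medians is bounded by those two sources
  sigma_day <- mean(attr(raw, "targets")$sigma_day)
  resid_sd <- tr$t_sel$natural_sd * exp(tr$t_sel$gamma0)
  expect_lt(sd(th$t_sel),
            1.5 * sqrt(resid_sd^2 + (1.2533 * sigma_day / sqrt(21))^2))
})
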