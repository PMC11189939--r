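test_that("thermal trait derivation matches the quantile oracle", {
  expect_equal(derive_thermal_traits(rep(30, 22)),
               list(t_sel = 30, t_set = 0, t_vmax = 30))
  x <- c(28, 30, 32, 34, 36)
  tr <- derive_thermal_traits(x)
  expect_equal(tr$t_sel, 32)
  expect_equal(tr$t_vmax, 36)
  expect_equal(tr$t_set, oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25))

  set.seed(1)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    x <- runif(n, 23, 60)
    tr <- derive_thermal_traits(x)
    expect_equal(tr$t_sel, oracle_quantile7(x, 0.5))
    expect_equal(tr$t_set,
                 oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25))
    expect_equal(tr$t_vmax, max(x))
    expect_gte(tr$t_vmax, tr$t_sel)
    expect_gte(tr$t_set, 0)
  }
  expect_error(derive_thermal_traits(c(30, 31, 32)), "at least 4")
  expect_error(derive_thermal_traits(c(30, 31, 32, NA)), "finite")
})

test_that("thermal derivation is permutation-invariant and affine-equivariant", {
  set.seed(2)
  for (i in 1:50) {
    x <- runif(22, 24, 45)
    base <- derive_thermal_traits(x)
    perm <- derive_thermal_traits(sample(x))
    expect_equal(base, perm)
    sh <- derive_thermal_traits(x + 3.7)
    expect_equal(sh$t_sel, base$t_sel + 3.7)
    expect_equal(sh$t_vmax, base$t_vmax + 3.7)
    expect_equal(sh$t_set, base$t_set)    # width is shift-invariant
    sc <- derive_thermal_traits(x * 1.8)
    expect_equal(sc$t_set, base$t_set * 1.8)
  }
})

test_that("behaviour traits follow the activity formula and its edge rules", {
  expect_equal(derive_behaviour_traits(3000, 0, 600, 100)$activity, 0)
  expect_equal(derive_behaviour_traits(3000, 12, 600, 100)$activity, 1.2)
  b <- derive_behaviour_traits(3600, 0, 0, 250)
  expect_true(is.na(b$activity))          # rate undefined when never outside
  expect_equal(b$sheltering, 3600)
  expect_error(derive_behaviour_traits(3600, 5, 0, 100), "inconsistent")
  expect_error(derive_behaviour_traits(-1, 0, 600, 100), "3600")
  expect_error(derive_behaviour_traits(100, 2.5, 600, 100), "integer")
  expect_error(derive_behaviour_traits(100, 2, 600, -3), ">= 0")
})

test_that("state covariates: head PCA, residual covariates, parasite mean", {
  cov <- simulate_covariate_table(sim_config(seed = 3))
  pc <- prepare_covariates(cov)
  pca <- attr(pc, "head_pca")
  expect_true(all(pca$loadings > 0))
  expect_equal(mean(pc$relative_head_size), 0, tolerance = 1e-10)
  expect_equal(mean(pc$condition), 0, tolerance = 1e-10)
  expect_equal(pc$parasite_intensity,
               rowMeans(cov[c("parasite_count_1", "parasite_count_2",
                              "parasite_count_3")]))
  # three smear scans (4, 5, 6) average to 5
  cov$parasite_count_1[1] <- 4
  cov$parasite_count_2[1] <- 5
  cov$parasite_count_3[1] <- 6
  expect_equal(prepare_covariates(cov)$parasite_intensity[1], 5)

  # perfectly collinear head measures collapse onto one component
  coll <- cov
  coll$pileus_width_cm <- 0.5 * coll$pileus_length_cm
  coll$head_width_cm <- 2 * coll$pileus_length_cm + 1
  p2 <- prepare_covariates(coll)
  expect_equal(attr(p2, "head_pca")$prop_var, 1)

  cc <- cov
  cc$head_width_cm <- 0.8
  expect_error(prepare_covariates(cc), "constant")
  expect_error(prepare_covariates(cov[1:2, ]), ">= 3 individuals")
})

test_that("standardization is exact, idempotent and invertible", {
  d <- tibble::tibble(x = c(1, 2, 3))
  z <- standardize_traits(d, "x")
  expect_equal(z$x_z, c(-1, 0, 1))        # sample-SD convention
  expect_equal(mean(z$x_z), 0, tolerance = 1e-12)
  expect_equal(sd(z$x_z), 1, tolerance = 1e-12)
  z2 <- standardize_traits(dplyr::rename(z["x_z"], x = x_z), "x")
  expect_equal(z2$x_z, z$x_z, tolerance = 1e-12)
  expect_error(standardize_traits(tibble::tibble(k = rep(2, 5)), "k"),
               "'k' has zero variance")
  # back-transforming a standardized location recovers natural units
  expect_equal(destandardize(0, z, "x"), 2, ignore_attr = TRUE)
  expect_equal(destandardize(z$x_z, z, "x"), d$x, ignore_attr = TRUE)
})

test_that("derived trait table satisfies its structural invariants", {
  raw <- simulate_raw_dataset(sim_config(seed = 4))
  tab <- derive_trait_table(raw)
  th <- tab[tab$assay == "thermal", ]
  expect_true(all(th$t_vmax >= th$t_sel))
  expect_true(all(th$t_set >= 0))
  for (cl in c("t_sel_z", "activity_z", "sheltering_z", "risk_taking_z",
               "svl_z", "condition_z")) {
    expect_equal(mean(tab[[cl]], na.rm = TRUE), 0, tolerance = 1e-8)
    expect_equal(sd(tab[[cl]], na.rm = TRUE), 1, tolerance = 1e-8)
  }
  # log transform applied to the two latency traits only
  bh <- tab[tab$assay == "behaviour", ]
  i <- which(!is.na(bh$sheltering))[1]
  ind <- bh$individual[i]; day <- bh$day[i]
  rawrow <- raw$behaviour_log[raw$behaviour_log$individual == ind &
                                raw$behaviour_log$day == day, ]
  expect_equal(bh$sheltering[i], log1p(rawrow$sheltering_s))
  expect_equal(bh$risk_taking[i], log1p(rawrow$risk_latency_s))
  expect_equal(bh$activity[i],
               rawrow$transitions / rawrow$time_outside_s * 60)
  # back-transformed standardized population mean = natural-scale mean
  expect_equal(destandardize(mean(tab$t_sel_z, na.rm = TRUE), tab, "t_sel"),
               mean(tab$t_sel, na.rm = TRUE), ignore_attr = TRUE)
})
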