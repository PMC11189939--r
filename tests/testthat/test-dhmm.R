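test_that("log-likelihood matches term-by-term brute force", {
  spec <- dhmm_spec("y", covariates = c("x1", "x2"), time = "time_z",
                    id = "individual")
  set.seed(1)
  n_ind <- 5
  d <- tibble::tibble(
    individual = rep(1:n_ind, each = 4),
    time_z = rep(scale(1:4)[, 1], n_ind),
    x1 = rnorm(20), x2 = rnorm(20), y = rnorm(20))
  params <- list(beta0 = 0.3, beta_time = -0.2,
                 beta = c(x1 = 0.5, x2 = -0.1),
                 gamma0 = -0.4, gamma = c(x1 = 0.15, x2 = 0.05),
                 a = rnorm(n_ind), b = rnorm(n_ind, 0, 0.3),
                 w = rnorm(n_ind, 0, 0.3))
  ll <- dhmm_loglik(spec, params, d)
  # independent brute force: evaluate every observation's normal density
  brute <- 0
  for (k in seq_len(nrow(d))) {
    i <- d$individual[k]
    mu <- params$beta0 + params$beta_time * d$time_z[k] +
      params$beta[["x1"]] * d$x1[k] + params$beta[["x2"]] * d$x2[k] +
      params$a[i] + params$b[i] * d$time_z[k]
    sig <- exp(params$gamma0 + params$gamma[["x1"]] * d$x1[k] +
                 params$gamma[["x2"]] * d$x2[k] + params$w[i])
    brute <- brute + dnorm(d$y[k], mu, sig, log = TRUE)
  }
  expect_equal(ll, brute, tolerance = 1e-10)

  # C++ evaluator used inside the sampler agrees with the R evaluator
  dz <- thermopred:::.dhmm_design(spec, d)
  ll_cpp <- thermopred:::dhmm_loglik_cpp(
    dz$y, dz$xm, dz$xr, dz$id - 1L, dz$t,
    c(params$beta0, params$beta_time, params$beta),
    c(params$gamma0, params$gamma),
    params$a, params$b, params$w)
  expect_equal(ll_cpp, ll, tolerance = 1e-10)

  # Gaussian sign symmetry: negating y and all location parameters leaves
  # the log-likelihood unchanged
  neg <- params
  neg$beta0 <- -neg$beta0; neg$beta_time <- -neg$beta_time
  neg$beta <- -neg$beta; neg$a <- -neg$a; neg$b <- -neg$b
  d2 <- d; d2$y <- -d$y
  expect_equal(dhmm_loglik(spec, neg, d2), ll, tolerance = 1e-10)

  # non-finite parameters surface as non-finite log-likelihood, not clipped
  bad <- params; bad$beta0 <- NaN
  expect_true(!is.finite(dhmm_loglik(spec, bad, d)))
})

test_that("single standard-normal observation at its mode", {
  spec <- dhmm_spec("y", covariates = character(0), time = NULL, id = "id")
  d <- tibble::tibble(id = 1, y = 0.7)
  ll <- dhmm_loglik(spec, list(beta0 = 0.7, gamma0 = 0), d)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("HPD interval equals the exhaustive shortest-window search", {
  set.seed(3)
  x <- sort(runif(1000))
  h <- hpd_interval(x, 0.95)
  expect_equal(diff(h), 0.95, tolerance = 0.02)

  ln <- rlnorm(1000, 0, 0.8)
  h <- hpd_interval(ln, 0.95)
  o <- oracle_hpd(ln, 0.95)
  spacing <- max(diff(sort(ln)))
  expect_lt(max(abs(h - o)), spacing + 1e-12)

  z <- rnorm(5000)
  h <- hpd_interval(z, 0.95)
  et <- quantile(z, c(0.025, 0.975))
  expect_equal(unname(h), unname(et), tolerance = 0.1)
  # independent implementation in coda agrees where the density is smooth
  # (conventions differ by one order statistic in the window size)
  hc <- coda::HPDinterval(coda::as.mcmc(z), 0.95)
  expect_equal(unname(h), unname(hc[1, ]), tolerance = 0.05)

  expect_error(hpd_interval(rnorm(50)), "at least 100")
  expect_error(hpd_interval(c(rnorm(100), NA)), "NA")
  expect_error(hpd_interval(rnorm(200), mass = 1), "mass")
})

test_that("diagnostics flag convergence exactly at the stated thresholds", {
  set.seed(4)
  good <- fake_posterior(tibble::tibble(theta = rnorm(4000),
                                        phi = rgamma(4000, 2)))
  rep <- diagnose(good)
  expect_true(all(rep$rhat < 1.01))
  expect_true(all(rep$ess > 2000))        # iid draws: ESS near draw count
  expect_true(attr(rep, "pass"))
  expect_equal(unname(attr(rep, "thresholds")),
               c(1.01, 400))

  # two chains centred apart must fail loudly
  sep <- fake_posterior(tibble::tibble(theta = c(rnorm(1000),
                                                 rnorm(1000, 3))),
                        n_chains = 2)
  rep2 <- diagnose(sep)
  expect_gt(rep2$rhat[1], 1.1)
  expect_false(attr(rep2, "pass"))

  one <- fake_posterior(tibble::tibble(theta = rnorm(500)), n_chains = 1)
  expect_error(diagnose(one), "at least 2 chains")
})

test_that("with no data the sampler returns the priors", {
  cfg <- sim_config(n_individuals = 4, seed = 3)
  tt <- simulate_trait_table(cfg, true_parameters("x"), n_occasions = 2)
  p <- quick_dhmm(tt, dhmm_spec("y", covariates = character(0)),
                  seed = 5, prior_only = TRUE, scale = "desk")
  # half-normal(0,1): mean sqrt(2/pi) = 0.798, sd = 0.603
  for (cl in c("sd_intercept", "sd_time", "omega")) {
    expect_equal(mean(p$draws[[cl]]), sqrt(2 / pi), tolerance = 0.05)
    expect_equal(sd(p$draws[[cl]]), sqrt(1 - 2 / pi), tolerance = 0.08)
  }
  expect_equal(mean(p$draws$beta0), 0, tolerance = 0.08)
  expect_equal(sd(p$draws$beta0), 1, tolerance = 0.06)
  # LKJ(1), d = 3: each correlation is Beta(1.5, 1.5) on (-1, 1) -> sd 0.5
  expect_equal(mean(p$draws$r_intercept_slope), 0, tolerance = 0.06)
  expect_equal(sd(p$draws$r_intercept_slope), 0.5, tolerance = 0.05)
})

test_that("population-level posteriors ignore individual labelling", {
  cfg <- sim_config(n_individuals = 20, seed = 6)
  tt <- simulate_trait_table(cfg, recovery_truth(), n_occasions = 6)
  spec <- dhmm_spec("y", covariates = character(0))
  p1 <- quick_dhmm(tt, spec, seed = 11, iter = 1200L, warmup = 400L,
                   thin = 2L, chains = 2L)
  tt2 <- tt
  tt2$individual <- tt2$individual + 100L   # order-preserving relabel
  p2 <- quick_dhmm(tt2, spec, seed = 11, iter = 1200L, warmup = 400L,
                   thin = 2L, chains = 2L)
  expect_equal(p1$draws, p2$draws)
})

test_that("sampler recovers generating parameters and flags significance", {
  cfg <- sim_config(seed = 11)
  tt <- simulate_trait_table(cfg, recovery_truth(), n_occasions = 6)
  p <- quick_dhmm(tt, dhmm_spec("y", covariates = character(0)),
                  seed = 5, scale = "desk")
  expect_true(attr(p$convergence, "pass"))
  s <- summary(p)
  est <- function(nm) s$mean[s$parameter == nm]
  expect_equal(est("sd_intercept"), 0.8, tolerance = 0.2)
  expect_equal(est("omega"), 0.4, tolerance = 0.45)
  expect_equal(est("gamma0"), -0.5, tolerance = 0.35)
  # the strong personality signal must be flagged by the HPD convention
  expect_true(s$significant[s$parameter == "sd_intercept"])
  lo <- s$hpd_low[s$parameter == "sd_intercept"]
  hi <- s$hpd_high[s$parameter == "sd_intercept"]
  expect_true(lo <= 0.8 && 0.8 <= hi)
  expect_error(sample_dhmm(tt[tt$individual == 1, ],
                           dhmm_spec("y", covariates = character(0))),
               "at least 2 individuals")
})
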