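fake_mv <- function(sb_draws, sw_draws, traits) {
  structure(list(mu = matrix(0, dim(sb_draws)[3], length(traits)),
                 sigma_b = sb_draws, sigma_w = sw_draws, traits = traits,
                 settings = list()),
            class = "multitrait_posterior")
}

test_that("correlation decomposition is exact on hand-built covariances", {
  # var 4, var 9, cov 3 -> r = 3/sqrt(36) = 0.5
  s <- matrix(c(4, 3, 3, 9), 2)
  arr <- array(s, c(2, 2, 200))
  dec <- decompose_correlations(fake_mv(arr, array(diag(2), c(2, 2, 200)),
                                        c("A", "B")))
  expect_equal(dec$mean[dec$level == "between"], 0.5)
  expect_equal(dec$ci_low[dec$level == "between"], 0.5)
  expect_true(dec$syndrome_flag[dec$level == "between"])
  # diagonal draws give exactly zero correlations
  expect_equal(dec$mean[dec$level == "within"], 0)
  expect_false(dec$syndrome_flag[dec$level == "within"])

  # a 6-trait posterior yields the full 15-pair reporting layout
  arr6 <- array(diag(6), c(6, 6, 120))
  d6 <- decompose_correlations(fake_mv(arr6, arr6, letters[1:6]))
  expect_equal(nrow(d6), 2 * 15)
  expect_setequal(unique(d6$level), c("between", "within"))
})

test_that("model fit validates identifiability and input shape", {
  cfg <- sim_config(n_individuals = 6, seed = 1)
  d <- simulate_multitrait_table(cfg, diag(2), diag(2), n_occasions = 3)
  expect_error(fit_multitrait(d, traits = c("V1", "nope")), "nope")
  single <- d[!duplicated(d$individual), ]
  expect_error(fit_multitrait(single, traits = c("V1", "V2"),
                              iter = 50, burnin = 10, thin = 1),
               "fewer than 2 occasions")
  # one trait observed once per individual everywhere -> named in the error
  d2 <- d
  d2$V2[duplicated(d2$individual)] <- NA
  expect_error(fit_multitrait(d2, traits = c("V1", "V2"),
                              iter = 50, burnin = 10, thin = 1), "'V2'")
})

test_that("between-individual correlation is recovered from known truth", {
  cfg <- sim_config(n_individuals = 120, seed = 2)
  sb <- matrix(c(1, 0.8, 0.8, 1), 2)
  d <- simulate_multitrait_table(cfg, sb, diag(2), n_occasions = 6)
  fit <- fit_multitrait(d, traits = c("V1", "V2"), seed = 4,
                        iter = 4000, burnin = 1000, thin = 5)
  dec <- decompose_correlations(fit)
  rb <- dec[dec$level == "between", ]
  rw <- dec[dec$level == "within", ]
  expect_equal(rb$mean, 0.8, tolerance = 0.15)
  expect_true(rb$syndrome_flag)
  expect_lt(abs(rw$mean), 0.12)
  expect_false(rw$syndrome_flag)
})

test_that("decomposition is invariant to per-trait affine rescaling", {
  cfg <- sim_config(n_individuals = 80, seed = 3)
  sb <- matrix(c(1, 0.5, 0.5, 1), 2)
  sw <- matrix(c(1, -0.3, -0.3, 1), 2)
  d <- simulate_multitrait_table(cfg, sb, sw, n_occasions = 6)
  d2 <- d
  d2$V1 <- 10 * d2$V1 + 3
  d2$V2 <- -2 * d2$V2      # sign flip flips correlations
  f1 <- fit_multitrait(d, traits = c("V1", "V2"), seed = 5,
                       iter = 3000, burnin = 1000, thin = 4)
  f2 <- fit_multitrait(d2, traits = c("V1", "V2"), seed = 5,
                       iter = 3000, burnin = 1000, thin = 4)
  c1 <- decompose_correlations(f1)
  c2 <- decompose_correlations(f2)
  expect_equal(c2$mean, -c1$mean, tolerance = 0.08)
})

test_that("missing-by-design layout is handled by the augmentation step", {
  pre <- syndrome_preset()
  d <- simulate_multitrait_table(sim_config(seed = 6), pre$sigma_b,
                                 pre$sigma_w, design = "interleaved")
  fit <- fit_multitrait(d, traits = pre$traits, seed = 7,
                        iter = 6000, burnin = 2000, thin = 8)
  dec <- decompose_correlations(fit)
  expect_equal(nrow(dec), 30)
  expect_true(all(is.finite(dec$mean)))
  expect_true(all(dec$mean >= -1 & dec$mean <= 1))
  # the strongest generating syndrome keeps its sign and rough size
  as <- dec[dec$trait_pair == "activity-sheltering" &
              dec$level == "between", ]
  expect_lt(as$mean, -0.4)
})
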