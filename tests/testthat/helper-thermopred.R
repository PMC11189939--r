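# shared fixtures and independent oracles, built in code at test time

# brute-force type-7 quantile: linear interpolation between order statistics
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive shortest-window HPD oracle (independent re-implementation used
# to pin hpd_interval; deliberately written from the definition)
oracle_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}

# minimal hand-built posterior object for functions that only need draws
fake_posterior <- function(draw_tbl, n_chains = 4) {
  n <- nrow(draw_tbl)
  stopifnot(n %% n_chains == 0)
  draws <- dplyr::bind_cols(
    tibble::tibble(.chain = rep(seq_len(n_chains), each = n / n_chains),
                   .iteration = rep(seq_len(n / n_chains), n_chains)),
    draw_tbl)
  structure(list(draws = draws), class = "dhmm_posterior")
}

# recovery-scenario truth shared by several tests: strong personality,
# moderate predictability variation, negative type-predictability link
recovery_truth <- function() {
  true_parameters("recovery",
                  sd_intercept = 0.8, sd_time = 0.2, omega = 0.4,
                  gamma0 = -0.5,
                  re_cor = matrix(c(1, 0, -0.6,
                                    0, 1, 0,
                                    -0.6, 0, 1), 3))
}

quick_dhmm <- function(data, spec, seed, ...) {
  suppressWarnings(suppressMessages(
    sample_dhmm(data, spec, seed = seed, ...)))
}
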