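test_that("a half lapse fixes the log-likelihood at n log(1/2)", {
  set.seed(81)
  tp <- task_params(category_info = 0.8)
  d <- itb_observer(50, tp, itb_params())
  a <- 2 * d$signals / (1 + tp$sigma_e^2)
  th <- c(category_prior = 0.5, lapse = 0.5, temperature = 1, noise = 0.2,
          bound = 3, leak = 0, signal_scale = 1)
  ll <- itb_log_likelihood(th, d, 0.8, logodds_signals = a)
  expect_equal(ll, 50 * log(0.5), tolerance = 1e-8)
})

test_that("duplicating the dataset doubles the log-likelihood", {
  set.seed(82)
  tp <- task_params(category_info = 0.85)
  d <- itb_observer(80, tp, itb_params(noise = 0.2, bound = 2))
  idx <- rep(seq_len(80), 2)
  d2 <- choice_dataset(d$signals[idx, ], d$choices[idx], d$categories[idx])
  a <- 2 * d$signals / (1 + tp$sigma_e^2)
  th <- c(category_prior = 0.5, lapse = 0.03, temperature = 1, noise = 0.25,
          bound = 2.5, leak = 0.1, signal_scale = 1)
  clip <- lpo_clip(signal_to_llo(a, 1, 0.85))
  l1 <- itb_log_likelihood(th, d, 0.85, logodds_signals = a, clip = clip)
  l2 <- itb_log_likelihood(th, d2, 0.85, logodds_signals = a[idx, ],
                           clip = clip)
  expect_equal(l2, 2 * l1, tolerance = 1e-8)
})

test_that("the evidence scale is exactly a scale: rescaling signals and s together", {
  set.seed(83)
  tp <- task_params(category_info = 0.8)
  d <- itb_observer(60, tp, itb_params(noise = 0.2, bound = 2))
  a <- 2 * d$signals / (1 + tp$sigma_e^2)
  th <- c(category_prior = 0.55, lapse = 0.02, temperature = 1.2, noise = 0.3,
          bound = 2.2, leak = -0.1, signal_scale = 1)
  th_scaled <- th; th_scaled["signal_scale"] <- 7
  d_scaled <- choice_dataset(d$signals, d$choices, d$categories)
  clip <- lpo_clip(signal_to_llo(a, 1, 0.8))
  l1 <- itb_log_likelihood(th, d, 0.8, logodds_signals = a, clip = clip)
  l2 <- itb_log_likelihood(th_scaled, d_scaled, 0.8, logodds_signals = a * 7,
                           clip = clip)
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("the likelihood matches Monte-Carlo choice frequencies per trial", {
  set.seed(84)
  tp <- task_params(category_info = 0.85, sigma_e = 1.2)
  d <- itb_observer(10, tp, itb_params())
  llo <- frame_llo(d$signals, tp)
  p <- itb_params(category_prior = 0.45, lapse = 0.04, temperature = 0.9,
                  noise = 0.3, bound = 2, leak = 0.12)
  exact <- itb_choice_probability(llo, p, clip = lpo_clip(llo, 0.45))
  y <- d$choices > 0
  for (t in 1:10) {
    mc <- mean(simulate_itb(llo[rep(t, 1e5), ], p)$choice > 0)
    p_obs <- if (y[t]) exact[t] else 1 - exact[t]
    mc_obs <- if (y[t]) mc else 1 - mc
    expect_lt(abs(log(p_obs) - log(mc_obs)), 0.02)
  }
})

test_that("with no data MH reproduces the prior marginals", {
  set.seed(85)
  d <- choice_dataset(matrix(numeric(0), 0, 10), numeric(0), numeric(0))
  mh <- run_mh_chains(d, 0.9, n_chains = 2, n_steps = 5000, n_adapt = 400,
                      n_scan = 40, fix_scale = TRUE)
  s <- do.call(rbind, mh$samples)
  thin <- s[seq(1, nrow(s), by = 18), ]
  pri <- itb_priors()
  checks <- list(
    category_prior = function(u) pbeta(u, 2, 2),
    lapse = function(u) pbeta(u, 1, 10) / pbeta(0.5, 1, 10),
    temperature = function(u) pexp(u, 1 / 4),
    noise = function(u) pexp(u, 1 / 0.25),
    bound = function(u) pgamma(u, 2, scale = 3),
    leak = function(u) punif(u, -1, 1))
  for (p in names(checks)) {
    ks <- suppressWarnings(stats::ks.test(thin[, p], checks[[p]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("split R-hat is near 1 for iid draws and undefined for one chain", {
  set.seed(86)
  chains <- lapply(1:4, function(i)
    matrix(rnorm(2500 * 2), 2500, 2, dimnames = list(NULL, c("a", "b"))))
  lps <- lapply(1:4, function(i) rnorm(2500))
  diag <- convergence_diagnostics(chains, lps)
  expect_true(all(diag$rhat < 1.01))
  expect_error(convergence_diagnostics(chains[1], lps[1]), "2 chains")
})

test_that("degenerate constant chains are flagged", {
  chains <- lapply(1:2, function(i)
    matrix(1, 100, 1, dimnames = list(NULL, "a")))
  lps <- lapply(1:2, function(i) rep(0, 100))
  diag <- convergence_diagnostics(chains, lps)
  expect_true(is.nan(diag$rhat["a"]))
})

test_that("burn-in is the first sample above the median log posterior, capped at 20%", {
  chains <- list(matrix(rnorm(200), 100, 2), matrix(rnorm(200), 100, 2))
  # monotone increasing log posterior: the cap binds
  lp_mono <- list(seq_len(100) / 10, seq_len(100) / 10)
  expect_equal(convergence_diagnostics(chains, lp_mono)$burn_in, c(20L, 20L))
  # immediately good chains: burn-in is the first crossing
  lp_fast <- list(c(100, rep(c(0, 200), 50))[1:100] + 0,
                  c(100, rep(c(0, 200), 50))[1:100] + 0)
  bi <- convergence_diagnostics(chains, lp_fast)$burn_in
  expect_true(all(bi <= 20))
})

test_that("priors evaluate and invert consistently", {
  pri <- itb_priors()
  u <- c(0.3, 0.2, 0.6, 0.4, 0.7, 0.5, 0.9)
  th <- pri$quantile(u)
  expect_true(is.finite(pri$log_density(th)))
  expect_equal(unname(th["leak"]), 0)
  bad <- th; bad["lapse"] <- 0.7
  expect_identical(pri$log_density(bad), -Inf)
})
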