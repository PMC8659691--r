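test_that("pseudo-posterior samples are symmetric under a flat belief", {
  set.seed(31)
  params <- task_params(category_info = 0.8, sigma_e = 1)
  cfg <- sampling_config(n_samples = 20000)
  s1 <- sample_posterior_x(0, 0.5, params, cfg)$samples
  s2 <- sample_posterior_x(0, 0.5, params, cfg)$samples
  ks <- suppressWarnings(stats::ks.test(s1, -s2))
  expect_gt(ks$p.value, 0.01)
})

test_that("pseudo-posterior concentrates at the evidence as noise vanishes", {
  set.seed(32)
  params <- task_params(category_info = 0.8, sigma_e = 1e-4)
  s <- sample_posterior_x(0.73, 0.6, params, sampling_config(n_samples = 500))
  expect_lt(max(abs(s$samples - 0.73)), 0.01)
})

test_that("pseudo-posterior sampler matches its analytic mixture density", {
  # Q(x) ~ p(e|x) * prior-mixture(x): conjugate two-Gaussian mixture.
  set.seed(33)
  params <- task_params(category_info = 0.85, sigma_e = 0.9)
  e <- 0.6; prior_c <- 0.75
  draws <- sample_posterior_x(e, prior_c, params,
                              sampling_config(n_samples = 200000))$samples
  q <- 0.85; mp <- q * prior_c + (1 - q) * (1 - prior_c)
  s2 <- 1 + 0.9^2
  wp <- mp * dnorm(e, 1, sqrt(s2))
  wm <- (1 - mp) * dnorm(e, -1, sqrt(s2))
  r <- wp / (wp + wm)
  sd_post <- sqrt(0.9^2 / s2)
  dens <- function(x) r * dnorm(x, (0.9^2 + e) / s2, sd_post) +
    (1 - r) * dnorm(x, (-0.9^2 + e) / s2, sd_post)
  hist_breaks <- seq(-4, 4, by = 0.25)
  emp <- hist(draws[draws > -4 & draws < 4], breaks = hist_breaks,
              plot = FALSE)$density
  theo <- vapply(seq_len(length(hist_breaks) - 1), function(i)
    stats::integrate(dens, hist_breaks[i], hist_breaks[i + 1])$value / 0.25, 0)
  expect_lt(max(abs(emp - theo)), 0.02)
  expect_equal(stats::integrate(dens, -Inf, Inf)$value, 1, tolerance = 1e-6)
})

test_that("normalized and raw importance weights give the same LLO estimate", {
  set.seed(34)
  params <- task_params(category_info = 0.8, sigma_e = 1.1)
  s <- sample_posterior_x(0.4, 0.7, params, sampling_config(n_samples = 7))
  a <- importance_llo_estimate(s$samples, s$raw_weights, params,
                               sampling_config(normalize_weights = TRUE))
  b <- importance_llo_estimate(s$samples, s$raw_weights, params,
                               sampling_config(normalize_weights = FALSE))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("many-sample importance estimate converges to the exact LLO", {
  set.seed(35)
  params <- task_params(category_info = 0.85, sigma_e = 1)
  cfg <- sampling_config(n_samples = 100000)
  for (e in c(-1.4, 0.3, 1.9)) {
    s <- sample_posterior_x(e, 0.5, params, cfg)
    est <- importance_llo_estimate(s$samples, s$raw_weights, params, cfg)
    expect_lt(abs(est - frame_llo(e, params)), 0.02)
  }
})

test_that("few-sample LLO estimates are biased toward the prior belief", {
  # with e = 0 the exact LLO is 0; with a prior favouring +1 and S = 5
  # the mean estimate is pulled positive
  set.seed(36)
  params <- task_params(category_info = 0.8, sigma_e = 1)
  cfg <- sampling_config(n_samples = 5)
  est <- vapply(1:8000, function(i) {
    s <- sample_posterior_x(0, 0.9, params, cfg)
    importance_llo_estimate(s$samples, s$raw_weights, params, cfg)
  }, 0)
  expect_gt(mean(est) / (sd(est) / sqrt(length(est))), 3)  # signed bias > 0
})

test_that("degenerate inputs are rejected", {
  params <- task_params()
  expect_error(sample_posterior_x(0.1, 1, params), "prior_c")
  expect_error(importance_llo_estimate(c(0, 1), c(0, 0), params), "degenerate")
})

test_that("with many samples the observer approaches ideal accuracy", {
  set.seed(37)
  params <- task_params(category_info = 0.8,
                        sigma_e = sigma_for_sensory_info(0.75))
  acc_ideal <- accuracy(ideal_observer(6000, params))
  acc_samp <- accuracy(sampling_observer(6000, params,
                                         sampling_config(n_samples = 3000,
                                                         n_updates = 1)))
  expect_lt(abs(acc_samp - acc_ideal), 0.025)
})

test_that("the observer shows primacy at LSHC and recency at HSLC", {
  set.seed(38)
  lshc <- task_params(category_info = 0.93,
                      sigma_e = sigma_for_sensory_info(0.69))
  d <- sampling_observer(8000, lshc, sampling_config(leak = 0))
  expect_lt(slope_of(d), -0.03)
  hslc <- task_params(category_info = 0.67,
                      sigma_e = sigma_for_sensory_info(0.995))
  d <- sampling_observer(8000, hslc, sampling_config(leak = 0.1))
  expect_gt(slope_of(d), 0.03)
})

test_that("primacy weakens toward zero as the sample count grows", {
  set.seed(39)
  lshc <- task_params(category_info = 0.93,
                      sigma_e = sigma_for_sensory_info(0.69))
  betas <- vapply(c(5, 50, 500), function(S) {
    slope_of(sampling_observer(5000, lshc, sampling_config(n_samples = S)))
  }, 0)
  expect_true(all(diff(abs(betas)) < 0.03))  # non-increasing up to MC noise
  expect_lt(abs(betas[3]), 0.05)
})

test_that("single-trial traces follow the leaky accumulation contract", {
  set.seed(40)
  params <- task_params(category_prior = 0.4, category_info = 0.85)
  trial <- sample_trial(params)
  tr <- run_trial_sampling(trial, params, sampling_config(leak = 0.2))
  expect_length(tr$lpo, 11)
  expect_equal(tr$lpo[1], log(0.4 / 0.6))
  expect_equal(tr$choice, sign(tr$lpo[11]))
})
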