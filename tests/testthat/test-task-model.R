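test_that("sensory information follows the printed AUC formula and inverts", {
  expect_equal(sensory_information(2), pnorm(1), tolerance = 1e-12)
  expect_lt(sensory_information(1e6), 0.5 + 1e-5)   # chance in the noise limit
  expect_gt(sensory_information(1e-3), 1 - 1e-10)
  sig <- c(0.8, 1, 2.7, 10)
  expect_equal(sigma_for_sensory_info(sensory_information(sig)), sig,
               tolerance = 1e-10)
  expect_error(sensory_information(0), "sigma_e")
  expect_error(sigma_for_sensory_info(1), "sensory information")
})

test_that("category information is the frame match fraction", {
  expect_identical(category_information_from_ratio(5, 10), 0.5)
  expect_identical(category_information_from_ratio(10, 10), 1)
  expect_identical(category_information_from_ratio(6, 10), 0.6)
  expect_error(category_information_from_ratio(11, 10), "n_match")
  expect_error(category_information_from_ratio(1, 0), "n_total")
})

test_that("task parameter domains are validated", {
  expect_error(task_params(category_prior = 0), "category_prior")
  expect_error(task_params(category_info = 0.4), "category_info")
  expect_error(task_params(sigma_e = -1), "sigma_e")
  expect_error(task_params(n_frames = 0), "n_frames")
})

test_that("sampled frames match the category at the category-information rate", {
  set.seed(11)
  for (q in c(0.5, 0.9)) {
    params <- task_params(category_info = q, n_frames = 10)
    tr <- sample_trials(10000, params)  # 1e5 frames
    match <- mean(sign(tr$features) == tr$categories)
    # binomial 3-sigma band around q (sigma_x = 1 flips ~16% of signs
    # relative to the mode, so compare against the analytic rate)
    p_match <- q * pnorm(1) + (1 - q) * pnorm(-1)
    expect_lt(abs(match - p_match), 3 * sqrt(p_match * (1 - p_match) / 1e5))
  }
})

test_that("noiseless high-category-information evidence approaches the category", {
  set.seed(1)
  params <- task_params(category_info = 1, sigma_x = 1e-8, sigma_e = 1e-8)
  tr <- sample_trials(200, params)
  expect_equal(tr$evidence, matrix(tr$categories, 200, 10), tolerance = 1e-6)
})

test_that("frame LLO matches numeric quadrature over the generative density", {
  params <- task_params(category_info = 0.8, sigma_e = 1.5)
  e <- c(-3, -1.2, -0.4, 0, 0.7, 2.1)
  quad <- function(ee, cc) {
    stats::integrate(function(x)
      (0.8 * dnorm(x, cc, 1) + 0.2 * dnorm(x, -cc, 1)) * dnorm(ee, x, 1.5),
      -20, 20)$value
  }
  expected <- vapply(e, function(ee) log(quad(ee, 1) / quad(ee, -1)), 0)
  expect_equal(frame_llo(e, params), expected, tolerance = 1e-8)
})

test_that("frame LLO is odd, increasing, and vanishes for uninformative frames", {
  params <- task_params(category_info = 0.75, sigma_e = 0.8)
  e <- seq(-4, 4, by = 0.25)
  llo <- frame_llo(e, params)
  expect_equal(llo, -rev(llo), tolerance = 1e-12)        # odd
  expect_true(all(diff(llo) > 0))                        # increasing
  expect_equal(frame_llo(0, params), 0, tolerance = 1e-12)
  flat <- task_params(category_info = 0.5, sigma_e = 0.8)
  expect_equal(frame_llo(e, flat), rep(0, length(e)), tolerance = 1e-12)
})

test_that("ideal observer accumulates exact LLOs and picks the LPO sign", {
  params <- task_params(category_prior = 0.3, category_info = 0.85)
  trial <- list(category = 1, evidence = c(0.4, -1.2, 2.2, 0.1, -0.3,
                                           1.1, 0.9, -2, 0.5, 0.2))
  tr <- run_ideal_observer(trial, params)
  expect_equal(tr$lpo[1], log(0.3 / 0.7))
  expect_equal(diff(tr$lpo), frame_llo(trial$evidence, params))
  expect_equal(tr$choice, sign(tr$lpo[11]))
})

test_that("single-frame posterior equals Bayes rule on the mixture", {
  params <- task_params(category_prior = 0.6, category_info = 0.8,
                        sigma_e = 1.2, n_frames = 1)
  e <- 0.9
  s <- sqrt(1 + 1.2^2)
  lik <- function(cc) 0.8 * dnorm(e, cc, s) + 0.2 * dnorm(e, -cc, s)
  post <- 0.6 * lik(1) / (0.6 * lik(1) + 0.4 * lik(-1))
  tr <- run_ideal_observer(list(evidence = e), params)
  expect_equal(plogis(tr$lpo[2]), post, tolerance = 1e-12)
})

test_that("all-zero evidence with a flat prior resolves ties by a fair coin", {
  params <- task_params(category_prior = 0.5, category_info = 0.8)
  trial <- list(evidence = rep(0, 10))
  set.seed(5)
  choices <- replicate(400, run_ideal_observer(trial, params)$choice)
  tr <- run_ideal_observer(trial, params)
  expect_equal(tr$lpo, rep(0, 11))
  expect_true(all(abs(choices) == 1))
  expect_gt(mean(choices > 0), 0.40)   # ~Binomial(400, 1/2)
  expect_lt(mean(choices > 0), 0.60)
})

test_that("ideal accuracy is monotone in both information axes", {
  set.seed(21)
  si <- c(0.55, 0.65, 0.75, 0.85, 0.95)
  ci <- c(0.55, 0.65, 0.75, 0.85, 0.95)
  acc <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    p <- task_params(category_info = ci[j],
                     sigma_e = sigma_for_sensory_info(si[i]))
    acc[i, j] <- accuracy(ideal_observer(4000, p))
  }
  # allow Monte-Carlo error of ~3 binomial sd on each comparison
  tol <- 3 * sqrt(0.25 / 4000) * sqrt(2)
  expect_true(all(apply(acc, 2, diff) > -tol))
  expect_true(all(apply(acc, 1, diff) > -tol))
})
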