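test_that("the noiseless unbounded accumulator sums the LLOs exactly", {
  llo <- c(0.5, -0.2, 1.1, 0.4, -0.9, 0.3, 0.8, -0.1, 0.2, 0.6)
  p <- itb_params(category_prior = 0.5, lapse = 0, noise = 0,
                  bound = Inf, leak = 0)
  set.seed(61)
  out <- simulate_itb_choice(llo, p)
  expect_equal(out$lpo_final, sum(llo), tolerance = 1e-12)
})

test_that("a full lapse makes choices independent of the evidence", {
  set.seed(62)
  llo <- matrix(5, 3000, 10)  # overwhelming evidence for +1
  p <- itb_params(lapse = 0.5)
  ch <- simulate_itb(llo, p)$choice
  expect_lt(abs(mean(ch > 0) - 0.5), 3 * sqrt(0.25 / 3000))
  probs <- itb_choice_probability(llo[1:2, ], p, clip = 200)
  expect_equal(probs, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("the bound is sticky: later frames cannot undo a crossing", {
  llo <- c(5, -3, -3, -3, -3, -3, -3, -3, -3, -3)
  p <- itb_params(bound = 1, noise = 0)
  set.seed(63)
  out <- simulate_itb_choice(llo, p)
  expect_equal(out$lpo_final, 1)
  # and the exact propagation agrees
  pr <- itb_choice_probability(llo, p, clip = 50)
  expect_equal(pr, plogis(1), tolerance = 1e-3)
})

test_that("noiseless propagation collapses to the deterministic trace", {
  set.seed(64)
  for (i in 1:5) {
    llo <- rnorm(10, 0, 0.8)
    p <- itb_params(lapse = 0.04, temperature = 1.3, noise = 0,
                    bound = 2.5, leak = 0.1)
    det <- simulate_itb_choice(llo, p)$lpo_final  # deterministic when noise=0
    pr <- itb_choice_probability(llo, p, clip = 30)
    expect_equal(pr, 0.04 + 0.92 * plogis(det / 1.3), tolerance = 2e-3)
  }
})

test_that("propagated mass is conserved at every frame", {
  # the reference engine propagates the full mass vector; total choice
  # probability of +1 and -1 must add to 1 (mass neither lost nor created)
  set.seed(65)
  llo <- matrix(rnorm(30, 0, 1), 3, 10)
  p <- itb_params(category_prior = 0.6, lapse = 0.1, temperature = 0.8,
                  noise = 0.3, bound = 1.6, leak = -0.1)
  pr_plus <- itb_choice_probability(llo, p, clip = 20, engine = "reference")
  pflip <- itb_params(category_prior = 0.4, lapse = 0.1, temperature = 0.8,
                      noise = 0.3, bound = 1.6, leak = -0.1)
  pr_minus <- itb_choice_probability(-llo, pflip, clip = 20,
                                     engine = "reference")
  expect_equal(pr_plus + pr_minus, rep(1, 3), tolerance = 1e-10)
})

test_that("fast engine matches the reference propagation", {
  set.seed(66)
  cases <- list(
    itb_params(category_prior = 0.45, lapse = 0.05, temperature = 1.2,
               noise = 0.4, bound = 1.8, leak = 0.15),
    itb_params(category_prior = 0.5, lapse = 0, temperature = 0.4,
               noise = 0.2, bound = 3, leak = -0.2),
    itb_params(category_prior = 0.7, lapse = 0.02, temperature = 2,
               noise = 0, bound = 1.2, leak = 0.3))
  for (p in cases) {
    llo <- matrix(rnorm(40, 0, 0.9), 4, 10)
    a <- itb_choice_probability(llo, p, clip = 18)
    b <- itb_choice_probability(llo, p, clip = 18, engine = "reference")
    expect_equal(a, b, tolerance = 0.005)
  }
})

test_that("discretized choice probabilities match Monte-Carlo simulation", {
  set.seed(67)
  n_mc <- 1e5
  for (i in 1:8) {
    llo <- rnorm(10, 0, runif(1, 0.3, 1.2))
    p <- itb_params(category_prior = runif(1, 0.3, 0.7),
                    lapse = runif(1, 0, 0.1),
                    temperature = runif(1, 0.4, 2),
                    noise = runif(1, 0, 0.5),
                    bound = runif(1, 0.8, 6),
                    leak = runif(1, -0.3, 0.3))
    exact <- itb_choice_probability(llo, p, clip = 25)
    mc <- mean(simulate_itb(matrix(llo, n_mc, 10, byrow = TRUE), p)$choice > 0)
    expect_lt(abs(exact - mc), 0.01)
  }
})

test_that("choice probability is monotone in each pre-bound LLO", {
  p <- itb_params(lapse = 0.02, temperature = 1, noise = 0.25,
                  bound = 4, leak = 0.1)
  base <- rep(0.2, 10)
  pr0 <- itb_choice_probability(base, p, clip = 20)
  for (f in c(1, 5, 10)) {
    up <- base; up[f] <- 0.8
    expect_gt(itb_choice_probability(up, p, clip = 20), pr0)
  }
})

test_that("sign-flip symmetry maps p to 1 - p", {
  set.seed(68)
  llo <- rnorm(10, 0.3, 0.8)
  p <- itb_params(category_prior = 0.65, lapse = 0.07, temperature = 1.1,
                  noise = 0.3, bound = 2.2, leak = 0.05)
  pf <- itb_params(category_prior = 0.35, lapse = 0.07, temperature = 1.1,
                   noise = 0.3, bound = 2.2, leak = 0.05)
  # exact up to the engine's documented kernel-band truncation (~1e-5)
  expect_equal(itb_choice_probability(llo, p, clip = 20),
               1 - itb_choice_probability(-llo, pf, clip = 20),
               tolerance = 1e-4)
})

test_that("the three dynamical regimes produce the annotated slope signs", {
  set.seed(69)
  tp <- task_params(category_info = 0.8,
                    sigma_e = sigma_for_sensory_info(0.75))
  # forgetful integration: recency
  d <- itb_observer(8000, tp, itb_params(leak = 0.3, bound = 50, noise = 0.2))
  expect_gt(slope_of(d), 0.05)
  # self-reinforcing integration: primacy
  d <- itb_observer(8000, tp, itb_params(leak = -0.3, bound = 50, noise = 0.2))
  expect_lt(slope_of(d), -0.05)
  # bounded integration with no leak: primacy
  d <- itb_observer(8000, tp, itb_params(leak = 0, bound = 1.2, noise = 0.2))
  expect_lt(slope_of(d), -0.05)
})

test_that("bin widths above the contract are rejected", {
  p <- itb_params()
  expect_error(itb_choice_probability(rep(0, 10), p, bin_width = 0.02),
               "bin_width")
  expect_error(itb_choice_probability(rep(0, 10), p, clip = Inf), "clip")
})

test_that("signal-to-log-odds mapping has the right limits", {
  a <- seq(-4, 4, by = 0.5)
  expect_equal(signal_to_llo(a, 1, 1), a, tolerance = 1e-12)    # identity at q=1
  expect_equal(signal_to_llo(a, 1, 0.5), rep(0, length(a)),
               tolerance = 1e-12)
  expect_equal(signal_to_llo(0, 1, 0.83), 0, tolerance = 1e-12)
  # equals the exact frame LLO on model evidence
  tp <- task_params(category_info = 0.8, sigma_e = 1.3)
  e <- c(-2, -0.5, 0.4, 1.7)
  expect_equal(signal_to_llo(2 * e / (1 + 1.3^2), 1, 0.8),
               frame_llo(e, tp), tolerance = 1e-10)
})
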