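test_that("an uninformative accuracy target resolves without search", {
  sp <- calibrate_ground_truth(ground_truth_spec("sampling", "LSHC",
                                                 target_accuracy = 0.5))
  expect_equal(sp$resolved$task$category_info, 0.5)
  set.seed(101)
  d <- generate_choice_dataset(sp, 4000, seed = 101)
  expect_lt(abs(accuracy(d) - 0.5), 3 * sqrt(0.25 / 4000))
  # choices carry no signal information, so the slope is not identified as
  # different from zero (its bootstrap interval straddles 0)
  bs <- bootstrap_slope(d, "exponential", n_boot = 60)
  expect_true(bs$ci[1] <= 0 && bs$ci[2] >= 0)
})

test_that("clearly infeasible targets raise an infeasibility report", {
  sp <- ground_truth_spec("sampling", "HSLC", target_beta = 0.9)
  expect_error(calibrate_ground_truth(sp, n_calib = 1500, n_polish = 1500),
               "infeasible|attainable")
  expect_error(
    calibrate_ground_truth(ground_truth_spec("sampling", "LSHC",
                                             target_accuracy = 1.2)),
    "accuracy")
})

test_that("dataset generation is deterministic given the seed", {
  sp <- ground_truth_spec("itb", "LSHC")
  sp$resolved <- list(task = task_params(category_info = 0.9, sigma_e = 1.4),
                      config = itb_params(noise = 0.2, bound = 1.2, leak = 0.1))
  d1 <- generate_choice_dataset(sp, 200, seed = 42)
  d2 <- generate_choice_dataset(sp, 200, seed = 42)
  expect_identical(d1$signals, d2$signals)
  expect_identical(d1$choices, d2$choices)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_choice_dataset(d1, f1); write_choice_dataset(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("an empty dataset round-trips with a valid header", {
  sp <- ground_truth_spec("itb", "LSHC")
  sp$resolved <- list(task = task_params(), config = itb_params())
  d <- generate_choice_dataset(sp, 0, seed = 1)
  expect_equal(nrow(d$signals), 0)
  f <- tempfile(fileext = ".csv")
  write_choice_dataset(d, f)
  expect_match(readLines(f, n = 1), "trial_id,category,choice")
  unlink(f)
})

test_that("choice datasets round-trip through CSV", {
  set.seed(102)
  d <- ideal_observer(50, task_params(category_info = 0.8))
  d$condition <- "LSHC"; d$seed <- 7L
  f <- tempfile(fileext = ".csv")
  write_choice_dataset(d, f)
  d2 <- read_choice_dataset(f)
  expect_equal(d2$signals, d$signals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(d2$choices, d$choices)
  expect_equal(d2$categories, d$categories)
  expect_equal(d2$model, "ideal")
  expect_equal(d2$condition, "LSHC")
  unlink(f)
})

test_that("per-frame trial records serialize in long format", {
  set.seed(103)
  tr <- sample_trials(5, task_params())
  f <- tempfile(fileext = ".csv")
  write_trials(tr, f)
  df <- read.csv(f)
  expect_equal(names(df), c("trial_id", "category", "frame_index", "x", "e"))
  expect_equal(nrow(df), 50)
  expect_equal(df$e[df$trial_id == 3], unname(tr$evidence[3, ]),
               tolerance = 1e-12)
  unlink(f)
})

test_that("task-space sweeps record accuracy and slope per grid point", {
  set.seed(104)
  sw <- taskspace_sweep("ideal", sensory_info = c(0.6, 0.8),
                        category_info = c(0.6, 0.8), n_trials = 800)
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$accuracy > 0.5))
  expect_true(all(is.finite(sw$beta)))
  # accuracy increases toward the information-rich corner
  expect_gt(sw$accuracy[sw$sensory_info == 0.8 & sw$category_info == 0.8],
            sw$accuracy[sw$sensory_info == 0.6 & sw$category_info == 0.6])
})

test_that("the iso-performance contour re-simulates to its level", {
  set.seed(105)
  sw <- taskspace_sweep("ideal",
                        sensory_info = seq(0.55, 0.95, length.out = 5),
                        category_info = seq(0.55, 0.95, length.out = 5),
                        n_trials = 3000, fit_beta = FALSE)
  contour <- iso_contour(sw, level = 0.70)
  expect_gt(nrow(contour), 2)
  idx <- round(seq(1, nrow(contour), length.out = 3))
  for (i in idx) {
    p <- task_params(category_info = contour$category_info[i],
                     sigma_e = sigma_for_sensory_info(contour$sensory_info[i]))
    expect_lt(abs(accuracy(ideal_observer(4000, p)) - 0.70), 0.02)
  }
})
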