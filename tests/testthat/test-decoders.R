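grid <- seq(0.25, 40, 0.1)
series <- function(v) tibble::tibble(time = grid, value = v)

test_that("the aEMG decoder recovers an exact linear torque map", {
  f <- series(pmax(0, sin(grid / 4)))
  tq <- series(2 * f$value + 1)
  m <- fit_aemg(f, tq)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-9)
  expect_equal(m$intercept, 1, tolerance = 1e-9)
  expect_equal(m$lag, 0)
  expect_lt(m$train_rmse, 1e-9)

  expect_error(fit_aemg(series(rep(3, length(grid))), tq), "degenerate")

  # uncorrelated torque: slope statistically indistinguishable from zero
  noise <- series(withr::with_seed(41, rnorm(length(grid))))
  m0 <- fit_aemg(f, noise)
  se <- summary(lm(noise$value ~ f$value))$coefficients[2, 2]
  expect_lt(abs(unname(m0$coefficients)), 3 * se)
})

test_that("unit refinement ranks by single-unit torque R-squared", {
  tq <- series(pmax(0, sin(grid / 4)))
  rates <- withr::with_seed(42, stats::setNames(lapply(1:15, function(i) {
    if (i <= 10) series(tq$value * i + rnorm(length(grid), sd = 0.05))
    else series(rnorm(length(grid)))
  }), 1:15))
  keep <- refine_units(rates, tq)
  expect_length(keep, 10)
  expect_setequal(keep, 1:10)  # the 5 noise units rank in the bottom 5

  # perfect unit ranks first; small sets are retained whole
  three <- rates[1:3]
  three[["2"]] <- tq
  expect_equal(refine_units(three, tq)[1], 2L)
  expect_length(refine_units(rates[1:3], tq), 3)
})

test_that("the ND decoder solves the multi-unit regression exactly", {
  fr1 <- series(pmax(0, sin(grid / 3)))
  fr2 <- series(pmax(0, cos(grid / 5)))
  tq <- series(3 * fr1$value - 1 * fr2$value + 0.5)
  m <- fit_nd(list(`1` = fr1, `2` = fr2), tq)
  expect_equal(unname(m$coefficients), c(3, -1), tolerance = 1e-8)
  expect_equal(m$intercept, 0.5, tolerance = 1e-8)

  single <- fit_nd(list(`1` = fr1), series(2 * fr1$value + 1))
  expect_equal(unname(single$coefficients), 2, tolerance = 1e-9)

  # exact duplicates fall back to ridge; predictions match the single fit
  expect_warning(
    dup <- fit_nd(list(`1` = fr1, `2` = fr1), series(2 * fr1$value + 1)),
    "ridge"
  )
  expect_equal(sum(dup$coefficients), 2, tolerance = 1e-6)
})

test_that("recruitment thresholds are read from EMG amplitude at rate onset", {
  fs <- 2222
  emg <- rep(0.05, 10 * fs)
  rate <- tibble::tibble(time = seq(0.25, 9.75, 0.1), value = 0)
  rate$value[rate$time >= 3] <- 8
  rate$value[rate$time >= 6] <- 12   # second crossing is ignored
  rt <- compute_rt(emg, rate, mvc_rms = 0.25, fs = fs)
  expect_equal(rt, 100 * 0.05 / 0.25)

  silent <- dplyr::mutate(rate, value = 0)
  rt_na <- compute_rt(emg, silent, mvc_rms = 0.25, fs = fs)
  expect_true(is.na(rt_na))
  expect_equal(attr(rt_na, "reason"), "no recruitment detected")
})

test_that("estimated thresholds rank-correlate with the generating ones", {
  b <- small_bundle()
  prep <- mudecode:::prepare_fold(b)
  units <- mudecode:::mudrive_units(prep)
  truth <- b$units$rt_true[match(units$id, b$units$id)]
  expect_gte(cor(units$rt, truth, method = "spearman"), 0.8)
})

test_that("prediction applies the stored lag and linear map deterministically", {
  b <- small_bundle()
  folds <- split_bundle(b)
  m <- fit_decoder(folds[[1]], "aEMG")
  # training-fold predictions reproduce the training fit
  pred_train <- predict(m, folds[[1]])
  ref_train <- preprocess_torque(folds[[1]]$torque, duration = folds[[1]]$duration)
  expect_equal(mudecode:::score_prediction(pred_train, ref_train),
               m$train_rmse, tolerance = 0.05)
  # held-out fold: finite predictions on its grid
  pred_test <- predict(m, folds[[2]])
  expect_true(all(is.finite(pred_test$value)))
  expect_identical(predict(m, folds[[2]]), pred_test)

  # zero EMG maps to the intercept everywhere
  bz <- folds[[2]]
  bz$emg <- rep(0, length(bz$emg))
  pz <- predict(m, bz)
  expect_true(all(abs(pz$value - m$intercept) < 1e-9))

  # a missing retained unit is a contract violation for unit-based models
  mn <- fit_decoder(folds[[1]], "ND")
  bm <- folds[[2]]
  bm$units <- bm$units[-match(mn$unit_ids[1], bm$units$id), ]
  expect_error(predict(mn, bm), "missing retained unit")
})

test_that("model summaries expose terms and fit quality", {
  b <- small_bundle()
  folds <- split_bundle(b)
  m <- fit_decoder(folds[[1]], "ND")
  td <- tidy(m)
  expect_equal(nrow(td), length(m$unit_ids) + 1)
  expect_equal(td$estimate[1], m$intercept)
  gl <- glance(m)
  expect_equal(gl$method, "ND")
  expect_equal(gl$n_units, length(m$unit_ids))
})
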