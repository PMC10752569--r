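# EMG built from a known template and spaced firings, optionally with noise
build_emg <- function(template, firings, fs, duration, noise_sd = 0) {
  n <- floor(duration * fs) + 1L
  emg <- numeric(n)
  off <- -(length(template) %/% 2)
  for (s in firings) {
    i0 <- round(s * fs) + 1L + off
    idx <- i0:(i0 + length(template) - 1L)
    emg[idx] <- emg[idx] + template
  }
  if (noise_sd > 0) emg <- emg + rnorm(n, sd = noise_sd)
  emg
}

fs <- 2222
tmpl <- mudecode:::muap_template(0.015, fs) * 0.1

test_that("the STA recovers the template exactly from clean spaced firings", {
  firings <- seq(1, 19, by = 0.25)
  emg <- build_emg(tmpl, firings, fs, 20)
  sta <- sta_template(emg, firings, fs = fs)
  lw <- length(sta)
  center <- (lw %/% 2) - (length(tmpl) %/% 2) + seq_along(tmpl)
  expect_lt(max(abs(sta[center] - tmpl)), 1e-12)
  expect_lt(max(abs(sta[-center])), 1e-12)
  expect_equal(attr(sta, "n_used"), length(firings))

  # a single firing returns the raw window
  one <- sta_template(emg, firings[5], fs = fs)
  i0 <- round(firings[5] * fs) + 1L - (length(one) %/% 2)
  expect_equal(as.numeric(one), emg[i0:(i0 + length(one) - 1)])

  # firings without full window support are skipped, not zero-padded
  skimmed <- sta_template(emg, c(0.001, firings), fs = fs)
  expect_equal(attr(skimmed, "n_skipped"), 1)
  expect_error(sta_template(emg, 0.0001, fs = fs), "support")
})

test_that("STA noise shrinks like one over the square root of the count", {
  firings <- seq(1, 59, by = 0.2)
  sigma <- 0.05
  emg <- withr::with_seed(3, build_emg(tmpl, firings, fs, 60, noise_sd = sigma))
  sta <- sta_template(emg, firings, fs = fs)
  lw <- length(sta)
  center <- (lw %/% 2) - (length(tmpl) %/% 2) + seq_along(tmpl)
  resid <- sqrt(mean(sta[-center]^2))
  expected <- sigma / sqrt(length(firings))
  expect_lt(resid / expected, 1.5)
  expect_gt(resid / expected, 1 / 1.5)
})

test_that("STA is linear in the EMG for fixed firings", {
  firings <- seq(1, 9, by = 0.3)
  e1 <- withr::with_seed(4, rnorm(10 * fs))
  e2 <- withr::with_seed(5, rnorm(10 * fs))
  s1 <- as.numeric(sta_template(e1, firings, fs = fs))
  s2 <- as.numeric(sta_template(e2, firings, fs = fs))
  s12 <- as.numeric(sta_template(2 * e1 + 3 * e2, firings, fs = fs))
  expect_equal(s12, 2 * s1 + 3 * s2, tolerance = 1e-12)
})

test_that("units matching their template pass; impostors and unstable units fail", {
  firings <- withr::with_seed(6, sort(runif(600, 0.5, 59.5)))
  emg <- withr::with_seed(7, build_emg(tmpl, firings, fs, 60, noise_sd = 0.005))
  good <- validate_mu(emg, firings, tmpl, fs = fs)
  expect_true(good$accepted)
  expect_gt(good$r_squared, 0.6)

  impostor <- withr::with_seed(8, sort(runif(600, 0.5, 59.5)))
  bad <- validate_mu(emg, impostor, tmpl, fs = fs)
  expect_false(bad$accepted)
  expect_lt(bad$r_squared, 0.6)

  # template amplitude quadrupling mid-trial destabilizes the p2p CV
  half <- floor(length(emg) / 2)
  emg_step <- c(emg[1:half], 4 * emg[(half + 1):length(emg)])
  unstable <- validate_mu(emg_step, firings, tmpl, fs = fs)
  expect_gte(unstable$p2p_cv, 0.5)
  expect_false(unstable$accepted)
  # a doubling is already visibly unstable
  emg_double <- c(emg[1:half], 2 * emg[(half + 1):length(emg)])
  expect_gte(validate_mu(emg_double, firings, tmpl, fs = fs)$p2p_cv, 0.3)
})

test_that("acceptance is invariant to a global EMG gain", {
  firings <- withr::with_seed(9, sort(runif(500, 0.5, 39.5)))
  emg <- withr::with_seed(10, build_emg(tmpl, firings, fs, 40, noise_sd = 0.01))
  a <- validate_mu(emg, firings, tmpl, fs = fs)
  b <- validate_mu(emg * 50, firings, tmpl * 50, fs = fs)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-9)
  expect_equal(a$p2p_cv, b$p2p_cv, tolerance = 1e-9)
  expect_equal(a$accepted, b$accepted)
})

test_that("too few usable segments rejects the unit with a reason", {
  firings <- seq(1, 3, by = 0.3)  # only one 8-s segment's worth of data
  emg <- build_emg(tmpl, firings, fs, 4)
  rep <- validate_mu(emg, firings, tmpl, fs = fs)
  expect_false(rep$accepted)
  expect_match(rep$reason, "insufficient segments")
})

test_that("validate_pool screens only the decomposed units of a bundle", {
  b <- small_bundle()
  rep <- validate_pool(b)
  expect_equal(nrow(rep), nrow(b$units))
  expect_gt(mean(rep$accepted), 0.8)
})
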