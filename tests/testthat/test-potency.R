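test_that("Hill and gain-loss curves match closed-form values", {
  hp <- hill_params(100, 1, log10(0.1))
  # half-maximal response at c = AC50, by definition
  expect_equal(hill_response(0.1, hp), 50, tolerance = 1e-9)
  expect_equal(hill_response(1, hp), 100 / 1.1, tolerance = 1e-9)
  # upper plateau approached asymptotically
  expect_equal(hill_response(1e8, hp), 100, tolerance = 1e-6)

  gp <- gainloss_params(100, 1, log10(0.1), log10(10))
  expect_equal(gainloss_response(1, gp), 100 / 1.1 / 1.1, tolerance = 1e-9)
  # an infinitely late loss phase reduces gain-loss to Hill
  gp_inf <- gainloss_params(100, 1, log10(0.1), 50)
  cs <- 10^seq(-4, 2, by = 0.5)
  expect_equal(gainloss_response(cs, gp_inf), hill_response(cs, hp),
               tolerance = 1e-9)
})

test_that("Hill response is monotone and gain-loss unimodal with a midpoint peak", {
  cs <- 10^seq(-6, 4, length.out = 2001)
  expect_true(all(diff(hill_response(cs, hill_params(80, 1.7, -1))) > 0))
  gp <- gainloss_params(100, 1.3, -2, 1)
  y <- gainloss_response(cs, gp)
  peak <- which.max(y)
  expect_true(all(diff(y[seq_len(peak)]) > 0))
  expect_true(all(diff(y[peak:length(y)]) < 0))
  # grid-search oracle: the maximum sits at the log-midpoint of the AC50s
  expect_lt(abs(log10(cs[peak]) - (-2 + 1) / 2), 0.01)
})

test_that("noiseless curves are recovered to high precision", {
  for (th in c(-3, -1, 1)) {
    p <- make_profile(hill_response(conc15, hill_params(100, 1, th)))
    f <- fit_hill(p)
    expect_true(f$converged)
    expect_equal(f$params$log10_ac50, th, tolerance = 1e-6)
    expect_equal(f$params$rmax, 100, tolerance = 1e-4)
    expect_equal(f$params$h, 1, tolerance = 1e-5)
  }
  # constant-zero responses are unidentifiable
  f0 <- fit_hill(make_profile(rep(0, 15)))
  expect_false(f0$converged)
})

test_that("fitting is equivariant to a tenfold concentration shift", {
  set.seed(31)
  y <- hill_response(conc15, hill_params(70, 1.2, -1)) + rnorm(15, 0, 3)
  f1 <- fit_hill(make_profile(y))
  f2 <- fit_hill(make_profile(y, conc = conc15 * 10))
  expect_equal(f2$params$log10_ac50, f1$params$log10_ac50 + 1,
               tolerance = 1e-6)
  expect_equal(f2$se_log10_ac50, f1$se_log10_ac50, tolerance = 1e-6)
})

test_that("fit agrees with an independent Levenberg-Marquardt implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(32)
  x <- log10(conc15)
  for (i in 1:5) {
    y <- hill_response(conc15, hill_params(80, 1.3, -0.5)) + rnorm(15, 0, 4)
    f1 <- fit_hill(make_profile(y))
    f2 <- minpack.lm::nlsLM(y ~ rmax / (1 + 10^(-h * (x - th))),
                            start = list(rmax = 80, h = 1, th = 0))
    expect_equal(f1$params$log10_ac50, unname(coef(f2)[["th"]]),
                 tolerance = 1e-4)
    expect_equal(f1$se_log10_ac50,
                 summary(f2)$coefficients["th", "Std. Error"],
                 tolerance = 1e-3)
  }
})

test_that("standard errors match the replicate spread of the estimator", {
  set.seed(33)
  ests <- numeric(300); ses <- numeric(300)
  for (i in 1:300) {
    y <- hill_response(conc15, hill_params(100, 1, -1)) + rnorm(15, 0, 5)
    f <- fit_hill(make_profile(y))
    ests[i] <- f$params$log10_ac50; ses[i] <- f$se_log10_ac50
  }
  expect_lt(abs(mean(ests) + 1), 0.01)  # near-zero bias with both plateaus
  expect_equal(mean(ses), sd(ests), tolerance = 0.2)
})

test_that("outlier removal excises an injected spike and nothing else", {
  y <- hill_response(conc15, hill_params(100, 1, -2))
  # noiseless curve: nothing to remove
  f <- fit_hill(make_profile(y))
  expect_length(remove_outliers(make_profile(y), f)$responses, 15L)
  # one +50 spike at a mid concentration
  y2 <- y; y2[8] <- y2[8] + 50
  set.seed(34)
  y2 <- y2 + rnorm(15, 0, 2)
  p2 <- make_profile(y2)
  f2 <- fit_hill(p2)
  cleaned <- remove_outliers(p2, f2)
  expect_length(cleaned$responses, 14L)
  expect_false(conc15[8] %in% cleaned$concentrations)
  # uniformly mild residuals are kept
  set.seed(35)
  y3 <- y + rnorm(15, 0, 2)
  p3 <- make_profile(y3)
  expect_length(remove_outliers(p3, fit_hill(p3))$responses, 15L)
})

test_that("aggregation strategies follow their definitions", {
  fake_fit <- function(th, se) {
    structure(list(params = hill_params(100, 1, th), se_log10_ac50 = se,
                   converged = TRUE, n_points_used = 15,
                   residual_ss = 1, fitted = NULL, leverage = NULL),
              class = "curve_fit")
  }
  fits <- list(fake_fit(-1, 1), fake_fit(-3, 0.1))
  w <- aggregate_ac50(fits, method = "weighted")
  expect_equal(w$log10_ac50, (1 * (-1) + 100 * (-3)) / 101,
               tolerance = 1e-9)
  fits3 <- list(fake_fit(-1, 1), fake_fit(-2, 2), fake_fit(-3, 3))
  expect_equal(aggregate_ac50(fits3, method = "median")$log10_ac50, -2)
  expect_equal(aggregate_ac50(fits3, method = "avg")$log10_ac50, -2)
  # equal SEs collapse weighted onto the plain average, exactly
  fits_eq <- list(fake_fit(-1, 0.5), fake_fit(-2.3, 0.5))
  expect_identical(aggregate_ac50(fits_eq, method = "weighted")$log10_ac50,
                   aggregate_ac50(fits_eq, method = "avg")$log10_ac50)
  # a zero SE gets the largest finite weight, not an infinite one
  fits0 <- list(fake_fit(-1, 0), fake_fit(-2, 0.1), fake_fit(-4, 1))
  w0 <- 1 / c(0.1, 1)^2
  expect_equal(aggregate_ac50(fits0, method = "weighted")$log10_ac50,
               sum(c(max(w0), w0) * c(-1, -2, -4)) / sum(c(max(w0), w0)),
               tolerance = 1e-12)
  # non-converged fits are excluded; none converged is an error
  nc <- structure(list(converged = FALSE), class = "curve_fit")
  expect_equal(aggregate_ac50(c(fits3, list(nc)),
                              method = "avg")$n_profiles, 3L)
  expect_error(aggregate_ac50(list(nc), method = "avg"), "no converged")
})

test_that("one_model pools the points of all profiles", {
  set.seed(36)
  profs <- lapply(1:3, function(j) {
    make_profile(hill_response(conc15, hill_params(100, 1, -1)) +
                   rnorm(15, 0, 3), rid = paste0("r", j))
  })
  est <- aggregate_ac50(NULL, profs, method = "one_model")
  expect_equal(est$log10_ac50, -1, tolerance = 0.1)
  expect_equal(est$n_profiles, 3L)
  expect_error(aggregate_ac50(NULL, list(), method = "one_model"))
})

test_that("per-cluster potency is estimated for active clusters only", {
  set.seed(37)
  band <- noise_band(2, 3)
  cd <- make_hill_compound("c1", list(hill_params(90, 1, -2),
                                      hill_params(0.1, 1, 0)),
                           c(3L, 3L), sd = 1)
  study <- assay_study(list(cd), noise_band = band)
  asg <- casanova_study(study)
  pot <- estimate_potency(study, asg, "weighted")
  expect_length(pot, length(asg[["c1"]]$conclusive))
  expect_equal(pot[[1]]$log10_ac50, -2, tolerance = 0.1)
})
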