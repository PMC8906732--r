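test_that("the Gaussian wavelength term matches its closed form", {
  expect_equal(wavelength_reward(700, 700, 150), 1, tolerance = 1e-15)
  expect_equal(wavelength_reward(550, 700, 150), exp(-0.5), tolerance = 1e-12)
  expect_equal(wavelength_reward(400, 700, 150), exp(-2), tolerance = 1e-12)
  # symmetric about the target, strictly decreasing in the detuning
  expect_equal(wavelength_reward(600, 700, 150), wavelength_reward(800, 700, 150))
  d <- wavelength_reward(700 + seq(0, 500, by = 25), 700, 150)
  expect_true(all(diff(d) < 0))
})

test_that("the oscillator-strength term behaves at and around threshold", {
  # at threshold the log difference is ~4.3e-7, so the squared variant ~0
  expect_lt(os_reward(0.01, 0.01, 1e-8, "literal_squared"), 1e-12)
  expect_equal(os_reward(0.1, 0.01, 1e-8, "literal_squared"), tanh(1),
               tolerance = 1e-7)   # epsilon shifts log10(0.1) by ~4e-8
  expect_equal(os_reward(0, 0.01, 1e-8, "signed_monotone"), 0)
  expect_error(os_reward(-0.1, 0.01), class = "fluortree_input_error")
  # signed variant is non-decreasing; both bounded in [0, 1)
  xs <- seq(0, 2, by = 0.01)
  sm <- os_reward(xs, 0.01, 1e-8, "signed_monotone")
  expect_true(all(diff(sm) >= 0))
  for (v in c("literal_squared", "signed_monotone")) {
    r <- os_reward(xs, 0.01, 1e-8, v)
    # bounded by 1 (tanh saturates to 1.0 in double precision far from
    # threshold, so the open bound is only mathematical)
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("the total reward reproduces an independent scalar evaluation", {
  # the coumarin-pyrazolopyrimidine reference profile, evaluated from the
  # component definitions written out long-hand as the oracle
  p <- photophysical_profile(433, 0.192, 580, 0.128)
  eps <- 1e-8
  expected <- 0.4 * exp(-(433 - 700)^2 / (2 * 150^2)) +
    0.1 * tanh((log10(0.192 + eps) - log10(0.01))^2) +
    0.4 * exp(-(580 - 1200)^2 / (2 * 150^2)) +
    0.1 * tanh((log10(0.128 + eps) - log10(0.01))^2)
  expect_equal(total_reward(p, reward_params()), expected, tolerance = 1e-12)
  expect_equal(expected, 0.259, tolerance = 2e-3)
})

test_that("failed evaluations score zero and weights must sum to one", {
  expect_identical(total_reward(photophysical_profile(status = "evaluation_failed")),
                   0)
  expect_error(reward_params(W_aw = 0.5, W_ai = 0.5, W_fw = 0.5, W_fi = 0.5),
               class = "fluortree_config_error")
  expect_error(reward_params(sigma_a = 0), class = "fluortree_config_error")
})

test_that("total reward is bounded in [0, 1] over random profiles", {
  set.seed(99)
  n <- 1e5
  aw <- runif(n, 50, 2000); ai <- runif(n, 0, 3)
  fw <- runif(n, 50, 2000); fi <- runif(n, 0, 3)
  params <- reward_params()
  # vectorized composition of the same components total_reward() uses
  r <- params$W_aw * wavelength_reward(aw, params$T_aw, params$sigma_a) +
    params$W_ai * os_reward(ai, params$T_ai, params$epsilon, params$os_variant) +
    params$W_fw * wavelength_reward(fw, params$T_fw, params$sigma_f) +
    params$W_fi * os_reward(fi, params$T_fi, params$epsilon, params$os_variant)
  expect_true(all(r >= 0 & r <= 1))
  # spot-check the scalar entry point against the vectorized form
  for (i in sample.int(n, 25)) {
    expect_equal(total_reward(photophysical_profile(aw[i], ai[i], fw[i], fi[i]),
                              params),
                 r[i], tolerance = 1e-12)
  }
})

test_that("the reward is symmetric under exchanging the two bands", {
  p1 <- photophysical_profile(500, 0.3, 900, 0.05)
  p2 <- photophysical_profile(900, 0.05, 500, 0.3)
  fwd <- reward_params(T_aw = 700, T_fw = 1200, T_ai = 0.02, T_fi = 0.005,
                       W_aw = 0.4, W_ai = 0.1, W_fw = 0.4, W_fi = 0.1,
                       sigma_a = 150, sigma_f = 120)
  swp <- reward_params(T_aw = 1200, T_fw = 700, T_ai = 0.005, T_fi = 0.02,
                       W_aw = 0.4, W_ai = 0.1, W_fw = 0.4, W_fi = 0.1,
                       sigma_a = 120, sigma_f = 150)
  expect_equal(total_reward(p1, fwd), total_reward(p2, swp), tolerance = 1e-12)
})
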