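test_that("translation-rate draws honour the configured mean and variance", {
  # degenerate law: zero variance returns the mean exactly
  expect_identical(draw_translation_rate(extrinsic_spec(45, 0), n = 5), rep(45, 5))

  spec <- extrinsic_spec(45, 100)
  x <- draw_translation_rate(spec, n = 1e5, seed = 11)
  expect_true(all(x > 0))
  # law of large numbers: 3 x SE bands around the configured moments
  expect_lt(abs(mean(x) - 45), 3 * 10 / sqrt(1e5))
  expect_lt(abs(var(x) - 100), 3 * sqrt(2 / 1e5) * 100 * 2)
  # deterministic given seed
  expect_identical(x, draw_translation_rate(spec, n = 1e5, seed = 11))

  expect_error(extrinsic_spec(45, -1), class = "noisetissue_parameter_error")
})

test_that("the empty state is absorbing when transcription is off", {
  p <- two_stage_params(v0 = 0, d0 = 1, v1 = 10, d1 = 0.1)
  tr <- ssa_two_stage(p,
    t_conversion = NA, t_end = 20,
    initial_state = c(mrna = 0, green = 0, red = 0), seed = 1
  )
  expect_true(all(tr$mrna == 0 & tr$green == 0 & tr$red == 0))
})

test_that("photoconversion transfers the green pool and conserves reporter copies", {
  p <- kikgr_params()
  for (seed in 1:5) {
    tr <- ssa_two_stage(p, t_conversion = 2, t_end = 4, sample_dt = 0.5, seed = seed)
    pre <- attr(tr, "conv_pre")
    post <- attr(tr, "conv_post")
    expect_identical(unname(post[["green"]]), 0)
    expect_identical(unname(post[["red"]]), unname(pre[["red"]] + pre[["green"]]))
    # total reporter count is continuous across the event
    expect_identical(
      unname(pre[["green"]] + pre[["red"]]),
      unname(post[["green"]] + post[["red"]])
    )
    expect_true(all(tr$mrna >= 0 & tr$green >= 0 & tr$red >= 0))
    expect_true(all(tr$mrna == floor(tr$mrna)))
  }
})

test_that("SSA ensemble moments match the closed-form moment solution", {
  p <- kikgr_params()
  n <- 3000
  times <- c(1, 3, 6)
  # fixed v1, growth from the empty state: compare against the matrix-
  # exponential solution of the moment ODEs at every read-out time
  set.seed(202)
  states <- replicate(n, {
    res <- noisetissue:::cpp_ssa_two_stage(p$v0, p$d0, p$v1, p$d1, -1, 0, 0, 0, times)
    res$states[, 1:2]
  })
  mo <- moments_two_stage(p, t = times)
  for (j in seq_along(times)) {
    m <- states[j, 1, ]
    g <- states[j, 2, ]
    expect_lt(abs(mean(m) - mo$mean_mrna[j]), 3 * sd(m) / sqrt(n))
    expect_lt(abs(mean(g) - mo$mean_protein[j]), 3 * sd(g) / sqrt(n))
    expect_lt(
      abs(var(g) - mo$var_protein[j]),
      3 * var(g) * sqrt(2 / (n - 1)) + 1e-9
    )
    expect_lt(abs(var(m) - mo$var_mrna[j]), 3 * var(m) * sqrt(2 / (n - 1)))
  }
})

test_that("stationary moments follow the standard two-stage closed forms", {
  p <- kikgr_params()
  mo <- moments_two_stage(p, t = Inf)
  expect_equal(mo$mean_mrna, 2.25 / 1.125)
  expect_equal(mo$mean_protein, 2 * 45 / 0.09) # 1000 molecules
  expect_equal(mo$var_protein, 1000 * (1 + 45 / (1.125 + 0.09)))
  # empty start at t = 0 has zero moments
  mo0 <- moments_two_stage(p, t = 0)
  expect_true(all(unlist(mo0[, -1]) == 0))
  # the matrix-exponential route needs no special case at d0 == d1
  pd <- two_stage_params(1, 0.5, 3, 0.5)
  mod <- moments_two_stage(pd, t = c(1, Inf))
  expect_true(all(is.finite(unlist(mod[, -1]))))
  expect_equal(mod$mean_protein[2], 1 / 0.5 * 3 / 0.5)
})

test_that("long-run SSA green pool reaches the stationary mean", {
  p <- kikgr_params()
  # the burn-in ends at conversion, so the red pool right after conversion
  # holds the stationary green count
  set.seed(7)
  r <- noisetissue:::cpp_kik_ensemble(
    rep(45, 2000), p$v0, p$d0, p$d1, 10 / p$d1, 0
  )$red[, 1]
  expect_lt(abs(mean(r) - 1000), 3 * sd(r) / sqrt(2000))
})

test_that("birth-death autocorrelation closed form and limits", {
  expect_identical(autocorr_birth_death(0.09, 3, 3), 1)
  expect_equal(autocorr_birth_death(0, 3, 6), sqrt(0.5))
  expect_equal(autocorr_birth_death(0.09, 3, 6),
    exp(-0.27) * sqrt((1 - exp(-0.27)) / (1 - exp(-0.54))),
    tolerance = 1e-12
  )
  expect_equal(round(autocorr_birth_death(0.09, 3, 6), 3), 0.575)
  expect_error(autocorr_birth_death(0.09, 6, 3), class = "noisetissue_argument_error")
  expect_error(autocorr_birth_death(0.09, 0, 3), class = "noisetissue_argument_error")
  expect_error(autocorr_birth_death(-1, 3, 6), class = "noisetissue_argument_error")
})

test_that("closed-form birth-death correlation matches an exact joint sampler", {
  # independent oracle: Poisson occupancy + binomial thinning, no SSA
  set.seed(31)
  s <- birth_death_pair_sample(1e5, birth = 90, death = 0.09, t1 = 3, t2 = 6)
  r_mc <- cor(s[, 1], s[, 2])
  expect_lt(
    abs(r_mc - autocorr_birth_death(0.09, 3, 6)),
    3 * (1 - r_mc^2) / sqrt(1e5)
  )
})

test_that("extrinsic noise raises the two-stage autocorrelation above the bound", {
  p <- kikgr_params()
  r0 <- autocorr_two_stage_mc(p, extrinsic_spec(45, 0), 3, 6,
    n_traj = 5000, seed = 5
  )
  r100 <- autocorr_two_stage_mc(p, extrinsic_spec(45, 100), 3, 6,
    n_traj = 5000, seed = 6
  )
  c0 <- autocorr_birth_death(p$d1, 3, 6)
  expect_gt(r0$r, c0 - 3 * r0$mc_se)
  expect_gt(r100$r, r0$r)
  expect_error(
    autocorr_two_stage_mc(p, extrinsic_spec(45, 0), 3, 6, n_traj = 10),
    class = "noisetissue_argument_error"
  )
  expect_error(
    autocorr_two_stage_mc(
      two_stage_params(0, 1, 1, 0.1), extrinsic_spec(0, 0), 3, 6,
      n_traj = 500, seed = 1
    ),
    class = "noisetissue_estimation_error"
  )
})

test_that("decay-rate estimation is exact on noise-free exponential input", {
  for (i in 1:20) {
    set.seed(i)
    rate <- runif(1, 0.01, 2)
    dt <- runif(1, 0.5, 10)
    r1 <- runif(50, 10, 200)
    r2 <- r1 * exp(-rate * dt)
    est <- estimate_decay_rate(r1, r2, dt)
    expect_equal(est$rate, rate, tolerance = 1e-12)
  }
  expect_equal(estimate_decay_rate(100, 76.338, 3)$rate, 0.09, tolerance = 1e-4)
  expect_equal(estimate_decay_rate(c(5, 9), c(5, 9), 3)$rate, 0)
})

test_that("decay-rate estimation excludes non-positive intensities", {
  expect_message(
    est <- estimate_decay_rate(c(100, -2, 80), c(76, 50, 0), 3),
    "excluded 2"
  )
  expect_identical(est$n_used, 1L)
  expect_identical(est$n_excluded, 2L)
  expect_error(
    suppressMessages(estimate_decay_rate(c(-1, 0), c(1, 2), 3)),
    class = "noisetissue_estimation_error"
  )
  expect_error(estimate_decay_rate(1:3, 1:2, 3), class = "noisetissue_argument_error")
})
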