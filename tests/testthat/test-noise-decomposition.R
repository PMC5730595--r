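test_that("hand-computed dual-reporter moments are reproduced", {
  # repeated (0.8, 1.2) / (1.2, 0.8) pattern keeps both means at 1
  c_vals <- rep(c(0.8, 1.2), 3)
  y_vals <- rep(c(1.2, 0.8), 3)
  res <- decompose_noise(c_vals, y_vals, scale = 1)
  expect_equal(res$eta2_int, 0.08, tolerance = 1e-12)
  expect_equal(res$eta2_ext, -0.04, tolerance = 1e-12)
  expect_equal(res$eta2_tot, 0.04, tolerance = 1e-12)

  # identical channels: purely extrinsic
  x <- c(0.6, 1.4, 1.0, 0.8, 1.2)
  res2 <- decompose_noise(x, x, scale = 1)
  expect_equal(res2$eta2_int, 0)
  expect_equal(res2$eta2_tot, res2$eta2_ext)
  expect_error(decompose_noise(1:5, 1:4), class = "noisetissue_argument_error")
})

test_that("decomposition matches a brute-force loop and is additive and symmetric", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:50, 1)
    c_vals <- rlnorm(n, 0, 0.4)
    y_vals <- rlnorm(n, 0, 0.4)
    res <- decompose_noise(c_vals, y_vals, scale = 1)
    oracle <- brute_noise(c_vals, y_vals)
    expect_equal(res$eta2_int, oracle$int, tolerance = 1e-12)
    expect_equal(res$eta2_ext, oracle$ext, tolerance = 1e-12)
    # additivity identity
    expect_lt(abs(res$eta2_tot - (res$eta2_int + res$eta2_ext)), 1e-9)
    # channel-swap symmetry
    swapped <- decompose_noise(y_vals, c_vals, scale = 1)
    expect_equal(res, swapped)
  }
})

test_that("generator tissues are recovered near their analytic noise targets", {
  gen <- generate_tissue(tissue_gen_config(n_cells = 2000, coupling = 0, seed = 301))
  norm <- suppressMessages(normalize_table(gen$table))
  res <- aggregate_noise(norm)
  expect_lt(
    abs(res$eta2_ext - attr(gen$truth, "eta2_ext_target")),
    0.15 * attr(gen$truth, "eta2_ext_target")
  )
  expect_lt(
    abs(res$eta2_int - attr(gen$truth, "eta2_int_target")),
    0.15 * attr(gen$truth, "eta2_int_target")
  )
})

test_that("intrinsic noise vanishes for a purely extrinsic generator", {
  gen <- generate_tissue(tissue_gen_config(
    n_cells = 5000, intrinsic_sd = 0,
    measurement_noise_sd = 0, coupling = 0, seed = 302
  ))
  norm <- suppressMessages(normalize_table(gen$table))
  res <- aggregate_noise(norm)
  # bootstrap SE of the intrinsic estimate under resampled cells
  wide <- noisetissue:::dual_channel_wide(norm, c("CFP", "YFP"))
  set.seed(1)
  boot <- replicate(200, {
    s <- sample.int(nrow(wide), replace = TRUE)
    decompose_noise(wide$c_value[s], wide$y_value[s])$eta2_int
  })
  expect_lt(abs(res$eta2_int), 3 * sd(boot) + 1e-9)
})

test_that("per-image aggregation respects the KS filter and image structure", {
  tabs <- purrr::map(1:4, function(i) {
    gen <- generate_tissue(tissue_gen_config(n_cells = 120, coupling = 0, seed = 400 + i),
      image_id = paste0("img", i)
    )
    tibble::as_tibble(gen$table)
  })
  combined <- nucleus_table(dplyr::bind_rows(tabs))
  norm <- suppressMessages(normalize_table(combined))
  res <- aggregate_noise(norm)
  expect_identical(nrow(res), 4L)
  expect_setequal(res$image_id, paste0("img", 1:4))

  # shuffling image order leaves group medians unchanged
  norm_shuffled <- nucleus_table(
    tibble::as_tibble(norm)[sample.int(nrow(norm)), ],
    state = "mean_normalized"
  )
  res2 <- aggregate_noise(norm_shuffled)
  s1 <- summarise_noise_groups(res)
  s2 <- summarise_noise_groups(res2)
  expect_equal(
    dplyr::arrange(s1, component),
    dplyr::arrange(s2, component),
    tolerance = 1e-12
  )

  # a channel-skewed image is excluded by the KS filter
  skew <- tibble::as_tibble(tabs[[1]])
  skew$image_id <- "img_skew"
  yfp <- skew$channel == "YFP"
  skew$mean_grey[yfp] <- pmin(
    skew$background_mean_grey[yfp] +
      (skew$mean_grey[yfp] - skew$background_mean_grey[yfp]) * 3,
    254
  )
  with_skew <- nucleus_table(dplyr::bind_rows(tabs[[2]], skew))
  norm3 <- suppressMessages(normalize_table(with_skew))
  expect_message(res3 <- aggregate_noise(norm3), "KS")
  expect_false("img_skew" %in% res3$image_id)
})

test_that("the rank-sum comparison is exact for small untied groups", {
  # completely separated groups of 10: the most extreme configuration
  res <- compare_groups(1:10, 11:20)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # all-tied groups carry no evidence
  expect_equal(compare_groups(rep(1, 5), rep(1, 6))$p_value, 1)
  # large/tied samples fall back to the tie-corrected normal approximation
  big <- compare_groups(rep(1:20, 2), rep(1:20, 2) + 0.5)
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("the rank-sum test detects a 3-SD shift between groups of 10", {
  set.seed(55)
  hits <- mean(replicate(200, {
    compare_groups(rnorm(10), rnorm(10) + 3)$p_value < 0.05
  }))
  expect_gt(hits, 0.95)
})

test_that("area quartiles use the tie-to-lower rule and flag sparse bins", {
  tab <- make_dual_table(runif(24, 30, 60), runif(24, 30, 60),
    area = rep(50, 24)
  )
  norm <- suppressMessages(normalize_table(tab))
  res <- area_quartile_noise(norm)
  expect_identical(res$n_cells, c(24L, 0L, 0L, 0L))
  expect_true(all(is.na(res$eta2_int[2:4])))
  expect_false(is.na(res$eta2_int[1]))
})

test_that("quartile noise is flat without an area effect and rises with one", {
  gen_flat <- generate_tissue(tissue_gen_config(
    n_cells = 2000, coupling = 0,
    area_noise_slope = 0, seed = 77
  ))
  norm_flat <- suppressMessages(normalize_table(gen_flat$table))
  flat <- area_quartile_noise(norm_flat)
  expect_lt(max(flat$eta2_int) / min(flat$eta2_int), 1.8)

  gen_up <- generate_tissue(tissue_gen_config(
    n_cells = 2000, coupling = 0,
    area_noise_slope = 1.5, seed = 78
  ))
  norm_up <- suppressMessages(normalize_table(gen_up$table))
  up <- area_quartile_noise(norm_up)
  expect_true(all(diff(up$eta2_ext) > 0))
})
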