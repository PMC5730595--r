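test_that("nearest neighbours are found with deterministic tie order", {
  pos <- tibble::tibble(x_um = c(0, 1, 3), y_um = c(0, 0, 0))
  nn <- k_nearest_neighbours(pos, 1)
  expect_identical(nn$neighbour, c(2L, 1L, 2L))
  expect_equal(nn$distance, c(1, 1, 2))

  # k = n - 1 returns every other cell sorted by distance
  all_nn <- k_nearest_neighbours(pos, 2)
  expect_identical(all_nn$neighbour[all_nn$cell == 3], c(2L, 1L))
  expect_error(k_nearest_neighbours(pos, 3), class = "noisetissue_argument_error")

  # ties are broken by cell index
  sq <- tibble::tibble(x_um = c(0, 1, -1, 0, 0), y_um = c(0, 0, 0, 1, -1))
  nn_sq <- k_nearest_neighbours(sq, 4)
  expect_identical(nn_sq$neighbour[nn_sq$cell == 1], c(2L, 3L, 4L, 5L))
})

test_that("k nearest neighbours agree with an all-pairs oracle", {
  set.seed(10)
  x <- runif(100, 0, 200)
  y <- runif(100, 0, 200)
  nn <- k_nearest_neighbours(tibble::tibble(x_um = x, y_um = y), 7)
  oracle <- brute_knn(x, y, 7)
  for (i in c(1, 17, 50, 100)) {
    expect_identical(nn$neighbour[nn$cell == i], oracle[[i]]$idx)
    expect_equal(nn$distance[nn$cell == i], oracle[[i]]$dist)
  }
})

test_that("stochastically identical adjacent cells give coupling 1", {
  # pairs of coincident-extrinsic cells with no intrinsic noise: the
  # cross-cell covariance must equal the extrinsic variance exactly
  set.seed(3)
  n_pairs <- 60
  E <- rlnorm(n_pairs, 0, 0.5)
  x <- rep(seq_len(n_pairs) * 30, each = 2) + rep(c(0, 1), n_pairs)
  vals <- 20 + 100 * rep(E, each = 2) / max(E)
  tab <- make_dual_table(vals, vals, x = x, y = rep(0, 2 * n_pairs))
  norm <- suppressMessages(normalize_table(tab))
  r <- neighbour_correlation(norm, spatial_config(k_neighbours = 1))
  expect_equal(r, 1, tolerance = 1e-10)
})

test_that("uncoupled tissues show no neighbour correlation", {
  gen <- generate_tissue(tissue_gen_config(n_cells = 1000, coupling = 0, seed = 91))
  norm <- suppressMessages(normalize_table(gen$table))
  r <- neighbour_correlation(norm, spatial_config())
  expect_lt(abs(r), 0.15) # 3 x the n = 1000 null sd of the estimator
  rt <- randomization_test(norm, spatial_config(n_permutations = 200, seed = 1))
  expect_gt(rt$p_value, 0.05)
})

test_that("coupling estimates are invariant to row relabelling and channel swap", {
  gen <- generate_tissue(tissue_gen_config(n_cells = 400, coupling = 0.5, seed = 92))
  norm <- suppressMessages(normalize_table(gen$table))
  cfg <- spatial_config(n_permutations = 100)
  r1 <- neighbour_correlation(norm, cfg)

  set.seed(5)
  shuffled <- nucleus_table(
    tibble::as_tibble(norm)[sample.int(nrow(norm)), ],
    state = "mean_normalized"
  )
  expect_equal(neighbour_correlation(shuffled, cfg), r1, tolerance = 1e-12)
  expect_equal(
    neighbour_correlation(norm, cfg, channels = c("YFP", "CFP")), r1,
    tolerance = 1e-12
  )
})

test_that("coupled generator tissue is recovered near its analytic target", {
  cfg_gen <- tissue_gen_config(
    n_cells = 1500, coupling = 0.6,
    correlation_length_um = 25, seed = 93
  )
  gen <- generate_tissue(cfg_gen)
  target <- attr(gen$truth, "nn_coupling_target")
  norm <- suppressMessages(normalize_table(gen$table))
  sc <- spatial_coupling(norm, spatial_config(n_permutations = 500, seed = 2))
  g <- glance(sc)
  expect_lt(abs(g$r - target), 0.17) # ~3 x the single-tissue sampling sd
  expect_lt(g$p_value, 0.05)
})

test_that("tier assignment uses rings of one mean nearest-neighbour distance", {
  # 40 cells on a line, spacing 10: ring width is exactly 10, so the
  # neighbours at 10, 20 and 30 um land in tiers 1, 2 and 3
  n <- 40
  tab <- make_dual_table(runif(n, 40, 80), runif(n, 40, 80),
    x = seq_len(n) * 10, y = rep(0, n)
  )
  norm <- suppressMessages(normalize_table(tab))
  tiers <- tier_correlation(norm, spatial_config(k_neighbours = 6, n_tiers = 5))
  expect_equal(tiers$dist_lo, (0:4) * 10)
  # interior cells contribute 2 neighbours per ring
  expect_identical(tiers$tier, 1:5)
  expect_true(all(tiers$n_pairs[1:3] > 0))
})

test_that("tier means decay for distance-decaying coupling and vanish without it", {
  gen <- generate_tissue(tissue_gen_config(
    n_cells = 1500, coupling = 0.7,
    correlation_length_um = 30, seed = 94
  ))
  norm <- suppressMessages(normalize_table(gen$table))
  tiers <- tier_correlation(norm, spatial_config())
  expect_gt(tiers$tier_mean[1], tiers$tier_mean[3])
  expect_gt(tiers$tier_mean[3], tiers$tier_mean[5])

  gen0 <- generate_tissue(tissue_gen_config(n_cells = 1000, coupling = 0, seed = 95))
  norm0 <- suppressMessages(normalize_table(gen0$table))
  tiers0 <- tier_correlation(norm0, spatial_config())
  se0 <- tiers0$tier_sd / sqrt(tiers0$n_pairs)
  expect_true(all(abs(tiers0$tier_mean) < 3 * se0 + 0.05))
})

test_that("tier 1 agrees with the nearest-neighbour estimator", {
  gen <- generate_tissue(tissue_gen_config(
    n_cells = 1500, coupling = 0.6,
    correlation_length_um = 25, seed = 96
  ))
  norm <- suppressMessages(normalize_table(gen$table))
  r_nn <- neighbour_correlation(norm, spatial_config())
  tiers <- tier_correlation(norm, spatial_config())
  se1 <- tiers$tier_sd[1] / sqrt(tiers$n_pairs[1])
  expect_lt(abs(tiers$tier_mean[1] - r_nn), 3 * se1 + 0.05)
})

test_that("spatial result objects expose tidy, glance and plots", {
  gen <- generate_tissue(tissue_gen_config(n_cells = 300, coupling = 0.4, seed = 97))
  norm <- suppressMessages(normalize_table(gen$table))
  sc <- spatial_coupling(norm, spatial_config(n_permutations = 100, seed = 1))
  g <- glance(sc)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("r", "p_value", "n_cells", "mean_nn_distance_um") %in% names(g)))
  td <- tidy(sc)
  expect_identical(nrow(td), 5L)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(plot_tier_profile(sc), "ggplot")
  expect_output(print(sc), "spatial_coupling")
})
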