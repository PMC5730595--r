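#' Configuration of the spatial coupling analysis
#'
#' @param k_neighbours Number of nearest neighbours analysed per cell
#'   (default 39).
#' @param n_tiers Number of concentric distance rings, each one mean
#'   nearest-neighbour distance wide (default 5).
#' @param n_permutations Randomization-test permutations (default 5000,
#'   giving a p-value floor of about 2e-4 with add-one smoothing).
#' @param n_bootstrap Bootstrap resamples for the CI of the coupling
#'   estimate.
#' @param seed Optional integer seed for permutations and bootstrap.
#' @return A `spatial_config` object.
#' @export
spatial_config <- function(k_neighbours = 39, n_tiers = 5,
                           n_permutations = 5000, n_bootstrap = 200,
                           seed = NULL) {
  if (k_neighbours < 1 || n_tiers < 1 || n_permutations < 100) {
    abort("need k_neighbours >= 1, n_tiers >= 1, n_permutations >= 100",
      class = "noisetissue_parameter_error"
    )
  }
  structure(
    list(
      k_neighbours = as.integer(k_neighbours), n_tiers = as.integer(n_tiers),
      n_permutations = as.integer(n_permutations),
      n_bootstrap = as.integer(n_bootstrap), seed = seed
    ),
    class = "spatial_config"
  )
}

#' k nearest neighbours by Euclidean distance
#'
#' Brute-force all-pairs nearest neighbours of 2D nucleus positions.
#' Neighbours are sorted by ascending distance with deterministic
#' tie-breaking by cell index.
#'
#' @param positions Data frame with numeric columns `x_um`, `y_um` (or
#'   `x`, `y`); one row per cell.
#' @param k Number of neighbours (`k < n`).
#' @return A tibble `cell`, `neighbour`, `rank`, `distance` with `n * k`
#'   rows (`cell` and `neighbour` are row indices of `positions`).
#' @export
k_nearest_neighbours <- function(positions, k) {
  xy <- normalize_xy(positions)
  n <- nrow(xy)
  if (k >= n) {
    abort("k must be smaller than the number of cells",
      class = "noisetissue_argument_error"
    )
  }
  d <- as.matrix(stats::dist(xy))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    o <- order(di, seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- di[o]
  }
  tibble::tibble(
    cell = rep(seq_len(n), each = k),
    neighbour = as.integer(t(idx)),
    rank = rep(seq_len(k), times = n),
    distance = as.numeric(t(dst))
  )
}

normalize_xy <- function(positions) {
  nm <- names(positions)
  if (all(c("x_um", "y_um") %in% nm)) {
    cbind(positions$x_um, positions$y_um)
  } else if (all(c("x", "y") %in% nm)) {
    cbind(positions$x, positions$y)
  } else {
    abort("positions need columns x_um/y_um (or x/y)",
      class = "noisetissue_schema_error"
    )
  }
}

# Covariance-normalized nearest-neighbour statistic on centred channels.
# Covariances use the 1/n convention in numerator and denominator so the
# normalization cancels.
nn_stat <- function(dc, dy, nn, den) {
  mean(0.5 * (dc * dy[nn] + dy * dc[nn])) / den
}

# Shared preparation: wide table, nn structure, centred channels.
spatial_prep <- function(table, config, channels) {
  wide <- dual_channel_wide(table, channels)
  n <- nrow(wide)
  if (n < 20) {
    abort("need at least 20 cells", class = "noisetissue_argument_error")
  }
  knn <- k_nearest_neighbours(wide, config$k_neighbours)
  dc <- wide$c_value - mean(wide$c_value)
  dy <- wide$y_value - mean(wide$y_value)
  den <- mean(dc * dy) # within-cell cross-channel covariance = extrinsic variance
  if (den <= 0) {
    abort("within-cell cross-channel covariance is not positive; estimator undefined",
      class = "noisetissue_estimation_error"
    )
  }
  nn1 <- knn$neighbour[knn$rank == 1]
  list(
    wide = wide, knn = knn, dc = dc, dy = dy, den = den, nn1 = nn1,
    mean_nn_distance = mean(knn$distance[knn$rank == 1])
  )
}

#' Nearest-neighbour coupling of extrinsic noise
#'
#' Cross-reporter, cross-cell correlation: the covariance between channel 1
#' of a cell and channel 2 of its nearest neighbour (both orderings pooled)
#' measures how strongly the cell-global, extrinsic fluctuations of
#' neighbouring cells co-vary, while intrinsic noise cancels because the
#' two reporters fluctuate independently. Since the covariance between
#' stochastically identical cells equals the extrinsic-noise variance, the
#' cross-cell covariance is normalized by the within-cell cross-channel
#' covariance, giving a measure in `[-1, 1]` (up to small-sample noise).
#'
#' @param table A mean-normalized dual-channel [nucleus_table()] with
#'   positions (one image).
#' @param config A [spatial_config()].
#' @param channels The two reporter channel names.
#' @return The coupling correlation `r` (scalar).
#' @export
neighbour_correlation <- function(table, config = spatial_config(),
                                  channels = c("CFP", "YFP")) {
  pr <- spatial_prep(table, config, channels)
  nn_stat(pr$dc, pr$dy, pr$nn1, pr$den)
}

#' Randomization test for neighbour coupling
#'
#' The (C, Y) intensity pairs are jointly reassigned to cell positions
#' `n_permutations` times; the one-sided p-value for positive coupling is
#' `(1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)` (add-one smoothing).
#'
#' @inheritParams neighbour_correlation
#' @return A one-row tibble: `r_obs`, `p_value`, `n_permutations`.
#' @export
randomization_test <- function(table, config = spatial_config(),
                               channels = c("CFP", "YFP")) {
  pr <- spatial_prep(table, config, channels)
  r_obs <- nn_stat(pr$dc, pr$dy, pr$nn1, pr$den)
  n <- length(pr$dc)
  B <- config$n_permutations
  r_perm <- with_seed_if(config$seed, {
    vapply(seq_len(B), function(b) {
      s <- sample.int(n)
      nn_stat(pr$dc[s], pr$dy[s], pr$nn1, pr$den)
    }, numeric(1))
  })
  tibble::tibble(
    r_obs = r_obs,
    p_value = (1 + sum(r_perm >= r_obs)) / (1 + B),
    n_permutations = B
  )
}

#' Distance-tier profile of neighbour coupling
#'
#' Each of a cell's `k_neighbours` nearest neighbours is assigned to a
#' concentric ring (tier) of width one mean nearest-neighbour distance (a
#' proxy for one cell diameter): tier `ceiling(distance / width)`, capped
#' at `n_tiers`. Within a tier the covariance-normalized cross-channel
#' product is evaluated for every (cell, neighbour) pair (both channel
#' orderings averaged) and summarized by mean and SD.
#'
#' @inheritParams neighbour_correlation
#' @return A tibble with one row per tier: `tier`, `n_pairs`, `tier_mean`,
#'   `tier_sd` (NA for empty tiers), `dist_lo`, `dist_hi`.
#' @export
tier_correlation <- function(table, config = spatial_config(),
                             channels = c("CFP", "YFP")) {
  pr <- spatial_prep(table, config, channels)
  width <- pr$mean_nn_distance
  knn <- pr$knn
  tier <- pmin(ceiling(knn$distance / width), config$n_tiers)
  tier[knn$distance == 0] <- 1L # coincident nuclei sit in the first ring
  z <- 0.5 * (pr$dc[knn$cell] * pr$dy[knn$neighbour] +
    pr$dy[knn$cell] * pr$dc[knn$neighbour]) / pr$den
  purrr::map_dfr(seq_len(config$n_tiers), function(tr) {
    zi <- z[tier == tr]
    tibble::tibble(
      tier = tr, n_pairs = length(zi),
      tier_mean = if (length(zi)) mean(zi) else NA_real_,
      tier_sd = if (length(zi) > 1) sd(zi) else NA_real_,
      dist_lo = (tr - 1) * width,
      dist_hi = if (tr == config$n_tiers) max(knn$distance) else tr * width
    )
  })
}

#' Full spatial coupling analysis of one image
#'
#' Runs the nearest-neighbour coupling estimate, its randomization test,
#' a pairs bootstrap CI, and the distance-tier profile.
#'
#' @inheritParams neighbour_correlation
#' @return An object of class `spatial_coupling`; see [tidy()] (tier
#'   profile), [glance()] (headline numbers) and [autoplot()] methods.
#' @export
spatial_coupling <- function(table, config = spatial_config(),
                             channels = c("CFP", "YFP")) {
  pr <- spatial_prep(table, config, channels)
  r_obs <- nn_stat(pr$dc, pr$dy, pr$nn1, pr$den)
  rt <- randomization_test(table, config, channels)
  tiers <- tier_correlation(table, config, channels)
  n <- length(pr$dc)
  boot <- with_seed_if(
    if (is.null(config$seed)) NULL else derive_seed(config$seed, 1),
    vapply(seq_len(config$n_bootstrap), function(b) {
      s <- sample.int(n, replace = TRUE)
      dcb <- pr$wide$c_value[s] - mean(pr$wide$c_value[s])
      dyb <- pr$wide$y_value[s] - mean(pr$wide$y_value[s])
      denb <- mean(dcb * dyb)
      if (denb <= 0) {
        return(NA_real_)
      }
      # neighbour values travel with the resampled cell (pairs bootstrap)
      mean(0.5 * (dcb * pr$dy[pr$nn1][s] + dyb * pr$dc[pr$nn1][s])) / denb
    }, numeric(1))
  )
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(
      r = r_obs, p = rt$p_value, n_cells = n,
      mean_nn_distance = pr$mean_nn_distance,
      boot_ci = c(lower = ci[1], upper = ci[2]),
      tier_profile = tiers, config = config, channels = channels,
      scatter = tibble::tibble(
        value = c(pr$wide$c_value, pr$wide$y_value),
        neighbour_value = c(pr$wide$y_value[pr$nn1], pr$wide$c_value[pr$nn1]),
        ordering = rep(c("C vs nn Y", "Y vs nn C"), each = n)
      )
    ),
    class = "spatial_coupling"
  )
}

#' @export
print.spatial_coupling <- function(x, ...) {
  cat(sprintf(
    "<spatial_coupling> n = %d cells; r = %.3f (95%% boot CI %.3f..%.3f); p = %.4g (%d permutations)\n",
    x$n_cells, x$r, x$boot_ci[1], x$boot_ci[2], x$p, x$config$n_permutations
  ))
  invisible(x)
}

#' @describeIn spatial_coupling Tier profile as a tibble.
#' @param x A `spatial_coupling` object.
#' @param ... Unused.
#' @export
tidy.spatial_coupling <- function(x, ...) {
  x$tier_profile
}

#' @describeIn spatial_coupling One-row summary tibble.
#' @export
glance.spatial_coupling <- function(x, ...) {
  tibble::tibble(
    r = x$r, p_value = x$p, n_cells = x$n_cells,
    mean_nn_distance_um = x$mean_nn_distance,
    ci_lower = x$boot_ci[["lower"]], ci_upper = x$boot_ci[["upper"]],
    n_permutations = x$config$n_permutations
  )
}

#' @describeIn spatial_coupling Nearest-neighbour scatter (both channel
#'   orderings) with the coupling estimate in the title.
#' @param object A `spatial_coupling` object.
#' @export
autoplot.spatial_coupling <- function(object, ...) {
  ggplot2::ggplot(
    object$scatter,
    ggplot2::aes(x = .data$value, y = .data$neighbour_value, colour = .data$ordering)
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = "normalized intensity (cell)",
      y = "normalized intensity (nearest neighbour)",
      title = sprintf(
        "Neighbour coupling: r = %.3f, p = %.4g (n = %d)",
        object$r, object$p, object$n_cells
      )
    ) +
    ggplot2::theme_minimal()
}

#' Tier-profile plot of coupling vs distance
#'
#' @param result A `spatial_coupling` object.
#' @return A ggplot: per-tier mean coupling with SD error bars, distance in
#'   cell diameters.
#' @export
plot_tier_profile <- function(result) {
  stopifnot(inherits(result, "spatial_coupling"))
  df <- result$tier_profile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$tier_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$tier_mean - .data$tier_sd,
        ymax = .data$tier_mean + .data$tier_sd
      ),
      width = 0.2
    ) +
    ggplot2::labs(
      x = "distance tier (cell diameters)",
      y = "covariance-normalized coupling"
    ) +
    ggplot2::theme_minimal()
}
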