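#' Dual-reporter decomposition of expression noise
#'
#' Two spectrally distinct reporters driven by identical promoters in the
#' same cell fluctuate together under cell-global (extrinsic) influences and
#' independently under gene-copy-local (intrinsic) influences. On
#' mean-normalized paired values `c` and `y` the squared-coefficient
#' decomposition is
#' \deqn{\eta^2_{int} = \frac{\langle (c-y)^2 \rangle}{2\langle c\rangle\langle y\rangle},\qquad
#'       \eta^2_{ext} = \frac{\langle c y\rangle - \langle c\rangle\langle y\rangle}{\langle c\rangle\langle y\rangle},\qquad
#'       \eta^2_{tot} = \eta^2_{int} + \eta^2_{ext}.}
#' Values are reported on a x100 scale (percent-squared-CV), matching the
#' convention in which tissue medians fall in the 10--55 range. The
#' extrinsic estimate may be slightly negative at small n; it is reported
#' as computed, not clipped, because clipping would bias group medians.
#'
#' @param c,y Paired mean-normalized channel values (means ~ 1),
#'   length >= 5.
#' @param scale Reporting scale factor (default 100).
#' @return A one-row tibble: `n_cells`, `eta2_int`, `eta2_ext`, `eta2_tot`.
#' @examples
#' decompose_noise(c(0.8, 1.2, 1.0, 0.9, 1.1), c(1.2, 0.8, 1.0, 1.1, 0.9))
#' @export
decompose_noise <- function(c, y, scale = 100) {
  if (length(c) != length(y)) {
    abort("c and y must have the same length", class = "noisetissue_argument_error")
  }
  if (length(c) < 5) {
    abort("need at least 5 cells", class = "noisetissue_argument_error")
  }
  mc <- mean(c)
  my <- mean(y)
  eta2_int <- scale * mean((c - y)^2) / (2 * mc * my)
  eta2_ext <- scale * (mean(c * y) - mc * my) / (mc * my)
  eta2_tot <- eta2_int + eta2_ext
  tibble::tibble(
    n_cells = length(c),
    eta2_int = eta2_int, eta2_ext = eta2_ext, eta2_tot = eta2_tot
  )
}

#' Per-image noise decomposition of a dual-reporter table
#'
#' Applies [decompose_noise()] to every image of a normalized dual-reporter
#' nucleus table. Images failing the [ks_skew_filter()] are dropped (with a
#' message) unless `ks_alpha = 0`.
#'
#' @param table A mean-normalized [nucleus_table()].
#' @param channels Length-2 character vector naming the two reporter
#'   channels.
#' @param ks_alpha Significance level of the channel-skew KS filter
#'   (0 disables it).
#' @param scale Reporting scale (see [decompose_noise()]).
#' @return A tibble with one row per retained image: `image_id`, `tissue`,
#'   `n_cells`, `eta2_int`, `eta2_ext`, `eta2_tot`.
#' @export
aggregate_noise <- function(table, channels = c("CFP", "YFP"),
                            ks_alpha = 0.05, scale = 100) {
  wide <- dual_channel_wide(table, channels)
  imgs <- split(wide, wide$image_id)
  if (length(imgs) == 0) {
    abort("no images to aggregate", class = "noisetissue_aggregation_error")
  }
  res <- purrr::map_dfr(imgs, function(df) {
    keep <- ks_alpha == 0 ||
      ks_skew_filter(df$c_value, df$y_value, alpha = ks_alpha)$keep
    if (!keep) {
      rlang::inform(sprintf(
        "aggregate_noise: image '%s' excluded by the KS channel-skew filter",
        df$image_id[1]
      ))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(image_id = df$image_id[1], tissue = df$tissue[1]),
      decompose_noise(df$c_value, df$y_value, scale = scale)
    )
  })
  if (nrow(res) == 0) {
    abort("all images excluded", class = "noisetissue_aggregation_error")
  }
  res
}

#' Group summary of per-image noise values
#'
#' Median and mean of each noise component across the images of each group
#' (tissue), the summary shown in box plots of per-image noise.
#'
#' @param results Per-image tibble from [aggregate_noise()].
#' @param group Grouping column (default `tissue`).
#' @return A tibble with one row per group and component:
#'   `component`, `median`, `mean`, `n_images`.
#' @export
summarise_noise_groups <- function(results, group = "tissue") {
  if (nrow(results) == 0) {
    abort("empty result set", class = "noisetissue_aggregation_error")
  }
  results |>
    tidyr::pivot_longer(
      dplyr::all_of(c("eta2_int", "eta2_ext", "eta2_tot")),
      names_to = "component", values_to = "value"
    ) |>
    dplyr::group_by(.data[[group]], .data$component) |>
    dplyr::summarise(
      median = median(.data$value), mean = mean(.data$value),
      n_images = dplyr::n(), .groups = "drop"
    )
}

#' Compare per-image noise between two groups
#'
#' Two-sided Wilcoxon rank-sum test: exact for groups of up to 12 untied
#' values, normal approximation with tie correction otherwise.
#'
#' @param a,b Per-image noise values of the two groups (length >= 3 each).
#' @return A one-row tibble: `statistic` (rank-sum W), `p_value`, `method`.
#' @examples
#' compare_groups(1:10, 11:20) # p = 2/choose(20, 10)
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    abort("need at least 3 values per group", class = "noisetissue_argument_error")
  }
  if (sd(c(a, b)) == 0) { # all tied: no evidence either way
    return(tibble::tibble(
      statistic = length(a) * length(b) / 2, p_value = 1,
      method = "Wilcoxon rank-sum (degenerate: all values tied)"
    ))
  }
  exact <- length(a) <= 12 && length(b) <= 12 && !any(duplicated(c(a, b)))
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  tibble::tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = if (exact) "Wilcoxon rank-sum (exact)" else "Wilcoxon rank-sum (normal approx., tie-corrected)"
  )
}

#' Noise by nuclear-area quartile
#'
#' Endoreduplication increases DNA content and with it nuclear size, so
#' nuclear area is used as an ordinal proxy for ploidy: cells are binned by
#' the empirical 25/50/75 percentiles of their maximal nuclear area and the
#' dual-reporter decomposition is applied within each bin. Ties at a bin
#' boundary go to the lower bin; a bin with fewer than 5 cells is reported
#' as missing.
#'
#' @inheritParams aggregate_noise
#' @param scale Reporting scale (see [decompose_noise()]).
#' @return A tibble with one row per quartile: `quartile`, `area_min`,
#'   `area_max`, `n_cells`, `eta2_int`, `eta2_ext`, `eta2_tot` (NA when
#'   missing).
#' @export
area_quartile_noise <- function(table, channels = c("CFP", "YFP"), scale = 100) {
  wide <- dual_channel_wide(table, channels)
  if (nrow(wide) < 20) {
    abort("need at least 20 cells", class = "noisetissue_argument_error")
  }
  qs <- quantile(wide$area_um2, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  wide$quartile <- 1L + (wide$area_um2 > qs[1]) + (wide$area_um2 > qs[2]) +
    (wide$area_um2 > qs[3])
  purrr::map_dfr(1:4, function(q) {
    df <- wide[wide$quartile == q, , drop = FALSE]
    base <- tibble::tibble(
      quartile = q,
      area_min = if (nrow(df)) min(df$area_um2) else NA_real_,
      area_max = if (nrow(df)) max(df$area_um2) else NA_real_
    )
    if (nrow(df) < 5) {
      return(dplyr::bind_cols(base, tibble::tibble(
        n_cells = nrow(df), eta2_int = NA_real_, eta2_ext = NA_real_,
        eta2_tot = NA_real_
      )))
    }
    dplyr::bind_cols(base, decompose_noise(df$c_value, df$y_value, scale = scale))
  })
}

# Pivot a normalized dual-channel table to one row per cell with c/y values.
dual_channel_wide <- function(table, channels) {
  stopifnot(inherits(table, "nucleus_tbl"), length(channels) == 2)
  if (norm_state(table) != "mean_normalized") {
    abort("normalize the table first", class = "noisetissue_state_error")
  }
  tibble::as_tibble(table) |>
    dplyr::filter(.data$channel %in% channels) |>
    dplyr::select(
      "image_id", "cell_id", "tissue", "x_um", "y_um", "area_um2",
      "channel", "value"
    ) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value") |>
    dplyr::rename(c_value = !!channels[1], y_value = !!channels[2]) |>
    dplyr::filter(is.finite(.data$c_value), is.finite(.data$y_value))
}
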