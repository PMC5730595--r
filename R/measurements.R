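#' @title Nucleus measurement tables
#'
#' @description A nucleus table is a tidy tibble with one row per nucleus,
#' channel, time point and technical replicate, the unit every analysis in
#' this package starts from. Columns:
#' `image_id`, `cell_id`, `tissue`, `x_um`, `y_um`, `area_um2`, `channel`,
#' `time_h`, `replicate`, `mean_grey`, `background_mean_grey`.
#' `mean_grey` is the mean grey value of the nuclear ROI in an 8-bit image
#' (0 = black, 255 = white); backgrounds are measured per image and channel.
#' The table carries a one-way normalization state
#' (`raw` -> `mean_normalized`) so that stages cannot be applied twice or
#' out of order.
#'
#' @param data A data frame with the columns above.
#' @param state Normalization state; new tables are `"raw"`.
#' @return A `nucleus_tbl` tibble.
#' @export
nucleus_table <- function(data, state = "raw") {
  data <- tibble::as_tibble(data)
  missing <- setdiff(nucleus_table_cols(), names(data))
  if (length(missing)) {
    abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "noisetissue_schema_error"
    )
  }
  num_cols <- c("x_um", "y_um", "area_um2", "time_h", "mean_grey", "background_mean_grey")
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[cl]]))))
      abort(
        sprintf(
          "column '%s' is not numeric (first offending row: %d)", cl,
          if (length(bad)) bad[1] else 1L
        ),
        class = "noisetissue_schema_error"
      )
    }
  }
  state <- match.arg(state, c("raw", "mean_normalized"))
  if (state == "raw") {
    rng <- range(data$mean_grey, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 255) {
      abort("raw mean grey values must lie in [0, 255]",
        class = "noisetissue_schema_error"
      )
    }
  }
  structure(data,
    class = c("nucleus_tbl", class(tibble::tibble())),
    norm_state = state
  )
}

nucleus_table_cols <- function() {
  c(
    "image_id", "cell_id", "tissue", "x_um", "y_um", "area_um2",
    "channel", "time_h", "replicate", "mean_grey", "background_mean_grey"
  )
}

#' Normalization state of a nucleus table
#' @param table A [nucleus_table()].
#' @return `"raw"` or `"mean_normalized"`.
#' @export
norm_state <- function(table) {
  attr(table, "norm_state") %||% "raw"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a nucleus measurement CSV
#'
#' Validates the documented schema; a missing column raises a schema error
#' naming the column, and a non-numeric intensity raises a row-level error
#' with the offending line.
#'
#' @param path CSV path.
#' @return A raw [nucleus_table()] with the file's row count preserved.
#' @export
read_nucleus_table <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(nucleus_table_cols(), names(raw))
  if (length(missing)) {
    abort(
      paste0(
        "schema error in ", path, ": missing column(s): ",
        paste(missing, collapse = ", ")
      ),
      class = "noisetissue_schema_error"
    )
  }
  num_cols <- c("x_um", "y_um", "area_um2", "time_h", "mean_grey", "background_mean_grey")
  for (cl in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(vals) & !is.na(raw[[cl]]))
    if (length(bad)) {
      abort(
        sprintf(
          "non-numeric value '%s' in column '%s' at data line %d of %s",
          raw[[cl]][bad[1]], cl, bad[1], path
        ),
        class = "noisetissue_schema_error"
      )
    }
    raw[[cl]] <- vals
  }
  raw$replicate <- as.integer(raw$replicate)
  nucleus_table(raw)
}

#' Write a nucleus table to CSV
#'
#' @param table A [nucleus_table()] (raw state: round-trips exactly through
#'   [read_nucleus_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table)[, union(
    nucleus_table_cols(),
    intersect(names(table), c(nucleus_table_cols(), "value"))
  )], path)
  invisible(path)
}

#' Average duplicate technical measurements
#'
#' Each nucleus is measured twice per channel and time point to control
#' technical error and bleaching; duplicates are replaced by their
#' arithmetic mean (single measurements pass through). Averaging two
#' i.i.d. technical errors halves the technical variance.
#'
#' @param table A [nucleus_table()].
#' @return A [nucleus_table()] with one row per nucleus/channel/time point
#'   and `replicate = 1`.
#' @export
average_duplicates <- function(table) {
  stopifnot(inherits(table, "nucleus_tbl"))
  st <- norm_state(table)
  if (st != "raw") {
    abort("average duplicates before normalizing", class = "noisetissue_state_error")
  }
  out <- tibble::as_tibble(table) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(
      nucleus_table_cols(), c("replicate", "mean_grey")
    )))) |>
    dplyr::summarise(
      mean_grey = mean(.data$mean_grey), replicate = 1L, .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(nucleus_table_cols()))
  nucleus_table(out, state = st)
}

#' Background-subtract and mean-normalize a nucleus table
#'
#' The per-image, per-channel background is subtracted from each mean grey
#' value, and the result is divided by the mean of the background-corrected
#' values of its image/channel/time-point group, so every group has mean 1.
#' Records that are non-positive after background subtraction are excluded
#' (not clamped -- clamping would bias the group mean) and their count is
#' reported.
#'
#' The transition is one-way: normalizing an already-normalized table is an
#' error.
#'
#' @param table A raw [nucleus_table()] (average duplicates first if
#'   present).
#' @return A `mean_normalized` [nucleus_table()] with a `value` column;
#'   attribute `n_excluded` counts dropped records.
#' @examples
#' # background 10, raw values 11 and 13 -> normalized 0.5 and 1.5
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "nucleus_tbl"))
  if (norm_state(table) != "raw") {
    abort("table is already normalized (transitions are one-way)",
      class = "noisetissue_state_error"
    )
  }
  df <- tibble::as_tibble(table)
  df$value <- df$mean_grey - df$background_mean_grey
  bad <- df$value <= 0 | !is.finite(df$value)
  n_excluded <- sum(bad)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "normalize_table: excluded %d record(s) non-positive after background subtraction",
      n_excluded
    ))
  }
  df <- df[!bad, , drop = FALSE]
  df <- df |>
    dplyr::group_by(.data$image_id, .data$channel, .data$time_h) |>
    dplyr::mutate(value = .data$value / mean(.data$value)) |>
    dplyr::ungroup()
  out <- nucleus_table(df, state = "mean_normalized")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Correlation between two paired intensity vectors
#'
#' Pearson or Spearman correlation of (typically) normalized fluorescence
#' read-outs of the same nuclei at two time points. Spearman ties are
#' handled by average ranks (the standard convention of [stats::cor()]).
#'
#' @param values_a,values_b Paired numeric vectors, length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient (scalar).
#' @export
timepoint_correlation <- function(values_a, values_b,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b)) {
    abort("paired vectors must have equal length", class = "noisetissue_argument_error")
  }
  if (length(values_a) < 3) {
    abort("need at least 3 pairs", class = "noisetissue_argument_error")
  }
  if (sd(values_a) == 0 || sd(values_b) == 0) {
    abort("correlation undefined for zero-variance input",
      class = "noisetissue_estimation_error"
    )
  }
  cor(values_a, values_b, method = method)
}

#' Per-image temporal correlation of a reporter channel
#'
#' Computes, for every image (leaf), the correlation of a channel's
#' normalized per-nucleus values between two time points. Per-image
#' coefficients are summarized across replicate leaves by unweighted mean.
#'
#' @param table A normalized [nucleus_table()] (see [normalize_table()]).
#' @param t1,t2 The two time points (h).
#' @param channel Channel name (default `"KikG"`).
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble `image_id`, `n_cells`, `r`, with the unweighted mean of
#'   the per-image coefficients in attribute `mean_r`.
#' @export
kik_temporal_correlation <- function(table, t1 = 3, t2 = 6, channel = "KikG",
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "nucleus_tbl"))
  if (norm_state(table) != "mean_normalized") {
    abort("normalize the table first", class = "noisetissue_state_error")
  }
  wide <- tibble::as_tibble(table) |>
    dplyr::filter(.data$channel == !!channel, .data$time_h %in% c(t1, t2)) |>
    dplyr::select("image_id", "cell_id", "time_h", "value") |>
    tidyr::pivot_wider(names_from = "time_h", values_from = "value") |>
    dplyr::filter(complete.cases(dplyr::pick(dplyr::everything())))
  a <- as.character(t1)
  b <- as.character(t2)
  out <- wide |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      r = timepoint_correlation(.data[[a]], .data[[b]], method = method),
      .groups = "drop"
    )
  attr(out, "mean_r") <- mean(out$r)
  out
}

#' Kolmogorov-Smirnov sample-skew filter
#'
#' Dual-reporter decomposition assumes the two channels report the same
#' expression law; an image in which the normalized CFP and YFP value
#' distributions differ significantly (two-sample KS test) is excluded from
#' the noise analysis.
#'
#' @param channel_a,channel_b Normalized per-nucleus values of the two
#'   channels (length >= 5 each).
#' @param alpha Significance level; the image is excluded when
#'   `p < alpha`. `alpha = 0` keeps everything.
#' @return A one-row tibble: `p_value`, `keep`.
#' @export
ks_skew_filter <- function(channel_a, channel_b, alpha = 0.05) {
  if (length(channel_a) < 5 || length(channel_b) < 5) {
    abort("need at least 5 values per channel", class = "noisetissue_argument_error")
  }
  p <- suppressWarnings(ks.test(channel_a, channel_b)$p.value)
  tibble::tibble(p_value = p, keep = !(p < alpha))
}
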