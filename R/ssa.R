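#' Simulate one trajectory of the photoconvertible reporter
#'
#' Exact stochastic simulation (direct method) of the two-stage model with a
#' green-to-red photoconvertible reporter. The reaction set is
#' `0 -> mRNA` at `v0`, `mRNA -> 0` at `d0*m`, `mRNA -> mRNA + green` at
#' `v1*m`, `green -> 0` at `d1*g`, `red -> 0` at `d1*r`. At
#' `t_conversion` the whole green pool is transferred to red instantaneously
#' (total reporter count is conserved across the event).
#'
#' @param params A [two_stage_params()].
#' @param t_conversion Conversion time (h), or `NA` for no conversion.
#' @param t_end End of the simulation (h).
#' @param v1 Translation rate for this cell; defaults to `params$v1`.
#'   Pass a draw from [draw_translation_rate()] to include extrinsic noise.
#' @param initial_state Named numeric `c(mrna=, green=, red=)`, or `NULL`
#'   (default) to start from a stationary draw obtained by a burn-in of
#'   `10/d1` hours before `t = 0` (cells are assumed to be in steady-state
#'   expression before conversion).
#' @param sample_dt Sampling grid spacing (h); states are recorded only at
#'   grid times to bound memory.
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `kik_trajectory` with columns `time_h`, `mrna`,
#'   `green`, `red`. Attributes: `v1`, `conversion_time_h`, `params`,
#'   `conv_pre`/`conv_post` (exact states around the conversion instant).
#' @examples
#' tr <- ssa_two_stage(kikgr_params(), t_conversion = 0, t_end = 6, seed = 1)
#' head(tr)
#' @export
ssa_two_stage <- function(params, t_conversion = NA, t_end,
                          v1 = params$v1, initial_state = NULL,
                          sample_dt = 0.05, seed = NULL) {
  stopifnot(inherits(params, "two_stage_params"))
  if (!is.finite(v1) || v1 < 0) {
    abort("v1 must be finite and >= 0", class = "noisetissue_parameter_error")
  }
  if (!is.na(t_conversion) && t_conversion > t_end) {
    abort("t_conversion must be <= t_end", class = "noisetissue_argument_error")
  }
  grid <- seq(0, t_end, by = sample_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)

  res <- with_seed_if(seed, {
    if (is.null(initial_state)) {
      burn <- if (params$d1 > 0) 10 / params$d1 else 0
      m0 <- rpois(1, if (params$d0 > 0) params$v0 / params$d0 else 0)
      st <- c(mrna = m0, green = 0, red = 0)
    } else {
      burn <- 0
      st <- initial_state
      if (any(st < 0) || any(st != floor(st))) {
        abort("initial_state must be non-negative integers",
          class = "noisetissue_argument_error"
        )
      }
    }
    tc <- if (is.na(t_conversion)) -1 else t_conversion + burn
    cpp_ssa_two_stage(
      params$v0, params$d0, v1, params$d1, tc,
      st[["mrna"]], st[["green"]], st[["red"]], grid + burn
    )
  })
  out <- tibble::tibble(
    time_h = grid,
    mrna = res$states[, 1], green = res$states[, 2], red = res$states[, 3]
  )
  structure(out,
    class = c("kik_trajectory", class(out)),
    v1 = v1, conversion_time_h = t_conversion, params = params,
    conv_pre = setNames(res$conv_pre, c("mrna", "green", "red")),
    conv_post = setNames(res$conv_post, c("mrna", "green", "red"))
  )
}

#' Simulate a cohort of photoconversion trajectories in tidy form
#'
#' Each cell draws its own translation rate from `spec`, equilibrates, is
#' photoconverted at `t = 0` and followed for `t_end` hours.
#'
#' @param params A [two_stage_params()].
#' @param spec An [extrinsic_spec()].
#' @param n_cells Number of cells.
#' @param t_end Hours of follow-up after conversion.
#' @param sample_dt Sampling grid spacing (h).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time_h`, `mrna`, `green`, `red`,
#'   `cell_id`, `v1`, `conversion_time_h` (the tidy trajectory export
#'   format).
#' @export
simulate_trajectories <- function(params, spec, n_cells, t_end = 6,
                                  sample_dt = 0.05, seed = NULL) {
  stopifnot(inherits(params, "two_stage_params"), inherits(spec, "extrinsic_spec"))
  with_seed_if(seed, {
    v1s <- draw_translation_rate(spec, n_cells)
    grid <- seq(0, t_end, by = sample_dt)
    ens <- cpp_kik_ensemble(
      v1s, params$v0, params$d0, params$d1,
      if (params$d1 > 0) 10 / params$d1 else 0, grid
    )
    purrr::map_dfr(seq_len(n_cells), function(i) {
      tibble::tibble(
        time_h = grid, mrna = NA_real_,
        green = ens$green[i, ], red = ens$red[i, ],
        cell_id = sprintf("cell_%04d", i), v1 = v1s[i],
        conversion_time_h = 0
      )
    })
  })
}

#' Monte-Carlo autocorrelation of the two-stage model with extrinsic noise
#'
#' Simulates `n_traj` independent cells, each with its own translation rate
#' drawn from `spec`, starting from the pre-conversion stationary state
#' (burn-in `10/d1` h). After photoconversion at `t = 0` the green counts
#' are read out at `t1` and `t2` hours, and their Pearson correlation across
#' cells estimates the non-stationary autocorrelation. The closed-form
#' birth-death correlation [autocorr_birth_death()] is a lower bound;
#' extrinsic noise raises the correlation above it.
#'
#' @param params A [two_stage_params()].
#' @param spec An [extrinsic_spec()]; use `var_v1 = 0` for the purely
#'   intrinsic case.
#' @param t1,t2 Read-out times after conversion (h), `0 < t1 <= t2`.
#' @param n_traj Number of trajectories (>= 100).
#' @param seed Optional integer seed.
#'
#' @return A one-row tibble: `t1`, `t2`, `r` (correlation estimate),
#'   `mc_se` (large-sample Monte-Carlo standard error), `n_traj`.
#' @examples
#' \donttest{
#' autocorr_two_stage_mc(kikgr_params(), extrinsic_spec(45, 100),
#'   t1 = 3, t2 = 6, n_traj = 1000, seed = 1
#' )
#' }
#' @export
autocorr_two_stage_mc <- function(params, spec, t1, t2, n_traj = 1e4,
                                  seed = NULL) {
  stopifnot(inherits(params, "two_stage_params"), inherits(spec, "extrinsic_spec"))
  if (n_traj < 100) {
    abort("n_traj must be >= 100", class = "noisetissue_argument_error")
  }
  if (t1 <= 0 || t1 > t2) {
    abort("need 0 < t1 <= t2", class = "noisetissue_argument_error")
  }
  g <- with_seed_if(seed, {
    v1s <- draw_translation_rate(spec, n_traj)
    cpp_kik_ensemble(
      v1s, params$v0, params$d0, params$d1,
      if (params$d1 > 0) 10 / params$d1 else 0, c(t1, t2)
    )$green
  })
  if (sd(g[, 1]) == 0 || sd(g[, 2]) == 0) {
    abort("degenerate ensemble: zero variance at a read-out time",
      class = "noisetissue_estimation_error"
    )
  }
  r <- cor(g[, 1], g[, 2])
  tibble::tibble(
    t1 = t1, t2 = t2, r = r,
    mc_se = (1 - r^2) / sqrt(n_traj - 1), n_traj = n_traj
  )
}

#' Estimate the reporter decay rate from a pulse-chase pair
#'
#' After photoconversion the red pool only decays, so for each nucleus
#' `ln(R(t1)/R(t2)) / dt` estimates the protein degradation rate `d1`.
#' Per-nucleus rates are aggregated by unweighted mean; the standard error
#' is the standard deviation of per-nucleus rates over `sqrt(n)`.
#'
#' @param red_t1,red_t2 Paired per-nucleus red intensities at the first and
#'   second read-out (background-corrected; same length).
#' @param dt Time between the read-outs (h).
#'
#' @return A one-row tibble: `rate` (h^-1), `se`, `n_used`, `n_excluded`
#'   (pairs dropped because an intensity was not positive).
#' @examples
#' estimate_decay_rate(100, 76.338, dt = 3) # rate ~ 0.09
#' @export
estimate_decay_rate <- function(red_t1, red_t2, dt) {
  if (length(red_t1) != length(red_t2)) {
    abort("red_t1 and red_t2 must have the same length",
      class = "noisetissue_argument_error"
    )
  }
  if (!is.finite(dt) || dt <= 0) {
    abort("dt must be > 0", class = "noisetissue_argument_error")
  }
  ok <- is.finite(red_t1) & is.finite(red_t2) & red_t1 > 0 & red_t2 > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "estimate_decay_rate: excluded %d nucleus pair(s) with non-positive intensities",
      n_excluded
    ))
  }
  if (!any(ok)) {
    abort("no usable nucleus pairs after exclusion",
      class = "noisetissue_estimation_error"
    )
  }
  rates <- log(red_t1[ok] / red_t2[ok]) / dt
  n <- length(rates)
  tibble::tibble(
    rate = mean(rates),
    se = if (n > 1) sd(rates) / sqrt(n) else NA_real_,
    n_used = n, n_excluded = n_excluded
  )
}

#' Write trajectories to CSV
#'
#' Writes the tidy trajectory format produced by [simulate_trajectories()]
#' (`time_h, mrna, green, red, cell_id, v1, conversion_time_h`).
#'
#' @param trajectories Tibble from [simulate_trajectories()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  cols <- c("time_h", "mrna", "green", "red", "cell_id", "v1", "conversion_time_h")
  missing <- setdiff(cols, names(trajectories))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
      class = "noisetissue_schema_error"
    )
  }
  readr::write_csv(trajectories[cols], path)
  invisible(path)
}
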