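#' Configuration of the cell-division inheritance simulation
#'
#' At division the mother's exact mRNA and protein content for both
#' reporters is copied to two daughters (content is copied, not
#' partitioned). In `state_only` mode each daughter then draws its own
#' translation rate (the extrinsic noise decorrelates at division); in
#' `full` mode both daughters keep the mother's rate permanently. Each pair
#' evolves independently for a common age drawn from the division-age law.
#'
#' @param params A [two_stage_params()].
#' @param spec An [extrinsic_spec()].
#' @param mode `"state_only"` or `"full"`.
#' @param mean_division_time Mean of the exponential division-age law (h).
#'   `NULL` (default) uses [default_division_time()], calibrated so that
#'   `state_only` sibling coupling is about 0.16.
#' @param division_age_law `"exponential"` (default) or `"fixed"` (every
#'   pair is measured exactly `mean_division_time` hours after division;
#'   mainly for studying the age dependence of the coupling).
#' @param n_pairs Number of daughter pairs (>= 100).
#' @param seed Optional integer seed.
#' @return An `inheritance_config` object.
#' @export
inheritance_config <- function(params, spec, mode = c("state_only", "full"),
                               mean_division_time = NULL,
                               division_age_law = c("exponential", "fixed"),
                               n_pairs = 1e4, seed = NULL) {
  stopifnot(inherits(params, "two_stage_params"), inherits(spec, "extrinsic_spec"))
  mode <- match.arg(mode)
  division_age_law <- match.arg(division_age_law)
  if (n_pairs < 100) {
    abort("n_pairs must be >= 100", class = "noisetissue_argument_error")
  }
  if (is.null(mean_division_time)) {
    mean_division_time <- default_division_time(params$d1)
  }
  if (mean_division_time < 0) {
    abort("mean_division_time must be >= 0", class = "noisetissue_parameter_error")
  }
  structure(
    list(
      params = params, spec = spec, mode = mode,
      mean_division_time = mean_division_time,
      division_age_law = division_age_law,
      n_pairs = as.integer(n_pairs), seed = seed
    ),
    class = "inheritance_config"
  )
}

#' Calibrated mean division time
#'
#' For the covariance-normalized sibling statistic, the extrinsic memory a
#' daughter keeps of its mother decays with weight `u = exp(-d1 * age)`
#' (mRNA turns over much faster than protein, so only the inherited protein
#' pool carries the mother's translation-rate signature). Averaging over an
#' exponential age law with mean `T` gives the state-only sibling coupling
#' \deqn{r(T) = \frac{E[u^2]}{E[u^2] + E[(1-u)^2]},\qquad
#'   E[u^k] = \frac{1}{1 + k\, d_1 T}.}
#' This function inverts that closed form for a target coupling, the
#' package's stand-in for the unavailable measured division rate; at
#' `d1 = 0.09` and target 0.16 it gives about 37.7 h, a plausible division
#' time for young-leaf epidermis.
#'
#' @param d1 Protein degradation rate (h^-1).
#' @param target_r Target state-only sibling coupling (default 0.16).
#' @return Mean division time `T` (h).
#' @export
default_division_time <- function(d1, target_r = 0.16) {
  stopifnot(d1 > 0, target_r > 0, target_r < 1)
  f <- function(x) {
    a <- 1 / (1 + 2 * x) # E[u^2]
    b <- 1 / (1 + x) # E[u]
    a / (2 * a - 2 * b + 1) - target_r
  }
  uniroot(f, c(1e-6, 1e3), tol = 1e-10)$root / d1
}

#' Simulate daughter-cell pairs after one division
#'
#' The mother equilibrates (burn-in `10/d1` h) with her own translation
#' rate applied to both reporter genes; both daughters start from her exact
#' dual-reporter state and evolve by exact SSA for a shared age drawn from
#' the exponential division-age law.
#'
#' @param config An [inheritance_config()].
#' @return A tibble of class `division_ensemble` with one row per pair:
#'   `pair`, `age_h`, `v1_mother`, `v1_d1`, `v1_d2`, mRNA and protein
#'   counts `mC1, pC1, mY1, pY1, mC2, pC2, mY2, pY2`. Attributes: `mode`,
#'   `mean_division_time`.
#' @export
simulate_division_pairs <- function(config) {
  stopifnot(inherits(config, "inheritance_config"))
  p <- config$params
  n <- config$n_pairs
  out <- with_seed_if(config$seed, {
    v1m <- draw_translation_rate(config$spec, n)
    if (config$mode == "full") {
      v1a <- v1m
      v1b <- v1m
    } else {
      v1a <- draw_translation_rate(config$spec, n)
      v1b <- draw_translation_rate(config$spec, n)
    }
    ages <- if (config$mean_division_time == 0) {
      rep(0, n)
    } else if (config$division_age_law == "fixed") {
      rep(config$mean_division_time, n)
    } else {
      rexp(n, rate = 1 / config$mean_division_time)
    }
    m <- cpp_division_pairs(
      p$v0, p$d0, p$d1, v1m, v1a, v1b, ages,
      if (p$d1 > 0) 10 / p$d1 else 0
    )
    colnames(m) <- c("mC1", "pC1", "mY1", "pY1", "mC2", "pC2", "mY2", "pY2")
    dplyr::bind_cols(
      tibble::tibble(
        pair = seq_len(n), age_h = ages,
        v1_mother = v1m, v1_d1 = v1a, v1_d2 = v1b
      ),
      tibble::as_tibble(m)
    )
  })
  structure(out,
    class = c("division_ensemble", class(tibble::tibble())),
    mode = config$mode, mean_division_time = config$mean_division_time
  )
}

#' Sibling coupling of extrinsic noise
#'
#' The cross-reporter, cross-sibling statistic of
#' [neighbour_correlation()] applied to daughter pairs: the pooled
#' covariance of (C of daughter 1, Y of daughter 2) and (Y of daughter 1,
#' C of daughter 2), normalized by the pooled within-cell cross-channel
#' covariance (`normalization = "covariance"`, the default). With
#' `"pearson"` the denominator is instead the pooled per-channel variance,
#' so intrinsic noise also enters the denominator; fully heritable
#' extrinsic states then give a coupling below 1 (see the methods
#' vignette).
#'
#' @param ensemble A `division_ensemble` from [simulate_division_pairs()],
#'   or any data frame with columns `pC1, pY1, pC2, pY2` (>= 100 rows).
#' @param normalization `"covariance"` or `"pearson"`.
#' @param n_bootstrap Bootstrap resamples for the Monte-Carlo SE.
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row tibble: `mode`, `n_pairs`, `mean_division_age_h`,
#'   `r`, `mc_se`, `normalization`.
#' @export
sibling_correlation <- function(ensemble,
                                normalization = c("covariance", "pearson"),
                                n_bootstrap = 200, seed = NULL) {
  normalization <- match.arg(normalization)
  need <- c("pC1", "pY1", "pC2", "pY2")
  if (!all(need %in% names(ensemble))) {
    abort("ensemble needs columns pC1, pY1, pC2, pY2",
      class = "noisetissue_argument_error"
    )
  }
  if (nrow(ensemble) < 100) {
    abort("need at least 100 pairs", class = "noisetissue_argument_error")
  }
  stat <- function(df) {
    cov1 <- function(a, b) mean((a - mean(a)) * (b - mean(b)))
    num <- 0.5 * (cov1(df$pC1, df$pY2) + cov1(df$pY1, df$pC2))
    den <- if (normalization == "covariance") {
      0.5 * (cov1(df$pC1, df$pY1) + cov1(df$pC2, df$pY2))
    } else {
      mean(c(
        cov1(df$pC1, df$pC1), cov1(df$pY1, df$pY1),
        cov1(df$pC2, df$pC2), cov1(df$pY2, df$pY2)
      ))
    }
    if (!is.finite(den) || den <= 0) {
      abort("degenerate ensemble: correlation undefined",
        class = "noisetissue_estimation_error"
      )
    }
    num / den
  }
  df <- tibble::as_tibble(ensemble)[need]
  r <- stat(df)
  boots <- with_seed_if(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      stat(df[sample.int(nrow(df), replace = TRUE), ])
    }, numeric(1))
  })
  tibble::tibble(
    mode = attr(ensemble, "mode") %||% NA_character_,
    n_pairs = nrow(df),
    mean_division_age_h = if (!is.null(attr(ensemble, "mean_division_time"))) {
      attr(ensemble, "mean_division_time")
    } else {
      NA_real_
    },
    r = r, mc_se = sd(boots), normalization = normalization
  )
}

#' @export
glance.division_ensemble <- function(x, ...) {
  sibling_correlation(x, ...)
}

#' @export
autoplot.division_ensemble <- function(object, ...) {
  df <- tibble::tibble(
    value = c(object$pC1, object$pY1),
    sibling_value = c(object$pY2, object$pC2),
    ordering = rep(c("C1 vs Y2", "Y1 vs C2"), each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$sibling_value,
    colour = .data$ordering
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "reporter count (daughter 1)", y = "reporter count (daughter 2)",
      title = sprintf("Sibling pairs (%s inheritance)", attr(object, "mode"))
    ) +
    ggplot2::theme_minimal()
}
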