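#' Exact moments of the two-stage model
#'
#' Means, variances and the mRNA-protein covariance of the linear two-stage
#' model at time `t`, starting from a deterministic initial copy-number
#' state. For linear kinetics the first two moments obey a closed linear ODE
#' system
#' \deqn{\dot x = A x + b,\qquad x = (\langle m\rangle, \langle p\rangle,
#'   \mathrm{Var}(m), \mathrm{Cov}(m,p), \mathrm{Var}(p)),}
#' solved exactly as \eqn{x(t) = x_{ss} + e^{At}(x_0 - x_{ss})} with
#' \eqn{x_{ss} = -A^{-1} b}. The matrix-exponential solution needs no
#' special-cased branch when `d0 == d1`.
#'
#' Stationary values are `mean_mrna = v0/d0`, `mean_protein = v0*v1/(d0*d1)`
#' and `var_protein = mean_protein * (1 + v1/(d0 + d1))`; the stationary
#' mRNA law is Poisson.
#'
#' @param params A [two_stage_params()]; `d0` and `d1` must be positive.
#' @param t Time (h), scalar or vector. `Inf` returns the stationary moments.
#' @param initial_state Named numeric `c(mrna =, protein =)` copy numbers at
#'   `t = 0`; default is the empty state.
#'
#' @return A tibble with one row per time: `t`, `mean_mrna`, `var_mrna`,
#'   `mean_protein`, `var_protein`, `cov_mrna_protein`.
#' @examples
#' moments_two_stage(kikgr_params(), t = Inf)
#' @export
moments_two_stage <- function(params, t,
                              initial_state = c(mrna = 0, protein = 0)) {
  stopifnot(inherits(params, "two_stage_params"))
  if (params$d0 <= 0 || params$d1 <= 0) {
    abort("d0 and d1 must be > 0 for moment evaluation",
      class = "noisetissue_parameter_error"
    )
  }
  m0 <- unname(initial_state[["mrna"]])
  p0 <- unname(initial_state[["protein"]])
  v0 <- params$v0; d0 <- params$d0; v1 <- params$v1; d1 <- params$d1

  A <- matrix(0, 5, 5)
  A[1, 1] <- -d0
  A[2, 1] <- v1; A[2, 2] <- -d1
  A[3, 1] <- d0; A[3, 3] <- -2 * d0
  A[4, 3] <- v1; A[4, 4] <- -(d0 + d1)
  A[5, 1] <- v1; A[5, 2] <- d1; A[5, 4] <- 2 * v1; A[5, 5] <- -2 * d1
  b <- c(v0, 0, v0, 0, 0)
  x_ss <- solve(A, -b)
  x0 <- c(m0, p0, 0, 0, 0) # deterministic start: zero (co)variances

  one_time <- function(ti) {
    if (is.infinite(ti)) {
      return(x_ss)
    }
    if (ti == 0) {
      return(x0)
    }
    eAt <- as.matrix(Matrix::expm(A * ti))
    x_ss + drop(eAt %*% (x0 - x_ss))
  }
  xs <- vapply(t, one_time, numeric(5))
  tibble::tibble(
    t = t,
    mean_mrna = xs[1, ], var_mrna = xs[3, ],
    mean_protein = xs[2, ], var_protein = xs[5, ],
    cov_mrna_protein = xs[4, ]
  )
}

#' Non-stationary autocorrelation of a birth-death process
#'
#' Correlation between the copy numbers at times `t1` and `t2` of a
#' constant-rate birth-death process started at zero -- the post-conversion
#' green reporter pool when mRNA fluctuations are ignored:
#' \deqn{c_0(t_2, t_1) = e^{-d (t_2 - t_1)}
#'   \sqrt{\frac{1 - e^{-d t_1}}{1 - e^{-d t_2}}}.}
#' This function lower-bounds the autocorrelation of the full two-stage
#' model, so it gives a parameter-light prediction for pulse-chase data when
#' only the protein decay rate is known. At `d = 0` the continuous limit
#' `sqrt(t1/t2)` is returned.
#'
#' @param d Decay rate (h^-1), >= 0.
#' @param t1,t2 Times since the pool was emptied (h), `0 < t1 <= t2`.
#'   Vectorized.
#'
#' @return Correlation value(s) in `[0, 1]`.
#' @examples
#' autocorr_birth_death(0.09, 3, 6) # ~ 0.575
#' @export
autocorr_birth_death <- function(d, t1, t2) {
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("d must be finite and >= 0", class = "noisetissue_argument_error")
  }
  if (any(t1 <= 0)) {
    abort("t1 must be > 0", class = "noisetissue_argument_error")
  }
  if (any(t1 > t2)) {
    abort("t1 must be <= t2", class = "noisetissue_argument_error")
  }
  out <- ifelse(
    d == 0,
    sqrt(t1 / t2),
    exp(-d * (t2 - t1)) * sqrt((1 - exp(-d * t1)) / (1 - exp(-d * t2)))
  )
  unname(out)
}
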