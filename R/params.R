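#' Kinetic parameters of the two-stage expression model
#'
#' The two-stage model is the linear kinetic scheme
#' \eqn{\emptyset \to mRNA \to protein} with first-order degradation of both
#' species: transcription at rate `v0`, mRNA decay at `d0`, translation at
#' `v1` per mRNA, and protein decay at `d1`. All rates are per hour.
#'
#' @param v0 Transcription rate (mRNA h^-1).
#' @param d0 mRNA degradation rate (h^-1).
#' @param v1 Translation rate (protein mRNA^-1 h^-1).
#' @param d1 Protein degradation rate (h^-1).
#'
#' @return An object of class `two_stage_params`.
#' @examples
#' kikgr_params()
#' two_stage_params(v0 = 2.25, d0 = 1.125, v1 = 45, d1 = 0.09)
#' @export
two_stage_params <- function(v0, d0, v1, d1) {
  rates <- c(v0 = v0, d0 = d0, v1 = v1, d1 = d1)
  if (!all(is.finite(rates)) || any(rates < 0)) {
    abort("all rates must be finite and >= 0", class = "noisetissue_parameter_error")
  }
  structure(as.list(rates), class = "two_stage_params")
}

#' @export
print.two_stage_params <- function(x, ...) {
  cat(sprintf(
    "<two_stage_params> v0 = %g /h, d0 = %g /h, v1 = %g /h, d1 = %g /h\n",
    x$v0, x$d0, x$v1, x$d1
  ))
  invisible(x)
}

#' Reference parameter set for the photoconvertible reporter
#'
#' The parameter set used throughout the modelling of the nuclear-localized
#' KikGR reporter: v0 = 2.25 h^-1, d0 = 1.125 h^-1, v1 = 45 h^-1,
#' d1 = 0.09 h^-1, giving a stationary mean of 2 mRNAs and 1000 proteins.
#'
#' @return A `two_stage_params` object.
#' @export
kikgr_params <- function() {
  two_stage_params(v0 = 2.25, d0 = 1.125, v1 = 45, d1 = 0.09)
}

#' Cell-to-cell distribution of the translation rate (extrinsic noise)
#'
#' Extrinsic noise is modelled as a quasi-static cell-to-cell variation of
#' the translation rate `v1`: each cell draws one rate for the whole
#' experiment. Only the mean and variance are constrained; draws use a gamma
#' law matched to `(mean_v1, var_v1)` so rates are guaranteed positive.
#'
#' @param mean_v1 Mean translation rate (h^-1).
#' @param var_v1 Cell-to-cell variance of the translation rate (h^-2).
#'   `0` gives the degenerate (no extrinsic noise) case.
#' @param distribution Sampling law; currently `"gamma"` (or the implied
#'   `"degenerate"` when `var_v1 = 0`).
#'
#' @return An object of class `extrinsic_spec` with fields `mean_v1`,
#'   `var_v1`, `distribution` and the coefficient of variation `cv`.
#' @examples
#' extrinsic_spec(45, 100)
#' @export
extrinsic_spec <- function(mean_v1, var_v1, distribution = "gamma") {
  if (!is.finite(mean_v1) || mean_v1 < 0) {
    abort("mean_v1 must be finite and >= 0", class = "noisetissue_parameter_error")
  }
  if (!is.finite(var_v1) || var_v1 < 0) {
    abort("var_v1 must be >= 0", class = "noisetissue_parameter_error")
  }
  distribution <- match.arg(distribution, "gamma")
  structure(
    list(
      mean_v1 = mean_v1, var_v1 = var_v1, distribution = distribution,
      cv = if (mean_v1 > 0) sqrt(var_v1) / mean_v1 else 0
    ),
    class = "extrinsic_spec"
  )
}

#' @export
print.extrinsic_spec <- function(x, ...) {
  cat(sprintf(
    "<extrinsic_spec> %s: mean v1 = %g /h, Var(v1) = %g /h^2 (CV = %.3f)\n",
    x$distribution, x$mean_v1, x$var_v1, x$cv
  ))
  invisible(x)
}

#' Draw per-cell translation rates
#'
#' Samples `n` translation rates from the configured cell-to-cell law.
#' With `var_v1 = 0` every draw equals `mean_v1` exactly.
#'
#' @param spec An [extrinsic_spec()].
#' @param n Number of cells.
#' @param seed Optional integer seed; the draw is deterministic given it.
#'
#' @return Numeric vector of length `n` (h^-1), all values >= 0.
#' @examples
#' draw_translation_rate(extrinsic_spec(45, 100), n = 3, seed = 1)
#' @export
draw_translation_rate <- function(spec, n = 1, seed = NULL) {
  stopifnot(inherits(spec, "extrinsic_spec"))
  if (spec$var_v1 == 0 || spec$mean_v1 == 0) {
    return(rep(spec$mean_v1, n))
  }
  shape <- spec$mean_v1^2 / spec$var_v1
  rate <- spec$mean_v1 / spec$var_v1
  with_seed_if(seed, rgamma(n, shape = shape, rate = rate))
}
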