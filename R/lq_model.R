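#' @title Linear-quadratic iso-effect engine
#' @description Closed-form conversion of total RBE-weighted doses between
#'   fractionation schemes under the linear-quadratic (LQ) cell-survival
#'   model.  Iso-effect between a scheme delivering `n1` fractions of `d1`
#'   Gy and one delivering `n2` fractions of `d2` Gy means equal
#'   biologically effective dose (BED): `n*d*(1 + d/(alpha/beta))`.
#' @name lq_model
NULL

#' Default rectal alpha/beta ratio in Gy
#'
#' The LQ fraction-size sensitivity parameter used throughout for rectum
#' constraints, 3.9 Gy.  All LQ operations take `alpha_beta` as an explicit
#' argument so other organs can be handled; this constant is only a default.
#'
#' @return A single numeric, 3.9.
#' @export
default_alpha_beta <- function() 3.9

.check_lq_args <- function(dose, n_fractions, alpha_beta) {
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("`dose` must be finite, non-negative Gy (RBE)", call. = FALSE)
  if (!is.numeric(n_fractions) || any(!is.finite(n_fractions)) ||
      any(n_fractions < 1) || any(n_fractions != round(n_fractions)))
    stop("`n_fractions` must be a positive integer count (>= 1)",
         call. = FALSE)
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L ||
      !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("`alpha_beta` must be a single positive dose in Gy", call. = FALSE)
  invisible(TRUE)
}

#' Biologically effective dose
#'
#' Computes `BED = N * d * (1 + d / (alpha/beta))` with dose-per-fraction
#' `d = dose / n_fractions`.
#'
#' @param dose Total RBE-weighted dose in Gy (RBE), non-negative.
#'   Vectorised.
#' @param n_fractions Number of fractions `N` (positive integer).
#'   Recycled against `dose`.
#' @param alpha_beta LQ alpha/beta ratio in Gy, strictly positive.
#' @return BED in Gy, same length as `dose` after recycling; non-negative
#'   and strictly increasing in `dose`.
#' @examples
#' bed(43.14, 16)            # 16 x 2.696 Gy (RBE) rectum constraint
#' bed(60, 1, 10)            # single fraction: D * (1 + D/(a/b))
#' @export
bed <- function(dose, n_fractions, alpha_beta = default_alpha_beta()) {
  .check_lq_args(dose, n_fractions, alpha_beta)
  d <- dose / n_fractions
  dose * (1 + d / alpha_beta)
}

#' Iso-effective total dose at another fractionation scheme
#'
#' Solves `N2*d2*(1 + d2/(a/b)) = N1*d1*(1 + d1/(a/b))` for `d2` via the
#' positive root of the quadratic,
#' `d2 = (-(a/b) + sqrt((a/b)^2 + 4*(a/b)*BED/N2)) / 2`,
#' and returns the total dose `N2*d2`.  When `n_from == n_to` the input is
#' returned exactly (no floating-point round trip).
#'
#' @param dose Total RBE-weighted dose in Gy (RBE) at the source scheme.
#'   Vectorised.
#' @param n_from,n_to Source and target fraction numbers (positive
#'   integers).
#' @param alpha_beta LQ alpha/beta ratio in Gy.
#' @return Total dose in Gy (RBE) at `n_to` fractions with the same BED.
#' @examples
#' isoeffect_dose(43.14, 16, 12)   # ~39.55 Gy (RBE)
#' @export
isoeffect_dose <- function(dose, n_from, n_to,
                           alpha_beta = default_alpha_beta()) {
  .check_lq_args(dose, n_from, alpha_beta)
  .check_lq_args(dose, n_to, alpha_beta)
  n <- max(length(dose), length(n_from), length(n_to))
  dose <- rep_len(dose, n)
  n_from <- rep_len(n_from, n)
  n_to <- rep_len(n_to, n)
  out <- dose
  i <- n_from != n_to
  if (any(i)) {
    b <- bed(dose[i], n_from[i], alpha_beta)
    d2 <- (-alpha_beta + sqrt(alpha_beta^2 + 4 * alpha_beta * b / n_to[i])) / 2
    out[i] <- n_to[i] * d2
  }
  out
}
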