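# Independent oracles used to freeze expected values.

# Bisection on the monotone BED-equality equation (independent of the
# closed-form root in the package).
ora_iso_bisect <- function(dose, n_from, n_to, alpha_beta = 3.9,
                           tol = 1e-12) {
  bed1 <- dose * (1 + (dose / n_from) / alpha_beta)
  f <- function(D2) D2 * (1 + (D2 / n_to) / alpha_beta) - bed1
  lo <- 0; hi <- max(dose * 2, 1)
  while (f(hi) < 0) hi <- hi * 2
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Brute-force DVH crossing: densify the piecewise-linear cumulative curve
# to a 10,000-point grid (refining the original one, so no kink is lost),
# scan for the first point at or below the level, then interpolate inside
# the located cell.
ora_dvh_crossing <- function(x, v, n_dense = 10000L) {
  dd <- sort(unique(c(x$dose,
                      seq(x$dose[1L], x$dose[length(x$dose)],
                          length.out = n_dense))))
  n_dense <- length(dd)
  vv <- stats::approx(x$dose, x$rel_volume, xout = dd, ties = "ordered")$y
  idx <- match(TRUE, vv <= v)
  if (is.na(idx)) return(dd[n_dense])
  if (idx == 1L) return(dd[1L])
  dd[idx - 1L] + (vv[idx - 1L] - v) / (vv[idx - 1L] - vv[idx]) *
    (dd[idx] - dd[idx - 1L])
}

# Manual bisection inverse of a package forward curve (independent of
# stats::uniroot).
ora_curve_inverse <- function(curve, y, tol = 1e-9) {
  lo <- curve$mkm[1L]; hi <- curve$mkm[length(curve$mkm)]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mkm_to_lem(curve, mid) < y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
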