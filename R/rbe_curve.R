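#' @title RBE-model dose-conversion curves
#' @description A conversion curve maps RBE-weighted total doses reported
#'   under the microdosimetric kinetic model (MKM) to those the same
#'   physical plan would report under the local effect model (LEM), for one
#'   fractionation scheme.  The curve is represented by strictly monotone
#'   dose anchors and a shape-preserving interpolant; the inverse direction
#'   is obtained by root finding on the forward map.
#' @name rbe_curve
NULL

# fraction of the anchor dose range tolerated beyond each end under the
# "linear-tail" extrapolation policy
.EXTRAP_FRACTION <- 0.10

#' Build an MKM-to-LEM conversion curve
#'
#' @param mkm,lem Paired anchor doses in Gy (RBE), both strictly positive.
#'   Anchors are sorted by `mkm`; after sorting both columns must be
#'   strictly increasing (joint strict monotonicity).
#' @param scheme Fraction number the curve was generated for (integer), or
#'   `NA` if scheme-agnostic (e.g. an identity test curve).
#' @param method Interpolation: `"monotone-cubic"` (default; Fritsch-Carlson
#'   shape-preserving Hermite via [stats::splinefun()], anchor-exact and
#'   monotone) or `"piecewise-linear"`.
#' @param extrapolation Policy outside the anchor range:
#'   `"linear-tail"` (default) extends the end segment's chord slope up to
#'   10 percent of the anchor dose range beyond each end, with a warning;
#'   `"error"` refuses any out-of-domain dose.
#' @param id Optional identifier recorded in conversion provenance;
#'   defaults to a label built from `scheme` and anchor count.
#' @return An object of class `conversion_curve`.
#' @examples
#' cv <- conversion_curve(c(10, 20), c(10, 20))   # identity on [10, 20]
#' mkm_to_lem(cv, 15)
#' @seealso [mkm_to_lem()], [lem_to_mkm()], [cirt_fixture_curve()]
#' @export
conversion_curve <- function(mkm, lem, scheme = NA_integer_,
                             method = c("monotone-cubic", "piecewise-linear"),
                             extrapolation = c("linear-tail", "error"),
                             id = NULL) {
  method <- match.arg(method)
  extrapolation <- match.arg(extrapolation)
  if (!is.numeric(mkm) || !is.numeric(lem) || length(mkm) != length(lem))
    stop("`mkm` and `lem` must be numeric vectors of equal length",
         call. = FALSE)
  if (length(mkm) < 2L)
    stop("a conversion curve needs at least 2 anchors", call. = FALSE)
  if (any(!is.finite(mkm)) || any(!is.finite(lem)) ||
      any(mkm <= 0) || any(lem <= 0))
    stop("anchor doses must be finite and strictly positive", call. = FALSE)
  o <- order(mkm)
  mkm <- mkm[o]; lem <- lem[o]
  bad <- which(diff(mkm) <= 0)
  if (length(bad))
    stop(sprintf(
      "anchors not strictly increasing in MKM dose: pair %d (%.4f) vs %d (%.4f)",
      bad[1L], mkm[bad[1L]], bad[1L] + 1L, mkm[bad[1L] + 1L]), call. = FALSE)
  bad <- which(diff(lem) <= 0)
  if (length(bad))
    stop(sprintf(
      "anchors not jointly monotone: LEM dose does not increase from pair %d (%.4f) to %d (%.4f)",
      bad[1L], lem[bad[1L]], bad[1L] + 1L, lem[bad[1L] + 1L]), call. = FALSE)
  if (is.null(id))
    id <- sprintf("curve-%sfx-%danchors",
                  ifelse(is.na(scheme), "NA", as.character(scheme)),
                  length(mkm))
  structure(
    list(mkm = mkm, lem = lem, scheme = as.integer(scheme),
         method = method, extrapolation = extrapolation, id = id),
    class = "conversion_curve")
}

#' @export
print.conversion_curve <- function(x, ...) {
  cat(sprintf("RBE conversion curve <%s> (%s, %s extrapolation)\n", x$id,
              x$method, x$extrapolation))
  cat(sprintf("  scheme: %s fractions, %d anchors\n",
              ifelse(is.na(x$scheme), "unspecified", x$scheme),
              length(x$mkm)))
  print(data.frame(mkm_dose_gy_rbe = x$mkm, lem_dose_gy_rbe = x$lem),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conversion_curve <- function(x, ...) {
  data.frame(mkm_dose_gy_rbe = x$mkm, lem_dose_gy_rbe = x$lem)
}

# interior interpolant (no extrapolation handling)
.curve_core <- function(curve) {
  if (curve$method == "monotone-cubic")
    stats::splinefun(curve$mkm, curve$lem, method = "monoH.FC")
  else
    stats::approxfun(curve$mkm, curve$lem, rule = 2)
}

# evaluate with tail policy along axis `x` (anchor abscissae) mapping to `y`
.curve_eval <- function(x_anchor, y_anchor, core, policy, x, what) {
  lo <- x_anchor[1L]; hi <- x_anchor[length(x_anchor)]
  span <- hi - lo
  tol <- .EXTRAP_FRACTION * span
  out <- numeric(length(x))
  inside <- x >= lo & x <= hi
  out[inside] <- core(x[inside])
  below <- x < lo; above <- x > hi
  if (any(below | above)) {
    beyond <- x < lo - tol | x > hi + tol
    if (policy == "error" || any(beyond)) {
      off <- if (policy == "error") x[which(below | above)[1L]]
             else x[which(beyond)[1L]]
      stop(sprintf(
        "%s dose %.4f Gy (RBE) outside curve range [%.4f, %.4f]%s",
        what, off, lo, hi,
        if (policy == "error") " (extrapolation policy = \"error\")"
        else sprintf(" by more than %.0f%%", 100 * .EXTRAP_FRACTION)),
        call. = FALSE)
    }
    warning(sprintf(
      "%s dose outside curve anchor range [%.4f, %.4f]; linear-tail extrapolation used",
      what, lo, hi), call. = FALSE)
    n <- length(x_anchor)
    s_lo <- (y_anchor[2L] - y_anchor[1L]) / (x_anchor[2L] - x_anchor[1L])
    s_hi <- (y_anchor[n] - y_anchor[n - 1L]) / (x_anchor[n] - x_anchor[n - 1L])
    out[below] <- y_anchor[1L] + s_lo * (x[below] - lo)
    out[above] <- y_anchor[n] + s_hi * (x[above] - hi)
  }
  out
}

#' Convert MKM dose to LEM dose along a curve
#'
#' Strictly increasing in `dose` and exact at every anchor.
#'
#' @param curve A [conversion_curve()].
#' @param dose MKM RBE-weighted total dose(s) in Gy (RBE).
#' @return LEM RBE-weighted dose(s) in Gy (RBE).
#' @export
mkm_to_lem <- function(curve, dose) {
  stopifnot(inherits(curve, "conversion_curve"))
  if (!is.numeric(dose) || any(!is.finite(dose)))
    stop("`dose` must be finite numeric", call. = FALSE)
  # snap to anchors so anchor-exactness is exact, not interpolant-limited
  out <- .curve_eval(curve$mkm, curve$lem, .curve_core(curve),
                     curve$extrapolation, dose, "MKM")
  hit <- match(dose, curve$mkm)
  out[!is.na(hit)] <- curve$lem[hit[!is.na(hit)]]
  out
}

#' Convert LEM dose back to MKM dose along a curve
#'
#' Inverse of [mkm_to_lem()] by bracketed root finding on the forward
#' interpolant ([stats::uniroot()], dose tolerance 1e-12); doses equal to
#' an anchor LEM value are returned anchor-exactly.  Doses outside the
#' curve image follow the curve's extrapolation policy (linear tails are
#' inverted analytically).
#'
#' @inheritParams mkm_to_lem
#' @param dose LEM RBE-weighted total dose(s) in Gy (RBE).
#' @return MKM RBE-weighted dose(s) in Gy (RBE), satisfying
#'   `mkm_to_lem(curve, lem_to_mkm(curve, x)) == x` to well under 1e-6.
#' @export
lem_to_mkm <- function(curve, dose) {
  stopifnot(inherits(curve, "conversion_curve"))
  if (!is.numeric(dose) || any(!is.finite(dose)))
    stop("`dose` must be finite numeric", call. = FALSE)
  core <- .curve_core(curve)
  n <- length(curve$mkm)
  y_lo <- curve$lem[1L]; y_hi <- curve$lem[n]
  x_lo <- curve$mkm[1L]; x_hi <- curve$mkm[n]
  span <- x_hi - x_lo
  s_lo <- (curve$lem[2L] - y_lo) / (curve$mkm[2L] - x_lo)
  s_hi <- (y_hi - curve$lem[n - 1L]) / (x_hi - curve$mkm[n - 1L])
  vapply(dose, function(y) {
    hit <- match(y, curve$lem)
    if (!is.na(hit)) return(curve$mkm[hit])
    if (y < y_lo || y > y_hi) {
      x <- if (y < y_lo) x_lo + (y - y_lo) / s_lo else x_hi + (y - y_hi) / s_hi
      if (curve$extrapolation == "error" ||
          x < x_lo - .EXTRAP_FRACTION * span ||
          x > x_hi + .EXTRAP_FRACTION * span)
        stop(sprintf(
          "LEM dose %.4f Gy (RBE) outside curve image [%.4f, %.4f]%s",
          y, y_lo, y_hi,
          if (curve$extrapolation == "error")
            " (extrapolation policy = \"error\")"
          else sprintf(" by more than %.0f%%", 100 * .EXTRAP_FRACTION)),
          call. = FALSE)
      warning(sprintf(
        "LEM dose outside curve image [%.4f, %.4f]; linear-tail extrapolation used",
        y_lo, y_hi), call. = FALSE)
      return(x)
    }
    i <- findInterval(y, curve$lem, rightmost.closed = TRUE)
    stats::uniroot(function(x) core(x) - y,
                   lower = curve$mkm[i], upper = curve$mkm[i + 1L],
                   tol = 1e-12)$root
  }, numeric(1L))
}

# --- packaged fixture curves ---------------------------------------------

# 16-fraction anchors: four published forward MKM->LEM rectum-constraint
# pairs merged with the three backward pairs from the CNAO absolute-volume
# constraint adaptation; jointly strictly monotone.
.ANCHORS_16FX <- data.frame(
  mkm = c(28.80, 39.99, 46.40, 49.84, 56.00, 57.31, 60.80),
  lem = c(43.14, 54.00, 58.48, 61.00, 65.11, 66.00, 68.33))

# MKM-LQ-strategy LEM outputs published per target scheme, in the anchor
# order above; used only for the reconstructed demonstration curves.
.MKM_LQ_LEM <- list(
  `12` = c(37.60, 45.97, 49.74, 51.70, 55.27, 55.97, 58.01),
  `8`  = c(30.40, 36.53, 39.25, 40.73, 43.41, 43.97, 45.46),
  `4`  = c(20.80, 23.94, 25.66, 26.62, 28.33, 28.67, 29.64))

#' Packaged RBE conversion curve fixtures
#'
#' @description
#' `"16fx"`: the 7-anchor 16-fraction rectum curve assembled from the
#' published forward pairs (28.80 to 43.14, 46.40 to 58.48, 56.00 to 65.11,
#' 60.80 to 68.33 Gy (RBE)) and the backward-converted CNAO pairs
#' (39.99 to 54.00, 49.84 to 61.00, 57.31 to 66.00).
#'
#' `"12fx-scanning"`: a 2-anchor 12-fraction curve from the published
#' spot-scanning 12-fraction protocol correspondence (41.28 to 49.00 for
#' the 80-percent isodose of a 51.6 Gy (RBE) prescription, and
#' 51.60 to 55.71 for the prescription itself).
#'
#' `"12fx-reconstructed"`, `"8fx-reconstructed"`, `"4fx-reconstructed"`:
#' SYNTHETIC reconstructions.  The true 12/8/4-fraction curves are not
#' published; these pair LQ-converted MKM anchor doses (via
#' [isoeffect_dose()] at `alpha_beta`) with the published MKM-LQ-strategy
#' LEM outputs, so they reproduce those outputs anchor-exactly *by
#' construction*.  They are demonstration fixtures, not evidence about the
#' unpublished curve shapes.
#'
#' @param name Fixture name.
#' @param alpha_beta alpha/beta used for the LQ step of the reconstructed
#'   fixtures.
#' @return A [conversion_curve()].
#' @export
cirt_fixture_curve <- function(name = c("16fx", "12fx-scanning",
                                        "12fx-reconstructed",
                                        "8fx-reconstructed",
                                        "4fx-reconstructed"),
                               alpha_beta = default_alpha_beta()) {
  name <- match.arg(name)
  if (name == "16fx")
    return(conversion_curve(.ANCHORS_16FX$mkm, .ANCHORS_16FX$lem,
                            scheme = 16L, id = "16fx-published-anchors"))
  if (name == "12fx-scanning")
    return(conversion_curve(c(41.28, 51.60), c(49.00, 55.71),
                            scheme = 12L, id = "12fx-scanning-protocol"))
  n_to <- as.integer(sub("fx.*", "", name))
  conversion_curve(
    isoeffect_dose(.ANCHORS_16FX$mkm, 16L, n_to, alpha_beta),
    .MKM_LQ_LEM[[as.character(n_to)]],
    scheme = n_to, id = sprintf("%dfx-reconstructed-synthetic", n_to))
}

#' Fixture curve set keyed by fraction number
#'
#' Convenience for [build_constraint_table()] and the command-line tools:
#' the published 16-fraction curve plus reconstructed curves for the
#' requested hypofractionated schemes, as a named list (`"16"`, `"12"`, ...).
#'
#' @param schemes Hypofractionated schemes to include (subset of 12, 8, 4).
#' @inheritParams cirt_fixture_curve
#' @return Named list of [conversion_curve()] objects.
#' @export
cirt_fixture_curves <- function(schemes = c(12, 8, 4),
                                alpha_beta = default_alpha_beta()) {
  stopifnot(all(schemes %in% c(12, 8, 4)))
  out <- c(list(`16` = cirt_fixture_curve("16fx")),
           stats::setNames(lapply(schemes, function(n)
             cirt_fixture_curve(sprintf("%dfx-reconstructed", n),
                                alpha_beta = alpha_beta)),
             as.character(schemes)))
  out
}
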