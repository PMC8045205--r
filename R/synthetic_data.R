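#' @title Seeded synthetic DVHs, cohorts and conversion curves
#' @description Generators for realistic rectal cumulative DVHs
#'   (sigmoid-shaped, optionally noisy, isotonically repaired), DVHs with
#'   prescribed D_x% / D_xcc values, patient cohorts with exactly
#'   controlled constraint-exceedance counts, and plausible monotone
#'   MKM-to-LEM conversion curves.  Everything is deterministic for a
#'   fixed seed; patient `i` of a cohort uses the derived stream
#'   `seed + i`, so growing a cohort never reshuffles earlier patients.
#' @name synthetic_data
NULL

#' Generate a sigmoid-shaped cumulative DVH
#'
#' Relative volume follows a logistic fall-off
#' `1 / (1 + exp((dose - d50) / steepness))` on a fixed dose grid from 0
#' to `tail_dmax`, clamped to 1 at 0 Gy.  Optional Gaussian noise is added
#' and repaired to a valid non-increasing curve with isotonic regression
#' ([stats::isoreg()]).
#'
#' @param d50 Dose at which half the structure volume is covered, Gy (RBE).
#' @param steepness Fall-off width in Gy (RBE); smaller is steeper.
#' @param tail_dmax Upper end of the dose grid in Gy (RBE); must exceed
#'   `d50`.
#' @param noise_sd Standard deviation of additive relative-volume noise
#'   (0 for a clean curve).
#' @param seed Integer seed (only consumed when `noise_sd > 0`).
#' @param structure,total_volume Passed to [dvh()].
#' @param grid_step Dose grid spacing in Gy (RBE); default 0.1, finer than
#'   any tolerance used downstream.
#' @return A [dvh()].
#' @export
generate_dvh <- function(d50, steepness = 5, tail_dmax = d50 * 1.6,
                         noise_sd = 0, seed = 1L, structure = "rectum",
                         total_volume = 50.66, grid_step = 0.1) {
  if (!is.numeric(d50) || d50 <= 0 || !is.numeric(steepness) ||
      steepness <= 0 || !is.numeric(tail_dmax) || tail_dmax <= d50 ||
      !is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid DVH shape parameters: need d50 > 0, steepness > 0, tail_dmax > d50, noise_sd >= 0",
         call. = FALSE)
  dose <- seq(0, tail_dmax, by = grid_step)
  rel <- 1 / (1 + exp((dose - d50) / steepness))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    rel <- rel + stats::rnorm(length(rel), sd = noise_sd)
    rel <- -stats::isoreg(dose, -rel)$yf   # non-increasing repair
  }
  rel <- cummin(pmin(1, pmax(0, rel)))
  rel[1L] <- 1
  dvh(dose, rel, structure = structure, total_volume = total_volume)
}

# "D20%" -> list(kind, volume fraction); "D10cc"/"D_10cc" -> cc
.parse_metric <- function(label) {
  m <- regmatches(label,
                  regexec("^D_?([0-9.]+)\\s*(%|cc)$", trimws(label)))[[1L]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse metric label '%s' (expected e.g. 'D20%%' or 'D10cc')",
                 label), call. = FALSE)
  val <- as.numeric(m[2L])
  if (m[3L] == "%")
    list(kind = "percent-volume", volume_param = val / 100)
  else
    list(kind = "absolute-volume", volume_param = val)
}

#' Generate a cumulative DVH with prescribed metric values
#'
#' Builds a piecewise-linear cumulative curve through the (dose, volume)
#' points implied by the requested metrics, then samples it onto a 0.1 Gy
#' grid augmented with the exact control doses, so every requested metric
#' is reproduced exactly by the measurement functions (well within the
#' 0.05 Gy (RBE) guarantee).
#'
#' @param targets Named numeric vector of metric targets in Gy (RBE),
#'   names parseable as `"D<x>%"` or `"D<x>cc"`, e.g.
#'   `c("D20%" = 37.91, "D10%" = 53.53)`.  Targets must be mutually
#'   consistent: dose must strictly decrease as the volume parameter
#'   increases.
#' @param seed Accepted for interface symmetry; the construction is
#'   deterministic and draws no random numbers.
#' @param structure,total_volume Passed to [dvh()]; `total_volume` is also
#'   used to express `cc` targets as volume fractions.
#' @param grid_step Base dose grid spacing in Gy (RBE).
#' @return A [dvh()] reproducing each target.
#' @export
generate_dvh_with_metrics <- function(targets, seed = 1L,
                                      structure = "rectum",
                                      total_volume = 50.66,
                                      grid_step = 0.1) {
  if (!is.numeric(targets) || is.null(names(targets)) || !length(targets))
    stop("`targets` must be a named numeric vector of metric values",
         call. = FALSE)
  parsed <- lapply(names(targets), .parse_metric)
  frac <- vapply(parsed, function(p)
    if (p$kind == "percent-volume") p$volume_param
    else p$volume_param / total_volume, numeric(1L))
  if (any(frac > 1))
    stop("an absolute-volume target exceeds the structure volume",
         call. = FALSE)
  pts <- data.frame(dose = as.numeric(targets), frac = frac,
                    label = names(targets))
  pts <- pts[order(pts$dose), ]
  if (any(pts$dose <= 0))
    stop("metric targets must be positive doses", call. = FALSE)
  if (any(diff(pts$dose) <= 0) || any(diff(pts$frac) >= 0))
    stop(paste("inconsistent metric targets: dose must strictly decrease",
               "as the volume parameter increases (e.g. D10% > D20%)"),
         call. = FALSE)
  # control polygon: full coverage at 0 Gy, targets, fall to 0 at the tail
  ctrl_d <- c(0, pts$dose)
  ctrl_v <- c(1, pts$frac)
  if (pts$frac[nrow(pts)] > 0) {
    ctrl_d <- c(ctrl_d, max(pts$dose) * 1.05 + 2)
    ctrl_v <- c(ctrl_v, 0)
  }
  dmax <- ctrl_d[length(ctrl_d)]
  dose <- sort(unique(c(seq(0, dmax, by = grid_step), ctrl_d, dmax)))
  rel <- stats::approx(ctrl_d, ctrl_v, xout = dose, ties = "ordered")$y
  dvh(dose, rel, structure = structure, total_volume = total_volume)
}

#' Generate a synthetic patient cohort with controlled exceedances
#'
#' For each constraint label in `exceed_counts`, exactly that many
#' patients exceed the constraint; exceeder sets are nested head-sets
#' (patients `1..k` exceed), so requesting e.g. 8 exceedances of D20% and
#' 4 of D10% makes the 4 D10% exceeders a subset of the 8 D20% exceeders.
#' Exceeding metrics sit `U(0, 2]` Gy (RBE) above the limit; passing
#' metrics sit `U(0.5, 5)` Gy (RBE) below it.  Per-patient metric targets
#' are redrawn (bounded retries, deterministic under the patient stream)
#' until jointly consistent; an impossible pattern raises an error.
#'
#' @param n_patients Cohort size.
#' @param constraints A [constraint_set()] evaluated on the cohort.
#' @param exceed_counts Named integer vector, names among
#'   `constraints$label`; omitted labels get 0 exceedances.
#' @param n_fractions Scheme recorded in the manifest.
#' @param volume_range Rectal volume sampling range in cc (default the
#'   published cohort range 34.59-75.29 cc).
#' @param seed Root seed; patient `i` uses stream `seed + i`.
#' @param id_prefix Patient identifier prefix.
#' @return A list of class `cirt_cohort`: `dvhs` (named list of [dvh()]),
#'   `truth` (data frame `patient_id, metric, true_value, exceeds`),
#'   `manifest` (data frame `patient_id, n_fractions`), and the arguments.
#' @export
generate_cohort <- function(n_patients, constraints, exceed_counts = NULL,
                            n_fractions = 16L,
                            volume_range = c(34.59, 75.29), seed = 1L,
                            id_prefix = "P") {
  stopifnot(inherits(constraints, "constraint_set"), n_patients >= 1)
  counts <- stats::setNames(rep(0L, nrow(constraints)), constraints$label)
  if (!is.null(exceed_counts)) {
    if (is.null(names(exceed_counts)) ||
        !all(names(exceed_counts) %in% constraints$label))
      stop("`exceed_counts` names must match constraint labels",
           call. = FALSE)
    if (any(exceed_counts > n_patients))
      stop("exceedance counts cannot exceed the cohort size", call. = FALSE)
    counts[names(exceed_counts)] <- as.integer(exceed_counts)
  }
  ids <- sprintf("%s%03d", id_prefix, seq_len(n_patients))
  dvhs <- vector("list", n_patients)
  names(dvhs) <- ids
  truth <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(as.integer(seed) + i)      # documented per-patient stream
    vol <- stats::runif(1L, volume_range[1L], volume_range[2L])
    exceeds <- counts >= i              # nested head-set membership
    ok <- FALSE
    for (try in 1:50) {
      tgt <- ifelse(exceeds,
                    constraints$limit + stats::runif(nrow(constraints),
                                                     0, 2),
                    constraints$limit - stats::runif(nrow(constraints),
                                                     0.5,
                                                     pmin(5, 0.9 * constraints$limit)))
      names(tgt) <- constraints$label
      dv <- tryCatch(
        generate_dvh_with_metrics(tgt, structure = "rectum",
                                  total_volume = vol),
        error = function(e) NULL)
      if (!is.null(dv)) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("infeasible joint exceedance pattern for patient %s",
                   ids[i]), call. = FALSE)
    dvhs[[i]] <- dv
    truth[[i]] <- data.frame(patient_id = ids[i],
                             metric = constraints$label,
                             true_value = unname(tgt),
                             exceeds = unname(exceeds),
                             stringsAsFactors = FALSE)
  }
  structure(list(dvhs = dvhs,
                 truth = do.call(rbind, truth),
                 manifest = data.frame(patient_id = ids,
                                       n_fractions = as.integer(n_fractions),
                                       stringsAsFactors = FALSE),
                 constraints = constraints, seed = as.integer(seed)),
            class = "cirt_cohort")
}

#' Fit ratio-decay parameters to two anchor ratios
#'
#' Solves `r = 1 + a * exp(-mkm / b)` through two (dose, ratio) points:
#' `b = (m2 - m1) / log((r1 - 1) / (r2 - 1))`, `a = (r1 - 1) * exp(m1 / b)`.
#'
#' @param mkm Two MKM doses in Gy (RBE).
#' @param ratio Two LEM/MKM dose ratios, both > 1, strictly decreasing in
#'   dose.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
fit_ratio_params <- function(mkm, ratio) {
  stopifnot(length(mkm) == 2L, length(ratio) == 2L)
  if (any(ratio <= 1) || diff(ratio) >= 0 || diff(mkm) <= 0)
    stop("need two anchors with decreasing ratio > 1 at increasing dose",
         call. = FALSE)
  b <- (mkm[2L] - mkm[1L]) / log((ratio[1L] - 1) / (ratio[2L] - 1))
  c(a = (ratio[1L] - 1) * exp(mkm[1L] / b), b = b)
}

#' Generate a plausible MKM-to-LEM conversion curve
#'
#' Anchors on a regular dose grid with
#' `lem = mkm * (1 + a * exp(-mkm / b))`: the LEM/MKM ratio decays with
#' dose, the pattern shown by the published 16-fraction anchors (ratio
#' about 1.50 at 28.8 Gy (RBE) falling to about 1.12 at 60.8 Gy (RBE)).
#' Defaults are fitted to those two extreme anchors.  Non-monotone
#' parameter choices are rejected by [conversion_curve()] validation.
#'
#' @param dose_range MKM anchor dose range in Gy (RBE).
#' @param a,b Ratio-decay parameters, `a >= 0`, `b > 0`.
#' @param spacing Anchor spacing in Gy (RBE).
#' @param scheme Fraction-number label for the curve.
#' @param seed Accepted for interface symmetry; the construction draws no
#'   random numbers.
#' @return A [conversion_curve()].
#' @export
generate_conversion_curve <- function(dose_range = c(25, 65), a = 1.7419,
                                      b = 22.998, spacing = 5,
                                      scheme = NA_integer_, seed = NULL) {
  if (!is.numeric(a) || a < 0 || !is.numeric(b) || b <= 0)
    stop("need a >= 0 and b > 0", call. = FALSE)
  mkm <- seq(dose_range[1L], dose_range[2L], by = spacing)
  lem <- mkm * (1 + a * exp(-mkm / b))
  conversion_curve(mkm, lem, scheme = scheme,
                   id = sprintf("synthetic-a%.3f-b%.2f", a, b))
}
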