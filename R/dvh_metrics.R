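#' @title Cumulative DVH metrics and constraint compliance
#' @description Dose metrics D_x% and D_xcc from cumulative dose-volume
#'   histograms, per-patient constraint compliance, and cohort summaries.
#'   The cumulative DVH convention is: relative volume (fraction of the
#'   structure) receiving at least each dose, linear interpolation between
#'   grid points, and left-most crossing on flat segments (the lowest dose
#'   achieving the volume level -- conservative for organ-at-risk limits).
#' @name dvh_metrics
NULL

#' Construct a cumulative DVH
#'
#' @param dose Strictly increasing dose grid in Gy (RBE), starting at 0.
#' @param rel_volume Relative volumes in `[0, 1]`, non-increasing, with
#'   `rel_volume[1] == 1` (the whole structure receives at least 0 Gy).
#' @param structure Structure name.
#' @param total_volume Total structure volume in cc, strictly positive.
#' @return An object of class `dvh`.
#' @export
dvh <- function(dose, rel_volume, structure = "structure", total_volume) {
  if (!is.numeric(dose) || !is.numeric(rel_volume) ||
      length(dose) != length(rel_volume) || length(dose) < 2L)
    stop("`dose` and `rel_volume` must be numeric vectors of equal length >= 2",
         call. = FALSE)
  if (any(!is.finite(dose)) || any(!is.finite(rel_volume)))
    stop("DVH values must be finite", call. = FALSE)
  if (dose[1L] != 0)
    stop("dose grid must start at 0 Gy", call. = FALSE)
  if (any(diff(dose) <= 0))
    stop("dose grid must be strictly increasing", call. = FALSE)
  if (any(rel_volume < 0) || any(rel_volume > 1))
    stop("relative volumes must lie in [0, 1]", call. = FALSE)
  if (rel_volume[1L] != 1)
    stop("cumulative DVH must start at relative volume 1", call. = FALSE)
  if (any(diff(rel_volume) > 0))
    stop(paste("relative volumes must be non-increasing -- is this a",
               "differential DVH? Convert to cumulative form upstream;",
               "only cumulative DVHs are supported"), call. = FALSE)
  if (!is.numeric(total_volume) || length(total_volume) != 1L ||
      !is.finite(total_volume) || total_volume <= 0)
    stop("`total_volume` must be a single positive volume in cc",
         call. = FALSE)
  structure(list(structure = as.character(structure),
                 total_volume = total_volume,
                 dose = as.numeric(dose), rel_volume = as.numeric(rel_volume)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH: %s (%.2f cc), %d dose points on [0, %.2f] Gy (RBE)\n",
              x$structure, x$total_volume, length(x$dose), max(x$dose)))
  invisible(x)
}

#' Dose received by the hottest fraction of a structure (D_x%)
#'
#' The dose at which the cumulative relative-volume curve crosses level
#' `v`, linearly interpolated and taking the left-most crossing on flat
#' segments.  `v = 0` gives the maximum dose received by any part of the
#' structure (the first dose at which the curve reaches 0, linearly
#' interpolated); if the curve never reaches `v`, the highest recorded
#' dose is returned.  `v = 1` gives 0 Gy.
#'
#' @param x A [dvh()].
#' @param v Volume fraction(s) in `[0, 1]` (e.g. `0.20` for D20%).
#' @return Dose(s) in Gy (RBE); non-increasing in `v`.
#' @export
dose_at_relative_volume <- function(x, v) {
  stopifnot(inherits(x, "dvh"))
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("`v` must be volume fraction(s) in [0, 1]", call. = FALSE)
  vapply(v, function(vi) {
    idx <- match(TRUE, x$rel_volume <= vi)
    if (is.na(idx)) return(x$dose[length(x$dose)])
    if (idx == 1L) return(x$dose[1L])
    v0 <- x$rel_volume[idx - 1L]; v1 <- x$rel_volume[idx]
    d0 <- x$dose[idx - 1L]; d1 <- x$dose[idx]
    d0 + (v0 - vi) / (v0 - v1) * (d1 - d0)
  }, numeric(1L))
}

#' Dose received by the hottest absolute volume (D_xcc)
#'
#' Identical to [dose_at_relative_volume()] at `v_cc / total_volume`.
#'
#' @param x A [dvh()].
#' @param v_cc Absolute volume(s) in cc, in `(0, total_volume]`.  A value
#'   above the structure volume makes the constraint vacuous for this
#'   structure and raises an error (callers evaluating compliance report
#'   such constraints as not evaluable instead of passing them silently).
#' @return Dose(s) in Gy (RBE).
#' @export
dose_at_absolute_volume <- function(x, v_cc) {
  stopifnot(inherits(x, "dvh"))
  if (!is.numeric(v_cc) || any(!is.finite(v_cc)) || any(v_cc <= 0))
    stop("`v_cc` must be positive volume(s) in cc", call. = FALSE)
  if (any(v_cc > x$total_volume))
    stop(sprintf(
      "requested volume %.2f cc exceeds the structure volume %.2f cc; the constraint is not evaluable for this structure",
      max(v_cc), x$total_volume), call. = FALSE)
  dose_at_relative_volume(x, v_cc / x$total_volume)
}

.measure_constraint <- function(x, kind, volume_param) {
  if (kind == "percent-volume")
    dose_at_relative_volume(x, volume_param)
  else
    dose_at_absolute_volume(x, volume_param)
}

#' Evaluate constraint compliance for one patient
#'
#' Measures each constraint's metric on the DVH and compares it with the
#' limit.  Absolute-volume constraints whose volume exceeds the structure
#' volume are reported as not evaluable (`evaluable = FALSE`, `pass = NA`)
#' rather than silently passed.
#'
#' @param x A [dvh()].
#' @param constraints A [constraint_set()] (typically LEM-tagged at the
#'   patient's scheme).
#' @param patient_id Identifier carried as an attribute on the report.
#' @return A data frame of class `compliance_report` with columns `label`,
#'   `metric_kind`, `volume_param`, `limit`, `measured`,
#'   `margin = measured - limit`, `pass` (`margin <= 0`), `evaluable`.
#' @export
evaluate_compliance <- function(x, constraints, patient_id = NA_character_) {
  stopifnot(inherits(x, "dvh"), inherits(constraints, "constraint_set"))
  n <- nrow(constraints)
  measured <- rep(NA_real_, n)
  evaluable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (constraints$metric_kind[i] == "absolute-volume" &&
        constraints$volume_param[i] > x$total_volume) {
      evaluable[i] <- FALSE
      next
    }
    measured[i] <- .measure_constraint(x, constraints$metric_kind[i],
                                       constraints$volume_param[i])
  }
  rep <- data.frame(label = constraints$label,
                    metric_kind = constraints$metric_kind,
                    volume_param = constraints$volume_param,
                    limit = constraints$limit,
                    measured = measured,
                    margin = measured - constraints$limit,
                    pass = measured - constraints$limit <= 0,
                    evaluable = evaluable,
                    stringsAsFactors = FALSE)
  structure(rep, patient_id = patient_id,
            class = c("compliance_report", "data.frame"))
}

#' Summarise compliance reports over a cohort
#'
#' Per constraint label: the median and maximum measured metric over
#' evaluable patients, the exceedance count, and the number of patients
#' for whom the constraint was not evaluable.
#'
#' @param reports List of [evaluate_compliance()] reports with identical
#'   constraint label sets (in order).
#' @return A data frame of class `cohort_summary` with columns `label`,
#'   `limit`, `median_measured`, `max_measured`, `n_exceed`,
#'   `n_not_evaluable`, `n_patients`.
#' @export
cohort_summary <- function(reports) {
  if (!length(reports))
    stop("need at least one compliance report", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1L), "compliance_report")))
  labels <- reports[[1L]]$label
  for (r in reports)
    if (!identical(r$label, labels))
      stop("compliance reports have inconsistent constraint labels",
           call. = FALSE)
  measured <- do.call(cbind, lapply(reports, `[[`, "measured"))
  pass <- do.call(cbind, lapply(reports, `[[`, "pass"))
  structure(data.frame(
    label = labels,
    limit = reports[[1L]]$limit,
    median_measured = apply(measured, 1L, stats::median, na.rm = TRUE),
    max_measured = apply(measured, 1L, max, na.rm = TRUE),
    n_exceed = apply(pass, 1L, function(p) sum(!p, na.rm = TRUE)),
    n_not_evaluable = apply(pass, 1L, function(p) sum(is.na(p))),
    n_patients = length(reports),
    stringsAsFactors = FALSE),
    class = c("cohort_summary", "data.frame"))
}
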