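#' @title Constraint conversion strategies
#' @description Composes the LQ engine and the RBE conversion curves into
#'   the two orderings used to derive hypofractionated LEM rectum
#'   constraints from 16-fraction experience:
#'   \itemize{
#'     \item \strong{MKM LQ}: LQ fractionation conversion first, in MKM
#'       dose space, then MKM-to-LEM conversion with the target scheme's
#'       curve.
#'     \item \strong{LEM LQ}: MKM-to-LEM conversion first, with the
#'       16-fraction curve, then LQ fractionation conversion in LEM space.
#'   }
#'   LEM-native source constraints (the CNAO absolute-volume set) are
#'   first converted backward to MKM for the MKM LQ ordering.
#' @name strategies
NULL

#' Construct a dose constraint
#'
#' One organ-at-risk dose limit at a volume parameter, tagged with the RBE
#' model and fractionation scheme it applies to.
#'
#' @param label Display label, e.g. `"D20%"` or `"D10cc"`.
#' @param metric_kind `"percent-volume"` or `"absolute-volume"`.
#' @param volume_param For percent-volume: volume fraction in `[0, 1]`
#'   (`0` means the near-maximum dose D0%).  For absolute-volume: volume
#'   in cc, strictly positive.
#' @param limit Dose limit in Gy (RBE), strictly positive.
#' @param model RBE model tag, `"MKM"` or `"LEM"`.
#' @param n_fractions Fraction number of the scheme the limit applies to.
#' @return A one-row `constraint_set` data frame.
#' @export
dose_constraint <- function(label, metric_kind = c("percent-volume",
                                                   "absolute-volume"),
                            volume_param, limit, model = c("MKM", "LEM"),
                            n_fractions) {
  metric_kind <- match.arg(metric_kind)
  model <- match.arg(model)
  if (!is.numeric(limit) || length(limit) != 1L || !is.finite(limit) ||
      limit <= 0)
    stop("`limit` must be a single positive dose in Gy (RBE)", call. = FALSE)
  if (!is.numeric(volume_param) || length(volume_param) != 1L ||
      !is.finite(volume_param))
    stop("`volume_param` must be a single finite number", call. = FALSE)
  if (metric_kind == "percent-volume" &&
      (volume_param < 0 || volume_param > 1))
    stop("percent-volume `volume_param` must be a fraction in [0, 1]",
         call. = FALSE)
  if (metric_kind == "absolute-volume" && volume_param <= 0)
    stop("absolute-volume `volume_param` must be > 0 cc", call. = FALSE)
  .check_lq_args(0, n_fractions, 1)
  constraint_set(data.frame(
    label = as.character(label), metric_kind = metric_kind,
    volume_param = volume_param, limit = limit, model = model,
    n_fractions = as.integer(n_fractions), stringsAsFactors = FALSE))
}

#' Construct a constraint set
#'
#' A named, ordered collection of [dose_constraint()]s sharing one RBE
#' model tag and one fractionation scheme.
#'
#' @param ... One-row constraint data frames (or a single data frame with
#'   the constraint columns) to combine.
#' @param name Set name carried as an attribute.
#' @return A data frame of class `constraint_set` with columns `label`,
#'   `metric_kind`, `volume_param`, `limit`, `model`, `n_fractions`.
#' @export
constraint_set <- function(..., name = NULL) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  need <- c("label", "metric_kind", "volume_param", "limit", "model",
            "n_fractions")
  if (!all(need %in% names(df)))
    stop("constraint set must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  if (nrow(df) > 0) {
    if (length(unique(df$model)) != 1L)
      stop("all constraints in a set must share one RBE model tag",
           call. = FALSE)
    if (length(unique(df$n_fractions)) != 1L)
      stop("all constraints in a set must share one fractionation scheme",
           call. = FALSE)
    if (any(df$limit <= 0))
      stop("constraint limits must be > 0 Gy (RBE)", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, name = name %||% attr(parts[[1L]], "name"),
            class = c("constraint_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged 16-fraction rectum constraint-set fixtures
#'
#' @description
#' \itemize{
#'   \item `"nirs-16fx"`: NIRS MKM percentage-volume rectum constraints,
#'     D20/10/5/0 percent limited to 28.80/46.40/56.00/60.80 Gy (RBE).
#'   \item `"nirs-16fx-cnao-cited"`: the NIRS set as cited by CNAO, with
#'     D5 percent limited to 60.00 and D1 percent to 66.00 Gy (RBE).
#'   \item `"cnao-16fx"`: CNAO LEM absolute-volume constraints, D10/5/1 cc
#'     limited to 54.00/61.00/66.00 Gy (RBE).
#'   \item `"nirs-16fx-lem"`: the NIRS percentage-volume set expressed in
#'     LEM via the 16-fraction conversion curve,
#'     43.14/58.48/65.11/68.33 Gy (RBE).
#' }
#'
#' @param name Fixture name.
#' @return A [constraint_set()].
#' @export
cirt_fixture_constraints <- function(name = c("nirs-16fx", "cnao-16fx",
                                              "nirs-16fx-lem",
                                              "nirs-16fx-cnao-cited")) {
  name <- match.arg(name)
  df <- switch(name,
    "nirs-16fx" = data.frame(
      label = c("D20%", "D10%", "D5%", "D0%"),
      metric_kind = "percent-volume",
      volume_param = c(0.20, 0.10, 0.05, 0.00),
      limit = c(28.80, 46.40, 56.00, 60.80),
      model = "MKM", n_fractions = 16L),
    "nirs-16fx-cnao-cited" = data.frame(
      label = c("D20%", "D10%", "D5%", "D1%"),
      metric_kind = "percent-volume",
      volume_param = c(0.20, 0.10, 0.05, 0.01),
      limit = c(28.80, 46.40, 60.00, 66.00),
      model = "MKM", n_fractions = 16L),
    "cnao-16fx" = data.frame(
      label = c("D10cc", "D5cc", "D1cc"),
      metric_kind = "absolute-volume",
      volume_param = c(10, 5, 1),
      limit = c(54.00, 61.00, 66.00),
      model = "LEM", n_fractions = 16L),
    "nirs-16fx-lem" = data.frame(
      label = c("D20%", "D10%", "D5%", "D0%"),
      metric_kind = "percent-volume",
      volume_param = c(0.20, 0.10, 0.05, 0.00),
      limit = c(43.14, 58.48, 65.11, 68.33),
      model = "LEM", n_fractions = 16L))
  constraint_set(df, name = name)
}

.one_constraint <- function(x) {
  if (!inherits(x, "constraint_set") || nrow(x) != 1L)
    stop("expected a single (one-row) dose constraint", call. = FALSE)
  x
}

.check_curve_scheme <- function(curve, n_to) {
  stopifnot(inherits(curve, "conversion_curve"))
  if (!is.na(curve$scheme) && curve$scheme != n_to)
    stop(sprintf("curve <%s> is labelled for %d fractions, not %d",
                 curve$id, curve$scheme, n_to), call. = FALSE)
  invisible(TRUE)
}

.conversion_result <- function(source, limit_to, n_to, strategy,
                               intermediates, curve_id, alpha_beta) {
  target <- source
  target$model <- "LEM"
  target$n_fractions <- as.integer(n_to)
  target$limit <- limit_to
  structure(list(source = source, target = target, strategy = strategy,
                 intermediates = intermediates, curve_id = curve_id,
                 alpha_beta = alpha_beta),
            class = "conversion_result")
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf("%s conversion of %s <= %.2f Gy (RBE) [%s, %d fx]\n",
              gsub("_", " ", x$strategy), x$source$label, x$source$limit,
              x$source$model, x$source$n_fractions))
  for (i in seq_along(x$intermediates))
    cat(sprintf("  %-12s %8.4f Gy (RBE)\n", names(x$intermediates)[i],
                x$intermediates[i]))
  cat(sprintf("  => %s <= %.2f Gy (RBE) [LEM, %d fx]  (curve %s, a/b %.2f Gy)\n",
              x$target$label, x$target$limit, x$target$n_fractions,
              paste(x$curve_id, collapse = "+"), x$alpha_beta))
  invisible(x)
}

#' MKM LQ strategy: LQ first in MKM space, then RBE conversion
#'
#' Converts an MKM-tagged source constraint to the target scheme with
#' [isoeffect_dose()], then maps the result to LEM with the target
#' scheme's conversion curve.
#'
#' @param source A one-row MKM-tagged [dose_constraint()].
#' @param n_to Target fraction number.
#' @param curve [conversion_curve()] for the *target* scheme.
#' @param alpha_beta LQ alpha/beta ratio in Gy.
#' @return A `conversion_result`: target constraint (LEM, `n_to`
#'   fractions) with step-by-step intermediates and provenance.
#' @export
convert_mkm_lq <- function(source, n_to, curve,
                           alpha_beta = default_alpha_beta()) {
  source <- .one_constraint(source)
  if (source$model != "MKM")
    stop("MKM LQ strategy expects an MKM-tagged source constraint",
         call. = FALSE)
  .check_curve_scheme(curve, n_to)
  m_n <- isoeffect_dose(source$limit, source$n_fractions, n_to, alpha_beta)
  l_n <- mkm_to_lem(curve, m_n)
  .conversion_result(
    source, l_n, n_to, "MKM_LQ",
    stats::setNames(c(m_n, l_n),
                    c(sprintf("MKM@%dfx", n_to), sprintf("LEM@%dfx", n_to))),
    curve$id, alpha_beta)
}

#' LEM LQ strategy: RBE conversion first, then LQ in LEM space
#'
#' Maps an MKM-tagged source constraint to LEM with the source scheme's
#' conversion curve, then converts to the target scheme with
#' [isoeffect_dose()].
#'
#' @inheritParams convert_mkm_lq
#' @param curve_from [conversion_curve()] for the *source* scheme
#'   (16 fractions in the published workflow).
#' @return A `conversion_result`.
#' @export
convert_lem_lq <- function(source, n_to, curve_from,
                           alpha_beta = default_alpha_beta()) {
  source <- .one_constraint(source)
  if (source$model != "MKM")
    stop("LEM LQ strategy expects an MKM-tagged source constraint",
         call. = FALSE)
  .check_curve_scheme(curve_from, source$n_fractions)
  l_from <- mkm_to_lem(curve_from, source$limit)
  l_n <- isoeffect_dose(l_from, source$n_fractions, n_to, alpha_beta)
  .conversion_result(
    source, l_n, n_to, "LEM_LQ",
    stats::setNames(c(l_from, l_n),
                    c(sprintf("LEM@%dfx", source$n_fractions),
                      sprintf("LEM@%dfx", n_to))),
    curve_from$id, alpha_beta)
}

#' Adapt a LEM-native source constraint (CNAO workflow)
#'
#' For LEM-tagged sources the LEM LQ ordering is a pure LQ conversion;
#' the MKM LQ ordering first converts the limit backward to MKM with the
#' source scheme's curve, applies LQ in MKM space, then re-converts to LEM
#' with the target scheme's curve.
#'
#' @param source A one-row LEM-tagged [dose_constraint()].
#' @param strategy `"MKM_LQ"` or `"LEM_LQ"`.
#' @param n_to Target fraction number.
#' @param curves Named list of [conversion_curve()]s keyed by fraction
#'   number as character (needs the source scheme's and, for `"MKM_LQ"`,
#'   the target scheme's); may be `NULL` for `"LEM_LQ"`.
#' @param alpha_beta LQ alpha/beta ratio in Gy.
#' @return A `conversion_result`.
#' @export
convert_lem_source <- function(source, strategy = c("LEM_LQ", "MKM_LQ"),
                               n_to, curves = NULL,
                               alpha_beta = default_alpha_beta()) {
  source <- .one_constraint(source)
  strategy <- match.arg(strategy)
  if (source$model != "LEM")
    stop("convert_lem_source() expects a LEM-tagged source constraint",
         call. = FALSE)
  if (strategy == "LEM_LQ") {
    l_n <- isoeffect_dose(source$limit, source$n_fractions, n_to, alpha_beta)
    return(.conversion_result(
      source, l_n, n_to, "LEM_LQ",
      stats::setNames(c(source$limit, l_n),
                      c(sprintf("LEM@%dfx", source$n_fractions),
                        sprintf("LEM@%dfx", n_to))),
      "none (pure LQ)", alpha_beta))
  }
  key_from <- as.character(source$n_fractions)
  key_to <- as.character(n_to)
  if (is.null(curves[[key_from]]) || is.null(curves[[key_to]]))
    stop(sprintf("MKM_LQ adaptation needs curves for %s and %s fractions",
                 key_from, key_to), call. = FALSE)
  .check_curve_scheme(curves[[key_from]], source$n_fractions)
  .check_curve_scheme(curves[[key_to]], n_to)
  m_from <- lem_to_mkm(curves[[key_from]], source$limit)
  m_n <- isoeffect_dose(m_from, source$n_fractions, n_to, alpha_beta)
  l_n <- mkm_to_lem(curves[[key_to]], m_n)
  .conversion_result(
    source, l_n, n_to, "MKM_LQ",
    stats::setNames(c(m_from, m_n, l_n),
                    c(sprintf("MKM@%dfx", source$n_fractions),
                      sprintf("MKM@%dfx", n_to), sprintf("LEM@%dfx", n_to))),
    c(curves[[key_from]]$id, curves[[key_to]]$id), alpha_beta)
}

#' Relative strategy difference in percent
#'
#' `(lem_lq - mkm_lq) / mkm_lq * 100`, the percentage by which the LEM LQ
#' ordering exceeds the MKM LQ ordering for the same constraint.
#'
#' @param lem_lq,mkm_lq Converted limits in Gy (RBE); `mkm_lq` must be
#'   strictly positive.  Vectorised.
#' @return Difference in percent.
#' @export
relative_difference <- function(lem_lq, mkm_lq) {
  if (any(!is.finite(mkm_lq)) || any(mkm_lq <= 0))
    stop("`mkm_lq` must be strictly positive", call. = FALSE)
  (lem_lq - mkm_lq) / mkm_lq * 100
}

#' Build a constraint conversion table
#'
#' One row per source constraint; per requested scheme, the converted
#' limit under each requested strategy plus, when both strategies are
#' present, their relative difference in percent.  Values are kept at full
#' floating precision; rounding happens only when rendering (see
#' [write_constraint_table()]).
#'
#' @param sources A [constraint_set()] (MKM- or LEM-tagged, one scheme).
#' @param schemes Integer vector of target fraction numbers.
#' @param strategies Character subset of `c("MKM_LQ", "LEM_LQ")`.
#' @param curves Named list of curves keyed by fraction number (character);
#'   defaults to the packaged fixtures for 16/12/8/4.
#' @param alpha_beta LQ alpha/beta ratio in Gy.
#' @return A data frame of class `constraint_table` with attribute
#'   `results` holding every underlying `conversion_result` (provenance).
#' @export
build_constraint_table <- function(sources, schemes = c(12, 8, 4),
                                   strategies = c("MKM_LQ", "LEM_LQ"),
                                   curves = cirt_fixture_curves(),
                                   alpha_beta = default_alpha_beta()) {
  stopifnot(inherits(sources, "constraint_set"))
  strategies <- match.arg(strategies, c("MKM_LQ", "LEM_LQ"),
                          several.ok = TRUE)
  out <- data.frame(label = sources$label,
                    source_model = sources$model,
                    source_limit = sources$limit,
                    stringsAsFactors = FALSE)
  results <- list()
  for (n_to in schemes) {
    key <- as.character(n_to)
    cols <- stats::setNames(
      rep(list(rep(NA_real_, nrow(sources))), length(strategies)),
      sprintf("%s_%dfx", tolower(strategies), n_to))
    for (i in seq_len(nrow(sources))) {
      src <- constraint_set(sources[i, , drop = FALSE])
      for (s in strategies) {
        res <- if (src$model == "MKM") {
          if (s == "MKM_LQ") {
            if (is.null(curves[[key]]))
              stop(sprintf("no conversion curve for %d fractions", n_to),
                   call. = FALSE)
            convert_mkm_lq(src, n_to, curves[[key]], alpha_beta)
          } else {
            key_from <- as.character(src$n_fractions)
            if (is.null(curves[[key_from]]))
              stop(sprintf("no conversion curve for %s fractions", key_from),
                   call. = FALSE)
            convert_lem_lq(src, n_to, curves[[key_from]], alpha_beta)
          }
        } else {
          convert_lem_source(src, s, n_to, curves, alpha_beta)
        }
        cols[[sprintf("%s_%dfx", tolower(s), n_to)]][i] <- res$target$limit
        results[[length(results) + 1L]] <- res
      }
    }
    for (nm in names(cols)) out[[nm]] <- cols[[nm]]
    if (all(c("MKM_LQ", "LEM_LQ") %in% strategies))
      out[[sprintf("diff_%dfx_pct", n_to)]] <-
        relative_difference(out[[sprintf("lem_lq_%dfx", n_to)]],
                            out[[sprintf("mkm_lq_%dfx", n_to)]])
  }
  structure(out, results = results, alpha_beta = alpha_beta,
            set_name = attr(sources, "name"),
            class = c("constraint_table", "data.frame"))
}
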