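#' @title File dialects
#' @description Plain-text readers and writers for constraint sets, curve
#'   anchor tables, cumulative DVHs and cohort manifests.  All files are
#'   CSV with `#`-prefixed `key=value` metadata lines where needed;
#'   constraint sets may also be JSON.
#' @name io
NULL

.read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$",
                           meta_lines))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
}

#' Read / write a constraint-set file
#'
#' CSV with columns `label,metric_kind,volume_param,limit_gy_rbe,model,`
#' `n_fractions` (optional `# name=` metadata line), or JSON with the same
#' fields plus an optional top-level `name`.
#'
#' @param path File path; format chosen by extension (`.json` vs CSV).
#' @return [read_constraints()]: a [constraint_set()].
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nm <- NULL
    df <- if (is.data.frame(obj)) obj else { nm <- obj$name; obj$constraints }
    names(df)[names(df) == "limit_gy_rbe"] <- "limit"
    return(constraint_set(df, name = nm))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df)[names(df) == "limit_gy_rbe"] <- "limit"
  constraint_set(df, name = .read_meta(path)[["name"]])
}

#' @rdname read_constraints
#' @param x A [constraint_set()].
#' @export
write_constraints <- function(x, path) {
  stopifnot(inherits(x, "constraint_set"))
  df <- as.data.frame(x)
  names(df)[names(df) == "limit"] <- "limit_gy_rbe"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(name = attr(x, "name"), constraints = df),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    if (!is.null(attr(x, "name")))
      writeLines(sprintf("# name=%s", attr(x, "name")), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write a conversion-curve anchor file
#'
#' CSV with header `mkm_dose_gy_rbe,lem_dose_gy_rbe`, one anchor per row,
#' and a `# scheme=<n>` metadata line naming the fractionation scheme.
#'
#' @param path File path.
#' @param method,extrapolation Passed to [conversion_curve()].
#' @return [read_curve_anchors()]: a [conversion_curve()].
#' @export
read_curve_anchors <- function(path, method = "monotone-cubic",
                               extrapolation = "linear-tail") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("mkm_dose_gy_rbe", "lem_dose_gy_rbe") %in% names(df)))
    stop("curve file needs columns mkm_dose_gy_rbe,lem_dose_gy_rbe",
         call. = FALSE)
  meta <- .read_meta(path)
  scheme <- if (!is.null(meta[["scheme"]]))
    as.integer(sub("fx$", "", meta[["scheme"]])) else NA_integer_
  conversion_curve(df$mkm_dose_gy_rbe, df$lem_dose_gy_rbe, scheme = scheme,
                   method = method, extrapolation = extrapolation,
                   id = meta[["id"]] %||% basename(path))
}

#' @rdname read_curve_anchors
#' @param x A [conversion_curve()].
#' @export
write_curve_anchors <- function(x, path) {
  stopifnot(inherits(x, "conversion_curve"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.na(x$scheme)) writeLines(sprintf("# scheme=%d", x$scheme), con)
  writeLines(sprintf("# id=%s", x$id), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a cumulative DVH file
#'
#' CSV with columns `dose_gy_rbe,relative_volume` plus metadata lines
#' `# structure=<name>` and `# total_volume_cc=<value>`.  Malformed rows
#' are reported with their line number; differential DVHs are rejected
#' with a hint to convert upstream.
#'
#' @param path File path.
#' @return [read_dvh()]: a [dvh()].
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- .read_meta(path)
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("empty DVH file: ", path, call. = FALSE)
  header_line <- body_idx[1L]
  header <- strsplit(trimws(lines[header_line]), ",")[[1L]]
  if (!identical(header[1:2], c("dose_gy_rbe", "relative_volume")))
    stop(sprintf("%s:%d: expected header dose_gy_rbe,relative_volume",
                 path, header_line), call. = FALSE)
  rows <- body_idx[-1L]
  vals <- strsplit(trimws(lines[rows]), ",")
  for (k in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop(sprintf("%s:%d: malformed DVH row '%s'", path, rows[k],
                   lines[rows[k]]), call. = FALSE)
  }
  num <- vapply(vals, function(v) as.numeric(v[1:2]), numeric(2L))
  if (is.null(meta[["total_volume_cc"]]))
    stop("DVH file is missing the '# total_volume_cc=' metadata line: ",
         path, call. = FALSE)
  dvh(num[1L, ], num[2L, ],
      structure = meta[["structure"]] %||% "structure",
      total_volume = as.numeric(meta[["total_volume_cc"]]))
}

#' @rdname read_dvh
#' @param x A [dvh()].
#' @export
write_dvh <- function(x, path) {
  stopifnot(inherits(x, "dvh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# structure=%s", x$structure),
               sprintf("# total_volume_cc=%.4f", x$total_volume)), con)
  utils::write.csv(data.frame(dose_gy_rbe = x$dose,
                              relative_volume = x$rel_volume),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' CSV with columns `patient_id,dvh_file,n_fractions`; `dvh_file` paths
#' are resolved relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @return Data frame with columns `patient_id`, `dvh_file` (absolute),
#'   `n_fractions`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("patient_id", "dvh_file", "n_fractions")
  if (!all(need %in% names(df)))
    stop("manifest needs columns: ", paste(need, collapse = ","),
         call. = FALSE)
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$dvh_file), df$dvh_file,
                file.path(base, df$dvh_file))
  missing <- abs[!file.exists(abs)]
  if (length(missing))
    stop("manifest references missing DVH file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$dvh_file <- abs
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes one DVH CSV per patient, a `manifest.csv`, and a `truth.csv`
#' (`patient_id,metric,true_value,exceeds`) under `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cirt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.csv", cohort$manifest$patient_id)
  for (i in seq_along(cohort$dvhs))
    write_dvh(cohort$dvhs[[i]], file.path(dir, files[i]))
  manifest <- cbind(cohort$manifest[, "patient_id", drop = FALSE],
                    dvh_file = files,
                    n_fractions = cohort$manifest$n_fractions)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
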