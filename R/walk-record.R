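#' @keywords internal
#' @useDynLib gaitsev, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Channel layout of a walk file: 8 left-foot sensors, 8 right-foot sensors,
# then the two per-foot totals. Totals are the sum of their 8 sensors.
VGRF_CHANNELS <- c(paste0("L", 1:8), paste0("R", 1:8), "TotalL", "TotalR")

#' Severity class labels
#'
#' The four-class severity coding used throughout the package: healthy
#' controls plus Hoehn–Yahr stages 2, 2.5 and 3.
#'
#' @return Character vector of the four class labels, in class-index order
#'   (index 0 to 3).
#' @export
severity_levels <- function() {
  c("Healthy", "Severity2", "Severity2.5", "Severity3")
}

#' Map a Hoehn–Yahr stage to a class index
#'
#' Bijective map from the stage coding found in demographics tables
#' (`"healthy"`, `"2"`, `"2.5"`, `"3"`) to the class indices 0–3 used for
#' model targets.
#'
#' @param hoehn_yahr Character or numeric vector of stages.
#' @return Integer vector of class indices in 0..3.
#' @examples
#' label_map(c("healthy", "2", "2.5", "3"))
#' @export
label_map <- function(hoehn_yahr) {
  key <- tolower(trimws(as.character(hoehn_yahr)))
  idx <- match(key, c("healthy", "2", "2.5", "3")) - 1L
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("unknown Hoehn-Yahr stage(s): ", paste(bad, collapse = ", "),
         "; expected one of healthy, 2, 2.5, 3")
  }
  idx
}

#' Construct a walk record
#'
#' A walk record holds one gait recording: a time vector at 100 Hz and a
#' T×18 force matrix (columns `L1..L8`, `R1..R8`, `TotalL`, `TotalR`, in
#' newtons), together with subject-level metadata.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing in steps of 1/`sampling_rate`.
#' @param forces Numeric T×18 matrix of forces in newtons.
#' @param subject_id Subject identifier.
#' @param walk_id Walk identifier (unique within subject).
#' @param study Study tag, one of `"Ga"`, `"Ju"`, `"Si"` (or `"Syn"` for
#'   simulated cohorts).
#' @param group `"PD"` or `"control"`.
#' @param severity Severity label (one of [severity_levels()]) or `NA` if
#'   unknown.
#' @param walk_type Walk protocol tag, e.g. `"normal"` or `"dual"`.
#' @param sampling_rate Samples per second; fixed at 100 for this archive.
#' @param total_tol Absolute tolerance, in newtons, for the consistency
#'   check that `TotalL`/`TotalR` equal the sum of their 8 sensors. Real
#'   files carry rounding, so a violation is a warning, not an error.
#' @param tags Character vector of provenance tags (e.g. augmentation
#'   recipe applied).
#' @return An object of class `walk_record`.
#' @export
walk_record <- function(time, forces, subject_id, walk_id = "w1",
                        study = "Syn", group = c("PD", "control"),
                        severity = NA_character_, walk_type = "normal",
                        sampling_rate = 100, total_tol = 1.0,
                        tags = character()) {
  group <- match.arg(group)
  forces <- as.matrix(forces)
  if (ncol(forces) != 18L)
    stop("forces must have 18 columns, got ", ncol(forces))
  if (length(time) != nrow(forces))
    stop("time length (", length(time), ") != nrow(forces) (",
         nrow(forces), ")")
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0))
      stop("time must be strictly increasing")
    if (max(abs(dt - 1 / sampling_rate)) > 1e-6)
      stop("time step deviates from 1/", sampling_rate, " s by more than 1e-6")
  }
  if (!is.na(severity) && !severity %in% severity_levels())
    stop("severity must be one of ", paste(severity_levels(), collapse = ", "))
  colnames(forces) <- VGRF_CHANNELS
  check_totals(forces, total_tol, id = paste0(subject_id, "/", walk_id))
  structure(list(
    subject_id = as.character(subject_id),
    walk_id = as.character(walk_id),
    study = study,
    group = group,
    severity = severity,
    walk_type = walk_type,
    sampling_rate = sampling_rate,
    time = as.numeric(time),
    forces = forces,
    tags = tags
  ), class = "walk_record")
}

# Totals-consistency check; warning only (real files round to 2 decimals).
check_totals <- function(forces, tol, id = "") {
  dl <- max(abs(forces[, "TotalL"] - rowSums(forces[, 1:8, drop = FALSE])))
  dr <- max(abs(forces[, "TotalR"] - rowSums(forces[, 9:16, drop = FALSE])))
  if (max(dl, dr) > tol)
    warning("walk ", id, ": total-force columns deviate from the sum of ",
            "their sensors by up to ", signif(max(dl, dr), 3), " N ",
            "(tolerance ", tol, " N)", call. = FALSE)
  invisible(max(dl, dr))
}

#' @export
print.walk_record <- function(x, ...) {
  cat(sprintf("<walk_record> subject %s walk %s (%s, %s%s)\n",
              x$subject_id, x$walk_id, x$study, x$group,
              if (!is.na(x$severity)) paste0(", ", x$severity) else ""))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), 18 channels\n",
              nrow(x$forces), x$sampling_rate,
              nrow(x$forces) / x$sampling_rate))
  if (length(x$tags)) cat("  tags:", paste(x$tags, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a walk record
#' @param record A `walk_record`.
#' @return Integer sample count T.
#' @export
n_samples <- function(record) nrow(record$forces)

#' Read one walk file
#'
#' Parses the whitespace-delimited 19-column text dialect used by public
#' plantar-pressure gait archives: time in seconds, then the 18 force
#' channels. Metadata (subject, group, severity) is supplied by the caller,
#' typically from a demographics table.
#'
#' @param path Path to the walk file.
#' @param subject_id,walk_id,study,group,severity,walk_type Metadata
#'   forwarded to [walk_record()].
#' @param total_tol Tolerance for the totals-consistency warning, newtons.
#' @return A `walk_record`.
#' @export
read_walk_file <- function(path, subject_id, walk_id = "w1", study = "Syn",
                           group = "PD", severity = NA_character_,
                           walk_type = "normal", total_tol = 1.0) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("failed to parse walk file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0)
    stop("walk file '", path, "' is empty")
  if (ncol(raw) != 19L)
    stop("walk file '", path, "' has ", ncol(raw),
         " columns; expected 19 (time + 18 channels)")
  walk_record(time = raw[[1]], forces = as.matrix(raw[, -1]),
              subject_id = subject_id, walk_id = walk_id, study = study,
              group = group, severity = severity, walk_type = walk_type,
              total_tol = total_tol)
}

#' Write one walk file
#'
#' Inverse of [read_walk_file()]: writes the 19-column whitespace-delimited
#' text dialect. Numeric content round-trips to the printed precision.
#'
#' @param record A `walk_record`.
#' @param path Output path.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_walk_file <- function(record, path, digits = 6) {
  m <- cbind(record$time, record$forces)
  txt <- apply(m, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Read a demographics table
#'
#' Reads a CSV/TSV with one row per subject carrying at least `subject_id`,
#' `group` and `hoehn_yahr` columns (optional: `study`, `age`, `sex`,
#' `height`, `weight`). Controls must be staged `healthy`; PD subjects with
#' stages outside \{2, 2.5, 3\} are retained but flagged
#' (`severity = NA`) and excluded from the four-class task.
#'
#' @param path Path to the table (comma- or tab-separated, with header).
#' @return A data.frame of subjects with an added `severity` column (one of
#'   [severity_levels()] or `NA`) and a logical `known_stage` column.
#' @export
read_demographics <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "hoehn_yahr")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("demographics table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_subject_table(df)
}

# Normalise a raw subjects data.frame: stage coding, severity labels,
# group/stage consistency checks.
as_subject_table <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  if (!all(df$group %in% c("PD", "control")))
    stop("group column must contain only 'PD' or 'control'")
  stage <- tolower(trimws(as.character(df$hoehn_yahr)))
  known <- stage %in% c("healthy", "2", "2.5", "3")
  bad_ctrl <- df$group == "control" & stage != "healthy"
  bad_pd <- df$group == "PD" & stage == "healthy"
  if (any(bad_ctrl | bad_pd))
    stop("group/stage mismatch for subject(s): ",
         paste(df$subject_id[bad_ctrl | bad_pd], collapse = ", "))
  df$known_stage <- known
  df$severity <- NA_character_
  df$severity[known] <- severity_levels()[label_map(stage[known]) + 1L]
  if (any(!known))
    message(sum(!known), " subject(s) with out-of-range stage flagged ",
            "unknown and excluded from the 4-class task")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in demographics table")
  df
}

#' Assemble a gait dataset
#'
#' Bundles walk records with their demographics table, enforcing that every
#' walk's subject resolves to exactly one subject row and that the walk's
#' severity label matches its subject's.
#'
#' @param walks List of `walk_record` objects.
#' @param subjects Subjects data.frame as returned by [read_demographics()].
#' @return An object of class `gait_dataset` with elements `walks` and
#'   `subjects`.
#' @export
gait_dataset <- function(walks, subjects) {
  stopifnot(is.list(walks), is.data.frame(subjects))
  ids <- vapply(walks, `[[`, "", "subject_id")
  unknown <- setdiff(ids, subjects$subject_id)
  if (length(unknown))
    stop("walk(s) reference unknown subject(s): ",
         paste(unique(unknown), collapse = ", "))
  # labels are a subject-level property: stamp them onto the walks
  sev <- subjects$severity[match(ids, subjects$subject_id)]
  grp <- subjects$group[match(ids, subjects$subject_id)]
  for (i in seq_along(walks)) {
    walks[[i]]$severity <- sev[i]
    walks[[i]]$group <- grp[i]
  }
  structure(list(walks = walks, subjects = subjects),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %d walks, %d subjects\n",
              length(x$walks), nrow(x$subjects)))
  tab <- table(x$subjects$severity, useNA = "ifany")
  cat("  subjects by class:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a dataset to disk in the walk-file dialect
#'
#' Writes each walk as `<subject>_<walk>.txt`, the demographics as
#' `demographics.csv`, and a JSON manifest mapping files to subject and
#' walk ids, so that synthetic and real cohorts share one loader.
#'
#' @param dataset A `gait_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(dataset$walks, function(w) {
    file <- paste0(w$subject_id, "_", w$walk_id, ".txt")
    write_walk_file(w, file.path(dir, file))
    list(file = file, subject_id = w$subject_id, walk_id = w$walk_id,
         study = w$study, walk_type = w$walk_type)
  })
  utils::write.csv(dataset$subjects, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a dataset written by [write_gait_dataset()]
#'
#' @param dir Directory containing `manifest.json`, `demographics.csv` and
#'   the walk files.
#' @param total_tol Totals-consistency tolerance in newtons.
#' @return A `gait_dataset`.
#' @export
read_gait_dataset <- function(dir, total_tol = 1.0) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  subjects <- read_demographics(file.path(dir, "demographics.csv"))
  walks <- lapply(manifest, function(m) {
    row <- subjects[subjects$subject_id == m$subject_id, , drop = FALSE]
    if (nrow(row) != 1)
      stop("manifest subject ", m$subject_id,
           " does not resolve to exactly one demographics row")
    read_walk_file(file.path(dir, m$file), subject_id = m$subject_id,
                   walk_id = m$walk_id, study = m$study, group = row$group,
                   severity = row$severity,
                   walk_type = m$walk_type %||% "normal",
                   total_tol = total_tol)
  })
  gait_dataset(walks, subjects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
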