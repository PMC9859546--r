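#' Read an OpenSim motion-storage (STO/MOT) or delimited text trace
#'
#' Accepts the OpenSim storage dialect — an optional key=value header block
#' terminated by an `endheader` line, then a row of column names, then data —
#' as well as plain CSV/TSV whose first row is the column names. Bodies may be
#' tab- or comma-delimited. The first column must be time in seconds. Units
#' are fixed by convention (s for time, dimensionless activations, N for
#' forces); no unit auto-detection is attempted.
#'
#' @param path Path to the file.
#' @param kind `"activation"` or `"force"`.
#' @param name Trial name; defaults to the file name.
#' @return A [mate_trace()].
#' @seealso [write_motion_storage()]
#' @export
read_motion_storage <- function(path, kind = c("activation", "force"),
                                name = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort_input(sprintf("File not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) > 0]
  end <- grep("^\\s*endheader\\s*$", lines, ignore.case = TRUE)

  declared_ncol <- NA_integer_
  if (length(end) > 0L) {
    header <- lines[seq_len(end[1L] - 1L)]
    body <- lines[-seq_len(end[1L])]
    kv <- grep("=", header, value = TRUE)
    ncol_line <- grep("^\\s*nColumns\\s*=", kv, ignore.case = TRUE, value = TRUE)
    if (length(ncol_line) > 0L) {
      declared_ncol <- suppressWarnings(
        as.integer(sub(".*=\\s*", "", ncol_line[1L])))
      if (is.na(declared_ncol)) {
        abort_input(sprintf("Malformed header line: '%s'", ncol_line[1L]),
                    class = "mate_format_error")
      }
    }
  } else {
    body <- lines
  }
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < 2L) {
    abort_input("File has no data rows after the column-name row.",
                class = "mate_format_error")
  }

  sep <- if (grepl(",", body[1L])) "," else "\t"
  split_row <- function(x) {
    f <- strsplit(x, sep, fixed = TRUE)[[1L]]
    trimws(f[nzchar(trimws(f)) | seq_along(f) <= length(f)])
  }
  cols <- trimws(strsplit(body[1L], if (sep == ",") "," else "[\t ]+")[[1L]])
  cols <- cols[nzchar(cols)]
  if (!is.na(declared_ncol) && length(cols) != declared_ncol) {
    abort_input(sprintf(
      "Header declares nColumns=%d but the column-name row '%s' has %d fields.",
      declared_ncol, body[1L], length(cols)), class = "mate_format_error")
  }

  rows <- lapply(body[-1L], function(line) {
    f <- trimws(strsplit(line, if (sep == ",") "," else "[\t ]+")[[1L]])
    f <- f[nzchar(f)]
    if (length(f) != length(cols)) {
      abort_input(sprintf(
        "Row '%s' has %d fields but the header declares %d columns.",
        line, length(f), length(cols)), class = "mate_format_error")
    }
    vals <- suppressWarnings(as.numeric(f))
    if (anyNA(vals)) {
      abort_input(sprintf("Non-numeric value in row '%s'.", line),
                  class = "mate_format_error")
    }
    vals
  })
  mat <- do.call(rbind, rows)
  df <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(df) <- cols
  names(df)[1L] <- "time"
  mate_trace(df, kind = kind, name = name %||% basename(path))
}

#' Write a trace in motion-storage format
#'
#' Emits a minimal OpenSim-storage header (`nRows`, `nColumns`, `endheader`)
#' followed by a tab-delimited body, so files round-trip through
#' [read_motion_storage()] (values preserved to at least 6 significant
#' digits, channel order preserved).
#'
#' @param trace A [mate_trace()].
#' @param path Output path.
#' @param delim Body delimiter, `"\t"` (default, STO convention) or `","`.
#' @return `path`, invisibly.
#' @export
write_motion_storage <- function(trace, path, delim = "\t") {
  stopifnot(inherits(trace, "mate_trace"))
  if (!delim %in% c("\t", ",")) abort_input("`delim` must be tab or comma.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    attr(trace, "trace_name") %||% "trace",
    sprintf("nRows=%d", nrow(trace)),
    sprintf("nColumns=%d", ncol(trace)),
    "inDegrees=no",
    "endheader",
    paste(names(trace), collapse = delim)
  ), con)
  body <- apply(as.data.frame(trace), 1L, function(r) {
    paste(formatC(r, digits = 9, format = "g"), collapse = delim)
  })
  writeLines(body, con)
  invisible(path)
}

#' Read the task, subject and muscle-group configuration
#'
#' The configuration is a YAML file with three sections: `task` (cycle
#' duration s, repetitions per minute, total duration min, handled mass kg),
#' `subject` (age yr, sex, and either `bmi` or `mass` kg + `height` m) and
#' `muscle_groups` (group name to agonist channel list; entries may be plain
#' channel names or `{channel: ..., side: left|right|central}`). Optional
#' `channels` section names the hip force channels and the L5 compressive
#' channel. When `sex` is absent it defaults to `"female"`, the protective
#' choice since female vertebral strength is lower.
#'
#' @param path Path to the YAML configuration.
#' @return A list with elements `schedule` ([task_schedule()]), `subject`
#'   ([subject_profile()]), `catalog` ([muscle_catalog()]) and `channels`
#'   (list with `hip`, `spine`, possibly `NULL`).
#' @export
read_task_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("task", "subject")) {
    if (is.null(cfg[[key]])) {
      abort_input(sprintf("Config is missing the required `%s` section.", key),
                  class = "mate_missing_key")
    }
  }
  tk <- cfg$task
  for (key in c("cycle_duration", "repetitions_per_minute", "total_duration")) {
    if (is.null(tk[[key]])) {
      abort_input(sprintf("Config `task` is missing `%s`.", key),
                  class = "mate_missing_key")
    }
  }
  schedule <- task_schedule(
    cycle_duration = tk$cycle_duration,
    repetitions_per_minute = tk$repetitions_per_minute,
    total_duration = tk$total_duration,
    handled_mass = tk$handled_mass %||% 0
  )
  sj <- cfg$subject
  if (is.null(sj$age)) {
    abort_input("Config `subject` is missing `age`.", class = "mate_missing_key")
  }
  subject <- subject_profile(
    age = sj$age, sex = sj$sex %||% "female",
    bmi = sj$bmi, mass = sj$mass, height = sj$height
  )
  catalog <- if (!is.null(cfg$muscle_groups)) {
    muscle_catalog(cfg$muscle_groups)
  } else {
    NULL
  }
  channels <- list(hip = cfg$channels$hip, spine = cfg$channels$spine)
  list(schedule = schedule, subject = subject, catalog = catalog,
       channels = channels)
}
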