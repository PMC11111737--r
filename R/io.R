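# Session-log and layout file formats.
#
# Session logs hold one record per fixation: subject_id, fixation_index,
# timestamp, pupil_x, pupil_y, corner_m, corner_n and, when the fixated
# target is known, tx, ty. Two equivalent dialects are supported: JSON Lines
# (one JSON object per line) and CSV with a fixed header.

log_columns <- c("subject_id", "fixation_index", "timestamp",
                 "pupil_x", "pupil_y", "corner_m", "corner_n", "tx", "ty")

#' Read and write session logs
#'
#' @param obs Observation table (as from [observations()]).
#' @param path File path; `.jsonl` for JSON Lines, anything else is CSV.
#' @param format `"jsonl"`, `"csv"`, or `"auto"` (by file extension).
#' @return `write_session_log()`: `path`, invisibly. `read_session_log()`:
#'   an observation `data.frame` (unknown targets read back as `NA`).
#' @export
write_session_log <- function(obs, path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  validate_observations(obs)
  out <- as.data.frame(obs)[, log_columns]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      rec <- as.list(out[i, ])
      rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, path)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "jsonl") {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      r[setdiff(log_columns, names(r))] <- NA
      as.data.frame(r[log_columns], stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(log_columns, names(df))
    if (length(missing) > 0L) {
      stop("session-log CSV lacks columns: ", paste(missing, collapse = ", "))
    }
    df <- df[, log_columns]
  }
  df$fixation_index <- as.integer(df$fixation_index)
  for (col in setdiff(log_columns, c("subject_id", "fixation_index"))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_observations(df)
  df
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
}

#' Read and write interactive-target layouts
#'
#' Layouts are YAML lists of targets: id, centre `(tx, ty)` and the two
#' radii.
#'
#' @param targets List of [interactive_target()] objects.
#' @param path YAML file path.
#' @return `write_target_layout()`: `path`, invisibly;
#'   `read_target_layout()`: a list of `interactive_target`.
#' @export
write_target_layout <- function(targets, path) {
  payload <- lapply(targets, function(t) {
    list(id = t$event_id, tx = t$center[1], ty = t$center[2],
         visual_radius = t$visual_radius, collider_radius = t$collider_radius)
  })
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_target_layout
#' @export
read_target_layout <- function(path) {
  payload <- yaml::read_yaml(path)
  lapply(payload, function(t) {
    interactive_target(c(t$tx, t$ty), visual_radius = t$visual_radius,
                       collider_radius = t$collider_radius, event_id = t$id)
  })
}

#' Write dwell trigger records as JSON Lines
#'
#' @param triggers List of trigger records from [step_dwell()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trigger_log <- function(triggers, path) {
  lines <- vapply(triggers, function(tr) {
    as.character(jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a session replay as CSV
#'
#' Writes per-fixation predictions and errors of an [run_session_replay()]
#' series.
#'
#' @param series An `error_series`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_error_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
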