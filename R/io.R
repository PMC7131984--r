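#' Write a session record to CSV
#'
#' One dialect: UTF-8, comma separated, `.` decimal.  A `# key=value`
#' meta header (the full task configuration is embedded as one JSON
#' line), then `t_ms,x_cm,y_cm,event,payload` rows.  Events are written
#' on the sample row of their timestamp; multiple events on one tick are
#' joined with `|`.  Floating-point columns are written with `%.17g`, so
#' reading the file back reproduces the record bit-exactly.
#'
#' @param record a `session_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  meta <- c(
    sprintf("# subject_id=%s", record$meta$subject_id),
    sprintf("# variant=%s", record$meta$variant),
    sprintf("# seed=%s", record$meta$seed),
    sprintf("# tick_ms=%d", record$meta$tick_ms),
    sprintf("# config=%s",
            as.character(jsonlite::toJSON(unclass_deep(record$config),
                                          auto_unbox = TRUE, digits = NA,
                                          null = "null"))))
  ev_col <- rep("", nrow(record$series))
  pl_col <- rep("", nrow(record$series))
  if (nrow(record$events) > 0L) {
    by_t <- split(record$events, match(record$events$t_ms, record$series$t_ms))
    idx <- as.integer(names(by_t))
    ev_col[idx] <- vapply(by_t, function(e) paste(e$kind, collapse = "|"), "")
    pl_col[idx] <- vapply(by_t, function(e) paste(e$payload, collapse = "|"), "")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(meta, "t_ms,x_cm,y_cm,event,payload"), con)
  body <- paste(sprintf("%.17g", record$series$t_ms),
                sprintf("%.17g", record$series$x_cm),
                sprintf("%.17g", record$series$y_cm),
                ev_col, pl_col, sep = ",")
  writeLines(body, con)
  invisible(path)
}

known_event_kinds <- c("trial_start", "cue_on", "threshold_cross", "reward",
                       "punishment_start", "iti_start", "block_switch")

#' Read a session record from CSV
#'
#' Inverse of [write_session()]: `read_session(write_session(r))` equals
#' `r`.  Also accepts a bare, headerless `t,x,y` stream (no meta block,
#' no events) for analysis-only use, in which case a default
#' configuration is attached.
#'
#' @param path file path.
#' @return a `session_record`.
#' @export
read_session <- function(path) {
  head_lines <- readLines(path, n = 200L)
  n_meta <- 0L
  while (n_meta < length(head_lines) && startsWith(head_lines[n_meta + 1L], "#"))
    n_meta <- n_meta + 1L
  headerless <- n_meta == 0L &&
    grepl("^\\s*-?[0-9]", head_lines[1L])

  if (headerless) {
    dt <- data.table::fread(path, header = FALSE, sep = ",")
    if (ncol(dt) != 3L)
      stop("headerless stream must have exactly 3 columns (t,x,y), found ",
           ncol(dt))
    series <- data.frame(t_ms = as.numeric(dt[[1L]]),
                         x_cm = as.numeric(dt[[2L]]),
                         y_cm = as.numeric(dt[[3L]]))
    check_monotonic(series$t_ms, offset = 0L)
    return(structure(
      list(meta = list(subject_id = "unknown", variant = "center_out",
                       seed = NA_integer_, tick_ms = infer_tick(series$t_ms)),
           series = series,
           events = events_to_df(list()),
           config = task_config()),
      class = "session_record"))
  }

  meta <- parse_meta(head_lines[seq_len(n_meta)])
  # collect parser warnings without interrupting fread (interrupting it
  # mid-parse corrupts its internal state), then escalate to a parse error
  warns <- character()
  dt <- withCallingHandlers(
    data.table::fread(path, skip = n_meta, header = TRUE, sep = ",",
                      colClasses = list(character = c("event", "payload"))),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(warns) > 0L)
    stop("malformed session file ", path, ": ", warns[1L], call. = FALSE)
  req <- c("t_ms", "x_cm", "y_cm", "event", "payload")
  if (!all(req %in% names(dt)))
    stop("malformed header: expected columns ", paste(req, collapse = ","))
  series <- data.frame(t_ms = as.numeric(dt$t_ms),
                       x_cm = as.numeric(dt$x_cm),
                       y_cm = as.numeric(dt$y_cm))
  check_monotonic(series$t_ms, offset = n_meta + 1L)

  has_ev <- which(!is.na(dt$event) & dt$event != "")
  if (length(has_ev) > 0L) {
    kinds <- strsplit(dt$event[has_ev], "|", fixed = TRUE)
    pls <- strsplit(dt$payload[has_ev], "|", fixed = TRUE)
    lens <- lengths(kinds)
    bad <- which(vapply(kinds, function(k) !all(k %in% known_event_kinds),
                        logical(1)))
    if (length(bad) > 0L)
      stop("unknown event code at line ",
           has_ev[bad[1L]] + n_meta + 1L, ": ", dt$event[has_ev[bad[1L]]])
    events <- data.frame(
      t_ms = rep(series$t_ms[has_ev], lens),
      kind = unlist(kinds),
      payload = unlist(pls),
      stringsAsFactors = FALSE)
    events$trial <- as.integer(payload_field(events$payload, "trial"))
    events <- events[, c("t_ms", "kind", "trial", "payload")]
  } else {
    events <- events_to_df(list())
  }

  config <- if (!is.null(meta$config))
    do.call(task_config, prep_task_args(
      jsonlite::fromJSON(meta$config, simplifyVector = TRUE)))
  else task_config()

  structure(
    list(meta = list(subject_id = meta$subject_id %||% "unknown",
                     variant = meta$variant %||% config$variant,
                     seed = suppressWarnings(as.integer(meta$seed)),
                     tick_ms = as.integer(meta$tick_ms %||% config$tick_ms)),
         series = series, events = events, config = config),
    class = "session_record")
}

parse_meta <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  eq <- regexpr("=", lines, fixed = TRUE)
  bad <- which(eq < 0L)
  if (length(bad) > 0L)
    stop("malformed meta line ", bad[1L], ": expected '# key=value'")
  keys <- substr(lines, 1L, eq - 1L)
  vals <- substr(lines, eq + 1L, nchar(lines))
  stats::setNames(as.list(vals), keys)
}

check_monotonic <- function(t, offset) {
  if (length(t) < 2L) return(invisible())
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0L)
    stop("non-monotonic t_ms at line ", bad[1L] + 1L + offset,
         " (t goes from ", t[bad[1L]], " to ", t[bad[1L] + 1L], ")")
  invisible()
}

infer_tick <- function(t) {
  if (length(t) < 2L) return(1L)
  as.integer(round(stats::median(diff(t))))
}

#' Write a reach table to CSV
#'
#' One row per reach: onset, offset, amplitude, peak outward velocity,
#' duration, direction, rewarded flag.
#'
#' @param reaches a `reach_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaches <- function(reaches, path) {
  out <- reaches[, c("onset_ms", "offset_ms", "amplitude_cm",
                     "peak_velocity_cm_s", "duration_ms", "direction_rad",
                     "rewarded")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write a session summary to JSON
#'
#' @param summary a `session_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  invisible(path)
}
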