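# Interchange formats: per-participant event CSVs with a JSON payload
# column, relapse calendar CSV, YAML configs, feature-matrix CSVs.

PAYLOAD_COLS <- c("subtype", "duration", "ax", "ay", "az", "app_id",
                  "lat", "lon", "onset", "wake", "sleep_h")

#' Write an event log as per-participant CSV files
#'
#' Columns: participant_id, channel, timestamp (ISO-8601 UTC), payload
#' (JSON object of channel-specific fields).
#'
#' @param events Event-log data.table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_event_csv <- function(events, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- data.table::as.data.table(events)
  cols <- intersect(PAYLOAD_COLS, names(ev))
  paths <- character(0)
  # vectorized JSON payload construction (row-wise toJSON is far too
  # slow for million-event logs); full double precision via %.17g
  build_payload <- function(sub) {
    parts <- lapply(cols, function(col) {
      v <- sub[[col]]
      if (is.character(v)) {
        out <- paste0('"', col, '":"', v, '"')
      } else {
        out <- paste0('"', col, '":', sprintf("%.17g", v))
      }
      out[is.na(v)] <- NA_character_
      out
    })
    pm <- do.call(cbind, parts)
    apply(pm, 1, function(r) paste0("{", paste(r[!is.na(r)],
                                               collapse = ","), "}"))
  }
  for (pid in unique(ev$participant_id)) {
    sub <- ev[participant_id == pid]
    payload <- build_payload(sub)
    out <- data.table(participant_id = sub$participant_id,
                      channel = sub$channel,
                      timestamp = format(sub$timestamp, "%Y-%m-%dT%H:%M:%OS3Z",
                                         tz = "UTC"),
                      payload = payload)
    p <- file.path(dir, paste0(pid, ".csv"))
    data.table::fwrite(out, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-participant event CSVs back into an event log
#'
#' @param dir Directory of CSVs written by [write_event_csv()].
#' @return Event-log data.table.
#' @export
read_event_csv <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  assert_that(length(files) > 0, "no event CSVs found")
  rbindlist(lapply(files, function(f) {
    raw <- data.table::fread(f, colClasses = list(character = "payload"))
    # fread leaves CSV-doubled quotes inside quoted fields; undo them
    pay <- lapply(gsub('""', '"', raw$payload, fixed = TRUE),
                  function(j) jsonlite::fromJSON(j))
    out <- raw[, .(participant_id, channel,
                   timestamp = as.POSIXct(timestamp,
                                          format = "%Y-%m-%dT%H:%M:%OSZ",
                                          tz = "UTC"))]
    for (col in PAYLOAD_COLS) {
      chr <- col %in% c("subtype", "app_id")
      na_val <- if (chr) NA_character_ else NA_real_
      v <- vapply(pay, function(p) {
        if (is.null(p[[col]])) na_val
        else if (chr) as.character(p[[col]]) else as.numeric(p[[col]])
      }, na_val)
      out[, (col) := v]
    }
    out
  }), fill = TRUE)
}

#' Write a relapse calendar CSV
#' @param relapses data.table (participant_id, relapse_date).
#' @param path Output file.
#' @export
write_calendar_csv <- function(relapses, path) {
  data.table::fwrite(relapses, path)
  invisible(path)
}

#' Read a relapse calendar CSV
#' @param path File written by [write_calendar_csv()].
#' @return data.table with Date-typed relapse_date.
#' @export
read_calendar_csv <- function(path) {
  out <- data.table::fread(path)
  out[, relapse_date := as.Date(relapse_date)]
  out[]
}

#' Save / load a cohort configuration as YAML
#' @param config An `sw_cohort_config`.
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$start_date <- format(x$start_date)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$signature <- x$signature %||% list()
  do.call(cohort_config, x)
}

#' Write an imputed feature matrix (and type-2 flags) as CSV
#' @param imp An `sw_imputed_matrix`.
#' @param path Feature CSV path; the type-2 flag table goes to
#'   `<path>.type2.csv`, the imputation report to `<path>.report.json`.
#' @export
write_feature_csv <- function(imp, path) {
  data.table::fwrite(imp$features, path)
  data.table::fwrite(imp$type2, paste0(path, ".type2.csv"))
  jsonlite::write_json(imp$report, paste0(path, ".report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
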