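## On-disk session format: one directory per session with meta.json,
## signal (CSV or raw little-endian float32), events.tsv and, for RSVP
## sessions, behavior.tsv.

#' Write a session to a directory
#'
#' Serializes an `eeg_session` (and optional behavior log) as
#' `meta.json`, `signal.csv` or `signal.f32` (row-major channels x
#' samples, little-endian 32-bit float), `events.tsv`, and
#' `behavior.tsv`.
#'
#' @param session An `eeg_session`.
#' @param dir Output directory (created if needed).
#' @param behavior Optional behavior log data frame.
#' @param format `"csv"` (plain text, for small fixtures) or `"f32"`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, behavior = NULL,
                          format = c("csv", "f32")) {
  stopifnot(inherits(session, "eeg_session"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(rate = session$rate,
               channel_names = session$channel_names,
               kind = session$kind,
               n_samples = ncol(session$signal),
               signal_format = format)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (format == "csv") {
    utils::write.table(
      t(session$signal), file.path(dir, "signal.csv"),
      sep = ",", row.names = FALSE, col.names = session$channel_names)
  } else {
    con <- file(file.path(dir, "signal.f32"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(session$signal)), con, size = 4,
             endian = "little")
  }
  utils::write.table(session$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(behavior)) {
    utils::write.table(behavior, file.path(dir, "behavior.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a session directory
#'
#' Counterpart of [write_session()].
#'
#' @param dir Session directory.
#' @return List with `session` (an `eeg_session`) and `behavior` (data
#'   frame or `NULL`).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n_ch <- length(meta$channel_names)
  if (identical(meta$signal_format, "f32")) {
    con <- file(file.path(dir, "signal.f32"), "rb")
    on.exit(close(con))
    raw <- readBin(con, what = "numeric", n = n_ch * meta$n_samples,
                   size = 4, endian = "little")
    signal <- t(matrix(raw, nrow = meta$n_samples, ncol = n_ch))
  } else {
    signal <- t(as.matrix(utils::read.csv(file.path(dir, "signal.csv"),
                                          check.names = FALSE)))
  }
  rownames(signal) <- meta$channel_names
  events <- utils::read.delim(file.path(dir, "events.tsv"),
                              stringsAsFactors = FALSE)
  events$character <- as.character(events$character)
  session <- .new_session(signal, meta$rate, meta$channel_names, events,
                          meta$kind)
  beh_path <- file.path(dir, "behavior.tsv")
  behavior <- if (file.exists(beh_path)) {
    b <- utils::read.delim(beh_path, stringsAsFactors = FALSE)
    b$true_target <- as.character(b$true_target)
    b$response <- as.character(b$response)
    b
  } else NULL
  list(session = session, behavior = behavior)
}

#' Validate a session directory
#'
#' Round-trip format check: required files present, signal dimensions
#' consistent with the metadata, events time-sorted and within the
#' recording.
#'
#' @param dir Session directory.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_session_dir <- function(dir) {
  if (!file.exists(file.path(dir, "meta.json"))) stop("meta.json missing")
  loaded <- read_session(dir)
  s <- loaded$session
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (ncol(s$signal) != meta$n_samples) stop("sample count mismatch")
  if (nrow(s$signal) != length(meta$channel_names)) {
    stop("channel count mismatch")
  }
  if (is.unsorted(s$events$sample)) stop("events not time-sorted")
  if (any(s$events$sample < 0 | s$events$sample >= ncol(s$signal))) {
    stop("event outside the recording")
  }
  invisible(TRUE)
}
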