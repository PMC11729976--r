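# Trace file I/O. A recording is stored as a pair of files:
#   <name>.csv  - header `time_ms,pointer_id,phase,x_px,y_px`, one sample/row
#   <name>.json - versioned sidecar with item, input kind, calibration,
#                 layout (cm) and metadata
# Coordinates are written with 17 significant digits so that doubles
# round-trip exactly.

TRACE_HEADER <- "time_ms,pointer_id,phase,x_px,y_px"

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to the shortest representation that still round-trips
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a trace recording to disk
#'
#' Emits the sample CSV at `path` and the JSON sidecar next to it (same name,
#' `.json` extension). Recordings in physical units are converted back to
#' pixels with their own calibration so that the on-disk format is always raw.
#' The emitted pair round-trips through [parse_recording()] exactly.
#'
#' @param rec a [trace_recording()].
#' @param path path of the CSV file to write.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "trace_recording"))
  rec <- to_pixels(rec)
  s <- rec$samples
  lines <- c(TRACE_HEADER,
             if (nrow(s)) sprintf("%d,%d,%s,%s,%s", s$time_ms, s$pointer_id,
                                  s$phase, fmt_num(s$x), fmt_num(s$y)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  side <- list(
    format_version = "1.0",
    item_id = rec$item_id,
    input_kind = rec$input_kind,
    calibration = calibration_to_list(rec$calibration),
    layout = layout_to_list(rec$layout),
    metadata = rec$metadata
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse a trace recording from disk
#'
#' Reads the sample CSV and its JSON sidecar and returns a validated
#' [trace_recording()]. Malformed rows raise an input error naming the line;
#' invariant violations (e.g. a `move` before any `down`) raise a validation
#' error naming the offending pointer and time.
#'
#' @param path path of the CSV file.
#' @param sidecar path of the sidecar JSON; defaults to `path` with a `.json`
#'   extension.
#' @return a [trace_recording()].
#' @export
parse_recording <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop_input("trace file not found: %s", path)
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  if (!file.exists(sidecar)) stop_input("sidecar not found: %s", sidecar)

  side <- tryCatch(jsonlite::read_json(sidecar),
                   error = function(e) stop_input(
                     "malformed sidecar %s: %s", sidecar, conditionMessage(e)))
  lines <- readLines(path)
  if (!length(lines) || lines[1] != TRACE_HEADER) {
    stop_input("%s: line 1 must be the header '%s'", path, TRACE_HEADER)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 5)) {
      bad <- which(nf != 5)[1]
      stop_input("%s: malformed row at line %d (expected 5 fields, got %d)",
                 path, bad + 1L, nf[bad])
    }
    m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
    num <- suppressWarnings(cbind(as.numeric(m[, 1]), as.numeric(m[, 2]),
                                  as.numeric(m[, 4]), as.numeric(m[, 5])))
    if (anyNA(num)) {
      bad <- which(apply(is.na(num), 1, any))[1]
      stop_input("%s: malformed row at line %d (non-numeric field)", path, bad + 1L)
    }
    samples <- data.frame(time_ms = num[, 1], pointer_id = num[, 2],
                          phase = m[, 3], x = num[, 3], y = num[, 4],
                          stringsAsFactors = FALSE)
  } else {
    samples <- data.frame(time_ms = integer(0), pointer_id = integer(0),
                          phase = character(0), x = numeric(0), y = numeric(0))
  }

  metadata <- side$metadata
  if (is.null(metadata)) metadata <- list()
  trace_recording(
    item_id = side$item_id,
    samples = samples,
    layout = layout_from_list(side$layout),
    calibration = calibration_from_list(side$calibration),
    input_kind = side$input_kind,
    metadata = metadata,
    unit = "px"
  )
}

#' Write automatic scores as CSV
#'
#' One row per recording with the score and all evidence measures; the
#' machine-readable audit companion of [score_recordings()].
#'
#' @param scores data.frame as returned by [score_recordings()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
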