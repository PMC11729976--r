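# Trace recordings: one item attempt as an ordered log of touch samples.

PHASES <- c("down", "move", "up")

#' Construct a trace recording
#'
#' A trace recording is one attempt at an item: an ordered table of touch
#' samples (`time_ms`, `pointer_id`, `phase`, `x`, `y`) together with the
#' device calibration, the support layout and free-form metadata. Raw
#' recordings are in device pixels (`unit = "px"`, y growing downward per the
#' calibration); [to_physical()] converts to the y-up cm frame shared with
#' the layout.
#'
#' Sample invariants are enforced: per pointer, time is non-decreasing and the
#' contact life cycle is `down` then zero or more `move` then `up` (a pointer
#' still down when the log ends is tolerated and flagged downstream, since
#' real logs truncate). Multi-touch is supported through interleaved
#' pointer ids.
#'
#' @param item_id 18, 19 or 22; must match `layout$item_id`.
#' @param samples data.frame with columns `time_ms` (non-negative ms),
#'   `pointer_id` (non-negative integer), `phase` (`down`/`move`/`up`),
#'   `x`, `y` (coordinates in `unit`). Zero rows allowed.
#' @param layout an `item_layout` for the item.
#' @param calibration a [device_calibration()].
#' @param input_kind `"finger"` or `"stylus"`. Item 19 is performed with the
#'   stylus; a finger recording for item 19 raises a warning, not an error.
#' @param metadata named list (subject pseudo-id, session, seed, ...).
#' @param unit `"px"` (raw) or `"cm"` (physical).
#' @return an object of class `trace_recording`.
#' @export
trace_recording <- function(item_id, samples, layout,
                            calibration = device_calibration(),
                            input_kind = c("finger", "stylus"),
                            metadata = list(), unit = c("px", "cm")) {
  input_kind <- match.arg(input_kind)
  unit <- match.arg(unit)
  item_id <- as.integer(item_id)
  if (!item_id %in% c(18L, 19L, 22L)) {
    stop_validation("item_id must be 18, 19 or 22 (got %s)", item_id)
  }
  stopifnot(inherits(layout, "item_layout"), inherits(calibration, "device_calibration"))
  if (layout$item_id != item_id) {
    stop_validation("layout is for item %d but recording declares item %d",
                    layout$item_id, item_id)
  }
  samples <- check_samples(samples, calibration, unit)
  if (item_id == 19L && input_kind != "stylus") {
    warning("item 19 recordings are normally made with the stylus", call. = FALSE)
  }
  structure(
    list(item_id = item_id, input_kind = input_kind,
         calibration = calibration, layout = layout,
         samples = samples, metadata = metadata, unit = unit),
    class = "trace_recording"
  )
}

check_samples <- function(samples, calibration, unit) {
  need <- c("time_ms", "pointer_id", "phase", "x", "y")
  if (!is.data.frame(samples)) stop_validation("samples must be a data.frame")
  if (!all(need %in% names(samples))) {
    stop_validation("samples must have columns %s", paste(need, collapse = ", "))
  }
  samples <- as.data.frame(samples)[need]
  rownames(samples) <- NULL
  if (nrow(samples) == 0) {
    samples$time_ms <- integer(0); samples$pointer_id <- integer(0)
    samples$phase <- character(0)
    samples$x <- numeric(0); samples$y <- numeric(0)
    return(samples)
  }
  samples$time_ms <- as.integer(round(samples$time_ms))
  samples$pointer_id <- as.integer(samples$pointer_id)
  samples$phase <- as.character(samples$phase)
  samples$x <- as.numeric(samples$x)
  samples$y <- as.numeric(samples$y)
  if (anyNA(samples)) stop_validation("samples contain missing values")
  if (any(samples$time_ms < 0)) stop_validation("time_ms must be non-negative")
  if (any(samples$pointer_id < 0)) stop_validation("pointer_id must be non-negative")
  bad <- which(!samples$phase %in% PHASES)
  if (length(bad)) {
    stop_validation("invalid phase '%s' at sample %d", samples$phase[bad[1]], bad[1])
  }
  if (is.unsorted(samples$time_ms)) {
    stop_validation("samples must be in non-decreasing time order")
  }
  if (unit == "px") {
    if (any(samples$x < 0 | samples$x > calibration$screen_w_px |
            samples$y < 0 | samples$y > calibration$screen_h_px)) {
      stop_validation("pixel coordinates fall outside the %g x %g screen",
                      calibration$screen_w_px, calibration$screen_h_px)
    }
  }
  # Per-pointer life cycle: down -> move* -> up, repeatable; trailing open ok.
  for (pid in unique(samples$pointer_id)) {
    ph <- samples$phase[samples$pointer_id == pid]
    tm <- samples$time_ms[samples$pointer_id == pid]
    if (is.unsorted(tm)) {
      stop_validation("pointer %d samples are not time-ordered", pid)
    }
    open <- FALSE
    for (k in seq_along(ph)) {
      if (ph[k] == "down") {
        if (open) stop_validation(
          "pointer %d: 'down' at t=%d ms while already down", pid, tm[k])
        open <- TRUE
      } else {
        if (!open) stop_validation(
          "pointer %d: '%s' at t=%d ms before any 'down'", pid, ph[k], tm[k])
        if (ph[k] == "up") open <- FALSE
      }
    }
  }
  samples
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("<trace_recording> item %d (%s), %d samples [%s], %d pointer(s)\n",
              x$item_id, x$input_kind, nrow(x$samples), x$unit,
              length(unique(x$samples$pointer_id))))
  invisible(x)
}

#' Split a recording into strokes
#'
#' A stroke is one pointer's contiguous contact episode, from a `down` sample
#' to its matching `up`. Strokes are returned in order of their start time;
#' every sample belongs to exactly one stroke. A pointer still down at the end
#' of the log is closed at its last sample and flagged (`open = TRUE`).
#'
#' @param rec a [trace_recording()].
#' @return list of `mfm_stroke` objects, each with `pointer_id`, `samples`,
#'   `open`, `start_ms`, `end_ms`, `duration_ms` and `path_length` (in the
#'   recording's unit).
#' @export
split_strokes <- function(rec) {
  stopifnot(inherits(rec, "trace_recording"))
  s <- rec$samples
  strokes <- list()
  if (nrow(s)) {
    open_idx <- list() # pointer id (as character) -> row indices of open stroke
    close_stroke <- function(idx, open) {
      st <- s[idx, , drop = FALSE]
      rownames(st) <- NULL
      structure(
        list(pointer_id = st$pointer_id[1], samples = st, open = open,
             start_ms = st$time_ms[1], end_ms = st$time_ms[nrow(st)],
             duration_ms = st$time_ms[nrow(st)] - st$time_ms[1],
             path_length = path_length(st[, c("x", "y")])),
        class = "mfm_stroke"
      )
    }
    for (i in seq_len(nrow(s))) {
      key <- as.character(s$pointer_id[i])
      open_idx[[key]] <- c(open_idx[[key]], i)
      if (s$phase[i] == "up") {
        strokes[[length(strokes) + 1L]] <- close_stroke(open_idx[[key]], FALSE)
        open_idx[[key]] <- NULL
      }
    }
    for (key in names(open_idx)) {
      strokes[[length(strokes) + 1L]] <- close_stroke(open_idx[[key]], TRUE)
    }
    strokes <- strokes[order(vapply(strokes, `[[`, numeric(1), "start_ms"))]
  }
  strokes
}

#' @export
print.mfm_stroke <- function(x, ...) {
  cat(sprintf("<mfm_stroke> pointer %d, %d samples, %d ms, path %.2f%s\n",
              x$pointer_id, nrow(x$samples), x$duration_ms, x$path_length,
              if (x$open) " (closed at log end)" else ""))
  invisible(x)
}

#' Convert a recording between pixel and physical coordinates
#'
#' `to_physical()` maps raw pixel samples into the y-up cm frame the layout
#' lives in: `x_cm = x_px / px_per_cm` and, for the usual `y_axis = "down"`
#' convention, `y_cm = (screen_h_px - y_px) / px_per_cm`, so pixel row 0 maps
#' to the top of the physical frame. `to_pixels()` is its inverse under the
#' same calibration.
#'
#' @param rec a [trace_recording()].
#' @return the recording with converted coordinates and updated `unit`.
#' @export
to_physical <- function(rec) {
  stopifnot(inherits(rec, "trace_recording"))
  if (rec$unit == "cm") return(rec)
  cal <- rec$calibration
  if (is.null(cal)) stop_input("recording has no calibration")
  rec$samples$x <- rec$samples$x / cal$px_per_cm
  rec$samples$y <- if (cal$y_axis == "down") {
    (cal$screen_h_px - rec$samples$y) / cal$px_per_cm
  } else {
    rec$samples$y / cal$px_per_cm
  }
  rec$unit <- "cm"
  rec
}

#' @rdname to_physical
#' @export
to_pixels <- function(rec) {
  stopifnot(inherits(rec, "trace_recording"))
  if (rec$unit == "px") return(rec)
  cal <- rec$calibration
  if (is.null(cal)) stop_input("recording has no calibration")
  rec$samples$x <- rec$samples$x * cal$px_per_cm
  rec$samples$y <- if (cal$y_axis == "down") {
    cal$screen_h_px - rec$samples$y * cal$px_per_cm
  } else {
    rec$samples$y * cal$px_per_cm
  }
  rec$unit <- "px"
  rec
}

#' Quality-control warnings for a recording
#'
#' Screens a parsed recording for conditions that degrade automatic scoring
#' without invalidating the file: the layout placed within `edge_margin_cm`
#' of the screen border (near the border, pixel recording can fail), a
#' pointer left open at the end of the log, sampling gaps longer than
#' `gap_ms` inside a stroke, and an empty sample table.
#'
#' @param rec a [trace_recording()].
#' @param edge_margin_cm minimum clearance between the drawn support and the
#'   screen border (cm).
#' @param gap_ms within-stroke sampling gap threshold (ms).
#' @return data.frame with columns `code` and `message`; zero rows when clean.
#' @export
validate_recording <- function(rec, edge_margin_cm = 0.5, gap_ms = 500) {
  stopifnot(inherits(rec, "trace_recording"))
  out <- list()
  add <- function(code, msg) out[[length(out) + 1L]] <<- data.frame(
    code = code, message = msg, stringsAsFactors = FALSE)

  sz <- screen_size_cm(rec$calibration)
  bb <- layout_bbox(rec$layout)
  clearance <- min(bb[1], bb[2], sz[1] - bb[3], sz[2] - bb[4])
  if (clearance < edge_margin_cm) {
    add("edge_margin", sprintf(
      "layout is %.2f cm from the screen border (< %.2f cm); pixel recording may fail near the edge",
      clearance, edge_margin_cm))
  }
  if (nrow(rec$samples) == 0) {
    add("no_samples", "recording contains no samples")
  } else {
    for (st in split_strokes(rec)) {
      if (st$open) {
        add("open_pointer", sprintf(
          "pointer %d is still down at the end of the recording", st$pointer_id))
      }
      if (nrow(st$samples) > 1) {
        gaps <- diff(st$samples$time_ms)
        if (any(gaps > gap_ms)) {
          add("sampling_gap", sprintf(
            "pointer %d stroke has a %d ms sampling gap (> %d ms)",
            st$pointer_id, max(gaps), as.integer(gap_ms)))
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(code = character(0), message = character(0),
               stringsAsFactors = FALSE)
  }
}
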