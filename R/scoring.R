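# Automatic 0-3 scoring (A-score). Each scorer walks the item's rubric as a
# top-down decision tree over geometric evidence computed from the physical
# trace, and returns the score together with every measure that justified it.
# Scoring is fully deterministic. The trees are a faithful implementation of
# the published rubric wording with declared parameters; they are not claimed
# to be bit-identical to any particular recording software's internals.

new_auto_score <- function(item_id, score, evidence, params) {
  structure(
    list(item_id = as.integer(item_id), score = as.integer(score),
         evidence = evidence, params = params),
    class = "auto_score"
  )
}

#' @export
print.auto_score <- function(x, ...) {
  cat(sprintf("<auto_score> item %d: score %d\n", x$item_id, x$score))
  ev <- x$evidence
  for (nm in names(ev)) {
    v <- ev[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.logical(v)) as.character(v) else format(v, digits = 4)))
  }
  invisible(x)
}

check_item <- function(rec, id) {
  stopifnot(inherits(rec, "trace_recording"))
  if (rec$item_id != id) {
    stop_validation("recording is for item %d, not item %d", rec$item_id, id)
  }
  if (is.null(rec$layout)) stop_input("recording has no layout")
}

total_pauses <- function(strokes, params) {
  sum(vapply(strokes, function(st) {
    nrow(detect_pauses(st, params$v_pause_cm_s, params$pause_min_ms))
  }, numeric(1)))
}

#' Score item 18: circumnavigating the CD
#'
#' The subject starts with a finger at the centre of the CD and must go round
#' its outer edge. Decision tree, evaluated top-down on the physical trace:
#'
#' * **3** - some single stroke (one pointer, one contact) sweeps a net angle
#'   of at least `theta_complete_deg` about the CD centre while keeping
#'   `min_radius >= r_large - eps_in_cm` (the finger goes *around* the disc,
#'   never into it beyond tolerance), `max_radius <= r_large + band_out_cm`
#'   (it stays near the edge), with no pauses;
#' * **2** - the pooled strokes still achieve the net sweep inside the wide
#'   annulus `[r_small + band_small_cm, r_large + band_out_cm]`, but some
#'   score-3 condition fails (entries into the disc, pauses, several strokes
#'   or a finger change);
#' * **1** - circumnavigation of the small centre circle: net sweep achieved
#'   with a median radius at most `r_small + band_small_cm`;
#' * **0** - otherwise (including an empty recording).
#'
#' @param rec a [trace_recording()] for item 18 (pixel or physical units).
#' @param params a [scoring_params()].
#' @return an `auto_score` with evidence fields `net_sweep_deg`,
#'   `min_radius_cm`, `median_radius_cm`, `max_radius_cm`, `n_pauses`,
#'   `n_strokes`, `n_pointer_changes`.
#' @export
score_item18 <- function(rec, params = scoring_params()) {
  check_item(rec, 18L)
  phys <- to_physical(rec)
  lay <- phys$layout
  center <- lay$center
  strokes <- split_strokes(phys)
  s <- phys$samples

  evidence <- list(net_sweep_deg = 0, min_radius_cm = NA_real_,
                   median_radius_cm = NA_real_, max_radius_cm = NA_real_,
                   n_pauses = 0L, n_strokes = length(strokes),
                   n_pointer_changes = max(0L, length(unique(s$pointer_id)) - 1L))
  if (nrow(s)) {
    r_all <- sqrt((s$x - center[1])^2 + (s$y - center[2])^2)
    evidence$min_radius_cm <- min(r_all)
    evidence$median_radius_cm <- stats::median(r_all)
    evidence$max_radius_cm <- max(r_all)
  }
  evidence$n_pauses <- as.integer(total_pauses(strokes, params))

  # score 3: a single clean stroke around the disc edge
  for (st in strokes) {
    if (nrow(st$samples) < 2) next
    sw <- angular_sweep(st$samples[, c("x", "y")], center)
    if (abs(sw$net_sweep_deg) >= params$theta_complete_deg &&
        sw$min_radius_cm >= lay$r_large - params$eps_in_cm &&
        sw$max_radius_cm <= lay$r_large + params$band_out_cm &&
        nrow(detect_pauses(st, params$v_pause_cm_s, params$pause_min_ms)) == 0) {
      evidence$net_sweep_deg <- sw$net_sweep_deg
      evidence$min_radius_cm <- sw$min_radius_cm
      evidence$median_radius_cm <- sw$median_radius_cm
      evidence$max_radius_cm <- sw$max_radius_cm
      return(new_auto_score(18L, 3L, evidence, params))
    }
  }

  if (nrow(s) >= 2) {
    # score 2: cumulative circumnavigation within the wide annulus
    r_lo <- lay$r_small + params$band_small_cm
    r_hi <- lay$r_large + params$band_out_cm
    r_all <- sqrt((s$x - center[1])^2 + (s$y - center[2])^2)
    in_ann <- s[r_all >= r_lo & r_all <= r_hi, , drop = FALSE]
    if (nrow(in_ann) >= 2) {
      sw2 <- angular_sweep(in_ann[, c("x", "y")], center)
      if (abs(sw2$net_sweep_deg) >= params$theta_complete_deg) {
        evidence$net_sweep_deg <- sw2$net_sweep_deg
        return(new_auto_score(18L, 2L, evidence, params))
      }
    }
    # score 1: circumnavigation of the small circle
    sw1 <- angular_sweep(s[, c("x", "y")], center)
    evidence$net_sweep_deg <- sw1$net_sweep_deg
    if (abs(sw1$net_sweep_deg) >= params$theta_complete_deg &&
        sw1$median_radius_cm <= lay$r_small + params$band_small_cm) {
      return(new_auto_score(18L, 1L, evidence, params))
    }
  }
  new_auto_score(18L, 0L, evidence, params)
}

# Loop analysis of one stroke against the frame. A loop is a completed
# alternation pair between the top and bottom contact bands: a visit
# sequence top-bottom-top (or its reverse) counts one loop.
stroke_loops19 <- function(st, lay, params) {
  frame <- region_rect(lay$origin[1], lay$origin[2],
                       lay$origin[1] + lay$width, lay$origin[2] + lay$height,
                       line_w = lay$line_w)
  cls <- region_contacts(st$samples[, c("x", "y")], frame, tol = params$tau_line_cm)
  inside <- st$samples[cls != "outside", , drop = FALSE]
  y_top <- lay$origin[2] + lay$height
  y_bot <- lay$origin[2]
  band <- character(0)
  if (nrow(inside)) {
    lab <- ifelse(inside$y >= y_top - params$tau_touch_cm, "T",
                  ifelse(inside$y <= y_bot + params$tau_touch_cm, "B", NA))
    band <- lab[!is.na(lab)]
    band <- band[c(TRUE, band[-1] != band[-length(band)])]
  }
  n_loops <- max(0L, (length(band) - 1L) %/% 2L)
  coverage <- if (nrow(inside) >= 2) {
    x_coverage(inside[, c("x", "y")], c(lay$origin[1], lay$origin[1] + lay$width))
  } else 0
  list(n_loops = n_loops, coverage = coverage,
       exited = any(cls == "outside"),
       n_pauses = nrow(detect_pauses(st, params$v_pause_cm_s, params$pause_min_ms)))
}

#' Score item 19: drawing loops in the frame
#'
#' The subject draws loops inside the 1 x 4 cm frame with the stylus. "Ink"
#' is the total path length of all strokes; a loop is a completed alternation
#' between the top and bottom contact bands (within `tau_touch_cm` of the
#' interior edges). Decision tree:
#'
#' * **0** - ink below `min_ink_cm` (no written mark; pencil grasp is not
#'   observable on a tablet, so "cannot pick up the pencil" collapses to
#'   "no ink");
#' * **3** - one stroke draws at least `min_loops_full` loops, spans at least
#'   `coverage_frac` of the frame width, never pauses and never leaves the
#'   frame beyond `tau_line_cm`;
#' * **2** - at least one loop in total, but the score-3 conditions fail;
#' * **1** - a written mark with no completed loop.
#'
#' A non-stylus recording is scored anyway, with a warning.
#'
#' @param rec a [trace_recording()] for item 19.
#' @param params a [scoring_params()].
#' @return an `auto_score` with evidence fields `ink_cm`, `n_loops`,
#'   `x_coverage_frac`, `exited_frame`, `n_pauses`, `n_strokes`.
#' @export
score_item19 <- function(rec, params = scoring_params()) {
  check_item(rec, 19L)
  if (rec$input_kind != "stylus") {
    warning("item 19 recording was not made with the stylus; scoring anyway",
            call. = FALSE)
  }
  phys <- to_physical(rec)
  lay <- phys$layout
  strokes <- split_strokes(phys)
  ink <- sum(vapply(strokes, `[[`, numeric(1), "path_length"))

  loops <- lapply(strokes, stroke_loops19, lay = lay, params = params)
  n_loops <- sum(vapply(loops, `[[`, integer(1), "n_loops"))
  evidence <- list(
    ink_cm = ink, n_loops = as.integer(n_loops),
    x_coverage_frac = if (length(loops)) max(vapply(loops, `[[`, numeric(1), "coverage")) else 0,
    exited_frame = any(vapply(loops, `[[`, logical(1), "exited")),
    n_pauses = as.integer(sum(vapply(loops, `[[`, numeric(1), "n_pauses"))),
    n_strokes = length(strokes)
  )

  if (ink < params$min_ink_cm) {
    return(new_auto_score(19L, 0L, evidence, params))
  }
  full <- vapply(loops, function(l) {
    l$n_loops >= params$min_loops_full &&
      l$coverage >= params$coverage_frac &&
      l$n_pauses == 0 && !l$exited
  }, logical(1))
  if (any(full)) {
    return(new_auto_score(19L, 3L, evidence, params))
  }
  if (n_loops >= 1) {
    return(new_auto_score(19L, 2L, evidence, params))
  }
  new_auto_score(19L, 1L, evidence, params)
}

#' Score item 22: lift-and-place on the diagram
#'
#' The subject starts with a finger on the centre of the diagram and must
#' lift it and place it on each of the 8 drawings. Strokes are classified as
#' taps (duration <= `tap_max_ms` and path <= `tap_max_path_cm`) or slides.
#' A tap hits a target *precisely* when all its samples are interior to that
#' target; *imprecisely* when it touches the target's boundary band or only
#' partly lies inside. A slide covers a target when any sample is interior.
#' A lift is deemed to have occurred when the recording contains at least two
#' strokes. Decision tree:
#'
#' * **3** - a lift occurred and all 8 distinct targets were precisely hit by
#'   taps ("without touching the lines");
#' * **2** - a lift occurred and at least one target was hit by a tap,
#'   precisely or imprecisely, but score 3 fails;
#' * **1** - no tap hit any target, but a slide covered at least one target
#'   (the subject cannot lift but can slide);
#' * **0** - otherwise.
#'
#' A first contact outside the start zone raises a warning, not a score
#' change.
#'
#' @param rec a [trace_recording()] for item 22.
#' @param params a [scoring_params()].
#' @return an `auto_score` with evidence fields `n_targets_precise`,
#'   `n_targets_imprecise`, `n_targets_slid`, `lifted`, `n_taps`, `n_slides`,
#'   `n_strokes`.
#' @export
score_item22 <- function(rec, params = scoring_params()) {
  check_item(rec, 22L)
  phys <- to_physical(rec)
  lay <- phys$layout
  strokes <- split_strokes(phys)

  is_tap <- vapply(strokes, function(st) {
    st$duration_ms <= params$tap_max_ms && st$path_length <= params$tap_max_path_cm
  }, logical(1))
  taps <- strokes[is_tap]
  slides <- strokes[!is_tap]

  if (length(strokes)) {
    first <- strokes[[1]]$samples[1, c("x", "y")]
    if (region_contacts(first, lay$start_zone, tol = params$tau_line_cm)[1] == "outside") {
      warning("first contact is outside the start zone", call. = FALSE)
    }
  }

  nt <- length(lay$targets)
  precise <- logical(nt); imprecise <- logical(nt); slid <- logical(nt)
  for (t in seq_len(nt)) {
    reg <- lay$targets[[t]]
    for (st in taps) {
      cls <- region_contacts(st$samples[, c("x", "y")], reg, tol = params$tau_line_cm)
      if (all(cls == "interior")) {
        precise[t] <- TRUE
      } else if (any(cls != "outside")) {
        imprecise[t] <- TRUE
      }
    }
    for (st in slides) {
      cls <- region_contacts(st$samples[, c("x", "y")], reg, tol = params$tau_line_cm)
      if (any(cls == "interior")) slid[t] <- TRUE
    }
  }
  lifted <- length(strokes) >= 2
  evidence <- list(
    n_targets_precise = sum(precise),
    n_targets_imprecise = sum(imprecise & !precise),
    n_targets_slid = sum(slid),
    lifted = lifted,
    n_taps = length(taps), n_slides = length(slides),
    n_strokes = length(strokes)
  )
  tap_hit_any <- any(precise | imprecise)
  score <- if (lifted && all(precise)) 3L
  else if (lifted && tap_hit_any) 2L
  else if (!tap_hit_any && any(slid)) 1L
  else 0L
  new_auto_score(22L, score, evidence, params)
}

#' Score any recording
#'
#' Dispatches to the item-specific scorer according to the recording's item.
#'
#' @param rec a [trace_recording()].
#' @param params a [scoring_params()].
#' @return an `auto_score`.
#' @export
score_recording <- function(rec, params = scoring_params()) {
  stopifnot(inherits(rec, "trace_recording"))
  switch(as.character(rec$item_id),
         "18" = score_item18(rec, params),
         "19" = score_item19(rec, params),
         "22" = score_item22(rec, params))
}

auto_score_row <- function(score, recording_id = NA_character_) {
  cols <- c("net_sweep_deg", "min_radius_cm", "median_radius_cm",
            "max_radius_cm", "ink_cm", "n_loops", "x_coverage_frac",
            "exited_frame", "n_targets_precise", "n_targets_imprecise",
            "n_targets_slid", "lifted", "n_taps", "n_slides", "n_pauses",
            "n_strokes", "n_pointer_changes")
  row <- as.list(rep(NA, length(cols)))
  names(row) <- cols
  for (nm in intersect(names(score$evidence), cols)) {
    row[[nm]] <- score$evidence[[nm]]
  }
  cbind(data.frame(recording_id = recording_id, item_id = score$item_id,
                   score = score$score, stringsAsFactors = FALSE),
        as.data.frame(row))
}

#' Score a list of recordings into a table
#'
#' @param recs named list of [trace_recording()] objects; names become
#'   `recording_id`.
#' @param params a [scoring_params()].
#' @return data.frame with one row per recording: `recording_id`, `item_id`,
#'   `score` and the full evidence column set (fields not applicable to an
#'   item are `NA`).
#' @export
score_recordings <- function(recs, params = scoring_params()) {
  ids <- names(recs)
  if (is.null(ids)) ids <- sprintf("rec%03d", seq_along(recs))
  rows <- Map(function(rec, id) auto_score_row(score_recording(rec, params), id),
              recs, ids)
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) out <- auto_score_row(
    new_auto_score(18L, 0L, list(), scoring_params()))[0, ]
  rownames(out) <- NULL
  out
}
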