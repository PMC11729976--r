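#' Scoring parameters
#'
#' Tunable thresholds of the automatic scorers. The rubric wording is
#' qualitative ("goes round the edge", "a continuous series of loops",
#' "without touching the lines"); these parameters make each clause
#' operational and are recorded with every score for auditability.
#'
#' @param theta_complete_deg net angular sweep (degrees) counting as a
#'   complete circumnavigation; slightly below 360 to tolerate endpoint
#'   clipping. Must be <= 360.
#' @param eps_in_cm tolerated entry depth inside the CD edge before the trace
#'   counts as entering the disc (cm); a sample exactly at
#'   `r_large - eps_in_cm` does not count as entering.
#' @param band_out_cm how far beyond the CD edge the finger may wander while
#'   still "on the edge" (cm).
#' @param band_small_cm half-width of the annulus around the small circle used
#'   for small-circle circumnavigation (cm).
#' @param v_pause_cm_s,pause_min_ms pause detection thresholds, see
#'   [detect_pauses()].
#' @param tau_line_cm extra tolerance beyond a drawn line for contact
#'   classification (cm), see [region_contacts()].
#' @param tau_touch_cm depth of the top/bottom contact bands inside the item
#'   19 frame (cm): a loop must reach within `tau_touch_cm` of both interior
#'   edges.
#' @param min_ink_cm minimum total path length counting as a written mark (cm).
#' @param min_loops_full number of loops constituting "a continuous series".
#' @param coverage_frac fraction of the frame width a full series must span.
#' @param tap_max_ms,tap_max_path_cm a stroke is a tap (a placement) when its
#'   duration and path length are both below these bounds; otherwise it is a
#'   slide.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(theta_complete_deg = 355,
                           eps_in_cm = 0.15,
                           band_out_cm = 1.5,
                           band_small_cm = 0.6,
                           v_pause_cm_s = 0.5,
                           pause_min_ms = 400,
                           tau_line_cm = 0.05,
                           tau_touch_cm = 0.1,
                           min_ink_cm = 0.2,
                           min_loops_full = 3,
                           coverage_frac = 0.9,
                           tap_max_ms = 600,
                           tap_max_path_cm = 0.5) {
  p <- list(theta_complete_deg = theta_complete_deg, eps_in_cm = eps_in_cm,
            band_out_cm = band_out_cm, band_small_cm = band_small_cm,
            v_pause_cm_s = v_pause_cm_s, pause_min_ms = pause_min_ms,
            tau_line_cm = tau_line_cm, tau_touch_cm = tau_touch_cm,
            min_ink_cm = min_ink_cm, min_loops_full = min_loops_full,
            coverage_frac = coverage_frac, tap_max_ms = tap_max_ms,
            tap_max_path_cm = tap_max_path_cm)
  bad <- names(p)[!vapply(p, function(v) is_scalar_number(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop_validation("scoring parameters must be positive numbers: %s",
                    paste(bad, collapse = ", "))
  }
  if (theta_complete_deg > 360) {
    stop_validation("theta_complete_deg must be <= 360")
  }
  if (coverage_frac > 1) stop_validation("coverage_frac must be <= 1")
  structure(p, class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("<scoring_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read or write scoring parameters as JSON
#'
#' @param params a [scoring_params()].
#' @param path file path.
#' @return `read_params_json()` returns a `scoring_params`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "scoring_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop_input("params file not found: %s", path)
  do.call(scoring_params, jsonlite::read_json(path))
}
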