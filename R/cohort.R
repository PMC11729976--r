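# Cohort-level simulation: draw archetypes per subject and item from stated
# marginals, synthesize the recordings, and generate a paired second scoring
# mode through a misclassification matrix - the structure an agreement study
# compares.

#' Cohort specification
#'
#' @param n number of subjects (>= 0).
#' @param marginals named list `item18`/`item19`/`item22` of archetype
#'   probability vectors (named `full`, `imperfect`, `minimal`, `unable`,
#'   summing to 1). The default reproduces the ability mix of the validation
#'   cohort's paper-support score distribution per item.
#' @param misclass 4 x 4 row-stochastic matrix: `misclass[s + 1, t + 1]` is
#'   the probability that a subject whose intended score is `s` receives
#'   mode-B score `t`. Identity (the default) makes mode B a perfect rater.
#' @param seed integer seed driving the whole cohort.
#' @param noise named list of [subject_profile()] noise overrides applied to
#'   every subject (e.g. `list(tremor_amp_cm = 0)` for noise-free cohorts).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        marginals = list(
                          item18 = c(full = 0.844, imperfect = 0.104,
                                     minimal = 0.021, unable = 0.031),
                          item19 = c(full = 0.427, imperfect = 0.500,
                                     minimal = 0.052, unable = 0.021),
                          item22 = c(full = 0.939, imperfect = 0.041,
                                     minimal = 0.000, unable = 0.020)),
                        misclass = diag(4), seed = 1, noise = list()) {
  stopifnot(is_scalar_number(n), n >= 0, n == round(n))
  items <- c("item18", "item19", "item22")
  if (!all(names(marginals) %in% items) || !length(marginals)) {
    stop_validation("marginals must be a named list over item18/item19/item22")
  }
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (!all(names(p) %in% ARCHETYPES) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6) {
      stop_validation("%s marginal must be non-negative over archetypes and sum to 1", nm)
    }
  }
  misclass <- as.matrix(misclass)
  if (!all(dim(misclass) == c(4, 4)) || any(misclass < 0) ||
      any(abs(rowSums(misclass) - 1) > 1e-6)) {
    stop_validation("misclass must be a 4 x 4 row-stochastic matrix")
  }
  structure(list(n = as.integer(n), marginals = marginals,
                 misclass = misclass, seed = seed, noise = noise),
            class = "cohort_spec")
}

#' Simulate a synthetic cohort
#'
#' For every subject and item, draws an archetype from the spec's marginals,
#' synthesizes the trace recording, records the intended (archetype) score as
#' the mode-A score, and draws the paired mode-B score through the
#' misclassification matrix. Fully deterministic for a given spec.
#'
#' @param spec a [cohort_spec()].
#' @param calibration a [device_calibration()].
#' @return list with `recordings` (named list of [trace_recording()]),
#'   `manifest` (data.frame `recording_id`, `subject_id`, `item`,
#'   `archetype`, `intended_score`, `score_b`, `seed`) and `pairs`
#'   (data.frame `subject_id`, `item`, `score_a`, `score_b`).
#' @export
simulate_cohort <- function(spec, calibration = device_calibration()) {
  stopifnot(inherits(spec, "cohort_spec"))
  items <- intersect(c("item18", "item19", "item22"), names(spec$marginals))
  item_no <- as.integer(sub("item", "", items))
  recordings <- list()
  rows <- list()
  with_seed(spec$seed, {
    for (s in seq_len(spec$n)) {
      arch <- list()
      for (it in items) {
        p <- spec$marginals[[it]]
        arch[[it]] <- sample(names(p), 1, prob = p)
      }
      prof_args <- c(
        list(archetype_18 = arch$item18 %||% "full",
             archetype_19 = arch$item19 %||% "full",
             archetype_22 = arch$item22 %||% "full"),
        spec$noise)
      prof <- do.call(subject_profile, prof_args)
      for (j in seq_along(items)) {
        it <- items[j]; no <- item_no[j]
        rec <- simulate_recording(prof, no, calibration = calibration, seed = NULL)
        id <- sprintf("s%03d_item%02d", s, no)
        recordings[[id]] <- rec
        a <- intended_score(arch[[it]])
        b <- sample(0:3, 1, prob = spec$misclass[a + 1, ])
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = id, subject_id = sprintf("s%03d", s), item = no,
          archetype = arch[[it]], intended_score = a, score_b = b,
          seed = spec$seed, stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else data.frame(
    recording_id = character(0), subject_id = character(0), item = integer(0),
    archetype = character(0), intended_score = integer(0),
    score_b = integer(0), seed = integer(0), stringsAsFactors = FALSE)
  pairs <- manifest[, c("subject_id", "item", "intended_score", "score_b")]
  names(pairs) <- c("subject_id", "item", "score_a", "score_b")
  list(recordings = recordings, manifest = manifest, pairs = pairs)
}

#' Write a simulated cohort as a fixture bundle
#'
#' Emits one trace CSV + JSON sidecar per recording, plus `manifest.csv`
#' (`recording_id,item,intended_score,seed`, with archetype and mode-B score)
#' and `pairs.csv` (`subject_id,item,score_a,score_b`).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    write_recording(cohort$recordings[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

cohort_spec_from_json <- function(path) {
  if (!file.exists(path)) stop_input("cohort spec not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(n = x$n)
  if (!is.null(x$marginals)) args$marginals <- lapply(x$marginals, unlist)
  if (!is.null(x$misclass)) {
    args$misclass <- if (is.matrix(x$misclass)) x$misclass else {
      matrix(unlist(x$misclass), 4, 4, byrow = TRUE)
    }
  }
  if (!is.null(x$seed)) args$seed <- x$seed
  if (!is.null(x$noise)) args$noise <- as.list(x$noise)
  do.call(cohort_spec, args)
}
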