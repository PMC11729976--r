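# Ordinal agreement between two scoring modes: weighted Cohen's kappa
# (Fleiss-Cohen quadratic weights by default) with its asymptotic confidence
# interval, percent agreement, Landis-Koch interpretation, and per-subject
# disagreement profiles. The Bangdiwala chart lives in bangdiwala.R.

#' Contingency table of paired ordinal scores
#'
#' `contingency_table()` validates a k x k count matrix (rows = mode A,
#' columns = mode B, categories in a fixed order). `pair_table()` tallies two
#' paired score vectors into one; pairs with a missing value are dropped
#' pairwise and counted in the `n_dropped` attribute (the denominators of an
#' agreement study vary by item for exactly this reason).
#'
#' @param counts square matrix of non-negative counts.
#' @param labels ordered category labels; defaults to `0:(k-1)`.
#' @param scores_a,scores_b equal-length vectors of scores drawn from
#'   `labels` (NA allowed).
#' @return an object of class `contingency_table` (a matrix with dimnames
#'   `labels` and attribute `n_dropped`).
#' @examples
#' pair_table(c(3, 3, 2), c(3, 2, 2))
#' @export
contingency_table <- function(counts, labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) != ncol(m) || nrow(m) < 2) {
    stop_validation("counts must be a square matrix with k >= 2")
  }
  if (any(m < 0) || anyNA(m) || any(m != round(m))) {
    stop_validation("counts must be non-negative integers")
  }
  if (is.null(labels)) labels <- 0:(nrow(m) - 1)
  if (length(labels) != nrow(m)) {
    stop_validation("labels length must match the table dimension")
  }
  dimnames(m) <- list(a = as.character(labels), b = as.character(labels))
  structure(m, class = c("contingency_table", class(m)), n_dropped = 0L)
}

#' @rdname contingency_table
#' @export
pair_table <- function(scores_a, scores_b, labels = 0:3) {
  if (length(scores_a) != length(scores_b)) {
    stop_input("score vectors have different lengths (%d vs %d)",
               length(scores_a), length(scores_b))
  }
  keep <- !(is.na(scores_a) | is.na(scores_b))
  dropped <- sum(!keep)
  a <- scores_a[keep]; b <- scores_b[keep]
  if (length(a) && !all(a %in% labels & b %in% labels)) {
    stop_input("scores outside the declared categories (%s)",
               paste(labels, collapse = ", "))
  }
  m <- table(factor(a, levels = labels), factor(b, levels = labels))
  out <- contingency_table(unclass(m), labels)
  attr(out, "n_dropped") <- as.integer(dropped)
  out
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d categories, N = %d", nrow(x), sum(x)))
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0) cat(sprintf(" (%d pairs dropped)", nd))
  cat("\n")
  print(matrix(x, nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Disagreement weights
#'
#' Agreement weights `w[i, j]` for k ordered categories: 1 on the diagonal,
#' decreasing with `|i - j|`. The quadratic (Fleiss-Cohen) scheme is
#' `w = 1 - (i - j)^2 / (k - 1)^2`.
#'
#' @param k number of categories.
#' @param scheme `"quadratic"`, `"linear"` or `"unweighted"`.
#' @return k x k weight matrix.
#' @export
kappa_weights <- function(k, scheme = c("quadratic", "linear", "unweighted")) {
  scheme <- match.arg(scheme)
  i <- matrix(0:(k - 1), k, k)
  j <- t(i)
  switch(scheme,
         quadratic = 1 - (i - j)^2 / (k - 1)^2,
         linear = 1 - abs(i - j) / (k - 1),
         unweighted = (i == j) * 1)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal paired ratings. With cell
#' proportions `p[i, j]`, row/column marginals `r`, `c` and weights `w`,
#' the observed and expected weighted agreements are
#' `po = sum(w * p)` and `pe = sum(w * (r %o% c))`, and
#' `kappa = (po - pe) / (1 - pe)`. The standard error is the large-sample
#' (Fleiss-Cohen-Everitt) estimate around the observed kappa, and the
#' confidence interval `kappa +/- z * se` is truncated to `[-1, 1]`.
#'
#' @param tab a [contingency_table()] (or square count matrix).
#' @param scheme weighting scheme, see [kappa_weights()]; the quadratic
#'   Fleiss-Cohen scheme is the default.
#' @param conf_level confidence level for the interval.
#' @return an object of class `kappa_result`: list with `kappa`, `po_w`,
#'   `pe_w`, `se`, `ci_low`, `ci_high`, `scheme`, `conf_level`, `n`.
#'   `se` and the interval are `NA` when `n < 2`.
#' @examples
#' tab <- contingency_table(diag(c(5, 10, 15, 20)))
#' weighted_kappa(tab)$kappa # 1
#' @export
weighted_kappa <- function(tab, scheme = c("quadratic", "linear", "unweighted"),
                           conf_level = 0.95) {
  scheme <- match.arg(scheme)
  m <- unclass(as.matrix(tab))
  n <- sum(m)
  if (n == 0) stop_computation("kappa is undefined for an empty table")
  k <- nrow(m)
  w <- kappa_weights(k, scheme)
  p <- m / n
  r <- rowSums(p)
  cc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cc))
  if (pe >= 1 - 1e-12) {
    stop_computation(
      "kappa is undefined: expected weighted agreement is 1 (degenerate table)")
  }
  kap <- (po - pe) / (1 - pe)
  se <- ci_lo <- ci_hi <- NA_real_
  if (n >= 2) {
    wi <- as.vector(w %*% cc)  # row-conditional expected weights
    wj <- as.vector(r %*% w)
    v <- (sum(p * (w * (1 - pe) - outer(wi, wj, "+") * (1 - po))^2) -
            (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
    se <- sqrt(max(0, v))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci_lo <- max(-1, kap - z * se)
    ci_hi <- min(1, kap + z * se)
  }
  structure(
    list(kappa = kap, po_w = po, pe_w = pe, se = se,
         ci_low = ci_lo, ci_high = ci_hi, scheme = scheme,
         conf_level = conf_level, n = n),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> %s kappa = %.2f [%s; %s] (n = %d, %s)\n",
              x$scheme, x$kappa,
              ifelse(is.na(x$ci_low), "NA", sprintf("%.2f", x$ci_low)),
              ifelse(is.na(x$ci_high), "NA", sprintf("%.2f", x$ci_high)),
              x$n, landis_koch_label(max(0, x$kappa))))
  invisible(x)
}

#' Confidence interval for weighted kappa
#'
#' @inheritParams weighted_kappa
#' @param level confidence level.
#' @return numeric `c(ci_low, ci_high)`, truncated to `[-1, 1]`.
#' @export
kappa_confidence_interval <- function(tab, scheme = "quadratic", level = 0.95) {
  if (sum(as.matrix(tab)) < 2) {
    stop_computation("confidence interval needs at least 2 paired ratings")
  }
  res <- weighted_kappa(tab, scheme, conf_level = level)
  c(ci_low = res$ci_low, ci_high = res$ci_high)
}

#' Percent agreement
#'
#' Exact agreement, `100 * sum(diag) / N`.
#'
#' @param tab a [contingency_table()] or square count matrix.
#' @return percentage in `[0, 100]`.
#' @export
percent_agreement <- function(tab) {
  m <- as.matrix(tab)
  n <- sum(m)
  if (n == 0) stop_computation("percent agreement is undefined for an empty table")
  100 * sum(diag(m)) / n
}

#' Landis-Koch interpretation of kappa
#'
#' Conventional verbal bins: 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect. The printed
#' bins have two decimals, so kappa is rounded to two decimals before
#' binning; a negative kappa is labelled `"poor"` with a warning.
#'
#' @param kappa a kappa value in `[-1, 1]`.
#' @return character label.
#' @examples
#' landis_koch_label(0.70) # "substantial"
#' landis_koch_label(0.93) # "almost perfect"
#' @export
landis_koch_label <- function(kappa) {
  stopifnot(is_scalar_number(kappa), kappa >= -1, kappa <= 1)
  k <- round(kappa, 2)
  if (k < 0) {
    warning("negative kappa: agreement worse than chance", call. = FALSE)
    return("poor")
  }
  if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Per-subject disagreement profile
#'
#' Classifies every subject by how their mode-B scores relate to their mode-A
#' scores across items: `identical` (all items equal), `b_lower_by_1` (at
#' least one item scored one point lower in mode B, none higher, no larger
#' gap), `b_higher_by_1` (the mirror image), or `other` (mixed directions or
#' a gap of 2+). Also tallies the per-item score-shift distribution.
#'
#' @param pairs data.frame with columns `subject_id`, `item`, `score_a`,
#'   `score_b`; rows with a missing score are dropped pairwise and counted.
#' @return list with `classes` (per-subject classification), `proportions`
#'   (percent of subjects per class), `per_item_shifts` (counts of
#'   `score_b - score_a` per item), `n_subjects`, `n_dropped`.
#' @export
disagreement_summary <- function(pairs) {
  need <- c("subject_id", "item", "score_a", "score_b")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    stop_input("pairs must be a data.frame with columns %s",
               paste(need, collapse = ", "))
  }
  keep <- !(is.na(pairs$score_a) | is.na(pairs$score_b))
  dropped <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) stop_input("no complete score pairs")

  classify <- function(d) {
    if (all(d == 0)) "identical"
    else if (all(d %in% c(0, -1)) && any(d == -1)) "b_lower_by_1"
    else if (all(d %in% c(0, 1)) && any(d == 1)) "b_higher_by_1"
    else "other"
  }
  d_all <- pairs$score_b - pairs$score_a
  cls <- vapply(split(d_all, pairs$subject_id), classify, character(1))
  lev <- c("identical", "b_lower_by_1", "b_higher_by_1", "other")
  counts <- table(factor(cls, levels = lev))
  shifts <- table(item = pairs$item, shift = d_all)
  list(
    classes = cls,
    proportions = stats::setNames(100 * as.numeric(counts) / length(cls), lev),
    per_item_shifts = shifts,
    n_subjects = length(cls),
    n_dropped = as.integer(dropped)
  )
}
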