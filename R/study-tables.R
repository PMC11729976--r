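#' Published validation-study contingency tables
#'
#' The multicentre tablet-validation study of the MFM distal items (98
#' subjects with neuromuscular disease) reported its paired score counts as
#' 4 x 4 tables; they are bundled here as in-package fixtures for examples
#' and reproduction of the published agreement statistics.
#'
#' * `p_vs_t` - paper-support score (P-score, rows) against therapist tablet
#'   score (T-score, columns), n = 96/96/98 for items 18/19/22;
#' * `t_vs_a` - therapist tablet score (T-score, rows) against the automatic
#'   score (A-score, columns) on the subset with automatic scoring,
#'   n = 29/28/25.
#'
#' Categories are the ordinal item scores 0-3.
#'
#' @return nested list `list(p_vs_t = list(item18, item19, item22),
#'   t_vs_a = list(item18, item19, item22))` of [contingency_table()] objects.
#' @examples
#' tabs <- mfm_study_tables()
#' weighted_kappa(tabs$p_vs_t$item18)$kappa
#' percent_agreement(tabs$t_vs_a$item18)
#' @export
mfm_study_tables <- function() {
  mk <- function(cells) {
    m <- matrix(0L, 4, 4)
    for (cell in cells) m[cell[1] + 1L, cell[2] + 1L] <- cell[3]
    contingency_table(m, labels = 0:3)
  }
  list(
    p_vs_t = list(
      item18 = mk(list(c(0, 0, 3), c(1, 1, 2), c(2, 2, 8), c(3, 3, 77),
                       c(3, 2, 4), c(2, 3, 1), c(2, 1, 1))),
      item19 = mk(list(c(0, 0, 2), c(1, 1, 5), c(2, 2, 43), c(3, 3, 21),
                       c(3, 2, 20), c(2, 3, 4), c(2, 1, 1))),
      item22 = mk(list(c(0, 0, 2), c(2, 2, 4), c(3, 3, 90), c(3, 2, 2)))
    ),
    t_vs_a = list(
      item18 = mk(list(c(3, 3, 6), c(2, 2, 1), c(3, 2, 2), c(3, 0, 10),
                       c(2, 3, 3), c(2, 0, 7))),
      item19 = mk(list(c(3, 3, 5), c(2, 2, 17), c(1, 1, 2), c(0, 0, 1),
                       c(3, 2, 2), c(2, 1, 1))),
      item22 = mk(list(c(3, 3, 16), c(2, 2, 6), c(3, 2, 3)))
    )
  )
}
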