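test_that("pair_table tallies paired scores and drops missings pairwise", {
  tab <- pair_table(c(3, 3, 2), c(3, 2, 2))
  expect_equal(tab["3", "3"], 1)
  expect_equal(tab["3", "2"], 1)
  expect_equal(tab["2", "2"], 1)
  expect_equal(sum(tab), 3)

  empty <- pair_table(integer(0), integer(0))
  expect_equal(sum(empty), 0)

  with_na <- pair_table(c(3, NA, 2, 1), c(3, 2, NA, 1))
  expect_equal(sum(with_na), 2)
  expect_equal(attr(with_na, "n_dropped"), 2L)

  expect_error(pair_table(1:3, 1:2), class = "mfm_input_error")
  expect_error(pair_table(c(0, 5), c(0, 1)), class = "mfm_input_error")

  set.seed(19)
  for (i in 1:10) {
    a <- sample(0:3, 50, replace = TRUE)
    b <- sample(0:3, 50, replace = TRUE)
    tab <- pair_table(a, b)
    for (x in 0:3) for (y in 0:3) {
      expect_equal(tab[x + 1, y + 1], sum(a == x & b == y))
    }
  }
})

test_that("weighted kappa agrees with a brute-force double-loop oracle", {
  set.seed(29)
  for (i in 1:50) {
    m <- random_table()
    for (scheme in c("quadratic", "linear", "unweighted")) {
      expect_equal(weighted_kappa(contingency_table(m), scheme)$kappa,
                   brute_kappa(m, scheme), tolerance = 1e-12)
    }
  }
})

test_that("kappa edge cases behave as defined", {
  diag_tab <- contingency_table(diag(c(5, 10, 15, 20)))
  for (scheme in c("quadratic", "unweighted")) {
    res <- weighted_kappa(diag_tab, scheme)
    expect_equal(res$kappa, 1)
    expect_equal(res$po_w, 1)
    expect_equal(res$ci_high, 1) # truncated
  }
  # all mass in a single cell: expected agreement 1, kappa undefined
  degen <- matrix(0, 4, 4); degen[2, 2] <- 12
  expect_error(weighted_kappa(contingency_table(degen)),
               class = "mfm_computation_error")
  expect_error(weighted_kappa(contingency_table(matrix(0, 4, 4))),
               class = "mfm_computation_error")
  # quadratic kappa is invariant to transposition
  set.seed(37)
  for (i in 1:10) {
    m <- random_table()
    expect_equal(weighted_kappa(contingency_table(m))$kappa,
                 weighted_kappa(contingency_table(t(m)))$kappa,
                 tolerance = 1e-12)
  }
  # consistent relabelling (category reversal) leaves unweighted kappa alone
  for (i in 1:5) {
    m <- random_table()
    rev <- m[4:1, 4:1]
    expect_equal(weighted_kappa(contingency_table(m), "unweighted")$kappa,
                 weighted_kappa(contingency_table(rev), "unweighted")$kappa,
                 tolerance = 1e-12)
  }
})

test_that("the asymptotic CI is sane against a bootstrap resampling check", {
  set.seed(43)
  m <- matrix(c(20, 4, 1, 0,
                3, 18, 5, 1,
                0, 4, 22, 3,
                1, 0, 2, 16), 4, 4, byrow = TRUE)
  tab <- contingency_table(m)
  res <- weighted_kappa(tab)
  ci <- kappa_confidence_interval(tab)
  expect_equal(unname(ci), c(res$ci_low, res$ci_high))
  expect_true(ci[1] <= res$kappa && res$kappa <= ci[2])
  # bootstrap the table and compare spreads
  n <- sum(m)
  boot <- replicate(400, {
    draw <- stats::rmultinom(1, n, as.vector(m) / n)
    bm <- matrix(draw, 4, 4)
    tryCatch(weighted_kappa(contingency_table(bm))$kappa, error = function(e) NA)
  })
  boot <- boot[!is.na(boot)]
  expect_equal(res$se, stats::sd(boot), tolerance = 0.5)
  bq <- stats::quantile(boot, c(0.025, 0.975))
  expect_lt(abs((ci[2] - ci[1]) - (bq[2] - bq[1])), (ci[2] - ci[1]))
  expect_error(kappa_confidence_interval(contingency_table(matrix(c(1, 0, 0, 0), 2))),
               class = "mfm_computation_error")
})

test_that("percent agreement is bounded and maximal exactly on diagonal tables", {
  set.seed(53)
  for (i in 1:20) {
    m <- random_table()
    pa <- percent_agreement(contingency_table(m))
    expect_gte(pa, 0); expect_lte(pa, 100)
    expect_equal(pa == 100, all(m[row(m) != col(m)] == 0))
  }
  expect_error(percent_agreement(matrix(0, 4, 4)),
               class = "mfm_computation_error")
})

test_that("Landis-Koch labels follow the published bins", {
  expect_equal(landis_koch_label(0.70), "substantial")
  expect_equal(landis_koch_label(0.93), "almost perfect")
  expect_equal(landis_koch_label(0.95), "almost perfect")
  expect_equal(landis_koch_label(0.00), "slight")
  expect_equal(landis_koch_label(0.20), "slight")
  expect_equal(landis_koch_label(0.21), "fair")
  expect_equal(landis_koch_label(0.404), "fair")   # gap value, rounds to 0.40
  expect_equal(landis_koch_label(0.407), "moderate") # gap value, rounds to 0.41
  expect_equal(landis_koch_label(0.41), "moderate")
  expect_equal(landis_koch_label(0.61), "substantial")
  expect_equal(landis_koch_label(0.81), "almost perfect")
  expect_equal(landis_koch_label(1), "almost perfect")
  expect_warning(lab <- landis_koch_label(-0.3), "negative")
  expect_equal(lab, "poor")
})

test_that("Bangdiwala geometry and B statistic follow the marginals", {
  d <- contingency_table(diag(c(2, 3, 4, 5)))
  cd <- bangdiwala_chart(d)
  expect_equal(cd$B, 1)
  # diagonal table: every dark square sits on the 45-degree line
  expect_equal(cd$dark$x0, cd$dark$y0)
  expect_equal(cd$dark$x1, cd$dark$y1)

  tabs <- mfm_study_tables()
  m22 <- unclass(as.matrix(tabs$p_vs_t$item22))
  c22 <- bangdiwala_chart(tabs$p_vs_t$item22)
  expect_equal(c22$B,
               (2^2 + 0^2 + 4^2 + 90^2) /
                 (2 * 2 + 0 * 0 + 6 * 4 + 92 * 90))
  expect_equal(sum(diag(m22)^2) / sum(rowSums(m22) * colSums(m22)), c22$B)

  z <- matrix(c(0, 3, 2, 0), 2, 2)
  expect_equal(bangdiwala_chart(contingency_table(z))$B, 0)

  # rectangles tile the cumulative marginals
  r <- c22$rectangles
  expect_equal(r$x1 - r$x0, unname(rowSums(m22)))
  expect_equal(r$y1 - r$y0, unname(colSums(m22)))
  # dark squares stay inside their rectangles; partial bands inside too
  expect_true(all(c22$dark$x0 >= r$x0 & c22$dark$x1 <= r$x1))
  expect_true(all(c22$partial$y0 >= r$y0 & c22$partial$y1 <= r$y1))
})

test_that("chart exports are deterministic files", {
  dir <- withr::local_tempdir()
  chart <- bangdiwala_chart(mfm_study_tables()$p_vs_t$item19)
  f1 <- file.path(dir, "a.svg"); f2 <- file.path(dir, "b.svg")
  write_bangdiwala_svg(chart, f1)
  write_bangdiwala_svg(chart, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1], "<svg")
  j <- file.path(dir, "a.json")
  write_bangdiwala_json(chart, j)
  expect_equal(jsonlite::read_json(j)$B, chart$B)
})

test_that("disagreement summary classifies subjects against a direct oracle", {
  pairs <- data.frame(
    subject_id = rep(c("s1", "s2", "s3", "s4"), each = 3),
    item = rep(c(18, 19, 22), 4),
    score_a = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 2, 3),
    score_b = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 1, 3))
  ds <- disagreement_summary(pairs)
  expect_equal(unname(ds$proportions["identical"]), 75)
  expect_equal(unname(ds$proportions["b_lower_by_1"]), 25)
  expect_equal(ds$n_subjects, 4)

  all_same <- within(pairs, score_b <- score_a)
  expect_equal(unname(disagreement_summary(all_same)$proportions["identical"]), 100)

  expect_error(disagreement_summary(pairs[0, ]), class = "mfm_input_error")

  set.seed(61)
  n <- 60
  rnd <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:n), each = 3),
    item = rep(c(18, 19, 22), n),
    score_a = sample(0:3, 3 * n, replace = TRUE),
    score_b = sample(0:3, 3 * n, replace = TRUE))
  ds2 <- disagreement_summary(rnd)
  oracle <- vapply(split(rnd, rnd$subject_id), function(df) {
    d <- df$score_b - df$score_a
    if (all(d == 0)) "identical"
    else if (all(d <= 0) && min(d) == -1) "b_lower_by_1"
    else if (all(d >= 0) && max(d) == 1) "b_higher_by_1"
    else "other"
  }, character(1))
  expect_equal(as.vector(table(factor(oracle, levels = names(ds2$proportions)))) /
                 n * 100,
               unname(ds2$proportions))
})
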