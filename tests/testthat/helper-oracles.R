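# Independent oracles and small builders shared by the test files. The
# oracles deliberately re-derive quantities with the most naive computation
# available so they stay independent of the implementation paths they check.

# Brute-force weighted kappa: explicit double loops over cells.
brute_kappa <- function(m, scheme = "quadratic") {
  k <- nrow(m)
  n <- sum(m)
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    w[i, j] <- switch(scheme,
      quadratic = 1 - (i - j)^2 / (k - 1)^2,
      linear = 1 - abs(i - j) / (k - 1),
      unweighted = as.numeric(i == j))
  }
  po <- 0
  for (i in 1:k) for (j in 1:k) po <- po + w[i, j] * m[i, j] / n
  pe <- 0
  for (i in 1:k) for (j in 1:k) {
    pe <- pe + w[i, j] * sum(m[i, ]) * sum(m[, j]) / n^2
  }
  (po - pe) / (1 - pe)
}

# Random non-degenerate 4x4 count table.
random_table <- function() {
  repeat {
    m <- matrix(rpois(16, 3), 4, 4)
    if (sum(m) == 0) next
    p <- m / sum(m)
    r <- rowSums(p); cc <- colSums(p)
    w <- mfmtrace::kappa_weights(4, "quadratic")
    if (sum(w * outer(r, cc)) < 1 - 1e-9) return(m)
  }
}

# All k x k tables of non-negative integers with total exactly n.
enumerate_tables <- function(n, k = 3) {
  cells <- k * k
  out <- list()
  rec <- function(pos, left, acc) {
    if (pos == cells) {
      out[[length(out) + 1L]] <<- matrix(c(acc, left), k, k, byrow = TRUE)
      return(invisible())
    }
    for (v in 0:left) rec(pos + 1L, left - v, c(acc, v))
  }
  rec(1L, n, integer(0))
  out
}

# Minimal hand-built recording: a single pointer polyline in cm placed
# straight into physical units (calibration y-up, px_per_cm = 1 keeps
# numbers readable; screen large enough for any test geometry).
cm_calibration <- function() {
  device_calibration(screen_w_px = 100, screen_h_px = 100, px_per_cm = 1,
                     y_axis = "up")
}

make_recording <- function(item_id, layout, xy, times_ms = NULL,
                           pointer = 0L, input_kind = "finger") {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (is.null(times_ms)) times_ms <- seq(0, by = 20, length.out = n)
  phase <- if (n == 1) "down" else c("down", rep("move", n - 2), "up")
  samples <- data.frame(time_ms = times_ms, pointer_id = pointer,
                        phase = phase, x = xy[, 1], y = xy[, 2])
  trace_recording(item_id, samples, layout, cm_calibration(),
                  input_kind = input_kind, unit = "px")
}

# Circle polyline around a centre (degrees swept, constant angular step).
circle_points <- function(center, radius, n = 360, sweep_deg = 360,
                          start_deg = 90) {
  a <- (start_deg + seq(0, sweep_deg, length.out = n)) * pi / 180
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
}

# Independent score-3 predicate checker for item 18: recomputes every
# clause from the raw physical samples of each stroke using plain loops.
check_item18_score3 <- function(rec, params = scoring_params()) {
  phys <- to_physical(rec)
  lay <- phys$layout
  for (st in split_strokes(phys)) {
    s <- st$samples
    if (nrow(s) < 2) next
    r <- sqrt((s$x - lay$center[1])^2 + (s$y - lay$center[2])^2)
    th <- atan2(s$y - lay$center[2], s$x - lay$center[1]) * 180 / pi
    net <- 0
    for (i in 2:length(th)) {
      d <- th[i] - th[i - 1]
      while (d <= -180) d <- d + 360
      while (d > 180) d <- d - 360
      net <- net + d
    }
    # pause: any window of consecutive slow samples lasting >= pause_min_ms
    sp_t <- s$time_ms[!duplicated(s$time_ms, fromLast = TRUE)]
    sp_x <- s$x[!duplicated(s$time_ms, fromLast = TRUE)]
    sp_y <- s$y[!duplicated(s$time_ms, fromLast = TRUE)]
    has_pause <- FALSE
    if (length(sp_t) >= 2) {
      v <- sqrt(diff(sp_x)^2 + diff(sp_y)^2) / (diff(sp_t) / 1000)
      v <- c(v[1], v)
      slow <- v < params$v_pause_cm_s
      i <- 1
      while (i <= length(slow)) {
        if (slow[i]) {
          j <- i
          while (j < length(slow) && slow[j + 1]) j <- j + 1
          if (sp_t[j] - sp_t[i] >= params$pause_min_ms) has_pause <- TRUE
          i <- j + 1
        } else i <- i + 1
      }
    }
    if (abs(net) >= params$theta_complete_deg &&
        min(r) >= lay$r_large - params$eps_in_cm &&
        max(r) <= lay$r_large + params$band_out_cm &&
        !has_pause) {
      return(TRUE)
    }
  }
  FALSE
}

# Loop-count oracle for item 19: walk the samples of one stroke and count
# completed top/bottom alternation pairs directly.
count_loops_oracle <- function(rec, params = scoring_params()) {
  phys <- to_physical(rec)
  lay <- phys$layout
  y_top <- lay$origin[2] + lay$height
  y_bot <- lay$origin[2]
  x0 <- lay$origin[1]; x1 <- x0 + lay$width
  half <- lay$line_w / 2 + params$tau_line_cm
  total <- 0
  for (st in split_strokes(phys)) {
    visits <- character(0)
    for (i in seq_len(nrow(st$samples))) {
      x <- st$samples$x[i]; y <- st$samples$y[i]
      inside <- x >= x0 - half && x <= x1 + half &&
        y >= y_bot - half && y <= y_top + half
      if (!inside) next
      lab <- if (y >= y_top - params$tau_touch_cm) "T"
      else if (y <= y_bot + params$tau_touch_cm) "B" else NA
      if (!is.na(lab) && (length(visits) == 0 || visits[length(visits)] != lab)) {
        visits <- c(visits, lab)
      }
    }
    total <- total + max(0, (length(visits) - 1) %/% 2)
  }
  total
}

# Random valid multi-stroke recording (pixel units, default tablet) for
# round-trip and partition properties.
random_recording <- function(n_strokes = 3) {
  cal <- device_calibration()
  lay <- item_layout_18()
  rows <- list()
  t <- 0
  for (k in seq_len(n_strokes)) {
    n <- sample(2:12, 1)
    times <- t + cumsum(sample(5:40, n, replace = TRUE))
    rows[[k]] <- data.frame(
      time_ms = times,
      pointer_id = sample(0:2, 1),
      phase = c("down", rep("move", n - 2), "up"),
      x = runif(n, 0, cal$screen_w_px),
      y = runif(n, 0, cal$screen_h_px))
    t <- max(times) + sample(10:100, 1)
  }
  samples <- do.call(rbind, rows)
  trace_recording(18, samples, lay, cal,
                  metadata = list(tag = sprintf("r%d", sample.int(1e6, 1))))
}
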