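# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's internal helpers: plain loops,
# direct formulas, no smoothing, no shared code paths.

# --- brute-force peak evaluation on an entry's raw traces -------------------
oracle_peak <- function(entry) {
  t0 <- entry$transitions[[1]]$times
  s <- rep(0, length(t0))
  for (tr in entry$transitions) s <- s + tr$intensities
  apex_i <- which.max(s)
  thr <- 0.01 * s[apex_i]
  lo <- apex_i
  while (lo > 1 && s[lo - 1] >= thr) lo <- lo - 1
  hi <- apex_i
  while (hi < length(s) && s[hi + 1] >= thr) hi <- hi + 1
  tl <- if (lo > 1) t0[lo] - (t0[lo] - t0[lo - 1]) * (s[lo] - thr) /
    (s[lo] - s[lo - 1]) else t0[1]
  th <- if (hi < length(s)) t0[hi] + (t0[hi + 1] - t0[hi]) * (s[hi] - thr) /
    (s[hi] - s[hi + 1]) else t0[length(t0)]
  tt <- c(tl, t0[lo:hi], th)
  yy <- c(thr, s[lo:hi], thr)
  area <- 0
  for (j in seq_len(length(tt) - 1))
    area <- area + (tt[j + 1] - tt[j]) * (yy[j] + yy[j + 1]) / 2
  list(apex_time = t0[apex_i], b_start = tl, b_end = th,
       width_s = (th - tl) * 60, area = area * 60)
}

oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  if (den == 0) 0 else num / den
}

# brute-force accepted set: evaluates area / width / clean-transition
# criteria with its own peak + correlation + collision code
oracle_accepted <- function(lib, cfg) {
  peaks <- lapply(lib$entries, oracle_peak)
  keys <- vapply(lib$entries, function(e) paste(e$sequence, e$charge),
                 character(1))
  acc <- character(0)
  for (i in seq_along(lib$entries)) {
    e <- lib$entries[[i]]
    pk <- peaks[[i]]
    if (pk$area < cfg$min_area) next
    if (pk$width_s < cfg$min_width || pk$width_s > cfg$max_width) next
    t0 <- e$transitions[[1]]$times
    inb <- t0 >= pk$b_start & t0 <= pk$b_end
    prof <- sapply(e$transitions, function(tr) tr$intensities[inb])
    med <- apply(prof, 1, function(r) sort(r)[ceiling(length(r) / 2)] / 2 +
                   sort(r)[floor(length(r) / 2) + 1] / 2)
    n_clean <- 0
    for (j in seq_along(e$transitions)) {
      r <- min(max(oracle_pearson(prof[, j], med), 0), 1)
      interfered <- r < cfg$coelution_threshold
      if (!interfered) {
        for (k in seq_along(lib$entries)) {
          if (k == i) next
          o <- lib$entries[[k]]
          if (abs(o$precursor_mz - e$precursor_mz) > cfg$isolation_width)
            next
          ob <- peaks[[k]]
          if (ob$b_end < pk$b_start || ob$b_start > pk$b_end) next
          for (otr in o$transitions)
            if (abs(otr$fragment_mz - e$transitions[[j]]$fragment_mz) <=
                cfg$fragment_tolerance) interfered <- TRUE
        }
      }
      if (!interfered) n_clean <- n_clean + 1
    }
    if (n_clean >= cfg$min_clean_transitions) acc <- c(acc, keys[i])
  }
  acc
}

# --- interval stabbing ------------------------------------------------------
oracle_max_concurrency <- function(starts, ends, grid_step = 0.01) {
  grid <- seq(min(starts), max(ends), by = grid_step)
  best <- 0
  for (g in grid) {
    cnt <- 0
    for (i in seq_along(starts))
      if (starts[i] <= g && g <= ends[i]) cnt <- cnt + 1
    if (cnt > best) best <- cnt
  }
  best
}

# --- exhaustive minimum-injection partition (n <= 12) -----------------------
oracle_min_injections <- function(starts, ends, cap, max_k = 4L) {
  n <- length(starts)
  feasible <- function(idx) {
    if (length(idx) <= cap) {
      if (length(idx) <= 1) return(TRUE)
    }
    oracle_max_concurrency(starts[idx], ends[idx]) <= cap
  }
  best <- Inf
  assign_next <- function(i, groups) {
    if (length(groups) >= best) return()
    if (i > n) {
      best <<- min(best, length(groups))
      return()
    }
    for (g in seq_along(groups)) {
      cand <- c(groups[[g]], i)
      if (feasible(cand)) {
        groups[[g]] <- cand
        assign_next(i + 1, groups)
        groups[[g]] <- cand[-length(cand)]
      }
    }
    if (length(groups) + 1 <= min(best - 1, max_k))
      assign_next(i + 1, c(groups, list(i)))
  }
  assign_next(1L, list(integer(0)))
  best
}

# --- Benjamini-Hochberg step-up, coded directly from the definition ---------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# --- exhaustive changepoint search (reimplementation of the two-segment
# least-squares model with plain loops) --------------------------------------
oracle_changepoint <- function(f, y, min_linear = 3L) {
  fs <- sort(unique(f))
  n_cand <- max(1L, length(fs) - min_linear + 1L)
  best_cp <- NA
  best_rss <- Inf
  for (ci in seq_len(n_cand)) {
    cp <- fs[ci]
    rss <- 0
    lo <- f < cp
    if (any(lo)) rss <- rss + sum((y[lo] - mean(y[lo]))^2)
    fx <- f[!lo]; fy <- y[!lo]
    if (length(unique(fx)) >= 2) {
      b <- sum((fx - mean(fx)) * (fy - mean(fy))) / sum((fx - mean(fx))^2)
      a <- mean(fy) - b * mean(fx)
      rss <- rss + sum((fy - a - b * fx)^2)
    } else rss <- rss + sum((fy - mean(fy))^2)
    if (!is.finite(best_rss) || rss < best_rss - 1e-9 * (1 + rss)) {
      best_rss <- rss
      best_cp <- cp
    }
  }
  best_cp
}

# --- pool-adjacent-violators isotonic regression ----------------------------
oracle_pava <- function(x, y) {
  o <- order(x)
  yy <- y[o]
  w <- rep(1, length(yy))
  repeat {
    viol <- which(diff(yy) < 0)
    if (!length(viol)) break
    i <- viol[1]
    m <- (w[i] * yy[i] + w[i + 1] * yy[i + 1]) / (w[i] + w[i + 1])
    yy[i] <- m
    w[i] <- w[i] + w[i + 1]
    yy <- yy[-(i + 1)]
    w <- w[-(i + 1)]
  }
  rep(yy, w)[order(order(x))]
}

# --- small fixture builders -------------------------------------------------
make_gauss_entry <- function(sequence = "PEPTIDEK", charge = 2L,
                             apex = 10, wid_min = 0.2, n_tr = 3L,
                             rel = NULL, step = 2.15 / 60,
                             height = 1000, rt = apex) {
  tt <- seq(apex - 3 * wid_min, apex + 3 * wid_min, by = step)
  if (is.null(rel)) rel <- seq(1, 0.5, length.out = n_tr)
  sig <- wid_min / 6.07 * 60  # 1%-base parameterization, seconds
  trs <- lapply(seq_len(n_tr), function(j)
    transition_trace(300 + 50 * j, paste0("y", j, "+"), tt,
                     height * rel[j] *
                       exp(-((tt - apex) * 60)^2 / (2 * sig^2))))
  chrom_entry(sequence, charge, "PROT1", rt, trs)
}

expect_lib_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  expect_equal(a$gradient_length, b$gradient_length)
  ka <- vapply(a$entries, function(e) paste(e$sequence, e$charge),
               character(1))
  kb <- vapply(b$entries, function(e) paste(e$sequence, e$charge),
               character(1))
  expect_setequal(ka, kb)
  for (i in seq_along(a$entries)) {
    ea <- a$entries[[i]]
    eb <- b$entries[[match(ka[i], kb)]]
    expect_equal(ea$precursor_mz, eb$precursor_mz, tolerance = 1e-9)
    expect_equal(ea$retention_time, eb$retention_time, tolerance = 1e-9)
    expect_setequal(ea$protein_ids, eb$protein_ids)
    expect_equal(length(ea$transitions), length(eb$transitions))
    for (j in seq_along(ea$transitions)) {
      ta <- ea$transitions[[j]]; tb <- eb$transitions[[j]]
      expect_equal(ta$fragment_mz, tb$fragment_mz, tolerance = 1e-9)
      expect_equal(ta$times, tb$times, tolerance = 1e-9)
      expect_equal(ta$intensities, tb$intensities, tolerance = 1e-9)
    }
  }
}
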