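test_that("peak detection recovers generator ground truth", {
  sim <- simulate_library(30, 30, noise = noise_model(
    multiplicative_cv = 0, interference_rate = 0, seed = 13))
  key <- paste(sim$truth$sequence, sim$truth$charge)
  rel_err <- numeric(0)
  for (e in sim$library$entries) {
    tr <- sim$truth[key == paste(e$sequence, e$charge), ][1, ]
    pk <- detect_peak(e)
    # apex within one grid step of truth
    expect_lt(abs(pk$apex_time - tr$apex_min), 2.15 / 60 + 1e-9)
    expect_lt(abs(pk$width - tr$width_base_s), 2.15)
    tot <- sum(sim$truth$area_cts_s[key == paste(e$sequence, e$charge)])
    # trapezoids on a 2.15-s grid discretize narrow peaks coarsely
    expect_lt(abs(pk$area - tot) / tot, 0.15)
    rel_err <- c(rel_err, abs(pk$area - tot) / tot)
  }
  expect_lt(median(rel_err), 0.05)
})

test_that("peak detection picks the candidate nearest the library RT", {
  tt <- seq(9, 12, by = 2.15 / 60)
  y <- 1000 * exp(-((tt - 9.7) * 60)^2 / (2 * 3^2)) +
    600 * exp(-((tt - 11.2) * 60)^2 / (2 * 3^2))
  e <- chrom_entry("AAAWNDK", 2, "P", 11.25,
                   list(transition_trace(400, "y4+", tt, y)))
  pk <- detect_peak(e)  # smaller second peak, but nearer the target RT
  expect_lt(abs(pk$apex_time - 11.2), 0.05)
  # flat zero trace: no peak
  e0 <- chrom_entry("AAAWNDK", 2, "P", 10,
                    list(transition_trace(400, "y4+", tt, rep(0, length(tt)))))
  expect_error(detect_peak(e0), "no peak")
})

test_that("coelution scoring separates clean and contaminated transitions", {
  e <- make_gauss_entry(n_tr = 4)
  pk <- detect_peak(e)
  lib <- chrom_library(list(e), 30)
  tq <- transition_quality(e, pk, lib)
  expect_equal(tq$coelution_score, rep(1, 4), tolerance = 1e-9)
  expect_false(any(tq$interfered))
  expect_equal(sum(tq$area_share), 1, tolerance = 1e-6)
  # generator-injected contaminant flagged
  sim <- simulate_library(40, 30, noise = noise_model(
    multiplicative_cv = 0, interference_rate = 0.3, seed = 17))
  key <- paste(sim$truth$sequence, sim$truth$charge)
  hits <- 0; total <- 0
  for (e2 in sim$library$entries) {
    tr <- sim$truth[key == paste(e2$sequence, e2$charge), ]
    if (!any(tr$interfered)) next
    tq2 <- transition_quality(e2, detect_peak(e2), sim$library)
    total <- total + sum(tr$interfered)
    hits <- hits + sum(tq2$interfered & tr$interfered)
  }
  expect_gt(hits / total, 0.95)
})

test_that("cross-precursor fragment collisions mark both transitions", {
  # two precursors 0.4 Th apart sharing a fragment within tolerance
  e1 <- make_gauss_entry("LLLNNNK", 2, apex = 10)
  e2 <- make_gauss_entry("LLLNNQK", 2, apex = 10.02)
  # force near-identical precursor m/z and exactly one shared fragment
  e2$precursor_mz <- e1$precursor_mz + 0.4
  for (j in seq_along(e2$transitions))
    e2$transitions[[j]]$fragment_mz <- e1$transitions[[j]]$fragment_mz + 37
  e2$transitions[[2]]$fragment_mz <- e1$transitions[[2]]$fragment_mz + 0.3
  lib <- chrom_library(list(e1, e2), 30)
  lib$entries[[1]]$peak <- detect_peak(e1)
  lib$entries[[2]]$peak <- detect_peak(e2)
  q1 <- transition_quality(e1, lib$entries[[1]]$peak, lib)
  q2 <- transition_quality(e2, lib$entries[[2]]$peak, lib)
  expect_true(q1$interfered[2])
  expect_true(q2$interfered[2])
  expect_false(q1$interfered[1])
})

test_that("precursor filtering reports the first failing criterion", {
  cfg <- refine_config(min_area = 500, min_width = 5.2, max_width = 26.1,
                       min_clean_transitions = 3)
  ok <- make_gauss_entry("AAANGWK", 2, apex = 5, wid_min = 0.2)
  small <- make_gauss_entry("CCCNGWK", 2, apex = 8, wid_min = 0.2,
                            height = 1)
  narrow <- make_gauss_entry("DDDNGWK", 2, apex = 11, wid_min = 0.05)
  wide <- make_gauss_entry("EEENGWK", 2, apex = 14, wid_min = 0.6)
  few <- make_gauss_entry("FFFNGWK", 2, apex = 17, n_tr = 2)
  lib <- chrom_library(list(ok, small, narrow, wide, few), 30)
  res <- filter_precursors(lib, cfg)
  expect_equal(length(res$accepted), 1)
  expect_equal(res$accepted$entries[[1]]$sequence, "AAANGWK")
  rep <- res$report
  expect_equal(rep$reason[rep$sequence == "CCCNGWK"], "area")
  expect_equal(rep$reason[rep$sequence == "DDDNGWK"], "width")
  expect_equal(rep$reason[rep$sequence == "EEENGWK"], "width")
  expect_equal(rep$reason[rep$sequence == "FFFNGWK"], "transitions")
  # vacuous thresholds accept everything
  allpass <- filter_precursors(lib, refine_config(
    min_area = 0, min_width = 0.001, max_width = Inf,
    min_clean_transitions = 1, coelution_threshold = 0))
  expect_equal(length(allpass$accepted), 5)
  # idempotence
  again <- filter_precursors(res$accepted, cfg)
  expect_equal(length(again$accepted), length(res$accepted))
})

test_that("accepted set matches the brute-force criterion oracle", {
  sim <- simulate_library(60, 30, noise = noise_model(
    multiplicative_cv = 0, interference_rate = 0.15, seed = 19))
  cfg <- refine_config(min_area = 1000, min_width = 8, max_width = 20,
                       min_clean_transitions = 3)
  res <- filter_precursors(sim$library, cfg)
  impl <- vapply(res$accepted$entries,
                 function(e) paste(e$sequence, e$charge), character(1))
  oracle <- oracle_accepted(sim$library, cfg)
  # disagreement allowed only within one grid step of a width bound
  excused <- res$report$sequence[
    abs(res$report$width_s - cfg$min_width) < 2.15 |
      abs(res$report$width_s - cfg$max_width) < 2.15]
  excused <- paste(excused, res$report$charge[
    abs(res$report$width_s - cfg$min_width) < 2.15 |
      abs(res$report$width_s - cfg$max_width) < 2.15])
  disagree <- c(setdiff(impl, oracle), setdiff(oracle, impl))
  expect_true(all(disagree %in% excused))
})

test_that("tightening any threshold never grows the accepted set", {
  sim <- simulate_library(40, 30, noise = noise_model(
    multiplicative_cv = 0.05, interference_rate = 0.15, seed = 23))
  base <- refine_config(min_area = 1000, min_width = 6, max_width = 30,
                        min_clean_transitions = 3)
  n0 <- length(filter_precursors(sim$library, base)$accepted)
  tighter <- list(
    refine_config(min_area = 5000, min_width = 6, max_width = 30,
                  min_clean_transitions = 3),
    refine_config(min_area = 1000, min_width = 10, max_width = 30,
                  min_clean_transitions = 3),
    refine_config(min_area = 1000, min_width = 6, max_width = 18,
                  min_clean_transitions = 3),
    refine_config(min_area = 1000, min_width = 6, max_width = 30,
                  min_clean_transitions = 5))
  for (cfg in tighter)
    expect_lte(length(filter_precursors(sim$library, cfg)$accepted), n0)
})

test_that("replicate-CV filtering uses non-log CV with optional TIC", {
  m <- rbind(a = c(100, 100, 160), b = c(100, 101, 99))
  kept30 <- filter_by_replicate_cv(m, 30)
  expect_setequal(kept30, c("a", "b"))  # 28.9% < 30
  kept20 <- filter_by_replicate_cv(m, 20)
  expect_equal(as.character(kept20), "b")
  expect_equal(unname(attr(kept30, "cv")["a"]),
               sd(c(100, 100, 160)) / mean(c(100, 100, 160)) * 100)
  # identical replicates: CV 0
  expect_setequal(filter_by_replicate_cv(rbind(x = c(5, 5, 5)), 30), "x")
  # a global 2x shift in one replicate is removed by TIC normalization
  m2 <- rbind(a = c(100, 100, 100), b = c(50, 50, 50))
  m2s <- m2
  m2s[, 2] <- m2s[, 2] * 2
  cv_plain <- attr(filter_by_replicate_cv(m2, 30, "tic"), "cv")
  cv_shift <- attr(filter_by_replicate_cv(m2s, 30, "tic"), "cv")
  expect_equal(cv_plain, cv_shift, tolerance = 1e-9)
  expect_warning(filter_by_replicate_cv(rbind(z = c(0, 0, 0),
                                              y = c(1, 1, 1)), 30),
                 "zero mean")
})

test_that("curve-performance selection respects its boundaries", {
  fom <- data.frame(
    precursor = rep(c("perfect", "boundary", "flat"), each = 2),
    fraction = rep(c(1, 0.5), 3),
    cv_pct = c(0, 0, 19.9, 19.9, 5, 5),
    observed_ratio = c(1, 0.5, 1, 0.5 * 1.49, 1, 0.98))
  kept <- select_by_curve_performance(fom)
  expect_true("perfect" %in% kept)
  expect_true("boundary" %in% kept)   # CV 19.9 < 20, deviation 49% <= 50%
  expect_false("flat" %in% kept)      # flat response: ratio off by ~96%
  fom$cv_pct[3:4] <- 20               # CV threshold is strict
  expect_false("boundary" %in% select_by_curve_performance(fom))
  # missing dilution points: skipped with a warning
  fom$observed_ratio[1] <- NA
  expect_warning(k2 <- select_by_curve_performance(fom), "missing")
  expect_false("perfect" %in% k2)
})
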