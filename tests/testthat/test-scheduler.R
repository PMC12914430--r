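test_that("cycle time is peak width over points per peak, rounded to 0.01 s", {
  expect_equal(compute_cycle_time(12.9, 6), 2.15)
  expect_equal(compute_cycle_time(12.93, 6), 2.15)
  expect_equal(compute_cycle_time(12, 7), 1.71)
  expect_equal(compute_cycle_time(13.07, 6), 2.18)
  expect_error(compute_cycle_time(12.9, 0))
  # exact pre-rounding identity
  w <- runif(20, 5, 45)
  p <- sample(4:9, 20, replace = TRUE)
  expect_equal(w / p * p, w)
})

test_that("scan duration combines scan-out, injection and overhead", {
  cfg <- schedule_config(scan_rate = 125000, scan_range = c(200, 1500),
                         min_injection_time = 15, per_scan_overhead = 0)
  expect_equal(scan_duration(cfg, 15), 1300 / 125000 + 0.015)
  expect_equal(scan_duration(cfg, 15), 0.0254)
  z <- schedule_config(scan_range = c(200, 200.001),
                       min_injection_time = 0, per_scan_overhead = 0)
  expect_lt(scan_duration(z, 0), 1e-7)
  # doubling the scan rate halves the scan-out term only
  cfg2 <- schedule_config(scan_rate = 250000, scan_range = c(200, 1500),
                          min_injection_time = 15, per_scan_overhead = 0)
  expect_equal(scan_duration(cfg, 15) - scan_duration(cfg2, 15),
               1300 / 125000 / 2)
})

test_that("capacity floors the cycle over the scan duration", {
  cfg <- schedule_config(per_scan_overhead = 0)
  expect_equal(capacity(2.15, cfg), 84)
  expect_equal(capacity(scan_duration(cfg), cfg), 1)
  expect_warning(k <- capacity(0.01, cfg), "capacity 0")
  expect_equal(k, 0)
  # non-increasing in injection time
  caps <- vapply(c(15, 30, 60, 120), function(it) capacity(2.15, cfg, it),
                 integer(1))
  expect_true(all(diff(caps) <= 0))
})

test_that("concurrency profile matches brute-force interval stabbing", {
  set.seed(7)
  n <- 500
  starts <- runif(n, 0, 28)
  tg <- data.frame(window_start = starts,
                   window_end = starts + runif(n, 0.2, 2))
  prof <- concurrency_profile(tg, 0.05)
  expect_equal(attr(prof, "max"),
               oracle_max_concurrency(tg$window_start, tg$window_end, 0.05))
  # disjoint windows -> max 1; identical windows -> max n
  expect_equal(attr(concurrency_profile(
    data.frame(window_start = 1:5, window_end = 1:5 + 0.4)), "max"), 1)
  expect_equal(attr(concurrency_profile(
    data.frame(window_start = rep(10, 10),
               window_end = rep(10.75, 10))), "max"), 10)
})

test_that("window optimization fits capacity and never loses the target RT", {
  sim <- simulate_library(80, 30, noise = noise_model(
    multiplicative_cv = 0, interference_rate = 0, seed = 29))
  plan <- optimize_windows(sim$library, schedule_config())
  tg <- plan$targets
  expect_true(all(tg$window_start <= tg$rt & tg$rt <= tg$window_end))
  expect_true(all(tg$window_end - tg$window_start >=
                    schedule_config()$min_window - 1e-9))
  expect_lte(attr(concurrency_profile(tg), "max"), plan$capacity)
  expect_equal(nrow(plan$overflow), 0)
})

test_that("overloaded retention times overflow by the pigeonhole principle", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "Q", "S", "T", "V", "W", "Y")
  mk_lib <- function(n, rt = 15) {
    chrom_library(lapply(seq_len(n), function(i)
      chrom_entry(paste0(aa[(i - 1) %% 17 + 1], aa[(i - 1) %/% 17 + 1],
                         "NGWK"), 2, "P", rt,
        list(transition_trace(300 + i, "y1+",
                              seq(rt - 0.3, rt + 0.3, by = 0.036),
                              rep(1, 17))))), 30)
  }
  cfg <- schedule_config()
  cap <- capacity(2.15, cfg)
  lib <- mk_lib(cap + 25)
  plan <- optimize_windows(lib, cfg)
  expect_equal(nrow(plan$overflow), 25)
  expect_equal(nrow(plan$targets), cap)
  # split puts them into exactly two injections
  plan2 <- split_injections(plan, cfg)
  expect_equal(plan2$n_injections, 2)
  for (inj in unique(plan2$targets$injection))
    expect_lte(attr(concurrency_profile(
      plan2$targets[plan2$targets$injection == inj, ]), "max"),
      plan2$capacity)
  # all fitting in one injection stays one injection
  small <- optimize_windows(mk_lib(cap - 1), cfg)
  expect_equal(split_injections(small, cfg)$n_injections, 1)
})

test_that("greedy injection count is within one of the exhaustive optimum", {
  cfg <- schedule_config()
  set.seed(31)
  for (case in 1:6) {
    n <- sample(6:12, 1)
    rts <- runif(n, 10, 11)
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "Q")
    lib <- chrom_library(lapply(seq_len(n), function(i)
      chrom_entry(paste0(aa[i], "AANGWK"), 2, "P", rts[i],
                  list(transition_trace(300 + i, "y1+",
                                        seq(rts[i] - 0.3, rts[i] + 0.3,
                                            by = 0.036), rep(1, 17))))), 30)
    cap <- sample(2:4, 1)
    plan <- optimize_windows(lib, cfg)
    plan$capacity <- cap
    greedy <- tryCatch(split_injections(plan, schedule_config(
      max_injections = 6))$n_injections, error = function(e) Inf)
    d <- rbind(plan$targets, plan$overflow)
    opt <- oracle_min_injections(d$window_start, d$window_end, cap,
                                 max_k = 6L)
    expect_lte(greedy, opt + 1)
  }
})

test_that("increasing the window floor never decreases injections", {
  sim <- simulate_library(60, 30, noise = noise_model(
    multiplicative_cv = 0, interference_rate = 0, seed = 37),
    rt_range = c(0.3, 0.5))
  cfg_small <- schedule_config(min_window = 0.75, max_injections = 10)
  cfg_big <- schedule_config(min_window = 2.5, max_injections = 10)
  n1 <- split_injections(optimize_windows(sim$library, cfg_small),
                         cfg_small)$n_injections
  n2 <- split_injections(optimize_windows(sim$library, cfg_big),
                         cfg_big)$n_injections
  expect_gte(n2, n1)
})

test_that("target lists export deterministically and round-trip", {
  sim <- simulate_library(20, 30, noise = noise_model(seed = 41))
  plan <- optimize_windows(sim$library, schedule_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  export_target_list(plan, path)
  back <- read_target_list(path)
  expect_equal(back$cycle_time, plan$cycle_time)
  expect_equal(back$capacity, plan$capacity)
  expect_equal(nrow(back$targets), nrow(plan$targets))
  expect_setequal(back$targets$sequence, plan$targets$sequence)
  # ties on window start are ordered by m/z
  p2 <- plan
  p2$targets <- data.frame(
    sequence = c("BBNGWK", "AANGWK"), charge = 2,
    precursor_mz = c(700, 500), rt = 10,
    window_start = 9.6, window_end = 10.4, injection = 0L)
  export_target_list(p2, path)
  out <- read.delim(path, comment.char = "#")
  expect_equal(out$precursor_mz, c(500, 700))
  # empty plan: header only
  p2$targets <- p2$targets[0, ]
  export_target_list(p2, path)
  expect_equal(nrow(read.delim(path, comment.char = "#")), 0)
})
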