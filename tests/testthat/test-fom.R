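mk_curve <- function(fractions = c(1, 0.5, 0.1, 0.05, 0.01),
                     reps = 3, A = 1e4, B = 0, noise_cv = 0,
                     n_tr = 4, seed = 1, model = c("linear", "flat"),
                     bad_tr = NULL, bad_level = NULL) {
  model <- match.arg(model)
  set.seed(seed)
  rel <- seq(1, 0.4, length.out = n_tr)
  pts <- do.call(rbind, lapply(fractions, function(f) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      mu <- if (model == "linear") pmax(f * A, B) else A
      a <- mu * rel / sum(rel)
      if (!is.null(bad_tr))  # noisy fraction-independent contamination
        a[bad_tr] <- a[bad_tr] + bad_level * exp(rnorm(1, 0, 0.6))
      if (noise_cv > 0) a <- a * pmax(0, rnorm(n_tr, 1, noise_cv))
      data.frame(fraction = f, replicate = r,
                 ion_label = paste0("y", seq_len(n_tr), "+"), area = a)
    }))
  }))
  calibration_curve("ELVISLIVESK", 2, pts)
}

test_that("a clean linear curve is quantifiable down to its lowest point", {
  fit <- fit_fom(mk_curve())
  expect_equal(fit$lod, 0.01)
  expect_equal(fit$loq, 0.01)
  expect_length(fit$flags, 0)
  expect_lte(fit$lod, fit$loq)
  expect_equal(unname(coef(fit)["slope"]) , 1e4, tolerance = 1e-6)
})

test_that("a fraction-independent response is flagged not quantifiable", {
  fit <- fit_fom(mk_curve(model = "flat", noise_cv = 0.02))
  expect_true("not_quantifiable" %in% fit$flags)
  expect_equal(fit$loq, 1)
  expect_lte(fit$lod, fit$loq)
})

test_that("the changepoint equals the exhaustive-search oracle", {
  set.seed(53)
  for (i in 1:25) {
    cv <- runif(1, 0, 0.15)
    B <- 10^runif(1, 2, 3.5)
    cur <- mk_curve(A = 1e4, B = B, noise_cv = cv, seed = 100 + i)
    d <- prmflow:::.curve_sums(cur, NULL)
    mod <- prmflow:::.fit_changepoint(d$fraction, d$area, 3L)
    expect_equal(mod$cp, oracle_changepoint(d$fraction, d$area, 3L))
  }
})

test_that("LOD tracks the generator's background crossover", {
  # B/A = 0.05: the response flattens below fraction 0.05
  hits <- 0
  for (i in 1:40) {
    cur <- mk_curve(fractions = c(1, 0.7, 0.5, 0.3, 0.1, 0.05, 0.01,
                                  0.005, 0.001),
                    A = 1e4, B = 500, noise_cv = 0.05, seed = 200 + i)
    fit <- fit_fom(cur)
    if (fit$lod %in% c(0.01, 0.05, 0.1)) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.8)
})

test_that("bootstrap LOQ is deterministic per peptide and bounded by noise", {
  cur <- mk_curve(noise_cv = 0.08, seed = 7)
  f1 <- fit_fom(cur)
  f2 <- fit_fom(cur)
  expect_equal(f1$loq, f2$loq)
  expect_equal(f1$boot_cv, f2$boot_cv)
  # heavier replicate noise never lowers the median LOQ (paired seeds)
  loq_lo <- loq_hi <- numeric(20)
  for (i in 1:20) {
    loq_lo[i] <- fit_fom(mk_curve(noise_cv = 0.03, seed = 300 + i,
                                  B = 300))$loq
    loq_hi[i] <- fit_fom(mk_curve(noise_cv = 0.25, seed = 300 + i,
                                  B = 300))$loq
  }
  expect_gte(median(loq_hi), median(loq_lo))
})

test_that("transition optimization drops the contaminated transition", {
  # one transition with a large fraction-independent add-on inflates the
  # low-fraction signal
  cur <- mk_curve(noise_cv = 0.05, bad_tr = 2, bad_level = 2000, seed = 11)
  full <- fit_fom(cur)
  res <- optimize_transitions(cur)
  expect_false("y2+" %in% res$selected_transitions)
  expect_lte(res$loq, full$loq)
  expect_lte(res$lod, res$loq)
  # all-clean curves keep the full set
  clean <- mk_curve(noise_cv = 0.02, seed = 13)
  res2 <- optimize_transitions(clean)
  expect_setequal(res2$selected_transitions, paste0("y", 1:4, "+"))
  expect_lte(res2$loq, fit_fom(clean)$loq)
})

test_that("CV tables use raw areas and are scale invariant", {
  pts <- data.frame(fraction = rep(c(1, 0.5, 0.1, 0.05), each = 3),
                    replicate = rep(1:3, 4),
                    ion_label = "y1+",
                    area = c(90, 100, 110, rep(50, 3), rep(10, 3),
                             rep(5, 3)))
  cur <- calibration_curve("PEPTIDEK", 2, pts)
  cv <- cv_table(cur)
  expect_equal(cv$cv_pct[cv$fraction == 1], 10, tolerance = 1e-3)
  expect_equal(cv$cv_pct[cv$fraction == 0.5], 0)
  pts2 <- pts
  pts2$area <- pts2$area * 7
  expect_equal(cv_table(calibration_curve("PEPTIDEK", 2, pts2))$cv_pct,
               cv$cv_pct)
  # zero-mean point flagged
  pts3 <- pts
  pts3$area[pts3$fraction == 0.05] <- 0
  expect_warning(cv_table(calibration_curve("PEPTIDEK", 2, pts3)),
                 "zero-mean")
})

test_that("ratio accuracy reports log2 observed vs expected", {
  cur <- mk_curve()
  ra <- ratio_accuracy(cur)
  expect_equal(ra$observed_log2[ra$fraction == 1], 0)
  expect_equal(ra$observed_log2[ra$fraction == 0.5], -1, tolerance = 1e-9)
  expect_equal(ra$deviation, rep(0, nrow(ra)), tolerance = 1e-9)
  # background-dominated peptide flattens: positive deviation at low f
  curb <- mk_curve(A = 1e4, B = 2000)
  rab <- ratio_accuracy(curb)
  expect_gt(rab$deviation[rab$fraction == 0.01], 1)
})

test_that("curves integrate from trace-level runs with boundary transfer", {
  apex <- 12
  mk_run <- function(f, r, scale = 1)
    list(lib = chrom_library(list(
      make_gauss_entry("AAAWNDK", 2, apex = apex, height = 1000 * f * scale,
                       n_tr = 3)), 30),
      fraction = f, replicate = r)
  runs <- list()
  bounds <- list()
  ref_b <- c(apex - 0.15, apex + 0.15)
  for (f in c(1, 0.5, 0.1, 0.05)) for (r in 1:2) {
    runs[[length(runs) + 1]] <- mk_run(f, r)
    bounds[[length(bounds) + 1]] <-
      transfer_boundaries(ref_b, warp_function("identity"))
  }
  cur <- integrate_curve(runs, bounds, "AAAWNDK", 2)
  d <- prmflow:::.curve_sums(cur, NULL)
  a1 <- mean(d$area[d$fraction == 1])
  expect_equal(mean(d$area[d$fraction == 0.5]) / a1, 0.5, tolerance = 1e-6)
  # per-point sums are additive over transitions
  expect_equal(sum(d$area), sum(cur$points$area))
  # boundaries shifted off-peak give near-zero areas
  off <- lapply(seq_along(runs), function(i) ref_b + 0.4)
  cur2 <- integrate_curve(runs, off, "AAAWNDK", 2)
  expect_lt(sum(cur2$points$area), 1e-6 * sum(cur$points$area))
  # boundaries fully outside the run error out
  expect_error(integrate_curve(runs[1], list(c(25, 26)), "AAAWNDK", 2),
               "outside")
})
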