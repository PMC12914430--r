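#' A matrix-matched calibration curve for one precursor
#'
#' @param sequence,charge precursor identity.
#' @param points data.frame with `fraction` (in `(0,1]`), `replicate`,
#'   `ion_label`, `area`.
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(sequence, charge, points) {
  stopifnot(all(c("fraction", "replicate", "ion_label", "area") %in%
                  names(points)))
  fs <- sort(unique(points$fraction))
  if (length(fs) < 4L || !1 %in% fs)
    stop("calibration curve needs >= 4 distinct fractions including 1.0")
  nrep <- tapply(points$replicate, points$fraction,
                 function(r) length(unique(r)))
  if (any(nrep < 2L))
    stop("every evaluated fraction needs >= 2 replicates")
  structure(list(sequence = sequence, charge = as.integer(charge),
                 points = points),
            class = "calibration_curve")
}

#' Figure-of-merit fitting parameters
#'
#' @param cv_ceiling bootstrap-CV ceiling defining the LOQ, percent.
#' @param bootstrap_reps bootstrap draws (>= 10).
#' @param seed base seed; the per-peptide bootstrap seed is derived from it
#'   and the peptide identity, so results are reproducible per peptide.
#' @param min_points_in_linear_segment minimum fractions in the linear
#'   segment.
#' @param signal_factor quantifiability gate: the fitted response at
#'   fraction 1.0 must exceed the fitted noise level by this factor.
#' @return object of class `fom_config`.
#' @export
fom_config <- function(cv_ceiling = 20, bootstrap_reps = 100L, seed = 1L,
                       min_points_in_linear_segment = 3L,
                       signal_factor = 1.5) {
  stopifnot(bootstrap_reps >= 10L)
  structure(list(cv_ceiling = cv_ceiling,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 min_points_in_linear_segment =
                   as.integer(min_points_in_linear_segment),
                 signal_factor = signal_factor),
            class = "fom_config")
}

.pep_seed <- function(sequence, charge, base = 0L) {
  h <- 0
  for (v in utf8ToInt(sequence)) h <- (h * 31 + v) %% 2147480009
  as.integer((h + 131 * charge + base) %% 2147480009)
}

# summed area per (fraction, replicate) over the selected transitions
.curve_sums <- function(curve, transitions = NULL) {
  p <- curve$points
  if (!is.null(transitions)) p <- p[p$ion_label %in% transitions, ,
                                    drop = FALSE]
  agg <- aggregate(area ~ fraction + replicate, data = p, FUN = sum)
  agg[order(agg$fraction, agg$replicate), , drop = FALSE]
}

# least-squares two-segment fit with the changepoint fixed at fraction cp:
# constant noise level below cp, straight line at/above cp
.segfit <- function(f, y, cp) {
  lo <- f < cp
  noise_level <- if (any(lo)) mean(y[lo]) else NA_real_
  fx <- f[!lo]; fy <- y[!lo]
  if (length(unique(fx)) >= 2L) {
    vx <- sum((fx - mean(fx))^2)
    slope <- sum((fx - mean(fx)) * (fy - mean(fy))) / vx
    intercept <- mean(fy) - slope * mean(fx)
  } else {
    slope <- 0; intercept <- mean(fy)
  }
  rss <- (if (any(lo)) sum((y[lo] - noise_level)^2) else 0) +
    sum((fy - (intercept + slope * fx))^2)
  list(cp = cp, noise_level = noise_level, slope = slope,
       intercept = intercept, rss = rss)
}

.segpredict <- function(mod, f) {
  ifelse(f < mod$cp & !is.na(mod$noise_level), mod$noise_level,
         mod$intercept + mod$slope * f)
}

# exhaustive changepoint search over measured fractions; tie -> lower cp
.fit_changepoint <- function(f, y, min_linear) {
  fs <- sort(unique(f))
  cands <- fs[seq_len(max(1L, length(fs) - min_linear + 1L))]
  forced <- length(fs) < min_linear
  fits <- lapply(cands, function(cp) .segfit(f, y, cp))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- fits[[which(rss <= min(rss) + 1e-9 * (1 + min(rss)))[1]]]
  best$forced <- forced
  best
}

#' Fit calibration figures of merit (LOD/LOQ) for one precursor
#'
#' Fits a two-segment response model of summed transition area versus
#' dilution fraction: a flat noise segment at low fractions and a straight
#' line above, with the changepoint chosen by exhaustive least squares over
#' the measured fractions (ties to the lower changepoint). The LOD is the
#' changepoint fraction. The LOQ is the smallest measured fraction at or
#' above the LOD whose bootstrap CV of the fitted prediction (replicates
#' resampled within each point) is at or below `cv_ceiling`; when no
#' fraction qualifies, or when the fitted line is flat (slope <= 0, or the
#' response at 1.0 within `signal_factor` of the noise level), the curve is
#' flagged not quantifiable with LOD = LOQ = 1.0.
#'
#' @param curve a [calibration_curve()].
#' @param transitions ion labels to sum (default: all).
#' @param cfg a [fom_config()].
#' @return object of class `fom_fit` with elements `lod`, `loq`, `flags`,
#'   `model` (changepoint, noise level, slope, intercept), `boot_cv`
#'   (per-fraction bootstrap CV, percent), `transitions`, `data`.
#' @export
fit_fom <- function(curve, transitions = NULL, cfg = fom_config()) {
  d <- .curve_sums(curve, transitions)
  f <- d$fraction; y <- d$area
  fs <- sort(unique(f))
  mod <- .fit_changepoint(f, y, cfg$min_points_in_linear_segment)
  flags <- character(0)
  if (mod$forced) flags <- c(flags, "forced_changepoint")
  ref_level <- if (!is.na(mod$noise_level)) mod$noise_level else
    .segpredict(mod, fs[1])
  quantifiable <- mod$slope > 0 &&
    .segpredict(mod, 1) > cfg$signal_factor * max(ref_level, 0)
  # bootstrap CV of the fitted prediction at each measured fraction
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(.pep_seed(curve$sequence, curve$charge, cfg$seed))
  idx_by_f <- split(seq_along(f), f)
  preds <- matrix(NA_real_, cfg$bootstrap_reps, length(fs))
  for (b in seq_len(cfg$bootstrap_reps)) {
    bi <- unlist(lapply(idx_by_f, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    bm <- .fit_changepoint(f[bi], y[bi], cfg$min_points_in_linear_segment)
    preds[b, ] <- .segpredict(bm, fs)
  }
  mu <- colMeans(preds)
  boot_cv <- ifelse(mu > 0, apply(preds, 2L, sd) / mu * 100, Inf)
  names(boot_cv) <- fs
  if (!quantifiable) {
    lod <- 1; loq <- 1
    flags <- c(flags, "not_quantifiable")
  } else {
    lod <- mod$cp
    ok <- fs >= lod & boot_cv <= cfg$cv_ceiling
    if (any(ok)) loq <- min(fs[ok]) else {
      loq <- 1
      flags <- c(flags, "not_quantifiable")
      if (lod > 1) lod <- 1
    }
  }
  structure(list(sequence = curve$sequence, charge = curve$charge,
                 lod = lod, loq = loq, flags = flags, model = mod,
                 boot_cv = boot_cv,
                 transitions = if (is.null(transitions))
                   unique(curve$points$ion_label) else transitions,
                 data = d, cfg = cfg),
            class = "fom_fit")
}

#' @export
print.fom_fit <- function(x, ...) {
  cat("Calibration figures of merit:", x$sequence, paste0("+", x$charge),
      "\n  LOD", signif(x$lod, 3), " LOQ", signif(x$loq, 3),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
      else "", "\n  transitions:", paste(x$transitions, collapse = " "),
      "\n")
  invisible(x)
}

#' @export
coef.fom_fit <- function(object, ...) {
  c(changepoint = object$model$cp, noise_level = object$model$noise_level,
    slope = object$model$slope, intercept = object$model$intercept)
}

#' @export
predict.fom_fit <- function(object, fraction = NULL, ...) {
  if (is.null(fraction)) fraction <- sort(unique(object$data$fraction))
  .segpredict(object$model, fraction)
}

#' @export
plot.fom_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$fraction, d$area, log = "xy",
                 xlab = "dilution fraction", ylab = "summed area",
                 main = paste(x$sequence, paste0("+", x$charge)), ...)
  fx <- exp(seq(log(min(d$fraction)), log(1), length.out = 100))
  graphics::lines(fx, pmax(.segpredict(x$model, fx), .Machine$double.xmin),
                  col = 2)
  graphics::abline(v = x$loq, lty = 2, col = 4)
  invisible(x)
}

#' Optimize the transition subset for the best LOQ
#'
#' Greedy backward elimination from the full transition set: repeatedly
#' drop the transition whose removal most lowers the LOQ (ties keep the
#' higher-area transition, i.e. the lower-area one is dropped), never going
#' below 3 transitions, stopping when no removal lowers the LOQ. The final
#' LOQ is never worse than the full-set LOQ.
#'
#' @param curve a [calibration_curve()].
#' @param cfg a [fom_config()].
#' @return a `fom_result`: list with `lod`, `loq`, `selected_transitions`,
#'   `cv_by_point`, `log2_ratio_by_point`, `fit` (the final `fom_fit`).
#' @export
optimize_transitions <- function(curve, cfg = fom_config()) {
  all_tr <- unique(curve$points$ion_label)
  if (length(all_tr) < 3L)
    stop("transition optimization needs >= 3 transitions")
  tr_area <- tapply(curve$points$area, curve$points$ion_label, sum)
  cur <- all_tr
  cur_fit <- fit_fom(curve, cur, cfg)
  while (length(cur) > 3L) {
    drops <- lapply(cur, function(tr) fit_fom(curve, setdiff(cur, tr), cfg))
    loqs <- vapply(drops, `[[`, numeric(1), "loq")
    if (min(loqs) >= cur_fit$loq) break
    best <- which(loqs <= min(loqs) + 1e-12)
    # among equally good removals, drop the lowest-area transition
    best <- best[order(tr_area[cur[best]])][1]
    cur <- setdiff(cur, cur[best])
    cur_fit <- drops[[best]]
  }
  structure(list(sequence = curve$sequence, charge = curve$charge,
                 lod = cur_fit$lod, loq = cur_fit$loq,
                 selected_transitions = cur,
                 cv_by_point = cv_table(curve, cur),
                 log2_ratio_by_point = ratio_accuracy(curve, cur),
                 fit = cur_fit),
            class = "fom_result")
}

#' @export
print.fom_result <- function(x, ...) {
  cat("fom_result:", x$sequence, paste0("+", x$charge), " LOD",
      signif(x$lod, 3), " LOQ", signif(x$loq, 3), " (",
      length(x$selected_transitions), "transitions )\n")
  invisible(x)
}

#' Replicate CV per dilution point
#'
#' CV is sd/mean x 100 on raw (non-log) summed areas.
#'
#' @param curve a [calibration_curve()].
#' @param transitions ion labels to sum (default: all).
#' @return data.frame with `fraction`, `cv_pct` (`NA` and a warning for
#'   zero-mean points).
#' @export
cv_table <- function(curve, transitions = NULL) {
  d <- .curve_sums(curve, transitions)
  fs <- sort(unique(d$fraction))
  cv <- vapply(fs, function(fr) {
    y <- d$area[d$fraction == fr]
    if (mean(y) == 0) return(NA_real_)
    sd(y) / mean(y) * 100
  }, numeric(1))
  if (anyNA(cv)) warning("zero-mean dilution point(s): CV undefined")
  data.frame(fraction = fs, cv_pct = cv)
}

#' Ratio accuracy per dilution point
#'
#' Observed log2 ratio of mean summed area at each fraction to the mean at
#' 1.0, against the expected `log2(fraction)`.
#'
#' @param curve a [calibration_curve()].
#' @param transitions ion labels to sum (default: all).
#' @return data.frame with `fraction`, `observed_log2`, `expected_log2`,
#'   `deviation`.
#' @export
ratio_accuracy <- function(curve, transitions = NULL) {
  d <- .curve_sums(curve, transitions)
  m1 <- mean(d$area[d$fraction == 1])
  if (m1 == 0) stop("zero mean area at the 100% point")
  fs <- sort(unique(d$fraction))
  obs <- vapply(fs, function(fr) log2(mean(d$area[d$fraction == fr]) / m1),
                numeric(1))
  data.frame(fraction = fs, observed_log2 = obs, expected_log2 = log2(fs),
             deviation = obs - log2(fs))
}

#' Integrate a calibration curve from trace-level runs
#'
#' Computes per-transition trapezoidal areas within per-run integration
#' boundaries (typically transferred from the 100% run through
#' [transfer_boundaries()]). Missing traces yield zero area and a flag.
#'
#' @param runs list of runs; each a list with `lib` (a [chrom_library()]),
#'   `fraction`, `replicate`.
#' @param boundaries list parallel to `runs` of `c(start, end)` minutes.
#' @param sequence,charge precursor to integrate.
#' @return a [calibration_curve()]; attribute `"flags"` lists runs with
#'   missing or off-scale traces.
#' @export
integrate_curve <- function(runs, boundaries, sequence, charge) {
  rows <- list()
  flags <- character(0)
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    b <- boundaries[[i]]
    e <- NULL
    for (ent in r$lib$entries)
      if (ent$sequence == sequence && ent$charge == charge) e <- ent
    if (is.null(e)) {
      flags <- c(flags, paste0("run", i, ":missing"))
      next
    }
    rng <- range(e$transitions[[1]]$times)
    if (b[1] > rng[2] || b[2] < rng[1])
      stop("boundaries [", b[1], ", ", b[2], "] outside run ", i,
           " time range")
    for (tr in e$transitions) {
      inb <- tr$times >= b[1] & tr$times <= b[2]
      a <- if (sum(inb) >= 2L)
        .trapz(tr$times[inb], tr$intensities[inb]) * 60 else 0
      if (a == 0) flags <- c(flags, paste0("run", i, ":", tr$ion_label,
                                           ":zero"))
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = r$fraction, replicate = r$replicate,
        ion_label = tr$ion_label, area = a, stringsAsFactors = FALSE)
    }
  }
  out <- calibration_curve(sequence, charge, do.call(rbind, rows))
  attr(out, "flags") <- flags
  out
}
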