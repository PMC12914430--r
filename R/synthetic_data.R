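#' Noise model for synthetic chromatograms
#'
#' @param multiplicative_cv replicate/point-level multiplicative CV
#'   (fraction in `[0,1)`).
#' @param additive_floor uniform baseline noise ceiling, counts.
#' @param interference_rate fraction of transitions receiving a co-eluting
#'   contaminant peak.
#' @param seed integer seed driving all randomness of the generators.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0.1, additive_floor = 0,
                        interference_rate = 0.1, seed = 1L) {
  stopifnot(multiplicative_cv >= 0, multiplicative_cv < 1,
            interference_rate >= 0, interference_rate < 1,
            additive_floor >= 0)
  structure(list(multiplicative_cv = multiplicative_cv,
                 additive_floor = additive_floor,
                 interference_rate = interference_rate,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Peak-shape prior for the library generator
#'
#' Widths are base widths: the span at 1% of apex height, the same
#' definition the peak detector measures, defaulting to 8-20 s (mean 14 s,
#' matching the ~13.9 s average peaks of a 30-min ion-trap gradient).
#' Asymmetry is the exponential-tail factor of an exponentially modified
#' Gaussian; apex intensities are log-uniform.
#'
#' @param width_range_s base-width range, seconds.
#' @param asymmetry_range exponential tail factor range (>= 0).
#' @param intensity_range apex intensity range, counts (log-uniform draw).
#' @return object of class `shape_prior`.
#' @export
shape_prior <- function(width_range_s = c(8, 20), asymmetry_range = c(0, 0.8),
                        intensity_range = c(1e3, 1e5)) {
  if (any(width_range_s <= 0) || diff(width_range_s) < 0 ||
      any(asymmetry_range < 0) || diff(asymmetry_range) < 0 ||
      any(intensity_range < 0))
    stop("degenerate shape prior: ranges must be non-negative and ordered")
  structure(list(width_range_s = width_range_s,
                 asymmetry_range = asymmetry_range,
                 intensity_range = intensity_range),
            class = "shape_prior")
}

.erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# Exponentially modified Gaussian evaluated at minutes t, parameterized by
# base width (span at 1% of apex) and tail factor; returns intensities with
# max apex_intensity at apex_time, plus the numerically measured ground
# truth (apex, base width, unit-apex area in counts*seconds).
.emg_shape <- function(t_min, apex_time, width_base_s, asymmetry,
                       apex_intensity) {
  sigma <- width_base_s / (6.07 + 4.61 * asymmetry)  # seconds, first guess
  tau <- asymmetry * sigma
  f <- function(ts) {  # ts: seconds relative to mu; log-space for stability
    if (tau < 0.02 * sigma) return(exp(-ts^2 / (2 * sigma^2)))
    z <- sigma / tau - ts / sigma
    lh <- sigma^2 / (2 * tau^2) - ts / tau + log(2) +
      pnorm(-z, log.p = TRUE)
    h <- exp(lh - max(lh[is.finite(lh)]))
    h[!is.finite(h)] <- 0
    h
  }
  measure <- function() {
    fine <- seq(-4 * sigma - 2 * tau, 4 * sigma + 8 * tau, by = 0.01)
    yf <- f(fine)
    pk <- max(yf)
    above <- which(yf >= 0.01 * pk)
    list(fine = fine, yf = yf, pk = pk, mode_s = fine[which.max(yf)],
         width = fine[above[length(above)]] - fine[above[1]],
         above = above)
  }
  m0 <- measure()
  # time axis scales linearly with (sigma, tau): one rescale pins the
  # measured 1% base width to the requested value
  sc <- width_base_s / m0$width
  sigma <- sigma * sc
  tau <- tau * sc
  m0 <- measure()
  fine <- m0$fine; yf <- m0$yf; pk <- m0$pk
  mode_s <- m0$mode_s
  width_meas <- m0$width
  # ground-truth area within the 1% base, matching the integration-boundary
  # definition the peak detector measures
  ab <- m0$above
  area_unit <- sum(diff(fine[ab]) *
                     (head(yf[ab], -1) + tail(yf[ab], -1)) / 2) / pk
  y <- f((t_min - apex_time) * 60 + mode_s) / pk * apex_intensity
  list(y = y, width_base_s = width_meas,
       area_cts_s = area_unit * apex_intensity)
}

#' Simulate a chromatogram library with known ground truth
#'
#' Each precursor receives 4-8 transitions sharing an exponentially
#' modified Gaussian elution profile with distinct fragment m/z and
#' relative intensities, sampled on a fixed cycle-time grid. A configurable
#' fraction of transitions receives an added offset contaminant peak.
#' Ground truth (true apex, base width, noiseless per-transition area,
#' interference flags) is returned alongside the library.
#'
#' @param n_precursors number of precursors (>= 1).
#' @param gradient_length gradient length, minutes.
#' @param shape_prior a [shape_prior()].
#' @param noise a [noise_model()]; its `seed` fixes all randomness.
#' @param sample_interval_s chromatogram sampling grid (the acquisition
#'   cycle time), seconds.
#' @param rt_range elution range as fractions of the gradient; peptides do
#'   not elute in the void volume, so the default starts at 12%.
#' @param n_transitions_range inclusive range for transitions per precursor.
#' @return list with `library` (a [chrom_library()]) and `truth`
#'   (data.frame, one row per transition: sequence, charge, ion_label,
#'   fragment_mz, rel_intensity, apex_min, width_base_s, area_cts_s,
#'   interfered).
#' @export
simulate_library <- function(n_precursors, gradient_length = 30,
                             shape_prior = prmflow::shape_prior(),
                             noise = noise_model(),
                             sample_interval_s = 2.15,
                             rt_range = c(0.12, 0.92),
                             n_transitions_range = c(4L, 8L)) {
  stopifnot(n_precursors >= 1, gradient_length > 0)
  set.seed(noise$seed)
  res_pool <- setdiff(names(.RESIDUE_MASS), c("K", "R", "P"))
  entries <- vector("list", n_precursors)
  truth <- list()
  seen <- character(0)
  for (i in seq_len(n_precursors)) {
    repeat {
      len <- sample(7:18, 1L)
      seqn <- paste0(paste(sample(res_pool, len - 1L, replace = TRUE),
                           collapse = ""),
                     sample(c("K", "R"), 1L))
      charge <- sample(2:3, 1L)
      if (!paste(seqn, charge) %in% seen) break
    }
    seen <- c(seen, paste(seqn, charge))
    apex <- runif(1, rt_range[1], rt_range[2]) * gradient_length
    wb <- runif(1, shape_prior$width_range_s[1], shape_prior$width_range_s[2])
    asym <- runif(1, shape_prior$asymmetry_range[1],
                  shape_prior$asymmetry_range[2])
    inten <- exp(runif(1, log(shape_prior$intensity_range[1]),
                       log(shape_prior$intensity_range[2])))
    ntr <- sample(n_transitions_range[1]:n_transitions_range[2], 1L)
    rel <- sort(runif(ntr, 0.15, 1), decreasing = TRUE)
    rel <- rel / max(rel)
    frag <- sort(runif(ntr, 200, 1400))
    pad <- max(0.4, 2.5 * wb / 60)
    tt <- seq(apex - pad, apex + pad, by = sample_interval_s / 60)
    trs <- vector("list", ntr)
    for (j in seq_len(ntr)) {
      sh <- .emg_shape(tt, apex, wb, asym, inten * rel[j])
      y <- sh$y
      interf <- runif(1) < noise$interference_rate
      c_off <- NA_real_; c_int <- NA_real_; c_wb <- NA_real_
      if (interf) {
        # contaminant inside the peak base (0.3-0.6 base-width offset) with
        # comparable intensity: it co-integrates with the peak rather than
        # resolving into a separate one, and decorrelates the trace shape
        c_off <- sample(c(-1, 1), 1L) * runif(1, 0.3, 0.6) *
          sh$width_base_s / 60
        c_int <- runif(1, 1.0, 2.0) * inten * rel[j]
        c_wb <- wb * runif(1, 0.9, 1.1)
        y <- y + .emg_shape(tt, apex + c_off, c_wb, asym, c_int)$y
      }
      if (noise$multiplicative_cv > 0)
        y <- y * pmax(0, rnorm(length(y), 1, noise$multiplicative_cv))
      if (noise$additive_floor > 0)
        y <- y + runif(length(y), 0, noise$additive_floor)
      trs[[j]] <- transition_trace(frag[j], paste0("t", j, "+"), tt, y)
      truth[[length(truth) + 1L]] <- data.frame(
        sequence = seqn, charge = charge, ion_label = paste0("t", j, "+"),
        fragment_mz = frag[j], rel_intensity = rel[j],
        apex_min = apex, width_base_s = sh$width_base_s,
        asymmetry = asym, area_cts_s = sh$area_cts_s, interfered = interf,
        contam_offset_min = c_off, contam_intensity = c_int,
        contam_width_s = c_wb, stringsAsFactors = FALSE)
    }
    entries[[i]] <- chrom_entry(seqn, charge, protein_ids = paste0("SYN", i),
                                retention_time = apex, transitions = trs)
  }
  list(library = chrom_library(entries, gradient_length,
                               metadata = list(source = "simulate_library",
                                               seed = noise$seed)),
       truth = do.call(rbind, truth))
}

#' Matrix-matched dilution design
#'
#' @param fractions dilution fractions in `(0, 1]`, strictly descending and
#'   including 1.0. Default is the 13-point volumetric series 100% to 0.1%.
#' @param replicates replicate injections per point.
#' @param background_response counts contributed by the background matrix to
#'   each peptide regardless of dilution (recycled over peptides).
#' @return object of class `dilution_design`.
#' @export
dilution_design <- function(fractions = c(1, 0.7, 0.5, 0.3, 0.1, 0.07, 0.05,
                                          0.03, 0.01, 0.007, 0.005, 0.003,
                                          0.001),
                            replicates = 3L, background_response = 0) {
  stopifnot(all(fractions > 0), all(fractions <= 1), 1 %in% fractions,
            all(diff(fractions) < 0), replicates >= 1)
  structure(list(fractions = fractions, replicates = as.integer(replicates),
                 background_response = background_response),
            class = "dilution_design")
}

#' Simulate a matrix-matched calibration run set
#'
#' Expected per-transition area at dilution fraction f is
#' `f * true_area + background + additive_floor`, with multiplicative
#' replicate noise at the configured CV. Peptides listed in
#' `shared_with_background` get a fraction-independent response (the analyte
#' sequence also exists in the background matrix), which is what flattens
#' low-dilution ratios.
#'
#' @param truth ground-truth table from [simulate_library()].
#' @param design a [dilution_design()].
#' @param noise a [noise_model()].
#' @param shared_with_background peptide sequences with fraction-independent
#'   response.
#' @param background_model `"additive"` (expected area
#'   `f * A + B + floor`) or `"floor"` (`max(f * A, B) + floor`): the floor
#'   model emulates detection-limited integration, where below the
#'   crossover the integrated signal is matrix background only, so the
#'   response is genuinely flat below `B / A`.
#' @return data.frame: sequence, charge, ion_label, fraction, replicate,
#'   area.
#' @export
simulate_calibration <- function(truth, design = dilution_design(),
                                 noise = noise_model(),
                                 shared_with_background = character(0),
                                 background_model = c("additive", "floor")) {
  background_model <- match.arg(background_model)
  set.seed(noise$seed + 7L)
  key <- paste(truth$sequence, truth$charge)
  pep <- unique(key)
  bg <- rep_len(design$background_response, length(pep))
  names(bg) <- pep
  out <- list()
  for (i in seq_len(nrow(truth))) {
    k <- key[i]
    share <- truth$rel_intensity[i] /
      sum(truth$rel_intensity[key == k])
    shared <- truth$sequence[i] %in% shared_with_background
    for (f in design$fractions) {
      f_eff <- if (shared) 1 else f
      mu <- if (background_model == "additive")
        f_eff * truth$area_cts_s[i] + bg[k] * share + noise$additive_floor
      else
        max(f_eff * truth$area_cts_s[i], bg[k] * share) +
          noise$additive_floor
      a <- mu * if (noise$multiplicative_cv > 0)
        pmax(0, rnorm(design$replicates, 1, noise$multiplicative_cv)) else
          rep(1, design$replicates)
      out[[length(out) + 1L]] <- data.frame(
        sequence = truth$sequence[i], charge = truth$charge[i],
        ion_label = truth$ion_label[i], fraction = f,
        replicate = seq_len(design$replicates), area = a,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Monotone retention-time warp
#'
#' Maps reference time to run time. Kinds: `identity`; `linear_shift`
#' (constant offset `shift`); `linear_stretch` (`intercept + slope * t`);
#' `piecewise` (monotone linear interpolant through `knots`, extrapolating
#' with the end-segment slopes).
#'
#' @param kind warp kind.
#' @param shift minutes, for `linear_shift`.
#' @param intercept,slope for `linear_stretch` (`slope > 0`).
#' @param knots data.frame with columns `reference`, `run`, both strictly
#'   increasing, for `piecewise`.
#' @return object of class `warp_fun`.
#' @export
warp_function <- function(kind = c("identity", "linear_shift",
                                   "linear_stretch", "piecewise"),
                          shift = 0, intercept = 0, slope = 1, knots = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear_stretch" && slope <= 0)
    stop("stretch slope must be positive")
  if (kind == "piecewise") {
    stopifnot(is.data.frame(knots), all(c("reference", "run") %in%
                                          names(knots)), nrow(knots) >= 2)
    if (any(diff(knots$reference) <= 0) || any(diff(knots$run) <= 0))
      stop("warp knots must be strictly increasing in both coordinates")
  }
  structure(list(kind = kind, shift = shift, intercept = intercept,
                 slope = slope, knots = knots),
            class = "warp_fun")
}

#' Evaluate a warp at reference times
#'
#' @param warp a [warp_function()].
#' @param t reference times, minutes.
#' @return run times, minutes.
#' @export
warp_time <- function(warp, t) {
  switch(warp$kind,
         identity = t,
         linear_shift = t + warp$shift,
         linear_stretch = warp$intercept + warp$slope * t,
         piecewise = {
           k <- warp$knots
           y <- approx(k$reference, k$run, xout = t, rule = 2)$y
           n <- nrow(k)
           sl1 <- (k$run[2] - k$run[1]) / (k$reference[2] - k$reference[1])
           sln <- (k$run[n] - k$run[n - 1]) /
             (k$reference[n] - k$reference[n - 1])
           lo <- t < k$reference[1]
           hi <- t > k$reference[n]
           y[lo] <- k$run[1] + sl1 * (t[lo] - k$reference[1])
           y[hi] <- k$run[n] + sln * (t[hi] - k$reference[n])
           y
         })
}

#' @export
predict.warp_fun <- function(object, t, ...) warp_time(object, t)

#' Invert a warp
#'
#' @param warp a [warp_function()].
#' @return the inverse warp (run time back to reference time).
#' @export
invert_warp <- function(warp) {
  switch(warp$kind,
         identity = warp,
         linear_shift = warp_function("linear_shift", shift = -warp$shift),
         linear_stretch = warp_function("linear_stretch",
                                        intercept = -warp$intercept /
                                          warp$slope,
                                        slope = 1 / warp$slope),
         piecewise = warp_function("piecewise",
                                   knots = data.frame(
                                     reference = warp$knots$run,
                                     run = warp$knots$reference)))
}

#' Apply a retention-time warp to an acquisition or library
#'
#' Every event time t becomes `warp(t)`; intensities are unchanged.
#'
#' @param x a `dia_run` (event table) or [chrom_library()].
#' @param warp a [warp_function()] (must be monotone).
#' @return the warped object.
#' @export
apply_warp <- function(x, warp) UseMethod("apply_warp")

#' @export
apply_warp.dia_run <- function(x, warp) {
  x$time <- warp_time(warp, x$time)
  x
}

#' @export
apply_warp.chrom_library <- function(x, warp) {
  for (i in seq_along(x$entries)) {
    e <- x$entries[[i]]
    e$retention_time <- warp_time(warp, e$retention_time)
    for (j in seq_along(e$transitions))
      e$transitions[[j]]$times <- warp_time(warp, e$transitions[[j]]$times)
    if (!is.null(e$peak)) {
      b <- warp_time(warp, c(e$peak$boundary_start, e$peak$apex_time,
                             e$peak$boundary_end))
      e$peak <- peak_feature(b[2], b[1], b[3], e$peak$area)
    }
    x$entries[[i]] <- e
  }
  x
}

#' Render a library as a wide-window DIA acquisition event stream
#'
#' Each precursor contributes its summed transition trace as MS events at
#' its precursor m/z, the signal the real-time alignment scans observe.
#'
#' @param lib a [chrom_library()].
#' @param rel_floor detection floor relative to each precursor's apex:
#'   points below it are not emitted (far peak tails are below the
#'   instrument noise floor, and after per-slice normalization they would
#'   otherwise carry full weight in the alignment map).
#' @return object of class `dia_run`: data.frame with `time` (minutes),
#'   `mz`, `intensity`; attribute `gradient_length`.
#' @export
simulate_dia_run <- function(lib, rel_floor = 0.005) {
  out <- lapply(lib$entries, function(e) {
    st <- .summed_trace(e)
    keep <- st$sum > rel_floor * max(st$sum)
    if (!any(keep)) return(NULL)
    data.frame(time = st$times[keep], mz = e$precursor_mz,
               intensity = st$sum[keep])
  })
  run <- do.call(rbind, out)
  run <- run[order(run$time, run$mz), , drop = FALSE]
  rownames(run) <- NULL
  structure(run, class = c("dia_run", "data.frame"),
            gradient_length = lib$gradient_length)
}
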