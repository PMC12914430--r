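#' Alignment parameters
#'
#' @param update_period shift-update cadence as a fraction of the expected
#'   peak width (default 1/5: five updates per LC peak).
#' @param search_half_width half-width of the shift search around the prior
#'   estimate during initial lock-on, minutes.
#' @param track_half_width narrower search half-width used once a shift has
#'   been locked (retention-time drift is slow relative to the update
#'   cadence, and a narrow tracking search avoids spurious matches in
#'   sparse gradient regions), minutes.
#' @param similarity `"cosine"` or `"dot"`.
#' @param smoothing number of most recent anchors used by the monotone warp
#'   fit.
#' @param lookback span of recent scans fed to each shift estimate, minutes.
#' @param min_similarity confidence floor: estimates whose best similarity
#'   falls below it are discarded (the prior shift is kept and no anchor is
#'   laid), so sparse low-signal stretches cannot walk the alignment away.
#' @return object of class `align_config`.
#' @export
align_config <- function(update_period = 0.2, search_half_width = 1.5,
                         track_half_width = 0.25,
                         similarity = c("cosine", "dot"), smoothing = 25L,
                         lookback = 1.0, min_similarity = 0.5) {
  similarity <- match.arg(similarity)
  stopifnot(update_period > 0, search_half_width > 0, lookback > 0,
            track_half_width > 0, min_similarity >= 0)
  structure(list(update_period = update_period,
                 search_half_width = search_half_width,
                 track_half_width = track_half_width,
                 similarity = similarity, smoothing = as.integer(smoothing),
                 lookback = lookback, min_similarity = min_similarity),
            class = "align_config")
}

.bin_events <- function(run, time_bin, mz_edges, t_start, n_rows) {
  m <- matrix(0, nrow = n_rows, ncol = length(mz_edges) - 1L)
  ti <- floor((run$time - t_start) / time_bin) + 1L
  mi <- findInterval(run$mz, mz_edges, rightmost.closed = TRUE)
  ok <- ti >= 1L & ti <= n_rows & mi >= 1L & mi <= ncol(m)
  for (i in which(ok)) m[ti[i], mi[i]] <- m[ti[i], mi[i]] + run$intensity[i]
  m
}

.row_normalize <- function(m) {
  rs <- rowSums(m)
  nz <- rs > 0
  m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  m
}

#' Compress a wide-window DIA run into a reference map
#'
#' Intensities are summed into a uniform time x m/z grid and each time
#' slice normalized to unit sum (all-zero slices stay zero), giving an
#' intensity-scale-free fingerprint of the gradient that a running
#' acquisition can be compared against in real time.
#'
#' @param run a `dia_run` (see [simulate_dia_run()]).
#' @param time_bin time bin width, minutes.
#' @param mz_edges m/z bin edges; default twelve 50-Th bins over 400-1000.
#' @param provenance free-text source run id.
#' @return object of class `reference_map`.
#' @export
compress_reference <- function(run, time_bin = 0.05,
                               mz_edges = seq(400, 1000, by = 50),
                               provenance = "unknown") {
  if (!nrow(run)) stop("empty run")
  glen <- attr(run, "gradient_length")
  if (is.null(glen)) glen <- max(run$time)
  n_rows <- ceiling(glen / time_bin) + 1L
  m <- .bin_events(run, time_bin, mz_edges, 0, n_rows)
  structure(list(time_bin = time_bin, t_start = 0, n_rows = n_rows,
                 mz_edges = mz_edges, intensity = .row_normalize(m),
                 gradient_length = glen, provenance = provenance,
                 version = "1.0"),
            class = "reference_map")
}

#' Serialize a reference map to a portable container
#'
#' A versioned, self-describing JSON document (grid definition plus the
#' normalized intensity matrix).
#'
#' @param ref a `reference_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  obj <- ref
  obj$intensity <- as.vector(ref$intensity)
  obj$dim <- dim(ref$intensity)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized reference map
#'
#' @param path file written by [write_reference()].
#' @return a `reference_map`.
#' @export
read_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$intensity <- matrix(obj$intensity, nrow = obj$dim[1],
                          ncol = obj$dim[2])
  obj$dim <- NULL
  obj$n_rows <- as.integer(obj$n_rows)
  structure(obj, class = "reference_map")
}

#' Estimate the current retention-time shift against the reference
#'
#' Evaluates candidate shifts on the reference time-bin grid within
#' `search_half_width` of the prior and returns the one maximizing the
#' similarity between the recent run scans and the shifted reference (run
#' time = reference time + shift). Ties break toward the prior; an all-zero
#' window returns the prior flagged `attr(,"flagged")`.
#'
#' @param window data.frame of recent run events (`time`, `mz`,
#'   `intensity`).
#' @param ref a `reference_map`.
#' @param prior_shift minutes.
#' @param cfg an [align_config()].
#' @return shift in minutes; attribute `"flagged"` TRUE when no signal was
#'   available.
#' @export
estimate_shift <- function(window, ref, prior_shift = 0,
                           cfg = align_config()) {
  if (!nrow(window) || all(window$intensity <= 0)) {
    out <- prior_shift
    attr(out, "flagged") <- TRUE
    return(out)
  }
  tb <- ref$time_bin
  t0 <- floor(min(window$time) / tb) * tb
  n <- ceiling((max(window$time) - t0) / tb) + 1L
  wm <- .row_normalize(.bin_events(window, tb, ref$mz_edges, t0, n))
  wv <- as.vector(t(wm))
  ks <- seq(round((prior_shift - cfg$search_half_width) / tb),
            round((prior_shift + cfg$search_half_width) / tb))
  sims <- vapply(ks, function(k) {
    # run rows [t0, ...] correspond to reference rows at t0 - shift
    ri <- round((t0 - k * tb) / tb) + seq_len(n)
    ok <- ri >= 1L & ri <= ref$n_rows
    rm <- matrix(0, n, length(ref$mz_edges) - 1L)
    rm[ok, ] <- ref$intensity[ri[ok], , drop = FALSE]
    rv <- as.vector(t(rm))
    if (cfg$similarity == "dot") return(sum(wv * rv))
    den <- sqrt(sum(wv^2)) * sqrt(sum(rv^2))
    if (den == 0) 0 else sum(wv * rv) / den
  }, numeric(1))
  best <- max(sims)
  if (cfg$similarity == "cosine" && best < cfg$min_similarity) {
    out <- prior_shift
    attr(out, "flagged") <- TRUE
    return(out)
  }
  cand <- ks[sims >= best - 1e-12]
  k_star <- cand[order(abs(cand * tb - prior_shift), cand)][1]
  out <- k_star * tb
  attr(out, "flagged") <- FALSE
  attr(out, "similarity") <- best
  out
}

#' Fit a monotone warp through alignment anchors
#'
#' Anchors are isotonic-regressed (run time as a non-decreasing function of
#' estimated reference time) and joined by a piecewise-linear interpolant
#' that extrapolates with its end-segment slopes. Flat isotonic stretches
#' are lifted by a microscopic ramp so the warp stays strictly monotone.
#'
#' @param anchors data.frame with `run_time` and `ref_time` (minutes).
#' @return a [warp_function()] of kind `piecewise` mapping reference time to
#'   run time.
#' @export
fit_warp <- function(anchors) {
  stopifnot(nrow(anchors) >= 2L)
  o <- order(anchors$ref_time, anchors$run_time)
  x <- anchors$ref_time[o]
  y <- anchors$run_time[o]
  iso <- isoreg(x, y)$yf
  ux <- !duplicated(x)
  x <- x[ux]; iso <- iso[ux]
  eps <- 1e-9
  iso <- iso + seq_along(iso) * eps  # break flat ties, keep strictness
  if (length(x) < 2L) {
    x <- c(x, x + 1); iso <- c(iso, iso + 1)
  }
  # pad both ends with knots at the whole-span slope so extrapolation is
  # robust to closely spaced (grid-quantized) end anchors
  n <- length(x)
  sl <- (iso[n] - iso[1]) / (x[n] - x[1])
  if (!is.finite(sl) || sl <= 0) sl <- 1
  x <- c(x[1] - 1, x, x[n] + 1)
  iso <- c(iso[1] - sl, iso, iso[n] + sl)
  warp_function("piecewise", knots = data.frame(reference = x, run = iso))
}

#' Transfer peak boundaries through a warp
#'
#' Maps integration boundaries picked in a reference run (e.g. the 100%
#' calibration point) into a target run's time scale.
#'
#' @param boundaries numeric vector `c(start, end)` or a data.frame with
#'   `boundary_start`, `boundary_end` (minutes, reference scale).
#' @param warp a [warp_function()] (reference -> target run).
#' @return same shape as `boundaries`, mapped.
#' @export
transfer_boundaries <- function(boundaries, warp) {
  if (is.data.frame(boundaries)) {
    boundaries$boundary_start <- warp_time(warp, boundaries$boundary_start)
    boundaries$boundary_end <- warp_time(warp, boundaries$boundary_end)
    return(boundaries)
  }
  warp_time(warp, boundaries)
}

#' Emulate a scheduled PRM acquisition with adaptive real-time alignment
#'
#' Advances an acquisition clock in cycle-time steps over a (possibly
#' retention-time-warped) run. At every `update_period * peak_width`, the
#' shift against the reference map is re-estimated from scans acquired
#' before that instant (the emulated real-time constraint) and target
#' windows are re-mapped through the maintained monotone warp. A target is
#' covered when at least `points_per_peak` cycles sample it inside its true
#' warped peak base.
#'
#' @param plan a `schedule_plan` (single injection; filter first for
#'   multi-injection plans).
#' @param run the warped `dia_run` the instrument observes.
#' @param ref the `reference_map` built from the unwarped reference run.
#' @param cfg an [align_config()].
#' @param scfg the [schedule_config()] used for the plan.
#' @param truth ground-truth table of [simulate_library()] (true apexes and
#'   base widths, reference time scale).
#' @param true_warp the [warp_function()] actually applied to the run.
#' @param align when `FALSE`, the shift stays 0 and windows are taken as
#'   scheduled (the no-alignment control).
#' @return list with `coverage` (per-target data.frame: sequence, charge,
#'   n_points, covered), `state` (anchors, shift trace), and
#'   `coverage_rate`.
#' @export
simulate_acquisition <- function(plan, run, ref, cfg = align_config(),
                                 scfg = schedule_config(), truth,
                                 true_warp = warp_function("identity"),
                                 align = TRUE) {
  tg <- plan$targets
  stopifnot(length(unique(tg$injection)) == 1L)
  key <- paste(tg$sequence, tg$charge)
  tr1 <- truth[!duplicated(paste(truth$sequence, truth$charge)), ]
  ti <- match(key, paste(tr1$sequence, tr1$charge))
  if (anyNA(ti)) stop("plan targets missing from ground truth")
  base_lo <- warp_time(true_warp, tr1$apex_min[ti] -
                         tr1$width_base_s[ti] / 120)
  base_hi <- warp_time(true_warp, tr1$apex_min[ti] +
                         tr1$width_base_s[ti] / 120)
  ct_min <- plan$cycle_time / 60
  upd_min <- cfg$update_period * scfg$expected_peak_width / 60
  glen <- attr(run, "gradient_length")
  if (is.null(glen)) glen <- max(run$time)
  t_end <- max(glen, max(base_hi)) + ct_min
  run <- run[order(run$time), , drop = FALSE]
  shift <- 0
  warp <- NULL
  anchors <- data.frame(run_time = numeric(0), ref_time = numeric(0))
  shift_trace <- list()
  n_pts <- integer(nrow(tg))
  next_update <- 0
  clock <- 0
  while (clock <= t_end) {
    if (align && clock >= next_update) {
      win <- run[run$time > clock - cfg$lookback & run$time <= clock, ,
                 drop = FALSE]
      ecfg <- cfg
      if (nrow(anchors)) ecfg$search_half_width <- cfg$track_half_width
      est <- estimate_shift(win, ref, prior_shift = shift, cfg = ecfg)
      if (!isTRUE(attr(est, "flagged"))) {
        shift <- as.numeric(est)
        anchors <- rbind(anchors,
                         data.frame(run_time = clock,
                                    ref_time = clock - shift))
        recent <- tail(anchors, cfg$smoothing)
        if (nrow(recent) >= 2L) warp <- fit_warp(recent)
      }
      shift_trace[[length(shift_trace) + 1L]] <-
        data.frame(run_time = clock, shift = shift,
                   flagged = isTRUE(attr(est, "flagged")))
      next_update <- next_update + upd_min
    }
    ws <- tg$window_start
    we <- tg$window_end
    if (align) {
      if (!is.null(warp)) {
        ws <- warp_time(warp, ws)
        we <- warp_time(warp, we)
      } else {
        ws <- ws + shift
        we <- we + shift
      }
    }
    active <- which(ws <= clock & clock <= we)
    if (length(active) > plan$capacity)
      active <- active[order(ws[active])][seq_len(plan$capacity)]
    hit <- active[base_lo[active] <= clock & clock <= base_hi[active]]
    n_pts[hit] <- n_pts[hit] + 1L
    clock <- clock + ct_min
  }
  cov <- data.frame(sequence = tg$sequence, charge = tg$charge,
                    n_points = n_pts,
                    covered = n_pts >= scfg$points_per_peak,
                    stringsAsFactors = FALSE)
  list(coverage = cov,
       state = list(anchors = anchors,
                    shift_trace = do.call(rbind, shift_trace)),
       coverage_rate = mean(cov$covered))
}
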