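#' Detected chromatographic peak
#'
#' @param apex_time,boundary_start,boundary_end minutes.
#' @param area summed transition area within the boundaries.
#' @return object of class `peak_feature`; `width` is seconds between the
#'   boundaries.
#' @export
peak_feature <- function(apex_time, boundary_start, boundary_end, area) {
  if (!(boundary_start < apex_time && apex_time < boundary_end))
    stop("peak boundaries must bracket the apex")
  structure(list(apex_time = apex_time, boundary_start = boundary_start,
                 boundary_end = boundary_end,
                 width = (boundary_end - boundary_start) * 60,
                 area = area),
            class = "peak_feature")
}

#' Refinement thresholds
#'
#' Defaults follow the filtering regime used for ion-trap survey assays:
#' minimum summed area 1000, integration-boundary width between 5.2 and
#' 26.1 s, and at least three interference-free transitions; coelution and
#' collision tolerances reflect unit-resolution trap fragments (0.7 Th) and
#' 1 Th precursor isolation.
#'
#' @param min_area minimum summed transition area (counts).
#' @param min_width,max_width integration-boundary width bounds, seconds.
#' @param min_clean_transitions minimum interference-free transitions.
#' @param coelution_threshold minimum Pearson coelution score in `[0,1]`.
#' @param fragment_tolerance fragment collision tolerance, Th.
#' @param isolation_width precursor isolation width, Th.
#' @return object of class `refine_config`.
#' @export
refine_config <- function(min_area = 1000, min_width = 5.2, max_width = 26.1,
                          min_clean_transitions = 3L,
                          coelution_threshold = 0.9,
                          fragment_tolerance = 0.7, isolation_width = 1.0) {
  stopifnot(min_width < max_width, min_clean_transitions >= 1)
  structure(list(min_area = min_area, min_width = min_width,
                 max_width = max_width,
                 min_clean_transitions = as.integer(min_clean_transitions),
                 coelution_threshold = coelution_threshold,
                 fragment_tolerance = fragment_tolerance,
                 isolation_width = isolation_width),
            class = "refine_config")
}

# 3-point moving average, ends kept
.smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  c(x[1], (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3, x[n])
}

# summed transition trace on the first transition's time grid
.summed_trace <- function(entry) {
  t0 <- entry$transitions[[1]]$times
  y <- rep(0, length(t0))
  for (tr in entry$transitions) {
    yi <- if (identical(tr$times, t0)) tr$intensities else
      approx(tr$times, tr$intensities, xout = t0, rule = 2)$y
    y <- y + yi
  }
  list(times = t0, sum = y)
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Detect the chromatographic peak of a library entry
#'
#' The summed transition trace is smoothed with a 3-point moving average;
#' candidate apexes are local maxima at or above 10% of the global maximum
#' and the candidate nearest the entry's library retention time is chosen
#' (ties go to the taller candidate). Boundaries walk outward to the nearest
#' point where the smoothed sum falls below 1% of the apex, or to a local
#' minimum below 10% of the apex; the area is the trapezoidal integral of
#' the raw sum between the boundaries.
#'
#' @param entry a [chrom_entry()] with at least 5 points per transition.
#' @return a [peak_feature()].
#' @export
detect_peak <- function(entry) {
  st <- .summed_trace(entry)
  if (length(st$times) < 5L)
    stop("entry ", entry$sequence, "/", entry$charge,
         ": need >= 5 points for peak detection")
  s <- .smooth3(st$sum)
  if (all(s <= 0))
    stop("entry ", entry$sequence, "/", entry$charge,
         ": all-zero traces, no peak")
  n <- length(s)
  gmax <- max(s)
  is_lmax <- vapply(seq_len(n), function(i) {
    l <- if (i > 1L) s[i - 1] else -Inf
    r <- if (i < n) s[i + 1] else -Inf
    s[i] >= l && s[i] >= r
  }, logical(1))
  cand <- which(is_lmax & s >= 0.1 * gmax)
  if (!length(cand)) cand <- which.max(s)
  rt <- entry$retention_time
  d <- abs(st$times[cand] - rt)
  cand <- cand[order(d, -s[cand])]
  apex_i <- cand[1]
  apex <- s[apex_i]
  stop_here <- function(i) {
    if (s[i] < 0.01 * apex) return(TRUE)
    l <- if (i > 1L) s[i - 1] else Inf
    r <- if (i < n) s[i + 1] else Inf
    s[i] < 0.1 * apex && s[i] <= l && s[i] <= r
  }
  lo <- apex_i
  while (lo > 1L && !stop_here(lo - 1L)) lo <- lo - 1L
  hi <- apex_i
  while (hi < n && !stop_here(hi + 1L)) hi <- hi + 1L
  # sub-grid boundary at the 1% crossing, interpolated on the raw sum (the
  # smoothed trace decides the search limits; the raw trace carries the
  # true base width, which smoothing would inflate by a grid step per side)
  thr <- 0.01 * st$sum[apex_i]
  lim_lo <- max(lo - 1L, 1L)
  lim_hi <- min(hi + 1L, n)
  t_lo <- st$times[lim_lo]
  j <- apex_i
  while (j > lim_lo) {
    if (st$sum[j - 1L] < thr) {
      t_lo <- st$times[j] - (st$times[j] - st$times[j - 1L]) *
        (st$sum[j] - thr) / (st$sum[j] - st$sum[j - 1L])
      break
    }
    j <- j - 1L
  }
  t_hi <- st$times[lim_hi]
  j <- apex_i
  while (j < lim_hi) {
    if (st$sum[j + 1L] < thr) {
      t_hi <- st$times[j] + (st$times[j + 1L] - st$times[j]) *
        (st$sum[j] - thr) / (st$sum[j] - st$sum[j + 1L])
      break
    }
    j <- j + 1L
  }
  ti <- c(t_lo, st$times[lo:hi], t_hi)
  yi <- c(approx(st$times, st$sum, t_lo)$y, st$sum[lo:hi],
          approx(st$times, st$sum, t_hi)$y)
  keep <- !duplicated(ti)
  area <- .trapz(ti[keep], yi[keep]) * 60  # counts * s
  peak_feature(st$times[apex_i], t_lo, t_hi, area)
}

#' Score transition coelution and interference
#'
#' The coelution score is the Pearson correlation of each transition against
#' the median transition profile inside the peak boundaries, clipped to
#' `[0,1]`. A transition is interfered when its score falls below the
#' coelution threshold, or when another library precursor within the
#' isolation width has a fragment within the fragment tolerance and a peak
#' overlapping this one.
#'
#' @param entry a [chrom_entry()].
#' @param peak the entry's [peak_feature()].
#' @param context the parent [chrom_library()] (for cross-precursor fragment
#'   collisions); entries are expected to carry `$peak` (see
#'   [filter_precursors()]), otherwise boundary overlap falls back to the
#'   library retention time.
#' @param cfg a [refine_config()].
#' @return data.frame with `ion_label`, `fragment_mz`, `coelution_score`,
#'   `interfered`, `area_share`.
#' @export
transition_quality <- function(entry, peak, context, cfg = refine_config()) {
  t0 <- entry$transitions[[1]]$times
  inb <- t0 >= peak$boundary_start & t0 <= peak$boundary_end
  prof <- vapply(entry$transitions, function(tr) {
    yi <- if (identical(tr$times, t0)) tr$intensities else
      approx(tr$times, tr$intensities, xout = t0, rule = 2)$y
    yi[inb]
  }, numeric(sum(inb)))
  prof <- matrix(prof, ncol = length(entry$transitions))
  if (nrow(prof) < 3L) {
    # too few in-boundary points to assess shape agreement
    score <- rep(0, ncol(prof))
    med <- rep(0, nrow(prof))
  } else {
    med <- apply(prof, 1L, median)
    score <- apply(prof, 2L, function(y) {
      if (sd(y) == 0 || sd(med) == 0) return(0)
      min(max(cor(y, med), 0), 1)
    })
  }
  areas <- vapply(seq_along(entry$transitions), function(j)
    .trapz(t0[inb], prof[, j]), numeric(1))
  share <- if (sum(areas) > 0) areas / sum(areas) else
    rep(1 / length(areas), length(areas))
  collide <- rep(FALSE, length(entry$transitions))
  frag_mz <- vapply(entry$transitions, `[[`, numeric(1), "fragment_mz")
  for (other in context$entries) {
    if (other$sequence == entry$sequence && other$charge == entry$charge) next
    if (abs(other$precursor_mz - entry$precursor_mz) > cfg$isolation_width)
      next
    ob <- if (!is.null(other$peak))
      c(other$peak$boundary_start, other$peak$boundary_end) else
      other$retention_time + c(-1, 1) * 0.25
    if (ob[2] < peak$boundary_start || ob[1] > peak$boundary_end) next
    omz <- vapply(other$transitions, `[[`, numeric(1), "fragment_mz")
    for (j in seq_along(frag_mz))
      if (any(abs(omz - frag_mz[j]) <= cfg$fragment_tolerance))
        collide[j] <- TRUE
  }
  data.frame(ion_label = vapply(entry$transitions, `[[`, character(1),
                                "ion_label"),
             fragment_mz = frag_mz,
             coelution_score = as.numeric(score),
             interfered = score < cfg$coelution_threshold | collide,
             area_share = share,
             stringsAsFactors = FALSE)
}

#' Filter library precursors into assay candidates
#'
#' Accepts a precursor when its peak area, boundary width and count of
#' interference-free transitions all pass the configured thresholds; the
#' report lists each rejection with the first failing criterion, checked in
#' the fixed order area, width, transitions.
#'
#' @param lib a [chrom_library()].
#' @param cfg a [refine_config()].
#' @return list with `accepted` (a [chrom_library()] whose entries carry
#'   `$peak`) and `report` (data.frame: sequence, charge, decision, reason,
#'   area, width_s, n_clean).
#' @export
filter_precursors <- function(lib, cfg = refine_config()) {
  peaks <- vector("list", length(lib$entries))
  for (i in seq_along(lib$entries))
    peaks[[i]] <- tryCatch(detect_peak(lib$entries[[i]]),
                           error = function(e) NULL)
  ctx <- lib
  for (i in seq_along(ctx$entries)) ctx$entries[[i]]$peak <- peaks[[i]]
  rows <- list()
  acc <- list()
  for (i in seq_along(ctx$entries)) {
    e <- ctx$entries[[i]]
    pk <- peaks[[i]]
    if (is.null(pk)) {
      rows[[i]] <- data.frame(sequence = e$sequence, charge = e$charge,
                              decision = "rejected", reason = "no_peak",
                              area = NA_real_, width_s = NA_real_,
                              n_clean = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    tq <- transition_quality(e, pk, ctx, cfg)
    n_clean <- sum(!tq$interfered)
    reason <- if (pk$area < cfg$min_area) "area"
      else if (pk$width < cfg$min_width || pk$width > cfg$max_width) "width"
      else if (n_clean < cfg$min_clean_transitions) "transitions"
      else ""
    rows[[i]] <- data.frame(sequence = e$sequence, charge = e$charge,
                            decision = if (reason == "") "accepted" else
                              "rejected",
                            reason = reason, area = pk$area,
                            width_s = pk$width, n_clean = n_clean,
                            stringsAsFactors = FALSE)
    if (reason == "") acc[[length(acc) + 1L]] <- e
  }
  list(accepted = chrom_library(acc, lib$gradient_length, lib$metadata),
       report = do.call(rbind, rows))
}

#' Filter precursors by replicate CV
#'
#' CV is computed on non-log areas (sd/mean x 100), optionally after total
#' ion current normalization of each replicate column.
#'
#' @param areas numeric matrix, precursors x replicates (rownames identify
#'   precursors).
#' @param threshold_pct keep precursors with CV strictly below this value.
#' @param normalize `"none"` or `"tic"`.
#' @return character vector of accepted precursor ids; attribute
#'   `"cv"` carries the CV per precursor.
#' @export
filter_by_replicate_cv <- function(areas, threshold_pct = 30,
                                   normalize = c("none", "tic")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(areas), ncol(areas) >= 2L)
  m <- areas
  if (normalize == "tic") {
    cs <- colSums(m)
    if (any(cs <= 0)) stop("zero-TIC replicate column")
    m <- sweep(m, 2L, cs, "/") * mean(cs)
  }
  mu <- rowMeans(m)
  cv <- apply(m, 1L, sd) / mu * 100
  zero <- !is.finite(cv) | mu == 0
  if (any(zero)) {
    warning(sum(zero), " precursor(s) with zero mean area excluded")
    cv[zero] <- Inf
  }
  out <- rownames(m)[cv < threshold_pct]
  attr(out, "cv") <- cv
  out
}

#' Down-select precursors on calibration-curve performance
#'
#' Keeps precursors whose replicate CV is strictly below `cv_threshold_pct`
#' and whose observed/expected dilution ratio deviates from 1 by at most
#' `ratio_tolerance` at every evaluated dilution point.
#'
#' @param fom data.frame with columns `precursor`, `fraction`, `cv_pct`,
#'   `observed_ratio` (mean area at the fraction over mean area at 1.0).
#' @param cv_threshold_pct CV ceiling, percent (strict).
#' @param ratio_tolerance allowed `|observed/expected - 1|` (inclusive).
#' @return character vector of retained precursor ids.
#' @export
select_by_curve_performance <- function(fom, cv_threshold_pct = 20,
                                        ratio_tolerance = 0.5) {
  need <- c("precursor", "fraction", "cv_pct", "observed_ratio")
  stopifnot(all(need %in% names(fom)))
  keep <- character(0)
  for (p in unique(fom$precursor)) {
    d <- fom[fom$precursor == p, , drop = FALSE]
    if (anyNA(d$cv_pct) || anyNA(d$observed_ratio)) {
      warning("precursor ", p, " has missing dilution points; skipped")
      next
    }
    dev <- abs(d$observed_ratio / d$fraction - 1)
    if (all(d$cv_pct < cv_threshold_pct) && all(dev <= ratio_tolerance))
      keep <- c(keep, p)
  }
  keep
}
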