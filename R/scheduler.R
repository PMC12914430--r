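#' Acquisition scheduling parameters
#'
#' Defaults reproduce the linear-ion-trap survey configuration: 125 kTh/s
#' scan rate over 200-1500 m/z, 15 ms minimum injection time, a 12.9 s
#' expected LC peak width with six points per peak (2.15 s cycle time), and
#' 0.75-min minimum scheduling windows.
#'
#' @param points_per_peak minimum sampling points across a peak.
#' @param expected_peak_width seconds.
#' @param scan_rate Th per second.
#' @param scan_range `c(low, high)` in Th.
#' @param min_injection_time ms.
#' @param min_window minimum scheduling window, minutes.
#' @param per_scan_overhead inter-scan processing overhead, ms.
#' @param max_injections maximum separate injections when splitting.
#' @return object of class `schedule_config`.
#' @export
schedule_config <- function(points_per_peak = 6L, expected_peak_width = 12.9,
                            scan_rate = 125000, scan_range = c(200, 1500),
                            min_injection_time = 15, min_window = 0.75,
                            per_scan_overhead = 2, max_injections = 3L) {
  stopifnot(points_per_peak >= 1, min_window > 0,
            scan_range[1] < scan_range[2], expected_peak_width > 0)
  structure(list(points_per_peak = as.integer(points_per_peak),
                 expected_peak_width = expected_peak_width,
                 scan_rate = scan_rate, scan_range = scan_range,
                 min_injection_time = min_injection_time,
                 min_window = min_window,
                 per_scan_overhead = per_scan_overhead,
                 max_injections = as.integer(max_injections)),
            class = "schedule_config")
}

#' Cycle time from expected peak width and points per peak
#'
#' @param expected_peak_width seconds.
#' @param points_per_peak sampling points per peak.
#' @return cycle time in seconds, rounded to 0.01 s.
#' @examples
#' compute_cycle_time(12.9, 6)   # 2.15
#' compute_cycle_time(12, 7)     # 1.71
#' compute_cycle_time(13.07, 6)  # 2.18
#' @export
compute_cycle_time <- function(expected_peak_width, points_per_peak) {
  stopifnot(expected_peak_width > 0, points_per_peak > 0)
  round(expected_peak_width / points_per_peak, 2)
}

#' Duration of one targeted scan
#'
#' Models an ion-trap scan as mass-range scan-out plus ion injection plus a
#' fixed inter-scan overhead.
#'
#' @param cfg a [schedule_config()].
#' @param injection_time ion injection time, ms (defaults to the configured
#'   minimum).
#' @return seconds.
#' @export
scan_duration <- function(cfg, injection_time = cfg$min_injection_time) {
  stopifnot(injection_time >= cfg$min_injection_time)
  diff(cfg$scan_range) / cfg$scan_rate + injection_time / 1000 +
    cfg$per_scan_overhead / 1000
}

#' Concurrent-target capacity of a cycle
#'
#' @param cycle_time seconds.
#' @param cfg a [schedule_config()].
#' @param injection_time ms.
#' @return integer: `floor(cycle_time / scan_duration)`.
#' @export
capacity <- function(cycle_time, cfg,
                     injection_time = cfg$min_injection_time) {
  stopifnot(cycle_time > 0)
  sd1 <- scan_duration(cfg, injection_time)
  k <- as.integer(floor(cycle_time / sd1 + 1e-9))
  if (k == 0L) warning("one scan exceeds the cycle time; capacity 0")
  k
}

#' Concurrency profile of scheduled windows
#'
#' Counts the scheduled windows covering each grid time, per injection.
#'
#' @param targets data.frame with `window_start`, `window_end` (minutes) and
#'   optionally `injection` (defaults to a single injection).
#' @param grid_step minutes.
#' @return list per injection with `time`, `count`, and `max`; overall
#'   maximum in attribute `"max"`.
#' @export
concurrency_profile <- function(targets, grid_step = 0.01) {
  if (is.null(targets$injection)) targets$injection <- 0L
  grid <- seq(floor(min(targets$window_start) / grid_step) * grid_step,
              max(targets$window_end), by = grid_step)
  out <- list()
  for (inj in sort(unique(targets$injection))) {
    d <- targets[targets$injection == inj, , drop = FALSE]
    cnt <- vapply(grid, function(g)
      sum(d$window_start <= g & g <= d$window_end), integer(1))
    out[[as.character(inj)]] <- list(time = grid, count = cnt,
                                     max = max(cnt))
  }
  attr(out, "max") <- max(vapply(out, `[[`, integer(1), "max"))
  out
}

.target_frame <- function(lib, cfg, rt_uncertainty) {
  rows <- lapply(lib$entries, function(e) {
    pw_min <- if (!is.null(e$peak)) e$peak$width / 60 else
      cfg$expected_peak_width / 60
    w <- max(cfg$min_window, 2 * rt_uncertainty + pw_min)
    data.frame(sequence = e$sequence, charge = e$charge,
               precursor_mz = e$precursor_mz, rt = e$retention_time,
               window_start = e$retention_time - w / 2,
               window_end = e$retention_time + w / 2,
               injection = 0L, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d[order(d$rt, d$precursor_mz, d$sequence), , drop = FALSE]
}

.new_plan <- function(targets, cycle_time, cap, overflow = NULL) {
  structure(list(targets = targets, cycle_time = cycle_time,
                 capacity = cap,
                 n_injections = length(unique(targets$injection)),
                 overflow = overflow),
            class = "schedule_plan")
}

#' @export
print.schedule_plan <- function(x, ...) {
  cat("schedule_plan:", nrow(x$targets), "targets,",
      x$n_injections, "injection(s), cycle", x$cycle_time,
      "s, capacity", x$capacity, "\n")
  if (!is.null(x$overflow) && nrow(x$overflow))
    cat("  overflow:", nrow(x$overflow), "targets unschedulable in one",
        "injection\n")
  invisible(x)
}

#' Schedule acquisition windows with optimized widths
#'
#' Windows start at `max(min_window, 2 * rt_uncertainty + peak width)`,
#' centered on the library retention time, then are symmetrically trimmed
#' (never below `min_window`, always containing the retention time) until
#' the concurrency at a 0.01-min grid fits the cycle capacity. Targets that
#' cannot fit a single injection even at `min_window` are returned in the
#' plan's `overflow` set for [split_injections()].
#'
#' @param accepted a [chrom_library()] of refined precursors (entries may
#'   carry `$peak` for per-target widths).
#' @param cfg a [schedule_config()].
#' @param rt_uncertainty half-width allowance for retention-time drift,
#'   minutes.
#' @return a `schedule_plan`.
#' @export
optimize_windows <- function(accepted, cfg = schedule_config(),
                             rt_uncertainty = 0.25) {
  ct <- compute_cycle_time(cfg$expected_peak_width, cfg$points_per_peak)
  cap <- capacity(ct, cfg)
  if (cap < 1L) stop("unschedulable: one scan does not fit the cycle time")
  d <- .target_frame(accepted, cfg, rt_uncertainty)
  step <- 0.01
  overflow_idx <- integer(0)
  repeat {
    act <- setdiff(seq_len(nrow(d)), overflow_idx)
    if (!length(act)) break
    prof <- concurrency_profile(d[act, , drop = FALSE], step)
    p <- prof[["0"]]
    over <- which(p$count > cap)
    if (!length(over)) break
    worst <- over[which.max(p$count[over])]
    tw <- p$time[worst]
    cov <- act[d$window_start[act] <= tw & tw <= d$window_end[act]]
    widths <- d$window_end[cov] - d$window_start[cov]
    shrinkable <- cov[widths > cfg$min_window + 1e-12]
    if (length(shrinkable)) {
      j <- shrinkable[which.max(d$window_end[shrinkable] -
                                  d$window_start[shrinkable])]
      w <- d$window_end[j] - d$window_start[j]
      w2 <- max(cfg$min_window, w - 2 * step)
      d$window_start[j] <- d$rt[j] - w2 / 2
      d$window_end[j] <- d$rt[j] + w2 / 2
    } else {
      # all at min_window: excess targets at this time go to the overflow
      keep <- cov[order(d$rt[cov], d$precursor_mz[cov])][seq_len(cap)]
      overflow_idx <- c(overflow_idx, setdiff(cov, keep))
    }
  }
  ov <- d[overflow_idx, , drop = FALSE]
  tg <- d[setdiff(seq_len(nrow(d)), overflow_idx), , drop = FALSE]
  rownames(tg) <- rownames(ov) <- NULL
  .new_plan(tg, ct, cap, overflow = ov)
}

# max concurrency that window [ws,we] would see against existing windows
.fits <- function(ws, we, starts, ends, cap, step = 0.01) {
  if (!length(starts)) return(cap >= 1L)
  grid <- seq(ws, we, by = step)
  cnt <- vapply(grid, function(g) sum(starts <= g & g <= ends), integer(1))
  max(cnt) + 1L <= cap
}

#' Partition targets into the fewest injections by greedy first-fit
#'
#' Targets (including any overflow of [optimize_windows()]) are taken in
#' retention-time order and each is assigned to the lowest-index injection
#' whose concurrency stays within capacity at the target's full window
#' width.
#'
#' @param plan a `schedule_plan` (its targets plus overflow are
#'   re-partitioned).
#' @param cfg a [schedule_config()].
#' @return a `schedule_plan` with `injection` indices starting at 0.
#' @export
split_injections <- function(plan, cfg = schedule_config()) {
  d <- rbind(plan$targets, plan$overflow)
  d <- d[order(d$rt, d$precursor_mz, d$sequence), , drop = FALSE]
  cap <- plan$capacity
  inj <- rep(NA_integer_, nrow(d))
  for (i in seq_len(nrow(d))) {
    placed <- FALSE
    for (k in 0:(cfg$max_injections - 1L)) {
      in_k <- which(inj == k)
      if (.fits(d$window_start[i], d$window_end[i],
                d$window_start[in_k], d$window_end[in_k], cap)) {
        inj[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot schedule within ", cfg$max_injections, " injections (",
           sum(is.na(inj)), "+ targets overflow)")
  }
  d$injection <- inj
  rownames(d) <- NULL
  .new_plan(d, plan$cycle_time, cap)
}

#' Export a schedule plan as a target-list table
#'
#' Stable sort: injection, then window start, then precursor m/z.
#'
#' @param plan a `schedule_plan`.
#' @param path output path.
#' @param sep separator.
#' @return `path`, invisibly.
#' @export
export_target_list <- function(plan, path, sep = "\t") {
  d <- plan$targets[order(plan$targets$injection, plan$targets$window_start,
                          plan$targets$precursor_mz), , drop = FALSE]
  d <- d[, c("precursor_mz", "charge", "sequence", "window_start",
             "window_end", "injection")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# prmflow target list; cycle_time=", plan$cycle_time,
                    "; capacity=", plan$capacity), con)
  write.table(d, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-list table back into a schedule plan
#'
#' @param path file written by [export_target_list()].
#' @param sep separator.
#' @return a `schedule_plan` (`rt` reconstructed as the window midpoint).
#' @export
read_target_list <- function(path, sep = "\t") {
  hdr <- readLines(path, n = 1L)
  ct <- as.numeric(sub(".*cycle_time=([0-9.]+).*", "\\1", hdr))
  cap <- as.integer(sub(".*capacity=([0-9]+).*", "\\1", hdr))
  d <- read.delim(path, sep = sep, comment.char = "#",
                  stringsAsFactors = FALSE)
  d$rt <- (d$window_start + d$window_end) / 2
  .new_plan(d, ct, cap)
}
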