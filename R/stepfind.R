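# Step and pause detection in noisy single-molecule traces.
#
# Two detectors with the same output contract:
#   tstep_find  - recursive binary segmentation on the Welch t statistic
#                 between the samples adjacent to each candidate changepoint
#                 (up to `window_samples` on each side).
#   km_step_find - iterative placement of the single best chi-square-reducing
#                 step, with the step count chosen by the counter-fit quality
#                 ratio (chi^2 of a deliberately mis-placed staircase over
#                 chi^2 of the best fit).
# Both are exact on noiseless staircases. Defaults were calibrated on
# synthetic benchmarks in the resolvable regime (dwells of order 1 s at
# 200 Hz with 14 nm noise and ~4 nm steps); no parameters are inherited from
# any instrument software.

.seg_stats <- function(cs, cs2, lo, hi) {
  n <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  ss <- cs2[hi + 1] - cs2[lo]
  m <- s / n
  v <- pmax((ss - s^2 / n) / pmax(n - 1, 1), 0)
  list(n = n, mean = m, var = v)
}

# best Welch-t split of y[lo..hi]; windows truncated at segment edges
.best_t_split <- function(cs, cs2, lo, hi, window, min_seg) {
  if (hi - lo + 1 < 2 * min_seg) return(NULL)
  cp <- (lo + min_seg - 1):(hi - min_seg)
  l_lo <- pmax(lo, cp - window + 1)
  r_hi <- pmin(hi, cp + window)
  L <- .seg_stats(cs, cs2, l_lo, cp)
  R <- .seg_stats(cs, cs2, cp + 1, r_hi)
  se2 <- L$var / L$n + R$var / R$n
  # absolute floor keeps float cancellation in flat segments from producing
  # astronomically large t values (zero variance, ~1e-13 mean differences)
  se_floor <- 1e-9 * (abs(L$mean) + abs(R$mean) + 1)
  tt <- (R$mean - L$mean) / pmax(sqrt(pmax(se2, 0)), se_floor)
  df <- se2^2 / pmax((L$var / L$n)^2 / pmax(L$n - 1, 1) +
                       (R$var / R$n)^2 / pmax(R$n - 1, 1), 1e-300)
  k <- which.max(abs(tt))
  list(cp = cp[k], t = tt[k], df = max(df[k], 1))
}

#' T-test based step finding
#'
#' Recursive segmentation: within each segment, the Welch t statistic between
#' the up-to-`window_samples` samples on either side of every candidate
#' changepoint is computed; the segment is split at the maximal |t| if it
#' exceeds the two-sided alpha-level critical value, and the halves are
#' segmented recursively. Levels are segment means.
#'
#' @param trace a `measured_trace` (or numeric vector; then `dt` is needed).
#' @param window_samples maximum samples per side entering the t statistic.
#' @param alpha two-sided significance level for accepting a split.
#' @param min_seg minimum segment length in samples (>= 4).
#' @param z_merge boundaries whose full-segment Welch |t| falls below this
#'   after re-localization are merged away (polish pass, shared with
#'   [km_step_find()]).
#' @param decimate block-averaging factor applied before detection (the final
#'   boundary polish and all levels use the full-resolution trace).
#'   Coarse-graining reduces the changepoint search multiplicity without
#'   discarding boundary evidence; useful when steps are close to the noise
#'   floor. `window_samples` and `min_seg` are in decimated samples when
#'   `decimate > 1`.
#' @param dt sample interval, seconds (taken from the trace if omitted).
#' @return a `step_fit`: data.frame with `start`, `end` (sample indices),
#'   `level` (segment mean, trace units), `duration_s`; attributes
#'   `algorithm`, `dt`, `units`, and the originating trace attributes.
#' @export
tstep_find <- function(trace, window_samples = 150L, alpha = 0.01,
                       min_seg = 20L, z_merge = 2, decimate = 1L,
                       dt = NULL) {
  y <- if (is.data.frame(trace)) trace$extension_nm else as.numeric(trace)
  dt <- dt %||% (if (is.data.frame(trace)) diff(trace$time_s[1:2]) else
    stop("dt required for bare vectors"))
  if (window_samples < 4) stop("window must be >= 4 samples")
  min_seg <- max(2L, as.integer(min_seg))
  decimate <- max(1L, as.integer(decimate))
  yd <- .block_means(y, decimate)
  nd <- length(yd)
  csd <- cumsum(c(0, yd)); csd2 <- cumsum(c(0, yd^2))
  bounds <- integer(0)
  recurse <- function(lo, hi) {
    sp <- .best_t_split(csd, csd2, lo, hi, window_samples, min_seg)
    if (is.null(sp)) return()
    crit <- stats::qt(1 - alpha / 2, df = sp$df)
    if (abs(sp$t) <= crit) return()
    bounds <<- c(bounds, sp$cp)
    recurse(lo, sp$cp)
    recurse(sp$cp + 1, hi)
  }
  if (nd >= 2 * min_seg) recurse(1, nd)
  bounds <- .finalize_bounds(y, sort(bounds), decimate, min_seg, z_merge)
  .build_step_fit(y, bounds, dt, "ttest", trace)
}

# block means for decimated detection; trailing remainder dropped from the
# working copy (the full series is always used for the final fit)
.block_means <- function(y, D) {
  if (D <= 1) return(y)
  nD <- length(y) %/% D
  colMeans(matrix(y[seq_len(nD * D)], nrow = D))
}

# map (possibly decimated) bounds to full resolution and polish there
.finalize_bounds <- function(y, bounds, D, min_seg, z_merge) {
  n <- length(y)
  if (D > 1) bounds <- pmin(bounds * D, n - 1)
  cs <- cumsum(c(0, y)); cs2 <- cumsum(c(0, y^2))
  .polish_bounds(cs, cs2, bounds, n, min_seg * D, z_merge)
}

# Polish a set of changepoints: (a) re-localize each boundary at the exact
# least-squares split of its flanking bracket; (b) drop boundaries whose
# level difference is insignificant (full-segment Welch |t| < z_merge).
# Iterated to a fixed point; shared by both detectors.
.polish_bounds <- function(cs, cs2, bounds, n, min_seg, z_merge = 2.8,
                           max_iter = 6L) {
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # re-localization sweep
    if (length(bounds)) {
      br <- c(0, bounds, n)
      for (j in seq_along(bounds)) {
        lo <- br[j] + 1; hi <- br[j + 2]
        sp <- .best_chisq_split(cs, cs2, lo, hi, min_seg)
        if (!is.null(sp) && sp$cp != bounds[j]) {
          bounds[j] <- sp$cp
          br <- c(0, bounds, n)
          changed <- TRUE
        }
      }
    }
    # merge sweep: drop the weakest insignificant boundary until none remain
    repeat {
      if (!length(bounds)) break
      br <- c(0, bounds, n)
      tt <- vapply(seq_along(bounds), function(j) {
        L <- .seg_stats(cs, cs2, br[j] + 1, br[j + 1])
        R <- .seg_stats(cs, cs2, br[j + 1] + 1, br[j + 2])
        se2 <- L$var / L$n + R$var / R$n
        se_floor <- 1e-9 * (abs(L$mean) + abs(R$mean) + 1)
        abs(R$mean - L$mean) / max(sqrt(max(se2, 0)), se_floor)
      }, numeric(1))
      if (all(tt >= z_merge)) break
      bounds <- bounds[-which.min(tt)]
      changed <- TRUE
    }
    if (!changed) break
  }
  sort(bounds)
}

.build_step_fit <- function(y, bounds, dt, algorithm, trace) {
  starts <- c(1, bounds + 1)
  ends <- c(bounds, length(y))
  level <- vapply(seq_along(starts),
                  function(i) mean(y[starts[i]:ends[i]]), numeric(1))
  out <- data.frame(start = starts, end = ends, level = level,
                    duration_s = (ends - starts + 1) * dt)
  attr(out, "algorithm") <- algorithm
  attr(out, "dt") <- dt
  attr(out, "units") <- "nm"
  if (is.data.frame(trace)) {
    attr(out, "trajectory") <- attr(trace, "trajectory")
    attr(out, "meas_config") <- attr(trace, "meas_config")
  }
  class(out) <- c("step_fit", "data.frame")
  out
}

# chi-square reduction achievable by the best single split of y[lo..hi]
.best_chisq_split <- function(cs, cs2, lo, hi, min_seg) {
  if (hi - lo + 1 < 2 * min_seg) return(NULL)
  cp <- (lo + min_seg - 1):(hi - min_seg)
  nL <- cp - lo + 1
  nR <- hi - cp
  mL <- (cs[cp + 1] - cs[lo]) / nL
  mR <- (cs[hi + 1] - cs[cp + 1]) / nR
  red <- nL * nR / (nL + nR) * (mL - mR)^2
  k <- which.max(red)
  list(cp = cp[k], reduction = red[k])
}

.fit_chisq <- function(cs, cs2, bounds, n) {
  starts <- c(1, bounds + 1); ends <- c(bounds, n)
  sum(vapply(seq_along(starts), function(i) {
    st <- .seg_stats(cs, cs2, starts[i], ends[i])
    st$var * pmax(st$n - 1, 0)
  }, numeric(1)))
}

#' Iterative chi-square step finding with counter-fit quality gate
#'
#' Places steps one at a time: at each iteration the single step that most
#' reduces the residual chi-square over the whole trace is added. Placement
#' stops when the best remaining step's chi-square reduction falls below
#' `z_accept^2` times a robust noise-variance estimate (from the median
#' absolute successive difference), which sets the step count. The fit is
#' then compared against a counter-fit with steps placed at the centers of
#' the fitted plateaus; the quality ratio chi^2(counter) / chi^2(fit) is
#' reported in the `quality` attribute (well above 1 for stepped traces).
#' When `quality_threshold` is supplied, a trace whose ratio falls below it
#' is declared step-free; the ratio scales with the step density, so no
#' universal default exists and the gate is off by default. On a noiseless
#' staircase the noise estimate collapses and every true step is recovered
#' exactly.
#'
#' @inheritParams tstep_find
#' @param max_steps upper bound on placed steps (default: trace length /
#'   (2 min_seg)).
#' @param quality_threshold optional minimum counter-fit quality ratio for
#'   the trace to count as stepped (`NULL`: no gate).
#' @param z_accept significance (in noise SDs) required of each placed step.
#' @param z_merge polish-pass merge threshold, as in [tstep_find()].
#' @return a `step_fit` (same contract as [tstep_find()]).
#' @export
km_step_find <- function(trace, max_steps = NULL, quality_threshold = NULL,
                         min_seg = 20L, z_accept = 2.4, z_merge = 2,
                         decimate = 1L, dt = NULL) {
  y <- if (is.data.frame(trace)) trace$extension_nm else as.numeric(trace)
  dt <- dt %||% (if (is.data.frame(trace)) diff(trace$time_s[1:2]) else
    stop("dt required for bare vectors"))
  min_seg <- max(2L, as.integer(min_seg))
  decimate <- max(1L, as.integer(decimate))
  yd <- .block_means(y, decimate)
  nd <- length(yd)
  max_steps <- max_steps %||% max(1L, nd %/% (2L * min_seg))
  csd <- cumsum(c(0, yd)); csd2 <- cumsum(c(0, yd^2))
  # robust noise variance; successive differences are insensitive to steps
  sigma2 <- (stats::median(abs(diff(yd))) / (0.6745 * sqrt(2)))^2
  # floor against float cancellation on noiseless staircases
  min_red <- max(z_accept^2 * sigma2, 1e-14 * csd2[nd + 1] / nd)
  bounds <- integer(0)
  for (k in seq_len(max_steps)) {
    segs <- cbind(c(1, bounds + 1), c(bounds, nd))
    best <- NULL
    for (i in seq_len(nrow(segs))) {
      sp <- .best_chisq_split(csd, csd2, segs[i, 1], segs[i, 2], min_seg)
      if (!is.null(sp) && (is.null(best) || sp$reduction > best$reduction)) {
        best <- sp
      }
    }
    if (is.null(best) || best$reduction <= min_red) break
    bounds <- sort(c(bounds, best$cp))
  }
  bounds <- .finalize_bounds(y, bounds, decimate, min_seg, z_merge)
  quality <- NA_real_
  if (length(bounds)) {
    n <- length(y)
    cs <- cumsum(c(0, y)); cs2 <- cumsum(c(0, y^2))
    chi_fit <- .fit_chisq(cs, cs2, bounds, n)
    starts <- c(1, bounds + 1); ends <- c(bounds, n)
    centers <- pmin(pmax(floor((starts + ends) / 2), 1), n - 1)
    cbounds <- sort(unique(centers[centers < n]))
    quality <- .fit_chisq(cs, cs2, cbounds, n) / max(chi_fit, 1e-300)
    if (!is.null(quality_threshold) && quality < quality_threshold) {
      bounds <- integer(0)
    }
  }
  out <- .build_step_fit(y, bounds, dt, "km", trace)
  attr(out, "quality") <- quality
  out
}

#' Convert a step fit or trace from nm to bp
#'
#' Divides extension levels by the per-bp extension rise
#' (2 x [wlc_extension_per_nt()]); with the default measurement conditions a
#' fully opened 174-bp hairpin level converts back to 174 bp.
#'
#' @param x a `step_fit` or `measured_trace` in nm.
#' @param mc a [meas_config()] (taken from `x` if attached).
#' @return the same object with levels/extension in bp and `units = "bp"`.
#' @export
to_bp <- function(x, mc = NULL) {
  mc <- mc %||% attr(x, "meas_config") %||% meas_config()
  f <- nm_per_bp(mc)
  if (inherits(x, "step_fit")) {
    if (identical(attr(x, "units"), "bp")) return(x)
    x$level <- x$level / f
    attr(x, "units") <- "bp"
  } else if (inherits(x, "measured_trace")) {
    x$extension_nm <- x$extension_nm / f
    names(x)[names(x) == "extension_nm"] <- "position_bp"
  } else stop("unsupported object")
  x
}

#' Position-resolved dwell-time histogram
#'
#' Accumulates each segment's duration into the bin of its (bp) level. The
#' total dwell equals the total trace duration exactly (conservation).
#' Accepts bp-scaled step fits or ground-truth trajectories (for which the
#' dwell at each pre-step position is that step's pause + translocation
#' time).
#'
#' @param fits list of `step_fit` (bp units) or `trajectory` objects.
#' @param bin_bp bin width in bp.
#' @param L substrate length (bins tile [0, L]; inferred if possible).
#' @return a `dwell_histogram`: data.frame `position_bp` (bin centers),
#'   `dwell_s`; attributes `trace_count`, `total_s`, `bin_bp`.
#' @export
dwell_histogram <- function(fits, bin_bp = 1, L = NULL) {
  if (inherits(fits, c("step_fit", "trajectory"))) fits <- list(fits)
  lv <- list(); du <- list()
  for (f in fits) {
    if (inherits(f, "trajectory")) {
      lev <- c(0, f$ledger$bp_to[-nrow(f$ledger)])
      lv[[length(lv) + 1]] <- lev
      du[[length(du) + 1]] <- f$ledger$pause_s + f$ledger$trans_s
      L <- L %||% f$L
    } else {
      if (!identical(attr(f, "units"), "bp")) {
        stop("step fits must be bp-scaled (see to_bp())")
      }
      lv[[length(lv) + 1]] <- f$level
      du[[length(du) + 1]] <- f$duration_s
    }
  }
  lev <- unlist(lv); dur <- unlist(du)
  L <- L %||% max(lev)
  breaks <- seq(-bin_bp / 2, L + bin_bp, by = bin_bp)
  idx <- findInterval(pmin(pmax(lev, breaks[1]), max(breaks) - 1e-9), breaks)
  dwell <- vapply(seq_len(length(breaks) - 1),
                  function(i) sum(dur[idx == i]), numeric(1))
  out <- data.frame(position_bp = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    dwell_s = dwell)
  attr(out, "trace_count") <- length(fits)
  attr(out, "total_s") <- sum(dur)
  attr(out, "bin_bp") <- bin_bp
  class(out) <- c("dwell_histogram", "data.frame")
  out
}

#' Extract pauses from a step fit
#'
#' Segments lasting at least `min_duration_s` that are bounded by forward
#' motion (the following segment sits at a higher level) are reported as
#' pauses at their bp level. The default threshold matches the mean pause
#' duration printed for the core helicase construct (0.14 s).
#'
#' @param fit a bp-scaled `step_fit`, or a `trajectory` (ground truth: every
#'   kinetic step's pause is a pause record).
#' @param min_duration_s minimum pause duration.
#' @param trace_id identifier stored with each record.
#' @return a `pause_table` data.frame: `position_bp`, `duration_s`,
#'   `trace_id`.
#' @export
extract_pauses <- function(fit, min_duration_s = 0.14, trace_id = 1L) {
  if (inherits(fit, "trajectory")) {
    keep <- fit$ledger$pause_s >= min_duration_s
    out <- data.frame(
      position_bp = c(0, fit$ledger$bp_to[-nrow(fit$ledger)])[keep],
      duration_s = fit$ledger$pause_s[keep],
      trace_id = rep(trace_id, sum(keep)))
  } else {
    if (!identical(attr(fit, "units"), "bp")) {
      stop("step fit must be bp-scaled (see to_bp())")
    }
    k <- nrow(fit)
    forward <- c(diff(fit$level) > 0, FALSE)
    keep <- forward & fit$duration_s >= min_duration_s
    out <- data.frame(position_bp = fit$level[keep],
                      duration_s = fit$duration_s[keep],
                      trace_id = rep(trace_id, sum(keep)))
  }
  class(out) <- c("pause_table", "data.frame")
  out
}

#' Step-size distribution with Gaussian peak fit
#'
#' Successive level differences are converted to bp and histogrammed; the
#' histogram is fitted with a BIC-selected sum of 1-3 Gaussians
#' ([fit_gaussian_peaks()]) and the dominant (largest-area) component is
#' reported as the mean step size. Merged steps (pauses below the detection
#' limit) populate satellite peaks at multiples of the true size, which the
#' multi-component fit keeps from biasing the main peak.
#'
#' @param fits list of `step_fit` objects (nm or bp units).
#' @param mc a [meas_config()] used for nm to bp conversion.
#' @param bin_bp histogram bin width.
#' @param max_bp sizes above this are discarded (tether artifacts).
#' @param min_bp sizes below this are discarded (level jitter).
#' @return a `step_size_distribution`: list with `sizes`, `hist`
#'   (data.frame `size_bp`, `count`), `center`, `sd`, `center_se`, `peaks`
#'   (full `peak_set`).
#' @export
step_size_distribution <- function(fits, mc = NULL, bin_bp = 1,
                                   max_bp = 25, min_bp = 1) {
  if (inherits(fits, "step_fit")) fits <- list(fits)
  sizes <- unlist(lapply(fits, function(f) {
    f <- to_bp(f, mc %||% attr(f, "meas_config") %||% meas_config())
    diff(f$level)
  }))
  sizes <- sizes[sizes >= min_bp & sizes <= max_bp]
  if (!length(sizes)) stop("no step sizes to histogram")
  breaks <- seq(0, max_bp + bin_bp, by = bin_bp)
  h <- graphics::hist(sizes, breaks = breaks, plot = FALSE)
  pk <- fit_gaussian_peaks(h$mids, h$counts, max_components = 3,
                           min_sd = bin_bp / 2)
  if (pk$n_components == 0) {       # featureless: fall back to sample moments
    center <- mean(sizes); sdv <- stats::sd(sizes)
    cse <- sdv / sqrt(length(sizes))
  } else {
    area <- pk$amplitudes * pk$widths
    dom <- which.max(area)
    center <- pk$centers[dom]; sdv <- pk$widths[dom]; cse <- pk$center_se[dom]
  }
  structure(list(sizes = sizes,
                 hist = data.frame(size_bp = h$mids, count = h$counts),
                 center = center, sd = sdv, center_se = cse, peaks = pk),
            class = "step_size_distribution")
}

#' @export
print.step_size_distribution <- function(x, ...) {
  cat(sprintf("<step_size_distribution: %d steps, center %.2f bp (sd %.2f)>\n",
              length(x$sizes), x$center, x$sd))
  invisible(x)
}
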