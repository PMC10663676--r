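# Capillary gel electrophoresis quantification: baseline correction by
# morphological opening, peak detection/integration, species assignment by
# migration window, and ssDNA trace identity comparison.

#' Construct an electropherogram
#'
#' @param time Migration time axis in minutes, strictly increasing.
#' @param signal Detector response (214 nm absorbance for the protein
#'   channel, fluorescence for the ssDNA channel).
#' @param channel `"protein"` or `"ssdna"`.
#' @return Object of class `electropherogram` (a data.frame with attributes).
#' @export
electropherogram <- function(time, signal, channel = c("protein", "ssdna")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(time), is.numeric(signal))
  if (length(time) != length(signal)) {
    stop("`time` and `signal` must have equal length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(signal)) {
    stop("electropherogram must not contain NA", call. = FALSE)
  }
  if (length(time) >= 2 && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time, signal = signal),
            channel = channel, class = c("electropherogram", "data.frame"))
}

#' Read an electropherogram from CSV
#'
#' Expects a two-column CSV with a header (minutes, signal).
#'
#' @param path CSV path.
#' @param channel Detector channel, `"protein"` or `"ssdna"`.
#' @return An [electropherogram()].
#' @export
read_electropherogram_csv <- function(path, channel = c("protein", "ssdna")) {
  df <- utils::read.csv(path)
  electropherogram(df[[1]], df[[2]], channel = match.arg(channel))
}

# window in minutes -> odd number of points on this axis
window_points <- function(time, window_min) {
  dt <- stats::median(diff(time))
  w <- max(3L, as.integer(round(window_min / dt)))
  if (w %% 2 == 0) w <- w + 1L
  w
}

rolling_extreme <- function(y, w, fun) {
  n <- length(y)
  half <- (w - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- fun(y[max(1, i - half):min(n, i + half)])
  }
  out
}

#' Baseline-correct an electropherogram
#'
#' Two-pass baseline estimation. A morphological opening (rolling minimum
#' then rolling maximum over `window`) of the smoothed trace first flags
#' peak regions; the baseline is then the smoothed signal itself outside
#' the peak regions and a straight interpolation across them (anchored on
#' short averages flanking each region), which is unbiased under additive
#' zero-mean noise and exact for locally linear drift. Applying the
#' correction twice leaves an already-corrected trace essentially unchanged.
#'
#' @param trace An [electropherogram()].
#' @param window Opening window width in minutes; must be shorter than the
#'   trace span and wider than the peaks to be removed from the baseline.
#' @param smooth_pts Odd moving-average width (points) defining the smooth
#'   trace the baseline follows.
#' @param region_frac Fraction of the maximum opened residual above which a
#'   point is considered part of a peak region.
#' @param region_pad Minutes by which each peak region is widened before
#'   interpolation, keeping slowly decaying tails out of the baseline.
#' @return Corrected [electropherogram()] with attribute `baseline`.
#' @export
baseline_correct <- function(trace, window = 2, smooth_pts = 21,
                             region_frac = 0.01, region_pad = 0.3) {
  stopifnot(inherits(trace, "electropherogram"))
  x <- trace$time
  span <- diff(range(x))
  if (window >= span) {
    stop("`window` must be shorter than the trace span", call. = FALSE)
  }
  n <- length(x)
  sm <- moving_average_linear(x, trace$signal, smooth_pts)
  w <- window_points(x, window)
  opened <- rolling_extreme(rolling_extreme(sm, w, min), w, max)
  resid <- sm - opened
  peakish <- resid > region_frac * max(resid, 0)
  if (any(peakish)) {
    pad <- as.integer(round(region_pad / stats::median(diff(x))))
    idx <- which(peakish)
    grown <- unique(unlist(lapply(idx, function(i)
      max(1L, i - pad):min(n, i + pad))))
    peakish <- logical(n)
    peakish[grown] <- TRUE
  }
  baseline <- sm
  if (any(peakish) && !all(peakish)) {
    runs <- rle(peakish)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- max(1L, (smooth_pts - 1L) %/% 2L)
    for (j in which(runs$values)) {
      a <- starts[j]
      b <- ends[j]
      left_ix <- max(1L, a - k):max(1L, a - 1L)
      right_ix <- min(n, b + 1L):min(n, b + k)
      if (a == 1L) {
        lv <- mean(sm[right_ix]); lx <- mean(x[right_ix])
        rv <- lv; rx <- lx + 1
      } else if (b == n) {
        lv <- mean(sm[left_ix]); lx <- mean(x[left_ix])
        rv <- lv; rx <- lx + 1
      } else {
        lv <- mean(sm[left_ix]); lx <- mean(x[left_ix])
        rv <- mean(sm[right_ix]); rx <- mean(x[right_ix])
      }
      baseline[a:b] <- lv + (rv - lv) * (x[a:b] - lx) / (rx - lx)
    }
  } else if (all(peakish)) {
    # no baseline support at all: fall back to the opening
    baseline <- opened
  }
  out <- trace
  out$signal <- trace$signal - baseline
  attr(out, "baseline") <- baseline
  out
}

#' Detect and integrate peaks
#'
#' Finds local maxima above `min_height` (as a fraction of the maximum
#' corrected signal) on a lightly smoothed copy of the trace, sets peak
#' bounds at the flanking valleys (minimum point between neighbouring
#' accepted apexes, or the trace ends), truncated where the smoothed signal
#' drops to baseline, integrates the corrected signal by the trapezoidal
#' rule between bounds, and assigns species labels when an apex falls
#' inside a configured migration window.
#'
#' @param trace Baseline-corrected [electropherogram()].
#' @param min_height Detection threshold as a fraction of the maximum
#'   corrected signal (default 1%).
#' @param windows Optional named list of `c(left, right)` migration windows
#'   in minutes, one per species; windows must not overlap.
#' @param smooth_pts Odd number of points for the detection-only moving
#'   average (integration always uses the raw signal).
#' @param min_separation Apexes closer than this (minutes) are merged into
#'   the taller one before bounds are drawn.
#' @param support_frac Fraction of `min_height` below which a peak's
#'   integration bound is truncated before reaching the valley, so long
#'   near-baseline stretches between well-separated peaks are not
#'   integrated into either neighbour.
#' @param support_pad Minutes added beyond the support crossing (capped at
#'   the valley) so slowly decaying peak tails are still integrated.
#' @return A `peak_table` data.frame: `species, apex_min, left_min,
#'   right_min, area, height`.
#' @export
detect_and_integrate <- function(trace, min_height = 0.01, windows = NULL,
                                 smooth_pts = 5, min_separation = 0.1,
                                 support_frac = 0.25, support_pad = 0.2) {
  stopifnot(inherits(trace, "electropherogram"))
  if (!is.null(windows)) {
    wmat <- do.call(rbind, windows)
    ord <- order(wmat[, 1])
    wmat <- wmat[ord, , drop = FALSE]
    if (any(wmat[, 2] <= wmat[, 1]) ||
        (nrow(wmat) > 1 && any(wmat[-1, 1] < wmat[-nrow(wmat), 2]))) {
      stop("species migration windows overlap or are inverted", call. = FALSE)
    }
  }
  x <- trace$time
  y <- trace$signal
  ys <- moving_average(y, smooth_pts)
  n <- length(ys)
  thr <- min_height * max(ys)
  is_max <- which(ys > thr &
                  ys >= c(-Inf, ys[-n]) &
                  ys >= c(ys[-1], -Inf))
  # collapse plateaus / adjacent indices into one apex
  if (length(is_max) > 1) {
    grp <- cumsum(c(1, diff(is_max) > 1))
    is_max <- vapply(split(is_max, grp), function(ix) ix[which.max(ys[ix])],
                     integer(1))
  }
  apexes <- sort(unname(is_max))
  # merge apexes closer than min_separation, keeping the taller
  while (length(apexes) > 1) {
    gaps <- diff(x[apexes])
    j <- which(gaps < min_separation)
    if (length(j) == 0) break
    j <- j[1]
    drop <- if (ys[apexes[j]] >= ys[apexes[j + 1]]) j + 1 else j
    apexes <- apexes[-drop]
  }
  if (length(apexes) == 0) {
    return(structure(data.frame(species = character(0), apex_min = numeric(0),
                                left_min = numeric(0), right_min = numeric(0),
                                area = numeric(0), height = numeric(0)),
                     class = c("peak_table", "data.frame")))
  }
  # valley between consecutive apexes; ties broken toward the earlier minimum
  bounds <- integer(length(apexes) + 1)
  bounds[1] <- 1L
  bounds[length(bounds)] <- n
  if (length(apexes) > 1) {
    for (i in seq_len(length(apexes) - 1)) {
      seg <- apexes[i]:apexes[i + 1]
      bounds[i + 1] <- seg[which.min(ys[seg])]
    }
  }
  # truncate each peak's bounds where the smoothed signal falls below the
  # support floor, so near-baseline stretches are not integrated
  floor_lvl <- support_frac * thr
  pad <- as.integer(round(support_pad / stats::median(diff(x))))
  lb <- integer(length(apexes))
  rb <- integer(length(apexes))
  for (i in seq_along(apexes)) {
    l <- bounds[i]
    r <- bounds[i + 1]
    below_l <- which(ys[l:apexes[i]] < floor_lvl)
    if (length(below_l) > 0) l <- max(bounds[i], l + max(below_l) - 1L - pad)
    below_r <- which(ys[apexes[i]:r] < floor_lvl)
    if (length(below_r) > 0) {
      r <- min(bounds[i + 1], apexes[i] + min(below_r) - 1L + pad)
    }
    lb[i] <- l
    rb[i] <- r
  }
  peaks <- data.frame(
    species = NA_character_,
    apex_min = x[apexes],
    left_min = x[lb],
    right_min = x[rb],
    area = vapply(seq_along(apexes), function(i) {
      ix <- lb[i]:rb[i]
      trapz(x[ix], y[ix])
    }, numeric(1)),
    height = y[apexes]
  )
  if (!is.null(windows)) {
    for (sp in names(windows)) {
      hit <- peaks$apex_min >= windows[[sp]][1] &
             peaks$apex_min <= windows[[sp]][2]
      if (any(hit)) {
        # largest peak in the window carries the species label
        j <- which(hit)[which.max(peaks$height[hit])]
        peaks$species[j] <- sp
      }
    }
  }
  structure(peaks, class = c("peak_table", "data.frame"))
}

#' Peak areas per species from a peak table
#'
#' @param peaks A `peak_table` from [detect_and_integrate()].
#' @return Named vector of areas for the assigned species.
#' @export
peak_areas <- function(peaks) {
  assigned <- peaks[!is.na(peaks$species), ]
  stats::setNames(assigned$area, assigned$species)
}

#' Compare two ssDNA traces for genome-length identity
#'
#' Two extracted-genome electropherograms are called "same" when their
#' dominant peak apexes agree within `tolerance` minutes.
#'
#' @param trace_a,trace_b ssDNA-channel [electropherogram()]s
#'   (baseline-corrected).
#' @param tolerance Apex agreement tolerance, minutes.
#' @param min_signal Minimum dominant-peak height; below it no call is made.
#' @return List with `same` (logical) and `shift` (apex_b - apex_a, min).
#' @export
ssdna_identity_check <- function(trace_a, trace_b, tolerance = 0.2,
                                 min_signal = 0) {
  stopifnot(inherits(trace_a, "electropherogram"),
            inherits(trace_b, "electropherogram"))
  if (attr(trace_a, "channel") != "ssdna" ||
      attr(trace_b, "channel") != "ssdna") {
    stop("both traces must be ssdna-channel electropherograms", call. = FALSE)
  }
  apex_of <- function(tr) {
    i <- which.max(tr$signal)
    if (tr$signal[i] <= min_signal) {
      stop("no dominant peak above the signal threshold", call. = FALSE)
    }
    tr$time[i]
  }
  a <- apex_of(trace_a)
  b <- apex_of(trace_b)
  list(same = abs(b - a) <= tolerance, shift = b - a)
}

#' Write a peak table as CSV
#'
#' Fixed header: `species, apex_min, left_min, right_min, area, height`.
#'
#' @param peaks A `peak_table`.
#' @param path Output path.
#' @export
write_peak_table_csv <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(peaks)
}
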