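# Charge detection mass spectrometry processing: multiplicative m/z
# calibration against a reference protein (e.g. GDH), per-ion mass, mass
# window filtering with an acquisition cap, mass histograms with mode mass
# and FWHM, and low-charge subpopulation reporting.

#' m/z calibration factor from reference peaks
#'
#' Fits the multiplicative correction `theoretical = factor * observed`
#' through the origin by least squares: `factor = sum(t*o) / sum(o^2)`.
#' Corrected m/z values are `factor * observed`.
#'
#' @param observed_mz Observed reference m/z values (> 0).
#' @param theoretical_mz Matching theoretical m/z values (> 0), same length.
#' @return Object of class `cdms_calibration` with field `factor`.
#' @export
calibration_factor <- function(observed_mz, theoretical_mz) {
  stopifnot(is.numeric(observed_mz), is.numeric(theoretical_mz))
  if (length(observed_mz) == 0 ||
      length(observed_mz) != length(theoretical_mz)) {
    stop("need equal-length, non-empty paired m/z lists", call. = FALSE)
  }
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0)) {
    stop("m/z values must be > 0", call. = FALSE)
  }
  structure(list(factor = sum(theoretical_mz * observed_mz) /
                   sum(observed_mz^2)),
            class = "cdms_calibration")
}

#' Neutral mass of a CDMS ion event
#'
#' `mass = charge * (factor * mz) - charge * 1.00728`: the calibrated m/z
#' times the (real-valued) measured charge, minus the proton-mass
#' correction (negligible at MDa scale but included for completeness).
#'
#' @param mz m/z in Thomson (> 0); vectorized.
#' @param charge Elementary charges (> 0), CDMS-measured, real-valued.
#' @param cal A `cdms_calibration` (default: identity).
#' @return Mass in Da.
#' @export
ion_mass <- function(mz, charge, cal = calibration_factor(1, 1)) {
  stopifnot(inherits(cal, "cdms_calibration"))
  if (any(mz <= 0) || any(charge <= 0)) {
    stop("mz and charge must be > 0", call. = FALSE)
  }
  charge * (cal$factor * mz) - charge * .proton_mass
}

#' Filter ion masses to a window with an acquisition cap
#'
#' Keeps, in acquisition order, the first `cap` masses falling in the closed
#' interval `[low, high]` — mirroring data collection "until N ions are
#' captured within the mass range".
#'
#' @param masses Ion masses in acquisition order, Da.
#' @param low,high Window bounds, Da (`low < high`; closed interval).
#' @param cap Maximum number of ions to keep (>= 1).
#' @return Filtered mass vector (possibly shorter than `cap`).
#' @export
filter_mass_window <- function(masses, low = 3e6, high = 5e6, cap = 3000) {
  if (low >= high) stop("`low` must be < `high`", call. = FALSE)
  if (cap < 1) stop("`cap` must be >= 1", call. = FALSE)
  inside <- masses[masses >= low & masses <= high]
  utils::head(inside, cap)
}

#' Mass histogram with mode mass and FWHM
#'
#' Bins masses into uniform bins of `bin_width`. The mode mass is the
#' vertex of a quadratic fitted to the log-counts of the +/- 5 bins around
#' the tallest bin (a local Gaussian fit); the FWHM is obtained by linear
#' interpolation of the half-maximum crossings of the lightly smoothed
#' binned counts, using the crossings flanking the mode when the histogram
#' is multimodal.
#'
#' @param masses Ion masses, Da (>= 10 values).
#' @param bin_width Bin width, Da (default 0.01 MDa).
#' @param smooth_bins Odd moving-average window (bins) applied to counts
#'   before half-maximum interpolation; stabilizes the FWHM of counting-noise
#'   limited histograms.
#' @return Object of class `mass_histogram` with `bin_edges`, `bin_centers`,
#'   `counts`, `mode_mass`, `fwhm`, `n_ions`.
#' @export
mass_histogram <- function(masses, bin_width = 1e4, smooth_bins = 5) {
  if (length(masses) < 10) {
    stop("need at least 10 ions for a mass histogram", call. = FALSE)
  }
  stop_if_not_number(bin_width, "bin_width", positive = TRUE)
  lo <- floor(min(masses) / bin_width) * bin_width
  hi <- ceiling(max(masses) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < max(masses)) edges <- c(edges, hi + bin_width)
  counts <- as.numeric(
    table(cut(masses, breaks = edges, include.lowest = TRUE)))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  sm <- moving_average(counts, smooth_bins)
  # anchor the mode neighbourhood on the smoothed tallest bin: the raw
  # tallest bin jitters by tens of kDa under counting noise
  peak_bin <- which.max(sm)

  # mode: count-weighted quadratic fit to log-counts over the contiguous
  # half-maximum neighbourhood of the peak (at least +/- 2 bins); the
  # half-height region carries enough counting statistics to pin the
  # vertex to a few kDa at n ~ 3000
  hm <- max(sm) / 2
  lo_nb <- peak_bin
  while (lo_nb > 1 && sm[lo_nb - 1] >= hm) lo_nb <- lo_nb - 1
  hi_nb <- peak_bin
  while (hi_nb < length(sm) && sm[hi_nb + 1] >= hm) hi_nb <- hi_nb + 1
  nb <- max(1, min(lo_nb, peak_bin - 2)):min(length(counts),
                                             max(hi_nb, peak_bin + 2))
  nb <- nb[counts[nb] > 0]
  mode_mass <- centers[peak_bin]
  if (length(nb) >= 3) {
    xc <- centers[nb] - centers[peak_bin]
    # count weights make the quadratic log fit approximate the Poisson MLE
    fit <- stats::lm(log(counts[nb]) ~ xc + I(xc^2), weights = counts[nb])
    a2 <- stats::coef(fit)[[3]]
    a1 <- stats::coef(fit)[[2]]
    if (is.finite(a2) && a2 < 0) {
      mode_mass <- centers[peak_bin] - a1 / (2 * a2)
      # keep the refined mode inside the fitted neighbourhood
      mode_mass <- min(max(mode_mass, centers[nb[1]]),
                       centers[nb[length(nb)]])
    }
  }

  half <- max(sm) / 2
  mode_bin <- which.min(abs(centers - mode_mass))
  left <- NA_real_
  if (mode_bin > 1) {
    for (i in mode_bin:2) {
      if (sm[i - 1] < half && sm[i] >= half) {
        left <- centers[i - 1] + (half - sm[i - 1]) / (sm[i] - sm[i - 1]) *
          (centers[i] - centers[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (mode_bin < length(sm)) {
    for (i in mode_bin:(length(sm) - 1)) {
      if (sm[i + 1] < half && sm[i] >= half) {
        right <- centers[i] + (sm[i] - half) / (sm[i] - sm[i + 1]) *
          (centers[i + 1] - centers[i])
        break
      }
    }
  }
  fwhm <- if (is.na(left) || is.na(right)) bin_width else right - left
  structure(list(bin_edges = edges, bin_centers = centers, counts = counts,
                 mode_mass = mode_mass, fwhm = fwhm,
                 n_ions = length(masses)),
            class = "mass_histogram")
}

#' @export
print.mass_histogram <- function(x, ...) {
  cat(sprintf("<mass_histogram> n = %d, mode = %.3f MDa, FWHM = %.3f MDa\n",
              x$n_ions, x$mode_mass / 1e6, x$fwhm / 1e6))
  invisible(x)
}

#' Fraction of low-charge ions in a mass window
#'
#' Reports the fraction of in-window ions whose measured charge falls below
#' `charge_threshold` — the compact/low-charge subpopulation visible in
#' charge-versus-mass scatterplots.
#'
#' @param events data.frame with columns `mz` and `charge`.
#' @param cal A `cdms_calibration`.
#' @param charge_threshold Elementary charges (> 0).
#' @param low,high Mass window, Da.
#' @return Fraction in `[0, 1]`.
#' @export
low_charge_fraction <- function(events, cal = calibration_factor(1, 1),
                                charge_threshold, low = 3e6, high = 5e6) {
  stop_if_not_number(charge_threshold, "charge_threshold", positive = TRUE)
  if (nrow(events) == 0) stop("no ion events", call. = FALSE)
  mass <- ion_mass(events$mz, events$charge, cal)
  inw <- mass >= low & mass <= high
  if (!any(inw)) stop("no ions inside the mass window", call. = FALSE)
  mean(events$charge[inw] < charge_threshold)
}

#' Write a mass histogram as CSV plus JSON summary
#'
#' @param hist A `mass_histogram`.
#' @param csv_path CSV path (`bin_center, count`).
#' @param json_path Optional JSON path for the
#'   `mode_mass`/`fwhm`/`n_ions` summary.
#' @export
write_mass_histogram <- function(hist, csv_path, json_path = NULL) {
  utils::write.csv(data.frame(bin_center = hist$bin_centers,
                              count = hist$counts),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(mode_mass = hist$mode_mass, fwhm = hist$fwhm,
                              n_ions = hist$n_ions),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(hist)
}
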