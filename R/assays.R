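# Assay readout processing: flow-cytometry potency normalization against a
# bulk reference, stoichiometry-potency correlation, and melting-temperature
# extraction from DSF barycentric-mean scans.

#' Relative potency against a bulk reference
#'
#' For each sample x MOI cell, divides the replicate mean of GFP-positive
#' fractions by the bulk reference mean at the same MOI. The SD is
#' propagated to first order for a ratio of means:
#' `sd = value * sqrt((sd_s/mean_s)^2 + (sd_b/mean_b)^2)`.
#'
#' @param records data.frame with columns `sample`, `moi`, `replicate`,
#'   `gfp_positive` (fractions in `[0, 1]`).
#' @param bulk_label Reference sample label (must be present at every MOI
#'   being normalized).
#' @return data.frame `sample, moi, value, sd` with the bulk rows equal to 1.
#' @export
relative_potency <- function(records, bulk_label = "bulk_wt") {
  stopifnot(is.data.frame(records),
            all(c("sample", "moi", "gfp_positive") %in% names(records)))
  if (any(records$gfp_positive < 0 | records$gfp_positive > 1)) {
    stop("gfp_positive must be in [0, 1]", call. = FALSE)
  }
  if (any(records$moi <= 0)) stop("moi must be > 0", call. = FALSE)
  mois <- sort(unique(records$moi))
  bulk <- records[records$sample == bulk_label, ]
  missing_moi <- setdiff(mois, unique(bulk$moi))
  if (length(missing_moi) > 0) {
    stop("bulk reference missing at MOI: ",
         paste(format(missing_moi, scientific = FALSE), collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(gfp_positive ~ sample + moi, records,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  agg <- data.frame(sample = agg$sample, moi = agg$moi,
                    mean = agg$gfp_positive[, "mean"],
                    sd = agg$gfp_positive[, "sd"])
  agg$sd[is.na(agg$sd)] <- 0
  bulk_agg <- agg[agg$sample == bulk_label, ]
  bmean <- stats::setNames(bulk_agg$mean, bulk_agg$moi)
  bsd <- stats::setNames(bulk_agg$sd, bulk_agg$moi)
  if (any(bmean <= 0)) {
    stop("bulk reference mean is zero at some MOI", call. = FALSE)
  }
  key <- as.character(agg$moi)
  value <- agg$mean / bmean[key]
  relsd <- sqrt((agg$sd / agg$mean)^2 + (bsd[key] / bmean[key])^2)
  relsd[agg$sample == bulk_label] <- 0
  value[agg$sample == bulk_label] <- 1
  out <- data.frame(sample = agg$sample, moi = agg$moi,
                    value = value, sd = value * relsd)
  out[order(out$sample, out$moi), ]
}

#' Correlate VP stoichiometry metrics with relative potency
#'
#' For each stoichiometry metric (VP1-only `VP1/(VP2+VP3_total)`, VP2-only
#' `VP2/(VP1+VP3_total)`, and combined `(VP1+VP2)/VP3_total`), computes the
#' Pearson correlation with relative potency across samples plus the
#' least-squares line.
#'
#' @param metrics data.frame with column `sample` plus one column per
#'   metric (any names).
#' @param potencies data.frame `sample, value` of relative potencies at a
#'   single MOI.
#' @return data.frame `metric, r, intercept, slope, degenerate`; metrics
#'   with zero variance are flagged degenerate with an NA correlation.
#' @export
stoich_potency_correlation <- function(metrics, potencies) {
  stopifnot(is.data.frame(metrics), "sample" %in% names(metrics),
            is.data.frame(potencies),
            all(c("sample", "value") %in% names(potencies)))
  merged <- merge(metrics, potencies[, c("sample", "value")], by = "sample")
  if (nrow(merged) < 3) {
    stop("need at least 3 samples for a correlation", call. = FALSE)
  }
  metric_names <- setdiff(names(metrics), "sample")
  rows <- lapply(metric_names, function(mn) {
    x <- merged[[mn]]
    y <- merged$value
    if (stats::sd(x) == 0) {
      return(data.frame(metric = mn, r = NA_real_, intercept = NA_real_,
                        slope = NA_real_, degenerate = TRUE))
    }
    fit <- stats::lm(y ~ x)
    data.frame(metric = mn, r = stats::cor(x, y),
               intercept = stats::coef(fit)[[1]],
               slope = stats::coef(fit)[[2]], degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Melting temperature from a barycentric-mean thermal scan
#'
#' The melting temperature is the midpoint of the fluorescence redshift:
#' the temperature at which the first derivative of the barycentric mean
#' (BCM) with respect to temperature peaks. The derivative is taken by
#' central differences, smoothed with a 3-point moving average, and the
#' peak position is refined by parabolic interpolation. A scan with no
#' transition (flat or linear BCM, i.e. no interior derivative peak) is an
#' error.
#'
#' @param scan data.frame with columns `temperature` (deg C, strictly
#'   increasing, >= 20 points) and `bcm` (nm).
#' @return Tm in deg C.
#' @export
tm_from_bcm <- function(scan) {
  stopifnot(is.data.frame(scan),
            all(c("temperature", "bcm") %in% names(scan)))
  t <- scan$temperature
  b <- scan$bcm
  if (length(t) < 20) stop("need at least 20 scan points", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("temperature must be strictly increasing", call. = FALSE)
  }
  n <- length(t)
  # central differences on the interior
  d <- (b[3:n] - b[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  td <- t[2:(n - 1)]
  d <- moving_average(d, 3)
  if (max(d) <= 0 || diff(range(b)) < 1e-12) {
    stop("no unfolding transition detected (flat BCM)", call. = FALSE)
  }
  i <- which.max(d)
  if (i == 1 || i == length(d)) {
    stop("no interior derivative peak: BCM has no sigmoidal transition",
         call. = FALSE)
  }
  # require a genuine peak, not a monotone ramp plateauing at the boundary
  if (d[i] - min(d) < 1e-9 * max(abs(d), 1) ||
      (d[i] - d[1] < 1e-6 * d[i] && d[i] - d[length(d)] < 1e-6 * d[i])) {
    stop("no unfolding transition detected (derivative is flat)",
         call. = FALSE)
  }
  # refine the peak position with a local quadratic fit (+/- 2 deg C):
  # the logistic derivative peak is broad, so a plain 3-point parabola is
  # noise-limited while a short quadratic window is stable
  jj <- which(abs(td - td[i]) <= 2)
  if (length(jj) >= 5) {
    xc <- td[jj] - td[i]
    fit <- stats::lm(d[jj] ~ xc + I(xc^2))
    a1 <- stats::coef(fit)[[2]]
    a2 <- stats::coef(fit)[[3]]
    if (is.finite(a2) && a2 < 0) {
      vertex <- td[i] - a1 / (2 * a2)
      if (abs(vertex - td[i]) <= 2) return(vertex)
    }
  }
  num <- (d[i - 1] - d[i + 1]) / 2
  den <- d[i - 1] - 2 * d[i] + d[i + 1]
  if (den < 0) {
    td[i] + num / den * (td[i + 1] - td[i])
  } else {
    td[i]
  }
}
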