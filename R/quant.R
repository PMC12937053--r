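#' Light-to-heavy ratio from transition-level peak areas
#'
#' The L/H ratio is the sum of light-channel peak areas over the sum of
#' heavy-channel peak areas across the selected fragment set. Under a
#' coisolating scheme the fragment set MUST be restricted to ions unique
#' to each channel (see [classify_pair_fragments()]); under a
#' pair-separating scheme every fragment is usable.
#'
#' @param measurements data.frame with columns `channel` ("light" /
#'   "heavy"), `fragment` (ion name, e.g. "y4") and `peak_area`;
#'   optionally `background`.
#' @param fragments optional character vector restricting the fragment
#'   set (e.g. the unique-ion set under coisolation); default: all
#'   fragments present.
#' @param subtract_background subtract the `background` column from peak
#'   areas (floored at 0) before summing; default FALSE.
#' @return the L/H ratio (numeric scalar).
#' @examples
#' m <- data.frame(channel = c("light", "light", "heavy", "heavy"),
#'                 fragment = c("y3", "y4", "y3", "y4"),
#'                 peak_area = c(10, 30, 20, 60))
#' lh_ratio(m)  # 0.5
#' @export
lh_ratio <- function(measurements, fragments = NULL, subtract_background = FALSE) {
  stopifnot(all(c("channel", "fragment", "peak_area") %in% names(measurements)))
  if (!is.null(fragments)) {
    measurements <- measurements[measurements$fragment %in% fragments, , drop = FALSE]
    if (!nrow(measurements))
      stop("no measurements left after restricting to the supplied fragment set; under a coisolating scheme restrict to channel-unique ions")
  }
  a <- measurements$peak_area
  if (subtract_background) {
    if (is.null(measurements$background))
      stop("subtract_background = TRUE but no background column present")
    a <- pmax(a - measurements$background, 0)
  }
  light <- sum(a[measurements$channel == "light"])
  heavy <- sum(a[measurements$channel == "heavy"])
  if (!sum(measurements$channel == "light") || !sum(measurements$channel == "heavy"))
    stop("both light and heavy channel measurements are required")
  if (heavy <= 0) stop("undefined L/H ratio: summed heavy peak area is zero")
  light / heavy
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit `ratio = m * amount + b` of mean L/H ratio
#' per nonzero calibration level against nominal spiked amount, with the
#' residual standard deviation Sy|x and blank-based detection limits
#' LOD = 3 Sa / m and LOQ = 10 Sa / m, where Sa is the standard
#' deviation of the blank (0 fmol) replicate ratios.
#'
#' @param levels data.frame with columns `nominal` (fmol; 0 denotes
#'   blanks) and `ratio` (one row per replicate).
#' @param fit `"mean"` (default: regress replicate-mean ratio per level)
#'   or `"replicates"` (regress every replicate ratio).
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `sy_x`, `s_a`, `lod`, `loq`, `cal_range`
#'   (range of nonzero nominals), `n_points` and `flags`.
#' @examples
#' lv <- data.frame(nominal = c(0.5, 1, 5, 25), ratio = 2 * c(0.5, 1, 5, 25) + 1)
#' fit_calibration(lv)$slope  # 2
#' @export
fit_calibration <- function(levels, fit = c("mean", "replicates"),
                            weighting = c("none", "1/x")) {
  fit <- match.arg(fit)
  weighting <- match.arg(weighting)
  stopifnot(all(c("nominal", "ratio") %in% names(levels)))
  if (any(levels$nominal < 0)) stop("nominal amounts must be >= 0")
  blanks <- levels$ratio[levels$nominal == 0]
  pts <- levels[levels$nominal > 0, , drop = FALSE]
  if (length(unique(pts$nominal)) < 3L)
    stop("calibration needs >= 3 distinct nonzero levels")
  if (fit == "mean") {
    agg <- stats::aggregate(ratio ~ nominal, data = pts, FUN = mean)
  } else {
    agg <- pts[, c("nominal", "ratio")]
  }
  if (length(unique(agg$nominal)) < 2L) stop("singular design: all levels identical")
  wts <- if (weighting == "1/x") 1 / agg$nominal else NULL
  mod <- stats::lm(ratio ~ nominal, data = agg, weights = wts)
  m <- unname(stats::coef(mod)[2])
  b <- unname(stats::coef(mod)[1])
  n <- nrow(agg)
  sy_x <- sqrt(sum(stats::residuals(mod)^2) / (n - 2))
  r2 <- suppressWarnings(summary(mod)$r.squared)  # noise-free fits are legitimate here
  s_a <- if (length(blanks) >= 2L) stats::sd(blanks) else NA_real_
  flags <- character()
  if (m < 0) {
    flags <- c(flags, "negative_slope")
    warning("calibration slope is negative")
  }
  lod <- if (!is.na(s_a) && m != 0) 3 * s_a / m else NA_real_
  loq <- if (!is.na(s_a) && m != 0) 10 * s_a / m else NA_real_
  structure(
    list(slope = m, intercept = b, r_squared = r2, sy_x = sy_x, s_a = s_a,
         lod = lod, loq = loq, cal_range = range(pts$nominal),
         blank_mean = if (length(blanks)) mean(blanks) else NA_real_,
         n_points = n, fit = fit, weighting = weighting, flags = flags),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> ratio = %.6g * fmol + %.6g  (R^2 = %.4f, Sy|x = %.4g)\n",
              x$slope, x$intercept, x$r_squared, x$sy_x))
  if (!is.na(x$s_a))
    cat(sprintf("  Sa = %.4g -> LOD = %.4g fmol, LOQ = %.4g fmol\n",
                x$s_a, x$lod, x$loq))
  else cat("  no blanks: LOD/LOQ unavailable\n")
  invisible(x)
}

#' Interpolate an L/H ratio against a calibration curve
#'
#' Converts a measured L/H ratio to an absolute amount,
#' `amount = (ratio - b) / m`, and to a concentration per microgram of
#' sample peptide. Amounts below LOD/LOQ or outside the calibrated range
#' are flagged, never silently clipped: a ratio below the blank mean
#' yields a negative amount carrying the `below_lod` flag.
#'
#' @param curve a [calibration_curve][fit_calibration()].
#' @param ratio measured L/H ratio.
#' @param sample_peptide_mass micrograms of sample peptide analyzed
#'   (default 1).
#' @return An object of class `quant_result`: list with `amount` (fmol),
#'   `concentration` (fmol/ug), `ratio` and logical flags `below_lod`,
#'   `below_loq`, `extrapolated`.
#' @examples
#' cv <- fit_calibration(data.frame(nominal = c(0, 0, 0.5, 1, 5, 25),
#'                                  ratio = c(0, 0, 0.02, 0.04, 0.2, 1)))
#' quantify(cv, 0.1)$amount  # 2.5
#' @export
quantify <- function(curve, ratio, sample_peptide_mass = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("cannot interpolate: calibration slope is zero")
  amount <- (ratio - curve$intercept) / curve$slope
  below_lod <- !is.na(curve$lod) && amount < curve$lod
  below_loq <- !is.na(curve$loq) && amount < curve$loq
  if (below_lod) below_loq <- TRUE  # LOD < LOQ always (3/10 of the same quantity)
  extrapolated <- amount > curve$cal_range[2] || amount < curve$cal_range[1]
  structure(
    list(amount = amount,
         concentration = amount / sample_peptide_mass,
         ratio = ratio,
         below_lod = below_lod, below_loq = below_loq,
         extrapolated = extrapolated),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  flags <- c("below_lod", "below_loq", "extrapolated")
  on <- flags[vapply(flags, function(f) isTRUE(x[[f]]), logical(1))]
  cat(sprintf("<quant_result> %.4g fmol (%.4g fmol/ug)%s\n", x$amount,
              x$concentration,
              if (length(on)) paste0(" [", paste(on, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Signed relative error
#'
#' `(actual - measured) / actual`; report the magnitude as "% RE".
#'
#' @param actual true (nominal) value, nonzero.
#' @param measured measured value.
#' @return signed fraction.
#' @examples
#' relative_error(2.5, 2.0)  # +0.2
#' @export
relative_error <- function(actual, measured) {
  if (any(actual == 0)) stop("relative error undefined for actual = 0")
  (actual - measured) / actual
}

#' Coefficient of variation of replicates
#'
#' Sample standard deviation over the mean.
#'
#' @param values numeric vector of >= 2 replicate values with nonzero
#'   mean.
#' @return CV as a fraction.
#' @examples
#' replicate_cv(c(9, 10, 11))  # 0.1
#' @export
replicate_cv <- function(values) {
  if (length(values) < 2L) stop("CV needs >= 2 replicate values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean of replicates is zero")
  stats::sd(values) / m
}

#' Mutant-versus-wild-type metrics
#'
#' From mutant and wild-type absolute concentrations: the mutant-to-WT
#' ratio and the mutant fraction mut / (mut + wt) -- the protein-level
#' analogue of a variant allele frequency. Reporting convention: ratio
#' to 1 decimal, fraction to integer percent.
#'
#' @param mutant_conc,wt_conc concentrations (fmol/ug).
#' @return list with `ratio`, `fraction`, and rounded `ratio_reported`,
#'   `fraction_percent`.
#' @examples
#' mutant_metrics(84.97, 27.16)$ratio_reported  # 3.1
#' @export
mutant_metrics <- function(mutant_conc, wt_conc) {
  if (wt_conc == 0) stop("mutant-to-WT ratio undefined: wild-type concentration is zero")
  if (mutant_conc + wt_conc == 0) stop("mutant fraction undefined: total concentration is zero")
  ratio <- mutant_conc / wt_conc
  fraction <- mutant_conc / (mutant_conc + wt_conc)
  list(ratio = ratio, fraction = fraction,
       ratio_reported = round_half_up(ratio, 1),
       fraction_percent = round_half_up(100 * fraction, 0))
}
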