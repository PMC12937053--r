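#' Peak-list spectrum
#'
#' @param mz strictly increasing m/z values (Th).
#' @param intensity nonnegative intensities.
#' @return data.frame of class `spectrum` with columns `mz`, `intensity`.
#' @export
spectrum <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (any(diff(mz) <= 0)) stop("spectrum m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("spectrum", "data.frame"))
}

as_spectrum <- function(x) {
  if (inherits(x, "spectrum")) return(x)
  if (is.data.frame(x) && all(c("mz", "intensity") %in% names(x)))
    return(spectrum(x$mz, x$intensity))
  stop("expected a spectrum or a data.frame with mz and intensity columns")
}

#' Cosine similarity between two spectra
#'
#' Dot product of relative intensities after greedy nearest-m/z peak
#' matching: candidate matches within `mz_tolerance` are accepted in
#' order of increasing m/z difference, each peak used at most once.
#' Unmatched peaks contribute nothing to the cross term but full weight
#' to the norms, so disjoint spectra score 0 and identical spectra 1.
#'
#' @param a,b spectra ([spectrum()] or data.frames with `mz`,
#'   `intensity`).
#' @param mz_tolerance match tolerance in Th (default 0.02).
#' @return similarity score in \[0, 1\].
#' @examples
#' a <- spectrum(c(100, 200), c(1, 0.5))
#' b <- spectrum(c(100, 200), c(0.5, 1))
#' cosine_similarity(a, b)  # 0.8
#' @export
cosine_similarity <- function(a, b, mz_tolerance = 0.02) {
  a <- as_spectrum(a); b <- as_spectrum(b)
  if (all(a$intensity == 0) || all(b$intensity == 0))
    stop("cosine similarity undefined for an all-zero spectrum")
  cand <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    j <- which(abs(b$mz - a$mz[i]) <= mz_tolerance)
    if (!length(j)) return(NULL)
    data.frame(i = i, j = j, d = abs(b$mz[j] - a$mz[i]))
  }))
  dot <- 0
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
    used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_i[i] && !used_j[j]) {
        dot <- dot + a$intensity[i] * b$intensity[j]
        used_i[i] <- TRUE; used_j[j] <- TRUE
      }
    }
  }
  dot / (sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2)))
}

#' Extracted-ion chromatogram container
#'
#' @param times increasing retention times (minutes).
#' @param intensities nonnegative intensities, same length.
#' @param peak_bounds optional `c(t_start, t_end)` integration bounds.
#' @return list of class `chromatogram`.
#' @export
chromatogram <- function(times, intensities, peak_bounds = NULL) {
  stopifnot(length(times) == length(intensities), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  if (!is.null(peak_bounds)) {
    stopifnot(length(peak_bounds) == 2L)
    if (peak_bounds[1] < times[1] || peak_bounds[2] > times[length(times)] ||
        peak_bounds[1] >= peak_bounds[2])
      stop("peak_bounds must lie within the time range")
  }
  structure(list(times = times, intensities = intensities,
                 peak_bounds = peak_bounds),
            class = "chromatogram")
}

# linear interpolation of intensity at time t
.chrom_at <- function(chrom, t)
  stats::approx(chrom$times, chrom$intensities, xout = t, rule = 2)$y

#' XIC peak area
#'
#' Trapezoidal integration of the chromatogram over its peak bounds,
#' optionally minus a linear baseline drawn between the boundary
#' intensities.
#'
#' @param chrom a [chromatogram()].
#' @param bounds integration bounds; default the chromatogram's
#'   `peak_bounds`, or the full time range when unset.
#' @param baseline_subtract subtract the linear baseline between the
#'   boundary intensities (default FALSE).
#' @return area in intensity x minutes.
#' @examples
#' ch <- chromatogram(c(0, 0.5, 1), c(0, 10, 0))
#' xic_area(ch)  # 5
#' @export
xic_area <- function(chrom, bounds = NULL, baseline_subtract = FALSE) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (is.null(bounds)) bounds <- chrom$peak_bounds
  if (is.null(bounds)) bounds <- range(chrom$times)
  if (bounds[1] < chrom$times[1] || bounds[2] > chrom$times[length(chrom$times)])
    stop("integration bounds outside chromatogram time range")
  inside <- chrom$times > bounds[1] & chrom$times < bounds[2]
  t <- c(bounds[1], chrom$times[inside], bounds[2])
  y <- c(.chrom_at(chrom, bounds[1]), chrom$intensities[inside],
         .chrom_at(chrom, bounds[2]))
  if (length(t) < 2L) stop("need >= 2 points inside the integration bounds")
  area <- sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  if (baseline_subtract) {
    # trapezoid of the straight line joining the boundary intensities
    area <- area - (y[1] + y[length(y)]) / 2 * (bounds[2] - bounds[1])
  }
  area
}

#' Signal-to-noise ratio of a chromatographic peak
#'
#' A robust S/N estimator: apex intensity above the median of the
#' flanking background, divided by 1.4826 x MAD of that background
#' (floored at `eps` so a perfectly flat background does not divide by
#' zero). Requires `min_background` points on each side of the peak
#' bounds. This is the package's own definition of S/N (vendor software
#' computes S/N internally and differently), so absolute values are not
#' comparable across tools.
#'
#' @param chrom a [chromatogram()] with `peak_bounds` set.
#' @param min_background minimum flanking points per side (default 5).
#' @param eps noise floor (default 0.01).
#' @return S/N ratio.
#' @export
snr <- function(chrom, min_background = 5L, eps = 0.01) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (is.null(chrom$peak_bounds)) stop("snr requires peak_bounds")
  b <- chrom$peak_bounds
  left <- chrom$times < b[1]
  right <- chrom$times > b[2]
  if (sum(left) < min_background || sum(right) < min_background)
    stop(sprintf("need >= %d background points on each side of the peak",
                 min_background))
  bg <- chrom$intensities[left | right]
  inside <- chrom$times >= b[1] & chrom$times <= b[2]
  apex <- max(chrom$intensities[inside])
  noise <- max(stats::mad(bg), eps)  # mad() already includes the 1.4826 factor
  (apex - stats::median(bg)) / noise
}

#' Per-sample mean pathway z-scores
#'
#' For each protein, z-scores its (log2) abundances across samples using
#' the sample standard deviation; a pathway's score in a sample is the
#' mean z of its member proteins. Zero-variance proteins contribute 0
#' with a warning; missing values are excluded pairwise. Median-center
#' the matrix with [normalize_abundance()] first when starting from raw
#' intensities.
#'
#' @param matrix numeric proteins x samples matrix of log2 abundances
#'   (rownames = protein ids).
#' @param pathways named list of character vectors of protein ids.
#' @return pathways x samples matrix of mean z-scores.
#' @examples
#' m <- matrix(c(1, 3), 1, 2, dimnames = list("P1", c("s1", "s2")))
#' pathway_zscore(m, list(pw = "P1"))  # -0.707, +0.707
#' @export
pathway_zscore <- function(matrix, pathways) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  z <- t(apply(matrix, 1, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }))
  dimnames(z) <- dimnames(matrix)
  if (any(apply(matrix, 1, function(x) {
    s <- stats::sd(x, na.rm = TRUE); is.na(s) || s == 0
  })))
    warning("zero-variance protein(s): z-scores set to 0")
  out <- do.call(rbind, lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], rownames(matrix))
    if (!length(members))
      stop(sprintf("pathway '%s' has no proteins present in the matrix", pw))
    colMeans(z[members, , drop = FALSE], na.rm = TRUE)
  }))
  rownames(out) <- names(pathways)
  out
}

#' Log2-transform and median-center an abundance matrix
#'
#' Standard pre-processing for global profiling comparisons: log2 of
#' intensities followed by per-sample (column) median subtraction.
#'
#' @param matrix proteins x samples matrix of raw intensities (or of
#'   log2 values with `log2_transform = FALSE`).
#' @param log2_transform apply log2 first (default TRUE).
#' @return matrix of centered log2 abundances.
#' @export
normalize_abundance <- function(matrix, log2_transform = TRUE) {
  if (log2_transform) matrix <- log2(matrix)
  med <- apply(matrix, 2, stats::median, na.rm = TRUE)
  sweep(matrix, 2, med, "-")
}

#' Differentially expressed protein filter
#'
#' Per-protein two-sided Wilcoxon rank-sum test between two sample
#' groups on log2 abundances, Benjamini-Hochberg adjustment across
#' tested proteins; proteins pass when |log2 fold change| >= log2 of
#' `fc_threshold` AND adjusted p <= `alpha`.
#'
#' @param matrix proteins x samples matrix of log2 abundances.
#' @param group_a,group_b column names (or indices) of the two groups,
#'   each of size >= 3.
#' @param fc_threshold minimum fold change on the natural scale
#'   (default 2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data.frame per protein: `log2_fc` (group_b minus group_a),
#'   `p_value`, `adj_p`, `up` (logical, higher in group_b) and
#'   `significant`.
#' @export
dep_filter <- function(matrix, group_a, group_b, fc_threshold = 2,
                       alpha = 0.05) {
  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  if (ncol(a) < 3L || ncol(b) < 3L)
    stop("each group needs >= 3 samples for the rank-sum test")
  res <- do.call(rbind, lapply(seq_len(nrow(matrix)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (all(is.na(xa)) || all(is.na(xb)))
      stop(sprintf("protein %s has no values in one group", rownames(matrix)[i]))
    p <- suppressWarnings(
      stats::wilcox.test(xb, xa, exact = NULL)$p.value)
    data.frame(log2_fc = mean(xb, na.rm = TRUE) - mean(xa, na.rm = TRUE),
               p_value = p)
  }))
  res$protein <- rownames(matrix)
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res$up <- res$log2_fc > 0
  res$significant <- abs(res$log2_fc) >= log2(fc_threshold) & res$adj_p <= alpha
  res[, c("protein", "log2_fc", "p_value", "adj_p", "up", "significant")]
}
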