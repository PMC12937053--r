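#' Isolation-window schemes
#'
#' A window scheme is an ordered, non-overlapping set of half-open
#' isolation windows `[start, end)` covering a scan range. Narrow
#' `narrow_target` windows isolate one precursor of a light/heavy pair
#' each; `wide_profile` windows tile the remaining m/z range for global
#' profiling. The half-open convention makes shared boundaries (e.g.
#' 453-457 / 457-461) unambiguous: a precursor sitting exactly on a
#' boundary belongs to the right-hand window.
#'
#' @param windows data.frame with columns `start_mz`, `end_mz`, `kind`
#'   and optionally `off_grid`.
#' @param scan_range numeric length-2, `c(min, max)` in Th.
#' @param narrow_width nominal narrow-window width in Th.
#' @param wide_bounds allowed wide-window widths `c(min, max)` in Th.
#' @param anchor_offset grid anchor for narrow windows (boundaries at
#'   `anchor_offset + k * narrow_width`).
#' @return An object of class `window_scheme`.
#' @export
window_scheme <- function(windows, scan_range, narrow_width = 4,
                          wide_bounds = c(narrow_width, 60),
                          anchor_offset = 1) {
  stopifnot(is.data.frame(windows),
            all(c("start_mz", "end_mz", "kind") %in% names(windows)))
  if (is.null(windows$off_grid)) windows$off_grid <- FALSE
  windows <- windows[order(windows$start_mz), , drop = FALSE]
  if (any(windows$end_mz <= windows$start_mz))
    stop("every window must satisfy start_mz < end_mz")
  windows$id <- seq_len(nrow(windows))
  windows$center_mz <- (windows$start_mz + windows$end_mz) / 2
  windows$width <- windows$end_mz - windows$start_mz
  rownames(windows) <- NULL
  structure(
    list(windows = windows[, c("id", "start_mz", "end_mz", "center_mz",
                               "width", "kind", "off_grid")],
         scan_range = as.numeric(scan_range), narrow_width = narrow_width,
         wide_bounds = as.numeric(wide_bounds), anchor_offset = anchor_offset),
    class = "window_scheme"
  )
}

#' @export
print.window_scheme <- function(x, ...) {
  k <- table(x$windows$kind)
  cat(sprintf("<window_scheme> %d windows over [%g, %g) Th (%s)\n",
              nrow(x$windows), x$scan_range[1], x$scan_range[2],
              paste(sprintf("%s: %d", names(k), k), collapse = ", ")))
  invisible(x)
}

# grid cell index of an m/z on the global narrow grid
.grid_cell <- function(mz, width, offset) floor((mz - offset) / width)

#' Place the two narrow windows for an isotope pair
#'
#' Narrow windows come from a single global grid of width `narrow_width`
#' anchored at `anchor_offset` (boundaries at `anchor_offset + k * width`),
#' so that every pair in a panel shares one consistent set of boundaries.
#' When light and heavy fall into the *same* grid cell (pair spacing
#' smaller than the width, e.g. heavy-Glu labels at 2+/3+), the two
#' windows are locally re-anchored so their shared boundary is the
#' midpoint of the two m/z values, and flagged `off_grid`.
#'
#' @param pair an [isotope_pair()], or a numeric length-2 vector
#'   `c(light_mz, heavy_mz)`.
#' @param narrow_width window width in Th (default 4).
#' @param anchor_offset grid anchor in Th (default 1: boundaries at
#'   ..., 453, 457, 461, ... -- the rule consistent with adjacent-window
#'   placement of both 2+ heavy-Lys reference pairs).
#' @param scan_range precursors must lie inside this range.
#' @return data.frame of two windows (light first) with columns
#'   `start_mz`, `end_mz`, `kind`, `off_grid`.
#' @examples
#' place_pair_windows(isotope_pair("ITDFGRAK", 2))  # [453,457) and [457,461)
#' @export
place_pair_windows <- function(pair, narrow_width = 4, anchor_offset = 1,
                               scan_range = c(400, 1000)) {
  mzs <- if (inherits(pair, "isotope_pair")) c(pair$light$mz, pair$heavy$mz)
         else if (is.numeric(pair) && length(pair) == 2L) sort(pair)
         else stop("pair must be an isotope_pair or c(light_mz, heavy_mz)")
  if (any(mzs < scan_range[1] | mzs >= scan_range[2]))
    stop(sprintf("precursor m/z %.4f outside scan range [%g, %g)",
                 mzs[which(mzs < scan_range[1] | mzs >= scan_range[2])][1],
                 scan_range[1], scan_range[2]))
  cells <- .grid_cell(mzs, narrow_width, anchor_offset)
  if (cells[1] == cells[2]) {
    # same-cell conflict: shared boundary at the pair midpoint, off grid
    mid <- mean(mzs)
    out <- data.frame(
      start_mz = c(mid - narrow_width, mid),
      end_mz   = c(mid, mid + narrow_width),
      kind = "narrow_target", off_grid = TRUE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      start_mz = anchor_offset + cells * narrow_width,
      end_mz   = anchor_offset + (cells + 1) * narrow_width,
      kind = "narrow_target", off_grid = FALSE, stringsAsFactors = FALSE)
  }
  out
}

# integrated (trapezoid) cumulative density over [lo, hi] on a fine grid;
# density points are interpreted as a piecewise-linear weight function,
# constant-extrapolated outside its support
.cumulative_density <- function(density, lo, hi, n_grid = 4096L) {
  x <- seq(lo, hi, length.out = n_grid)
  w <- stats::approx(density$mz, density$weight, xout = x, rule = 2)$y
  if (any(w < 0)) stop("density weights must be nonnegative")
  cum <- c(0, cumsum(diff(x) * (w[-1] + w[-length(w)]) / 2))
  list(x = x, cum = cum, total = cum[length(cum)])
}

# boundaries splitting [lo, hi) into k sub-windows at equal
# cumulative-density quantiles (equal widths when density is NULL)
.quantile_boundaries <- function(lo, hi, k, density = NULL) {
  if (is.null(density)) return(lo + (hi - lo) * (0:k) / k)
  cd <- .cumulative_density(density, lo, hi)
  if (cd$total <= 0) return(lo + (hi - lo) * (0:k) / k)  # no mass: equal split
  targets <- cd$total * (0:k) / k
  b <- stats::approx(cd$cum, cd$x, xout = targets, ties = "ordered")$y
  b[1] <- lo; b[k + 1] <- hi
  b
}

# clamp sub-window widths into [min, max], redistributing the deficit
# over unclamped windows; falls back to equal widths (always feasible
# when k was chosen so that k*min <= span <= k*max)
.clamp_widths <- function(boundaries, bounds) {
  k <- length(boundaries) - 1L
  span <- boundaries[k + 1L] - boundaries[1L]
  w <- diff(boundaries)
  for (iter in 1:100) {
    lo_viol <- w < bounds[1] - 1e-9
    hi_viol <- w > bounds[2] + 1e-9
    if (!any(lo_viol | hi_viol)) break
    fixed <- lo_viol | hi_viol
    w[lo_viol] <- bounds[1]
    w[hi_viol] <- bounds[2]
    free <- !fixed
    deficit <- span - sum(w)
    if (!any(free)) { w <- rep(span / k, k); break }
    w[free] <- w[free] + deficit * w[free] / sum(w[free])
  }
  if (any(w < bounds[1] - 1e-6) || any(w > bounds[2] + 1e-6))
    w <- rep(span / k, k)
  boundaries[1L] + c(0, cumsum(w))
}

# largest-remainder apportionment of n items across masses, respecting
# per-gap count bounds [lo_i, hi_i]
.largest_remainder <- function(mass, n, lo, hi) {
  g <- length(mass)
  if (sum(lo) > n)
    stop(sprintf("cannot tile gaps within width bounds: at least %d wide windows needed, %d allotted",
                 sum(lo), n))
  if (sum(hi) < n)
    stop(sprintf("cannot tile gaps within width bounds: at most %d wide windows fit, %d allotted",
                 sum(hi), n))
  total <- sum(mass)
  quota <- if (total > 0) n * mass / total else rep(n / g, g)
  cnt <- floor(quota)
  rem <- quota - cnt
  cnt <- pmin(pmax(cnt, lo), hi)
  # distribute the remaining units by largest fractional remainder
  while (sum(cnt) < n) {
    cand <- which(cnt < hi)
    pick <- cand[which.max(rem[cand])]
    cnt[pick] <- cnt[pick] + 1L
    rem[pick] <- rem[pick] - 1
  }
  while (sum(cnt) > n) {
    cand <- which(cnt > lo)
    pick <- cand[which.min(rem[cand])]
    cnt[pick] <- cnt[pick] - 1L
    rem[pick] <- rem[pick] + 1
  }
  as.integer(cnt)
}

#' Design a dual-window acquisition scheme
#'
#' The core scheme designer: one narrow window per target precursor
#' (light and heavy of each pair in adjacent windows from the global
#' grid), with the remaining m/z gaps tiled by `n_wide` wide windows.
#' Wide windows are apportioned across gaps by largest-remainder on the
#' gap's density mass (gap width when no density is supplied), with
#' boundaries inside each gap at equal cumulative-density quantiles and
#' widths clamped to `wide_bounds`.
#'
#' @param pairs list of [isotope_pair()] objects (may be empty).
#' @param scan_range acquisition m/z range, default `c(400, 1000)`.
#' @param narrow_width narrow-window width in Th (default 4).
#' @param n_wide number of wide profiling windows (default 20).
#' @param density optional [precursor_density()] (data.frame `mz`,
#'   `weight`) steering wide-window widths toward precursor-dense
#'   regions.
#' @param wide_bounds allowed wide-window widths; default `c(0, Inf)`
#'   (unconstrained). Pass e.g. `c(4, 60)` to respect an instrument's
#'   isolation-width limits, at the cost of needing enough wide windows
#'   to tile every gap.
#' @param anchor_offset narrow-grid anchor, default 1.
#' @return A [window_scheme()].
#' @examples
#' sch <- design_scheme(list(isotope_pair("ITDFGRAK", 2)), n_wide = 2)
#' sch$windows
#' @export
design_scheme <- function(pairs, scan_range = c(400, 1000), narrow_width = 4,
                          n_wide = 20L, density = NULL,
                          wide_bounds = c(0, Inf),
                          anchor_offset = 1) {
  n_wide <- as.integer(n_wide)
  narrow <- if (length(pairs)) {
    do.call(rbind, lapply(pairs, place_pair_windows,
                          narrow_width = narrow_width,
                          anchor_offset = anchor_offset,
                          scan_range = scan_range))
  } else NULL
  if (!is.null(narrow)) {
    # clip to scan range, merge duplicated grid cells (distinct pairs may
    # legitimately share a cell), reject partial overlaps
    narrow$start_mz <- pmax(narrow$start_mz, scan_range[1])
    narrow$end_mz <- pmin(narrow$end_mz, scan_range[2])
    narrow <- narrow[!duplicated(narrow[c("start_mz", "end_mz")]), , drop = FALSE]
    narrow <- narrow[order(narrow$start_mz), , drop = FALSE]
    if (nrow(narrow) > 1L) {
      ov <- narrow$start_mz[-1] < narrow$end_mz[-nrow(narrow)] - 1e-9
      if (any(ov))
        stop("narrow windows overlap partially (off-grid re-anchoring collides with a neighboring target); adjust narrow_width or anchor_offset")
    }
  }
  # gaps: complement of the narrow blocks within the scan range
  edges <- c(scan_range[1],
             if (!is.null(narrow)) as.vector(t(narrow[, c("start_mz", "end_mz")])),
             scan_range[2])
  gap_lo <- edges[seq(1, length(edges), by = 2)]
  gap_hi <- edges[seq(2, length(edges), by = 2)]
  keep <- gap_hi - gap_lo > 1e-9
  gap_lo <- gap_lo[keep]; gap_hi <- gap_hi[keep]
  g <- length(gap_lo)
  wide <- NULL
  if (g > 0L) {
    if (n_wide < g)
      stop(sprintf("n_wide = %d but the narrow blocks leave %d gaps to tile",
                   n_wide, g))
    width <- gap_hi - gap_lo
    mass <- if (is.null(density)) width else
      vapply(seq_len(g), function(i)
        .cumulative_density(density, gap_lo[i], gap_hi[i])$total, numeric(1))
    if (all(mass <= 0)) mass <- width
    # count bounds so each gap can be tiled within wide_bounds; gaps
    # narrower than the lower bound get one (flagged) undersized window
    lo <- pmax(1L, ceiling(width / wide_bounds[2] - 1e-9))
    hi <- pmax(1L, floor(width / wide_bounds[1] + 1e-9))
    cnt <- .largest_remainder(mass, n_wide, lo, hi)
    wide <- do.call(rbind, lapply(seq_len(g), function(i) {
      b <- .quantile_boundaries(gap_lo[i], gap_hi[i], cnt[i], density)
      b <- .clamp_widths(b, wide_bounds)
      data.frame(start_mz = b[-length(b)], end_mz = b[-1],
                 kind = "wide_profile",
                 off_grid = width[i] < wide_bounds[1] - 1e-9,
                 stringsAsFactors = FALSE)
    }))
  } else if (n_wide > 0L) {
    stop("narrow windows cover the whole scan range; no room for wide windows")
  }
  window_scheme(rbind(narrow, wide), scan_range, narrow_width, wide_bounds,
                anchor_offset)
}

#' Fixed equal-width scheme
#'
#' The conventional fixed-window DIA reference: `n` contiguous windows of
#' identical width across the scan range (40 x 15 Th over 400-1000 by
#' default arguments of the comparison workflow).
#'
#' @param scan_range acquisition m/z range.
#' @param n number of windows.
#' @return A [window_scheme()] of `wide_profile` windows.
#' @examples
#' equal_width_scheme(c(400, 1000), 40)$windows$width[1]  # 15
#' @export
equal_width_scheme <- function(scan_range = c(400, 1000), n = 40L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  b <- scan_range[1] + (scan_range[2] - scan_range[1]) * (0:n) / n
  window_scheme(
    data.frame(start_mz = b[-length(b)], end_mz = b[-1],
               kind = "wide_profile", stringsAsFactors = FALSE),
    scan_range,
    narrow_width = (scan_range[2] - scan_range[1]) / n,
    wide_bounds = c(0, Inf))
}

#' Precursor-density reference
#'
#' Density of precursor ion signal along m/z (e.g. MS1 intensity binned
#' by m/z), used to equalize precursor load across variable windows.
#' Interpreted as a piecewise-linear weight function over m/z.
#'
#' @param mz increasing m/z positions (Th).
#' @param weight nonnegative weights.
#' @return data.frame of class `precursor_density`.
#' @export
precursor_density <- function(mz, weight) {
  stopifnot(length(mz) == length(weight), length(mz) >= 1L)
  if (any(weight < 0)) stop("density weights must be nonnegative")
  o <- order(mz)
  structure(data.frame(mz = mz[o], weight = weight[o]),
            class = c("precursor_density", "data.frame"))
}

#' Variable-width scheme from a precursor density
#'
#' `n` windows whose boundaries sit at the n-quantiles of the cumulative
#' precursor density over the scan range, so each window carries roughly
#' equal precursor load; widths are clamped to `wide_bounds`. With a
#' uniform density this reduces exactly to [equal_width_scheme()].
#'
#' @param scan_range acquisition m/z range.
#' @param n number of windows.
#' @param density a [precursor_density()].
#' @param wide_bounds allowed window widths, default `c(0, Inf)`.
#' @return A [window_scheme()].
#' @export
variable_width_scheme <- function(scan_range = c(400, 1000), n = 40L, density,
                                  wide_bounds = c(0, Inf)) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  cd <- .cumulative_density(density, scan_range[1], scan_range[2])
  if (cd$total <= 0)
    stop("precursor density has no mass inside the scan range")
  b <- .quantile_boundaries(scan_range[1], scan_range[2], n, density)
  b <- .clamp_widths(b, wide_bounds)
  window_scheme(
    data.frame(start_mz = b[-length(b)], end_mz = b[-1],
               kind = "wide_profile", stringsAsFactors = FALSE),
    scan_range,
    narrow_width = (scan_range[2] - scan_range[1]) / n,
    wide_bounds = wide_bounds)
}

#' Assign an m/z to its isolation window
#'
#' @param scheme a [window_scheme()].
#' @param mz m/z value(s) in Th, each within the scan range.
#' @return integer window id(s) (`start <= mz < end`, half-open rule).
#' @export
assign_window <- function(scheme, mz) {
  stopifnot(inherits(scheme, "window_scheme"))
  w <- scheme$windows
  out <- vapply(mz, function(m) {
    if (m < scheme$scan_range[1] || m >= scheme$scan_range[2])
      stop(sprintf("m/z %.4f outside scan range [%g, %g)", m,
                   scheme$scan_range[1], scheme$scan_range[2]))
    i <- findInterval(m, w$start_mz)
    if (i < 1L || m >= w$end_mz[i])
      stop(sprintf("m/z %.4f falls into a hole of the scheme", m))
    w$id[i]
  }, integer(1))
  out
}

#' Validate a window scheme against its invariants
#'
#' Machine-readable report: full coverage of the scan range, no
#' overlaps, widths within their nominal bounds, window counts by kind,
#' and -- when pairs are supplied -- whether each pair's light and heavy
#' precursors land in different windows (the scheme's defining
#' guarantee).
#'
#' @param scheme a [window_scheme()].
#' @param pairs optional list of [isotope_pair()] objects.
#' @param tol numeric tolerance for boundary comparisons.
#' @return list of class `scheme_validation` with elements `coverage_ok`,
#'   `overlap_ok`, `widths_ok`, `counts`, `pair_separation` (data.frame)
#'   and `ok` (all checks combined).
#' @export
validate_scheme <- function(scheme, pairs = NULL, tol = 1e-6) {
  w <- scheme$windows
  coverage_ok <- abs(w$start_mz[1] - scheme$scan_range[1]) <= tol &&
    abs(w$end_mz[nrow(w)] - scheme$scan_range[2]) <= tol &&
    (nrow(w) == 1L || all(abs(w$start_mz[-1] - w$end_mz[-nrow(w)]) <= tol))
  overlap_ok <- nrow(w) == 1L || all(w$start_mz[-1] >= w$end_mz[-nrow(w)] - tol)
  narrow <- w$kind == "narrow_target" & !w$off_grid
  wide <- w$kind == "wide_profile" & !w$off_grid
  widths_ok <- all(abs(w$width[narrow] - scheme$narrow_width) <= tol |
                     # windows clipped at the scan edge may be shorter
                     w$start_mz[narrow] <= scheme$scan_range[1] + tol |
                     w$end_mz[narrow] >= scheme$scan_range[2] - tol) &&
    all(w$width[wide] >= scheme$wide_bounds[1] - tol &
          w$width[wide] <= scheme$wide_bounds[2] + tol)
  counts <- table(factor(w$kind, levels = c("narrow_target", "wide_profile")))
  pair_separation <- NULL
  if (!is.null(pairs) && length(pairs)) {
    pair_separation <- do.call(rbind, lapply(pairs, function(p) {
      il <- tryCatch(assign_window(scheme, p$light$mz), error = function(e) NA_integer_)
      ih <- tryCatch(assign_window(scheme, p$heavy$mz), error = function(e) NA_integer_)
      data.frame(sequence = p$sequence, charge = p$charge,
                 light_window = il, heavy_window = ih,
                 pair_separation_ok = !is.na(il) && !is.na(ih) && il != ih,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(coverage_ok = coverage_ok, overlap_ok = overlap_ok,
         widths_ok = widths_ok,
         counts = c(narrow_target = unname(counts["narrow_target"]),
                    wide_profile = unname(counts["wide_profile"])),
         pair_separation = pair_separation,
         ok = coverage_ok && overlap_ok && widths_ok &&
           (is.null(pair_separation) || all(pair_separation$pair_separation_ok))),
    class = "scheme_validation")
}

#' @export
print.scheme_validation <- function(x, ...) {
  cat(sprintf("<scheme_validation> coverage %s | overlaps %s | widths %s | narrow %d wide %d\n",
              x$coverage_ok, x$overlap_ok, x$widths_ok,
              x$counts["narrow_target"], x$counts["wide_profile"]))
  if (!is.null(x$pair_separation))
    cat(sprintf("  pairs separated: %d / %d\n",
                sum(x$pair_separation$pair_separation_ok),
                nrow(x$pair_separation)))
  invisible(x)
}
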