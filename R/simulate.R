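# run code under a temporary RNG state so generators are deterministic
# per seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a panel of light/heavy isotope pairs
#'
#' Random tryptic-like sequences (C-terminal K or E matching the label
#' kind, no internal cleavage residues) whose precursors at the given
#' charge fall inside the scan range. Pairs are kept mutually separated
#' in m/z so each precursor occupies its own narrow-grid cell.
#' Deterministic under a fixed seed.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param scan_range acquisition m/z range.
#' @param charge precursor charge.
#' @param label_kind `"heavy_K"` or `"heavy_E"`.
#' @param seed integer seed.
#' @param min_spacing minimum m/z distance between any two precursors of
#'   different pairs (default 12 Th, i.e. three 4-Th grid cells).
#' @param length_range candidate peptide lengths (default 7-14).
#' @return list of [isotope_pair()] objects.
#' @examples
#' length(synth_panel(8, seed = 7))  # 8
#' @export
synth_panel <- function(n_pairs, scan_range = c(400, 1000), charge = 2L,
                        label_kind = c("heavy_K", "heavy_E"), seed = 1L,
                        min_spacing = 12, length_range = c(7L, 14L)) {
  label_kind <- match.arg(label_kind)
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop("n_pairs must be >= 1")
  cterm <- isotope_label(label_kind)$residue
  # residues drawn for internal positions: no K/R (tryptic-like), and no
  # C-terminal-label residue to keep the label position unambiguous
  pool <- setdiff(names(.RESIDUE_MASSES), c("K", "R", cterm))
  shift_mz <- isotope_label(label_kind)$mass_shift / charge
  .with_seed(seed, {
    pairs <- list()
    taken <- numeric()
    tries <- 0L
    while (length(pairs) < n_pairs) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place the requested pairs inside the scan range; relax n_pairs, min_spacing or scan_range")
      len <- sample(length_range[1]:length_range[2], 1L)
      seq_ <- paste0(paste(sample(pool, len - 1L, replace = TRUE), collapse = ""),
                     cterm)
      mz <- precursor_mz(labeled_peptide(seq_), charge)
      lo <- mz; hi <- mz + shift_mz
      if (lo < scan_range[1] + 1 || hi >= scan_range[2] - 1) next
      if (length(taken) && min(abs(taken - lo)) < min_spacing) next
      if (length(taken) && min(abs(taken - hi)) < min_spacing) next
      pairs[[length(pairs) + 1L]] <- isotope_pair(seq_, charge, label_kind)
      taken <- c(taken, lo, hi)
    }
    pairs
  })
}

#' Simulated peptide mixture
#'
#' The species list a simulated acquisition fragments: labeled peptides
#' with charge, spiked amount and retention time. Fragment-ion relative
#' intensities are drawn once per species from a seeded distribution, so
#' spectra are reproducible without a fragmentation model.
#'
#' @param species data.frame with columns `sequence`, `label` (label
#'   kind), `charge`, `amount` (fmol) and optionally `rt` (minutes).
#' @param seed integer seed for the per-species fragment-intensity
#'   profiles.
#' @return list of class `simulated_mixture`.
#' @export
simulated_mixture <- function(species, seed = 1L) {
  stopifnot(is.data.frame(species),
            all(c("sequence", "label", "charge", "amount") %in% names(species)))
  if (any(species$amount < 0)) stop("amounts must be >= 0")
  if (is.null(species$rt)) species$rt <- 10
  structure(list(species = species, seed = as.integer(seed)),
            class = "simulated_mixture")
}

#' Mixture from a pair panel
#'
#' Expands a list of isotope pairs into a two-channel mixture with given
#' light amounts and a fixed heavy spike.
#'
#' @param pairs list of [isotope_pair()] objects.
#' @param light_amounts fmol per pair (recycled).
#' @param heavy_amount fixed heavy internal-standard spike (fmol),
#'   default 25.
#' @param seed seed passed to [simulated_mixture()].
#' @return A `simulated_mixture`.
#' @export
mixture_from_pairs <- function(pairs, light_amounts, heavy_amount = 25,
                               seed = 1L) {
  light_amounts <- rep_len(light_amounts, length(pairs))
  species <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(
      sequence = p$sequence,
      label = c("none", p$heavy$peptide$label$kind),
      charge = p$charge,
      amount = c(light_amounts[i], heavy_amount),
      stringsAsFactors = FALSE)
  }))
  simulated_mixture(species, seed)
}

# deterministic per-species fragment intensity profile: relative
# intensities shared by the light and heavy twin of a sequence
.fragment_profile <- function(sequence, charge, mixture_seed) {
  key <- sum(utf8ToInt(sequence)) * 31L + as.integer(charge)
  .with_seed((mixture_seed * 1009L + key) %% .Machine$integer.max, {
    n <- nchar(sequence) - 1L
    # b/y relative intensities in (0.05, 1], y-ions on average hotter
    b <- stats::runif(n, 0.05, 0.6)
    y <- stats::runif(n, 0.2, 1)
    stats::setNames(c(b, y), c(paste0("b", 1:n), paste0("y", 1:n)))
  })
}

#' Simulate a DIA acquisition of a mixture under a window scheme
#'
#' Assigns every precursor to its isolation window, builds per-window
#' composite MS2 spectra by summing the theoretical fragment spectra of
#' all coisolated species (intensity = amount x per-species fragment
#' profile), and reports, per light/heavy pair, the fragments whose
#' light and heavy m/z collide within tolerance in the *same* window --
#' the interference a pair-separating scheme is designed to remove.
#'
#' @param mixture a [simulated_mixture()].
#' @param scheme a [window_scheme()].
#' @param mz_tolerance fragment m/z collision tolerance (default 0.02 Th).
#' @return list of class `acquisition_result` with `assignments`
#'   (data.frame species -> window), `spectra` (named list of composite
#'   [spectrum()] per window id) and `interference` (data.frame per
#'   pair: `coisolated`, `n_collisions`, colliding ion names).
#' @export
simulate_acquisition <- function(mixture, scheme, mz_tolerance = 0.02) {
  stopifnot(inherits(mixture, "simulated_mixture"),
            inherits(scheme, "window_scheme"))
  sp <- mixture$species
  sp$mz <- vapply(seq_len(nrow(sp)), function(i)
    precursor_mz(labeled_peptide(sp$sequence[i], sp$label[i]), sp$charge[i]),
    numeric(1))
  sp$window <- assign_window(scheme, sp$mz)
  frag <- lapply(seq_len(nrow(sp)), function(i) {
    fr <- fragment_series(labeled_peptide(sp$sequence[i], sp$label[i]))
    prof <- .fragment_profile(sp$sequence[i], sp$charge[i], mixture$seed)
    fr$intensity <- sp$amount[i] * unname(prof[fr$ion])
    fr
  })
  spectra <- lapply(split(seq_len(nrow(sp)), sp$window), function(idx) {
    peaks <- do.call(rbind, frag[idx])
    # coincident fragment m/z (e.g. shared b-ions of a coisolated pair)
    # merge into a single composite peak
    key <- round(peaks$mz, 6)
    agg <- stats::aggregate(peaks$intensity, list(mz = key), sum)
    spectrum(agg$mz, agg$x)
  })
  # pair up light/heavy species of the same sequence+charge
  is_light <- sp$label == "none"
  inter <- NULL
  lights <- which(is_light)
  for (i in lights) {
    j <- which(!is_light & sp$sequence == sp$sequence[i] &
                 sp$charge == sp$charge[i])
    if (!length(j)) next
    j <- j[1]
    co <- sp$window[i] == sp$window[j]
    if (co) {
      dl <- abs(frag[[j]]$mz - frag[[i]]$mz)
      collide <- frag[[i]]$ion[dl <= mz_tolerance]
    } else collide <- character()
    inter <- rbind(inter, data.frame(
      sequence = sp$sequence[i], charge = sp$charge[i],
      light_window = sp$window[i], heavy_window = sp$window[j],
      coisolated = co, n_collisions = length(collide),
      colliding_ions = paste(collide, collapse = ";"),
      stringsAsFactors = FALSE))
  }
  structure(list(assignments = sp, spectra = spectra, interference = inter),
            class = "acquisition_result")
}

#' Transition measurements from a simulated acquisition
#'
#' Converts a simulated acquisition into the transition-level peak-area
#' table the quantification layer consumes: per species and fragment,
#' the "peak area" is the simulated fragment intensity, optionally with
#' multiplicative lognormal noise.
#'
#' @param mixture a [simulated_mixture()].
#' @param acq result of [simulate_acquisition()] on that mixture.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   noise on each transition area (default 0 = noise-free).
#' @param seed seed for the noise draws.
#' @return data.frame with columns `sequence`, `charge`, `channel`,
#'   `fragment`, `peak_area`, `window`.
#' @export
acquisition_transitions <- function(mixture, acq, noise_cv = 0, seed = 1L) {
  sp <- acq$assignments
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    fr <- fragment_series(labeled_peptide(sp$sequence[i], sp$label[i]))
    prof <- .fragment_profile(sp$sequence[i], sp$charge[i], mixture$seed)
    data.frame(sequence = sp$sequence[i], charge = sp$charge[i],
               channel = if (sp$label[i] == "none") "light" else "heavy",
               fragment = fr$ion,
               peak_area = sp$amount[i] * unname(prof[fr$ion]),
               window = sp$window[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    out$peak_area <- .with_seed(seed,
      out$peak_area * stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog))
  }
  out
}

#' Simulate a calibration dilution series
#'
#' Replicate L/H ratios from a known line `ratio = m x + b` with
#' multiplicative lognormal noise of mean 1, plus blank (0 fmol)
#' replicates drawn normal around the intercept and truncated at 0. The
#' default levels mirror a serial-dilution design of 0.5-500 fmol with
#' the heavy standard fixed, three replicates per level.
#'
#' @param true_slope slope of the generating line (ratio per fmol).
#' @param true_intercept intercept (default 0).
#' @param levels nonzero calibration amounts in fmol, default
#'   `c(0.5, 1, 5, 25, 100, 500)`.
#' @param reps replicates per level (default 3).
#' @param noise_cv lognormal CV of the ratio noise (default 0.05).
#' @param n_blanks number of blank replicates (default 3).
#' @param blank_sd standard deviation of blank ratios (default
#'   `true_slope * 0.01`).
#' @param seed integer seed.
#' @return data.frame with columns `nominal`, `ratio` suitable for
#'   [fit_calibration()].
#' @export
simulate_calibration_series <- function(true_slope, true_intercept = 0,
                                        levels = c(0.5, 1, 5, 25, 100, 500),
                                        reps = 3L, noise_cv = 0.05,
                                        n_blanks = 3L,
                                        blank_sd = true_slope * 0.01,
                                        seed = 1L) {
  stopifnot(noise_cv >= 0)
  .with_seed(seed, {
    nominal <- rep(levels, each = reps)
    mu <- true_slope * nominal + true_intercept
    ratio <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    } else mu
    blanks <- if (n_blanks > 0)
      pmax(stats::rnorm(n_blanks, true_intercept, blank_sd), 0) else numeric()
    data.frame(nominal = c(rep(0, n_blanks), nominal),
               ratio = c(blanks, ratio))
  })
}

#' Simulate an extracted-ion chromatogram
#'
#' Gaussian elution peak whose area (above background) equals `amount`,
#' over a constant background of `5 * noise_sd` with additive Gaussian
#' noise. The offset keeps the noise distribution intact after the
#' nonnegativity clamp; `peak_bounds` are set at +/- 4 peak widths with
#' ample flanking background for S/N estimation.
#'
#' @param amount peak area (arbitrary intensity x minutes).
#' @param rt apex retention time (minutes, default 10).
#' @param width Gaussian sigma in minutes (default 0.05).
#' @param noise_sd additive noise standard deviation (default 0).
#' @param seed integer seed.
#' @param dt sampling interval in minutes (default `width / 12`).
#' @return a [chromatogram()].
#' @export
simulate_chromatogram <- function(amount, rt = 10, width = 0.05,
                                  noise_sd = 0, seed = 1L, dt = width / 12) {
  stopifnot(width > 0, amount >= 0)
  times <- seq(rt - 10 * width, rt + 10 * width, by = dt)
  y <- 5 * noise_sd + amount * stats::dnorm(times, rt, width)
  if (noise_sd > 0)
    y <- .with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  chromatogram(times, pmax(y, 0), peak_bounds = c(rt - 4 * width, rt + 4 * width))
}
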