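#' Labeled peptide
#'
#' The unit of targeting: a peptide sequence with an optional C-terminal
#' stable-isotope label and (optionally) coordinates in its parent
#' protein.
#'
#' @param sequence peptide sequence, canonical one-letter codes only.
#' @param label an [isotope_label()] object or a kind string
#'   (`"none"`, `"heavy_K"`, `"heavy_E"`). Heavy kinds require the
#'   C-terminal residue to match the labeled amino acid.
#' @param protein_id identifier of the parent protein (optional).
#' @param start 1-based start coordinate in the parent protein.
#' @param protease name of the protease that generated the peptide
#'   (optional).
#' @return An object of class `labeled_peptide`.
#' @examples
#' labeled_peptide("ITDFGRAK", "heavy_K", protein_id = "EGFR", start = 853)
#' @export
labeled_peptide <- function(sequence, label = "none", protein_id = NA_character_,
                            start = 1L, protease = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(residues %in% names(.RESIDUE_MASSES)))
  if (length(bad))
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], sequence))
  if (is.character(label)) label <- isotope_label(label)
  stopifnot(inherits(label, "isotope_label"))
  n <- length(residues)
  if (label$kind != "none") {
    if (residues[n] != label$residue)
      stop(sprintf("label %s requires C-terminal residue %s, found %s",
                   label$kind, label$residue, residues[n]))
  }
  start <- as.integer(start)
  if (is.na(start) || start < 1L) stop("start must be a positive integer")
  structure(
    list(sequence = sequence, residues = residues, label = label,
         protein_id = protein_id, start = start, end = start + n - 1L,
         # C-terminal labels sit on the last residue
         labeled_position = if (label$kind == "none") NA_integer_ else n,
         protease = protease),
    class = "labeled_peptide"
  )
}

#' @export
print.labeled_peptide <- function(x, ...) {
  coord <- if (!is.na(x$protein_id))
    sprintf(" [%s %d-%d]", x$protein_id, x$start, x$end) else ""
  cat(sprintf("<labeled_peptide> %s (%s)%s\n", x$sequence, x$label$kind, coord))
  invisible(x)
}

as_labeled_peptide <- function(x, label = "none") {
  if (inherits(x, "labeled_peptide")) x else labeled_peptide(x, label)
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses + water + isotope-label
#' shift + any fixed modifications in the table. Full precision is kept;
#' rounding happens only at reporting time.
#'
#' @param peptide a [labeled_peptide()] or a plain sequence string
#'   (treated as unlabeled).
#' @param aa an [amino_acid_table()].
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("ITDFGRAK")  # 906.4923
#' @export
peptide_mass <- function(peptide, aa = amino_acid_table()) {
  peptide <- as_labeled_peptide(peptide)
  m <- sum(aa$residue_masses[peptide$residues]) + aa$water_mass +
    peptide$label$mass_shift
  if (length(aa$fixed_mods)) {
    counts <- table(factor(peptide$residues, levels = names(aa$fixed_mods)))
    m <- m + sum(as.numeric(counts) * aa$fixed_mods)
  }
  unname(m)
}

#' Precursor m/z
#'
#' @param peptide a [labeled_peptide()] or sequence string.
#' @param charge precursor charge state (positive integer).
#' @param aa an [amino_acid_table()].
#' @return m/z in Thomson, full precision (round with [round_half_up()]
#'   for reporting).
#' @examples
#' round_half_up(precursor_mz("ITDFGRAK", 2))                 # 454.25
#' round_half_up(precursor_mz(labeled_peptide("ITDFGRAK", "heavy_K"), 2))  # 458.26
#' @export
precursor_mz <- function(peptide, charge, aa = amino_acid_table()) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  (peptide_mass(peptide, aa) + charge * aa$proton_mass) / charge
}

#' b/y fragment-ion series
#'
#' Singly (or multiply) protonated b- and y-ions for indices 1..n-1.
#' A C-terminal isotope label shifts every y-ion and no b-ion; the
#' `carries_label` column records, for each fragment, whether its residue
#' span contains the labeled position.
#'
#' @param peptide a [labeled_peptide()] or sequence string.
#' @param fragment_charge fragment charge state (default 1).
#' @param aa an [amino_acid_table()].
#' @return data.frame with columns `ion` (e.g. "b3", "y4"), `series`,
#'   `index`, `charge`, `mz`, `carries_label`.
#' @examples
#' fr <- fragment_series(labeled_peptide("ELREATSPK", "heavy_K"))
#' fr[fr$ion == "y4", "mz"]
#' @export
fragment_series <- function(peptide, fragment_charge = 1L, aa = amino_acid_table()) {
  peptide <- as_labeled_peptide(peptide)
  z <- as.integer(fragment_charge)
  if (is.na(z) || z < 1L) stop("fragment_charge must be a positive integer")
  res <- peptide$residues
  n <- length(res)
  if (n < 2L) stop("fragment series requires a peptide of length >= 2")
  rm <- unname(aa$residue_masses[res])
  if (length(aa$fixed_mods)) {
    idx <- match(res, names(aa$fixed_mods))
    hit <- !is.na(idx)
    rm[hit] <- rm[hit] + unname(aa$fixed_mods[idx[hit]])
  }
  shift <- peptide$label$mass_shift
  lp <- peptide$labeled_position
  i <- seq_len(n - 1L)
  # b_i spans residues 1..i, y_j spans residues (n-j+1)..n
  suffix_sums <- rev(cumsum(rev(rm)))          # sum of residues k..n
  b_neutral <- cumsum(rm)[i]
  y_neutral <- suffix_sums[n - i + 1L] + aa$water_mass
  b_label <- if (is.na(lp)) rep(FALSE, n - 1L) else i >= lp
  y_label <- if (is.na(lp)) rep(FALSE, n - 1L) else (n - i + 1L) <= lp
  b_neutral <- b_neutral + ifelse(b_label, shift, 0)
  y_neutral <- y_neutral + ifelse(y_label, shift, 0)
  out <- rbind(
    data.frame(series = "b", index = i, charge = z,
               mz = (b_neutral + z * aa$proton_mass) / z,
               carries_label = b_label, stringsAsFactors = FALSE),
    data.frame(series = "y", index = i, charge = z,
               mz = (y_neutral + z * aa$proton_mass) / z,
               carries_label = y_label, stringsAsFactors = FALSE)
  )
  out$ion <- paste0(out$series, out$index)
  out[, c("ion", "series", "index", "charge", "mz", "carries_label")]
}

#' Light/heavy isotope pair
#'
#' A light precursor and its heavy-labeled twin: same sequence and charge,
#' differing only in the C-terminal isotope label. The m/z spacing is
#' `label_shift / charge` (4.0071 Th for heavy-Lys at 2+).
#'
#' @param sequence peptide sequence (C-terminal residue must match the
#'   heavy label kind).
#' @param charge precursor charge state.
#' @param heavy_kind `"heavy_K"` or `"heavy_E"`; default chosen from the
#'   C-terminal residue (K -> heavy_K, E -> heavy_E).
#' @param protein_id,start,protease passed to [labeled_peptide()].
#' @param aa an [amino_acid_table()].
#' @return An object of class `isotope_pair`: list with `light`, `heavy`
#'   (each a list `peptide`, `charge`, `mz`), `spacing` and `sequence`.
#' @examples
#' p <- isotope_pair("ELREATSPK", 2)
#' round_half_up(c(p$light$mz, p$heavy$mz))  # 515.78 519.79
#' @export
isotope_pair <- function(sequence, charge, heavy_kind = NULL,
                         protein_id = NA_character_, start = 1L,
                         protease = NA_character_, aa = amino_acid_table()) {
  cterm <- substring(sequence, nchar(sequence), nchar(sequence))
  if (is.null(heavy_kind)) {
    heavy_kind <- switch(cterm, K = "heavy_K", E = "heavy_E",
      stop(sprintf("no C-terminal heavy label available for residue '%s'", cterm)))
  }
  light <- labeled_peptide(sequence, "none", protein_id, start, protease)
  heavy <- labeled_peptide(sequence, heavy_kind, protein_id, start, protease)
  lmz <- precursor_mz(light, charge, aa)
  hmz <- precursor_mz(heavy, charge, aa)
  structure(
    list(sequence = sequence, charge = as.integer(charge),
         light = list(peptide = light, charge = as.integer(charge), mz = lmz),
         heavy = list(peptide = heavy, charge = as.integer(charge), mz = hmz),
         spacing = hmz - lmz),
    class = "isotope_pair"
  )
}

#' @export
print.isotope_pair <- function(x, ...) {
  cat(sprintf("<isotope_pair> %s %d+  light %.4f / heavy %.4f (spacing %.4f Th)\n",
              x$sequence, x$charge, x$light$mz, x$heavy$mz, x$spacing))
  invisible(x)
}

#' Partition pair fragments into shared and unique ions
#'
#' Under coisolation (light and heavy precursors fragmented in the same
#' isolation window) an ion is *shared* when its light and heavy m/z
#' coincide within tolerance -- for C-terminal labels this is exactly the
#' b-series -- and only the unique ions are usable for quantification.
#' When the pair is isolated in separate windows every fragment of each
#' channel is quantifiable.
#'
#' @param pair an [isotope_pair()].
#' @param coisolated logical: were both channels fragmented together?
#' @param mz_tolerance m/z match tolerance in Th (default 0.02).
#' @param fragments optional character vector of ion names (e.g.
#'   `c("b3","y4")`) restricting the fragment set considered (an observed
#'   ion set); default: the full b/y series at charge 1.
#' @param fragment_charge fragment charge used to build the series.
#' @param aa an [amino_acid_table()].
#' @return list with data.frames `shared_ions`, `unique_light`,
#'   `unique_heavy` and the integer `quantifiable_count_light`.
#' @examples
#' p <- isotope_pair("ELREATSPK", 2)
#' classify_pair_fragments(p, coisolated = TRUE)$quantifiable_count_light  # 8 y-ions
#' @export
classify_pair_fragments <- function(pair, coisolated, mz_tolerance = 0.02,
                                    fragments = NULL, fragment_charge = 1L,
                                    aa = amino_acid_table()) {
  stopifnot(inherits(pair, "isotope_pair"))
  if (pair$light$peptide$sequence != pair$heavy$peptide$sequence)
    stop("light and heavy peptides must share the same sequence")
  fl <- fragment_series(pair$light$peptide, fragment_charge, aa)
  fh <- fragment_series(pair$heavy$peptide, fragment_charge, aa)
  if (!is.null(fragments)) {
    keep <- fl$ion %in% fragments
    if (!any(keep)) stop("no fragments left after restricting to the supplied ion set")
    fl <- fl[keep, , drop = FALSE]
    fh <- fh[keep, , drop = FALSE]
  }
  delta <- abs(fh$mz - fl$mz)
  if (isTRUE(coisolated)) {
    shared <- delta <= mz_tolerance
  } else {
    shared <- rep(FALSE, nrow(fl))
  }
  list(
    shared_ions  = fl[shared, , drop = FALSE],
    unique_light = fl[!shared, , drop = FALSE],
    unique_heavy = fh[!shared, , drop = FALSE],
    quantifiable_count_light = sum(!shared)
  )
}
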