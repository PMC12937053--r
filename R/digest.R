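#' Protease definition
#'
#' Cleavage rules for the proteases used to generate variant-covering
#' peptides. `trypsin_p` cleaves C-terminal to K/R including before
#' proline (the "Trypsin/P" convention common in DIA searches); set
#' `before_proline = FALSE` for the classical rule. `lysc` cleaves after
#' K, `gluc` after E (after D too when `gluc_d = TRUE`; E-specificity is
#' the default in bicarbonate-style buffers).
#'
#' @param name one of `"trypsin_p"`, `"lysc"`, `"gluc"`.
#' @param before_proline trypsin only: cleave even when the next residue
#'   is proline (default TRUE).
#' @param gluc_d GluC only: also cleave after aspartate (default FALSE).
#' @return An object of class `protease`.
#' @export
protease <- function(name = c("trypsin_p", "lysc", "gluc"),
                     before_proline = TRUE, gluc_d = FALSE) {
  name <- match.arg(name)
  cleave_after <- switch(name,
    trypsin_p = c("K", "R"),
    lysc      = "K",
    gluc      = if (gluc_d) c("E", "D") else "E"
  )
  no_cleave_before <- if (name == "trypsin_p" && !before_proline) "P" else character()
  structure(list(name = name, cleave_after = cleave_after,
                 no_cleave_before = no_cleave_before),
            class = "protease")
}

as_protease <- function(x) {
  if (inherits(x, "protease")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% c("trypsin_p", "lysc", "gluc"))
      stop(sprintf("unknown protease '%s'", x))
    return(protease(x))
  }
  stop("protease must be a protease object or one of 'trypsin_p', 'lysc', 'gluc'")
}

#' In-silico digestion
#'
#' Cleaves a protein with a protease. At 0 missed cleavages the peptides
#' partition the protein; with `max_missed = k`, every concatenation of up
#' to k+1 adjacent fragments is also emitted. Coordinates are 1-based
#' inclusive.
#'
#' @param protein protein sequence string.
#' @param enzyme a [protease()] or protease name.
#' @param max_missed maximum number of missed cleavages (default 0).
#' @param protein_id identifier recorded with each peptide.
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`,
#'   `protease`, `protein_id`.
#' @examples
#' digest("AKELREATSPKG", "lysc")
#' @export
digest <- function(protein, enzyme, max_missed = 0L, protein_id = NA_character_) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty sequence string")
  enzyme <- as_protease(enzyme)
  max_missed <- as.integer(max_missed)
  stopifnot(max_missed >= 0L)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut <- which(res[-n] %in% enzyme$cleave_after)
  if (length(enzyme$no_cleave_before))
    cut <- cut[!(res[cut + 1L] %in% enzyme$no_cleave_before)]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  k <- length(starts)
  out <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    if (m + 1L > k) break
    i <- seq_len(k - m)
    s <- starts[i]
    e <- ends[i + m]
    out[[m + 1L]] <- data.frame(
      sequence = vapply(seq_along(s), function(j)
        paste(res[s[j]:e[j]], collapse = ""), character(1)),
      start = s, end = e, missed = m,
      protease = enzyme$name, protein_id = protein_id,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Apply a variant to a protein sequence
#'
#' @param protein wild-type sequence string.
#' @param variant a list: `type = "sub"` with `pos`, `ref`, `alt`, or
#'   `type = "del"` with `start`, `end` (residues removed, inclusive).
#' @return list with `sequence` (mutant), and `site`: for substitutions
#'   the variant position (mutant coordinates = wild-type coordinates);
#'   for deletions the two mutant positions flanking the novel junction.
#' @export
apply_variant <- function(protein, variant) {
  n <- nchar(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (identical(variant$type, "sub")) {
    pos <- as.integer(variant$pos)
    if (is.na(pos) || pos < 1L || pos > n)
      stop(sprintf("variant position %s outside protein (length %d)", variant$pos, n))
    if (!is.null(variant$ref) && !is.na(variant$ref) && res[pos] != variant$ref)
      stop(sprintf("reference mismatch at %d: expected %s, found %s",
                   pos, variant$ref, res[pos]))
    res[pos] <- variant$alt
    list(sequence = paste(res, collapse = ""), site = c(pos, pos))
  } else if (identical(variant$type, "del")) {
    s <- as.integer(variant$start); e <- as.integer(variant$end)
    if (is.na(s) || is.na(e) || s < 1L || e > n || s > e)
      stop("deletion range outside protein or inverted")
    mut <- paste(res[-(s:e)], collapse = "")
    # novel junction between mutant positions s-1 and s (clamped at termini)
    left <- max(s - 1L, 1L)
    right <- min(s, nchar(mut))
    list(sequence = mut, site = c(left, right))
  } else stop("variant$type must be 'sub' or 'del'")
}

#' Variant-covering peptide panel
#'
#' Digests the wild-type and the mutant protein with one or more
#' proteases and returns light/heavy candidate pairs whose span contains
#' the variant site (for deletions, the novel junction), together with
#' the matched wild-type counterpart peptides. The heavy label follows
#' the C-terminal residue (K -> heavy-Lys, E -> heavy-Glu); candidates
#' with no labelable C-terminus or failing the length / precursor-m/z
#' constraints are excluded with a recorded reason.
#'
#' @param protein_wt wild-type protein sequence.
#' @param variant variant specification, see [apply_variant()].
#' @param proteases character vector of protease names (default LysC and
#'   GluC, the usual choices for EGFR variant coverage).
#' @param protein_id protein identifier for the emitted peptides.
#' @param max_missed missed cleavages allowed when digesting (default 2).
#' @param length_range allowed peptide lengths, default `c(7, 52)`.
#' @param charges precursor charges considered, default `2:3`.
#' @param scan_range acquisition m/z range a precursor must fall in at
#'   one of the allowed charges, default `c(400, 1000)`.
#' @param aa an [amino_acid_table()].
#' @return list with `panel` (data.frame: form mutant/wt, sequence,
#'   start, end, protease, charge, label, light_mz, heavy_mz) and
#'   `excluded` (data.frame with a `reason` column). Both may have zero
#'   rows; an empty panel is returned with diagnostics rather than an
#'   error.
#' @examples
#' variant_panel("MKAAGKLLRKE", list(type = "sub", pos = 4, ref = "A", alt = "V"),
#'               proteases = "lysc", length_range = c(2, 52),
#'               scan_range = c(100, 2000))
#' @export
variant_panel <- function(protein_wt, variant, proteases = c("lysc", "gluc"),
                          protein_id = NA_character_, max_missed = 2L,
                          length_range = c(7L, 52L), charges = 2:3,
                          scan_range = c(400, 1000), aa = amino_acid_table()) {
  mut <- apply_variant(protein_wt, variant)
  wt_site <- if (identical(variant$type, "sub"))
    c(variant$pos, variant$pos) else c(variant$start, variant$end)

  collect <- function(protein, site, form) {
    out <- lapply(proteases, function(pn) {
      d <- digest(protein, pn, max_missed, protein_id)
      # span must contain the variant site / both junction flanks
      d[d$start <= site[1] & d$end >= site[2], , drop = FALSE]
    })
    d <- do.call(rbind, out)
    if (is.null(d) || !nrow(d)) return(NULL)
    d$form <- form
    d
  }

  cand <- rbind(collect(mut$sequence, mut$site, "mutant"),
                collect(protein_wt, wt_site, "wt"))
  panel <- list(); excluded <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[!duplicated(cand[c("form", "sequence", "start", "protease")]), ]
    for (r in seq_len(nrow(cand))) {
      row <- cand[r, ]
      len <- nchar(row$sequence)
      if (len < length_range[1] || len > length_range[2]) {
        row$reason <- sprintf("length %d outside [%d, %d]", len,
                              length_range[1], length_range[2])
        excluded[[length(excluded) + 1L]] <- row
        next
      }
      cterm <- substring(row$sequence, len, len)
      kind <- switch(cterm, K = "heavy_K", E = "heavy_E", NA_character_)
      if (is.na(kind)) {
        row$reason <- sprintf("C-terminal '%s' has no heavy label", cterm)
        excluded[[length(excluded) + 1L]] <- row
        next
      }
      mzs <- vapply(charges, function(z)
        precursor_mz(labeled_peptide(row$sequence), z, aa), numeric(1))
      ok <- mzs >= scan_range[1] & mzs < scan_range[2]
      if (!any(ok)) {
        row$reason <- sprintf("precursor m/z outside [%g, %g) at charges %s",
                              scan_range[1], scan_range[2],
                              paste(charges, collapse = ","))
        excluded[[length(excluded) + 1L]] <- row
        next
      }
      for (z in charges[ok]) {
        pr <- isotope_pair(row$sequence, z, kind, protein_id, row$start,
                           row$protease, aa)
        panel[[length(panel) + 1L]] <- data.frame(
          form = row$form, sequence = row$sequence, start = row$start,
          end = row$end, protease = row$protease, charge = z, label = kind,
          light_mz = pr$light$mz, heavy_mz = pr$heavy$mz,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_panel <- data.frame(form = character(), sequence = character(),
                            start = integer(), end = integer(),
                            protease = character(), charge = integer(),
                            label = character(), light_mz = numeric(),
                            heavy_mz = numeric(), stringsAsFactors = FALSE)
  list(panel = if (length(panel)) do.call(rbind, panel) else empty_panel,
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(sequence = character(), reason = character(),
                    stringsAsFactors = FALSE))
}
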