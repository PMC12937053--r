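#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences (names = first token of
#'   each FASTA header).
#' @export
read_fasta_proteins <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  names(seqs) <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Read a variant specification table
#'
#' Tab-separated, columns: `protein_id`, `type` ("sub" or "del"),
#' `position` (for del: "start-end"), `ref`, `alt` (ref/alt may be empty
#' for deletions).
#'
#' @param path TSV file.
#' @return list of variant specs (each a list with `protein_id` plus the
#'   fields [apply_variant()] expects).
#' @export
read_variant_spec <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("protein_id", "type", "position")
  if (!all(need %in% names(tb)))
    stop(sprintf("variant spec %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  lapply(seq_len(nrow(tb)), function(i) {
    row <- tb[i, ]
    if (row$type == "sub") {
      list(protein_id = row$protein_id, type = "sub",
           pos = as.integer(row$position),
           ref = if (!is.null(row$ref) && nzchar(row$ref)) row$ref else NA,
           alt = row$alt)
    } else if (row$type == "del") {
      se <- as.integer(strsplit(row$position, "-", fixed = TRUE)[[1]])
      if (length(se) != 2L || any(is.na(se)))
        stop(sprintf("%s line %d: deletion position must be 'start-end'", path, i))
      list(protein_id = row$protein_id, type = "del", start = se[1], end = se[2])
    } else stop(sprintf("%s line %d: unknown variant type '%s'", path, i, row$type))
  })
}

#' Write / read a target-panel table
#'
#' Tab-separated panel in the dialect [design_scheme()] inputs are built
#' from: `sequence`, `start`, `end`, `protease`, `charge`, `label`,
#' `light_mz`, `heavy_mz` (m/z reported to 4 decimals).
#'
#' @param panel data.frame as returned in `variant_panel()$panel`.
#' @param path output TSV path.
#' @return `write_panel`: the path, invisibly. `read_panel`: the panel
#'   data.frame.
#' @export
write_panel <- function(panel, path) {
  panel$light_mz <- round(panel$light_mz, 4)
  panel$heavy_mz <- round(panel$heavy_mz, 4)
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "charge", "label")
  if (!all(need %in% names(tb)))
    stop(sprintf("panel %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  tb
}

#' Isotope pairs from a panel table
#'
#' Rebuilds [isotope_pair()] objects from the rows of a panel table
#' (one pair per unique sequence/charge/label).
#'
#' @param panel data.frame with `sequence`, `charge`, `label` columns.
#' @return list of `isotope_pair`.
#' @export
panel_pairs <- function(panel) {
  key <- !duplicated(panel[c("sequence", "charge", "label")])
  lapply(which(key), function(i)
    isotope_pair(panel$sequence[i], panel$charge[i], panel$label[i]))
}

#' Write / read an isolation-window scheme
#'
#' CSV with columns `window_id`, `start_mz`, `end_mz`, `center_mz`,
#' `width`, `kind`; the round-trip reader rebuilds the
#' [window_scheme()].
#'
#' @param scheme a [window_scheme()].
#' @param path CSV path.
#' @return `write_scheme`: the path, invisibly. `read_scheme`: a
#'   `window_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  w <- scheme$windows
  out <- data.frame(window_id = w$id, start_mz = w$start_mz,
                    end_mz = w$end_mz, center_mz = w$center_mz,
                    width = w$width, kind = w$kind, off_grid = w$off_grid)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_mz", "end_mz", "kind")
  if (!all(need %in% names(tb)))
    stop(sprintf("scheme %s must have columns: %s", path,
                 paste(need, collapse = ", ")))
  nw <- tb$width[tb$kind == "narrow_target"]
  window_scheme(tb[, c("start_mz", "end_mz", "kind",
                       intersect("off_grid", names(tb)))],
                scan_range = c(min(tb$start_mz), max(tb$end_mz)),
                narrow_width = if (length(nw)) stats::median(nw) else
                  stats::median(tb$width),
                wide_bounds = c(0, Inf))
}

#' Write a scheme in instrument-paste format
#'
#' Two-column table (center m/z, isolation width) in acquisition order,
#' the dialect instrument method editors accept for pasting.
#'
#' @param scheme a [window_scheme()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_instrument_table <- function(scheme, path) {
  w <- scheme$windows
  utils::write.table(
    data.frame(center_mz = w$center_mz, isolation_width = w$width),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transition-level peak-area table
#'
#' Tolerant reader for Skyline-style transition exports: recognizes the
#' header variants `Peptide`/`Peptide Sequence`, `Isotope Label Type`,
#' `Fragment Ion`, `Area`/`Total Area Fragment`, `Background`,
#' `Replicate`/`Replicate Name` (case- and punctuation-insensitive) as
#' well as the package's own plain names.
#'
#' @param path CSV file.
#' @return data.frame with normalized columns `replicate`, `sequence`,
#'   `channel` ("light"/"heavy"), `fragment`, `peak_area`, `background`
#'   (0 when absent).
#' @export
read_transitions <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  norm <- gsub("[^a-z0-9]", "", tolower(names(tb)))
  pick <- function(cands, required = TRUE) {
    i <- which(norm %in% cands)[1]
    if (is.na(i)) {
      if (required)
        stop(sprintf("%s: no column matching any of: %s", path,
                     paste(cands, collapse = ", ")))
      return(NULL)
    }
    tb[[i]]
  }
  sequence <- pick(c("peptide", "peptidesequence", "sequence"))
  channel <- tolower(pick(c("isotopelabeltype", "channel", "label")))
  if (!all(channel %in% c("light", "heavy")))
    stop(sprintf("%s: channel values must be 'light' or 'heavy'", path))
  fragment <- pick(c("fragmention", "fragment", "ion"))
  area <- as.numeric(pick(c("area", "totalareafragment", "peakarea")))
  background <- pick(c("background"), required = FALSE)
  replicate <- pick(c("replicate", "replicatename"), required = FALSE)
  data.frame(
    replicate = if (is.null(replicate)) "rep1" else as.character(replicate),
    sequence = sequence, channel = channel, fragment = fragment,
    peak_area = area,
    background = if (is.null(background)) 0 else as.numeric(background),
    stringsAsFactors = FALSE)
}

#' Read a calibration level specification
#'
#' TSV with columns `level` (replicate label or level id) and
#' `nominal_fmol`.
#'
#' @param path TSV file.
#' @return data.frame `level`, `nominal_fmol`.
#' @export
read_calibration_spec <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("level", "nominal_fmol") %in% names(tb)))
    stop(sprintf("calibration spec %s must have columns level, nominal_fmol", path))
  tb$nominal_fmol <- as.numeric(tb$nominal_fmol)
  tb
}
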