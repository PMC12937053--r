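# reference pairs used across tests: the two 2+ heavy-Lys pairs with
# printed m/z (454.25/458.26 and 515.78/519.79)
pair_l858r <- isotope_pair("ITDFGRAK", 2)
pair_del19wt <- isotope_pair("ELREATSPK", 2)

# synthetic miniature of an EGFR-like context around an L->R substitution:
# LysC releases ITDFGLAK (wild type) / ITDFGRAK (mutant)
egfr_like_wt <- "MAAAKITDFGLAKEEEGK"
egfr_like_variant <- list(type = "sub", pos = 11, ref = "L", alt = "R")

# independent residue-mass oracle assembled from elemental monoisotopic
# masses (H 1.0078250319, C 12, N 14.0030740052, O 15.9949146221,
# S 31.97207069), kept separate from the package's table
oracle_residue_mass <- local({
  H <- 1.0078250319; C <- 12; N <- 14.0030740052; O <- 15.9949146221
  S <- 31.97207069
  comp <- list( # residue formulas C H N O S
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  vapply(comp, function(x) sum(x * c(C, H, N, O, S)), numeric(1))
})

oracle_peptide_mass <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  sum(oracle_residue_mass[res]) + 2 * 1.0078250319 + 15.9949146221
}
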