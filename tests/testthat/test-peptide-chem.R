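test_that("monoisotopic masses match an independent elemental-composition oracle", {
  expect_equal(peptide_mass("ITDFGRAK"), 906.4923, tolerance = 1e-4)
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-4)
  for (seq_ in c("ITDFGRAK", "ELREATSPK", "GASPVTCLINDQKEMHFRYW"))
    expect_equal(peptide_mass(seq_), oracle_peptide_mass(seq_), tolerance = 1e-6)
  # label shift is purely additive
  expect_equal(peptide_mass(labeled_peptide("ITDFGRAK", "heavy_K")),
               peptide_mass("ITDFGRAK") + 8.014199, tolerance = 1e-6)
})

test_that("label shifts and water/proton constants hit their reference values", {
  expect_equal(isotope_label("heavy_K")$mass_shift, 8.0142, tolerance = 1e-3)
  expect_equal(isotope_label("heavy_E")$mass_shift, 6.0138, tolerance = 1e-3)
  tab <- amino_acid_table()
  expect_equal(tab$water_mass, 18.0106, tolerance = 1e-4)
  expect_equal(tab$proton_mass, 1.00728, tolerance = 1e-5)
  expect_true(all(tab$residue_masses > 0))
  expect_length(tab$residue_masses, 20L)
})

test_that("non-canonical residues are rejected with character and position", {
  expect_error(labeled_peptide("PEPTIDEX"), "X.*position 8|position 8.*X")
  expect_error(labeled_peptide("ABC"), "'B' at position 2")
  expect_error(labeled_peptide(""), "non-empty")
  expect_error(labeled_peptide("PEPTIDE", "heavy_K"), "C-terminal residue K")
})

test_that("2+ precursor m/z of the reference pairs round to the printed values", {
  expect_identical(round_half_up(precursor_mz("ITDFGRAK", 2)), 454.25)
  expect_identical(round_half_up(precursor_mz(labeled_peptide("ITDFGRAK", "heavy_K"), 2)), 458.26)
  expect_identical(round_half_up(precursor_mz("ELREATSPK", 2)), 515.78)
  expect_identical(round_half_up(precursor_mz(labeled_peptide("ELREATSPK", "heavy_K"), 2)), 519.79)
  expect_error(precursor_mz("ITDFGRAK", 0), "charge")
})

test_that("charge relation holds for every precursor across charges", {
  aa <- amino_acid_table()
  for (seq_ in c("ITDFGRAK", "ELREATSPK")) for (z in 1:4) {
    mz <- precursor_mz(seq_, z, aa)
    expect_equal(mz * z - z * aa$proton_mass, peptide_mass(seq_, aa),
                 tolerance = 1e-4)
  }
})

test_that("pair m/z spacing equals label shift over charge", {
  for (z in 2:3) {
    p <- isotope_pair("ELREATSPK", z)
    expect_equal(p$spacing, isotope_label("heavy_K")$mass_shift / z,
                 tolerance = 1e-4)
  }
  expect_equal(isotope_pair("ITDFGRAK", 2)$spacing, 4.0071, tolerance = 1e-4)
})

test_that("fragment series: worked y-ion values, label placement, complementarity", {
  fr_l <- fragment_series("ELREATSPK")
  fr_h <- fragment_series(labeled_peptide("ELREATSPK", "heavy_K"))
  expect_equal(fr_l$mz[fr_l$ion == "y4"], 432.245, tolerance = 1e-3)
  expect_equal(fr_h$mz[fr_h$ion == "y4"],
               fr_l$mz[fr_l$ion == "y4"] + 8.0142, tolerance = 1e-3)
  # C-terminal label: all y-ions carry it, no b-ion does
  expect_true(all(fr_h$carries_label[fr_h$series == "y"]))
  expect_false(any(fr_h$carries_label[fr_h$series == "b"]))
  # b_i + y_{n-i} = neutral mass + 2 protons, against the oracle mass
  n <- nchar("ELREATSPK")
  total <- oracle_peptide_mass("ELREATSPK") + 2 * 1.00728
  for (i in 1:(n - 1)) {
    b <- fr_l$mz[fr_l$ion == paste0("b", i)]
    y <- fr_l$mz[fr_l$ion == paste0("y", n - i)]
    expect_equal(b + y, total, tolerance = 1e-3)
  }
  expect_error(fragment_series("G"), "length")
})

test_that("complementarity is an identity for random peptides", {
  set.seed(11)
  aa_pool <- c("G","A","S","P","V","T","L","I","N","D","Q","K","E","M","H","F","R","Y","W")
  for (rep in 1:20) {
    seq_ <- paste(sample(aa_pool, sample(4:15, 1), replace = TRUE), collapse = "")
    fr <- fragment_series(seq_)
    n <- nchar(seq_)
    total <- peptide_mass(seq_) + 2 * amino_acid_table()$proton_mass
    for (i in 1:(n - 1))
      expect_equal(fr$mz[fr$ion == paste0("b", i)] + fr$mz[fr$ion == paste0("y", n - i)],
                   total, tolerance = 1e-9)
  }
})

test_that("coisolated pairs share exactly the b-series (brute-force m/z oracle)", {
  for (seq_ in c("ELREATSPK", "ITDFGRAK", "AAVNDTWGSEK")) {
    p <- isotope_pair(seq_, 2)
    cls <- classify_pair_fragments(p, coisolated = TRUE)
    # brute-force oracle: compare per-fragment light/heavy m/z directly
    fl <- fragment_series(p$light$peptide)
    fh <- fragment_series(p$heavy$peptide)
    oracle_shared <- fl$ion[abs(fh$mz - fl$mz) <= 0.02]
    expect_setequal(cls$shared_ions$ion, oracle_shared)
    expect_setequal(cls$shared_ions$ion,
                    paste0("b", 1:(nchar(seq_) - 1)))
    expect_setequal(cls$unique_light$ion,
                    paste0("y", 1:(nchar(seq_) - 1)))
  }
})

test_that("worked quantifiable-ion count: separated isolation with the observed ion set", {
  p <- isotope_pair("ELREATSPK", 2)
  co <- classify_pair_fragments(p, coisolated = TRUE)
  expect_identical(nrow(co$shared_ions), 8L)
  expect_identical(co$quantifiable_count_light, 8L)
  sep <- classify_pair_fragments(p, coisolated = FALSE,
    fragments = c("b3", "b4", "b5", "b6", "b7", "y3", "y4", "y5", "y6", "y8"))
  expect_identical(sep$quantifiable_count_light, 10L)
})

test_that("an unlabeled 'pair' coisolated shares everything", {
  p <- isotope_pair("ELREATSPK", 2)
  p$heavy <- p$light  # same species in both channels
  cls <- classify_pair_fragments(p, coisolated = TRUE)
  expect_identical(cls$quantifiable_count_light, 0L)
  expect_identical(nrow(cls$unique_light), 0L)
})

test_that("digestion partitions the protein and handles missed cleavages", {
  d <- digest("AKELREATSPKG", "lysc")
  expect_identical(d$sequence, c("AK", "ELREATSPK", "G"))
  expect_identical(d$start, c(1L, 3L, 12L))
  expect_identical(d$end, c(2L, 11L, 12L))
  d1 <- digest("AKELREATSPKG", "lysc", max_missed = 1)
  expect_true(all(c("AKELREATSPK", "ELREATSPKG") %in% d1$sequence))
  g <- digest("AEKVE", "gluc")
  expect_identical(g$sequence, c("AE", "KVE"))
  expect_error(digest("AEKVE", "chymotrypsin"), "unknown protease")
})

test_that("digestion round-trip: 0-missed peptides concatenate to the protein", {
  set.seed(5)
  aa_pool <- names(amino_acid_table()$residue_masses)
  for (enz in c("trypsin_p", "lysc", "gluc")) for (rep in 1:10) {
    prot <- paste(sample(aa_pool, sample(10:60, 1), replace = TRUE), collapse = "")
    d <- digest(prot, enz)
    expect_identical(paste(d$sequence, collapse = ""), prot)
    expect_identical(d$start[1], 1L)
    expect_identical(d$end[nrow(d)], nchar(prot))
    expect_true(all(d$start[-1] == d$end[-nrow(d)] + 1L))
  }
})

test_that("trypsin/P cleaves before proline, classical rule does not", {
  expect_identical(digest("AKPG", "trypsin_p")$sequence, c("AK", "PG"))
  expect_identical(digest("AKPG", protease("trypsin_p", before_proline = FALSE))$sequence,
                   "AKPG")
  expect_identical(digest("ADAE", protease("gluc", gluc_d = TRUE))$sequence,
                   c("AD", "AE"))
})

test_that("variant panel covers the variant site and applies constraints", {
  res <- variant_panel("MKAAGKLLRKE", list(type = "sub", pos = 4, ref = "A", alt = "V"),
                       proteases = "lysc", length_range = c(2, 52),
                       scan_range = c(100, 2000))
  expect_true(all(res$panel$start <= 4 & res$panel$end >= 4))
  expect_true("AVGK" %in% res$panel$sequence)
  # mutant peptide from the EGFR-like miniature
  res2 <- variant_panel(egfr_like_wt, egfr_like_variant, proteases = "lysc",
                        scan_range = c(400, 1000))
  expect_true("ITDFGRAK" %in% res2$panel$sequence[res2$panel$form == "mutant"])
  expect_true("ITDFGLAK" %in% res2$panel$sequence[res2$panel$form == "wt"])
  mut_row <- res2$panel[res2$panel$sequence == "ITDFGRAK" & res2$panel$charge == 2, ]
  expect_identical(round_half_up(mut_row$light_mz[1]), 454.25)
  expect_identical(round_half_up(mut_row$heavy_mz[1]), 458.26)
})

test_that("length bounds 7-52 exclude boundary-length candidates with a reason", {
  # the only 0-missed variant-covering LysC peptide (AAVGK) is 5 residues
  res <- variant_panel("MKAAAGK", list(type = "sub", pos = 5, ref = "A", alt = "V"),
                       proteases = "lysc", max_missed = 0)
  expect_identical(nrow(res$panel), 0L)
  expect_true(any(grepl("length", res$excluded$reason)))
  # a 53-residue candidate fails the upper bound too
  long_pep <- paste(rep("A", 52), collapse = "")
  res2 <- variant_panel(paste0("K", long_pep, "K"),
                        list(type = "sub", pos = 10, ref = "A", alt = "V"),
                        proteases = "lysc", max_missed = 0,
                        scan_range = c(0, 1e5))
  expect_true(any(grepl("length 53", res2$excluded$reason)))
})

test_that("deletion panels cover the novel junction", {
  # removing residues 4-6 creates a junction between positions 3 and 4
  wt <- "MAKLLLITDFGK"
  res <- variant_panel(wt, list(type = "del", start = 4, end = 6),
                       proteases = "lysc", length_range = c(2, 52),
                       scan_range = c(100, 2000))
  mutseq <- apply_variant(wt, list(type = "del", start = 4, end = 6))$sequence
  expect_identical(mutseq, "MAKITDFGK")
  expect_true(all(res$panel$start[res$panel$form == "mutant"] <= 3 &
                    res$panel$end[res$panel$form == "mutant"] >= 4))
  expect_error(apply_variant(wt, list(type = "sub", pos = 99, ref = "A", alt = "V")),
               "outside")
})
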