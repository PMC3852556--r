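test_that("kmer_frequencies: trivial cases and ambiguity handling", {
  expect_equal(kmer_frequencies("AAAA", 1),
               c(A = 1, C = 0, G = 0, T = 0))
  f2 <- kmer_frequencies("ACGT", 2)
  expect_equal(unname(f2[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(f2), 1)
  # ambiguous windows skipped, denominator reduced
  expect_equal(kmer_frequencies("AANA", 1)[["A"]], 1)
  expect_equal(unname(kmer_frequencies("AANAA", 2)[["AA"]]), 1)
  expect_error(kmer_frequencies("NNN", 1), "no valid")
})

test_that("k-mer block matches the sliding-window oracle and sums to 1", {
  for (s in 1:5) {
    seq <- random_dna(1000, p_ambiguous = 0.02, seed = s)
    for (k in 1:3) {
      expect_equal(unname(kmer_frequencies(seq, k)),
                   unname(oracle_kmer_freq(seq, k)),
                   tolerance = 1e-12)
      expect_equal(sum(kmer_frequencies(seq, k)), 1)
    }
  }
})

test_that("Z-curve: length 252, bounds, degenerate and symmetric inputs", {
  z <- zcurve_features(strrep("A", 90))
  expect_length(z, 252)
  # all mass on A: every x, y, z component of occupied prefixes equals 1
  expect_equal(unname(z[c("zc.all.k1.x", "zc.all.k1.y", "zc.all.k1.z")]),
               c(1, 1, 1))
  z2 <- zcurve_features(strrep("ACGT", 3))
  expect_equal(unname(z2[c("zc.all.k1.x", "zc.all.k1.y", "zc.all.k1.z")]),
               c(0, 0, 0))
  for (s in 1:3) {
    zi <- zcurve_features(random_dna(200, seed = s))
    expect_true(all(zi >= -1 & zi <= 1))
  }
})

test_that("Z-curve matches the independent counting oracle", {
  for (s in 1:10) {
    seq <- random_dna(sample(60:400, 1), p_ambiguous = 0.02, seed = s)
    expect_equal(unname(zcurve_features(seq)), oracle_zcurve(seq),
                 tolerance = 1e-12)
  }
})

test_that("gc_content: trivial values and counting oracle", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_error(gc_content("NNN"), "no unambiguous")
  for (s in 1:5) {
    seq <- random_dna(300, p_ambiguous = 0.05, seed = s)
    expect_equal(gc_content(seq), oracle_gc(seq), tolerance = 1e-12)
  }
})

test_that("gc3s_composition: hand counts, truncation rule, oracle", {
  expect_equal(gc3s_composition("ATGGCA"),
               c(A = 0.5, C = 0, G = 0.5, T = 0))
  expect_equal(gc3s_composition("AAAAAA"), c(A = 1, C = 0, G = 0, T = 0))
  # length-7 input behaves as its first 6 bases
  expect_equal(gc3s_composition("ATGGCAT"), gc3s_composition("ATGGCA"))
  expect_error(gc3s_composition("AT"), "no complete codon")
  for (s in 1:5) {
    seq <- random_dna(200, seed = s)
    expect_equal(gc3s_composition(seq), oracle_gc3s(seq), tolerance = 1e-12)
  }
})

toy_reference <- function(w_values) {
  ref <- data.frame(codon = names(Biostrings::GENETIC_CODE),
                    aa = unname(Biostrings::GENETIC_CODE),
                    w = 1, optimal = FALSE, stringsAsFactors = FALSE)
  ref$w[ref$aa == "*"] <- NA
  for (cod in names(w_values)) ref$w[ref$codon == cod] <- w_values[cod]
  for (aa in unique(ref$aa[ref$aa != "*"])) {
    i <- which(ref$aa == aa)
    if (length(i) > 1) ref$optimal[i] <- ref$w[i] == max(ref$w[i])
  }
  class(ref) <- c("codon_reference", "data.frame")
  ref
}

test_that("codon usage indices: identity reference, hand CAI, optimal codons", {
  ref1 <- toy_reference(c())          # w = 1 everywhere
  ci <- codon_usage_indices("GCAGCGTTT", ref1)
  expect_equal(unname(ci["cai"]), 1)  # identity reference
  expect_equal(unname(ci["fop"]), 1)  # every codon optimal

  ref2 <- toy_reference(c(GCG = 0.5))
  ci2 <- codon_usage_indices("GCAGCG", ref2)
  expect_equal(unname(ci2["cai"]), sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(ci2["fop"]), 0.5)  # GCA optimal, GCG not
  expect_error(codon_usage_indices("GCA", NULL), "reference")
  expect_error(codon_usage_indices("NNNNNN", ref1), "zero countable")
})

test_that("codon reference builder: w in (0,1], argmax optimal, round-trip", {
  set.seed(5)
  seqs <- dna_set(sprintf("c%d", 1:30),
                  replicate(30, paste(sample(c("GCA", "GCG", "AAA", "TTT"),
                                             40, replace = TRUE,
                                             prob = c(.5, .1, .2, .2)),
                                      collapse = "")))
  ref <- suppressMessages(codon_reference_from_sequences(seqs))
  w <- ref$w[!is.na(ref$w)]
  expect_true(all(w > 0 & w <= 1))
  expect_true(ref$optimal[ref$codon == "GCA"])   # argmax of Ala family
  expect_false(ref$optimal[ref$codon == "GCG"])
  expect_false(any(ref$optimal[ref$aa %in% c("M", "W", "*")]))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_codon_reference(ref, f)
  ref2 <- read_codon_reference(f)
  expect_equal(ref2$w, ref$w, tolerance = 1e-12)
  expect_identical(ref2$optimal, ref$optimal)
})

test_that("protein properties: aromaticity extremes and table lookup", {
  expect_equal(unname(protein_properties(strrep("TTT", 10))["aromaticity"]),
               1)   # poly-Phe
  expect_equal(unname(protein_properties(strrep("GGT", 10))["aromaticity"]),
               0)   # poly-Gly
  expect_equal(unname(protein_properties(strrep("TTT", 5))["hydrophobicity"]),
               unname(kyte_doolittle()["F"]))
  expect_error(protein_properties("TAATAA"), "zero residues")
})

test_that("rho statistic: hand count, zero convention, iid calibration", {
  expect_equal(unname(rho_statistic("ACAC")["AC"]), (2 / 3) / 0.25,
               tolerance = 1e-12)
  no_c <- rho_statistic("AGTAGTAGT")
  expect_true(all(no_c[grepl("C", names(no_c))] == 0))
  # long iid uniform sequences: all entries near 1
  for (s in 1:20) {
    r <- rho_statistic(random_dna(10000, seed = 100 + s))
    expect_true(all(abs(r - 1) < 0.15))
  }
})

test_that("dinucleotide property profile: constants, single window, oracle", {
  tab <- read_dinuc_properties()
  expect_equal(dim(tab), c(16L, 65L))
  const <- matrix(3.5, 16, 2, dimnames = list(rownames(tab), c("c1", "c2")))
  expect_equal(unname(dinucleotide_property_profile("ACGTACGT", const)),
               c(3.5, 3.5))
  expect_equal(unname(dinucleotide_property_profile("AA", tab)),
               unname(tab["AA", ]))
  incomplete <- tab[-3, ]
  expect_error(dinucleotide_property_profile("ACGT", incomplete), "missing")
  for (s in 1:5) {
    seq <- random_dna(250, p_ambiguous = 0.03, seed = s)
    expect_equal(unname(dinucleotide_property_profile(seq, tab)),
                 oracle_dinuc_profile(seq, tab), tolerance = 1e-12)
  }
})

test_that("build_feature_matrix: widths, order, determinism, TSV round-trip", {
  seqs <- generate_sequence_dataset(8, 8, c(60, 150), seed = 3)
  ref <- codon_reference_from_sequences(seqs[which(seqs$label == 1)])
  cfg <- feature_config(codon_reference = ref)
  fm <- build_feature_matrix(seqs, cfg)
  expect_equal(dim(fm), c(16L, 426L))
  expect_equal(attr(fm, "block_widths"),
               c(zcurve = 252L, kmer = 84L, gc_cai = 3L, gc3s = 4L,
                 aa_props = 2L, rho = 16L, dinuc_props = 65L))
  expect_true(all(is.finite(fm)))
  # column order is a pure function of the config; rerun is bit-identical
  fm2 <- build_feature_matrix(seqs, cfg)
  expect_identical(colnames(fm), colnames(fm2))
  expect_identical(unclass(fm)[, ], unclass(fm2)[, ])
  # kmer-only config has width 84
  fk <- build_feature_matrix(seqs, feature_config("kmer"))
  expect_equal(ncol(fk), 84L)
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back, unclass(fm)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(rownames(back), seqs$id)
  # failures name the sequence and the block
  bad <- dna_set(c("ok", "tiny"), c(strrep("ACG", 30), "AC"))
  expect_error(build_feature_matrix(bad, feature_config("gc3s")),
               "gc3s.*tiny")
  expect_error(build_feature_matrix(bad[integer(0)], cfg), "empty")
})

test_that("gc_cai block requires a codon reference", {
  expect_error(feature_config("gc_cai"), "codon reference")
})
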