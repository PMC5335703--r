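test_that("FASTA IO round-trips and disambiguates duplicate ids", {
  recs <- tibble::tibble(id = c("a", "b"), seq = c("MKLV", "ACDEFG"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  expect_equal(read_fasta(path), recs)
  # empty file reads as an empty set
  writeLines(character(), path)
  expect_equal(nrow(read_fasta(path)), 0)
  # duplicate ids get suffixes, with a warning
  writeLines(c(">x", "MKL", ">x", "MKV"), path)
  expect_warning(dup <- read_fasta(path), "duplicate")
  expect_equal(anyDuplicated(dup$id), 0L)
})

test_that("self-alignment is the identity with an identity position map", {
  ref <- acr_reference()
  aln <- global_align(ref, ref)
  expect_equal(aln$map, seq_len(nchar(ref)))
  expect_equal(aln$aligned_query, ref)
  rep <- residue_at_reference_position(ref, 90)
  expect_equal(rep$residue, "E")
  expect_equal(rep$query_index, 90L)
})

test_that("alignment score equals the exhaustive affine-gap optimum on toys", {
  set.seed(11)
  for (k in 1:8) {
    nq <- sample(3:6, 1); nr <- sample(3:6, 1)
    q <- random_protein(nq); r <- random_protein(nr)
    expect_equal(global_align(q, r)$score,
                 align_score_exhaustive(q, r, blosum62),
                 info = paste(q, r))
  }
  # one longer pair at the stated toy bound
  q <- random_protein(8); r <- random_protein(8)
  expect_equal(global_align(q, r)$score,
               align_score_exhaustive(q, r, blosum62))
})

test_that("a single substitution changes the score by the matrix difference", {
  set.seed(3)
  r <- random_protein(30)
  chars <- strsplit(r, "")[[1]]
  old <- chars[12]
  chars[12] <- if (old == "W") "F" else "W"
  q <- paste(chars, collapse = "")
  expect_equal(global_align(q, r)$score - global_align(r, r)$score,
               blosum62[chars[12], old] - blosum62[old, old])
})

test_that("non-amino-acid characters are an input error", {
  expect_error(global_align("MKX1", acr_reference()), "non-amino-acid")
  expect_error(global_align("", acr_reference()), "nonempty")
})

test_that("fixture homologs report the documented native indices", {
  fx <- acr_fixture_sequences()
  gt <- fx$seq[fx$id == "GtACR1_like"]
  rep <- residue_at_reference_position(gt, c(83, 90, 97, 101))
  # the 90-position glutamate sits at native position 68; the helix-2
  # alanines at 61 and 75; the 101-position homolog at 79
  expect_equal(rep$residue, c("A", "E", "A", "N"))
  expect_equal(rep$query_index, c(61L, 68L, 75L, 79L))
})

test_that("the reference fingerprint carries the canonical residues", {
  fp <- extract_fingerprint(acr_reference())
  expect_equal(fp$residue,
               c("E", "E", "E", "E", "E", "Q", "E", "C", "V"))
  expect_equal(fp$query_index, FINGERPRINT_POSITIONS)
  expect_equal(classify_selectivity(fp)$label, "CCR-like")
})

test_that("the ZipACR-like fixture reports Glu96/Asn108/Gly114", {
  zp <- acr_fixture_sequences()$seq[2]
  fp <- extract_fingerprint(zp)
  sel <- fp[fp$ref_pos %in% c(101, 117, 123), ]
  expect_equal(sel$residue, c("E", "N", "G"))
  expect_equal(sel$query_index, c(96L, 108L, 114L))
  expect_equal(classify_selectivity(fp)$label, "natural-ACR-like")
})

test_that("classification separates natural, engineered and cation channels", {
  gt <- acr_fixture_sequences()$seq[1]
  expect_equal(classify_selectivity(extract_fingerprint(gt))$label,
               "natural-ACR-like")
  # lysine at the 90-position marks the engineered anion mutants
  ek <- apply_mutations(gt, "E68K")
  cl <- classify_selectivity(extract_fingerprint(ek))
  expect_equal(cl$label, "engineered-anion-like")
  expect_match(cl$caveat, "helix-2")
})

test_that("partial sequences are rejected from fingerprinting", {
  half <- substr(acr_reference(), 1, 150)
  expect_error(extract_fingerprint(half), "partial")
})

test_that("mutations validate the wild type, apply, and revert", {
  fx <- acr_fixture_sequences()
  gt <- fx$seq[fx$id == "GtACR1_like"]
  mut <- apply_mutations(gt, "A61E,A75E,N79E")
  expect_equal(substr(mut, 61, 61), "E")
  expect_equal(substr(mut, 75, 75), "E")
  expect_equal(substr(mut, 79, 79), "E")
  expect_identical(apply_mutations(mut, "E61A,E75A,E79N"), gt)
  zp <- fx$seq[fx$id == "ZipACR_like"]
  expect_silent(apply_mutations(zp, "E96N,N108P,G114S"))
  expect_error(apply_mutations(gt, "W61E"), "wild-type mismatch")
  # reference numbering translates through the alignment: the
  # 90-position of the GtACR1-like fixture is native 68
  expect_identical(apply_mutations(gt, "E90Q", numbering = "reference"),
                   apply_mutations(gt, "E68Q"))
})

test_that("synthetic families honour divergence, pinning and seeding", {
  ref <- acr_reference()
  # zero divergence returns exact copies with the pinned fingerprint
  fam0 <- generate_synthetic_family(ref, 0, n = 3, seed = 2,
                                    fingerprint = c("90" = "E",
                                                    "123" = "A"))
  expect_equal(length(unique(fam0$seq)), 1)
  expect_equal(substr(fam0$seq[1], 123, 123), "A")
  # realized substitution fraction is binomial around the divergence
  fam <- generate_synthetic_family(ref, 0.2, n = 20, seed = 5)
  frac <- vapply(fam$seq, function(s) {
    mean(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1))
  sd3 <- 3 * sqrt(0.2 * 0.8 / nchar(ref))
  expect_lt(abs(mean(frac) - 0.2), sd3)
  # same seed, same output; pins survive mutation
  expect_identical(fam, generate_synthetic_family(ref, 0.2, n = 20,
                                                  seed = 5))
  expect_error(generate_synthetic_family("MKLV", 0.1, n = 1,
                                         fingerprint = c("242" = "E")),
               "unaligned|outside")
})

test_that("fingerprints of generated families equal their pinned spec", {
  spec <- c("90" = "E", "97" = "A", "101" = "N", "117" = "N",
            "123" = "S", "242" = "E")
  fam <- generate_synthetic_family(acr_reference(), 0.1, n = 4, seed = 8,
                                   fingerprint = spec)
  for (s in fam$seq) {
    fp <- extract_fingerprint(s)
    got <- fp$residue[match(as.integer(names(spec)), fp$ref_pos)]
    expect_equal(got, unname(spec))
    expect_equal(classify_selectivity(fp)$label, "natural-ACR-like")
  }
})
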