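ident_hit <- function(q, s, qstart = 1) {
  data.frame(qstart = qstart, qend = qstart + nchar(q) - 1,
             aligned_q = q, aligned_s = s, stringsAsFactors = FALSE)
}

test_that("map_element walks alignment columns correctly", {
  # identity alignment returns the element slice unchanged
  h <- ident_hit("AATATAATCC", "AATATAATCC")
  expect_equal(map_element(h, c(3, 8)), "TATAAT")
  # substitution at element position 3
  h2 <- ident_hit("AATATAATCC", "AATACAATCC")
  obs <- map_element(h2, c(3, 8))
  expect_equal(obs, "TACAAT")
  expect_false(obs == "TATAAT")
  # query gap inside the element -> observed longer
  h3 <- ident_hit("AATAT-AATCC", "AATATGAATCC")
  expect_equal(map_element(h3, c(3, 8)), "TATGAAT")
  # subject gap inside the element -> observed shorter
  h4 <- ident_hit("AATATAATCC", "AATA--ATCC")
  expect_equal(map_element(h4, c(3, 8)), "TAAT")
  # interval outside the hit -> NULL
  expect_null(map_element(ident_hit("ACGT", "ACGT", qstart = 10), c(1, 6)))
  # offset hits map through qstart
  h5 <- ident_hit("TATAAT", "TATGAT", qstart = 101)
  expect_equal(map_element(h5, c(103, 105)), "TGA")
})

test_that("element_identity counts and ranks variants", {
  obs <- c("TTGTAA", "TTGTAA", "TTGTAA", "TTGTAC")
  ei <- element_identity(obs, "TTGTAA")
  expect_equal(ei$fraction_identical, 0.75)
  expect_equal(ei$variants$variant[1], "TTGTAA")
  expect_equal(ei$variants$frequency, c(0.75, 0.25))
  # all identical
  expect_equal(element_identity(rep("AAA", 5), "AAA")$fraction_identical, 1)
  # 2:1 mixture mirrors the two-variant promoter case
  ei2 <- element_identity(c("A", "A", "C"), "A")
  expect_equal(ei2$variants$frequency, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # ties broken lexicographically
  ei3 <- element_identity(c("B", "A"), "A")
  expect_equal(ei3$variants$variant, c("A", "B"))
  expect_error(element_identity(character(), "A"), "no observations")
})

test_that("build_consensus information content closed forms", {
  # single sequence: every column 2 bits
  cm <- build_consensus("ACGT")
  expect_equal(cm$bits, rep(2, 4))
  expect_equal(cm$consensus, "ACGT")
  # equal ACGT column: 0 bits
  cm2 <- build_consensus(c("A", "C", "G", "T"))
  expect_equal(cm2$bits, 0)
  expect_equal(cm2$consensus, "N")  # four-way tie -> IUPAC N
  # 80/20 column: 2 - H(0.8, 0.2)
  cm3 <- build_consensus(c(rep("A", 8), rep("C", 2)))
  expect_equal(cm3$bits, 2 - (-0.8 * log2(0.8) - 0.2 * log2(0.2)),
               tolerance = 1e-12)
  expect_equal(cm3$consensus, "A")
  # two-way tie -> IUPAC code
  expect_equal(build_consensus(c("A", "G"))$consensus, "R")
  # bounds hold on random alignments
  set.seed(1)
  seqs <- vapply(1:30, function(i) generate_background(25, 0.5, i),
                 character(1))
  cm4 <- build_consensus(seqs)
  expect_true(all(cm4$bits >= 0 & cm4$bits <= 2))
  expect_true(all(rowSums(cm4$counts) == 30))
  # gap-majority columns are masked
  cm5 <- build_consensus(c("A-", "A-", "AC"))
  expect_true(is.na(cm5$bits[2]))
  expect_equal(substr(cm5$consensus, 2, 2), "-")
  expect_error(build_consensus(c("AC", "A")), "length mismatch")
  # protein alphabet: single sequence column = log2(21)
  cmp <- build_consensus("MK", alphabet = "protein")
  expect_equal(cmp$bits, rep(log2(21), 2))
})

test_that("translate_orf matches the Biostrings translation oracle", {
  expect_equal(translate_orf("ATG")$protein, "M")
  # 90-nt ORF (29 codons + stop) -> 29-aa protein
  tpl <- example_template()
  orf <- substr(tpl$sequence, 401, 490)
  tr <- translate_orf(orf)
  expect_equal(nchar(tr$protein), 29)
  expect_false(tr$truncated)
  for (i in 1:10) {
    dna <- generate_background(60, 0.5, i + 50)
    mine <- translate_orf(dna)
    ref <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                              no.init.codon = TRUE))
    ref_protein <- sub("\\*.*$", "", ref)
    expect_equal(mine$protein, ref_protein)
    expect_equal(mine$truncated,
                 grepl("\\*", substr(ref, 1, nchar(ref) - 1)))
  }
  # partial codon flagged, N codons become X, junk rejected
  expect_true(translate_orf("ATGA")$partial_codon)
  expect_equal(translate_orf("ATGANT")$protein, "MX")
  expect_error(translate_orf("ATG!"), "non-DNA")
})

test_that("protein_variants labels substitutions relative to the reference", {
  ref <- "MNAKLV"
  pv <- protein_variants(c(ref, "MSAKLV", "MSAKLV", "MNAKLI"), ref)
  expect_setequal(pv$label, c("reference", "N2S", "V6I"))
  expect_equal(pv$frequency[pv$label == "N2S"], 0.5)
  expect_equal(pv$frequency[pv$label == "reference"], 0.25)
  # all identical
  pv2 <- protein_variants(rep(ref, 3), ref)
  expect_equal(pv2$label, "reference")
  expect_equal(pv2$frequency, 1)
  # multiple substitutions joined
  pv3 <- protein_variants("MSTKLV", ref)
  expect_equal(pv3$label, "N2S+A3T")
  expect_error(protein_variants("MK", ref), "length")
})

test_that("planted variant frequencies are recovered exactly", {
  tpl <- example_template()
  orf_iv <- c(401, 490)
  ref <- translate_orf(substr(tpl$sequence, orf_iv[1], orf_iv[2]))$protein
  # plant a serine codon at ORF position 2 (an N2S-style change)
  edit <- data.frame(pos = 404:406, base = c("A", "G", "C"))
  ref_aa2 <- substr(ref, 2, 2)
  stopifnot(ref_aa2 != "S")
  n_var <- 29
  n_ref <- 71
  prots <- character()
  bg <- generate_background(2000, 0.5, 1)
  for (i in seq_len(n_var + n_ref)) {
    spec <- if (i <= n_var) plant_spec("full", variant_edits = edit) else
      plant_spec("full")
    pl <- plant_locus(bg, tpl, spec, 300, seed = i)
    frag <- substr(pl$sequence, pl$truth$start, pl$truth$end)
    if (pl$truth$strand == "-") frag <- revcomp(frag)
    prots <- c(prots, translate_orf(substr(frag, orf_iv[1],
                                           orf_iv[2]))$protein)
  }
  pv <- protein_variants(prots, ref)
  expect_equal(sum(pv$frequency), 1)
  expect_equal(pv$count[pv$label == "reference"], n_ref)
  other <- pv[pv$label != "reference", ]
  expect_equal(nrow(other), 1)
  expect_equal(other$count, n_var)
  expect_equal(other$label, paste0(ref_aa2, "2S"))  # position-2 X -> S
})

test_that("conservation calibration: identity ~ (1-r)^len without protection", {
  # r = 0.02 on a 6-nt element over 500 loci
  r <- 0.02
  el <- "TATAAT"
  n <- 500
  obs <- vapply(seq_len(n), function(i)
    tascan:::mutate_sequence(el, r, seed = i), character(1))
  frac <- mean(obs == el)
  p <- (1 - r)^6
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("element_conservation over screened full loci", {
  tpl <- example_template()
  pg <- simulate_pangenome(8, mix = data.frame(
    label = "one_full", full = 1L, interrupted = 0L, antitoxin_only = 0L,
    toxin_only = 0L, on_plasmid = FALSE, prob = 1),
    seed = 77, mutation_rate = 0.03)
  scr <- screen_assemblies(pg$assemblies, tpl)
  fc <- scr$calls[scr$calls$category == "full", ]
  ec <- element_conservation(fc, tpl)
  expect_equal(nrow(ec), nrow(tpl$elements))
  # protected elements are perfectly conserved despite background noise
  expect_true(all(ec$fraction_identical == 1))
  expect_true(all(ec$n == nrow(fc)))
})
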