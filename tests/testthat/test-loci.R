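# The locus-calling layer, exercised on constructed hits and on synthetic
# pan-genomes (round trips through the aligner).

TPL_NAME <- example_template()$name

make_hit <- function(qstart, qend, sstart, send, strand = "+", bit = 100,
                     qid = TPL_NAME, sid = "s") {
  data.frame(qseqid = qid, sseqid = sid, strand = strand,
             pident = 100, length = qend - qstart + 1, mismatch = 0L,
             gapopen = 0L, qstart = qstart, qend = qend, sstart = sstart,
             send = send, evalue = 1e-10, bitscore = bit,
             raw = 2L * (qend - qstart + 1L), qcovs = NA_real_,
             aligned_q = "", aligned_s = "", stringsAsFactors = FALSE)
}

test_that("cluster_hits: one full hit yields one single-segment profile", {
  h <- make_hit(1, 520, 1000, 1519)
  pr <- cluster_hits(h)
  expect_length(pr, 1)
  expect_equal(nrow(pr[[1]]$segments), 1)
  expect_true(pr[[1]]$collinear)
})

test_that("cluster_hits: a 1200-nt subject insertion gives two collinear segments", {
  h <- rbind(make_hit(1, 260, 1000, 1259), make_hit(261, 520, 2460, 2719))
  pr <- cluster_hits(h)
  expect_length(pr, 1)
  expect_equal(nrow(pr[[1]]$segments), 2)
  expect_true(pr[[1]]$collinear)
  expect_gte(pr[[1]]$max_gap_in_subject, 1200)
})

test_that("cluster_hits: loci 50 kb apart form distinct profiles", {
  h <- rbind(make_hit(1, 520, 1000, 1519), make_hit(1, 520, 51000, 51519))
  expect_length(cluster_hits(h), 2)
})

test_that("cluster_hits: word-size chance matches cluster separately", {
  h <- rbind(make_hit(1, 520, 1000, 1519), make_hit(200, 210, 2600, 2610))
  pr <- cluster_hits(h)
  expect_length(pr, 2)
  spans <- vapply(pr, function(p) diff(p$cluster), numeric(1))
  expect_true(any(spans > 400) && any(spans < 50))
})

test_that("filter_spurious removes short 3'-terminator matches, keeps loci", {
  tpl <- example_template()
  # 25-nt match confined to the query 3' end, mirroring short istR hits
  short <- cluster_hits(make_hit(492, 516, 5000, 5024))
  expect_length(filter_spurious(short, tpl), 0)
  full <- cluster_hits(make_hit(1, 520, 1000, 1519))
  expect_length(filter_spurious(full, tpl), 1)
  # a 25-nt match elsewhere in the query is not blacklisted
  other <- cluster_hits(make_hit(50, 74, 5000, 5024))
  expect_length(filter_spurious(other, tpl), 1)
})

test_that("filter_spurious drops opposite-strand matches inside a counted cluster", {
  tpl <- example_template()
  pr <- cluster_hits(rbind(
    make_hit(1, 520, 1000, 1519, strand = "-", bit = 900),
    make_hit(275, 310, 1200, 1235, strand = "+", bit = 60)))
  kept <- filter_spurious(pr, tpl)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$strand, "-")
})

test_that("classify_locus on constructed profiles", {
  tpl <- example_template()
  # noise-free full plant
  full <- filter_spurious(cluster_hits(make_hit(1, 520, 1000, 1519)), tpl)
  call <- classify_locus(full[[1]], tpl)
  expect_equal(call$category, "full")
  expect_equal(call$copy_units, 1)
  # antitoxin segment + 28-nt UTR stub -> antitoxin_only, 0.5 copies
  anti <- cluster_hits(rbind(make_hit(1, 160, 1000, 1159, bit = 290),
                             make_hit(221, 248, 1160, 1187, bit = 50)))
  call <- classify_locus(anti[[1]], tpl)
  expect_equal(call$category, "antitoxin_only")
  expect_equal(call$copy_units, 0.5)
  # interrupted: split coverage with a large subject gap
  intr <- cluster_hits(rbind(make_hit(1, 260, 1000, 1259),
                             make_hit(261, 520, 2460, 2719)))
  expect_equal(classify_locus(intr[[1]], tpl)$category, "interrupted")
  # a fragment matching the UTR only is partial (0 copy units)
  part <- cluster_hits(make_hit(230, 340, 1000, 1110))
  call <- classify_locus(part[[1]], tpl)
  expect_equal(call$category, "partial")
  expect_equal(call$copy_units, 0)
  # toxin transcript alone
  tox <- cluster_hits(make_hit(221, 490, 1000, 1269))
  expect_equal(classify_locus(tox[[1]], tpl)$category, "toxin_only")
  # mismatched query errors
  expect_error(classify_locus(structure(list(query_id = "other"),
                                        class = "coverage_profile"), tpl),
               "mismatch")
})

test_that("assign_locus_type applies the bit-score cutoffs", {
  tpl <- example_template()
  full <- classify_locus(
    filter_spurious(cluster_hits(make_hit(1, 520, 1000, 1519)), tpl)[[1]],
    tpl)
  # full locus above 650 takes the winning query's type
  expect_equal(assign_locus_type(full, c(O = 700, P = 300))$locus_type, "O")
  expect_equal(assign_locus_type(full, c(O = 700, P = 920))$locus_type, "P")
  # ties broken by the fixed precedence O > P
  expect_equal(assign_locus_type(full, c(O = 700, P = 700))$locus_type, "O")
  expect_equal(assign_locus_type(full, c(O = 600, P = 640))$locus_type,
               "unassigned")
  anti <- classify_locus(cluster_hits(
    rbind(make_hit(1, 160, 1000, 1159), make_hit(221, 248, 1160, 1187)))[[1]],
    tpl)
  # O cutoff 280 checked first, then P at 250
  expect_equal(assign_locus_type(anti, c(O = 290, P = 290))$locus_type, "O")
  expect_equal(assign_locus_type(anti, c(O = 260, P = 260))$locus_type, "P")
  expect_equal(assign_locus_type(anti, c(O = 260, P = 240))$locus_type,
               "unassigned")
})

test_that("detect_plasmid string rule", {
  expect_true(detect_plasmid("Escherichia coli plasmid p11A_p2, complete"))
  expect_true(detect_plasmid("an EXTRACHROMOSOMAL element"))
  expect_false(detect_plasmid("chromosome, complete genome"))
})

test_that("set_categorize reproduces the set-difference rule", {
  res <- set_categorize(full_ids = c("a", "b", "c", "d"),
                        toxin_ids = c("a", "b"),
                        antitoxin_ids = c("a", "c"),
                        all_ids = c("a", "b", "c", "d", "e", "x"))
  cat_of <- function(id) res$category[res$assembly_id == id]
  expect_equal(cat_of("a"), "paired")
  expect_equal(cat_of("b"), "toxin_only")
  expect_equal(cat_of("c"), "antitoxin_only")
  expect_equal(cat_of("e"), "absent")
  # single-gene hit without a full-query hit is an anomaly
  res2 <- set_categorize("a", "a", c("a", "z"))
  expect_true(res2$anomaly[res2$assembly_id == "z"])
})

test_that("dedupe_assemblies keeps one representative per copy vector", {
  rep <- data.frame(
    assembly_id = c("A1", "A2", "A3"),
    strain_name = "DH5alpha",
    copy_number = c(0.5, 0.5, 2), stringsAsFactors = FALSE)
  dd <- dedupe_assemblies(rep)
  expect_equal(nrow(dd$kept), 2)
  expect_setequal(dd$kept$copy_number, c(0.5, 2))
  expect_equal(dd$removed$assembly_id, "A2")
  # five same-name identical reports -> keep 1
  rep5 <- data.frame(assembly_id = paste0("B", 1:5), strain_name = "K12",
                     copy_number = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_assemblies(rep5)$kept), 1)
  # unique names untouched; unknown names never deduped
  repu <- data.frame(assembly_id = c("C1", "C2", "C3", "C4"),
                     strain_name = c("s1", "s2", NA, NA),
                     copy_number = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_assemblies(repu)$kept), 4)
  # idempotence
  dd2 <- dedupe_assemblies(dd$kept)
  expect_identical(dd2$kept, dd$kept)
})

test_that("round trip: noise-free recovery and set/classify consistency", {
  tpl <- example_template()
  mix <- data.frame(
    label = c("one_full", "two_full", "orz_only", "absent"),
    full = c(1L, 2L, 0L, 0L), interrupted = 0L,
    antitoxin_only = c(0L, 0L, 1L, 0L), toxin_only = 0L,
    on_plasmid = FALSE, prob = c(0.4, 0.2, 0.3, 0.1))
  pg <- simulate_pangenome(15, mix = mix, seed = 31)
  scr <- screen_assemblies(pg$assemblies, tpl)
  m <- merge(truth_copy_number(pg), scr$reports, by = "assembly_id")
  expect_equal(m$copy_number.y, m$copy_number.x)
  # copy-unit conservation
  for (aid in unique(scr$calls$assembly_id))
    expect_equal(sum(scr$calls$copy_units[scr$calls$assembly_id == aid]),
                 scr$reports$copy_number[scr$reports$assembly_id == aid])
  # set-logic categorization agrees with per-locus classification
  anti_q <- stats::setNames(substr(tpl$sequence, tpl$antitoxin_segment[1],
                                   tpl$antitoxin_segment[2]), "anti")
  tox_q <- stats::setNames(substr(tpl$sequence, tpl$toxin_segment[1],
                                  tpl$toxin_segment[2]), "tox")
  full_q <- stats::setNames(tpl$sequence, "full")
  ids_hit <- function(query) {
    hit <- vapply(names(pg$assemblies), function(aid) {
      h <- seed_extend_search(query, pg$assemblies[[aid]]$replicons,
                              scoring_scheme())
      any(h$length >= 60)  # substantial hits only, as in manual curation
    }, logical(1))
    names(hit)[hit]
  }
  sc <- set_categorize(ids_hit(full_q), ids_hit(tox_q), ids_hit(anti_q),
                       all_ids = names(pg$assemblies))
  truth_cat <- vapply(names(pg$assemblies), function(aid) {
    cats <- pg$truth$category[pg$truth$assembly_id == aid]
    if (length(cats) == 0) "absent"
    else if (all(cats == "antitoxin_only")) "antitoxin_only"
    else if (all(cats == "toxin_only")) "toxin_only"
    else "paired"
  }, character(1))
  expect_equal(sc$category[match(names(truth_cat), sc$assembly_id)],
               unname(truth_cat))
  expect_false(any(sc$anomaly))
})
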