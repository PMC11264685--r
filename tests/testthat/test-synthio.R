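test_that("generate_background is deterministic and validates inputs", {
  x <- generate_background(1000, 0.5, 7)
  expect_equal(nchar(x), 1000)
  expect_identical(x, generate_background(1000, 0.5, 7))
  expect_false(identical(x, generate_background(1000, 0.5, 8)))
  expect_error(generate_background(0, 0.5, 1), "positive")
  expect_error(generate_background(10, 1.2, 1), "gc")
  # near-degenerate GC
  y <- generate_background(200, 0.999, 1)
  expect_gt(mean(strsplit(y, "")[[1]] %in% c("G", "C")), 0.97)
})

test_that("background GC is within 3 binomial SD of its target", {
  n <- 100000
  x <- generate_background(n, 0.5, 1)
  gc <- sum(strsplit(x, "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(n * 0.25)
  expect_lt(abs(gc - n * 0.5), sd3)
})

test_that("locus_template validates intervals and records references", {
  tpl <- example_template()
  expect_equal(tpl$elements$ref,
               substring(tpl$sequence, tpl$elements$start,
                         tpl$elements$end))
  expect_error(locus_template("x", "ACGT", data.frame(
    name = "e", start = 1, end = 9), c(1, 2), c(3, 4), c(1, 2)),
    "out of bounds")
  expect_error(locus_template("x", "ACGTACGT",
                              data.frame(name = character(),
                                         start = integer(), end = integer()),
                              c(1, 4), c(3, 6), c(1, 2)), "overlap")
})

test_that("plant_locus: noise-free full plant reproduces the template", {
  tpl <- example_template()
  bg <- generate_background(3000, 0.5, 3)
  pl <- plant_locus(bg, tpl, plant_spec("full"), 500, seed = 4)
  frag <- substr(pl$sequence, pl$truth$start, pl$truth$end)
  if (pl$truth$strand == "-") frag <- revcomp(frag)
  expect_identical(frag, tpl$sequence)
  expect_equal(pl$truth$end - pl$truth$start + 1, nchar(tpl$sequence))
})

test_that("plant_locus category geometries", {
  tpl <- example_template()
  bg <- generate_background(5000, 0.5, 3)
  # antitoxin-only: antitoxin gene plus a 28-nt UTR stub
  pl <- plant_locus(bg, tpl, plant_spec("antitoxin_only"), 500, seed = 9)
  expect_equal(pl$truth$end - pl$truth$start + 1,
               (tpl$antitoxin_segment[2] - tpl$antitoxin_segment[1] + 1) + 28)
  # the stub range matches the observed 27-29 nt remnant
  for (stub in c(27L, 29L)) {
    p2 <- plant_locus(bg, tpl, plant_spec("antitoxin_only",
                                          utr_stub = stub), 500, seed = 9)
    expect_equal(p2$truth$end - p2$truth$start + 1, 160 + stub)
  }
  # interrupted: template length plus the spacer
  p3 <- plant_locus(bg, tpl, plant_spec("interrupted"), 500, seed = 9)
  expect_equal(p3$truth$end - p3$truth$start + 1, 520 + 1200)
  # toxin-only: the toxin transcript alone
  p4 <- plant_locus(bg, tpl, plant_spec("toxin_only"), 500, seed = 9)
  expect_equal(p4$truth$end - p4$truth$start + 1,
               tpl$toxin_segment[2] - tpl$toxin_segment[1] + 1)
  expect_error(plant_locus(bg, tpl, plant_spec("full"), 4900, seed = 1),
               "fit")
})

test_that("plant_spec validation", {
  expect_error(plant_spec("absent", copies = 1), "absent")
  expect_error(plant_spec("full", copies = 0.3), "multiple of 0.5")
  expect_error(plant_spec("full", mutation_rate = 0.5), "mutation_rate")
  expect_equal(plant_spec("antitoxin_only")$copies, 0.5)
})

test_that("mutation noise never falls inside protected elements", {
  tpl <- example_template()
  bg <- generate_background(3000, 0.5, 3)
  for (seed in 1:5) {
    pl <- plant_locus(bg, tpl, plant_spec("full", mutation_rate = 0.2),
                      500, seed = seed)
    frag <- substr(pl$sequence, pl$truth$start, pl$truth$end)
    if (pl$truth$strand == "-") frag <- revcomp(frag)
    for (k in seq_len(nrow(tpl$elements)))
      expect_identical(substr(frag, tpl$elements$start[k],
                              tpl$elements$end[k]), tpl$elements$ref[k])
    expect_false(identical(frag, tpl$sequence))  # noise did land elsewhere
  }
})

test_that("simulate_pangenome: determinism, mix accounting, metadata", {
  mix <- default_mix()
  pg <- simulate_pangenome(15, mix = mix, seed = 5)
  pg2 <- simulate_pangenome(15, mix = mix, seed = 5)
  expect_identical(pg$truth, pg2$truth)
  expect_identical(pg$metadata, pg2$metadata)
  expect_identical(
    pg$assemblies[["ASM0001"]]$replicons,
    pg2$assemblies[["ASM0001"]]$replicons)
  expect_equal(nrow(pg$metadata), 15)
  expect_true(all(pg$metadata$pathotype %in% metadata_model()$pathotypes))
  # category vocabulary includes the pathotype groups used downstream
  expect_true(all(c("healthy", "intestinal disease") %in%
                    metadata_model()$pathotypes))
  # single-assembly, single-category sanity
  one <- simulate_pangenome(1, mix = data.frame(
    label = "one_full", full = 1L, interrupted = 0L, antitoxin_only = 0L,
    toxin_only = 0L, on_plasmid = FALSE, prob = 1), seed = 2)
  expect_equal(nrow(one$truth), 1)
  expect_equal(one$truth$category, "full")
})

test_that("pangenome write/read round trip is byte-stable", {
  dir <- withr::local_tempdir()
  pg <- simulate_pangenome(4, seed = 8)
  write_pangenome(pg, dir)
  f <- list.files(file.path(dir, "genomes"), full.names = TRUE)
  expect_equal(length(f), 4)
  bytes1 <- lapply(f, readBin, what = "raw", n = 1e6)
  write_pangenome(simulate_pangenome(4, seed = 8), dir)
  bytes2 <- lapply(f, readBin, what = "raw", n = 1e6)
  expect_identical(bytes1, bytes2)
  back <- read_genomes(dir)
  expect_equal(sort(names(back)), sort(names(pg$assemblies)))
  a <- back[["ASM0001"]]
  expect_identical(unname(a$replicons),
                   unname(pg$assemblies[["ASM0001"]]$replicons))
  # plasmid records carry the word "plasmid" in their description
  pl <- grep("_p\\d$", names(a$descriptions))
  if (length(pl))
    expect_true(all(grepl("plasmid", a$descriptions[pl])))
  expect_error(read_genomes(withr::local_tempdir()), "no FASTA")
})

test_that("truth copy accounting matches the planted categories", {
  pg <- simulate_pangenome(30, seed = 13)
  tc <- truth_copy_number(pg)
  units <- c(full = 1, interrupted = 1, antitoxin_only = 0.5,
             toxin_only = 0.5)
  for (aid in tc$assembly_id) {
    rows <- pg$truth[pg$truth$assembly_id == aid, ]
    expect_equal(tc$copy_number[tc$assembly_id == aid],
                 sum(units[rows$category]))
  }
})
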