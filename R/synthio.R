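# Synthetic pan-genomes with planted type I toxin-antitoxin loci and ground
# truth, so the detection/classification pipeline is testable offline.

#' Random background DNA
#'
#' @param length number of residues (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; the same (length, gc, seed) always returns the
#'   same string.
#' @return a single DNA string over A/C/G/T.
#' @export
generate_background <- function(length, gc = 0.5, seed = 1L) {
  if (length < 1) stop("length must be positive", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  with_seed(seed, paste(
    sample(DNA_BASES, length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

#' Annotated reference locus template
#'
#' A toxin-antitoxin locus used both as the search query and as the material
#' planted into synthetic genomes. `elements` annotates regulatory features
#' (promoter hexamers, transcription-factor boxes, RBS, RSS, EAP, pairing
#' region, toxin ORF) as 1-based inclusive intervals on `sequence`; each
#' element's reference string is the corresponding sequence slice.
#'
#' @param name locus name.
#' @param sequence the locus DNA string.
#' @param elements data frame with columns `name`, `start`, `end`.
#' @param toxin_segment,antitoxin_segment,utr_segment 1-based inclusive
#'   `c(start, end)` intervals; toxin and antitoxin segments must not
#'   overlap.
#' @return an object of class `locus_template`.
#' @export
locus_template <- function(name, sequence, elements, toxin_segment,
                           antitoxin_segment, utr_segment) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  check_interval(toxin_segment, len, "toxin_segment")
  check_interval(antitoxin_segment, len, "antitoxin_segment")
  check_interval(utr_segment, len, "utr_segment")
  if (max(toxin_segment[1], antitoxin_segment[1]) <=
      min(toxin_segment[2], antitoxin_segment[2]))
    stop("toxin and antitoxin segments overlap", call. = FALSE)
  stopifnot(is.data.frame(elements),
            all(c("name", "start", "end") %in% names(elements)))
  for (k in seq_len(nrow(elements)))
    check_interval(c(elements$start[k], elements$end[k]), len,
                   elements$name[k])
  elements$ref <- substring(sequence, elements$start, elements$end)
  structure(list(name = name, sequence = sequence, elements = elements,
                 toxin_segment = as.integer(toxin_segment),
                 antitoxin_segment = as.integer(antitoxin_segment),
                 utr_segment = as.integer(utr_segment)),
            class = "locus_template")
}

#' @export
print.locus_template <- function(x, ...) {
  cat(sprintf("locus_template '%s': %d nt, %d elements\n", x$name,
              nchar(x$sequence), nrow(x$elements)))
  cat(sprintf("  antitoxin %d-%d | UTR %d-%d | toxin %d-%d\n",
              x$antitoxin_segment[1], x$antitoxin_segment[2],
              x$utr_segment[1], x$utr_segment[2],
              x$toxin_segment[1], x$toxin_segment[2]))
  invisible(x)
}

element_interval <- function(template, name) {
  k <- match(name, template$elements$name)
  if (is.na(k)) return(NULL)
  c(template$elements$start[k], template$elements$end[k])
}

# Positions covered by any annotated element (protected from mutation).
element_positions <- function(template) {
  if (nrow(template$elements) == 0) return(integer())
  sort(unique(unlist(mapply(seq, template$elements$start,
                            template$elements$end, SIMPLIFY = FALSE))))
}

#' Built-in synthetic locus templates
#'
#' Constructs a synthetic 520-nt toxin-antitoxin locus with a realistic
#' architecture: an antitoxin sRNA gene (positions 1-160, with its own -35 /
#' -10 promoter), a 60-nt intergenic region carrying the toxin promoter and
#' a LexA box, a 180-nt toxin 5' UTR containing the EAP region (whose
#' central 36 nt are the antitoxin pairing target and are perfectly
#' antisense to the antitoxin 3' half), an RSS and an RBS, and a 90-nt toxin
#' ORF encoding a 29-aa protein. These are synthetic stand-ins, not the
#' MG1655/EDL933 sequences. `variant = "P"` returns a diverged paralog
#' (15 percent substitutions outside annotated elements) for locus-type
#' assignment exercises; `"Q"` a 20 percent diverged one.
#'
#' @param variant `"O"`, `"P"` or `"Q"`.
#' @param seed seed for the deterministic construction.
#' @return a [locus_template()].
#' @export
example_template <- function(variant = c("O", "P", "Q"), seed = 101L) {
  variant <- match.arg(variant)
  base <- with_seed(seed, {
    s <- seq_chars(paste(sample(DNA_BASES, 520, replace = TRUE),
                         collapse = ""))
    put <- function(s, at, motif) {
      s[at:(at + nchar(motif) - 1)] <- seq_chars(motif)
      s
    }
    s <- put(s, 5, "TTGACA")      # antitoxin -35
    s <- put(s, 28, "TATAAT")     # antitoxin -10
    s <- put(s, 165, "TTGACA")    # toxin -35
    s <- put(s, 172, "CTGTATATATATACAG")  # LexA box
    s <- put(s, 194, "TATAAT")    # toxin -10
    s <- put(s, 290, "GGAGTG")    # standby-site-like motif inside the EAP
    s <- put(s, 330, "AAGGAG")    # RSS
    s <- put(s, 385, "AGGAGG")    # RBS
    # toxin ORF: ATG + 28 sense codons + TAA (29-aa protein)
    sense <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                           paste, collapse = ""),
                     c("TAA", "TAG", "TGA"))
    orf <- paste0("ATG", paste(sample(sense, 28, replace = TRUE),
                               collapse = ""), "TAA")
    s <- put(s, 401, orf)
    # antitoxin 3' half = reverse complement of the UTR pairing target;
    # the target sits deep in the UTR so the 27-29 nt remnant of an
    # antitoxin-only locus does not reach it
    s <- put(s, 120, revcomp(paste(s[275:310], collapse = "")))
    paste(s, collapse = "")
  })
  divergence <- c(O = 0, P = 0.15, Q = 0.20)[[variant]]
  elements <- data.frame(
    name = c("ant_minus35", "ant_minus10", "minus35", "lexA", "minus10",
             "EAP", "pairing", "RSS", "RBS", "ORF"),
    start = c(5L, 28L, 165L, 172L, 194L, 270L, 275L, 330L, 385L, 401L),
    end = c(10L, 33L, 170L, 187L, 199L, 315L, 310L, 335L, 390L, 490L),
    stringsAsFactors = FALSE)
  tpl <- locus_template(paste0("zorX_orzX_", variant, "_syn"), base, elements,
                        toxin_segment = c(221L, 490L),
                        antitoxin_segment = c(1L, 160L),
                        utr_segment = c(221L, 400L))
  if (divergence > 0) {
    prot <- union(element_positions(tpl), 120:155)
    tpl$sequence <- mutate_sequence(tpl$sequence, divergence,
                                    protect = prot, seed = seed + 7L)
    tpl$elements$ref <- substring(tpl$sequence, tpl$elements$start,
                                  tpl$elements$end)
  }
  tpl
}

# i.i.d. substitutions at `rate`, never at `protect` positions. Uses the
# caller's RNG stream unless `seed` is given.
mutate_sequence <- function(x, rate, protect = integer(), seed = NULL) {
  if (rate <= 0) return(x)
  body <- function() {
    ch <- seq_chars(x)
    idx <- setdiff(which(runif(length(ch)) < rate), protect)
    for (i in idx) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Specification of one planted locus
#'
#' @param category one of `full`, `interrupted`, `antitoxin_only`,
#'   `toxin_only`, `absent`.
#' @param copies copy-number contribution; defaults to 1 for
#'   full/interrupted, 0.5 for the orphan categories, 0 for absent.
#' @param on_plasmid plant on a plasmid replicon rather than the chromosome.
#' @param mutation_rate per-base substitution probability in `[0, 0.2]`.
#' @param variant_edits optional data frame with columns `pos`, `base`
#'   (template coordinates) of forced edits, e.g. a toxin N2S codon change.
#' @param spacer_length insertion length splitting an interrupted locus.
#' @param utr_stub length of toxin 5' UTR retained by an antitoxin-only
#'   locus (27-29 nt observed; default 28).
#' @param allow_element_mutation if `TRUE`, random substitutions may also
#'   fall inside annotated elements.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(category = c("full", "interrupted", "antitoxin_only",
                                    "toxin_only", "absent"),
                       copies = NULL, on_plasmid = FALSE, mutation_rate = 0,
                       variant_edits = NULL, spacer_length = 1200L,
                       utr_stub = 28L, allow_element_mutation = FALSE) {
  category <- match.arg(category)
  if (is.null(copies))
    copies <- switch(category, full = 1, interrupted = 1,
                     antitoxin_only = 0.5, toxin_only = 0.5, absent = 0)
  if (category == "absent" && copies != 0)
    stop("absent implies copies = 0", call. = FALSE)
  if (copies < 0 || (copies * 2) %% 1 != 0)
    stop("copies must be a non-negative multiple of 0.5", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 0.2)
    stop("mutation_rate must be in [0, 0.2]", call. = FALSE)
  structure(list(category = category, copies = copies,
                 on_plasmid = on_plasmid, mutation_rate = mutation_rate,
                 variant_edits = variant_edits,
                 spacer_length = as.integer(spacer_length),
                 utr_stub = as.integer(utr_stub),
                 allow_element_mutation = allow_element_mutation),
            class = "plant_spec")
}

# Build the DNA fragment for one planted instance plus the map from fragment
# positions back to template positions (NA for spacer residues).
build_fragment <- function(template, spec) {
  seqn <- template$sequence
  if (!is.null(spec$variant_edits))
    for (k in seq_len(nrow(spec$variant_edits)))
      substr(seqn, spec$variant_edits$pos[k], spec$variant_edits$pos[k]) <-
        spec$variant_edits$base[k]
  len <- nchar(seqn)
  switch(spec$category,
    full = list(frag = seqn, map = seq_len(len)),
    interrupted = {
      split_at <- len %/% 2
      spacer <- paste(sample(DNA_BASES, spec$spacer_length, replace = TRUE),
                      collapse = "")
      list(frag = paste0(substr(seqn, 1, split_at), spacer,
                         substr(seqn, split_at + 1, len)),
           map = c(seq_len(split_at), rep(NA_integer_, spec$spacer_length),
                   seq(split_at + 1, len)))
    },
    antitoxin_only = {
      a <- template$antitoxin_segment
      u <- template$utr_segment
      stub <- c(u[1], min(u[2], u[1] + spec$utr_stub - 1L))
      list(frag = paste0(substr_iv(seqn, a), substr_iv(seqn, stub)),
           map = c(seq(a[1], a[2]), seq(stub[1], stub[2])))
    },
    toxin_only = {
      t <- template$toxin_segment
      list(frag = substr_iv(seqn, t), map = seq(t[1], t[2]))
    },
    stop("cannot build a fragment for category 'absent'", call. = FALSE))
}

#' Plant one locus instance into a background sequence
#'
#' Overwrites the background at `position` with the fragment dictated by the
#' plant specification: the whole template (`full`), the template split by a
#' random spacer insertion (`interrupted`), the antitoxin gene plus a short
#' toxin-UTR stub (`antitoxin_only`), or the toxin transcript alone
#' (`toxin_only`). Substitution noise at `spec$mutation_rate` never falls
#' inside annotated elements unless `spec$allow_element_mutation`. The
#' strand is a seeded coin flip.
#'
#' @param background replicon DNA string.
#' @param template a [locus_template()].
#' @param spec a [plant_spec()] (category != "absent").
#' @param position 1-based start of the planted fragment on the replicon.
#' @param seed integer seed.
#' @return a list: `sequence` (modified background) and `truth` (one-row
#'   data frame: category, start, end, strand, template_name).
#' @export
plant_locus <- function(background, template, spec, position, seed = 1L) {
  with_seed(seed, {
    built <- build_fragment(template, spec)
    frag <- built$frag
    if (spec$mutation_rate > 0) {
      prot <- if (spec$allow_element_mutation) integer() else
        which(built$map %in% element_positions(template))
      frag <- mutate_sequence(frag, spec$mutation_rate, protect = prot)
    }
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") frag <- revcomp(frag)
    flen <- nchar(frag)
    if (position < 1 || position + flen - 1 > nchar(background))
      stop("planted fragment does not fit at this position", call. = FALSE)
    substr(background, position, position + flen - 1) <- frag
    list(sequence = background,
         truth = data.frame(category = spec$category, start = position,
                            end = position + flen - 1L, strand = strand,
                            template_name = template$name,
                            stringsAsFactors = FALSE))
  })
}

#' Default planted-category mix
#'
#' Mirrors the observed zor/orz copy-number spectrum: 3 percent absent, 25
#' percent one full locus, 42 percent two full loci, 27 percent
#' antitoxin-only (0.5 copies), plus rare three-copy, 1.5-copy, interrupted
#' and plasmid-borne two-copy assemblies. Columns `full`, `interrupted`,
#' `antitoxin_only`, `toxin_only` are planted instance counts.
#'
#' @return a data frame with one row per assembly shape and a `prob` column
#'   summing to 1.
#' @export
default_mix <- function() {
  data.frame(
    label = c("absent", "one_full", "two_full", "orz_only", "three_full",
              "one_and_a_half", "interrupted", "plasmid_two"),
    full = c(0L, 1L, 2L, 0L, 3L, 1L, 0L, 2L),
    interrupted = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L),
    antitoxin_only = c(0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L),
    toxin_only = 0L,
    on_plasmid = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    prob = c(0.03, 0.25, 0.42, 0.27, 0.005, 0.01, 0.005, 0.01),
    stringsAsFactors = FALSE)
}

#' Default metadata model
#'
#' Pathotype, geography and isolation-source vocabularies with sampling
#' probabilities, plus an optional planted copy-number effect: assemblies in
#' `effect_group` receive `effect_size` extra full copies on average.
#'
#' @param effect_group pathotype receiving the effect (`NULL` for none).
#' @param effect_size mean extra copies for the effect group.
#' @return a list describing the model.
#' @export
metadata_model <- function(effect_group = NULL, effect_size = 0) {
  list(pathotypes = c("healthy", "intestinal disease", "extraintestinal",
                      "unknown"),
       pathotype_probs = c(0.40, 0.25, 0.20, 0.15),
       geographies = c("North America", "Europe", "Asia"),
       geography_probs = c(1 / 3, 1 / 3, 1 / 3),
       sources = c("environmental", "laboratory"),
       source_probs = c(0.9, 0.1),
       effect_group = effect_group, effect_size = effect_size)
}

#' Simulate a synthetic pan-genome with planted loci and ground truth
#'
#' Generates `n` assemblies (one chromosome plus 0-2 plasmids each), plants
#' toxin-antitoxin loci according to a category mix, injects duplicate
#' strain names, samples metadata labels, and returns the planted truth.
#' One master `seed` drives everything; per-assembly streams are derived as
#' `seed + assembly index`, so outputs are reproducible and independent of
#' iteration order.
#'
#' @param n number of assemblies.
#' @param mix a data frame as returned by [default_mix()].
#' @param templates list of [locus_template()]; each assembly draws one.
#' @param meta a [metadata_model()].
#' @param seed master integer seed.
#' @param chrom_length,plasmid_length replicon lengths (desk scale).
#' @param mutation_rate substitution noise applied to planted fragments
#'   (annotated elements protected).
#' @param dup_rate probability that an assembly duplicates an earlier
#'   strain name (with identical planted copy numbers).
#' @param dh5a_mode also append three "DH5alpha" assemblies with copy
#'   numbers 0.5 / 0.5 / 2 to exercise the conflicting-duplicate rule.
#' @param gc background GC fraction.
#' @param shapes optional character vector (length `n` of `mix$label`
#'   values) fixing each assembly's shape deterministically instead of
#'   sampling from `mix$prob`; disables duplicate-name injection.
#' @return an object of class `pangenome`: list with `assemblies` (per
#'   assembly: named `replicons` strings and `descriptions`), `truth` and
#'   `metadata` data frames.
#' @export
simulate_pangenome <- function(n, mix = default_mix(),
                               templates = list(example_template()),
                               meta = metadata_model(), seed = 1L,
                               chrom_length = 20000L, plasmid_length = 6000L,
                               mutation_rate = 0, dup_rate = 0.04,
                               dh5a_mode = FALSE, gc = 0.5, shapes = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(templates) == 0) stop("empty template list", call. = FALSE)
  if (abs(sum(mix$prob) - 1) > 1e-8) stop("mix probabilities must sum to 1",
                                          call. = FALSE)
  if (is.null(shapes)) {
    shapes <- with_seed(seed, sample(nrow(mix), n, replace = TRUE,
                                     prob = mix$prob))
  } else {
    stopifnot(length(shapes) == n, all(shapes %in% mix$label))
    shapes <- match(shapes, mix$label)
    dup_rate <- 0
  }
  tpl_idx <- with_seed(seed + 500000L, sample(length(templates), n,
                                              replace = TRUE))
  assemblies <- list()
  truth <- list()
  metadata <- list()
  strain_names <- character(n)
  for (i in seq_len(n)) {
    aid <- sprintf("ASM%04d", i)
    dup_from <- with_seed(seed + 900000L + i,
                          if (i > 1 && runif(1) < dup_rate)
                            sample(i - 1, 1) else NA_integer_)
    if (!is.na(dup_from)) {
      strain_names[i] <- strain_names[dup_from]
      shapes[i] <- shapes[dup_from]
      tpl_idx[i] <- tpl_idx[dup_from]
    } else strain_names[i] <- sprintf("strain_%04d", i)
    shape <- mix[shapes[i], ]
    md <- with_seed(seed + 700000L + i, data.frame(
      assembly_id = aid, strain_name = strain_names[i],
      source_category = sample(meta$sources, 1, prob = meta$source_probs),
      pathotype = sample(meta$pathotypes, 1, prob = meta$pathotype_probs),
      geography = sample(meta$geographies, 1, prob = meta$geography_probs),
      stringsAsFactors = FALSE))
    extra_full <- 0L
    if (!is.null(meta$effect_group) && md$pathotype == meta$effect_group) {
      extra_full <- with_seed(seed + 800000L + i,
                              floor(meta$effect_size) +
                                rbinom(1, 1, meta$effect_size %% 1))
    }
    built <- build_assembly(aid, shape, extra_full, templates[[tpl_idx[i]]],
                            seed + i, chrom_length, plasmid_length,
                            mutation_rate, gc)
    assemblies[[aid]] <- built$assembly
    if (nrow(built$truth)) {
      built$truth$strain_name <- strain_names[i]
      truth[[aid]] <- built$truth
    }
    metadata[[aid]] <- md
  }
  pg <- list(assemblies = assemblies,
             truth = do.call(rbind, c(truth, list(empty_truth()))),
             metadata = do.call(rbind, metadata),
             seed = seed)
  rownames(pg$truth) <- NULL
  rownames(pg$metadata) <- NULL
  class(pg) <- "pangenome"
  if (dh5a_mode) pg <- append_dh5a(pg, templates[[1]], seed, chrom_length,
                                   plasmid_length, gc)
  pg
}

empty_truth <- function() {
  data.frame(assembly_id = character(), strain_name = character(),
             replicon_id = character(), replicon_type = character(),
             category = character(), start = integer(), end = integer(),
             strand = character(), template_name = character(),
             stringsAsFactors = FALSE)
}

build_assembly <- function(aid, shape, extra_full, template, seed,
                           chrom_length, plasmid_length, mutation_rate, gc) {
  counts <- c(full = shape$full, interrupted = shape$interrupted,
              antitoxin_only = shape$antitoxin_only,
              toxin_only = shape$toxin_only)
  cats <- rep(names(counts), counts)
  # a planted metadata effect always adds chromosomal full copies
  extra_cats <- rep("full", extra_full)
  n_plasmids <- with_seed(seed + 300000L,
                          max(if (shape$on_plasmid) 1L else 0L,
                              sample(0:2, 1, prob = c(0.6, 0.3, 0.1))))
  chrom_id <- paste0(aid, "_chr")
  reps <- list()
  reps[[chrom_id]] <- generate_background(chrom_length, gc, seed)
  descs <- paste0(aid, " chromosome, complete genome")
  names(descs) <- chrom_id
  if (n_plasmids > 0) for (p in seq_len(n_plasmids)) {
    pid <- paste0(aid, "_p", p)
    reps[[pid]] <- generate_background(plasmid_length, gc,
                                       seed + 100000L + p)
    descs[pid] <- paste0(aid, " plasmid pTA", p, ", complete sequence")
  }
  truth <- list()
  plan <- list()
  if (length(cats)) {
    target <- if (shape$on_plasmid) paste0(aid, "_p1") else chrom_id
    plan[[1]] <- list(cats = cats, target = target, offset = 0L)
  }
  if (length(extra_cats))
    plan[[length(plan) + 1L]] <- list(
      cats = extra_cats, target = chrom_id,
      offset = if (length(cats) && !shape$on_plasmid) length(cats) else 0L)
  kk <- 0L
  for (pl in plan) {
    # positions spaced so distinct copies never share one hit cluster
    plasmid <- !grepl("_chr$", pl$target)
    step <- if (plasmid) 2800L else 4500L
    base_pos <- (if (plasmid) 400L else 2000L) + pl$offset * step
    for (k in seq_along(pl$cats)) {
      kk <- kk + 1L
      spec <- plant_spec(pl$cats[k], mutation_rate = mutation_rate)
      pos <- base_pos + (k - 1L) * step
      planted <- plant_locus(reps[[pl$target]], template, spec, pos,
                             seed = seed + 200000L + kk)
      reps[[pl$target]] <- planted$sequence
      tr <- planted$truth
      tr$assembly_id <- aid
      tr$replicon_id <- pl$target
      tr$replicon_type <- if (plasmid) "plasmid" else "chromosome"
      truth[[kk]] <- tr
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  if (nrow(truth))
    truth <- truth[, c("assembly_id", "replicon_id", "replicon_type",
                       "category", "start", "end", "strand",
                       "template_name")]
  list(assembly = list(replicons = unlist(reps), descriptions = descs),
       truth = truth)
}

append_dh5a <- function(pg, template, seed, chrom_length, plasmid_length,
                        gc) {
  shapes <- list(
    data.frame(label = "dh5a_half", full = 0L, interrupted = 0L,
               antitoxin_only = 1L, toxin_only = 0L, on_plasmid = FALSE),
    data.frame(label = "dh5a_half", full = 0L, interrupted = 0L,
               antitoxin_only = 1L, toxin_only = 0L, on_plasmid = FALSE),
    data.frame(label = "dh5a_two", full = 2L, interrupted = 0L,
               antitoxin_only = 0L, toxin_only = 0L, on_plasmid = FALSE))
  for (k in seq_along(shapes)) {
    aid <- sprintf("DH5A%02d", k)
    built <- build_assembly(aid, shapes[[k]], 0L, template,
                            seed + 600000L + k, chrom_length,
                            plasmid_length, 0, gc)
    pg$assemblies[[aid]] <- built$assembly
    built$truth$strain_name <- "DH5alpha"
    pg$truth <- rbind(pg$truth, built$truth)
    pg$metadata <- rbind(pg$metadata, data.frame(
      assembly_id = aid, strain_name = "DH5alpha",
      source_category = "laboratory", pathotype = "unknown",
      geography = "North America", stringsAsFactors = FALSE))
  }
  pg
}

#' True per-assembly copy number from a planted truth table
#'
#' @param pg a `pangenome` (or its `truth` data frame) from
#'   [simulate_pangenome()].
#' @return data frame with `assembly_id`, `copy_number` (full/interrupted
#'   count 1.0 each, orphan categories 0.5), including 0 rows for
#'   locus-free assemblies.
#' @export
truth_copy_number <- function(pg) {
  truth <- if (inherits(pg, "pangenome")) pg$truth else pg
  ids <- if (inherits(pg, "pangenome")) names(pg$assemblies) else
    unique(truth$assembly_id)
  units <- c(full = 1, interrupted = 1, antitoxin_only = 0.5,
             toxin_only = 0.5)
  cn <- vapply(ids, function(a)
    sum(units[truth$category[truth$assembly_id == a]]), numeric(1))
  data.frame(assembly_id = ids, copy_number = unname(cn),
             stringsAsFactors = FALSE)
}

#' Write a pan-genome to disk
#'
#' One 60-column wrapped multi-record FASTA per assembly under
#' `dir/genomes/` (plasmid records carry the word "plasmid" in their
#' description), plus `truth.tsv` and `metadata.tsv`.
#'
#' @param pg a `pangenome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(pg, dir) {
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (aid in names(pg$assemblies)) {
    a <- pg$assemblies[[aid]]
    dss <- Biostrings::DNAStringSet(a$replicons)
    names(dss) <- paste(names(a$replicons),
                        a$descriptions[names(a$replicons)])
    Biostrings::writeXStringSet(dss, file.path(gdir, paste0(aid, ".fasta")),
                                width = 60L)
  }
  write.table(pg$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pg$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read assemblies written by [write_pangenome()]
#'
#' @param dir directory containing a `genomes/` folder of FASTA files (or a
#'   directory of FASTA files itself).
#' @return a named list (assembly id from the file name) of lists with
#'   `replicons` (named DNA strings) and `descriptions`.
#' @export
read_genomes <- function(dir) {
  gdir <- if (dir.exists(file.path(dir, "genomes")))
    file.path(dir, "genomes") else dir
  files <- list.files(gdir, pattern = "\\.(fa|fasta|fna)$",
                      full.names = TRUE)
  if (length(files) == 0)
    stop("no FASTA files found in ", gdir, call. = FALSE)
  out <- list()
  for (f in files) {
    dss <- Biostrings::readDNAStringSet(f)
    headers <- names(dss)
    ids <- sub("\\s.*$", "", headers)
    reps <- as.character(dss)
    names(reps) <- ids
    descs <- headers
    names(descs) <- ids
    out[[tools::file_path_sans_ext(basename(f))]] <-
      list(replicons = reps, descriptions = descs)
  }
  out
}
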