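# End-to-end orchestration: simulate -> scan -> classify -> conserve ->
# pair -> stats -> report, with deterministic file outputs.

#' Pipeline configuration
#'
#' @param genomes directory of assembly FASTA files (a `genomes/`
#'   subdirectory is used when present).
#' @param out output directory.
#' @param template a [locus_template()], or path prefix readable by
#'   [read_template()].
#' @param metadata optional path to a metadata TSV (`assembly_id`,
#'   `strain_name`, `source_category`, `pathotype`, `geography`); defaults
#'   to `metadata.tsv` next to the genomes when present.
#' @param typing optional named list of typing [locus_template()]s.
#' @param evalue,max_targets,word_size,reward,penalty,gap_open,gap_extend
#'   search parameters (defaults 10, 10000, 11, +2, -3, 5, 2).
#' @param full_cov,utr_slack classification parameters.
#' @param iterations,seed Monte Carlo statistics parameters.
#' @param dedupe drop duplicate strain names before statistics.
#' @param wobble count G:U pairs in the pairing scan.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, out, template = example_template(),
                            metadata = NULL, typing = NULL,
                            evalue = 10, max_targets = 10000L,
                            word_size = 11L, reward = 2L, penalty = -3L,
                            gap_open = 5L, gap_extend = 2L,
                            full_cov = 0.95, utr_slack = 30L,
                            iterations = 10000L, seed = 1L,
                            dedupe = TRUE, wobble = FALSE) {
  stopifnot(evalue > 0, max_targets >= 1, full_cov > 0, full_cov <= 1,
            iterations >= 1)
  structure(list(genomes = genomes, out = out, template = template,
                 metadata = metadata, typing = typing, evalue = evalue,
                 max_targets = as.integer(max_targets),
                 word_size = as.integer(word_size),
                 reward = as.integer(reward), penalty = as.integer(penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), full_cov = full_cov,
                 utr_slack = as.integer(utr_slack),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), dedupe = dedupe, wobble = wobble),
            class = "pipeline_config")
}

#' Write / read a locus template as FASTA + element TSV
#'
#' `<prefix>.fasta` holds the sequence; `<prefix>.elements.tsv` has columns
#' `role` (element / toxin_segment / antitoxin_segment / utr_segment),
#' `name`, `start`, `end`.
#'
#' @param template a [locus_template()].
#' @param prefix file path prefix.
#' @return `read_template` returns a [locus_template()].
#' @export
write_template <- function(template, prefix) {
  dss <- Biostrings::DNAStringSet(template$sequence)
  names(dss) <- template$name
  Biostrings::writeXStringSet(dss, paste0(prefix, ".fasta"), width = 60L)
  segs <- data.frame(
    role = c("toxin_segment", "antitoxin_segment", "utr_segment"),
    name = "",
    start = c(template$toxin_segment[1], template$antitoxin_segment[1],
              template$utr_segment[1]),
    end = c(template$toxin_segment[2], template$antitoxin_segment[2],
            template$utr_segment[2]), stringsAsFactors = FALSE)
  els <- data.frame(role = "element", name = template$elements$name,
                    start = template$elements$start,
                    end = template$elements$end, stringsAsFactors = FALSE)
  write.table(rbind(segs, els), paste0(prefix, ".elements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_template
#' @export
read_template <- function(prefix) {
  dss <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  tab <- read.delim(paste0(prefix, ".elements.tsv"),
                    stringsAsFactors = FALSE)
  seg <- function(role) {
    r <- tab[tab$role == role, ]
    c(r$start[1], r$end[1])
  }
  els <- tab[tab$role == "element", c("name", "start", "end")]
  locus_template(sub("\\s.*$", "", names(dss)[1]), as.character(dss[[1]]),
                 els, seg("toxin_segment"), seg("antitoxin_segment"),
                 seg("utr_segment"))
}

pipeline_log <- function(lines, path) {
  con <- file(path, "a")
  writeLines(lines, con)
  close(con)
}

#' Run the whole analysis pipeline
#'
#' Scans every assembly for the locus, classifies and counts copies,
#' summarizes element conservation and protein variants, scores pairing
#' potential, and (when metadata with at least two usable pathotype groups
#' is available) runs the Monte Carlo ANOVA and Tukey tests on copy number.
#' All outputs are plain text (TSV + one JSON summary + run log) and a
#' rerun with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main result tables and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out, "run.log")
  if (file.exists(logf)) unlink(logf)
  log <- function(...) pipeline_log(sprintf(...), logf)
  log("tascan pipeline, package version %s",
      as.character(utils::packageVersion("tascan")))
  cfg_echo <- config
  cfg_echo$template <- config$template$name %||% "file"
  cfg_echo$typing <- names(config$typing)
  log("config: %s", jsonlite::toJSON(cfg_echo[!vapply(cfg_echo, is.null,
                                                      logical(1))],
                                     auto_unbox = TRUE))

  template <- if (is.character(config$template))
    read_template(config$template) else config$template
  scheme <- scoring_scheme(config$reward, config$penalty, config$gap_open,
                           config$gap_extend, config$word_size)
  assemblies <- read_genomes(config$genomes)
  log("read %d assemblies from %s", length(assemblies), config$genomes)

  typing <- if (!is.null(config$typing)) typing_queries(config$typing)
  scr <- screen_assemblies(assemblies, template, scheme, typing = typing,
                           evalue_cutoff = config$evalue,
                           max_targets = config$max_targets,
                           full_cov = config$full_cov,
                           utr_slack = config$utr_slack)
  calls <- scr$calls
  log("called %d loci (%d partial matches reported separately)",
      nrow(calls), nrow(scr$partial))

  # metadata
  md_path <- config$metadata %||% {
    cand <- file.path(config$genomes, "metadata.tsv")
    cand2 <- file.path(dirname(config$genomes), "metadata.tsv")
    if (file.exists(cand)) cand else if (file.exists(cand2)) cand2 else NULL
  }
  reports <- scr$reports
  if (!is.null(md_path) && file.exists(md_path)) {
    md <- read.delim(md_path, stringsAsFactors = FALSE)
    reports <- merge(reports, md, by = "assembly_id", all.x = TRUE,
                     sort = TRUE)
  } else reports$strain_name <- NA_character_
  reports <- reports[order(reports$assembly_id), , drop = FALSE]
  names(reports)[names(reports) == "copy_number"] <- "copy_number"

  dedup_removed <- 0L
  if (isTRUE(config$dedupe) && "strain_name" %in% names(reports)) {
    dd <- dedupe_assemblies(reports, copy_cols = "copy_number")
    dedup_removed <- nrow(dd$removed)
    reports_kept <- dd$kept
  } else reports_kept <- reports
  log("dedupe: removed %d duplicate assemblies", dedup_removed)

  # conservation over full loci
  full_calls <- calls[calls$category == "full", , drop = FALSE]
  cons <- NULL
  pvtab <- NULL
  if (nrow(full_calls)) {
    cons <- element_conservation(full_calls, template)
    write.table(cons, file.path(config$out, "element_conservation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    eap <- element_interval(template, "EAP")
    if (!is.null(eap)) {
      obs <- unlist(lapply(seq_len(nrow(full_calls)), function(i)
        map_element(full_calls[i, ], eap)))
      obs <- obs[nchar(obs) == iv_width(eap)]
      if (length(obs))
        write_consensus(build_consensus(obs),
                        file.path(config$out, "consensus_EAP.tsv"))
    }
    orf <- element_interval(template, "ORF")
    if (!is.null(orf)) {
      ref_prot <- translate_orf(substr_iv(template$sequence, orf))$protein
      prots <- character()
      for (i in seq_len(nrow(full_calls))) {
        o <- map_element(full_calls[i, ], orf)
        if (is.null(o)) next
        tr <- translate_orf(o)
        if (!tr$truncated && nchar(tr$protein) == nchar(ref_prot))
          prots <- c(prots, tr$protein)
      }
      if (length(prots)) {
        pvtab <- protein_variants(prots, ref_prot)
        write.table(pvtab, file.path(config$out, "protein_variants.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  # pairing potential per full locus
  pairing_rows <- list()
  ant_iv <- template$antitoxin_segment
  tgt_iv <- element_interval(template, "pairing") %||% template$utr_segment
  for (i in seq_len(nrow(full_calls))) {
    a_obs <- map_element(full_calls[i, ], ant_iv)
    t_obs <- map_element(full_calls[i, ], tgt_iv)
    if (is.null(a_obs) || is.null(t_obs)) next
    bd <- best_duplex(a_obs, t_obs, wobble = config$wobble)
    pairing_rows[[length(pairing_rows) + 1L]] <- data.frame(
      assembly_id = full_calls$assembly_id[i],
      replicon_id = full_calls$replicon_id[i],
      contiguous = bd$contiguous$length,
      one_mismatch = bd$one_mismatch$length,
      repressive = is_repressive(bd), stringsAsFactors = FALSE)
  }
  pairing_tab <- if (length(pairing_rows)) do.call(rbind, pairing_rows)
  frac_repressive <- if (length(pairing_rows))
    mean(pairing_tab$repressive) else NA_real_
  if (!is.null(pairing_tab))
    write.table(pairing_tab, file.path(config$out, "pairing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  log("pairing: %d full loci scored, repressive fraction %s",
      length(pairing_rows), format(frac_repressive))

  # Monte Carlo statistics on copy number by pathotype
  stats_res <- NULL
  if ("pathotype" %in% names(reports_kept)) {
    labs <- reports_kept$pathotype
    labs[labs %in% c("unknown", "")] <- NA  # excluded, as with real metadata
    ok <- !is.na(labs)
    tab <- table(labs[ok])
    if (length(tab[tab >= 2]) >= 2) {
      use <- ok & labs %in% names(tab[tab >= 2])
      gd <- grouped_data(reports_kept$copy_number[use], labs[use])
      fit <- try(mc_anova(gd, iterations = config$iterations,
                          seed = config$seed), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        tk <- mc_tukey(gd, iterations = config$iterations,
                       seed = config$seed)
        write.table(tk, file.path(config$out, "tukey.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        stats_res <- list(observed_f = fit$observed_f,
                          p_value = fit$p_value,
                          iterations = fit$iterations,
                          groups = as.list(stats::setNames(as.integer(tab),
                                                           names(tab))))
        log("mc_anova: F = %.4f p = %.4g", fit$observed_f, fit$p_value)
      } else log("mc_anova skipped: %s", attr(fit, "condition")$message)
    } else log("stats skipped: fewer than two usable groups")
  }

  # tables
  write.table(calls, file.path(config$out, "locus_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(scr$partial))
    write.table(scr$partial, file.path(config$out, "partial_matches.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(reports_kept, file.path(config$out, "copy_number.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  spectrum <- table(reports_kept$copy_number)
  summary <- list(
    n_assemblies = length(assemblies),
    n_after_dedupe = nrow(reports_kept),
    dedup_removed = dedup_removed,
    category_counts = as.list(table(calls$category)),
    copy_number_spectrum = as.list(spectrum),
    fraction_repressive = frac_repressive,
    stats = stats_res)
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  log("done")
  invisible(list(calls = calls, reports = reports_kept, partial = scr$partial,
                 conservation = cons, protein_variants = pvtab,
                 pairing = pairing_tab, stats = stats_res,
                 summary = summary))
}
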