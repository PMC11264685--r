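# From alignment hits to locus calls: clustering, spurious-hit filtering,
# category classification, bit-score locus typing, plasmid detection,
# set-logic categorization and duplicate-strain deduplication.

#' Cluster hits into per-locus coverage profiles
#'
#' Hits of one query on the same subject and strand within `max_gap` nt of
#' each other form one genomic cluster; the covered query intervals are
#' projected and merged. Tandem loci further apart than `max_gap` stay
#' distinct.
#'
#' @param hits a hit data frame from [seed_extend_search()] (one query).
#' @param max_gap maximum subject gap joining hits into a cluster, nt.
#' @param min_hit_len alignments shorter than this cluster only among
#'   themselves: word-size chance matches must neither bridge two loci nor
#'   contaminate a locus profile.
#' @return a list of `coverage_profile` objects: `query_id`, `subject_id`,
#'   `strand`, `cluster` (subject interval), `segments` (matrix of merged
#'   query intervals), `collinear`, `max_gap_in_subject`, `max_query_gap`,
#'   `best_bit`, and the contributing `hits` rows.
#' @export
cluster_hits <- function(hits, max_gap = 2000L, min_hit_len = 20L) {
  if (nrow(hits) == 0) return(list())
  stopifnot(length(unique(hits$qseqid)) == 1)
  profiles <- list()
  micro <- hits$length < min_hit_len
  for (sid in unique(hits$sseqid)) {
    for (strand in c("+", "-")) for (grp in c(FALSE, TRUE)) {
      h <- hits[hits$sseqid == sid & hits$strand == strand & micro == grp, ,
                drop = FALSE]
      if (nrow(h) == 0) next
      h <- h[order(h$sstart), , drop = FALSE]
      gap_new <- c(TRUE, h$sstart[-1] - h$send[-nrow(h)] > max_gap)
      cl_id <- cumsum(gap_new)
      for (ci in unique(cl_id)) {
        hc <- h[cl_id == ci, , drop = FALSE]
        # structural segments: the abutting query halves of an interrupted
        # locus may overlap by a few chance-extension nucleotides, so only
        # substantial overlaps merge; coverage uses the plain union
        segs <- merge_query_segments(hc$qstart, hc$qend, min_overlap = 30L)
        qr <- IRanges::reduce(IRanges::IRanges(hc$qstart, hc$qend))
        union_width <- sum(IRanges::width(qr))
        # collinearity: subject order must follow query order (reversed on -)
        qo <- order(hc$qstart)
        collinear <- if (strand == "+") all(diff(qo) > 0) else
          all(diff(rev(qo)) > 0)
        sgaps <- if (nrow(hc) > 1) diff(hc$sstart) - (hc$send[-nrow(hc)] -
                                                        hc$sstart[-nrow(hc)] + 1) else 0L
        qgaps <- if (nrow(segs) > 1)
          segs[-1, "start"] - segs[-nrow(segs), "end"] - 1L else 0L
        profiles[[length(profiles) + 1L]] <- structure(
          list(query_id = hc$qseqid[1], subject_id = sid, strand = strand,
               cluster = c(min(hc$sstart), max(hc$send)),
               segments = segs, union_width = union_width,
               collinear = collinear,
               max_gap_in_subject = max(0L, sgaps),
               max_query_gap = max(0L, qgaps),
               best_single_cov = max(hc$qend - hc$qstart + 1),
               best_bit = max(hc$bitscore), hits = hc),
          class = "coverage_profile")
      }
    }
  }
  profiles
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s on %s (%s) %d-%d: %d segment(s)\n",
              x$query_id, x$subject_id, x$strand, x$cluster[1], x$cluster[2],
              nrow(x$segments)))
  invisible(x)
}

profile_coverage <- function(profile, qlen) {
  w <- profile$union_width %||%
    sum(profile$segments[, "end"] - profile$segments[, "start"] + 1)
  w / qlen
}

# Merge query intervals whose overlap is at least `min_overlap` nt;
# smaller overlaps (chance extension across a breakpoint) stay separate.
merge_query_segments <- function(starts, ends, min_overlap = 11L) {
  ord <- order(starts, ends)
  starts <- starts[ord]
  ends <- ends[ord]
  out <- list()
  cs <- starts[1]
  ce <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (ce - starts[k] + 1 >= min_overlap || ends[k] <= ce) {
      ce <- max(ce, ends[k])
    } else {
      out[[length(out) + 1L]] <- c(cs, ce)
      cs <- starts[k]
      ce <- ends[k]
    }
  }
  out[[length(out) + 1L]] <- c(cs, ce)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

segments_overlap <- function(segs, iv) {
  any(pmin(segs[, "end"], iv[2]) - pmax(segs[, "start"], iv[1]) >= 0)
}

segments_within <- function(segs, ivs) {
  # every segment contained in at least one allowed interval
  all(apply(segs, 1, function(sg)
    any(ivs[, 1] <= sg[1] & sg[2] <= ivs[, 2])))
}

coverage_of <- function(segs, iv) {
  ov <- pmin(segs[, "end"], iv[2]) - pmax(segs[, "start"], iv[1]) + 1
  sum(pmax(0, ov)) / (iv[2] - iv[1] + 1)
}

#' Remove spurious short and palindromic matches
#'
#' Drops (i) profiles confined to the query's 3' terminator-like region and
#' spanning fewer than `min_span` nt (short matches to the antitoxin 3' end
#' that do not represent loci), and (ii) opposite-strand profiles whose
#' genomic cluster falls inside an already-counted cluster (near-palindromic
#' self-matches, never counted as extra copies).
#'
#' @param profiles list of `coverage_profile`.
#' @param template the query [locus_template()].
#' @param min_span minimum query span for a blacklisted-region match, nt.
#' @param blacklist query interval of the 3' terminator region (default:
#'   the final 40 nt).
#' @return the retained profiles.
#' @export
filter_spurious <- function(profiles, template, min_span = 60L,
                            blacklist = NULL) {
  qlen <- nchar(template$sequence)
  if (is.null(blacklist)) blacklist <- c(qlen - 39L, qlen)
  keep <- rep(TRUE, length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    span <- max(p$segments[, "end"]) - min(p$segments[, "start"]) + 1
    if (span < min_span &&
        all(p$segments[, "start"] >= blacklist[1] &
            p$segments[, "end"] <= blacklist[2]))
      keep[i] <- FALSE
  }
  # palindromic opposite-strand matches inside a counted cluster
  ord <- order(-vapply(profiles, function(p) p$best_bit, numeric(1)))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (!keep[j]) next
      pi <- profiles[[i]]; pj <- profiles[[j]]
      if (pi$subject_id == pj$subject_id && pi$strand != pj$strand &&
          pj$cluster[1] >= pi$cluster[1] - 10 &&
          pj$cluster[2] <= pi$cluster[2] + 10)
        keep[j] <- FALSE
    }
  }
  profiles[keep]
}

#' Classify one coverage profile into a locus category
#'
#' Categories: `full` (one collinear segment covering at least `full_cov`
#' of the query), `interrupted` (split coverage totalling at least
#' `full_cov` with an internal subject insertion >= `interrupted_gap` nt or
#' internal query deletion >= `interrupted_del` nt), `antitoxin_only`
#' (coverage confined to the antitoxin gene plus at most `utr_slack` nt of
#' the toxin 5' UTR, with no coverage of the toxin ORF or of the pairing
#' region), `toxin_only` (the symmetric case), else `partial` (reported but
#' not counted towards copy number).
#'
#' @param profile a `coverage_profile` that survived [filter_spurious()].
#' @param template the query [locus_template()].
#' @param full_cov query-coverage fraction defining a full match.
#' @param utr_slack tolerated UTR overhang of an antitoxin-only locus, nt.
#' @param interrupted_gap,interrupted_del numeric rules for "interrupted".
#' @param orphan_cov minimum coverage of the orphan gene itself.
#' @param boundary_slack tolerated chance extension of a local alignment
#'   beyond a segment boundary, nt.
#' @return a one-row data frame (`locus_call`): `replicon_id`, `strand`,
#'   `category`, `copy_units`, `locus_type`, `best_bit_score`,
#'   `cluster_start`, `cluster_end`, `coverage`.
#' @export
classify_locus <- function(profile, template, full_cov = 0.95,
                           utr_slack = 30L, interrupted_gap = 100L,
                           interrupted_del = 50L, orphan_cov = 0.8,
                           boundary_slack = 10L) {
  if (profile$query_id != template$name)
    stop("profile/query mismatch: ", profile$query_id, " vs ",
         template$name, call. = FALSE)
  qlen <- nchar(template$sequence)
  segs <- profile$segments
  cov <- profile_coverage(profile, qlen)
  ant <- template$antitoxin_segment
  tox <- template$toxin_segment
  utr <- template$utr_segment
  orf <- element_interval(template, "ORF") %||% tox
  pairing <- element_interval(template, "pairing")
  stub <- c(utr[1], min(utr[2], utr[1] + utr_slack - 1L))

  # a locus whose cluster attracted extra short chance hits is still full
  # if a single collinear alignment covers the query
  single_cov <- (profile$best_single_cov %||% 0) / qlen
  bs <- boundary_slack
  widen <- function(iv) c(iv[1] - bs, iv[2] + bs)
  category <- "partial"
  if ((single_cov >= full_cov) ||
      (nrow(segs) == 1 && cov >= full_cov && profile$collinear)) {
    category <- "full"
  } else if (nrow(segs) >= 2 && cov >= full_cov &&
             (profile$max_gap_in_subject >= interrupted_gap ||
              profile$max_query_gap >= interrupted_del)) {
    category <- "interrupted"
  } else if (!segments_overlap(segs, orf) &&
             (is.null(pairing) || !segments_overlap(segs, pairing)) &&
             segments_within(segs, rbind(widen(ant), widen(stub))) &&
             coverage_of(segs, ant) >= orphan_cov) {
    category <- "antitoxin_only"
  } else if (!segments_overlap(segs, ant) &&
             segments_within(segs, rbind(widen(tox))) &&
             coverage_of(segs, orf) >= orphan_cov) {
    category <- "toxin_only"
  }
  units <- c(full = 1, interrupted = 1, antitoxin_only = 0.5,
             toxin_only = 0.5, partial = 0)
  data.frame(replicon_id = profile$subject_id, strand = profile$strand,
             category = category, copy_units = unname(units[category]),
             locus_type = "unassigned", best_bit_score = profile$best_bit,
             cluster_start = profile$cluster[1],
             cluster_end = profile$cluster[2], coverage = cov,
             stringsAsFactors = FALSE)
}

#' Assign a locus type from per-query bit scores
#'
#' Full loci take the type of the typing query whose bit score exceeds the
#' `full` threshold (highest score wins, ties broken by the order of
#' `thresholds`); antitoxin-only loci are compared against the
#' antitoxin-query thresholds in order (type O cutoff 280, then type P
#' cutoff 250); anything below every cutoff stays `unassigned`.
#'
#' @param call a `locus_call` row from [classify_locus()].
#' @param scores_by_query named numeric vector of bit scores, names are
#'   type labels (`"O"`, `"P"`, `"Q"`).
#' @param thresholds named cutoffs; `full` applies to full loci, the
#'   remaining names (in order) to antitoxin-only loci.
#' @return the call with `locus_type` filled in.
#' @export
assign_locus_type <- function(call, scores_by_query,
                              thresholds = c(full = 650, O = 280, P = 250)) {
  if (call$category %in% c("full", "interrupted")) {
    cand <- scores_by_query[scores_by_query > thresholds[["full"]]]
    if (length(cand)) {
      best <- max(cand)
      # highest score wins; ties by fixed precedence (order of the vector)
      call$locus_type <- names(cand)[which(cand == best)[1]]
    }
  } else if (call$category == "antitoxin_only") {
    for (ty in setdiff(names(thresholds), "full")) {
      sc <- scores_by_query[[ty]] %||% NA_real_
      if (!is.na(sc) && sc > thresholds[[ty]]) {
        call$locus_type <- ty
        break
      }
    }
  }
  call
}

#' Is a replicon description plasmid-like?
#'
#' @param description FASTA description line text.
#' @return `TRUE` iff it contains "plasmid" or "extrachromosomal"
#'   (case-insensitive).
#' @export
detect_plasmid <- function(description) {
  grepl("plasmid|extrachromosomal", description, ignore.case = TRUE)
}

#' Set-logic categorization from per-query hit membership
#'
#' Reproduces the command-line set logic: an assembly hit by the full-locus
#' query and by both single-gene queries is `paired`; hit by the full query
#' but not the antitoxin query is `toxin_only`; hit by the full query but
#' not the toxin query is `antitoxin_only`; hit by none is `absent`. An
#' assembly hit by a single-gene query but not the full query is flagged as
#' an anomaly.
#'
#' @param full_ids,toxin_ids,antitoxin_ids character vectors of assembly
#'   ids hit by the full-locus, toxin-only and antitoxin-only queries.
#' @param all_ids the assembly universe (default: union of the three).
#' @return data frame with `assembly_id`, `category`, `anomaly`.
#' @export
set_categorize <- function(full_ids, toxin_ids, antitoxin_ids,
                           all_ids = NULL) {
  if (is.null(all_ids))
    all_ids <- sort(unique(c(full_ids, toxin_ids, antitoxin_ids)))
  res <- lapply(all_ids, function(id) {
    inf <- id %in% full_ids
    int <- id %in% toxin_ids
    ina <- id %in% antitoxin_ids
    cat <- if (!inf && !int && !ina) "absent"
    else if (inf && int && !ina) "toxin_only"
    else if (inf && ina && !int) "antitoxin_only"
    else if (inf) "paired"
    else "anomaly"
    data.frame(assembly_id = id, category = cat,
               anomaly = (!inf && (int || ina)), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Deduplicate assemblies sharing a strain name
#'
#' Groups assembly reports by strain name and, within a group, keeps exactly
#' one representative (first assembly id in lexicographic order) per
#' distinct copy-number vector; the rest are removed. Assemblies with
#' missing or empty strain names are never deduplicated.
#'
#' @param reports data frame with `assembly_id`, `strain_name` and one or
#'   more copy-number columns.
#' @param copy_cols names of the copy-number columns (default: all columns
#'   starting with "copy").
#' @return a list with `kept` and `removed` report data frames.
#' @export
dedupe_assemblies <- function(reports,
                              copy_cols = grep("^copy", names(reports),
                                               value = TRUE)) {
  stopifnot(length(copy_cols) > 0)
  reports <- reports[order(reports$assembly_id), , drop = FALSE]
  known <- !is.na(reports$strain_name) & nzchar(reports$strain_name)
  key <- paste(reports$strain_name,
               do.call(paste, c(reports[copy_cols], sep = "|")), sep = "||")
  keep <- !known | !duplicated(key)
  keep[!known] <- TRUE
  list(kept = reports[keep, , drop = FALSE],
       removed = reports[!keep, , drop = FALSE])
}

#' Screen assemblies for a toxin-antitoxin locus and call copy number
#'
#' Runs the full detection path per assembly: seed-and-extend search of the
#' locus query against every replicon, hit clustering, spurious-match
#' filtering, category classification and (optionally) bit-score locus
#' typing; marks plasmid-borne calls via the replicon description.
#'
#' @param assemblies a named list as produced by [simulate_pangenome()]
#'   (`$assemblies`) or [read_genomes()].
#' @param template the query [locus_template()].
#' @param scheme a [scoring_scheme()].
#' @param typing list of typing query sets, or `NULL` to skip typing:
#'   `list(full = c(O = seq, ...), antitoxin = c(O = seq, ...))`.
#' @param evalue_cutoff,max_targets search parameters.
#' @param max_gap cluster gap, nt.
#' @param full_cov,utr_slack,orphan_cov classification parameters.
#' @param thresholds locus-typing bit-score cutoffs.
#' @return a list: `calls` (one row per detected locus, with
#'   `assembly_id`, `on_plasmid`), `reports` (one row per assembly with
#'   `copy_number`, partial matches excluded), `partial` (calls classified
#'   partial, reported separately).
#' @export
screen_assemblies <- function(assemblies, template,
                              scheme = scoring_scheme(), typing = NULL,
                              evalue_cutoff = 10, max_targets = 10000L,
                              max_gap = 2000L, full_cov = 0.95,
                              utr_slack = 30L, orphan_cov = 0.8,
                              thresholds = c(full = 650, O = 280, P = 250)) {
  query <- stats::setNames(template$sequence, template$name)
  calls <- list()
  for (aid in names(assemblies)) {
    a <- assemblies[[aid]]
    hits <- seed_extend_search(query, a$replicons, scheme,
                               evalue_cutoff = evalue_cutoff,
                               max_targets = max_targets)
    profiles <- filter_spurious(cluster_hits(hits, max_gap), template)
    for (p in profiles) {
      call <- classify_locus(p, template, full_cov = full_cov,
                             utr_slack = utr_slack, orphan_cov = orphan_cov)
      if (!is.null(typing))
        call <- type_call(call, p, a, typing, scheme, thresholds)
      bh <- p$hits[which.max(p$hits$bitscore), ]
      call$qstart <- bh$qstart
      call$qend <- bh$qend
      call$aligned_q <- bh$aligned_q
      call$aligned_s <- bh$aligned_s
      call$assembly_id <- aid
      call$on_plasmid <- detect_plasmid(a$descriptions[[call$replicon_id]] %||% "")
      calls[[length(calls) + 1L]] <- call
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    cbind(classify_empty(), qstart = integer(), qend = integer(),
          aligned_q = character(), aligned_s = character(),
          assembly_id = character(), on_plasmid = logical())
  rownames(calls) <- NULL
  partial <- calls[calls$category == "partial", , drop = FALSE]
  counted <- calls[calls$category != "partial", , drop = FALSE]
  cn <- vapply(names(assemblies), function(aid)
    sum(counted$copy_units[counted$assembly_id == aid]), numeric(1))
  reports <- data.frame(assembly_id = names(assemblies),
                        copy_number = unname(cn), stringsAsFactors = FALSE)
  list(calls = counted, partial = partial, reports = reports)
}

classify_empty <- function() {
  data.frame(replicon_id = character(), strand = character(),
             category = character(), copy_units = numeric(),
             locus_type = character(), best_bit_score = numeric(),
             cluster_start = integer(), cluster_end = integer(),
             coverage = numeric(), stringsAsFactors = FALSE)
}

# Re-search the called cluster region with each typing query and apply the
# bit-score thresholds.
type_call <- function(call, profile, assembly, typing, scheme, thresholds) {
  rep_seq <- assembly$replicons[[call$replicon_id]]
  lo <- max(1L, call$cluster_start - 100L)
  hi <- min(nchar(rep_seq), call$cluster_end + 100L)
  region <- c(region = substr(rep_seq, lo, hi))
  queries <- if (call$category == "antitoxin_only") typing$antitoxin else
    typing$full
  scores <- vapply(names(queries), function(ty) {
    h <- seed_extend_search(stats::setNames(queries[[ty]], ty), region,
                            scheme, evalue_cutoff = Inf)
    if (nrow(h)) max(h$bitscore) else 0
  }, numeric(1))
  assign_locus_type(call, scores, thresholds)
}

#' Build typing query sets from locus templates
#'
#' @param templates named list (names are type labels) of
#'   [locus_template()] objects.
#' @return a `typing` list for [screen_assemblies()]: full-locus sequences
#'   and antitoxin-gene sequences per type.
#' @export
typing_queries <- function(templates) {
  full <- vapply(templates, function(t) t$sequence, character(1))
  anti <- vapply(templates, function(t)
    substr_iv(t$sequence, t$antitoxin_segment), character(1))
  list(full = full, antitoxin = anti)
}
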