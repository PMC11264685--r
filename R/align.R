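# Seed-and-extend local nucleotide search (BLASTn stand-in) and the
# Smith-Waterman oracle it is tested against.

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic-programming local alignment used as the internal oracle for
#' [seed_extend_search()]. A gap of length L costs `gap_open + L *
#' gap_extend`. Ties on the optimal score are broken by the smallest end
#' coordinate in `b`, then in `a`.
#'
#' @param a,b DNA strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return a list: `score`, `a_start`, `a_end`, `b_start`, `b_end` (1-based
#'   inclusive; all 0 when the optimal local score is 0), `a_aln`, `b_aln`
#'   (gapped strings).
#' @examples
#' smith_waterman("ACGT", "ACGA", scoring_scheme())$score  # 6, local "ACG"
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  sw_align_cpp(toupper(a), toupper(b), scheme$match, scheme$mismatch,
               scheme$gap_open, scheme$gap_extend,
               -nchar(a), nchar(b))
}

# Recompute the raw score of a gapped alignment (invariant check).
rescore_alignment <- function(a_aln, b_aln, scheme) {
  ca <- seq_chars(a_aln); cb <- seq_chars(b_aln)
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  valid <- c("A", "C", "G", "T")
  ident <- !gap & ca == cb & ca %in% valid
  score <- sum(ident) * scheme$match + sum(!gap & !ident) * scheme$mismatch
  runs <- rle(gap)
  ngaps <- sum(runs$values)
  score - ngaps * scheme$gap_open - sum(runs$lengths[runs$values]) * scheme$gap_extend
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), strand = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), raw = integer(), qcovs = numeric(),
             aligned_q = character(), aligned_s = character(),
             stringsAsFactors = FALSE)
}

# Greedy diagonal clustering of exact-word seeds. `seeds` has columns
# qstart, sstart (1-based); returns a list of integer index vectors.
cluster_seeds <- function(seeds, band, join_gap, word) {
  ord <- order(seeds[, "sstart"], seeds[, "qstart"])
  seeds <- seeds[ord, , drop = FALSE]
  d <- seeds[, "sstart"] - seeds[, "qstart"]
  clusters <- list()
  meta <- list()  # dmin, dmax, send
  for (k in seq_len(nrow(seeds))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      m <- meta[[ci]]
      if (d[k] >= m[1] - band && d[k] <= m[2] + band &&
          seeds[k, "sstart"] - m[3] <= join_gap) {
        clusters[[ci]] <- c(clusters[[ci]], k)
        meta[[ci]] <- c(min(m[1], d[k]), max(m[2], d[k]),
                        max(m[3], seeds[k, "sstart"] + word - 1L))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- k
      meta[[length(meta) + 1L]] <- c(d[k], d[k], seeds[k, "sstart"] + word - 1L)
    }
  }
  lapply(clusters, function(ix) seeds[ix, , drop = FALSE])
}

hit_from_alignment <- function(aln, qid, sid, strand, wlo, slen, qlen, scheme,
                               m, n) {
  ca <- seq_chars(aln$a_aln); cb <- seq_chars(aln$b_aln)
  gap <- ca == "-" | cb == "-"
  ident <- !gap & ca == cb
  s1 <- aln$b_start + wlo - 1L
  s2 <- aln$b_end + wlo - 1L
  if (strand == "-") {
    tmp <- s1
    s1 <- slen - s2 + 1L
    s2 <- slen - tmp + 1L
  }
  be <- bit_score_evalue(aln$score, scheme, m, n)
  runs <- rle(gap)
  data.frame(qseqid = qid, sseqid = sid, strand = strand,
             pident = 100 * sum(ident) / length(ca),
             length = length(ca),
             mismatch = sum(!gap & !ident),
             gapopen = sum(runs$values),
             qstart = aln$a_start, qend = aln$a_end,
             sstart = s1, send = s2,
             evalue = be$evalue, bitscore = be$bits, raw = aln$score,
             qcovs = (aln$a_end - aln$a_start + 1) / qlen,
             aligned_q = aln$a_aln, aligned_s = aln$b_aln,
             stringsAsFactors = FALSE)
}

#' Seed-and-extend local homology search
#'
#' BLASTn-like search of one query against a set of subject sequences:
#' exact `word_size`-mer seeding on both strands, greedy diagonal clustering
#' of seeds, ungapped X-drop extension to delimit the high-scoring region,
#' then banded gapped Smith-Waterman extension with traceback. Overlapping
#' hits on the same subject/strand are merged by keeping the higher-scoring
#' one; hits with E-value above `evalue_cutoff` are removed; at most
#' `max_targets` subjects are reported. For minus-strand hits `sstart` <
#' `send` still refer to the subject plus strand; `aligned_s` is written in
#' query orientation (reverse complement of the subject slice).
#'
#' @param query a single named DNA string (or an unnamed string, id
#'   `"query"`).
#' @param subjects a named character vector of DNA strings (or a
#'   `Biostrings::DNAStringSet`).
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff maximum reported E-value (default 10).
#' @param max_targets maximum number of distinct subjects reported
#'   (default 10000).
#' @param x_drop ungapped extension X-drop, raw score points.
#' @param band half-width of the gapped extension diagonal band.
#' @param seed_join_gap maximum subject gap joining seeds into one cluster.
#' @param pad extra window padding around a seed cluster, nt.
#' @return a data frame of hits sorted by (bitscore desc, sseqid, sstart),
#'   with BLAST outfmt-6 style columns plus `strand`, `raw`, `qcovs`,
#'   `aligned_q`, `aligned_s`.
#' @export
seed_extend_search <- function(query, subjects, scheme = scoring_scheme(),
                               evalue_cutoff = 10, max_targets = 10000L,
                               x_drop = 20L, band = 40L,
                               seed_join_gap = 200L, pad = 150L) {
  if (inherits(subjects, "DNAStringSet")) {
    nm <- names(subjects)
    subjects <- as.character(subjects)
    names(subjects) <- nm
  }
  qid <- names(query) %||% "query"
  if (is.null(names(query)) || !nzchar(qid)) qid <- "query"
  q <- toupper(unname(query[1]))
  if (nchar(q) == 0) stop("empty query", call. = FALSE)
  if (scheme$word_size > nchar(q))
    stop("word_size exceeds query length", call. = FALSE)
  if (length(subjects) == 0) stop("no subjects", call. = FALSE)
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  qlen <- nchar(q)
  n_total <- sum(nchar(subjects))
  out <- list()
  for (sid in names(subjects)) {
    s <- toupper(subjects[[sid]])
    slen <- nchar(s)
    for (strand in c("+", "-")) {
      so <- if (strand == "+") s else revcomp(s)
      seeds <- find_seeds_cpp(q, so, scheme$word_size)
      if (nrow(seeds) == 0) next
      for (cl in cluster_seeds(seeds, band, seed_join_gap, scheme$word_size)) {
        dmin <- min(cl[, "sstart"] - cl[, "qstart"])
        dmax <- max(cl[, "sstart"] - cl[, "qstart"])
        hsp <- ungapped_extend_cpp(q, so, cl[1, "qstart"], cl[1, "sstart"],
                                   scheme$word_size, scheme$match,
                                   scheme$mismatch, x_drop)
        wlo <- max(1L, min(min(cl[, "sstart"]) - (min(cl[, "qstart"]) - 1L),
                           hsp[["sstart"]]) - pad)
        whi <- min(slen,
                   max(max(cl[, "sstart"]) + scheme$word_size - 1L +
                         (qlen - (max(cl[, "qstart"]) + scheme$word_size - 1L)),
                       hsp[["send"]]) + pad)
        aln <- sw_align_cpp(q, substr(so, wlo, whi),
                            scheme$match, scheme$mismatch,
                            scheme$gap_open, scheme$gap_extend,
                            dmin - band - (wlo - 1L), dmax + band - (wlo - 1L))
        if (aln$score <= 0) next
        out[[length(out) + 1L]] <-
          hit_from_alignment(aln, qid, sid, strand, wlo, slen, qlen, scheme,
                             qlen, n_total)
      }
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- merge_overlapping_hits(hits)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (length(unique(hits$sseqid)) > max_targets) {
    best <- tapply(hits$bitscore, hits$sseqid, max)
    keep <- names(sort(best, decreasing = TRUE))[seq_len(max_targets)]
    hits <- hits[hits$sseqid %in% keep, , drop = FALSE]
  }
  hits <- hits[order(-hits$bitscore, hits$sseqid, hits$sstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Keep the higher-scoring of any two hits on the same subject and strand
# whose subject intervals overlap by more than half of the shorter one.
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  drop <- rep(FALSE, nrow(hits))
  ord <- order(-hits$raw)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (drop[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (drop[j]) next
      if (hits$sseqid[i] != hits$sseqid[j] || hits$strand[i] != hits$strand[j])
        next
      ov <- min(hits$send[i], hits$send[j]) - max(hits$sstart[i], hits$sstart[j]) + 1
      shorter <- min(hits$send[i] - hits$sstart[i], hits$send[j] - hits$sstart[j]) + 1
      if (ov > shorter / 2) drop[j] <- TRUE
    }
  }
  hits[!drop, , drop = FALSE]
}

#' Write / read hits in BLAST outfmt-6 layout
#'
#' Twelve tab-separated columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore), 1-based inclusive
#' coordinates; minus-strand hits have `sstart > send` in the file, as in
#' BLAST. The in-memory representation always has `sstart <= send` plus a
#' `strand` column.
#'
#' @param hits a hit data frame from [seed_extend_search()].
#' @param path file path.
#' @return `read_outfmt6` returns a hit data frame (without alignment
#'   strings); `write_outfmt6` returns `path` invisibly.
#' @export
write_outfmt6 <- function(hits, path) {
  tab <- hits[, c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")]
  minus <- hits$strand == "-"
  tab$sstart[minus] <- hits$send[minus]
  tab$send[minus] <- hits$sstart[minus]
  tab$pident <- sprintf("%.3f", tab$pident)
  tab$evalue <- signif(tab$evalue, 3)
  tab$bitscore <- sprintf("%.1f", tab$bitscore)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_outfmt6
#' @export
read_outfmt6 <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "mismatch", "gapopen", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore"))
  minus <- tab$sstart > tab$send
  tmp <- tab$sstart[minus]
  tab$sstart[minus] <- tab$send[minus]
  tab$send[minus] <- tmp
  tab$strand <- ifelse(minus, "-", "+")
  tab
}
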