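# Element-level conservation: mapping annotated intervals through gapped
# alignments, identity fractions, consensus/information-content matrices,
# ORF translation and protein variant tables.

#' Map an annotated query interval through a gapped alignment
#'
#' Walks the alignment columns of a hit and returns the subject residues
#' aligned to the query positions inside `element_interval`, with subject
#' gap characters removed. Returns `NULL` when the hit does not fully cover
#' the interval. Insertions in the subject (query gaps) inside the interval
#' make the observed string longer than the reference.
#'
#' @param hit one row of a hit data frame (needs `qstart`, `qend`,
#'   `aligned_q`, `aligned_s`).
#' @param element_interval query interval `c(start, end)`.
#' @return the observed subject string (query orientation), or `NULL`.
#' @export
map_element <- function(hit, element_interval) {
  if (hit$qstart > element_interval[1] || hit$qend < element_interval[2])
    return(NULL)
  qa <- seq_chars(hit$aligned_q)
  sa <- seq_chars(hit$aligned_s)
  if (length(qa) != length(sa)) stop("malformed gapped strings",
                                     call. = FALSE)
  qpos <- hit$qstart - 1L + cumsum(qa != "-")
  qpos[qa == "-"] <- NA_integer_
  # columns inside the element: query positions in range, plus query-gap
  # columns strictly between them (subject insertions)
  inside <- !is.na(qpos) & qpos >= element_interval[1] &
    qpos <= element_interval[2]
  first <- which(inside)[1]
  last <- tail(which(inside), 1)
  cols <- seq(first, last)
  obs <- sa[cols]
  paste(obs[obs != "-"], collapse = "")
}

#' Fraction of observations identical to a reference element
#'
#' @param observations character vector of observed element strings.
#' @param reference the reference string.
#' @return a list: `fraction_identical` and `variants`, a data frame of
#'   distinct observed strings ranked by frequency (ties broken
#'   lexicographically).
#' @export
element_identity <- function(observations, reference) {
  if (length(observations) == 0) stop("no observations", call. = FALSE)
  tab <- table(observations)
  variants <- data.frame(variant = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
  variants$frequency <- variants$count / sum(variants$count)
  variants <- variants[order(-variants$frequency, variants$variant), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  list(fraction_identical = mean(observations == reference),
       variants = variants)
}

IUPAC_FROM_SET <- c(A = "A", C = "C", G = "G", T = "T",
                    AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                    GT = "K", ACG = "V", ACT = "H", AGT = "D", CGT = "B",
                    ACGT = "N")

#' Per-column consensus and information content
#'
#' Builds the symbol-count matrix of an alignment (equal-length strings),
#' the modal consensus (nucleotide ties become IUPAC ambiguity codes,
#' protein ties `X`), and the per-column information content
#' `R_i = log2(|alphabet|) - H_i`, where the entropy `H_i` is computed over
#' non-gap symbols. Columns with more than half gaps are masked (`bits`
#' set to `NA`, consensus `-`). The small-sample correction
#' `(|alphabet| - 1) / (2 ln 2 n)` is off by default.
#'
#' @param seqs character vector of equal-length (gapped) strings.
#' @param alphabet `"dna"` or `"protein"`.
#' @param small_sample apply the small-sample correction.
#' @return an object of class `consensus_matrix`: list with `counts`
#'   (columns x symbols), `bits`, `consensus`, `n`.
#' @export
build_consensus <- function(seqs, alphabet = c("dna", "protein"),
                            small_sample = FALSE) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0) stop("no sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) stop("length mismatch",
                                             call. = FALSE)
  symbols <- if (alphabet == "dna") DNA_BASES else
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
      "R", "S", "T", "V", "W", "Y", "*")
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  ncol_aln <- ncol(mat)
  counts <- matrix(0L, nrow = ncol_aln, ncol = length(symbols) + 1L,
                   dimnames = list(NULL, c(symbols, "-")))
  bits <- numeric(ncol_aln)
  consensus <- character(ncol_aln)
  maxbits <- log2(length(symbols))
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    col[!col %in% c(symbols, "-")] <- "-"
    tab <- table(factor(col, levels = c(symbols, "-")))
    counts[j, ] <- as.integer(tab)
    ng <- tab[symbols]
    n_nongap <- sum(ng)
    if (n_nongap < length(col) / 2) {
      bits[j] <- NA_real_
      consensus[j] <- "-"
      next
    }
    f <- ng[ng > 0] / n_nongap
    h <- -sum(f * log2(f))
    r <- maxbits - h
    if (small_sample)
      r <- r - (length(symbols) - 1) / (2 * log(2) * n_nongap)
    bits[j] <- max(0, r)
    modal <- names(ng)[ng == max(ng)]
    consensus[j] <- if (length(modal) == 1) modal
    else if (alphabet == "dna")
      IUPAC_FROM_SET[[paste(sort(modal), collapse = "")]]
    else "X"
  }
  structure(list(counts = counts, bits = bits,
                 consensus = paste(consensus, collapse = ""),
                 n = length(seqs), alphabet = alphabet),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("consensus_matrix: %d sequences x %d columns (%s)\n", x$n,
              nrow(x$counts), x$alphabet))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Write a consensus matrix as TSV
#'
#' One row per alignment column: position, per-symbol counts, bits.
#'
#' @param cm a `consensus_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(cm, path) {
  df <- data.frame(position = seq_len(nrow(cm$counts)), cm$counts,
                   bits = cm$bits, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Standard genetic code, built from the canonical codon order
# (TTT, TTC, TTG, TTA, ...) independently of any external table.
GENETIC_CODE_TA <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

#' Translate a toxin ORF with the standard genetic code
#'
#' A trailing partial codon is trimmed (and flagged); translation stops at
#' the first stop codon, which is stripped from the reported protein. An
#' internal stop (before the final codon) flags the ORF as truncated so it
#' can be excluded from full-length variant tables. Codons containing `N`
#' translate to `X`.
#'
#' @param dna DNA string.
#' @return a list: `protein`, `truncated`, `partial_codon`.
#' @export
translate_orf <- function(dna) {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) stop("non-DNA symbols in ORF", call. = FALSE)
  partial <- nchar(dna) %% 3 != 0
  n_codons <- nchar(dna) %/% 3
  if (n_codons == 0) return(list(protein = "", truncated = FALSE,
                                 partial_codon = partial))
  codons <- substring(dna, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  aas <- GENETIC_CODE_TA[codons]
  aas[is.na(aas)] <- "X"  # N-containing codons
  stop_at <- which(aas == "*")[1]
  truncated <- !is.na(stop_at) && stop_at < n_codons
  if (!is.na(stop_at)) aas <- aas[seq_len(stop_at - 1)]
  list(protein = paste(aas, collapse = ""), truncated = truncated,
       partial_codon = partial)
}

#' Catalogue protein variants relative to a reference
#'
#' Variants are labelled by their substitutions relative to the reference
#' (e.g. `N2S`, `T3S`, multiple changes joined by `+`); the unchanged
#' protein is labelled `reference`. All inputs must be full length (equal
#' to the reference); exclude truncated ORFs upstream.
#'
#' @param proteins character vector of amino-acid strings.
#' @param reference reference amino-acid string.
#' @return a data frame: `label`, `protein`, `count`, `frequency`, sorted
#'   by frequency (ties lexicographically by label).
#' @export
protein_variants <- function(proteins, reference) {
  stopifnot(length(proteins) > 0)
  if (any(nchar(proteins) != nchar(reference)))
    stop("all proteins must match the reference length", call. = FALSE)
  ref <- seq_chars(reference)
  label_of <- function(p) {
    ch <- seq_chars(p)
    d <- which(ch != ref)
    if (length(d) == 0) "reference" else
      paste(paste0(ref[d], d, ch[d]), collapse = "+")
  }
  tab <- table(proteins)
  out <- data.frame(protein = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$label <- vapply(out$protein, label_of, character(1))
  out$frequency <- out$count / sum(out$count)
  out <- out[order(-out$frequency, out$label),
             c("label", "protein", "count", "frequency")]
  rownames(out) <- NULL
  out
}

#' Element conservation across a set of full-locus hits
#'
#' Maps every annotated element of the template through each hit, then
#' summarizes per-element identity and variants. Loci whose hit does not
#' fully cover an element are excluded from that element's denominator
#' (their count is reported).
#'
#' @param hits hit data frame (typically the best full hit per locus).
#' @param template the query [locus_template()].
#' @return a data frame: `element`, `reference`, `n`, `n_uncovered`,
#'   `fraction_identical`, `top_variants` (text `variant:freq` list).
#' @export
element_conservation <- function(hits, template) {
  rows <- lapply(seq_len(nrow(template$elements)), function(k) {
    el <- template$elements[k, ]
    obs <- character()
    n_uncov <- 0L
    for (i in seq_len(nrow(hits))) {
      o <- map_element(hits[i, ], c(el$start, el$end))
      if (is.null(o)) n_uncov <- n_uncov + 1L else obs <- c(obs, o)
    }
    if (length(obs) == 0)
      return(data.frame(element = el$name, reference = el$ref, n = 0L,
                        n_uncovered = n_uncov, fraction_identical = NA_real_,
                        top_variants = "", stringsAsFactors = FALSE))
    ei <- element_identity(obs, el$ref)
    topv <- head(ei$variants, 3)
    data.frame(element = el$name, reference = el$ref, n = length(obs),
               n_uncovered = n_uncov,
               fraction_identical = ei$fraction_identical,
               top_variants = paste(sprintf("%s:%.3f", topv$variant,
                                            topv$frequency),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
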