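# Scoring schemes and Karlin-Altschul normalization.

#' Nucleotide scoring scheme
#'
#' Bundles the match/mismatch rewards, affine gap costs, seeding word size
#' and the Karlin-Altschul parameters used to convert raw alignment scores
#' into bit scores and E-values. Defaults mirror the megablast-era `blastn`
#' task: reward +2, penalty -3, gap open 5, gap extend 2, word size 11.
#' `lambda` is computed from the substitution scores and the background
#' composition unless supplied; `K` is a user-set constant (default 0.41,
#' the standard value for +2/-3).
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch penalty.
#' @param gap_open non-negative gap opening cost (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param gap_extend non-negative per-residue gap extension cost.
#' @param word_size exact-match seed length (>= 4).
#' @param lambda Karlin-Altschul lambda; computed by [karlin_lambda()] when
#'   `NULL`.
#' @param K Karlin-Altschul K.
#' @param background base frequencies for A, C, G, T used when computing
#'   lambda.
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(match = 1, mismatch = -1)$lambda  # log(3)
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, word_size = 11L,
                           lambda = NULL, K = 0.41,
                           background = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            word_size >= 4, K > 0,
            length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  sch <- structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size), K = K,
         background = background),
    class = "scoring_scheme")
  sch$lambda <- if (is.null(lambda)) karlin_lambda(sch, background) else lambda
  stopifnot(sch$lambda > 0)
  sch
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "scoring_scheme: match %+d mismatch %+d gap %d/%d word %d lambda %.4f K %.3f\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$word_size, x$lambda, x$K))
  invisible(x)
}

#' Karlin-Altschul lambda for an ungapped scoring scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s(i, j)) = 1` for the unique positive
#' root, where `s(i, j)` is `match` on the diagonal and `mismatch` off it.
#' Requires a negative expected score under the background composition.
#'
#' @param scheme a [scoring_scheme()] (its `lambda`/`K` slots are ignored).
#' @param background base frequencies for A, C, G, T.
#' @param tol root-finding tolerance.
#' @return the positive real lambda.
#' @examples
#' karlin_lambda(scoring_scheme(match = 1, mismatch = -1, lambda = 1)) # log(3)
#' @export
karlin_lambda <- function(scheme, background = scheme$background,
                          tol = 1e-12) {
  p <- background / sum(background)
  p_match <- sum(p^2)
  p_mis <- 1 - p_match
  es <- p_match * scheme$match + p_mis * scheme$mismatch
  if (es >= 0)
    stop("expected score is non-negative; lambda does not exist", call. = FALSE)
  f <- function(l) p_match * exp(l * scheme$match) +
    p_mis * exp(l * scheme$mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(1e-12, hi), tol = tol)$root
}

#' Bit score and E-value from a raw alignment score
#'
#' `bits = (lambda * raw - log(K)) / log(2)`; `evalue = m * n * 2^-bits`
#' with the raw `m * n` search space (no finite-size length adjustment).
#'
#' @param raw integer raw score.
#' @param scheme a [scoring_scheme()] with `lambda` and `K` set.
#' @param m query length.
#' @param n total subject length in the search.
#' @return a list with elements `bits` and `evalue`.
#' @export
bit_score_evalue <- function(raw, scheme, m, n) {
  bits <- (scheme$lambda * raw - log(scheme$K)) / log(2)
  list(bits = bits, evalue = m * n * 2^(-bits))
}
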