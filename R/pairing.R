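# Antitoxin-to-toxin base-pairing repression potential: a gapless antisense
# scan scored by the experimentally derived sufficiency rule (15 nt of
# contiguous pairing, or a 17-nt window with one internal mismatch).

pair_ok <- function(a, t, wobble) {
  # a: antitoxin base (5'->3', reversed), t: toxin base; Watson-Crick
  wc <- (a == "A" & t == "T") | (a == "T" & t == "A") |
    (a == "G" & t == "C") | (a == "C" & t == "G")
  if (wobble) wc <- wc | (a == "G" & t == "T") | (a == "T" & t == "G")
  wc
}

best_windows_from_matches <- function(m) {
  # m: logical vector of paired positions along the toxin window
  best_c <- 0L
  ci <- c(0L, 0L)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] > best_c) {
      best_c <- r$lengths[k]
      ci <- c(starts[k], ends[k])
    }
  }
  # longest window with at most one internal mismatch: a TRUE run, a single
  # FALSE, then a TRUE run (both runs non-empty keeps the mismatch internal)
  best_m <- best_c
  mi <- ci
  for (k in seq_along(r$values)) {
    if (!r$values[k] && r$lengths[k] == 1L && k > 1 && k < length(r$values) &&
        r$values[k - 1] && r$values[k + 1]) {
      len <- r$lengths[k - 1] + 1L + r$lengths[k + 1]
      if (len > best_m) {
        best_m <- len
        mi <- c(starts[k - 1], ends[k + 1])
      }
    }
  }
  list(contiguous = list(length = best_c, window = ci),
       one_mismatch = list(length = best_m, window = mi))
}

#' Best antisense duplex between an antitoxin and a toxin region
#'
#' Slides the antitoxin antisense against the toxin region at every offset
#' (gapless; no bulges) and reports the longest run of consecutive
#' Watson-Crick pairs and the longest window containing at most one
#' internal mismatch. Coordinates are 1-based on each input.
#'
#' @param antitoxin,toxin DNA strings (the antitoxin pairs with the toxin
#'   via reverse-complementarity).
#' @param wobble also count G:U (G:T in DNA space) pairs.
#' @return a list of class `pairing_assessment`: `contiguous` and
#'   `one_mismatch`, each with `length`, `toxin_interval`,
#'   `antitoxin_interval`.
#' @export
best_duplex <- function(antitoxin, toxin, wobble = FALSE) {
  stopifnot(nchar(antitoxin) > 0, nchar(toxin) > 0)
  ar <- rev(seq_chars(antitoxin))  # reversed, so position i pairs toxin j
  tc <- seq_chars(toxin)
  la <- length(ar)
  lt <- length(tc)
  best <- list(contiguous = list(length = 0L, toxin_interval = c(0L, 0L),
                                 antitoxin_interval = c(0L, 0L)),
               one_mismatch = list(length = 0L, toxin_interval = c(0L, 0L),
                                   antitoxin_interval = c(0L, 0L)))
  for (off in (1 - la):(lt - 1)) {
    # antitoxin reversed index i aligns toxin index i + off
    i1 <- max(1L, 1L - off)
    i2 <- min(la, lt - off)
    if (i2 < i1) next
    idx <- i1:i2
    m <- pair_ok(ar[idx], tc[idx + off], wobble)
    bw <- best_windows_from_matches(m)
    for (kind in c("contiguous", "one_mismatch")) {
      b <- bw[[kind]]
      if (b$length > best[[kind]]$length) {
        wi <- idx[b$window]  # indices into reversed antitoxin
        best[[kind]] <- list(
          length = b$length,
          toxin_interval = c(wi[1] + off, wi[2] + off),
          antitoxin_interval = c(la - wi[2] + 1L, la - wi[1] + 1L))
      }
    }
  }
  structure(best, class = "pairing_assessment")
}

#' @export
print.pairing_assessment <- function(x, ...) {
  cat(sprintf("pairing: contiguous %d nt; one-internal-mismatch %d nt; %s\n",
              x$contiguous$length, x$one_mismatch$length,
              if (is_repressive(x)) "repressive" else "not repressive"))
  invisible(x)
}

#' Repression-potential call
#'
#' An antitoxin is deemed able to repress its cognate toxin when it can form
#' at least `min_contiguous` (15) nt of continuous base pairing, or a
#' discontinuous window of at least `min_one_mismatch` (17) nt containing a
#' single internal mismatch.
#'
#' @param assessment a `pairing_assessment` from [best_duplex()].
#' @param min_contiguous contiguous-pairing threshold, nt.
#' @param min_one_mismatch one-internal-mismatch window threshold, nt.
#' @return logical flag.
#' @export
is_repressive <- function(assessment, min_contiguous = 15L,
                          min_one_mismatch = 17L) {
  assessment$contiguous$length >= min_contiguous ||
    assessment$one_mismatch$length >= min_one_mismatch
}

#' Repression potential of a planted or observed locus
#'
#' Convenience wrapper: extracts the antitoxin gene and the toxin 5' UTR
#' pairing target from a [locus_template()] (or uses mapped observed
#' strings) and applies [best_duplex()] + [is_repressive()].
#'
#' @param template a [locus_template()] with a `pairing` element.
#' @param antitoxin,toxin optional observed strings overriding the template
#'   slices.
#' @param wobble count G:U pairs.
#' @return a list: `assessment`, `repressive`.
#' @export
assess_pairing <- function(template, antitoxin = NULL, toxin = NULL,
                           wobble = FALSE) {
  if (is.null(antitoxin))
    antitoxin <- substr_iv(template$sequence, template$antitoxin_segment)
  if (is.null(toxin)) {
    iv <- element_interval(template, "pairing") %||% template$utr_segment
    toxin <- substr_iv(template$sequence, iv)
  }
  a <- best_duplex(antitoxin, toxin, wobble = wobble)
  list(assessment = a, repressive = is_repressive(a))
}
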