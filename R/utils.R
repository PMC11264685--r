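# Shared helpers: local RNG scoping, DNA string utilities, interval checks.

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Reverse complement of a DNA string
#'
#' @param x a single character string over the DNA alphabet (ambiguous
#'   residues other than `N` are passed through `N`).
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  comp <- DNA_COMPLEMENT[ch]
  comp[is.na(comp)] <- "N"
  paste(comp, collapse = "")
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# 1-based inclusive interval c(start, end); width helper
iv_width <- function(iv) iv[2] - iv[1] + 1L

check_interval <- function(iv, len, what = "interval") {
  if (length(iv) != 2L || any(is.na(iv)) || iv[1] < 1L || iv[2] > len ||
      iv[1] > iv[2])
    stop(sprintf("%s [%s] out of bounds for length %d", what,
                 paste(iv, collapse = ", "), len), call. = FALSE)
  invisible(iv)
}

substr_iv <- function(x, iv) substr(x, iv[1], iv[2])

`%||%` <- function(a, b) if (is.null(a)) b else a
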