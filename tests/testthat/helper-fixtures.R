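# Shared fixtures: all synthetic material is built in code at test time.

default_scheme <- function() scoring_scheme()

# A random query/subject pair with a planted exact shared segment.
planted_pair <- function(seed, qlen = 150, seg_len = 30, flank = 80) {
  q <- generate_background(qlen, 0.5, seed)
  at <- min(50, qlen - seg_len)
  seg <- substr(q, at, at + seg_len - 1)
  subj <- paste0(generate_background(flank, 0.5, seed + 1000), seg,
                 generate_background(flank, 0.5, seed + 2000))
  list(q = q, subj = subj, seg = seg)
}

# Independent bisection solver for the Karlin-Altschul lambda equation.
bisect_lambda <- function(match, mismatch, p = rep(0.25, 4), tol = 1e-9) {
  pm <- sum(p^2)
  f <- function(l) pm * exp(l * match) + (1 - pm) * exp(l * mismatch) - 1
  lo <- 1e-9
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force duplex oracle: enumerate every (offset, window) of the
# reverse-complemented antitoxin against the toxin region.
brute_duplex <- function(antitoxin, toxin) {
  rc <- strsplit(tascan::revcomp(antitoxin), "")[[1]]
  tc <- strsplit(toupper(toxin), "")[[1]]
  la <- length(rc)
  lt <- length(tc)
  best_c <- 0L
  best_m <- 0L
  for (off in (-la + 1):(lt - 1)) {
    i1 <- max(1, 1 - off)
    i2 <- min(la, lt - off)
    if (i2 < i1) next
    m <- rc[i1:i2] == tc[(i1:i2) + off]
    n <- length(m)
    for (a in seq_len(n)) for (b in a:n) {
      w <- m[a:b]
      len <- b - a + 1
      if (all(w) && len > best_c) best_c <- len
      if (sum(!w) <= 1 && len > best_m &&
          (all(w) || (which(!w) > 1 && which(!w) < len)))
        best_m <- len
    }
  }
  list(contiguous = best_c, one_mismatch = best_m)
}

# Toy grouped data used across mcstats tests.
toy_groups <- function() {
  grouped_data(c(1, 2, 3, 4, 3, 5, 6, 5, 7),
               rep(c("a", "b", "c"), each = 3))
}
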