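# Monte Carlo one-way ANOVA (label shuffling) and a Monte Carlo Tukey-style
# maximum-studentized-range pairwise test for copy-number differences.

#' Grouped copy-number data
#'
#' @param values numeric copy numbers (non-negative multiples of 0.5 in
#'   typical use; treated as plain numerics).
#' @param labels group labels, same length; observations with `NA` labels
#'   are dropped.
#' @return an object of class `grouped_data` (list with `values`, `labels`,
#'   `groups`, `sizes`).
#' @export
grouped_data <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  ok <- !is.na(labels) & !is.na(values)
  values <- values[ok]
  labels <- as.character(labels[ok])
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  structure(list(values = values, labels = labels,
                 groups = names(sizes), sizes = as.integer(sizes)),
            class = "grouped_data")
}

anova_terms <- function(values, labels, groups) {
  N <- length(values)
  k <- length(groups)
  gsum <- vapply(groups, function(g) sum(values[labels == g]), numeric(1))
  n <- vapply(groups, function(g) sum(labels == g), numeric(1))
  G <- sum(values)
  ssb <- sum(gsum^2 / n) - G^2 / N
  sst <- sum(values^2) - G^2 / N
  ssw <- sst - ssb
  list(ssb = ssb, ssw = ssw, df1 = k - 1, df2 = N - k, n = n, gsum = gsum)
}

#' One-way ANOVA F statistic
#'
#' @param data a [grouped_data()] object.
#' @return the classic F = between-group MS / within-group MS. Zero
#'   within-group variance signals an error (F undefined).
#' @export
f_statistic <- function(data) {
  tr <- anova_terms(data$values, data$labels, data$groups)
  if (tr$ssw <= 0)
    stop("zero within-group variance: F undefined", call. = FALSE)
  (tr$ssb / tr$df1) / (tr$ssw / tr$df2)
}

# F from a permuted value vector given fixed group index slices; SST and
# group sizes are shuffle-invariant.
f_from_perm <- function(xp, slices, n, inv) {
  gsum <- vapply(slices, function(ix) sum(xp[ix]), numeric(1))
  ssb <- sum(gsum^2 / n) - inv$g2n
  ((ssb) / inv$df1) / ((inv$sst - ssb) / inv$df2)
}

perm_invariants <- function(data) {
  N <- length(data$values)
  k <- length(data$groups)
  lab <- data$labels
  slices <- lapply(data$groups, function(g) which(lab == g))
  list(slices = slices, n = vapply(slices, length, numeric(1)),
       inv = list(g2n = sum(data$values)^2 / N,
                  sst = sum(data$values^2) - sum(data$values)^2 / N,
                  df1 = k - 1, df2 = N - k))
}

#' Monte Carlo one-way ANOVA
#'
#' Compares the observed F statistic to its distribution under
#' `iterations` uniformly random label shuffles that preserve the group
#' sizes; the global p-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + iterations)`.
#'
#' @param data a [grouped_data()] object.
#' @param iterations number of shuffles (default 10000).
#' @param seed integer seed (mandatory for reproducibility).
#' @return an object of class `group_comparison`: `observed_f`, `null_f`,
#'   `p_value`, `iterations`, `seed`.
#' @export
mc_anova <- function(data, iterations = 10000L, seed = 1L) {
  obs <- f_statistic(data)
  pv <- perm_invariants(data)
  null_f <- with_seed(seed, {
    vapply(seq_len(iterations), function(b)
      f_from_perm(sample(data$values), pv$slices, pv$n, pv$inv),
      numeric(1))
  })
  structure(list(observed_f = obs, null_f = null_f,
                 p_value = (1 + sum(null_f >= obs)) / (1 + iterations),
                 iterations = iterations, seed = seed,
                 groups = data$groups, sizes = data$sizes),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo ANOVA: F = %.4f, p = %.4g (%d shuffles, %d groups)\n",
    x$observed_f, x$p_value, x$iterations, length(x$groups)))
  invisible(x)
}

#' Monte Carlo Tukey-style pairwise test
#'
#' The observed statistic per group pair is the studentized mean difference
#' `q_ij = |mean_i - mean_j| / sqrt(MS_within (1/n_i + 1/n_j) / 2)`; the
#' null distribution is the MAXIMUM q over all pairs under label shuffling
#' (family-wise control); each pairwise p-value is
#' `(1 + #(max-null >= q_ij)) / (1 + iterations)`.
#'
#' @param data a [grouped_data()] object.
#' @param iterations number of shuffles (default 10000).
#' @param seed integer seed.
#' @return a data frame: `group1`, `group2`, `q`, `mean_diff`, `p_value`.
#' @export
mc_tukey <- function(data, iterations = 10000L, seed = 1L) {
  pv <- perm_invariants(data)
  pairs <- combn(seq_along(data$groups), 2)
  q_of <- function(xp) {
    gsum <- vapply(pv$slices, function(ix) sum(xp[ix]), numeric(1))
    means <- gsum / pv$n
    ssb <- sum(gsum^2 / pv$n) - pv$inv$g2n
    msw <- (pv$inv$sst - ssb) / pv$inv$df2
    if (msw <= 0) stop("zero within-group variance: q undefined",
                       call. = FALSE)
    apply(pairs, 2, function(ij)
      abs(means[ij[1]] - means[ij[2]]) /
        sqrt(msw * (1 / pv$n[ij[1]] + 1 / pv$n[ij[2]]) / 2))
  }
  q_obs <- q_of(data$values)
  max_null <- with_seed(seed, vapply(seq_len(iterations), function(b)
    max(q_of(sample(data$values))), numeric(1)))
  means <- vapply(pv$slices, function(ix) mean(data$values[ix]), numeric(1))
  data.frame(
    group1 = data$groups[pairs[1, ]], group2 = data$groups[pairs[2, ]],
    mean_diff = means[pairs[1, ]] - means[pairs[2, ]],
    q = q_obs,
    p_value = vapply(q_obs, function(q)
      (1 + sum(max_null >= q)) / (1 + iterations), numeric(1)),
    stringsAsFactors = FALSE)
}

# All distinct assignments of `values` to groups with the given sizes,
# enumerated as index sets (combinadic recursion).
enumerate_assignments <- function(N, sizes) {
  if (length(sizes) == 1) return(list(list(seq_len(N))))
  total <- round(exp(lgamma(N + 1) - sum(lgamma(sizes + 1))))
  if (total > 1e6) stop("too many permutations to enumerate", call. = FALSE)
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1) return(list(list(avail)))
    first <- combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- recurse(setdiff(avail, f), sizes[-1])
      for (r in rest) out[[length(out) + 1L]] <- c(list(f), r)
    }
    out
  }
  recurse(seq_len(N), sizes)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every distinct assignment of the observed values to groups
#' preserving the group sizes and returns the exact proportion of
#' assignments whose statistic is at least the observed one (the identity
#' assignment is included, so the p-value is never zero).
#'
#' @param data a [grouped_data()] object.
#' @param statistic function of (values, labels, groups) -> scalar; default
#'   the one-way F.
#' @return exact p-value.
#' @export
exhaustive_permutation_p <- function(data, statistic = NULL) {
  if (is.null(statistic))
    statistic <- function(values, labels, groups)
      f_statistic(grouped_data(values, labels))
  obs <- statistic(data$values, data$labels, data$groups)
  # enumerate which observation indices receive each group label
  sizes <- data$sizes
  assigns <- enumerate_assignments(length(data$values), sizes)
  hits <- 0L
  labs <- character(length(data$values))
  for (a in assigns) {
    for (g in seq_along(a)) labs[a[[g]]] <- data$groups[g]
    s <- statistic(data$values, labs, data$groups)
    if (s >= obs - 1e-12) hits <- hits + 1L
  }
  hits / length(assigns)
}
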