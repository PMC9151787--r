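# Independent oracles used to validate the package's implementations.
# These deliberately avoid the dynamic-programming / closed-form routes
# taken by the package itself.

# Weighted Levenshtein by exhaustive enumeration of all monotone pairings:
# choose k positions in each sequence (order-preserving alignment), pay the
# substitution cost for each matched pair and 1 per unmatched symbol. Valid
# whenever substitution costs are <= 1 (so matching is never worse than
# delete + insert), which holds for all LSI cost models here.
oracle_wld <- function(a, b, cost_matrix) {
  n <- length(a)
  m <- length(b)
  ai <- match(a, rownames(cost_matrix))
  bi <- match(b, colnames(cost_matrix))
  best <- n + m
  for (k in seq_len(min(n, m))) {
    ia <- combn(n, k)
    ib <- combn(m, k)
    for (ci in seq_len(ncol(ia))) {
      for (cj in seq_len(ncol(ib))) {
        subs <- sum(cost_matrix[cbind(ai[ia[, ci]], bi[ib[, cj]])])
        best <- min(best, subs + (n - k) + (m - k))
      }
    }
  }
  best
}

# Adjusted Rand index by brute-force pair counting.
oracle_ari <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (!sx && !sy) n00 <- n00 + 1
      else if (sx) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Exact Mann-Whitney U null by full enumeration of rank assignments.
oracle_mw_null <- function(n1, n2) {
  ranks <- combn(n1 + n2, n1)
  u <- colSums(ranks) - n1 * (n1 + 1) / 2
  counts <- tabulate(u + 1L, nbins = n1 * n2 + 1L)
  counts
}

# Small deterministic fixtures -------------------------------------------

toy_dictionary <- function() {
  unit_dictionary(
    c("A", "B", "C", "D"),
    matrix(c(0.5, 1.0, 1.5, 2.0,
             200, 400, 600, 800,
             10, 20, 30, 40), nrow = 4,
           dimnames = list(NULL, c("duration_s", "peak_frequency_hz",
                                   "fm_extent_hz"))))
}

# two cycles, two themes, theme 2 of cycle 1 has a single repetition
toy_phrases <- function() {
  data.frame(
    cycle_id = c("c1", "c1", "c1", "c2", "c2", "c2", "c2"),
    singer_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s2"),
    population = c("EA", "EA", "EA", "NC", "NC", "NC", "NC"),
    year = 2009L,
    song_type = "Purple",
    theme_id = c(1L, 1L, 2L, 1L, 1L, 2L, 2L),
    phrase_index = c(0L, 1L, 0L, 0L, 1L, 0L, 1L),
    unit_sequence = c("A B", "A B", "C D", "A B", "A B", "C D", "C D"),
    phrase_duration_s = c(2, 2, 3.5, 2, 2, 3.5, 3.5),
    cycle_duration_s = c(10, 10, 10, 14, 14, 14, 14),
    stringsAsFactors = FALSE)
}

toy_corpus <- function() song_corpus(toy_phrases(), toy_dictionary())

# substitution cost object with a single off-unit cost, for hand examples
manual_costs <- function(labels, pairs = list(), default = 1) {
  n <- length(labels)
  cost <- matrix(default, n, n, dimnames = list(labels, labels))
  diag(cost) <- 0
  for (p in pairs) {
    cost[p[[1]], p[[2]]] <- p[[3]]
    cost[p[[2]], p[[1]]] <- p[[3]]
  }
  structure(list(labels = labels, cost = cost, beta = 1),
            class = "substitution_costs")
}
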