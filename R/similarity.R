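# Levenshtein-distance similarity index (LSI) machinery.
#
# Phrase-level comparisons are weighted: substituting one unit for another
# costs the normalized acoustic distance between the two unit types raised
# to the exponent beta (beta = 1 by default), so that confusing two
# acoustically similar units is penalized less than substituting unrelated
# ones. Insertions and deletions always cost 1. Theme-sequence comparisons
# are unweighted (every substitution costs 1).

#' Acoustic substitution costs for a unit dictionary
#'
#' Features are z-scored per feature across the dictionary, pairwise
#' Euclidean distances are computed in the standardized feature space and
#' divided by the maximum pairwise distance, and the normalized distance is
#' raised to the power `beta`. Identical feature vectors give cost 0; the
#' most dissimilar pair of units gives cost 1 for any `beta`. With
#' `beta = 0`, every non-identical pair costs 1 and the weighted LSI reduces
#' to the unweighted one.
#'
#' @param dictionary a [unit_dictionary()].
#' @param beta non-negative weighting exponent (default 1).
#' @return An object of class `substitution_costs`: list with `labels`,
#'   `cost` (symmetric matrix in `[0, 1]` with zero diagonal) and `beta`.
#' @export
unit_similarity_costs <- function(dictionary, beta = 1) {
  stopifnot(inherits(dictionary, "unit_dictionary"), beta >= 0)
  f <- dictionary$features
  sds <- apply(f, 2, sd)
  if (all(sds == 0))
    stop("all acoustic features have zero variance across the dictionary")
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(f)[sds == 0], collapse = ", "))
    f <- f[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(f)
  d <- as.matrix(dist(z))
  mx <- max(d)
  if (mx == 0) stop("all units have identical features")
  cost <- (d / mx)^beta
  diag(cost) <- 0
  dimnames(cost) <- list(dictionary$labels, dictionary$labels)
  structure(list(labels = dictionary$labels, cost = cost, beta = beta),
            class = "substitution_costs")
}

#' Unweighted (0/1) substitution costs over a label set
#'
#' @param labels character vector of unit or theme labels.
#' @return A `substitution_costs` object whose substitutions all cost 1.
#' @export
identity_costs <- function(labels) {
  labels <- as.character(unique(labels))
  n <- length(labels)
  cost <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(cost) <- 0
  structure(list(labels = labels, cost = cost, beta = 0),
            class = "substitution_costs")
}

encode_seq <- function(x, labels) {
  idx <- match(x, labels)
  if (anyNA(idx))
    stop("label(s) not covered by substitution costs: ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  as.integer(idx)
}

#' Weighted Levenshtein distance
#'
#' Dynamic-programming edit distance between two label sequences with
#' insertion and deletion cost 1 and substitution cost taken from `costs`.
#' With all substitution costs equal to 1 this is the classic Levenshtein
#' distance.
#'
#' @param a,b character vectors of labels.
#' @param costs a `substitution_costs` object covering every label in `a`
#'   and `b`.
#' @return Non-negative numeric distance.
#' @export
weighted_levenshtein <- function(a, b, costs) {
  stopifnot(inherits(costs, "substitution_costs"))
  wld_cpp(encode_seq(a, costs$labels), encode_seq(b, costs$labels),
          costs$cost)
}

#' Levenshtein-distance similarity index (LSI)
#'
#' `LSI(a, b) = 1 - WLD(a, b) / max(length(a), length(b))`, where WLD is the
#' (weighted) Levenshtein distance. Identical sequences score 1; sequences
#' with no shared or acoustically similar material score 0. With
#' `costs = NULL` the unweighted form is used, as for theme sequences.
#'
#' @param a,b non-empty character vectors of labels.
#' @param costs a `substitution_costs` object, or `NULL` for the unweighted
#'   index.
#' @return Similarity in `[0, 1]`.
#' @export
lsi <- function(a, b, costs = NULL) {
  if (length(a) == 0L || length(b) == 0L)
    stop("LSI is undefined for empty sequences")
  if (is.null(costs)) costs <- identity_costs(c(a, b))
  1 - weighted_levenshtein(a, b, costs) / max(length(a), length(b))
}

#' Pairwise LSI matrix
#'
#' Computes the full symmetric matrix of LSI values over a set of sequences
#' (phrases, or theme sequences of song cycles), evaluating each unordered
#' pair once.
#'
#' @param items list of non-empty character vectors; names (or `ids`) give
#'   the item identifiers.
#' @param costs a `substitution_costs` object, or `NULL` for the unweighted
#'   index.
#' @param ids optional character vector of item identifiers.
#' @param level label recorded on the result, conventionally
#'   `"phrase_weighted"` or `"theme_sequence_unweighted"`.
#' @return An object of class `similarity_matrix`: list with `item_ids`,
#'   `values` (symmetric, unit diagonal, entries in `[0, 1]`) and `level`.
#' @export
pairwise_lsi_matrix <- function(items, costs = NULL, ids = names(items),
                                level = if (is.null(costs))
                                  "theme_sequence_unweighted" else
                                  "phrase_weighted") {
  if (length(items) < 2L) stop("need at least 2 items")
  if (any(lengths(items) == 0L)) stop("empty sequence among items")
  if (is.null(ids)) ids <- paste0("item", seq_along(items))
  if (is.null(costs)) costs <- identity_costs(unlist(items))
  enc <- lapply(items, encode_seq, labels = costs$labels)
  wld <- pairwise_wld_cpp(enc, costs$cost)
  len <- lengths(items)
  values <- 1 - wld / outer(len, len, pmax)
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  structure(list(item_ids = ids, values = values, level = level),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("LSI similarity matrix (", x$level, "): ", length(x$item_ids),
      " items, mean off-diagonal similarity ",
      round(mean(x$values[lower.tri(x$values)]), 3), "\n", sep = "")
  invisible(x)
}

#' Convert a similarity matrix to distances
#'
#' @param sim a `similarity_matrix`.
#' @return A [stats::dist] object of `1 - LSI` values.
#' @export
lsi_dist <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  as.dist(1 - sim$values)
}

#' Export a similarity matrix as TSV
#'
#' Writes item ids as header row and first column, with the lower triangle
#' and diagonal populated to 6 decimals (upper triangle left empty).
#'
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  v <- sim$values
  ch <- matrix("", nrow(v), ncol(v))
  lw <- lower.tri(v, diag = TRUE)
  ch[lw] <- formatC(v[lw], digits = 6, format = "f")
  out <- cbind(sim$item_ids, ch)
  writeLines(c(paste(c("item_id", sim$item_ids), collapse = "\t"),
               apply(out, 1, paste, collapse = "\t")), path)
  invisible(path)
}
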