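# Cluster-based verification of theme and song-type assignments.
# Distances are 1 - LSI; trees are average-linkage (UPGMA) and validated
# with the cophenetic correlation coefficient. Cluster support comes from an
# ordinary bootstrap over items: resampling sequences with replacement,
# reclustering the induced distance submatrix, and matching leaf sets.

as_distance <- function(x) {
  if (inherits(x, "similarity_matrix")) return(lsi_dist(x))
  if (inherits(x, "dist")) return(x)
  if (is.matrix(x)) {
    if (!isSymmetric(unname(x)) || any(diag(x) != 0))
      stop("distance matrix must be symmetric with zero diagonal")
    return(as.dist(x))
  }
  stop("cannot interpret input as distances")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Builds the UPGMA merge tree of a distance or LSI matrix and checks the
#' monotonicity of merge heights (guaranteed for average linkage).
#'
#' @param x a `similarity_matrix` (converted to distances `1 - LSI`), a
#'   [stats::dist] object, or a symmetric zero-diagonal distance matrix.
#' @return An object of class `song_dendrogram`: list with `hclust` (the
#'   [stats::hclust] tree), `dist` (the input distances) and `support`
#'   (`NULL` until [bootstrap_support()] fills it).
#' @export
average_linkage <- function(x) {
  d <- as_distance(x)
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  if (attr(d, "Size") < 2L) stop("need at least 2 items")
  h <- hclust(d, method = "average")
  if (is.unsorted(h$height, strictly = FALSE))
    stop("internal error: non-monotone average-linkage merge heights")
  structure(list(hclust = h, dist = d, support = NULL),
            class = "song_dendrogram")
}

#' @export
print.song_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram:", length(x$hclust$labels), "leaves, root height",
      round(max(x$hclust$height), 4),
      if (!is.null(x$support)) "(with bootstrap support)" else "", "\n")
  invisible(x)
}

#' Cophenetic correlation coefficient (CCC)
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic (merge-height) distances of the dendrogram. CCC above 0.8 is
#' conventionally read as the tree representing the associations in the
#' data well.
#'
#' @param x the distances the dendrogram was built from (same forms as
#'   [average_linkage()]).
#' @param dendrogram a `song_dendrogram` built from `x`; if missing, it is
#'   built.
#' @param threshold pass/fail threshold on the CCC (default 0.8).
#' @return list with `ccc`, `pass` (`ccc > threshold`) and `threshold`.
#' @export
cophenetic_correlation <- function(x, dendrogram = NULL, threshold = 0.8) {
  d <- as_distance(x)
  if (is.null(dendrogram)) dendrogram <- average_linkage(d)
  stopifnot(inherits(dendrogram, "song_dendrogram"))
  coph <- cophenetic(dendrogram$hclust)
  dv <- as.vector(d)
  cv <- as.vector(coph)
  if (sd(dv) == 0 || sd(cv) == 0)
    stop("cophenetic correlation undefined: zero variance in distances")
  ccc <- cor(dv, cv)
  list(ccc = ccc, pass = ccc > threshold, threshold = threshold)
}

#' Cut a dendrogram into clusters
#'
#' Clusters are the connected components joined below the given distance
#' threshold. A threshold of 0 on distinct items yields singletons; a
#' threshold above the root height yields a single cluster.
#'
#' @param dendrogram a `song_dendrogram`.
#' @param threshold non-negative cut height in distance units (`1 - LSI`).
#' @return An object of class `cluster_assignment`: named integer vector of
#'   cluster labels with attributes `threshold` and `method`.
#' @export
cut_clusters <- function(dendrogram, threshold) {
  stopifnot(inherits(dendrogram, "song_dendrogram"), threshold >= 0)
  cl <- cutree(dendrogram$hclust, h = threshold)
  structure(cl, threshold = threshold, method = "upgma_height_cut",
            class = c("cluster_assignment", class(cl)))
}

# leaf sets (as sorted label vectors) of every internal node of an hclust
internal_leaf_sets <- function(h) {
  n <- length(h$labels)
  sets <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    kids <- h$merge[k, ]
    sets[[k]] <- sort(unique(c(
      if (kids[1] < 0) h$labels[-kids[1]] else sets[[kids[1]]],
      if (kids[2] < 0) h$labels[-kids[2]] else sets[[kids[2]]])))
  }
  sets
}

#' Bootstrap support for dendrogram clusters
#'
#' Ordinary bootstrap over items: each replicate resamples the items with
#' replacement, takes the induced pairwise LSI distances (pairwise LSI
#' between two items does not depend on the rest of the sample, so the
#' precomputed matrix is reused), reclusters with average linkage, and
#' records the clusters present. Each internal node of the reference tree is
#' scored by the fraction of replicates that contain a cluster with the same
#' leaf set, restricted to the leaves drawn in that replicate; restrictions
#' to fewer than two distinct leaves are trivially contained.
#'
#' @param items list of label sequences (as for [pairwise_lsi_matrix()]).
#' @param costs `substitution_costs` or `NULL` for unweighted LSI.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; identical seed and input give identical
#'   supports.
#' @param ids optional item identifiers.
#' @return A `song_dendrogram` for the full data whose `support` is a
#'   numeric vector in `[0, 1]`, one entry per internal node (in
#'   `hclust$merge` order).
#' @export
bootstrap_support <- function(items, costs = NULL, B = 100L, seed = 1L,
                              ids = names(items)) {
  if (B < 1L) stop("B must be >= 1")
  sim <- pairwise_lsi_matrix(items, costs, ids = ids)
  dend <- average_linkage(sim)
  n <- length(sim$item_ids)
  dmat <- as.matrix(dend$dist)
  ref_sets <- internal_leaf_sets(dend$hclust)
  hits <- numeric(length(ref_sets))
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.restore_seed(old))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    labs <- sim$item_ids[idx]
    sub <- dmat[idx, idx]
    dimnames(sub) <- list(labs, labs)
    # duplicated draws are distinct leaves at distance 0
    hb <- hclust(as.dist(sub), method = "average")
    hb$labels <- labs
    rep_sets <- c(lapply(internal_leaf_sets(hb), unique),
                  as.list(unique(labs)))
    rep_keys <- unique(vapply(rep_sets, paste, "", collapse = "\r"))
    sampled <- unique(labs)
    for (k in seq_along(ref_sets)) {
      restr <- ref_sets[[k]][ref_sets[[k]] %in% sampled]
      if (length(restr) < 2L ||
          paste(restr, collapse = "\r") %in% rep_keys)
        hits[k] <- hits[k] + 1
    }
  }
  dend$support <- hits / B
  dend
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Agreement between a cluster assignment and reference labels
#'
#' Quantitative verification of qualitative assignments: cross-tabulates the
#' two labelings, computes the adjusted Rand index, and reports per
#' reference-label purity (the largest fraction of a reference label's items
#' falling in one cluster).
#'
#' @param assignment a `cluster_assignment` or named vector of cluster
#'   labels.
#' @param reference named vector of reference labels over the same items.
#' @return list with `ari`, `contingency` and `purity`.
#' @export
verify_assignments <- function(assignment, reference) {
  if (is.null(names(assignment)) || is.null(names(reference)))
    stop("both labelings must be named by item id")
  if (!setequal(names(assignment), names(reference)) ||
      length(assignment) != length(reference))
    stop("assignment and reference cover different item sets")
  reference <- reference[names(assignment)]
  tab <- table(reference = as.character(reference),
               cluster = as.character(assignment))
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  list(ari = mclust::adjustedRandIndex(as.character(assignment),
                                       as.character(reference)),
       contingency = tab, purity = purity)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences; bootstrap support values (if
#' present) become internal node labels.
#'
#' @param dendrogram a `song_dendrogram`.
#' @param path output file path.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "song_dendrogram"))
  phy <- ape::as.phylo(dendrogram$hclust)
  if (!is.null(dendrogram$support)) {
    # hclust merge order k -> phylo internal node for the same leaf set
    sets <- internal_leaf_sets(dendrogram$hclust)
    keys <- vapply(sets, paste, "", collapse = "\r")
    phy$node.label <- rep("", phy$Nnode)
    for (nd in seq_len(phy$Nnode)) {
      tips <- sort(ape::extract.clade(phy, nd + ape::Ntip(phy))$tip.label)
      m <- match(paste(tips, collapse = "\r"), keys)
      if (!is.na(m))
        phy$node.label[nd] <- formatC(dendrogram$support[m], digits = 3,
                                      format = "f")
    }
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Verify theme assignments by phrase clustering
#'
#' Phrases are pooled per stratum (by default per population and year, i.e.
#' each population's song in each year is evaluated separately), their
#' weighted pairwise LSI matrix is clustered with average linkage, the tree
#' is cut at `cut_height`, and the resulting clusters are compared against
#' the transcribed theme ids.
#'
#' @param corpus a filtered [song_corpus()].
#' @param costs `substitution_costs` from the corpus dictionary (built with
#'   `beta` = 1 if omitted).
#' @param by character vector of phrase-table columns defining the strata
#'   (default `c("population", "year")`).
#' @param cut_height dendrogram cut height (default 0.2).
#' @return data.frame with one row per stratum: `n_phrases`, `ccc`, `ari`;
#'   the per-stratum detail lists are attached as attribute `"detail"`.
#' @export
verify_theme_assignments <- function(corpus, costs = NULL,
                                     by = c("population", "year"),
                                     cut_height = 0.2) {
  stopifnot(inherits(corpus, "song_corpus"))
  if (is.null(costs)) costs <- unit_similarity_costs(corpus$dictionary)
  ps <- phrase_sequences(corpus)
  key <- interaction(ps$meta[by], drop = TRUE, sep = "_")
  rows <- list(); detail <- list()
  for (s in levels(key)) {
    sel <- which(key == s)
    seqs <- ps$seqs[sel]
    ids <- paste0("p", sel)
    sim <- pairwise_lsi_matrix(seqs, costs, ids = ids)
    dend <- average_linkage(sim)
    cc <- cophenetic_correlation(sim, dend)
    cl <- cut_clusters(dend, cut_height)
    ref <- setNames(as.character(ps$meta$theme_id[sel]), ids)
    ver <- verify_assignments(cl, ref)
    rows[[s]] <- data.frame(stratum = s, n_phrases = length(sel),
                            ccc = cc$ccc, ari = ver$ari)
    detail[[s]] <- list(dendrogram = dend, verification = ver)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "detail") <- detail
  out
}

#' Verify song-type assignments by theme-sequence clustering
#'
#' Builds, for each song type (or for the whole corpus when
#' `per_song_type = FALSE`), the unweighted theme-sequence LSI matrix over
#' its song cycles, clusters it with average linkage, and reports the CCC.
#' When clustering the whole corpus, the ARI of a cut at `cut_height`
#' against the song-type labels is also reported.
#'
#' @param corpus a filtered [song_corpus()].
#' @param per_song_type cluster each song type separately (default) or the
#'   pooled corpus.
#' @param cut_height cut height used for the pooled song-type ARI
#'   (default 0.5).
#' @return data.frame with one row per tree: `group`, `n_cycles`, `ccc`,
#'   `ccc_pass` and (pooled only) `ari`; dendrograms attached as attribute
#'   `"detail"`.
#' @export
verify_song_assignments <- function(corpus, per_song_type = TRUE,
                                    cut_height = 0.5) {
  stopifnot(inherits(corpus, "song_corpus"))
  seqs <- theme_sequences(corpus)
  cyc <- cycle_table(corpus)
  groups <- if (per_song_type) split(cyc$cycle_id, cyc$song_type)
            else list(all = cyc$cycle_id)
  rows <- list(); detail <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    sim <- pairwise_lsi_matrix(seqs[ids], NULL, ids = ids)
    dend <- average_linkage(sim)
    # a fully homogeneous group has no distance variance; its (trivial)
    # tree represents it perfectly but the CCC is undefined
    cc <- tryCatch(cophenetic_correlation(sim, dend),
                   error = function(e) list(ccc = NA_real_, pass = NA))
    ari <- NA_real_
    if (!per_song_type) {
      cl <- cut_clusters(dend, cut_height)
      ref <- setNames(cyc$song_type, cyc$cycle_id)[ids]
      ari <- verify_assignments(cl, ref)$ari
    }
    rows[[g]] <- data.frame(group = g, n_cycles = length(ids),
                            ccc = cc$ccc, ccc_pass = cc$pass, ari = ari)
    detail[[g]] <- dend
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "detail") <- detail
  out
}
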