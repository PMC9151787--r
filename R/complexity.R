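# Composite complexity scores.
#
# Structural variables are reduced to a single axis by PCA on the
# correlation matrix (variables standardized to zero mean, unit variance);
# the complexity score of an entity is its projection on the first
# principal component, with the sign oriented so that the loading on the
# unit-count variable is positive — higher scores mean higher relative
# complexity. Song-cycle scores use six variables (three at the song level,
# three at the theme level); theme scores use three phrase-level variables.

#' First-principal-component scores
#'
#' @param x numeric matrix or data.frame, entities in rows, variables in
#'   columns; no missing values. Zero-variance variables are dropped with a
#'   warning.
#' @param orient_on name of the variable whose PC1 loading is forced
#'   positive (default: the first column whose name contains
#'   `"total_units"` or `"mean_units"`, else the first column).
#' @return list with `scores` (named by rownames of `x`), `loadings`,
#'   `explained_variance` (fraction for PC1) and `flipped` (whether the
#'   sign was reversed to satisfy the orientation rule).
#' @export
pc1_scores <- function(x, orient_on = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in complexity variables")
  if (nrow(x) < 2L) stop("need at least 2 entities for a PCA")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 non-degenerate variables")
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- p$x[, 1]
  loadings <- p$rotation[, 1]
  if (is.null(orient_on) || !orient_on %in% colnames(x)) {
    # orientation anchor (possibly dropped as degenerate): fall back to
    # another unit-count variable, then to the first remaining one
    hit <- grep("total_units|units", colnames(x))
    orient_on <- if (length(hit)) colnames(x)[hit[1]] else colnames(x)[1]
  }
  flipped <- FALSE
  if (loadings[orient_on] < 0) {
    scores <- -scores
    loadings <- -loadings
    flipped <- TRUE
  }
  list(scores = scores, loadings = loadings,
       explained_variance = unname(p$sdev[1]^2 / sum(p$sdev^2)),
       flipped = flipped)
}

#' Structural variables of one song cycle
#'
#' @param corpus a filtered [song_corpus()].
#' @param theme_scores optional named lookup of theme complexity scores (as
#'   produced internally from [theme_complexity()]), keyed
#'   `"<song_type>|<theme_id>|<population>"`; computed from the corpus when
#'   omitted.
#' @return data.frame with one row per song cycle: `cycle_id`, `singer_id`,
#'   `population`, `year`, `song_type`, then the six variables
#'   `total_units`, `unique_units`, `song_duration_s`, `n_themes`,
#'   `mean_phrase_duration_s`, `mean_theme_complexity`.
#' @export
cycle_variables <- function(corpus, theme_scores = NULL) {
  stopifnot(inherits(corpus, "song_corpus"))
  if (is.null(theme_scores))
    theme_scores <- tryCatch(theme_score_lookup(corpus), error = function(e) {
      warning("theme-level PCA unavailable (", conditionMessage(e),
              "); mean_theme_complexity set to 0")
      numeric(0)
    })
  ph <- corpus$phrases
  units <- strsplit(ph$unit_sequence, " ", fixed = TRUE)
  cyc <- cycle_table(corpus)
  idx <- split(seq_len(nrow(ph)),
               factor(ph$cycle_id, levels = cyc$cycle_id))
  rows <- lapply(cyc$cycle_id, function(cid) {
    i <- idx[[cid]]
    u <- units[i]
    occ <- !duplicated(ph$occurrence_index[i])
    key <- paste(ph$song_type[i][occ], ph$theme_id[i][occ],
                 ph$population[i][occ], sep = "|")
    mtc <- mean(theme_scores[key], na.rm = TRUE)
    if (!is.finite(mtc)) mtc <- 0
    data.frame(
      total_units = length(unlist(u)),
      unique_units = length(unique(unlist(u))),
      song_duration_s = ph$cycle_duration_s[i][1],
      n_themes = sum(occ),
      mean_phrase_duration_s = mean(ph$phrase_duration_s[i]),
      mean_theme_complexity = mtc)
  })
  out <- cbind(cyc[c("cycle_id", "singer_id", "population", "year",
                     "song_type")],
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

theme_variable_table <- function(corpus) {
  ph <- corpus$phrases
  units <- strsplit(ph$unit_sequence, " ", fixed = TRUE)
  key <- paste(ph$song_type, ph$theme_id, ph$population, sep = "|")
  agg <- lapply(split(seq_len(nrow(ph)), key), function(i) {
    data.frame(
      song_type = ph$song_type[i][1],
      theme_id = as.character(ph$theme_id[i][1]),
      population = ph$population[i][1],
      mean_units_per_phrase = mean(lengths(units[i])),
      mean_unique_units_per_phrase =
        mean(vapply(units[i], function(x) length(unique(x)), 0)),
      mean_phrase_duration_s = mean(ph$phrase_duration_s[i]),
      n_phrase_reps = length(i))
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out[order(out$song_type, out$theme_id, out$population), , drop = FALSE]
}

#' Theme complexity scores per population
#'
#' Each (song type, theme, population) combination is summarized by three
#' phrase-level variables (mean units per phrase, mean unique units per
#' phrase, mean phrase duration), averaged over every repetition of the
#' theme in that population. Within each song type, the rows are reduced to
#' PC1 scores (see [pc1_scores()]); this is the per-theme quantity compared
#' between populations.
#'
#' @param corpus a filtered [song_corpus()].
#' @param pooling `"per_song_type"` (default: one PCA per song type, scores
#'   comparable within a song type) or `"pooled"` (one PCA over all rows).
#' @return A `complexity_table` data.frame: one row per (song type, theme,
#'   population) with the raw variables, `n_phrase_reps` and `pc1_score`;
#'   PCA loadings and explained variance per fitted PCA are in
#'   `attr(, "pca")`.
#' @export
theme_complexity <- function(corpus,
                             pooling = c("per_song_type", "pooled")) {
  pooling <- match.arg(pooling)
  tv <- theme_variable_table(corpus)
  vars <- c("mean_units_per_phrase", "mean_unique_units_per_phrase",
            "mean_phrase_duration_s")
  groups <- if (pooling == "per_song_type") split(seq_len(nrow(tv)),
                                                  tv$song_type)
            else list(pooled = seq_len(nrow(tv)))
  tv$pc1_score <- NA_real_
  pca_info <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    m <- as.matrix(tv[i, vars])
    rownames(m) <- paste(tv$theme_id[i], tv$population[i], sep = "|")
    p <- pc1_scores(m, orient_on = "mean_units_per_phrase")
    tv$pc1_score[i] <- p$scores
    pca_info[[g]] <- p[c("loadings", "explained_variance", "flipped")]
  }
  structure(tv, pca = pca_info, level = "theme_by_population",
            class = c("complexity_table", class(tv)))
}

# named score lookup "<song_type>|<theme_id>|<population>" -> pc1
theme_score_lookup <- function(corpus) {
  tc <- theme_complexity(corpus)
  setNames(tc$pc1_score, paste(tc$song_type, tc$theme_id, tc$population,
                               sep = "|"))
}

#' Song-type complexity scores per population
#'
#' Computes the six structural variables of every song cycle
#' ([cycle_variables()]), reduces them to per-cycle PC1 scores by one PCA
#' (pooled over all cycles by default so scores are comparable across song
#' types), and averages the per-cycle scores within each
#' (song type, population).
#'
#' @param corpus a filtered [song_corpus()].
#' @param pooling `"pooled"` (default) or `"per_song_type"`.
#' @return A `complexity_table` data.frame: one row per (song type,
#'   population) with `pc1_score` (the mean per-cycle score), `n_cycles`
#'   and the stratum means of the six variables; per-cycle scores in
#'   `attr(, "cycle_scores")`, PCA detail in `attr(, "pca")`.
#' @export
song_type_complexity <- function(corpus,
                                 pooling = c("pooled", "per_song_type")) {
  pooling <- match.arg(pooling)
  cv <- cycle_variables(corpus)
  vars <- c("total_units", "unique_units", "song_duration_s", "n_themes",
            "mean_phrase_duration_s", "mean_theme_complexity")
  groups <- if (pooling == "pooled") list(pooled = seq_len(nrow(cv)))
            else split(seq_len(nrow(cv)), cv$song_type)
  cv$pc1_score <- NA_real_
  pca_info <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    m <- as.matrix(cv[i, vars])
    rownames(m) <- cv$cycle_id[i]
    p <- pc1_scores(m, orient_on = "total_units")
    cv$pc1_score[i] <- p$scores
    pca_info[[g]] <- p[c("loadings", "explained_variance", "flipped")]
  }
  key <- paste(cv$song_type, cv$population, sep = "|")
  rows <- lapply(split(seq_len(nrow(cv)), key), function(i) {
    data.frame(song_type = cv$song_type[i][1],
               population = cv$population[i][1],
               n_cycles = length(i),
               as.list(colMeans(cv[i, vars])),
               pc1_score = mean(cv$pc1_score[i]))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$song_type, out$population), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, pca = pca_info, cycle_scores = cv,
            level = "song_type_by_population",
            class = c("complexity_table", class(out)))
}

#' Export a complexity table
#'
#' Writes the table as CSV plus a sidecar JSON (`<path>.pca.json`) holding
#' PC1 loadings, explained variance and the orientation flag of each fitted
#' PCA.
#'
#' @param table a `complexity_table`.
#' @param path output CSV path.
#' @export
write_complexity_csv <- function(table, path) {
  stopifnot(inherits(table, "complexity_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  pca <- lapply(attr(table, "pca"), function(p)
    list(loadings = as.list(p$loadings),
         explained_variance = p$explained_variance,
         orientation_flipped = p$flipped))
  jsonlite::write_json(pca, paste0(path, ".pca.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
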