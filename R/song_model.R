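# Hierarchical song structure: units -> phrases -> themes -> song cycles.
# A corpus is stored flat (one row per phrase repetition) together with the
# unit dictionary that fixes the alphabet; theme occurrences are recovered
# from runs of consecutive rows sharing a theme id within a cycle.

#' Construct a unit dictionary
#'
#' A unit dictionary defines the alphabet of discrete sound units ("units")
#' over which all song sequences are written, together with an acoustic
#' feature vector per unit (e.g. duration, peak frequency, extent of
#' frequency modulation). The features define the substitution costs used by
#' the weighted Levenshtein-distance similarity index (see
#' [unit_similarity_costs()]).
#'
#' @param labels character vector of unique unit labels.
#' @param features numeric matrix, one row per unit, with named feature
#'   columns. All values must be finite; any column whose name contains
#'   `"duration"` must be strictly positive and any column whose name ends in
#'   `"_hz"` must be non-negative.
#' @return An object of class `unit_dictionary` with elements `labels`,
#'   `features` (row names = labels) and `feature_names`.
#' @examples
#' unit_dictionary(c("A", "B"),
#'                 matrix(c(1, 2, 300, 600), 2,
#'                        dimnames = list(NULL, c("duration_s", "peak_hz"))))
#' @export
unit_dictionary <- function(labels, features) {
  labels <- as.character(labels)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (length(labels) != nrow(features))
    stop("number of labels must match number of feature rows")
  if (anyDuplicated(labels))
    stop("duplicate unit label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(labels) < 2L)
    stop("a unit dictionary needs at least 2 units")
  if (is.null(colnames(features)) || any(!nzchar(colnames(features))))
    stop("feature columns must be named")
  if (!all(is.finite(features)))
    stop("all acoustic features must be finite")
  dur <- grepl("duration", colnames(features), ignore.case = TRUE)
  if (any(features[, dur, drop = FALSE] <= 0))
    stop("durations must be > 0")
  hz <- grepl("_hz$", colnames(features), ignore.case = TRUE)
  if (any(features[, hz, drop = FALSE] < 0))
    stop("frequencies must be >= 0")
  rownames(features) <- labels
  structure(list(labels = labels, features = features,
                 feature_names = colnames(features)),
            class = "unit_dictionary")
}

#' @export
print.unit_dictionary <- function(x, ...) {
  cat("Unit dictionary:", length(x$labels), "units,",
      length(x$feature_names), "acoustic features (",
      paste(x$feature_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Read / write a unit dictionary CSV
#'
#' The file format is one row per unit: a `label` column followed by one
#' numeric column per acoustic feature, UTF-8, comma separated, header
#' required. `write_unit_dictionary()` and `load_unit_dictionary()` are exact
#' inverses on canonical files.
#'
#' @param path path to a CSV file.
#' @return `load_unit_dictionary()` returns a [unit_dictionary()].
#' @export
load_unit_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% names(df)) stop("dictionary file must have a 'label' column")
  feat_cols <- setdiff(names(df), "label")
  if (length(feat_cols) == 0L) stop("dictionary file has no feature columns")
  feats <- as.matrix(df[feat_cols])
  if (!is.numeric(feats)) stop("non-numeric feature value in ", path)
  unit_dictionary(df$label, feats)
}

#' @param dictionary a [unit_dictionary()].
#' @rdname load_unit_dictionary
#' @export
write_unit_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "unit_dictionary"))
  df <- data.frame(label = dictionary$labels, dictionary$features,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

transcription_cols <- c("cycle_id", "singer_id", "population", "year",
                        "song_type", "theme_id", "phrase_index",
                        "unit_sequence", "phrase_duration_s",
                        "cycle_duration_s")

#' Construct a song corpus
#'
#' A song corpus couples a phrase table with the unit dictionary governing
#' its alphabet. The phrase table holds one row per phrase repetition, in
#' singing order within each song cycle, with columns `cycle_id`,
#' `singer_id`, `population`, `year`, `song_type`, `theme_id`,
#' `occurrence_index` (which consecutive block of this theme within the
#' cycle), `phrase_index` (0-based position within the occurrence),
#' `unit_sequence` (space-separated unit labels), `phrase_duration_s` and
#' `cycle_duration_s`.
#'
#' @param phrases data.frame as described above (`occurrence_index` is
#'   recomputed if absent).
#' @param dictionary the governing [unit_dictionary()].
#' @param provenance free-text metadata carried along with the corpus.
#' @return An object of class `song_corpus`.
#' @export
song_corpus <- function(phrases, dictionary, provenance = "") {
  stopifnot(inherits(dictionary, "unit_dictionary"))
  phrases <- as.data.frame(phrases, stringsAsFactors = FALSE)
  need <- setdiff(setdiff(transcription_cols, "phrase_index"), names(phrases))
  if (length(need)) stop("phrase table missing column(s): ",
                         paste(need, collapse = ", "))
  if (nrow(phrases) == 0L) stop("empty corpus")
  labs <- unique(unlist(strsplit(phrases$unit_sequence, " ", fixed = TRUE)))
  unknown <- setdiff(labs, dictionary$labels)
  if (length(unknown)) stop("unit label(s) not in dictionary: ",
                            paste(unknown, collapse = ", "))
  if (any(phrases$cycle_duration_s <= 0)) stop("cycle durations must be > 0")
  if (any(phrases$phrase_duration_s < 0)) stop("phrase durations must be >= 0")
  if (is.null(phrases$occurrence_index)) {
    phrases <- merge_adjacent_occurrences(phrases)
  }
  # a theme sung 'without repetition' may still legitimately reappear in
  # messy field data; warn rather than reject
  seqs <- split(phrases[!duplicated(paste(phrases$cycle_id,
                                          phrases$occurrence_index)), ],
                phrases$cycle_id[!duplicated(paste(phrases$cycle_id,
                                                   phrases$occurrence_index))])
  rep_cycles <- names(seqs)[vapply(seqs, function(d)
    anyDuplicated(d$theme_id) > 0L, logical(1))]
  if (length(rep_cycles))
    warning("theme repeated non-consecutively within cycle(s): ",
            paste(head(rep_cycles, 5L), collapse = ", "))
  rownames(phrases) <- NULL
  structure(list(phrases = phrases, dictionary = dictionary,
                 provenance = provenance),
            class = "song_corpus")
}

# Group consecutive rows of equal theme_id within a cycle into one theme
# occurrence and renumber phrase_index 0..k-1. Rows must already be in
# singing order. Each incoming run's phrase_index must be 0-based contiguous.
merge_adjacent_occurrences <- function(phrases) {
  out <- lapply(split(phrases, factor(phrases$cycle_id,
                                      levels = unique(phrases$cycle_id))),
                function(d) {
    run <- cumsum(c(TRUE, d$theme_id[-1] != d$theme_id[-nrow(d)]))
    if ("phrase_index" %in% names(d)) {
      ok <- unlist(lapply(split(d$phrase_index, run), function(p) {
        brk <- which(p == 0L)  # sub-run starts
        all(p == sequence(diff(c(brk, length(p) + 1L))) - 1L) && p[1] == 0L
      }))
      if (!all(ok))
        stop("non-contiguous phrase indices in cycle ", d$cycle_id[1])
    }
    d$occurrence_index <- run
    d$phrase_index <- unlist(lapply(split(seq_len(nrow(d)), run),
                                    seq_along)) - 1L
    d
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.song_corpus <- function(x, ...) {
  s <- strata_counts(x)
  cat("Song corpus:", length(unique(x$phrases$cycle_id)), "song cycles,",
      nrow(x$phrases), "phrase repetitions,",
      length(unique(x$phrases$theme_id)), "theme ids,",
      nrow(s), "population-year strata\n")
  invisible(x)
}

#' Read / write a transcription CSV
#'
#' One row per phrase repetition (see [song_corpus()] for columns; the stored
#' file omits `occurrence_index`, which is reconstructed on read by merging
#' consecutive rows of the same theme). Rows must appear in singing order
#' within each cycle.
#'
#' @param path path to a CSV file.
#' @param dictionary the [unit_dictionary()] governing unit labels.
#' @return `read_transcriptions()` returns a [song_corpus()].
#' @export
read_transcriptions <- function(path, dictionary) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(transcription_cols, names(df))
  if (length(need)) stop("transcription file missing column(s): ",
                         paste(need, collapse = ", "))
  labs <- strsplit(df$unit_sequence, " ", fixed = TRUE)
  bad <- which(vapply(labs, function(u)
    any(!u %in% dictionary$labels), logical(1)))
  if (length(bad))
    stop("unknown unit label at row ", bad[1], " of ", path)
  song_corpus(df, dictionary, provenance = paste("read from", path))
}

#' @param corpus a [song_corpus()].
#' @rdname read_transcriptions
#' @export
write_transcriptions <- function(corpus, path) {
  stopifnot(inherits(corpus, "song_corpus"))
  write.csv(corpus$phrases[transcription_cols], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-stratum cycle and singer counts
#'
#' @param corpus a [song_corpus()].
#' @return data.frame with one row per (population, year) stratum and
#'   columns `n_cycles`, `n_singers`.
#' @export
strata_counts <- function(corpus) {
  p <- corpus$phrases[!duplicated(corpus$phrases$cycle_id), ]
  out <- aggregate(cbind(n_cycles = p$cycle_id, n_singers = p$singer_id),
                   by = list(population = p$population, year = p$year),
                   FUN = function(v) length(unique(v)))
  out[order(out$population, out$year), , drop = FALSE]
}

#' Apply the corpus inclusion rules
#'
#' Theme occurrences with fewer than `min_phrase_reps` phrase repetitions in
#' a song cycle are removed: such one-off "transitional" themes are too rare
#' and unstereotyped to treat as part of the song pattern. Population-year
#' strata sampled from fewer than `min_singers_per_stratum` singers are
#' flagged in the attached report but retained (small strata still carry the
#' population song, just with less confidence that it is representative).
#' The filter is idempotent.
#'
#' @param corpus a [song_corpus()].
#' @param min_phrase_reps minimum phrase repetitions for a theme occurrence
#'   to count (default 2).
#' @param min_singers_per_stratum minimum singers per (population, year)
#'   stratum below which the stratum is flagged (default 6).
#' @return The filtered `song_corpus`, with a report available via
#'   [filter_report()].
#' @export
filter_corpus <- function(corpus, min_phrase_reps = 2,
                          min_singers_per_stratum = 6) {
  stopifnot(inherits(corpus, "song_corpus"))
  ph <- corpus$phrases
  key <- paste(ph$cycle_id, ph$occurrence_index)
  reps <- table(key)
  keep <- reps[key] >= min_phrase_reps
  removed <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]
  if (nrow(ph) == 0L)
    stop("filtering removed every phrase; corpus is empty")
  # renumber occurrences (removal may leave gaps; adjacent runs can merge)
  ph$occurrence_index <- NULL
  out <- song_corpus(ph, corpus$dictionary, corpus$provenance)
  strata <- strata_counts(out)
  strata$flagged <- strata$n_singers < min_singers_per_stratum
  attr(out, "filter_report") <- list(
    removed_occurrences = removed,
    min_phrase_reps = min_phrase_reps,
    min_singers_per_stratum = min_singers_per_stratum,
    strata = strata)
  out
}

#' Retrieve the report attached by [filter_corpus()]
#' @param corpus a filtered [song_corpus()].
#' @return list with `removed_occurrences`, the thresholds used, and the
#'   per-stratum table with its `flagged` column, or `NULL` if the corpus has
#'   not been filtered.
#' @export
filter_report <- function(corpus) attr(corpus, "filter_report")

#' Theme sequences of each song cycle
#'
#' The broad-scale representation of a song cycle: its ordered theme ids,
#' one symbol per theme occurrence. Used for the unweighted LSI analysis of
#' song-type structure, which avoids the length skew of full unit sequences.
#'
#' @param corpus a [song_corpus()].
#' @return Named list (by `cycle_id`, in order of first appearance) of
#'   character vectors of theme ids.
#' @export
theme_sequences <- function(corpus) {
  ph <- corpus$phrases
  occ <- ph[!duplicated(paste(ph$cycle_id, ph$occurrence_index)), ]
  lapply(split(as.character(occ$theme_id),
               factor(occ$cycle_id, levels = unique(occ$cycle_id))),
         identity)
}

#' Phrase unit sequences
#'
#' @param corpus a [song_corpus()].
#' @return list with `seqs` (list of character vectors of unit labels, one
#'   per phrase repetition) and `meta` (the corresponding phrase-table rows).
#' @export
phrase_sequences <- function(corpus) {
  list(seqs = strsplit(corpus$phrases$unit_sequence, " ", fixed = TRUE),
       meta = corpus$phrases)
}

#' Cycle-level metadata table
#'
#' @param corpus a [song_corpus()].
#' @return data.frame, one row per song cycle, with `cycle_id`, `singer_id`,
#'   `population`, `year`, `song_type`, `cycle_duration_s`.
#' @export
cycle_table <- function(corpus) {
  ph <- corpus$phrases
  out <- ph[!duplicated(ph$cycle_id),
            c("cycle_id", "singer_id", "population", "year", "song_type",
              "cycle_duration_s")]
  rownames(out) <- NULL
  out
}
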