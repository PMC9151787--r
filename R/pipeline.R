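# End-to-end orchestration: filter -> phrase-level LSI theme verification ->
# theme-sequence LSI song-type verification (with bootstrap support and CCC)
# -> complexity scores -> population comparisons -> theme occupancy.

#' Pipeline configuration
#'
#' All thresholds and switches of the full analysis live here; the
#' configuration is validated up front and embedded in the run report.
#'
#' @param dictionary_path,transcriptions_path input CSV paths (see
#'   [load_unit_dictionary()], [read_transcriptions()]). May be `NULL` when
#'   a corpus is passed to [run_pipeline()] directly.
#' @param out_dir output directory for stage artifacts.
#' @param beta LSI weighting exponent for phrase-level comparisons.
#' @param bootstrap_B bootstrap replicates for song-type dendrogram
#'   support (0 disables the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param theme_cut_height phrase-dendrogram cut height for theme
#'   verification (calibrated on synthetic corpora).
#' @param song_cut_height pooled theme-sequence dendrogram cut height for
#'   song-type verification.
#' @param ccc_threshold pass threshold on the cophenetic correlation
#'   coefficient.
#' @param pca_pooling `"pooled"` or `"per_song_type"` for song-type
#'   complexity.
#' @param shared_only restrict theme-level population comparisons to
#'   shared themes.
#' @param min_phrase_reps,min_singers_per_stratum corpus filter settings
#'   (see [filter_corpus()]).
#' @param phrase_level run the (heavier) phrase-level theme verification
#'   stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(dictionary_path = NULL,
                            transcriptions_path = NULL,
                            out_dir = tempfile("songculture_run_"),
                            beta = 1,
                            bootstrap_B = 100L,
                            seed = 1L,
                            theme_cut_height = 0.2,
                            song_cut_height = 0.5,
                            ccc_threshold = 0.8,
                            pca_pooling = c("pooled", "per_song_type"),
                            shared_only = TRUE,
                            min_phrase_reps = 2L,
                            min_singers_per_stratum = 6L,
                            phrase_level = TRUE) {
  pca_pooling <- match.arg(pca_pooling)
  stopifnot(beta >= 0, bootstrap_B >= 0, theme_cut_height >= 0,
            song_cut_height >= 0, ccc_threshold > -1, ccc_threshold < 1)
  structure(list(dictionary_path = dictionary_path,
                 transcriptions_path = transcriptions_path,
                 out_dir = out_dir, beta = beta,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed),
                 theme_cut_height = theme_cut_height,
                 song_cut_height = song_cut_height,
                 ccc_threshold = ccc_threshold,
                 pca_pooling = pca_pooling, shared_only = shared_only,
                 min_phrase_reps = as.integer(min_phrase_reps),
                 min_singers_per_stratum =
                   as.integer(min_singers_per_stratum),
                 phrase_level = isTRUE(phrase_level)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full song-culture analysis
#'
#' Stages: load inputs, apply the corpus filter, verify theme assignments by
#' weighted phrase-level LSI clustering per population-year (optional),
#' verify song types by unweighted theme-sequence LSI clustering per song
#' type (with CCC and bootstrap support; trees exported as Newick), compute
#' theme and song-type complexity scores, compare populations with exact
#' rank-sum tests, and tally theme occupancy with unique-theme phrase
#' shares. All numeric outputs are deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param corpus optionally, an already-loaded [song_corpus()] (bypasses
#'   the input paths).
#' @return The run report (list of stage results, also written as
#'   `summary.json` with CSV/TSV/Newick artifacts under
#'   `config$out_dir`), invisibly.
#' @export
run_pipeline <- function(config, corpus = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(corpus)) {
    if (is.null(config$dictionary_path) ||
        is.null(config$transcriptions_path))
      stop("either a corpus or both input paths must be provided")
    corpus <- stage("load", {
      dict <- load_unit_dictionary(config$dictionary_path)
      read_transcriptions(config$transcriptions_path, dict)
    })
  }
  filtered <- stage("filter", filter_corpus(
    corpus, config$min_phrase_reps, config$min_singers_per_stratum))
  costs <- stage("costs",
                 unit_similarity_costs(filtered$dictionary, config$beta))

  themes_ver <- NULL
  if (config$phrase_level) {
    themes_ver <- stage("verify-themes", verify_theme_assignments(
      filtered, costs, cut_height = config$theme_cut_height))
    write.csv(themes_ver, file.path(config$out_dir, "theme_verification.csv"),
              row.names = FALSE, quote = FALSE)
  }

  songs_ver <- stage("verify-songs", {
    sv <- verify_song_assignments(filtered)
    seqs <- theme_sequences(filtered)
    cyc <- cycle_table(filtered)
    for (g in unique(cyc$song_type)) {
      ids <- cyc$cycle_id[cyc$song_type == g]
      dend <- if (config$bootstrap_B > 0L)
        bootstrap_support(seqs[ids], NULL, B = config$bootstrap_B,
                          seed = config$seed, ids = ids)
      else attr(sv, "detail")[[g]]
      write_newick(dend, file.path(config$out_dir,
                                   paste0("songtype_", g, ".nwk")))
      write_similarity_tsv(pairwise_lsi_matrix(seqs[ids], NULL, ids = ids),
                           file.path(config$out_dir,
                                     paste0("songtype_", g, "_lsi.tsv")))
    }
    sv$ccc_pass <- sv$ccc > config$ccc_threshold
    write.csv(sv, file.path(config$out_dir, "songtype_verification.csv"),
              row.names = FALSE, quote = FALSE)
    sv
  })

  theme_cx <- stage("theme-complexity", theme_complexity(filtered))
  song_cx <- stage("songtype-complexity",
                   song_type_complexity(filtered, config$pca_pooling))
  write_complexity_csv(theme_cx,
                       file.path(config$out_dir, "theme_complexity.csv"))
  write_complexity_csv(song_cx,
                       file.path(config$out_dir, "songtype_complexity.csv"))

  cmp_song <- stage("compare", compare_population_complexity(song_cx))
  cmp_theme <- stage("compare-themes", compare_population_complexity(
    theme_cx, "theme_within_song_type", shared_only = config$shared_only))

  occ <- stage("occupancy", theme_occupancy(filtered))
  uniq_prop <- unique_theme_phrase_proportion(occ)
  write_occupancy_csv(occ, file.path(config$out_dir, "occupancy.csv"))

  report <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    strata = strata_counts(filtered),
    filter = filter_report(filtered)[c("removed_occurrences",
                                       "min_phrase_reps")],
    theme_verification = if (!is.null(themes_ver))
      as.data.frame(themes_ver),
    songtype_verification = as.data.frame(songs_ver),
    songtype_complexity = as.data.frame(song_cx),
    songtype_comparison = unclass(cmp_song),
    theme_comparisons = cmp_theme,
    occupancy_counts = occupancy_counts(occ),
    unique_theme_phrase_pct = uniq_prop)
  jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(report)
}
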