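# Synthetic two-population song cultures.
#
# The generator emulates the statistical structure of the field corpora the
# analysis is designed for: a source population introduces one song type
# per year (either a wholesale 'revolution' or an 'evolution' of the
# previous year's pattern); a second population sings the same song type
# with a fixed transmission lag; copying is high-fidelity with rare
# unit-level copy errors biased toward acoustically similar units; and each
# population occasionally injects its own population-unique themes, more
# often in evolutionary song types. Ground truth (theme templates, lineage,
# shared/unique status, mutation events) is returned alongside the corpus.

#' Simulation configuration
#'
#' @param n_unit_types number of unit types in the dictionary (>= 2).
#' @param feature_dims number of acoustic features (>= 2; the first three
#'   are duration (s), peak frequency (Hz) and frequency-modulation extent
#'   (Hz)).
#' @param n_song_types number of song types, introduced one per year.
#' @param lineage character vector (`"revolution"`/`"evolution"`) per song
#'   type; the first must be a revolution.
#' @param song_type_names labels for the song types.
#' @param populations length-2 character vector, source population first.
#' @param start_year year the source population sings the first song type.
#' @param cycles_per_stratum integer range of song cycles per
#'   (population, year) stratum.
#' @param total_cycles optional total cycle budget; stratum counts are
#'   drawn from `cycles_per_stratum` and then nudged within that range
#'   until they sum to the budget.
#' @param phrase_reps_per_theme integer range of phrase repetitions per
#'   theme occurrence.
#' @param themes_per_song integer range of themes per song type.
#' @param phrase_length integer range of units per theme template phrase.
#' @param unit_substitution_rate per-unit copy-error probability when a
#'   phrase is rendered.
#' @param similar_substitution_bias bias (>= 0) toward acoustically similar
#'   substitution targets: the replacement for unit `u` is drawn with
#'   probability proportional to `exp(-bias * cost(u, v))`.
#' @param evolution_edit_rate per-unit substitution rate applied to
#'   retained themes when a song type evolves from its predecessor.
#' @param theme_insert_delete_prob probability a retained theme is dropped
#'   during an evolution step (insertions then top the count back up).
#' @param unique_theme_injection_prob baseline per-theme probability that a
#'   population injects a population-unique theme into a song type.
#' @param evolution_injection_multiplier multiplier on the injection
#'   probability for evolutionary song types.
#' @param receiver_injection_multiplier multiplier for the receiving
#'   (lagged) population.
#' @param unique_theme_presence_prob probability that a rendition variant
#'   within the stratum carries a population-unique theme (each unique
#'   theme is carried by at least one variant).
#' @param theme_skip_prob probability that a non-primary rendition variant
#'   omits a shared theme. Each stratum holds 2-3 shared rendition
#'   variants that singers conform to (the primary variant is the full
#'   arrangement).
#' @param singer_lapse_prob per-theme probability that an individual cycle
#'   deviates from its singer's rendition variant (omitting a carried
#'   theme, or slipping in an omitted one).
#' @param transmission_lag_years lag before the receiving population sings
#'   each song type.
#' @param copy_population if `TRUE`, the receiving population's cycles are
#'   exact copies of the source population's (same rendered phrases, new
#'   cycle and singer ids, lagged years) and no unique themes are injected.
#' @param complexity_gradient if `TRUE`, song type `k` gets `4 + k` themes
#'   of `3 + k` units each (a designed monotone complexity gradient, every
#'   ingredient growing together) instead of drawing from
#'   `themes_per_song` and `phrase_length`.
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_unit_types = 30L,
                       feature_dims = 3L,
                       n_song_types = 6L,
                       lineage = NULL,
                       song_type_names = NULL,
                       populations = c("EA", "NC"),
                       start_year = 2009L,
                       cycles_per_stratum = c(10L, 36L),
                       total_cycles = NULL,
                       phrase_reps_per_theme = c(2L, 6L),
                       themes_per_song = c(5L, 8L),
                       phrase_length = c(3L, 8L),
                       unit_substitution_rate = 0.02,
                       similar_substitution_bias = 4,
                       evolution_edit_rate = 0.1,
                       theme_insert_delete_prob = 0.3,
                       unique_theme_injection_prob = 0.04,
                       evolution_injection_multiplier = 2.5,
                       receiver_injection_multiplier = 2.5,
                       unique_theme_presence_prob = 0.25,
                       theme_skip_prob = 0.25,
                       singer_lapse_prob = 0.005,
                       transmission_lag_years = 1L,
                       copy_population = FALSE,
                       complexity_gradient = FALSE,
                       seed = 1L) {
  if (is.null(lineage)) {
    # study pattern: four revolutions, with the second and fourth types
    # evolving from their predecessors
    lineage <- rep("revolution", n_song_types)
    if (n_song_types >= 2L) lineage[2L] <- "evolution"
    if (n_song_types >= 4L) lineage[4L] <- "evolution"
  }
  if (length(lineage) != n_song_types)
    stop("lineage must have one entry per song type")
  if (is.null(song_type_names))
    song_type_names <- if (n_song_types == 6L)
      c("Purple", "LightPurple", "Brown", "LightBrown", "Teal", "Orange")
    else paste0("Type", seq_len(n_song_types))
  cfg <- list(n_unit_types = as.integer(n_unit_types),
              feature_dims = as.integer(feature_dims),
              n_song_types = as.integer(n_song_types),
              lineage = lineage, song_type_names = song_type_names,
              populations = populations, start_year = as.integer(start_year),
              cycles_per_stratum = as.integer(cycles_per_stratum),
              total_cycles = total_cycles,
              phrase_reps_per_theme = as.integer(phrase_reps_per_theme),
              themes_per_song = as.integer(themes_per_song),
              phrase_length = as.integer(phrase_length),
              unit_substitution_rate = unit_substitution_rate,
              similar_substitution_bias = similar_substitution_bias,
              evolution_edit_rate = evolution_edit_rate,
              theme_insert_delete_prob = theme_insert_delete_prob,
              unique_theme_injection_prob = unique_theme_injection_prob,
              evolution_injection_multiplier = evolution_injection_multiplier,
              receiver_injection_multiplier = receiver_injection_multiplier,
              unique_theme_presence_prob = unique_theme_presence_prob,
              theme_skip_prob = theme_skip_prob,
              singer_lapse_prob = singer_lapse_prob,
              transmission_lag_years = as.integer(transmission_lag_years),
              copy_population = isTRUE(copy_population),
              complexity_gradient = isTRUE(complexity_gradient),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_unit_types >= 2L, cfg$feature_dims >= 2L,
            cfg$n_song_types >= 1L, length(cfg$populations) == 2L,
            cfg$transmission_lag_years >= 0L)
  for (r in c("cycles_per_stratum", "phrase_reps_per_theme",
              "themes_per_song", "phrase_length")) {
    v <- cfg[[r]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 1L)
      stop("invalid range for ", r)
  }
  for (p in c("unit_substitution_rate", "theme_insert_delete_prob",
              "unique_theme_injection_prob", "unique_theme_presence_prob",
              "theme_skip_prob", "singer_lapse_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$similar_substitution_bias < 0)
    stop("similar_substitution_bias must be >= 0")
  if (!all(cfg$lineage %in% c("revolution", "evolution")))
    stop("lineage entries must be 'revolution' or 'evolution'")
  if (cfg$lineage[1] != "revolution")
    stop("the first song type has no predecessor and must be a revolution")
  invisible(cfg)
}

#' Generate a synthetic acoustic unit dictionary
#'
#' Unit feature vectors are drawn from multivariate normal clusters in a
#' standardized latent space, then mapped to acoustic scales (log-normal
#' durations and frequencies), so that acoustically similar units exist and
#' substitution costs have real structure. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default: the config seed).
#' @return A [unit_dictionary()] with the latent cluster of each unit in
#'   `attr(, "cluster")`.
#' @export
make_unit_inventory <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_unit_types
  k <- max(2L, round(n / 5))
  d <- config$feature_dims
  centers <- matrix(rnorm(k * d, sd = 1.5), k, d)
  cl <- rep(seq_len(k), length.out = n)
  z <- centers[cl, , drop = FALSE] + matrix(rnorm(n * d, sd = 0.35), n, d)
  feats <- z
  feats[, 1] <- exp(0.5 * z[, 1]) * 0.8          # duration_s
  feats[, 2] <- exp(0.7 * z[, 2]) * 600          # peak_frequency_hz
  if (d >= 3L) feats[, 3] <- exp(0.8 * z[, 3]) * 80  # fm_extent_hz
  colnames(feats) <- c("duration_s", "peak_frequency_hz",
                       if (d >= 3L) "fm_extent_hz",
                       if (d > 3L) paste0("feature_", seq_len(d - 3L)))
  labels <- sprintf("U%02d", seq_len(n))
  dict <- unit_dictionary(labels, feats)
  attr(dict, "cluster") <- setNames(cl, labels)
  dict
}

# uniform draw(s) from an inclusive integer range; safe for degenerate
# ranges (sample(5, 1) would draw from 1:5)
sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(r[1], n)
  else sample(seq(r[1], r[2]), n, replace = TRUE)
}

# draw a replacement for unit index u, biased toward low-cost targets
biased_substitute <- function(u, cost, bias) {
  w <- exp(-bias * cost[u, ])
  w[u] <- 0
  sample.int(ncol(cost), 1L, prob = w)
}

# render one phrase from a template (integer unit indices) with copy error
render_phrase <- function(template, rate, cost, bias) {
  if (rate <= 0) return(template)
  hit <- runif(length(template)) < rate
  if (any(hit))
    template[hit] <- vapply(template[hit], biased_substitute, 0L,
                            cost = cost, bias = bias)
  template
}

#' Simulate a two-population song culture
#'
#' See [sim_config()] for the model. Returns the rendered corpus together
#' with complete ground truth for parameter-recovery testing.
#'
#' @param config a [sim_config()].
#' @return list with elements `corpus` (a [song_corpus()]) and `truth`
#'   (list: `themes` — one row per theme with template units, song type,
#'   shared/unique status and owning population; `song_types` — lineage,
#'   design complexity (total template units) and year per type;
#'   `mutations` — evolution-step edit log; `config`).
#' @export
simulate_song_culture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  dict <- make_unit_inventory(config)          # seeds the RNG stream
  costs <- unit_similarity_costs(dict, beta = 1)
  cost <- costs$cost
  nU <- config$n_unit_types
  pops <- config$populations
  lag <- config$transmission_lag_years

  theme_counter <- 0L
  new_theme_id <- function() {
    theme_counter <<- theme_counter + 1L
    theme_counter
  }
  labels_all <- dict$labels
  wld_units <- function(a, b)
    1 - lsi(labels_all[a], labels_all[b], costs)
  # fresh themes are drawn to be acoustically distinct from the others in
  # their song type (weighted LSI distance >= 0.4), so that the truth is
  # identifiable: two near-identical templates would be one theme to any
  # observer, human or algorithmic
  fresh_theme <- function(len = sample_range(config$phrase_length),
                          apart_from = list()) {
    best <- NULL
    best_sep <- -Inf
    for (try in 1:50) {
      units <- sample.int(nU, len, replace = TRUE)
      sep <- if (!length(apart_from)) Inf
             else min(vapply(apart_from, function(e) wld_units(units, e),
                             0))
      if (sep > best_sep) {
        best <- units
        best_sep <- sep
      }
      if (best_sep >= 0.4) break
    }
    list(id = new_theme_id(), units = best)
  }

  # --- song-type templates -------------------------------------------------
  # under the designed gradient, song type k has 4 + k themes of 3 + k
  # units each, so every complexity ingredient (theme count, phrase
  # length, total material) grows together and the design ordering is
  # identifiable despite rendition variation
  templates <- vector("list", config$n_song_types)  # list of themes per type
  mutations <- list()
  for (t in seq_len(config$n_song_types)) {
    target_n <- if (config$complexity_gradient) 4L + t
                else sample_range(config$themes_per_song)
    fresh_t <- function(apart_from = list()) {
      if (config$complexity_gradient) fresh_theme(3L + t, apart_from)
      else fresh_theme(apart_from = apart_from)
    }
    theme_units <- function(ths) lapply(ths, `[[`, "units")
    if (config$lineage[t] == "revolution") {
      themes <- list()
      for (i in seq_len(target_n))
        themes <- c(themes, list(fresh_t(theme_units(themes))))
    } else {
      prev <- templates[[t - 1L]]
      keep <- runif(length(prev)) >= config$theme_insert_delete_prob
      if (!any(keep)) keep[1] <- TRUE
      themes <- list()
      for (th in prev[keep]) {
        # redraw edits that would collapse two themes into one: such a
        # mutation would not be transcribed as a separate theme
        best <- NULL
        best_sep <- -Inf
        for (try in 1:30) {
          units <- render_phrase(th$units, config$evolution_edit_rate,
                                 cost, config$similar_substitution_bias)
          sep <- if (!length(themes)) Inf
                 else min(vapply(theme_units(themes),
                                 function(e) wld_units(units, e), 0))
          if (sep > best_sep) {
            best <- units
            best_sep <- sep
          }
          if (best_sep >= 0.4) break
        }
        units <- best
        nid <- new_theme_id()
        if (!identical(units, th$units))
          mutations[[length(mutations) + 1L]] <- list(
            event = "evolution_unit_edit", parent_theme = th$id,
            child_theme = nid)
        themes <- c(themes, list(list(id = nid, units = units,
                                      parent = th$id)))
      }
      while (length(themes) > target_n)
        themes <- themes[-sample(length(themes), 1L)]
      while (length(themes) < target_n) {
        pos <- sample(length(themes) + 1L, 1L)
        themes <- append(themes, list(fresh_t(theme_units(themes))),
                         after = pos - 1L)
        mutations[[length(mutations) + 1L]] <- list(
          event = "evolution_theme_insertion",
          child_theme = themes[[pos]]$id)
      }
    }
    templates[[t]] <- themes
  }

  # --- population-unique theme injection ----------------------------------
  # unique[[t]][[pop]] = list of list(theme, position)
  uniques <- lapply(seq_len(config$n_song_types), function(t)
    setNames(vector("list", 2L), pops))
  if (!config$copy_population) {
    for (t in seq_len(config$n_song_types)) {
      for (j in 1:2) {
        p <- config$unique_theme_injection_prob
        if (config$lineage[t] == "evolution")
          p <- p * config$evolution_injection_multiplier
        if (j == 2L) p <- p * config$receiver_injection_multiplier
        p <- min(1, p)
        # at most two novel themes take hold per population and song type
        n_uniq <- min(rbinom(1L, length(templates[[t]]), p), 2L)
        if (n_uniq > 0L) {
          apart <- lapply(templates[[t]], `[[`, "units")
          for (i in seq_len(n_uniq)) {
            th <- fresh_theme(apart_from = apart)
            apart <- c(apart, list(th$units))
            uniques[[t]][[j]] <- c(uniques[[t]][[j]], list(
              list(theme = th,
                   position = sample(length(templates[[t]]) + 1L, 1L))))
          }
        }
      }
    }
  }

  # --- stratum schedule ----------------------------------------------------
  strata <- data.frame(
    population = rep(pops, each = config$n_song_types),
    song_type_idx = rep(seq_len(config$n_song_types), 2L))
  strata$year <- config$start_year + strata$song_type_idx - 1L +
    ifelse(strata$population == pops[2], lag, 0L)
  n_str <- nrow(strata)
  rng <- config$cycles_per_stratum
  strata$n_cycles <- sample_range(rng, n_str)
  if (!is.null(config$total_cycles)) {
    for (guard in seq_len(100000L)) {
      diff <- sum(strata$n_cycles) - config$total_cycles
      if (diff == 0L) break
      i <- sample.int(n_str, 1L)
      if (diff > 0L && strata$n_cycles[i] > rng[1])
        strata$n_cycles[i] <- strata$n_cycles[i] - 1L
      if (diff < 0L && strata$n_cycles[i] < rng[2])
        strata$n_cycles[i] <- strata$n_cycles[i] + 1L
    }
    if (sum(strata$n_cycles) != config$total_cycles)
      stop("total_cycles infeasible for the cycles_per_stratum range")
  }

  # --- rendering -----------------------------------------------------------
  labels <- dict$labels
  unit_dur <- dict$features[, "duration_s"]
  rows <- list()
  truth_cycles <- list()
  render_stratum <- function(pop, j, t, year, n_cycles) {
    st_name <- config$song_type_names[t]
    shared <- templates[[t]]
    uq <- uniques[[t]][[j]]
    # roster: shared themes in order with uniques at their positions
    roster <- lapply(shared, function(th)
      c(th, list(status = "shared")))
    if (length(uq)) {
      for (u in uq) {
        pos <- min(u$position, length(roster) + 1L)
        roster <- append(roster, list(c(u$theme, list(status = "unique"))),
                         after = pos - 1L)
      }
    }
    n_singers <- min(n_cycles, max(6L, ceiling(n_cycles / 4)))
    singer_of <- sample(rep(seq_len(n_singers), length.out = n_cycles))
    # song conformity: each stratum carries a small number of shared
    # rendition variants (the full arrangement plus one or two reduced or
    # embellished versions); singers conform to a variant rather than
    # improvising their own theme subset every cycle
    n_var <- min(sample(2:3, 1L), n_singers)
    vdef <- matrix(TRUE, n_var, length(roster))
    shared_i <- which(vapply(roster, function(th) th$status == "shared",
                             logical(1)))
    # derived variants are nested reductions of the full arrangement:
    # variant k omits everything variant k-1 omits, and possibly more
    for (v in seq_len(n_var)[-1L]) {
      vdef[v, shared_i] <- vdef[v - 1L, shared_i] &
        runif(length(shared_i)) >= config$theme_skip_prob
    }
    for (i in setdiff(seq_along(roster), shared_i)) {
      # a novel theme is the signature of one rendition variant, with a
      # chance of spreading to each of the others
      vdef[, i] <- runif(n_var) < config$unique_theme_presence_prob
      vdef[sample.int(n_var, 1L), i] <- TRUE
      if (all(vdef[, i]) && n_var > 1L)
        vdef[1L, i] <- FALSE    # unique themes are never universal
    }
    w <- runif(n_var)
    w[1L] <- w[1L] + 1          # primary variant is the most common
    # every variant has at least one conforming singer (n_singers >= 6),
    # so every recorded unique theme is actually sung
    variant_of <- sample(c(seq_len(n_var),
                           sample.int(n_var, n_singers - n_var,
                                      replace = TRUE, prob = w / sum(w))))
    jitter <- config$singer_lapse_prob
    out <- vector("list", n_cycles)
    for (cyc in seq_len(n_cycles)) {
      cid <- sprintf("%s%d_c%02d", pop, year, cyc)
      sid <- sprintf("%s%d_s%02d", pop, year, singer_of[cyc])
      carries <- vdef[variant_of[singer_of[cyc]], ]
      flip <- runif(length(roster)) < jitter
      sung <- ifelse(flip, !carries, carries)
      if (!any(sung)) sung[1] <- TRUE
      occ <- list()
      for (i in which(sung)) {
        th <- roster[[i]]
        reps <- sample_range(config$phrase_reps_per_theme)
        phr <- lapply(seq_len(reps), function(r)
          render_phrase(th$units, config$unit_substitution_rate, cost,
                        config$similar_substitution_bias))
        occ[[length(occ) + 1L]] <- list(theme = th, phrases = phr)
      }
      dur <- vapply(occ, function(o)
        sum(vapply(o$phrases, function(p)
          sum(unit_dur[p]) + 0.15 * (length(p) - 1L), 0)), 0)
      cyc_dur <- sum(dur) + 1.5 * (length(occ) - 1L) + 2
      cyc_rows <- do.call(rbind, lapply(occ, function(o) {
        data.frame(
          cycle_id = cid, singer_id = sid, population = pop, year = year,
          song_type = st_name, theme_id = o$theme$id,
          phrase_index = seq_along(o$phrases) - 1L,
          unit_sequence = vapply(o$phrases, function(p)
            paste(labels[p], collapse = " "), ""),
          phrase_duration_s = vapply(o$phrases, function(p)
            sum(unit_dur[p]) + 0.15 * (length(p) - 1L), 0),
          cycle_duration_s = NA_real_)
      }))
      cyc_rows$cycle_duration_s <- cyc_dur
      out[[cyc]] <- cyc_rows
      truth_cycles[[length(truth_cycles) + 1L]] <<- data.frame(
        cycle_id = cid, population = pop, year = year, song_type = st_name,
        song_type_idx = t,
        n_true_themes = length(occ))
    }
    do.call(rbind, out)
  }
  for (s in seq_len(n_str)) {
    pop <- strata$population[s]
    if (config$copy_population && pop == pops[2]) next
    rows[[s]] <- render_stratum(pop, match(pop, pops),
                                strata$song_type_idx[s], strata$year[s],
                                strata$n_cycles[s])
  }
  phrases <- do.call(rbind, rows)
  if (config$copy_population) {
    dup <- phrases
    dup$population <- pops[2]
    dup$year <- dup$year + lag
    dup$cycle_id <- sub(paste0("^", pops[1]), pops[2], dup$cycle_id)
    dup$cycle_id <- paste0(dup$cycle_id, "_copy")
    dup$singer_id <- paste0(sub(paste0("^", pops[1]), pops[2],
                                dup$singer_id), "_copy")
    phrases <- rbind(phrases, dup)
  }
  rownames(phrases) <- NULL
  corpus <- song_corpus(phrases, dict,
                        provenance = sprintf("synthetic corpus (seed %d)",
                                             config$seed))

  theme_rows <- list()
  for (t in seq_len(config$n_song_types)) {
    for (th in templates[[t]])
      theme_rows[[length(theme_rows) + 1L]] <- data.frame(
        theme_id = th$id, song_type = config$song_type_names[t],
        status = "shared", population = NA_character_,
        template = paste(labels[th$units], collapse = " "))
    for (j in 1:2) for (u in uniques[[t]][[j]])
      theme_rows[[length(theme_rows) + 1L]] <- data.frame(
        theme_id = u$theme$id, song_type = config$song_type_names[t],
        status = "unique", population = pops[j],
        template = paste(labels[u$theme$units], collapse = " "))
  }
  truth <- list(
    themes = do.call(rbind, c(theme_rows, list(make.row.names = FALSE))),
    song_types = data.frame(
      song_type = config$song_type_names,
      lineage = config$lineage,
      source_year = config$start_year + seq_len(config$n_song_types) - 1L,
      design_complexity = vapply(templates, function(ths)
        sum(vapply(ths, function(th) length(th$units), 0L)), 0)),
    mutations = mutations,
    cycles = do.call(rbind, c(truth_cycles, list(make.row.names = FALSE))),
    seed = config$seed,
    config = unclass(config))
  list(corpus = corpus, truth = truth)
}

#' Named simulation presets
#'
#' * `"clean"`: no unit-level copy error and a designed complexity
#'   gradient (song type `k` has `4 + k` themes) — used for
#'   exact-recovery checks.
#' * `"noisy"`: realistic copy error (3% per unit).
#' * `"study_scale"`: low copy error (2%) under a 353-cycle total budget.
#'
#' All presets use the study's corpus structure: six song types, two
#' populations, 10-36 song cycles per population-year stratum.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
preset_config <- function(name = c("clean", "noisy", "study_scale"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    clean = sim_config(unit_substitution_rate = 0,
                       complexity_gradient = TRUE, seed = seed),
    noisy = sim_config(unit_substitution_rate = 0.03, seed = seed),
    study_scale = sim_config(unit_substitution_rate = 0.02,
                             cycles_per_stratum = c(10L, 36L),
                             total_cycles = 353L, seed = seed))
}

#' Write canonical fixture files for one or more presets
#'
#' For each preset, writes `<dir>/<preset>/dictionary.csv`,
#' `transcriptions.csv` and a `truth.json` sidecar.
#'
#' @param dir target directory.
#' @param presets character vector of [preset_config()] names.
#' @param seed integer seed.
#' @param force overwrite an existing non-empty target (default `FALSE`).
#' @return Invisibly, the per-preset directories written.
#' @export
render_fixture_suite <- function(dir, presets = c("clean", "noisy",
                                                  "study_scale"),
                                 seed = 1L, force = FALSE) {
  written <- character(0)
  for (p in presets) {
    target <- file.path(dir, p)
    if (dir.exists(target) && length(list.files(target)) && !force)
      stop("target directory not empty (use force = TRUE): ", target)
    dir.create(target, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_song_culture(preset_config(p, seed = seed))
    write_unit_dictionary(sim$corpus$dictionary,
                          file.path(target, "dictionary.csv"))
    write_transcriptions(sim$corpus, file.path(target, "transcriptions.csv"))
    truth <- sim$truth
    truth$mutations <- truth$mutations
    jsonlite::write_json(truth, file.path(target, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    written <- c(written, target)
  }
  invisible(written)
}
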