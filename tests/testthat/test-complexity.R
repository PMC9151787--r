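# a corpus where every theme has >= 2 reps, two themes per cycle
complexity_phrases <- function() {
  rbind(
    data.frame(cycle_id = "c1", singer_id = "s1", population = "EA",
               year = 2009L, song_type = "Purple",
               theme_id = c(1L, 1L, 2L, 2L),
               phrase_index = c(0L, 1L, 0L, 1L),
               unit_sequence = c("A B", "A B", "C D A", "C D A"),
               phrase_duration_s = c(3, 3, 5, 5), cycle_duration_s = 20),
    data.frame(cycle_id = "c2", singer_id = "s2", population = "NC",
               year = 2010L, song_type = "Purple",
               theme_id = c(1L, 1L, 2L, 2L),
               phrase_index = c(0L, 1L, 0L, 1L),
               unit_sequence = c("A B", "A B", "C D A", "C D A"),
               phrase_duration_s = c(3, 3, 5, 5), cycle_duration_s = 20))
}

test_that("cycle variables match hand counts", {
  corpus <- song_corpus(complexity_phrases(), toy_dictionary())
  cv <- cycle_variables(corpus, theme_scores = c(`Purple|1|EA` = 0,
                                                 `Purple|2|EA` = 0,
                                                 `Purple|1|NC` = 0,
                                                 `Purple|2|NC` = 0))
  expect_equal(cv$total_units, c(10, 10))     # 2x2 + 2x3
  expect_equal(cv$unique_units, c(4, 4))
  expect_equal(cv$n_themes, c(2, 2))
  expect_equal(cv$mean_phrase_duration_s, c(4, 4))
  expect_equal(cv$song_duration_s, c(20, 20))

  # duplicating every phrase doubles total units, unique unchanged
  ph <- complexity_phrases()[rep(1:8, each = 2), ]
  ph$phrase_index <- unlist(lapply(split(ph$phrase_index,
                                         paste(ph$cycle_id, ph$theme_id)),
                                   function(x) seq_along(x) - 1L))
  doubled <- song_corpus(ph, toy_dictionary())
  cv2 <- cycle_variables(doubled, theme_scores = c(`Purple|1|EA` = 0,
                                                   `Purple|2|EA` = 0,
                                                   `Purple|1|NC` = 0,
                                                   `Purple|2|NC` = 0))
  expect_equal(cv2$total_units, 2 * cv$total_units)
  expect_equal(cv2$unique_units, cv$unique_units)
})

test_that("PC1 scores behave as a standardized composite", {
  x <- cbind(total_units = c(10, 10, 20, 30),
             unique_units = c(4, 4, 6, 9),
             song_duration_s = c(100, 100, 180, 260))
  p <- pc1_scores(x)
  # identical rows get equal scores
  expect_equal(unname(p$scores[1]), unname(p$scores[2]))
  # orientation: loading on total_units positive, so the uniformly larger
  # entity scores higher
  expect_gt(p$loadings["total_units"], 0)
  expect_gt(p$scores[4], p$scores[1])
  expect_gt(p$explained_variance, 0.5)

  # changing raw units (s -> ms) leaves scores unchanged
  x2 <- x
  x2[, "song_duration_s"] <- x2[, "song_duration_s"] * 1000
  expect_equal(pc1_scores(x2)$scores, p$scores, tolerance = 1e-10)

  # two-entity dominance case against a direct eigendecomposition
  y <- cbind(a = c(1, 2), b = c(3, 5))
  py <- pc1_scores(y, orient_on = "a")
  z <- scale(y)
  ev <- eigen(cov(z))$vectors[, 1]
  if (ev[1] < 0) ev <- -ev
  expect_equal(unname(abs(py$scores)), abs(as.vector(z %*% ev)),
               tolerance = 1e-10)
  expect_gt(py$scores[2], py$scores[1])

  expect_warning(pc1_scores(cbind(a = c(1, 2, 3), b = 1, cc = c(2, 1, 0))),
                 "zero-variance")
  expect_error(suppressWarnings(pc1_scores(cbind(a = c(1, 2, 3), b = 1))),
               "fewer than 2")
})

test_that("on positively correlated variables all PC1 loadings share a sign", {
  set.seed(31)
  base <- rnorm(40)
  x <- cbind(total_units = 50 + 10 * base + rnorm(40),
             unique_units = 10 + 2 * base + rnorm(40, sd = 0.5),
             song_duration_s = 300 + 60 * base + rnorm(40, sd = 5),
             n_themes = 6 + base + rnorm(40, sd = 0.3))
  p <- pc1_scores(x)
  expect_true(all(p$loadings > 0))
})

test_that("theme complexity ranks structured themes above trivial ones", {
  ph <- rbind(
    data.frame(cycle_id = "c1", singer_id = "s1", population = "EA",
               year = 2009L, song_type = "Purple",
               theme_id = c(1L, 1L, 2L, 2L),
               phrase_index = c(0L, 1L, 0L, 1L),
               unit_sequence = c("A A B", "A A B", "A", "A"),
               phrase_duration_s = c(4, 4, 1, 1), cycle_duration_s = 12))
  corpus <- song_corpus(ph, toy_dictionary())
  tc <- theme_complexity(corpus)
  s1 <- tc$pc1_score[tc$theme_id == "1"]
  s2 <- tc$pc1_score[tc$theme_id == "2"]
  expect_gt(s1, s2)
})

test_that("identical populations get identical complexity scores", {
  corpus <- song_corpus(complexity_phrases(), toy_dictionary())
  tc <- theme_complexity(corpus)
  for (th in unique(tc$theme_id)) {
    s <- tc$pc1_score[tc$theme_id == th]
    expect_equal(s[1], s[2])
  }
  cfg <- sim_config(copy_population = TRUE, cycles_per_stratum = c(6L, 8L),
                    n_song_types = 4L, seed = 8)
  sim <- simulate_song_culture(cfg)
  f <- filter_corpus(sim$corpus)
  sc <- song_type_complexity(f)
  expect_equal(nrow(sc), 8L)  # 4 song types x 2 populations
  for (st in unique(sc$song_type)) {
    s <- sc$pc1_score[sc$song_type == st]
    expect_equal(s[1], s[2], tolerance = 1e-10)
  }
})

test_that("song-type complexity table has one row per type and population", {
  sim <- simulate_song_culture(sim_config(cycles_per_stratum = c(4L, 6L),
                                          seed = 12))
  f <- filter_corpus(sim$corpus)
  sc <- song_type_complexity(f)
  expect_equal(nrow(sc), 12L)
  expect_setequal(unique(sc$population), c("EA", "NC"))
  pca <- attr(sc, "pca")
  expect_named(pca, "pooled")
  expect_true(pca$pooled$loadings["total_units"] > 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_complexity_csv(sc, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".pca.json")))
  back <- read.csv(path)
  expect_equal(nrow(back), 12L)
})
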