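test_that("acoustic substitution costs normalize as specified", {
  dict <- toy_dictionary()
  costs <- unit_similarity_costs(dict, beta = 1)
  expect_true(isSymmetric(costs$cost))
  expect_equal(unname(diag(costs$cost)), rep(0, 4))
  expect_true(all(costs$cost >= 0 & costs$cost <= 1))
  # the toy features are collinear: units sit on a line at equal z-spacing,
  # so costs are proportional to label distance
  expect_equal(unname(costs$cost["A", "D"]), 1)
  expect_equal(unname(costs$cost["A", "B"]), 1 / 3, tolerance = 1e-10)
  expect_equal(unname(costs$cost["A", "C"]), 2 / 3, tolerance = 1e-10)

  # identical feature vectors cost 0, the most distant pair costs 1 for
  # any beta
  d2 <- unit_dictionary(c("X", "Y", "Z"),
                        matrix(c(1, 1, 2, 5, 5, 9), 3,
                               dimnames = list(NULL, c("duration_s", "f"))))
  for (beta in c(0.5, 1, 2)) {
    cc <- unit_similarity_costs(d2, beta = beta)
    expect_equal(unname(cc$cost["X", "Y"]), 0)
    expect_equal(unname(cc$cost["X", "Z"]), 1)
  }
})

test_that("three equally spaced units give costs (0, 0.5, 1)", {
  d <- unit_dictionary(c("U1", "U2", "U3"),
                       matrix(c(1, 2, 3, 100, 200, 300), 3,
                              dimnames = list(NULL, c("duration_s",
                                                      "peak_frequency_hz"))))
  cc <- unit_similarity_costs(d, beta = 1)
  # oracle: direct pairwise distance enumeration on the z-scored features
  z <- scale(d$features)
  dm <- as.matrix(dist(z))
  expect_equal(unname(cc$cost), unname(dm / max(dm)))
  expect_equal(unname(cc$cost["U1", "U2"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(cc$cost["U1", "U3"]), 1)
})

test_that("zero-variance features are dropped with a warning", {
  d <- unit_dictionary(c("U1", "U2"),
                       matrix(c(1, 2, 7, 7), 2,
                              dimnames = list(NULL, c("duration_s", "flat"))))
  expect_warning(cc <- unit_similarity_costs(d), "flat")
  expect_equal(unname(cc$cost["U1", "U2"]), 1)
  dd <- unit_dictionary(c("U1", "U2"),
                        matrix(c(3, 3, 7, 7), 2,
                               dimnames = list(NULL, c("duration_s", "flat"))))
  expect_error(suppressWarnings(unit_similarity_costs(dd)), "variance")
})

test_that("weighted Levenshtein matches hand examples and handles errors", {
  costs <- manual_costs(c("A", "B", "C", "D"),
                        pairs = list(list("B", "D", 0.4)))
  expect_equal(weighted_levenshtein(c("A", "B", "C"), c("A", "B", "C"),
                                    costs), 0)
  expect_equal(weighted_levenshtein(character(0), c("A", "B", "C"), costs), 3)
  expect_equal(weighted_levenshtein(c("A", "B", "C"), c("A", "D", "C"),
                                    costs), 0.4)
  expect_error(weighted_levenshtein(c("A", "Z"), c("A"), costs), "Z")
})

test_that("LSI normalizes by the longer sequence and lies in [0, 1]", {
  costs <- manual_costs(c("A", "B", "C", "D"),
                        pairs = list(list("B", "D", 0.4)))
  expect_equal(lsi(c("A", "B"), c("A", "B")), 1)
  expect_equal(lsi(c("A", "B", "C"), c("A", "D", "C"), costs), 1 - 0.4 / 3)
  # disjoint same-length sequences with all substitution costs 1
  expect_equal(lsi(c("A", "B"), c("C", "D")), 0)
  expect_error(lsi(character(0), c("A")), "empty")
})

test_that("weighted edit distance agrees with the exhaustive pairing oracle", {
  set.seed(101)
  labels <- c("A", "B", "C", "D")
  dict <- toy_dictionary()
  weighted <- unit_similarity_costs(dict)
  unweighted <- identity_costs(labels)
  for (i in 1:300) {
    a <- sample(labels, sample(0:6, 1), replace = TRUE)
    b <- sample(labels, sample(1:6, 1), replace = TRUE)
    for (cc in list(weighted, unweighted)) {
      expect_equal(weighted_levenshtein(a, b, cc),
                   oracle_wld(a, b, cc$cost), tolerance = 1e-12)
    }
  }
})

test_that("unweighted WLD is a metric and dominates the weighted form", {
  set.seed(202)
  labels <- c("A", "B", "C", "D")
  weighted <- unit_similarity_costs(toy_dictionary())
  unweighted <- identity_costs(labels)
  for (i in 1:100) {
    a <- sample(labels, sample(1:6, 1), replace = TRUE)
    b <- sample(labels, sample(1:6, 1), replace = TRUE)
    c_ <- sample(labels, sample(1:6, 1), replace = TRUE)
    dab <- weighted_levenshtein(a, b, unweighted)
    dba <- weighted_levenshtein(b, a, unweighted)
    dac <- weighted_levenshtein(a, c_, unweighted)
    dcb <- weighted_levenshtein(c_, b, unweighted)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_lte(weighted_levenshtein(a, b, weighted), dab + 1e-12)
  }
})

test_that("LSI is invariant under cost-preserving relabeling", {
  set.seed(303)
  labels <- c("A", "B", "C", "D")
  perm <- c(A = "C", B = "D", C = "A", D = "B")
  costs <- unit_similarity_costs(toy_dictionary())
  pcost <- costs$cost[perm, perm]
  dimnames(pcost) <- dimnames(costs$cost)
  pcosts <- structure(list(labels = labels, cost = pcost, beta = 1),
                      class = "substitution_costs")
  for (i in 1:25) {
    a <- sample(labels, sample(1:6, 1), replace = TRUE)
    b <- sample(labels, sample(1:6, 1), replace = TRUE)
    # relabeled sequences under the permuted cost matrix score identically
    expect_equal(lsi(a, b, costs),
                 lsi(unname(perm[a]), unname(perm[b]), pcosts))
  }
})

test_that("beta = 0 reduces weighted costs to the unweighted form, and
           raising beta never increases a cost", {
  dict <- toy_dictionary()
  c0 <- unit_similarity_costs(dict, beta = 0)
  off <- row(c0$cost) != col(c0$cost)
  expect_true(all(c0$cost[off] == 1))
  c1 <- unit_similarity_costs(dict, beta = 1)
  c2 <- unit_similarity_costs(dict, beta = 2)
  expect_true(all(c2$cost <= c1$cost + 1e-12))
  expect_true(all(c1$cost <= c0$cost + 1e-12))
})

test_that("pairwise LSI matrix matches element-wise recomputation", {
  set.seed(404)
  labels <- c("A", "B", "C", "D")
  costs <- unit_similarity_costs(toy_dictionary())
  items <- replicate(5, sample(labels, sample(2:6, 1), replace = TRUE),
                     simplify = FALSE)
  names(items) <- paste0("p", 1:5)
  sim <- pairwise_lsi_matrix(items, costs)
  expect_true(isSymmetric(sim$values))
  expect_equal(unname(diag(sim$values)), rep(1, 5))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(sim$values[i, j], lsi(items[[i]], items[[j]], costs))
    }
  }
  # two identical phrases give a matrix of ones
  twin <- pairwise_lsi_matrix(list(a = c("A", "B"), b = c("A", "B")))
  expect_equal(unname(twin$values), matrix(1, 2, 2))
  expect_error(pairwise_lsi_matrix(list(c("A"))), "at least 2")
})

test_that("similarity TSV export writes the lower triangle", {
  sim <- pairwise_lsi_matrix(list(a = c("A", "B"), b = c("A", "C"),
                                  c = c("B", "C")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(sim, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  expect_match(lines[2], "^a\t1\\.000000\t\t$")
})
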