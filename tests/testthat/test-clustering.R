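four_point_dist <- function() {
  m <- matrix(0.9, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                         c("A", "B", "C", "D")))
  m["A", "B"] <- m["B", "A"] <- 0.2
  m["C", "D"] <- m["D", "C"] <- 0.3
  diag(m) <- 0
  m
}

test_that("UPGMA reproduces hand-computed merge orders and heights", {
  # 3 points: {1,2} forced first, then the root
  m3 <- matrix(c(0, 0.1, 0.8, 0.1, 0, 0.8, 0.8, 0.8, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d3 <- average_linkage(m3)
  expect_equal(d3$hclust$height, c(0.1, 0.8))
  expect_equal(sort(cutree(d3$hclust, k = 2)[c("x", "y")]),
               c(x = 1L, y = 1L))

  # 4 points: merges {A,B}@0.2, {C,D}@0.3, root@0.9
  d4 <- average_linkage(four_point_dist())
  expect_equal(d4$hclust$height, c(0.2, 0.3, 0.9))
  cl <- cut_clusters(d4, 0.5)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_equal(cl[["C"]], cl[["D"]])
  expect_false(cl[["A"]] == cl[["C"]])

  # n identical items merge at height 0
  m0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(average_linkage(m0)$hclust$height, c(0, 0))
})

test_that("non-ultrametric 4-point example matches hand-computed UPGMA", {
  # d(A,B)=0.2 d(A,C)=0.5 d(B,C)=0.6 d(A,D)=0.9 d(B,D)=0.8 d(C,D)=0.7
  m <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  m["A", "B"] <- 0.2; m["A", "C"] <- 0.5; m["B", "C"] <- 0.6
  m["A", "D"] <- 0.9; m["B", "D"] <- 0.8; m["C", "D"] <- 0.7
  m <- m + t(m)
  dend <- average_linkage(m)
  # hand UPGMA: {A,B}@0.2; d(AB,C)=0.55 -> {AB,C}@0.55; root@(0.9+0.8+0.7)/3
  expect_equal(dend$hclust$height, c(0.2, 0.55, 0.8))
  coph <- as.matrix(cophenetic(dend$hclust))
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.55)
  expect_equal(coph["B", "D"], 0.8)
  # CCC equals the direct Pearson correlation of the two 6-vectors
  cc <- cophenetic_correlation(m, dend)
  direct <- cor(c(0.2, 0.5, 0.9, 0.6, 0.8, 0.7),
                c(0.2, 0.55, 0.8, 0.55, 0.8, 0.8))
  expect_equal(cc$ccc, direct, tolerance = 1e-12)
  expect_true(cc$pass)
})

test_that("CCC is 1 on ultrametric input and errors on zero variance", {
  cc <- cophenetic_correlation(four_point_dist())
  expect_equal(cc$ccc, 1)
  meq <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(meq) <- 0
  expect_error(cophenetic_correlation(meq), "variance")
})

test_that("merge heights are monotone and cophenetic matrices ultrametric", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
    dend <- average_linkage(m)
    expect_false(is.unsorted(dend$hclust$height))
    coph <- as.matrix(cophenetic(dend$hclust))
    for (a in 1:(n - 2)) {
      for (b in (a + 1):(n - 1)) {
        for (cc in (b + 1):n) {
          expect_lte(coph[a, cc], max(coph[a, b], coph[b, cc]) + 1e-12)
        }
      }
    }
  }
})

test_that("cut thresholds 0 and above-root behave as connected components", {
  dend <- average_linkage(four_point_dist())
  expect_equal(length(unique(cut_clusters(dend, 0))), 4L)
  expect_equal(length(unique(cut_clusters(dend, 1.5))), 1L)
})

test_that("bootstrap support separates tight clusters and is deterministic", {
  # two well-separated families of sequences
  items <- c(
    lapply(1:6, function(i) c("A", "A", "B", "A")),
    lapply(1:6, function(i) c("C", "D", "D", "C", "D")))
  names(items) <- paste0("s", 1:12)
  dend <- bootstrap_support(items, NULL, B = 100, seed = 9)
  # locate the two 6-leaf family nodes: they must have support >= 0.95
  h <- dend$hclust
  leafsets <- list()
  for (k in seq_len(nrow(h$merge))) {
    kids <- h$merge[k, ]
    leafsets[[k]] <- sort(c(
      if (kids[1] < 0) h$labels[-kids[1]] else leafsets[[kids[1]]],
      if (kids[2] < 0) h$labels[-kids[2]] else leafsets[[kids[2]]]))
  }
  fam1 <- which(vapply(leafsets, function(s)
    setequal(s, paste0("s", 1:6)), logical(1)))
  fam2 <- which(vapply(leafsets, function(s)
    setequal(s, paste0("s", 7:12)), logical(1)))
  expect_length(fam1, 1)
  expect_gte(dend$support[fam1], 0.95)
  expect_gte(dend$support[fam2], 0.95)

  again <- bootstrap_support(items, NULL, B = 100, seed = 9)
  expect_identical(dend$support, again$support)

  b1 <- bootstrap_support(items, NULL, B = 1, seed = 4)
  expect_true(all(b1$support %in% c(0, 1)))
  expect_error(bootstrap_support(items, NULL, B = 0), "B must be")
})

test_that("assignment verification matches the pair-counting ARI oracle", {
  ref <- setNames(rep(c("t1", "t2"), each = 5), paste0("i", 1:10))
  same <- verify_assignments(setNames(rep(1:2, each = 5), paste0("i", 1:10)),
                             ref)
  expect_equal(same$ari, 1)
  expect_true(all(same$purity == 1))

  # one item moved between two equal clusters of size 5
  moved <- setNames(c(rep(1L, 4), 2L, rep(2L, 5)), paste0("i", 1:10))
  got <- verify_assignments(moved, ref)
  expect_equal(got$ari, oracle_ari(unname(moved), unname(ref)),
               tolerance = 1e-12)

  # random assignment at large n has ARI near 0
  set.seed(11)
  n <- 300
  big_ref <- setNames(sample(1:3, n, replace = TRUE), paste0("x", 1:n))
  rand <- setNames(sample(1:3, n, replace = TRUE), paste0("x", 1:n))
  expect_lt(abs(verify_assignments(rand, big_ref)$ari), 0.05)

  expect_error(verify_assignments(setNames(1:2, c("a", "b")),
                                  setNames(1:2, c("a", "c"))),
               "different item sets")
})

test_that("random small labelings agree with the ARI oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    x <- setNames(sample(1:3, n, replace = TRUE), paste0("i", 1:n))
    y <- setNames(sample(1:3, n, replace = TRUE), paste0("i", 1:n))
    expect_equal(verify_assignments(x, y)$ari,
                 oracle_ari(unname(x), unname(y)), tolerance = 1e-12)
  }
})

test_that("Newick export carries support values and reparses", {
  items <- c(lapply(1:3, function(i) c("A", "B")),
             lapply(1:3, function(i) c("C", "D", "C")))
  names(items) <- paste0("s", 1:6)
  dend <- bootstrap_support(items, NULL, B = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, names(items))
  expect_true(any(nzchar(phy$node.label)))
})
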