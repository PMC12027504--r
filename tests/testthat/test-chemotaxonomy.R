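test_that("ordinal coding follows the bin convention", {
  expect_equal(code_profile(c(0, 0.02, 0.7, 3, 39.4)), c(0L, 1L, 2L, 3L, 4L))
  expect_equal(code_profile(NA), 0L)               # nd
  # boundary convention: [0.5, 1) -> 2, [1, 5] -> 3, (5, inf) -> 4
  expect_equal(code_profile(c(0.4999, 0.5, 0.9999, 1, 5, 5.0001)),
               c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(code_profile(-0.1), ">= 0")
  # custom bounds are honoured
  expect_equal(code_profile(0.7, bounds = c(0.8, 2, 5)), 1L)
})

test_that("re-coding bin representatives is idempotent", {
  set.seed(17)
  p <- c(0, exp(runif(200, log(0.001), log(40))))
  codes <- code_profile(p)
  reps <- c(0, 0.25, 0.75, 3, 10)[codes + 1L]   # a representative per bin
  expect_equal(code_profile(reps), codes)
})

test_that("the coded reference matrix mirrors the fixture", {
  long <- population_means()
  cm <- coded_matrix(long, chc_catalog())
  expect_equal(dim(cm), c(6L, 30L))
  expect_true(all(cm %in% 0:4))
  # zero codes coincide exactly with the nd cells
  expect_equal(sum(cm == 0), sum(!long$detected))
  nd_wdln <- long$label[long$population == "WDLN" & !long$detected]
  expect_equal(sort(colnames(cm)[cm["WDLN", ] == 0]), sort(nd_wdln))
  # spot checks against printed means
  expect_equal(cm["EDJL", "11-meC27"], 1L)   # 0.02 %
  expect_equal(cm["ARIM", "9-C27:1"], 4L)    # 39.4 %
  expect_error(coded_matrix(cbind(`not-a-compound` = 1), chc_catalog()),
               "not in the catalog")
  expect_warning(coded_matrix(rbind(long,
    within(long[long$population == "MJHL", ], {mean <- 0; population <- "EMPTY"})),
    chc_catalog()), "EMPTY")
})

test_that("UPGMA reproduces the closed-form three-item tree", {
  d <- as.dist(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- upgma(d)
  expect_equal(tr$height, c(2, 8))
  phy <- ape::as.phylo(tr)
  depth <- max(ape::node.depth.edgelength(phy))
  expect_equal(depth, 4)                      # node height = half merge distance
  expect_equal(write_newick(tr), "((A:1,B:1):3,C:4);")
})

test_that("UPGMA agrees with the reference agglomeration on random matrices", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    x <- matrix(rexp(n * 5), n)
    rownames(x) <- LETTERS[seq_len(n)]
    d <- dist(x)
    mine <- upgma(d)
    ref <- stats::hclust(d, method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    # same partition (up to cluster relabeling) at every merge level
    for (k in 2:(n - 1)) {
      a <- stats::cutree(mine, k); b <- stats::cutree(ref, k)
      expect_equal(length(unique(paste(a, b))), k,
                   label = sprintf("rep %d k %d", rep, k))
    }
    # ultrametric by construction
    expect_true(ape::is.ultrametric(ape::as.phylo(mine)))
  }
})

test_that("UPGMA ties break lexicographically and deterministically", {
  m <- matrix(c(0, 1, 1, 1,
                1, 0, 2, 2,
                1, 2, 0, 2,
                1, 2, 2, 0), 4,
              dimnames = list(c("d", "c", "b", "a"), c("d", "c", "b", "a")))
  tr <- upgma(as.dist(m))
  # pairs (d,c), (d,b), (d,a) all tie at 1: (a,d) merges first
  first <- sort(tr$labels[-tr$merge[1, ]])
  expect_equal(first, c("a", "d"))
  expect_identical(write_newick(tr), write_newick(upgma(as.dist(m))))
})

test_that("two items join at their distance", {
  d <- dist(matrix(c(0, 3), 2, dimnames = list(c("a", "b"), NULL)))
  tr <- upgma(d)
  expect_equal(tr$height, 3)
})

test_that("newick serialization is canonical and byte-stable", {
  set.seed(29)
  for (rep in 1:5) {
    x <- matrix(rexp(30), 6)
    rownames(x) <- sample(LETTERS[1:6])
    tr <- upgma(dist(x))
    s1 <- write_newick(tr)
    s2 <- write_newick(ape::read.tree(text = s1))
    expect_identical(s1, s2)
  }
  # file round trip
  f <- tempfile(fileext = ".nwk")
  tr <- upgma(dist(matrix(c(0, 1, 5), 3,
                          dimnames = list(c("a", "b", "c"), NULL))))
  write_newick(tr, file = f)
  expect_identical(write_newick(f), write_newick(tr))
})

test_that("Robinson-Foulds matches the quartet brute-force oracle", {
  expect_equal(compare_trees("((A,B),(C,D));", "((A,B),(C,D));")$rf, 0)
  expect_equal(compare_trees("((A,B),(C,D));", "((A,C),(B,D));")$rf, 2)
  # caterpillar vs balanced six-leaf trees
  catp <- "(((((A,B),C),D),E),F);"
  bal <- "(((A,B),(C,D)),(E,F));"
  expect_equal(compare_trees(catp, bal)$rf,
               oracle_rf(ape::read.tree(text = catp),
                         ape::read.tree(text = bal)))
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    t1 <- random_labelled_tree(n)
    t2 <- random_labelled_tree(n)
    expect_equal(compare_trees(t1, t2)$rf, oracle_rf(t1, t2),
                 label = sprintf("rep %d n %d", rep, n))
    expect_equal(compare_trees(t1, t2)$rf,
                 as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))))
    expect_equal(compare_trees(t1, t1)$rf, 0)
    expect_true(compare_trees(t1, t2)$normalized >= 0 &&
                  compare_trees(t1, t2)$normalized <= 1)
  }
  expect_error(compare_trees("((A,B),(C,D));", "((A,B),(C,E));"),
               "leaf sets differ")
})

test_that("the coded reference tree pairs GHIM with YCHL first", {
  cm <- coded_matrix(population_means(), chc_catalog())
  tr <- upgma(bray_curtis(cm))
  first <- sort(tr$labels[-tr$merge[1, ]])
  expect_equal(first, c("GHIM", "YCHL"))
})
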