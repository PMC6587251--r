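test_that("pca_reduce yields requested shape with ordered variance", {
  set.seed(21)
  m <- matrix(rnorm(9 * 30), 9, 30,
              dimnames = list(paste0("s", 1:9), NULL))
  red <- pca_reduce(m, 6)
  expect_equal(dim(red$components), c(9L, 6L))
  expect_length(red$explained_variance, 6L)
  expect_true(all(diff(red$explained_variance) <= 1e-12))
  expect_true(all(red$explained_variance >= 0))
  expect_error(pca_reduce(m, 10), "min\\(N, p\\)")
})

test_that("total variance is conserved and rank-1 data is preserved by 1 PC", {
  set.seed(22)
  m <- matrix(rnorm(8 * 5), 8, 5)
  red <- pca_reduce(m, 5)
  col_var <- sum(apply(scale(m, scale = FALSE), 2, stats::var))
  expect_equal(red$total_variance, col_var, tolerance = 1e-9)
  expect_equal(sum(red$explained_variance), col_var, tolerance = 1e-9)

  # points on a line in feature space: one component captures all geometry
  t_par <- rnorm(7)
  line <- outer(t_par, c(1, -2, 0.5, 3))
  rownames(line) <- paste0("p", 1:7)
  red1 <- pca_reduce(line, 1)
  d_red <- as.matrix(stats::dist(red1$components))
  d_raw <- as.matrix(stats::dist(line))
  expect_equal(unname(d_red), unname(d_raw), tolerance = 1e-9)
})

test_that("PCA at full rank is an isometry for Euclidean distances", {
  set.seed(23)
  m <- matrix(rnorm(10 * 40), 10, 40, dimnames = list(paste0("s", 1:10), NULL))
  red <- pca_reduce(m, 10)       # full rank: min(N, p) components
  d_red <- sequence_distances(red, "euclidean")
  d_raw <- as.matrix(stats::dist(scale(m, scale = FALSE)))
  expect_equal(unname(d_red), unname(d_raw), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA sign convention makes repeated runs identical", {
  set.seed(24)
  m <- matrix(rnorm(6 * 12), 6, 12, dimnames = list(letters[1:6], NULL))
  r1 <- pca_reduce(m, 4)
  r2 <- pca_reduce(m, 4)
  expect_identical(r1$components, r2$components)
  for (j in seq_len(ncol(r1$rotation))) {
    i_max <- which.max(abs(r1$rotation[, j]))
    expect_gt(r1$rotation[i_max, j], 0)
  }
})

test_that("the four metrics match hand-computed values", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(sequence_distances(m, "euclidean")["a", "b"], 5)
  expect_equal(sequence_distances(m, "manhattan")["a", "b"], 7)
  m2 <- rbind(a = c(1, 0), b = c(0, 1), c = c(2, 0))
  expect_equal(sequence_distances(m2, "cosine")["a", "b"], 1)
  expect_equal(sequence_distances(m2, "cosine")["a", "c"], 0)
  m3 <- rbind(a = c(1, 0), b = c(1, 0), c = c(4, 6))
  d3 <- sequence_distances(m3, "euclidean")
  expect_equal(d3["a", "b"], 0)
  # standardized Euclidean: divide columns by sample sd
  sds <- apply(m3, 2, sd)
  expect_equal(sequence_distances(m3, "seuclidean")["a", "c"],
               sqrt(sum(((m3["a", ] - m3["c", ]) / sds)^2)), tolerance = 1e-12)
})

test_that("metric edge cases: zero vectors and zero-variance columns", {
  m <- rbind(a = c(0, 0), b = c(1, 2))
  expect_error(sequence_distances(m, "cosine"), "a")
  m2 <- rbind(a = c(1, 5), b = c(2, 5), c = c(4, 5))
  expect_warning(d <- sequence_distances(m2, "seuclidean"), "zero-variance")
  # constant column dropped; remaining column has sd = sd(c(1,2,4))
  expect_equal(d["a", "c"], 3 / sd(c(1, 2, 4)), tolerance = 1e-12)
})

test_that("distance matrices are symmetric, non-negative, zero-diagonal", {
  set.seed(25)
  m <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(paste0("s", 1:8), NULL))
  for (metric in c("euclidean", "manhattan", "cosine", "seuclidean")) {
    d <- sequence_distances(m, metric)
    expect_equal(d, t(d), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(d >= 0))
    expect_true(all(diag(d) == 0))
  }
})

test_that("UPGMA reproduces the hand-run 3-leaf example", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  tree <- build_tree(d, "upgma")
  expect_true(ape::is.ultrametric(tree, tol = 1e-9))
  heights <- sort(unname(ape::branching.times(tree)))
  expect_equal(heights, c(1, 4), tolerance = 1e-12)  # A,B join at 1; C at 4
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(coph["A", "B"], 2, tolerance = 1e-12)
  expect_equal(coph["A", "C"], 8, tolerance = 1e-12)
})

test_that("UPGMA trees are ultrametric on random inputs", {
  set.seed(26)
  for (rep in 1:5) {
    m <- matrix(rnorm(7 * 10), 7, 10, dimnames = list(paste0("s", 1:7), NULL))
    tree <- build_tree(sequence_distances(m, "euclidean"), "upgma")
    coph <- ape::cophenetic.phylo(tree)
    for (trip in utils::combn(7, 3, simplify = FALSE)) {
      dd <- sort(c(coph[trip[1], trip[2]], coph[trip[1], trip[3]],
                   coph[trip[2], trip[3]]))
      expect_lt(dd[3] - dd[2], 1e-9)
    }
  }
})

test_that("NJ recovers an additive tree exactly", {
  set.seed(27)
  gen <- ape::rtree(6, br = stats::runif)
  gen$edge.length <- gen$edge.length + 0.1
  d_add <- ape::cophenetic.phylo(gen)
  nj_tree <- build_tree(d_add, "nj")
  expect_equal(
    unname(ape::cophenetic.phylo(nj_tree)[rownames(d_add), colnames(d_add)]),
    unname(d_add), tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(nj_tree)), 0,
               ignore_attr = TRUE)
})

test_that("identical sequences become siblings at height zero", {
  catalog <- fixture_catalog()
  set.seed(28)
  s <- random_protein(60)
  fm <- feature_matrix(c(x1 = s, x2 = s, y = random_protein(60),
                         z = random_protein(60)), catalog)
  red <- pca_reduce(fm, 3)
  tree <- build_tree(sequence_distances(red, "euclidean"), "upgma")
  coph <- ape::cophenetic.phylo(tree)
  expect_lt(coph["x1", "x2"], 1e-9)
  expect_true(ape::is.monophyletic(tree, c("x1", "x2")))
})

test_that("newick export round-trips and sanitizes labels", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- build_tree(d, "upgma")
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tf)
  expect_identical(readLines(tf), "(A:1,B:1);")

  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("Fin whale", "Blue whale", "Opossum"),
                               c("Fin whale", "Blue whale", "Opossum")))
  t3 <- build_tree(d3, "upgma")
  write_newick(t3, tf)
  back <- ape::read.tree(tf)
  expect_setequal(back$tip.label, c("Fin_whale", "Blue_whale", "Opossum"))
  expect_equal(sort(unname(ape::branching.times(back))), c(1, 4),
               tolerance = 1e-9)
})

test_that("build_tree validates input", {
  d <- matrix(c(0, Inf, Inf, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(build_tree(d), "non-finite")
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(build_tree(d2, "nj"), "at least 3")
})

test_that("distance TSV and PHYLIP exports round-trip / are well-formed", {
  set.seed(29)
  m <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  d <- sequence_distances(m, "manhattan")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_distances_tsv(d, tf)
  expect_equal(read_distances_tsv(tf), unclass(d), tolerance = 1e-15,
               ignore_attr = TRUE)
  pf <- withr::local_tempfile(fileext = ".phy")
  write_distances_phylip(d, pf)
  lines <- readLines(pf)
  expect_equal(as.integer(trimws(lines[1])), 5L)
  expect_length(lines, 6L)
})
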