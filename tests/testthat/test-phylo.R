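test_that("Poisson distance matches the closed form with pairwise deletion", {
  expect_equal(poisson_distance("ACDEFG", "ACDEFG"), 0)
  # p = 0.1 over 10 comparable sites
  expect_equal(poisson_distance("AAAAAAAAAA", "AAAAAAAAAC"), -log(0.9),
               tolerance = 1e-12)
  # 10 residues, 2 gapped columns, 2 differences: p = 0.25
  expect_equal(poisson_distance("AAAAAAAA--", "CCAAAAAAAA"), -log(0.75),
               tolerance = 1e-12)
  # ambiguity codes are not comparable
  expect_equal(poisson_distance("AXAA", "AKAC"), -log(1 - 1 / 3))
  expect_error(poisson_distance("AAAA", "CCCC"), "saturated")
  expect_error(poisson_distance("--AA", "AA--"), "comparable")
  # symmetric and monotone in the proportion of differences
  a <- "AAAAAAAAAA"
  ds <- vapply(1:8, function(k) {
    b <- paste0(strrep("C", k), strrep("A", 10 - k))
    poisson_distance(a, b)
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_equal(poisson_distance("AC-D", "AKKD"),
               poisson_distance("AKKD", "AC-D"))
})

test_that("complete deletion drops every gapped column first", {
  aln <- c(s1 = "AK-DE", s2 = "AKCDE", s3 = "GKCDE")
  d <- poisson_dist(aln, deletion = "complete")
  # column 3 removed for all pairs: s2 vs s3 compare 4 sites, 1 diff
  expect_equal(d["s2", "s3"], -log(1 - 1 / 4))
})

test_that("three-taxon NJ solves the three-point equations", {
  d <- matrix(c(0, 5, 6, 5, 0, 9, 6, 9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 4, c = 5))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ".")
  asym <- d
  asym[1, 2] <- 4
  expect_error(nj_tree(asym), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(4:10, 1)
      tr <- ape::rtree(n, rooted = FALSE)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
      d <- ape::cophenetic.phylo(tr)
      out <- nj_tree(d)
      dd <- ape::cophenetic.phylo(out)[rownames(d), colnames(d)]
      expect_lt(max(abs(dd - d)), 1e-8)
    }
  })
})

test_that("NJ topology is invariant to taxon order and matches ape::nj", {
  withr::with_seed(23, {
    tr <- ape::rtree(8, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1)
    d <- ape::cophenetic.phylo(tr)
    d <- d + matrix(stats::runif(64, 0, 0.01), 8, 8)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    t1 <- nj_tree(d)
    perm <- sample(rownames(d))
    t2 <- nj_tree(d[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1),
                                           ape::unroot(t2))), 0)
    # independent implementation agrees on the topology
    t3 <- ape::nj(stats::as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1),
                                           ape::unroot(t3))), 0)
  })
})

# alignment with n1 columns supporting AB|CD, n2 supporting AC|BD, rest
# constant
quartet_alignment <- function(n1, n2, n_const) {
  col1 <- c("K", "K", "R", "R")
  col2 <- c("K", "R", "K", "R")
  col0 <- c("A", "A", "A", "A")
  m <- cbind(matrix(rep(col1, n1), 4), matrix(rep(col2, n2), 4),
             matrix(rep(col0, n_const), 4))
  stats::setNames(apply(m, 1, paste, collapse = ""),
                  c("A", "B", "C", "D"))
}

test_that("clean hierarchical signal gives 100% support everywhere", {
  col_ab <- c("K", "K", "R", "R", "R")
  col_cd <- c("G", "G", "H", "H", "G")
  col0 <- rep("A", 5)
  m <- cbind(matrix(rep(col_ab, 30), 5), matrix(rep(col_cd, 30), 5),
             matrix(rep(col0, 40), 5))
  aln <- stats::setNames(apply(m, 1, paste, collapse = ""),
                         c("A", "B", "C", "D", "E"))
  bs <- bootstrap_support(aln, n_reps = 200, seed = 3)
  expect_equal(bs$n_completed, 200L)
  expect_true(all(bs$support$support_pct == 100))
  # deterministic given the seed
  bs2 <- bootstrap_support(aln, n_reps = 200, seed = 3)
  expect_identical(bs$support, bs2$support)
})

test_that("quartet support tracks the column-resampling oracle", {
  # 80% of informative columns favour AB|CD
  aln <- quartet_alignment(16, 4, 80)
  bs <- bootstrap_support(aln, n_reps = 500, seed = 1)
  ab_cd <- bs$support$support_pct[bs$support$bipartition %in%
                                    c("A|B", "C|D")]
  # oracle: a replicate recovers AB|CD iff it resamples at least as many
  # AB|CD columns as AC|BD columns (ties go to the first joined pair)
  oracle <- withr::with_seed(99, {
    draws <- stats::rmultinom(20000, 100, c(16, 4, 80) / 100)
    100 * mean(draws[1, ] >= draws[2, ])
  })
  expect_lt(abs(ab_cd - oracle), 5)

  # a more finely balanced case
  aln2 <- quartet_alignment(12, 8, 80)
  bs2 <- bootstrap_support(aln2, n_reps = 500, seed = 1)
  ab_cd2 <- bs2$support$support_pct[bs2$support$bipartition %in%
                                      c("A|B", "C|D")]
  oracle2 <- withr::with_seed(99, {
    draws <- stats::rmultinom(20000, 100, c(12, 8, 80) / 100)
    100 * mean(draws[1, ] >= draws[2, ])
  })
  expect_lt(abs(ab_cd2 - oracle2), 5)
})

test_that("supports land on the right internal nodes in Newick output", {
  aln <- quartet_alignment(20, 0, 80)
  bs <- bootstrap_support(aln, n_reps = 100, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(bs, f)
  txt <- readLines(f)
  expect_match(txt, "100")
  reread <- ape::read.tree(f)
  expect_setequal(reread$tip.label, c("A", "B", "C", "D"))
})
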