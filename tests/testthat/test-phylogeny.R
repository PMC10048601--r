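test_that("genotype distance is discordance over co-observed sites", {
  m <- rbind(a = c(0, 2, 0, 2), b = c(0, 2, 0, 2), c = c(2, 0, 2, 0),
             d = c(0, 2, 2, 0))
  d <- genotype_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "d"], 0.5)
  expect_equal(d, t(d))
  # missing calls shrink the denominator
  m2 <- rbind(a = c(0, 2, NA, 2), b = c(0, 0, 0, NA))
  expect_equal(genotype_distance(m2)["a", "b"], 0.5)  # 1 of 2 co-observed
  # a pair with no co-observed sites is an error naming the pair
  m3 <- rbind(a = c(0, NA), b = c(NA, 2))
  expect_error(genotype_distance(m3), "co-observed")
})

test_that("genotype distance is a pseudo-metric on complete matrices", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(sample(0:2, 8 * 30, replace = TRUE), nrow = 8,
                dimnames = list(paste0("s", 1:8), NULL))
    d <- genotype_distance(m)
    expect_equal(diag(d), stats::setNames(rep(0, 8), paste0("s", 1:8)))
    expect_equal(d, t(d))
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("neighbor joining reproduces the 4-taxon worked example", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  # additive matrix: the tree's path lengths reproduce d exactly
  pd <- oracle_tip_dists(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # four-point condition identifies the AB|CD split:
  expect_lt(d["A", "B"] + d["C", "D"],
            min(d["A", "C"] + d["B", "D"], d["A", "D"] + d["B", "C"]))
  # external branches 1,2,3,4 and internal branch 1
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  tip_edge <- function(lab) {
    tr$edge.length[tr$edge[, 2] == match(lab, tr$tip.label)]
  }
  expect_equal(tip_edge("A"), 1)
  expect_equal(tip_edge("B"), 2)
  expect_equal(tip_edge("C"), 3)
  expect_equal(tip_edge("D"), 4)
})

test_that("three taxa resolve by the closed-form star formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$edge.length), c(1, 2, 3))
  expect_equal(oracle_tip_dists(tr)[rownames(d), colnames(d)], d)
})

test_that("NJ exactly recovers 50 random additive trees (6-10 leaves)", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(6:10, 1)
    true_tree <- oracle_random_tree(n)
    d <- oracle_tip_dists(true_tree)
    tr <- neighbor_joining(d)
    pd <- oracle_tip_dists(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(pd - d)), 1e-9)
    # independent topology cross-check against ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("label order does not affect the reconstructed tree", {
  set.seed(13)
  true_tree <- oracle_random_tree(7)
  d <- oracle_tip_dists(true_tree)
  perm <- sample(nrow(d))
  d2 <- d[perm, perm]
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d2)
  p1 <- oracle_tip_dists(t1)
  p2 <- oracle_tip_dists(t2)[rownames(p1), colnames(p1)]
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(d), ">= 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighbor_joining(d3), "symmetric")
  d4 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(d4), "nonnegative")
})

test_that("origin ranking uses proximity with an alphabetical tie-break", {
  # focal F sits close to species Q members, far from P members
  m <- rbind(F  = c(0, 0, 0, 0, 2, 2, 0, 0),
             Q1 = c(0, 0, 0, 0, 2, 2, 0, 2),
             Q2 = c(0, 0, 0, 0, 2, 0, 0, 0),
             P1 = c(2, 2, 2, 2, 0, 0, 2, 0),
             P2 = c(2, 2, 2, 0, 0, 0, 2, 2))
  tr <- neighbor_joining(genotype_distance(m))
  o <- assign_origin(tr, "F", c(Q1 = "Q", Q2 = "Q", P1 = "P", P2 = "P"))
  expect_equal(o$species[1], "Q")
  expect_equal(o$rank, 1:2)
  expect_error(assign_origin(tr, "nope", c(Q1 = "Q")), "not a leaf")

  # two perfectly equidistant species tie and resolve alphabetically
  d <- matrix(0.5, 3, 3, dimnames = list(c("F", "b1", "a1"),
                                         c("F", "b1", "a1")))
  diag(d) <- 0
  tr2 <- neighbor_joining(d)
  o2 <- assign_origin(tr2, "F", c(b1 = "beta", a1 = "alpha"))
  expect_equal(o2$species, c("alpha", "beta"))
  expect_equal(o2$min_dist[1], o2$min_dist[2])
})

test_that("per-chromosome trees subset sites and write Newick files", {
  set.seed(55)
  panel <- simulate_panel(small_config(), seed = 9)
  dir <- withr::local_tempdir()
  res <- chromosome_trees(panel, panel$focal, panel$species_of,
                          newick_dir = dir)
  expect_setequal(names(res$trees), c("chr1", "chr2"))
  expect_true(all(file.exists(file.path(dir, c("tree_chr1.nwk",
                                               "tree_chr2.nwk")))))
  # emitted Newick re-parses to a tree with the same leaf set
  back <- ape::read.tree(file.path(dir, "tree_chr1.nwk"))
  expect_setequal(back$tip.label, rownames(panel$dosage))
  expect_true(all(back$edge.length >= 0))
  # the introgressed chromosome clusters with the donor species
  top <- res$origins[res$origins$rank == 1, ]
  expect_equal(top$species[top$chrom == "chr2"], panel$donor_species)
  expect_equal(top$species[top$chrom == "chr1"], panel$background_species)
})
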