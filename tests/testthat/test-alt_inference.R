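test_that("Fitch scores match hand passes and the enumeration oracle", {
  inv <- MitoAlignment(matrix("C", 4, 6, dimnames = list(c("a1", "a2", "t1", "t2"), NULL)))
  expect_equal(fitchScore(ape::read.tree(text = "((a1,a2),(t1,t2));"), inv), 0L)

  col <- MitoAlignment(c(a1 = "A", a2 = "A", t1 = "T", t2 = "T"))
  expect_equal(fitchScore(ape::read.tree(text = "((a1,a2),(t1,t2));"), col), 1L)
  expect_equal(fitchScore(ape::read.tree(text = "((a1,t1),(a2,t2));"), col), 2L)

  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:6, 1)
    tr <- randomTree(n, seed = seed)
    m <- matrix(sample(c("A", "C", "G", "T", "R", "-"), n * 4, TRUE),
                n, 4, dimnames = list(tr$tip.label, NULL))
    aln <- MitoAlignment(m)
    expect_equal(fitchScore(tr, aln), fitchOracle(tr, aln),
                 label = paste("seed", seed))
  }
})

test_that("Fitch score is additive over concatenated blocks", {
  tr <- randomTree(5, seed = 2)
  mA <- matrix(sample(c("A", "C", "G", "T"), 20, TRUE), 5, 4,
               dimnames = list(tr$tip.label, NULL))
  mB <- matrix(sample(c("A", "C", "G", "T"), 15, TRUE), 5, 3,
               dimnames = list(tr$tip.label, NULL))
  expect_equal(fitchScore(tr, MitoAlignment(cbind(mA, mB))),
               fitchScore(tr, MitoAlignment(mA)) +
                 fitchScore(tr, MitoAlignment(mB)))
})

test_that("exhaustive parsimony search finds all minimal trees", {
  ## one informative column: exactly one MP quartet
  aln <- MitoAlignment(c(a1 = "AAG", a2 = "AAG", t1 = "TAG", t2 = "TAG"))
  mp <- mpSearch(aln, "exhaustive")
  expect_length(mp$trees, 1L)
  expect_true(mp$complete)
  expect_identical(topologyKey(mp$trees[[1]]),
                   topologyKey(ape::read.tree(text = "((a1,a2),(t1,t2));")))

  ## two conflicting informative columns of equal weight: two tied trees
  aln2 <- MitoAlignment(c(w = "AA", x = "AT", y = "TA", z = "TT"))
  mp2 <- mpSearch(aln2, "exhaustive")
  expect_length(mp2$trees, 2L)

  ## tied trees collapse to a star under majority rule
  cons <- majorityRuleConsensus(mp2$trees)
  expect_length(mitopart:::.bipartitions(cons), 0L)

  expect_error(mpSearch(tinyAlignment(10, 20), "exhaustive"), "> 9 taxa")
})

test_that("exhaustive search is invariant to taxon input order", {
  set.seed(3)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 12, TRUE), 5, 12,
              dimnames = list(paste0("t", 1:5), NULL))
  aln <- MitoAlignment(m)
  aln2 <- MitoAlignment(m[c(4, 2, 5, 1, 3), ])
  k1 <- sort(vapply(mpSearch(aln, "exhaustive")$trees, topologyKey, ""))
  k2 <- sort(vapply(mpSearch(aln2, "exhaustive")$trees, topologyKey, ""))
  expect_identical(k1, k2)
})

test_that("Fitch agrees with phangorn's parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  tr <- randomTree(6, seed = 7)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, TRUE), 6, 30,
              dimnames = list(tr$tip.label, NULL))
  expect_equal(fitchScore(tr, MitoAlignment(m)),
               as.integer(phangorn::parsimony(tr, phangorn::phyDat(m))))
})

test_that("ML hill climbing improves monotonically and recovers the truth", {
  set.seed(5)
  tree <- simulateTree(5, height = 0.2, minInternalFrac = 0.08)
  n <- 800L
  gen <- onePartModel(SubstitutionModel("GTR", rates = c(1, 6, 1.5, .8, 10, 1),
                                        freqs = c(.39, .11, .11, .39),
                                        gammaShape = 0.5), n)
  hits <- 0L
  for (rep in 1:5) {
    set.seed(rep * 13)
    aln <- simulateAlignment(tree, singlePartition(n), gen)
    wrong <- ape::unroot(ape::rtopology(5, rooted = FALSE,
                                        tip.label = tree$tip.label))
    wrong$edge.length <- rep(0.05, nrow(wrong$edge))
    res <- mlSearch(aln, gen, start = wrong)
    expect_false(is.unsorted(res$lnLTrace))
    hits <- hits + (rfDistance(res$tree, tree) == 0L)
  }
  expect_gte(hits, 4L)

  ## starting at the generating tree stays put on clean data
  set.seed(99)
  aln <- simulateAlignment(tree, singlePartition(n), gen)
  res0 <- mlSearch(aln, gen, start = tree)
  expect_equal(rfDistance(res0$tree, tree), 0L)
})

test_that("bootstrap supports are percentages with seeded reproducibility", {
  set.seed(5)
  tree <- simulateTree(5, height = 0.2, minInternalFrac = 0.1)
  n <- 500L
  gen <- onePartModel(SubstitutionModel("GTR", rates = c(1, 6, 1.5, .8, 10, 1),
                                        freqs = c(.39, .11, .11, .39),
                                        gammaShape = 0.5), n)
  aln <- simulateAlignment(tree, singlePartition(n), gen)
  bs <- bootstrapSupport(aln, "MP", nReplicates = 20, seed = 4)
  expect_length(bs$trees, 20L)
  expect_true(all(bs$support$percent >= 0 & bs$support$percent <= 100))
  ## trivial leaf bipartitions are reported at 100
  leaf <- bs$support$percent[bs$support$bipartition %in% taxa(aln)]
  expect_true(all(leaf == 100))
  ## replicate columns equal the original count (resampling contract)
  expect_true(all(vapply(bs$trees, function(t) length(t$tip.label), 1L) == 5L))
  bs2 <- bootstrapSupport(aln, "MP", nReplicates = 20, seed = 4)
  expect_identical(bs$support, bs2$support)
  ## strong signal: true internal bipartitions well supported
  truthBip <- mitopart:::.bipartitions(tree)
  sup <- bs$support$percent[match(truthBip, bs$support$bipartition)]
  expect_true(all(!is.na(sup)) && all(sup >= 75))
})

test_that("majority-rule consensus retains the right bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  t2 <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  same <- majorityRuleConsensus(list(t1, t1, t1))
  expect_identical(topologyKey(same), topologyKey(t1))

  ## two trees one NNI apart: the conflicting edge collapses
  maj <- majorityRuleConsensus(list(t1, t2, t1))
  expect_identical(topologyKey(maj), topologyKey(t1))
  strict <- majorityRuleConsensus(list(t1, t2), 1.0)
  expect_identical(mitopart:::.bipartitions(strict), "e,f")

  ## cross-check against ape's consensus on random tree sets
  set.seed(6)
  trees <- lapply(1:7, function(i) ape::rtree(6, tip.label = paste0("t", 1:6)))
  mine <- majorityRuleConsensus(trees, 0.5)
  ref <- ape::consensus(trees, p = 0.5)
  expect_setequal(mitopart:::.bipartitions(mine),
                  mitopart:::.bipartitions(ref))
})
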