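test_that("NNI proposals hit both alternative quartets equally", {
  tr <- quartet()
  set.seed(1)
  keys <- replicate(1000, topologyKey(proposeMove(list(tree = tr),
                                                  "NNI")$state$tree))
  tab <- table(keys)
  expect_length(tab, 2L)                     # never the current topology
  expect_false(topologyKey(tr) %in% names(tab))
  expect_gt(min(tab) / 1000, 0.45)           # ~1/2 each
})

test_that("branch multiplier move reports ln m as Hastings ratio", {
  tr <- quartet()
  set.seed(2)
  for (i in 1:20) {
    before <- tr$edge.length
    mv <- proposeMove(list(tree = tr), "branch")
    after <- mv$state$tree$edge.length
    changed <- which(after != before)
    expect_length(changed, 1L)
    expect_equal(mv$lhr, log(after[changed] / before[changed]),
                 tolerance = 1e-12)
  }
})

test_that("Dirichlet moves stay on the simplex", {
  md <- list(def = mitopart:::.familyDef("GTR"),
             classRates = rep(1 / 6, 6), freqs = c(.4, .2, .2, .2),
             shape = 0.5, family = "GTR")
  st <- list(models = list(md), tree = quartet(), mult = 1)
  set.seed(3)
  for (i in 1:20) {
    f <- proposeMove(st, "freqs", partition = 1L)
    expect_equal(sum(f$state$models[[1]]$freqs), 1, tolerance = 1e-12)
    expect_true(all(f$state$models[[1]]$freqs >= 0))
    e <- proposeMove(st, "exch", partition = 1L)
    expect_equal(sum(e$state$models[[1]]$classRates), 1, tolerance = 1e-12)
  }
})

test_that("identical seeds give identical traces", {
  aln <- tinyAlignment(5, 40, seed = 6)
  pm <- onePartModel(SubstitutionModel("GTR", gammaShape = 0.5), 40)
  cfg <- McmcConfig(nChains = 2L, nGenerations = 300L, sampleEvery = 10L,
                    seed = 99L)
  t1 <- runMcmc(compressPatterns(aln), pm, cfg, monitorTrees = FALSE)
  t2 <- runMcmc(compressPatterns(aln), pm, cfg, monitorTrees = FALSE)
  expect_identical(traceSamples(t1), traceSamples(t2))
})

test_that("prior-only sampling reproduces the prior", {
  ## all-missing data: likelihood is identically 1, so the chain samples
  ## the prior: uniform quartet topologies, exponential branch lengths
  aln <- MitoAlignment(matrix("?", 4, 8,
                              dimnames = list(paste0("t", 1:4), NULL)))
  pm <- onePartModel(SubstitutionModel("JC", nGammaCat = 1L), 8)
  cfg <- McmcConfig(nChains = 1L, nGenerations = 30000L, sampleEvery = 10L,
                    seed = 11L)
  tr <- runMcmc(compressPatterns(aln), pm, cfg, monitorTrees = FALSE)
  post <- postBurnin(tr)
  freq <- table(post$topologyKey) / nrow(post)
  expect_length(freq, 3L)
  ## three MC SE bound using the ESS-deflated sample size
  ess <- effectiveSampleSize(as.numeric(post$topologyKey ==
                                          names(freq)[1]))
  se <- sqrt((1 / 3) * (2 / 3) / max(ess, 50))
  expect_true(all(abs(freq - 1 / 3) < 3 * se + 0.02))
  ## exponential(0.1) branch prior: mean tree length 5 * 0.1
  expect_equal(mean(post$treeLength), 0.5, tolerance = 0.05)
})

test_that("two-taxon branch posterior matches the quadrature oracle", {
  aln <- MitoAlignment(c(a = "AAAAAAAAAA", b = "AAAAAAATTT"))
  pm <- onePartModel(SubstitutionModel("JC", nGammaCat = 1L), 10)
  cfg <- McmcConfig(nChains = 1L, nGenerations = 60000L, sampleEvery = 10L,
                    seed = 7L)
  tr <- runMcmc(compressPatterns(aln), pm, cfg, monitorTrees = FALSE)
  postT <- mean(postBurnin(tr)$treeLength)
  ## the two exponential(10) edges only enter through their sum T,
  ## distributed Gamma(2, 10) a priori
  lik <- function(T) {
    ps <- 0.25 + 0.75 * exp(-4 * T / 3)
    ps^7 * ((1 - ps) / 3)^3
  }
  num <- stats::integrate(function(T) T * lik(T) * stats::dgamma(T, 2, 10),
                          0, 10, rel.tol = 1e-10)$value
  den <- stats::integrate(function(T) lik(T) * stats::dgamma(T, 2, 10),
                          0, 10, rel.tol = 1e-10)$value
  expect_lt(abs(postT - num / den) / (num / den), 0.02)
})

test_that("generating parameters are recovered on a known eight-taxon tree", {
  nwk <- "(((a:.06,b:.06):.03,(c:.06,d:.06):.03):.04,((e:.06,f:.06):.03,(g:.06,h:.06):.03):.04);"
  tree <- ape::unroot(ape::read.tree(text = nwk))
  n <- 1800L
  sch <- PartitionScheme("PS10", list(p1 = 1:600, p2 = 601:1200,
                                      p3 = 1201:1800), n)
  gen <- PartitionedModel(
    lapply(1:3, function(i)
      SubstitutionModel("GTR", rates = c(1, 6, 1.5, .8, 10, 1),
                        freqs = c(.39, .11, .11, .39), gammaShape = 0.5)),
    c(1, 0.4, 4), weights = rep(600L, 3))
  genMult <- rateMultipliers(gen)
  nrep <- 12L
  okT <- okS <- okM <- 0L
  for (rep in seq_len(nrep)) {
    set.seed(rep * 11)
    aln <- simulateAlignment(tree, sch, gen)
    cfg <- McmcConfig(nChains = 1L, nGenerations = 1500L, sampleEvery = 10L,
                      seed = rep * 7L)
    run <- runMcmc(compressPatterns(aln, sch),
                   PartitionedModel(lapply(1:3, function(i)
                     SubstitutionModel("GTR", gammaShape = 0.5)),
                     weights = rep(600L, 3)),
                   cfg, startTree = guideTree(aln), monitorTrees = FALSE)
    post <- postBurnin(run)
    okT <- okT + (mean(post$topologyKey == topologyKey(tree)) >= 0.95)
    ciS <- stats::quantile(post$shape1, c(.025, .975))
    ciM <- stats::quantile(post$mult3, c(.025, .975))
    okS <- okS + (ciS[1] <= 0.5 && 0.5 <= ciS[2])
    okM <- okM + (ciM[1] <= genMult[3] && genMult[3] <= ciM[2])
  }
  expect_gte(okT / nrep, 0.9)
  expect_gte(okS / nrep, 0.9)
  expect_gte(okM / nrep, 0.75)
})

test_that("ESS matches iid and AR(1) references and flags constants", {
  set.seed(4)
  x <- rnorm(10000)
  expect_lt(abs(effectiveSampleSize(x) - 10000) / 10000, 0.1)

  ## AR(1) with rho = 0.5: ESS -> n (1-rho)/(1+rho) = n/3
  n <- 20000
  ar <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  expect_lt(abs(effectiveSampleSize(ar) - n / 3) / (n / 3), 0.15)

  cst <- effectiveSampleSize(rep(2, 100))
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "degenerate"))
  expect_error(effectiveSampleSize(1:5), ">= 10")
})

test_that("the harmonic-mean estimator is exact on worked examples", {
  expect_equal(harmonicMeanLnL(rep(-3.7, 50)), -3.7)
  expect_equal(harmonicMeanLnL(c(0, 1)), log(2 / (1 + exp(-1))),
               tolerance = 1e-12)
  x <- c(-301234.5, -301240.2, -301237.9)
  expect_equal(harmonicMeanLnL(x + 17.3), harmonicMeanLnL(x) + 17.3,
               tolerance = 1e-9)
  expect_true(is.finite(harmonicMeanLnL(rep(-3e5, 10))))
  expect_error(harmonicMeanLnL(numeric(0)))
})

test_that("stationarity assessment accepts, extends and caps", {
  mkTrace <- function(x) {
    n <- length(x)
    new("PosteriorTrace",
        samples = data.frame(generation = seq_len(n) * 10L, lnL = x,
                             treeLength = abs(x) / 100 + seq_len(n) %% 3,
                             topologyKey = "k"),
        trees = list(), config = McmcConfig(nGenerations = n * 10L,
                                            sampleEvery = 10L,
                                            burninFraction = 0))
  }
  set.seed(5)
  good <- mkTrace(rnorm(500))
  expect_identical(assessStationarity(good)$decision, "accept")

  slow <- mkTrace(as.numeric(stats::arima.sim(list(ar = 0.995), 300)))
  res <- assessStationarity(slow)
  expect_identical(res$decision, "extend")
  expect_gt(res$newGenerations, 3000)

  capped <- slow
  capped@config@extensionCap <- capped@config@nGenerations
  res2 <- assessStationarity(capped)
  expect_identical(res2$decision, "accept")
  expect_true(res2$warning)
})

test_that("heating leaves the cold-chain target unchanged", {
  ## a quickly-converging 4-taxon target: the cold-chain equilibrium
  ## moments must agree with and without Metropolis coupling, within
  ## combined ESS-based Monte Carlo error
  set.seed(9)
  tree <- simulateTree(4, height = 0.12, minInternalFrac = 0.1)
  n <- 200L
  gen <- onePartModel(SubstitutionModel("GTR", rates = c(1, 6, 1.5, .8, 10, 1),
                                        freqs = c(.39, .11, .11, .39),
                                        gammaShape = 0.5), n)
  aln <- simulateAlignment(tree, singlePartition(n), gen)
  pats <- compressPatterns(aln)
  cold <- runMcmc(pats, gen, McmcConfig(nChains = 1L, nGenerations = 12000L,
                                        sampleEvery = 10L, seed = 21L),
                  monitorTrees = FALSE)
  hot <- runMcmc(pats, gen, McmcConfig(nChains = 4L, nGenerations = 12000L,
                                       sampleEvery = 10L, seed = 22L),
                 monitorTrees = FALSE)
  for (col in c("lnL", "treeLength")) {
    a <- postBurnin(cold)[[col]]; b <- postBurnin(hot)[[col]]
    se <- sqrt(stats::var(a) / max(effectiveSampleSize(a), 20) +
                 stats::var(b) / max(effectiveSampleSize(b), 20))
    expect_lt(abs(mean(a) - mean(b)), 4 * se + 1e-8, label = col)
  }
})
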