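## Metropolis-coupled MCMC over topology, branch lengths, substitution
## parameters and partition rate multipliers; trace diagnostics and the
## harmonic-mean marginal-likelihood estimator.

#' Prior settings for the Bayesian sampler
#'
#' Topology: uniform over unrooted binary labeled topologies; branch
#' lengths: iid exponential; exchangeabilities and base frequencies:
#' flat Dirichlet; gamma shape: uniform on (0, shapeMax); rate
#' multipliers: flat Dirichlet on the site-weighted simplex (so the
#' site-weighted mean stays 1).
#'
#' @param branchMean mean of the exponential branch-length prior.
#' @param shapeMax upper bound of the uniform gamma-shape prior.
#' @return a list of prior settings.
#' @export
PriorSet <- function(branchMean = 0.1, shapeMax = 200) {
  stopifnot(branchMean > 0, shapeMax > 0)
  list(branchMean = branchMean, shapeMax = shapeMax)
}

## ---- proposal machinery -------------------------------------------------

## Random draw from Dirichlet(alpha)
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (all(x == 0)) x <- rep(1, length(alpha))
  x / sum(x)
}

.ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

## Dirichlet random-walk proposal centred at p with concentration a0.
## Returns new point and log Hastings ratio.
.dirichletMove <- function(p, a0 = 300) {
  p <- pmax(p, 1e-8); p <- p / sum(p)
  q <- .rdirichlet(a0 * p)
  q <- pmax(q, 1e-10); q <- q / sum(q)
  lhr <- .ldirichlet(p, a0 * q) - .ldirichlet(q, a0 * p)
  list(value = q, lhr = lhr)
}

## One NNI move on an unrooted binary phylo. The chosen internal edge
## (u, v) has four incident subtrees; swapping one child of v with one
## other child of u realizes each of the two NNI neighbours with equal
## probability, by direct edge-matrix surgery.
.nniMove <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(NULL)
  e <- tree$edge
  internal <- which(e[, 2] > ntip)
  if (!length(internal)) return(NULL)
  pick <- internal[sample.int(length(internal), 1L)]
  u <- e[pick, 1]; v <- e[pick, 2]
  vkids <- which(e[, 1] == v)
  ukids <- setdiff(which(e[, 1] == u), pick)
  if (!length(vkids) || !length(ukids)) return(NULL)
  a <- vkids[sample.int(length(vkids), 1L)]
  b <- ukids[sample.int(length(ukids), 1L)]
  tmp <- e[a, 2]; e[a, 2] <- e[b, 2]; e[b, 2] <- tmp
  tree$edge <- e
  attr(tree, "order") <- NULL
  tree
}

#' Propose a new sampler state
#'
#' One reversible move of the requested type, returning the new state
#' component and the log Hastings ratio. Exposed mainly for tests of
#' proposal correctness; \code{\link{runMcmc}} uses it internally.
#'
#' @param state list with elements tree (phylo), models (list of
#'   per-partition lists: classRates, freqs, shape, def), mult.
#' @param move one of "NNI", "branch", "freqs", "exch", "shape", "mult".
#' @param priors a \code{\link{PriorSet}}.
#' @param weights site counts per partition (for the multiplier move).
#' @param partition index of the partition a parameter move targets.
#' @return list(state, lhr) or NULL when the move is unavailable.
#' @export
proposeMove <- function(state, move, priors = PriorSet(), weights = NULL,
                        partition = 1L) {
  switch(move,
    NNI = {
      tr <- .nniMove(state$tree)
      if (is.null(tr)) return(NULL)
      ## rescale one random edge to help cross branch-length valleys
      i <- sample.int(length(tr$edge.length), 1L)
      m <- exp(2 * (stats::runif(1) - 0.5))
      tr$edge.length[i] <- tr$edge.length[i] * m
      state$tree <- tr
      list(state = state, lhr = log(m))
    },
    branch = {
      i <- sample.int(length(state$tree$edge.length), 1L)
      m <- exp(2 * (stats::runif(1) - 0.5))
      state$tree$edge.length[i] <- state$tree$edge.length[i] * m
      list(state = state, lhr = log(m))
    },
    freqs = {
      md <- state$models[[partition]]
      if (!md$def$free_freqs) return(NULL)
      mv <- .dirichletMove(md$freqs)
      state$models[[partition]]$freqs <- mv$value
      list(state = state, lhr = mv$lhr)
    },
    exch = {
      md <- state$models[[partition]]
      ncl <- max(md$def$classes)
      if (ncl < 2L) return(NULL)
      mv <- .dirichletMove(md$classRates / sum(md$classRates))
      state$models[[partition]]$classRates <- mv$value
      list(state = state, lhr = mv$lhr)
    },
    shape = {
      md <- state$models[[partition]]
      if (is.na(md$shape)) return(NULL)
      m <- exp(2 * (stats::runif(1) - 0.5))
      s2 <- md$shape * m
      if (s2 >= priors$shapeMax) return(list(state = state, lhr = -Inf))
      state$models[[partition]]$shape <- s2
      list(state = state, lhr = log(m))
    },
    mult = {
      k <- length(state$mult)
      if (k < 2L) return(NULL)
      w <- weights / sum(weights)
      x <- w * state$mult                      # simplex coordinates
      mv <- .dirichletMove(x, a0 = 1000)
      state$mult <- mv$value / w
      list(state = state, lhr = mv$lhr)
    },
    stop("unknown move '", move, "'"))
}

## expand a sampler model (classRates/freqs/shape/def) to SubstitutionModel
.stateModel <- function(md, nGammaCat) {
  new("SubstitutionModel", family = md$family,
      rates = md$classRates[md$def$classes], freqs = md$freqs,
      gammaShape = md$shape, nGammaCat = nGammaCat)
}

## flat parameter tables for the compiled kernel
.flatten <- function(models, nGammaCat) {
  k <- length(models)
  ratesMat <- matrix(0, k, 6)
  freqsMat <- matrix(0, k, 4)
  catList <- vector("list", k)
  for (p in seq_len(k)) {
    md <- models[[p]]
    ratesMat[p, ] <- md$classRates[md$def$classes]
    freqsMat[p, ] <- md$freqs
    catList[[p]] <- discreteGammaRates(md$shape, nGammaCat)
  }
  list(rates = ratesMat, freqs = freqsMat, cats = catList)
}

.chainLnLs <- function(state, patterns, nGammaCat, po = NULL, flat = NULL) {
  if (is.null(po)) po <- .postorderEdges(state$tree)
  if (is.null(flat)) flat <- .flatten(state$models, nGammaCat)
  .pruningLnLMulti(patterns, po$edge, po$len, flat$rates, flat$freqs,
                   flat$cats, state$mult, seq_along(patterns))
}

.branchPrior <- function(tree, priors)
  sum(stats::dexp(tree$edge.length, rate = 1 / priors$branchMean, log = TRUE))

#' Run the Metropolis-coupled MCMC sampler
#'
#' Samples topology, branch lengths, substitution parameters and
#' partition rate multipliers under the partitioned likelihood. Chain r
#' (r = 0 cold) runs at temperature beta_r = 1/(1 + lambda r); a state
#' swap between a random chain pair is attempted every generation; the
#' cold chain is recorded every \code{sampleEvery} generations. Each
#' chain owns an RNG substream derived from the run seed, so traces are
#' reproducible and unaffected by adding chains.
#'
#' @param patterns per-partition pattern tables from
#'   \code{\link{compressPatterns}}.
#' @param startModels a \code{PartitionedModel} giving each partition's
#'   family (its constraints are respected during sampling) and starting
#'   values.
#' @param config an \code{\link{McmcConfig}}.
#' @param priors a \code{\link{PriorSet}}.
#' @param startTree optional starting \code{phylo}; default is a random
#'   topology with branch lengths drawn from the prior.
#' @param monitorTrees logical, keep sampled trees in the trace.
#' @return a \code{PosteriorTrace}.
#' @export
runMcmc <- function(patterns, startModels, config = McmcConfig(),
                    priors = PriorSet(), startTree = NULL,
                    monitorTrees = TRUE) {
  taxa <- rownames(patterns[[1]]$masks)
  k <- length(patterns)
  wts <- vapply(patterns, function(p) sum(p$weights), 1)
  nGammaCat <- partitionModels(startModels)[[1]]@nGammaCat

  set.seed(config@seed)
  ## fixed taxon order: reorder masks rows once to a canonical order
  patterns <- lapply(patterns, function(p) {
    p$masks <- p$masks[taxa, , drop = FALSE]; p
  })

  ## canonical tip ids: tip i carries label taxa[i], so one shared
  ## pattern table serves every chain
  conformTips <- function(tr) {
    m <- match(tr$tip.label, taxa)
    ntip <- length(tr$tip.label)
    tipRows <- tr$edge[, 2] <= ntip
    tr$edge[tipRows, 2] <- m[tr$edge[tipRows, 2]]
    tr$tip.label <- taxa
    attr(tr, "order") <- NULL
    tr
  }
  makeTree <- function() {
    if (!is.null(startTree)) {
      tr <- if (length(taxa) > 3L) ape::unroot(startTree) else startTree
      if (is.null(tr$edge.length))
        tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / priors$branchMean)
    } else if (length(taxa) == 2L) {
      tr <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                           tip.label = taxa, Nnode = 1L,
                           edge.length = stats::rexp(2, 1 / priors$branchMean)),
                      class = "phylo")
    } else {
      tr <- ape::unroot(ape::rtopology(length(taxa), rooted = FALSE,
                                       tip.label = taxa))
      tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / priors$branchMean)
    }
    conformTips(tr)
  }

  initModels <- lapply(partitionModels(startModels), function(m) {
    def <- .familyDef(m@family)
    cr <- vapply(seq_len(max(def$classes)),
                 function(cl) m@rates[match(cl, def$classes)], 1)
    list(family = m@family, def = def, classRates = cr / sum(cr),
         freqs = m@freqs, shape = m@gammaShape)
  })

  nchain <- config@nChains
  beta <- 1 / (1 + config@heatIncrement * (seq_len(nchain) - 1L))

  chains <- vector("list", nchain)
  for (r in seq_len(nchain)) {
    set.seed(config@seed * 97L + r)
    st <- list(tree = makeTree(), models = initModels,
               mult = rateMultipliers(startModels))
    po <- .postorderEdges(st$tree)
    flat <- .flatten(st$models, nGammaCat)
    lnls <- .chainLnLs(st, patterns, nGammaCat, po, flat)
    if (any(!is.finite(lnls)))
      stop("non-finite lnL at initialization (partition ",
           which(!is.finite(lnls))[1], ")")
    chains[[r]] <- list(state = st, lnls = lnls,
                        lprior = .branchPrior(st$tree, priors),
                        rng = .Random.seed, po = po, flat = flat)
  }
  set.seed(config@seed * 97L)  # swap/bookkeeping stream
  swapRng <- .Random.seed

  ## per-partition parameter move types available under each family
  paramMoves <- lapply(initModels, function(md) {
    mv <- character(0)
    if (md$def$free_freqs) mv <- c(mv, "freqs")
    if (max(md$def$classes) > 1L) mv <- c(mv, "exch")
    if (!is.na(md$shape)) mv <- c(mv, "shape")
    mv
  })
  doNNI <- length(taxa) >= 4L
  doMult <- k > 1L

  n_samp <- config@nGenerations %/% config@sampleEvery
  rec <- list(generation = integer(n_samp), lnL = numeric(n_samp),
              treeLength = numeric(n_samp),
              topologyKey = character(n_samp))
  shapeTr <- matrix(NA_real_, n_samp, k)
  multTr <- matrix(NA_real_, n_samp, k)
  treeList <- if (monitorTrees) vector("list", n_samp) else list()
  si <- 0L

  ## one full tree-level MH step (NNI / branch / multipliers)
  treeStep <- function(ch, mv, b) {
    prop <- proposeMove(ch$state, mv, priors, wts)
    if (is.null(prop) || !is.finite(prop$lhr)) return(ch)
    newpo <- if (mv == "mult") ch$po else .postorderEdges(prop$state$tree)
    newlnls <- .pruningLnLMulti(patterns, newpo$edge, newpo$len,
                                ch$flat$rates, ch$flat$freqs, ch$flat$cats,
                                prop$state$mult, seq_len(k))
    if (any(!is.finite(newlnls))) return(ch)
    newlp <- .branchPrior(prop$state$tree, priors)
    dpost <- (sum(newlnls) + newlp) - (sum(ch$lnls) + ch$lprior)
    if (log(stats::runif(1)) < b * dpost + prop$lhr) {
      ch$state <- prop$state
      ch$lnls <- newlnls
      ch$lprior <- newlp
      ch$po <- newpo
    }
    ch
  }

  ## batched per-partition parameter sweep: the likelihood factorizes
  ## across partitions, so proposals are evaluated in one kernel call and
  ## accepted independently.
  paramSweep <- function(ch, b) {
    prop <- ch$flat
    lhr <- numeric(k)
    newshape <- vapply(ch$state$models, function(m) m$shape, 1)
    mvsel <- character(k)
    for (p in seq_len(k)) {
      avail <- paramMoves[[p]]
      if (!length(avail)) next
      mv <- if (length(avail) == 1L) avail else
        avail[sample.int(length(avail), 1L)]
      mvsel[p] <- mv
      md <- ch$state$models[[p]]
      if (mv == "freqs") {
        d <- .dirichletMove(md$freqs)
        prop$freqs[p, ] <- d$value
        lhr[p] <- d$lhr
      } else if (mv == "exch") {
        d <- .dirichletMove(md$classRates / sum(md$classRates))
        prop$rates[p, ] <- d$value[md$def$classes]
        lhr[p] <- d$lhr
      } else {
        m <- exp(2 * (stats::runif(1) - 0.5))
        s2 <- md$shape * m
        if (s2 >= priors$shapeMax) { mvsel[p] <- ""; next }
        newshape[p] <- s2
        prop$cats[[p]] <- discreteGammaRates(s2, nGammaCat)
        lhr[p] <- log(m)
      }
    }
    todo <- which(mvsel != "")
    if (!length(todo)) return(ch)
    newlnls <- .pruningLnLMulti(patterns, ch$po$edge, ch$po$len,
                                prop$rates, prop$freqs, prop$cats,
                                ch$state$mult, todo)
    u <- log(stats::runif(length(todo)))
    for (idx in seq_along(todo)) {
      p <- todo[idx]
      if (!is.finite(newlnls[p])) next
      if (u[idx] < b * (newlnls[p] - ch$lnls[p]) + lhr[p]) {
        ch$lnls[p] <- newlnls[p]
        ch$flat$rates[p, ] <- prop$rates[p, ]
        ch$flat$freqs[p, ] <- prop$freqs[p, ]
        ch$flat$cats[[p]] <- prop$cats[[p]]
        md <- ch$state$models[[p]]
        if (mvsel[p] == "freqs") md$freqs <- prop$freqs[p, ]
        if (mvsel[p] == "exch") {
          cr <- prop$rates[p, match(seq_len(max(md$def$classes)),
                                    md$def$classes)]
          md$classRates <- cr
        }
        if (mvsel[p] == "shape") md$shape <- newshape[p]
        ch$state$models[[p]] <- md
      }
    }
    ch
  }

  for (g in seq_len(config@nGenerations)) {
    for (r in seq_len(nchain)) {
      ch <- chains[[r]]
      .Random.seed <<- ch$rng
      if (doNNI) ch <- treeStep(ch, "NNI", beta[r])
      ch <- treeStep(ch, "branch", beta[r])
      ch <- paramSweep(ch, beta[r])
      if (doMult) ch <- treeStep(ch, "mult", beta[r])
      ch$rng <- .Random.seed
      chains[[r]] <- ch
    }
    if (nchain > 1L) {
      .Random.seed <<- swapRng
      pr <- sample.int(nchain, 2L)
      i <- pr[1]; j <- pr[2]
      dij <- (beta[i] - beta[j]) *
        ((sum(chains[[j]]$lnls) + chains[[j]]$lprior) -
         (sum(chains[[i]]$lnls) + chains[[i]]$lprior))
      if (log(stats::runif(1)) < dij) {
        fields <- c("state", "lnls", "lprior", "po", "flat")
        tmp <- chains[[i]][fields]
        chains[[i]][fields] <- chains[[j]][fields]
        chains[[j]][fields] <- tmp
      }
      swapRng <- .Random.seed
    }
    if (g %% config@sampleEvery == 0L) {
      si <- si + 1L
      cold <- chains[[1]]
      rec$generation[si] <- g
      rec$lnL[si] <- sum(cold$lnls)
      rec$treeLength[si] <- sum(cold$state$tree$edge.length)
      rec$topologyKey[si] <- topologyKey(cold$state$tree)
      shapeTr[si, ] <- vapply(cold$state$models, function(m) m$shape, 1)
      multTr[si, ] <- cold$state$mult
      if (monitorTrees) treeList[[si]] <- cold$state$tree
    }
  }

  samples <- data.frame(generation = rec$generation, lnL = rec$lnL,
                        treeLength = rec$treeLength,
                        topologyKey = rec$topologyKey,
                        stringsAsFactors = FALSE)
  if (!all(is.na(shapeTr)))
    for (p in seq_len(k)) samples[[paste0("shape", p)]] <- shapeTr[, p]
  if (k > 1L)
    for (p in seq_len(k)) samples[[paste0("mult", p)]] <- multTr[, p]
  new("PosteriorTrace", samples = samples, trees = treeList,
      config = config)
}

#' Effective sample size of a scalar MCMC trace
#'
#' n / (1 + 2 sum rho_k), with autocorrelations summed until the first
#' nonpositive estimate (initial positive sequence truncation). A
#' constant series is reported as ESS 0 with attribute
#' \code{degenerate = TRUE}.
#'
#' @param x numeric series (post-burn-in).
#' @return ESS estimate.
#' @export
effectiveSampleSize <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need >= 10 samples")
  if (stats::var(x) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ac <- stats::acf(x, lag.max = min(n - 1L, 10000L), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Harmonic-mean marginal log-likelihood
#'
#' ln HM = ln n - logsumexp(-lnL_i) over post-burn-in likelihood
#' samples; numerically stable for lnL of order -1e5 and beyond.
#'
#' @param lnL numeric vector of sampled log-likelihoods.
#' @return the log harmonic mean.
#' @export
harmonicMeanLnL <- function(lnL) {
  if (length(lnL) < 1L || any(!is.finite(lnL))) stop("need finite lnL samples")
  x <- -lnL
  m <- max(x)
  log(length(lnL)) - (m + log(sum(exp(x - m))))
}

#' Assess trace stationarity via ESS
#'
#' Accepts when every monitored scalar's ESS (after burn-in discard)
#' reaches the configured threshold; otherwise requests an extension of
#' the run, doubling generations up to the extension cap, after which
#' the run is accepted with a warning flag.
#'
#' @param trace a PosteriorTrace.
#' @param config an McmcConfig (defaults to the trace's own).
#' @return list(decision = "accept" | "extend", newGenerations, warning,
#'   ess = named vector of ESS values).
#' @export
assessStationarity <- function(trace, config = NULL) {
  if (is.null(config)) config <- trace@config
  sm <- postBurnin(trace, config@burninFraction)
  scalars <- sm[, setdiff(names(sm), c("generation", "topologyKey")),
                drop = FALSE]
  ess <- vapply(scalars, function(x) as.numeric(effectiveSampleSize(x)), 1)
  if (all(ess >= config@essThreshold))
    return(list(decision = "accept", newGenerations = config@nGenerations,
                warning = FALSE, ess = ess))
  newgen <- min(2L * config@nGenerations, config@extensionCap)
  if (newgen <= config@nGenerations)
    return(list(decision = "accept", newGenerations = config@nGenerations,
                warning = TRUE, ess = ess))
  list(decision = "extend", newGenerations = newgen, warning = FALSE,
       ess = ess)
}
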