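## Maximum-likelihood hill climbing, Fitch parsimony with exhaustive and
## NNI-heuristic search, nonparametric bootstrap, and majority-rule
## consensus.

#' Fitch parsimony score of a tree
#'
#' Minimal number of state changes over all sites (Fitch down-pass on
#' the binary tree rooted along an edge). IUPAC ambiguities enter as
#' state sets; gaps and '?' as the full state set.
#'
#' @param tree a binary \code{phylo}.
#' @param aln a MitoAlignment with matching taxa.
#' @return integer score.
#' @export
fitchScore <- function(tree, aln) {
  pat <- compressPatterns(aln)[[1]]
  po <- .postorderEdges(tree)
  ord <- match(po$tips, rownames(pat$masks))
  if (anyNA(ord)) stop("labeling error: tree taxa not in alignment")
  masks <- pat$masks[ord, , drop = FALSE]
  npat <- ncol(masks)
  nnode <- max(po$edge)
  sets <- matrix(NA_integer_, nnode, npat)
  sets[seq_len(nrow(masks)), ] <- masks
  changes <- integer(npat)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (is.na(sets[p, 1])) {
      sets[p, ] <- sets[ch, ]
    } else {
      inter <- bitwAnd(sets[p, ], sets[ch, ])
      zero <- inter == 0L
      inter[zero] <- bitwOr(sets[p, zero], sets[ch, zero])
      changes <- changes + zero
      sets[p, ] <- inter
    }
  }
  as.integer(sum(changes * pat$weights))
}

## Attach a new tip on edge `e` of `tree` (topology only).
.addTipToEdge <- function(tree, e, label) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ed <- tree$edge
  ed[ed > ntip] <- ed[ed > ntip] + 1L   # shift internal ids for new tip
  newtip <- ntip + 1L
  newint <- ntip + 1L + nnode + 1L
  p <- ed[e, 1]; ch <- ed[e, 2]
  ed[e, ] <- c(p, newint)
  ed <- rbind(ed, c(newint, ch), c(newint, newtip))
  structure(list(edge = ed, tip.label = c(tree$tip.label, label),
                 Nnode = nnode + 1L), class = "phylo")
}

## Enumerate all unrooted binary topologies on the given taxa.
.allTopologies <- function(taxa) {
  n <- length(taxa)
  stopifnot(n >= 3L)
  base <- structure(list(edge = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                         tip.label = taxa[1:3], Nnode = 1L),
                    class = "phylo")
  trees <- list(base)
  for (k in seq(4L, length.out = n - 3L)) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)),
             function(e) .addTipToEdge(tr, e, taxa[k]))
    }), recursive = FALSE)
  }
  trees
}

## All distinct NNI neighbours of an unrooted binary tree.
.nniNeighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  e <- tree$edge
  out <- list()
  for (pick in which(e[, 2] > ntip)) {
    u <- e[pick, 1]; v <- e[pick, 2]
    vkids <- which(e[, 1] == v)
    ukids <- setdiff(which(e[, 1] == u), pick)
    for (a in vkids) for (b in ukids) {
      e2 <- e
      tmp <- e2[a, 2]; e2[a, 2] <- e2[b, 2]; e2[b, 2] <- tmp
      tr2 <- tree
      tr2$edge <- e2
      attr(tr2, "order") <- NULL
      out[[length(out) + 1L]] <- tr2
    }
  }
  keys <- vapply(out, topologyKey, "")
  out[!duplicated(keys) & keys != topologyKey(tree)]
}

#' Most-parsimonious tree search
#'
#' Exhaustive mode enumerates every unrooted binary topology (allowed up
#' to 9 taxa) and returns all trees attaining the minimal Fitch score;
#' heuristic mode hill-climbs over NNI neighbourhoods from a starting
#' topology and returns the best-found set, flagged as possibly
#' incomplete.
#'
#' @param aln a MitoAlignment (>= 4 taxa).
#' @param mode "exhaustive" or "nni".
#' @param start optional starting \code{phylo} for the heuristic.
#' @return list(trees, score, complete).
#' @export
mpSearch <- function(aln, mode = c("exhaustive", "nni"), start = NULL) {
  mode <- match.arg(mode)
  taxa <- taxa(aln)
  stopifnot(length(taxa) >= 4L)
  if (mode == "exhaustive") {
    if (length(taxa) > 9L)
      stop("exhaustive search refused for > 9 taxa")
    cand <- .allTopologies(taxa)
    sc <- vapply(cand, fitchScore, 1L, aln = aln)
    best <- min(sc)
    return(list(trees = cand[sc == best], score = best, complete = TRUE))
  }
  cur <- if (is.null(start)) ape::rtopology(length(taxa), rooted = FALSE,
                                            tip.label = taxa) else start
  cur$edge.length <- NULL
  curScore <- fitchScore(cur, aln)
  repeat {
    nb <- .nniNeighbors(cur)
    sc <- vapply(nb, fitchScore, 1L, aln = aln)
    if (!length(sc) || min(sc) >= curScore) break
    cur <- nb[[which.min(sc)]]
    curScore <- min(sc)
  }
  nb <- .nniNeighbors(cur)
  ties <- nb[vapply(nb, fitchScore, 1L, aln = aln) == curScore]
  list(trees = c(list(cur), ties), score = curScore, complete = FALSE)
}

## Optimize branch lengths of a tree by cycled 1-D Brent maximization.
.optimizeBranchLengths <- function(tree, models, patterns, tol = 1e-6,
                                   maxCycles = 5L) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.05, nrow(tree$edge))
  cur <- logLikelihood(tree, models, patterns)
  for (cyc in seq_len(maxCycles)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tr2 <- tree
        tr2$edge.length[e] <- x
        logLikelihood(tr2, models, patterns)
      }
      opt <- stats::optimize(f, c(1e-8, 10), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  list(tree = tree, lnL = cur)
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Alternates branch-length optimization (per-branch Brent maximization
#' cycled to tolerance) with NNI moves, accepting the best improving
#' neighbour until none improves. The log-likelihood trace is monotone
#' non-decreasing. Substitution parameters are held at the supplied
#' values.
#'
#' @param aln a MitoAlignment.
#' @param models a PartitionedModel.
#' @param scheme optional PartitionScheme matching \code{models}.
#' @param start starting \code{phylo}; default \code{guideTree(aln)}.
#' @return list(tree, lnL, lnLTrace).
#' @export
mlSearch <- function(aln, models, scheme = NULL, start = NULL) {
  patterns <- compressPatterns(aln, scheme)
  cur <- if (is.null(start)) guideTree(aln) else start
  res <- .optimizeBranchLengths(cur, models, patterns)
  trace <- res$lnL
  repeat {
    nb <- .nniNeighbors(res$tree)
    if (!length(nb)) break
    cand <- lapply(nb, function(t) {
      t$edge.length <- res$tree$edge.length[seq_len(nrow(t$edge))]
      .optimizeBranchLengths(t, models, patterns, maxCycles = 2L)
    })
    lls <- vapply(cand, `[[`, 1, "lnL")
    if (max(lls) <= res$lnL + 1e-6) break
    res <- .optimizeBranchLengths(cand[[which.max(lls)]]$tree, models,
                                  patterns)
    trace <- c(trace, res$lnL)
  }
  list(tree = res$tree, lnL = res$lnL, lnLTrace = trace)
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement to the original length,
#' infers a tree per replicate (ML hill climb or heuristic parsimony),
#' and reports bipartition frequencies as percentages. Trivial (leaf)
#' bipartitions are reported as 100.
#'
#' @param aln a MitoAlignment.
#' @param method "ML" or "MP".
#' @param nReplicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @param models PartitionedModel for ML replicates (single partition is
#'   applied to the resampled matrix); defaults to GTR+G with empirical
#'   frequencies left at 1/4.
#' @return list(trees, support = data.frame(bipartition, percent)).
#' @export
bootstrapSupport <- function(aln, method = c("ML", "MP"), nReplicates = 100L,
                             seed = 1L, models = NULL) {
  method <- match.arg(method)
  stopifnot(nReplicates >= 1L)
  set.seed(seed)
  m <- alignmentMatrix(aln)
  if (is.null(models))
    models <- PartitionedModel(list(SubstitutionModel("GTR", gammaShape = 0.5)),
                               weights = ncol(m))
  trees <- vector("list", nReplicates)
  for (b in seq_len(nReplicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- MitoAlignment(m[, cols, drop = FALSE])
    trees[[b]] <- if (method == "MP")
      mpSearch(rep_aln, "nni", start = guideTree(rep_aln))$trees[[1]]
    else mlSearch(rep_aln, models)$tree
  }
  counts <- table(unlist(lapply(trees, .bipartitions)))
  support <- data.frame(bipartition = names(counts),
                        percent = 100 * as.vector(counts) / nReplicates,
                        stringsAsFactors = FALSE)
  leafs <- data.frame(bipartition = sort(taxa(aln)), percent = 100,
                      stringsAsFactors = FALSE)
  list(trees = trees, support = rbind(support, leafs))
}

#' Majority-rule consensus tree
#'
#' Retains bipartitions whose frequency across the input trees exceeds
#' the threshold (strictly; a threshold of 1 keeps exactly the
#' bipartitions present in every tree, i.e. the strict consensus). The
#' retained set is compatible by construction for thresholds >= 0.5.
#'
#' @param trees list of \code{phylo} on a shared taxon set.
#' @param threshold frequency threshold in [0.5, 1].
#' @return a (possibly multifurcating) \code{phylo}.
#' @export
majorityRuleConsensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1L, threshold >= 0.5, threshold <= 1)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!setequal(t$tip.label, taxa))
    stop("trees must share a taxon set")
  counts <- table(unlist(lapply(trees, .bipartitions)))
  freq <- as.vector(counts) / length(trees)
  keep <- names(counts)[freq > min(threshold, 1 - 1e-9)]
  clades <- lapply(strsplit(keep, ","), sort)
  ## nest clades (all exclude the anchor taxon) into a rooted newick
  clades <- clades[order(-lengths(clades))]
  buildNewick <- function(set, cl) {
    kids <- list()
    used <- character(0)
    for (s in cl) {
      if (all(s %in% set) && length(s) < length(set) &&
          !any(s %in% used)) {
        sub <- Filter(function(z) all(z %in% s) && length(z) < length(s), cl)
        kids[[length(kids) + 1L]] <- buildNewick(s, sub)
        used <- c(used, s)
      }
    }
    singles <- setdiff(set, used)
    paste0("(", paste(c(unlist(kids), singles), collapse = ","), ")")
  }
  nwk <- paste0(buildNewick(taxa, clades), ";")
  tr <- ape::read.tree(text = nwk)
  if (length(taxa) >= 3L) tr <- ape::unroot(tr)
  tr
}
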