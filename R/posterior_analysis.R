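## Comparison layer: canonical topology keys, credible sets of trees,
## harmonic-mean Bayes factors with Kass-Raftery interpretation, tree
## length statistics and topology congruence.

## Non-trivial bipartitions of an unrooted tree, as canonical strings.
## Each bipartition is written as the sorted labels of the side NOT
## containing the lexicographically smallest taxon.
.bipartitions <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  anchor <- sort(tr$tip.label)[1]
  nnode <- max(tr$edge)
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    side <- below[[ch]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(tr$tip.label, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  sort(unique(out))
}

#' Canonical topology key of a tree
#'
#' The sorted set of non-trivial bipartitions, independent of rooting,
#' rotation and branch lengths: two trees have equal keys exactly when
#' they are the same unrooted topology.
#'
#' @param tree a \code{phylo} (binary or multifurcating).
#' @return character scalar key.
#' @export
topologyKey <- function(tree) {
  if (length(tree$tip.label) < 4L) return(paste(sort(tree$tip.label),
                                                collapse = ","))
  paste(.bipartitions(tree), collapse = "|")
}

#' Credible-set sizes of sampled topologies
#'
#' Topologies are ranked by sampled frequency (descending, ties broken
#' by first occurrence); a level's credible set is the smallest prefix
#' whose cumulative frequency reaches the level.
#'
#' @param trace a PosteriorTrace (burn-in is discarded first), or a
#'   character vector of topology keys.
#' @param levels confidence levels (default 0.95 and 0.99).
#' @return a \code{CredibleSetSummary}.
#' @export
credibleSets <- function(trace, levels = c(0.95, 0.99)) {
  keys <- if (is.character(trace)) trace else postBurnin(trace)$topologyKey
  if (!length(keys)) stop("no post-burn-in samples")
  freq <- table(factor(keys, levels = unique(keys)))  # first-occurrence order
  ord <- order(-as.vector(freq))                      # stable: keeps 1st-occ ties
  p <- as.vector(freq)[ord] / length(keys)
  cp <- cumsum(p)
  setSize <- function(level) as.integer(which(cp >= level - 1e-12)[1])
  new("CredibleSetSummary", nDistinct = length(p),
      n99 = setSize(max(levels)), n95 = setSize(min(levels)))
}

#' Twice the log Bayes factor from two harmonic means
#'
#' 2lnB10 = 2 (lnHM1 - lnHM0); positive values prefer model 1.
#'
#' @param lnHM1,lnHM0 log harmonic-mean marginal likelihoods.
#' @return numeric scalar.
#' @export
bayesFactor2ln <- function(lnHM1, lnHM0) {
  stopifnot(is.finite(lnHM1), is.finite(lnHM0))
  2 * (lnHM1 - lnHM0)
}

#' Kass-Raftery interpretation of a 2lnB10 value
#'
#' |v| in [0,2): no preference; [2,6): favoured; [6,10): strongly
#' favoured; >= 10: very strongly preferred (flagged significant). The
#' sign names the preferred model.
#'
#' @param v 2lnB10 value.
#' @return character category, with attributes \code{significant} and
#'   \code{preferred} ("M1", "M0" or "none").
#' @export
interpretBF <- function(v) {
  stopifnot(is.finite(v))
  a <- abs(v)
  cat <- if (a < 2) "none" else if (a < 6) "favoured" else if (a < 10)
    "strong" else "very strong"
  out <- cat
  attr(out, "significant") <- a >= 10
  attr(out, "preferred") <- if (a < 2) "none" else if (v > 0) "M1" else "M0"
  out
}

#' Pairwise Bayes-factor matrix over strategies
#'
#' Computes the harmonic-mean marginal likelihood of each trace and all
#' pairwise 2lnB10 values (row strategy = model 1, column = model 0),
#' with Kass-Raftery categories attached.
#'
#' @param traces named list of PosteriorTrace objects (>= 2).
#' @return a \code{BayesFactorMatrix}.
#' @export
bfMatrix <- function(traces) {
  if (length(traces) < 2L) stop("need >= 2 strategies")
  if (is.null(names(traces)) || any(names(traces) == ""))
    stop("labeled error: traces must be named by strategy")
  hm <- vapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    if (is.null(tr)) stop("labeled error: missing trace for ", nm)
    harmonicMeanLnL(postBurnin(tr)$lnL)
  }, 1)
  v <- outer(hm, hm, function(a, b) 2 * (a - b))
  diag(v) <- 0
  interp <- matrix("none", nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
    if (i != j) interp[i, j] <- as.character(interpretBF(v[i, j]))
  new("BayesFactorMatrix", values = v, interpretation = interp)
}

#' Tree-length mean and SD from a trace
#'
#' Sample mean and (n-1)-denominator standard deviation of the
#' per-sample sum of branch lengths, after burn-in.
#'
#' @param trace a PosteriorTrace, or a numeric vector of tree lengths.
#' @return named numeric c(mean, sd).
#' @export
treeLengthStats <- function(trace) {
  tl <- if (is.numeric(trace)) trace else postBurnin(trace)$treeLength
  if (length(tl) < 2L) stop("need >= 2 post-burn-in samples")
  c(mean = mean(tl), sd = stats::sd(tl))
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#' Optionally normalized by the maximum possible count.
#'
#' @param t1,t2 \code{phylo} objects on the same taxon set.
#' @param normalize divide by the total number of non-trivial
#'   bipartitions in both trees (default FALSE).
#' @return integer distance (numeric in [0,1] when normalized).
#' @export
rfDistance <- function(t1, t2, normalize = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("taxon mismatch between trees")
  b1 <- .bipartitions(t1); b2 <- .bipartitions(t2)
  d <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalize) {
    tot <- length(b1) + length(b2)
    return(if (tot == 0L) 0 else d / tot)
  }
  as.integer(d)
}

#' Congruence of single-gene trees with a reference topology
#'
#' Per-gene Robinson-Foulds distance to the whole-matrix reference tree
#' and a flag for exact topological identity (equal topology keys;
#' branch lengths ignored).
#'
#' @param geneTrees named list of \code{phylo}, one per gene.
#' @param reference the reference \code{phylo}.
#' @return data.frame with columns gene, rf, identical.
#' @export
congruenceReport <- function(geneTrees, reference) {
  refKey <- topologyKey(reference)
  data.frame(
    gene = names(geneTrees),
    rf = vapply(geneTrees, function(t) rfDistance(t, reference), 1L),
    identical = vapply(geneTrees,
                       function(t) identical(topologyKey(t), refKey), TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}
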