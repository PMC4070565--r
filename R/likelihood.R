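## Partitioned phylogenetic log-likelihood: pattern compression, the
## pruning kernel driver, and a brute-force enumeration oracle.

.maskRow <- function(chars) unname(.IUPAC_MASK[chars])

#' Compress alignment columns into site patterns
#'
#' Identical columns within a partition collapse into one pattern with a
#' multiplicity weight. Patterns are kept separate per partition (the
#' same column content in two partitions stays in both).
#'
#' @param aln a MitoAlignment.
#' @param scheme optional PartitionScheme; default = one partition of
#'   all sites.
#' @return named list, one element per partition: list(masks = integer
#'   matrix taxa x patterns of IUPAC state masks, weights = integer
#'   multiplicities). Sum of weights equals the partition's site count.
#' @export
compressPatterns <- function(aln, scheme = NULL) {
  m <- alignmentMatrix(aln)
  masks <- matrix(.maskRow(m), nrow = nrow(m),
                  dimnames = list(rownames(m), NULL))
  if (is.null(scheme))
    scheme <- PartitionScheme("PS1", list(all = seq_len(ncol(m))), ncol(m))
  lapply(charsets(scheme), function(sites) {
    sub <- masks[, sites, drop = FALSE]
    key <- apply(sub, 2, paste, collapse = ",")
    first <- !duplicated(key)
    w <- as.vector(table(factor(key, levels = key[first])))
    list(masks = sub[, first, drop = FALSE], weights = as.integer(w))
  })
}

## postorder edge representation of a phylo tree
.postorderEdges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, len = tr$edge.length, tips = tr$tip.label)
}

## lnL of one partition under one SubstitutionModel
.partitionLnL <- function(tree, model, pat, multiplier = 1) {
  po <- .postorderEdges(tree)
  ord <- match(po$tips, rownames(pat$masks))
  if (anyNA(ord)) stop("labeling error: tree taxa not found in alignment")
  .pruningLnL(pat$masks[ord, , drop = FALSE], as.numeric(pat$weights),
              po$edge, po$len, model@rates, model@freqs,
              discreteGammaRates(model@gammaShape, model@nGammaCat),
              multiplier)
}

#' Partitioned log-likelihood by Felsenstein pruning
#'
#' Sums, over partitions and site patterns, the pruning log-likelihood
#' under each partition's substitution model, with that partition's
#' branch lengths scaled by its rate multiplier. IUPAC ambiguity codes
#' at the leaves enter as possibility vectors (1 on each compatible
#' state); gaps and '?' are all-ones.
#'
#' @param tree unrooted \code{phylo}; tip labels must match the
#'   alignment's taxa.
#' @param models a PartitionedModel aligned to the pattern table.
#' @param patterns output of \code{\link{compressPatterns}}.
#' @return total log-likelihood (numeric scalar).
#' @export
logLikelihood <- function(tree, models, patterns) {
  ms <- partitionModels(models)
  mult <- rateMultipliers(models)
  stopifnot(length(ms) == length(patterns))
  ll <- 0
  for (k in seq_along(patterns)) {
    lk <- .partitionLnL(tree, ms[[k]], patterns[[k]], mult[k])
    if (!is.finite(lk))
      stop("numerical error: non-finite lnL in partition ",
           names(patterns)[k] %||% k)
    ll <- ll + lk
  }
  ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brute-force log-likelihood by enumeration (test oracle)
#'
#' Explicit sum over all internal-node state assignments (and compatible
#' leaf states under ambiguity), per site and gamma category. Refuses
#' more than 6 taxa.
#'
#' @param tree unrooted \code{phylo}.
#' @param models a PartitionedModel.
#' @param aln the (uncompressed) MitoAlignment.
#' @param scheme optional PartitionScheme matching \code{models}.
#' @return log-likelihood.
#' @export
bruteForceLogLikelihood <- function(tree, models, aln, scheme = NULL) {
  if (length(tree$tip.label) > 6L)
    stop("brute-force oracle refuses > 6 taxa")
  m <- alignmentMatrix(aln)
  if (is.null(scheme))
    scheme <- PartitionScheme("PS1", list(all = seq_len(ncol(m))), ncol(m))
  ms <- partitionModels(models)
  mult <- rateMultipliers(models)
  po <- .postorderEdges(tree)
  ntax <- length(po$tips)
  nnode <- max(po$edge)
  root <- po$edge[nrow(po$edge), 1]
  rowidx <- match(po$tips, rownames(m))
  total <- 0
  for (k in seq_along(charsets(scheme))) {
    model <- ms[[k]]
    rates <- discreteGammaRates(model@gammaShape, model@nGammaCat)
    pi <- model@freqs
    Plist <- lapply(rates, function(r) {
      lapply(seq_len(nrow(po$edge)), function(e) {
        mdl <- model; mdl@gammaShape <- NA_real_; mdl@nGammaCat <- 1L
        transitionProbabilities(mdl, po$len[e] * r * mult[k])[[1]]
      })
    })
    for (site in charsets(scheme)[[k]]) {
      states <- lapply(seq_len(nnode), function(nd) {
        if (nd <= ntax) which(bitwAnd(.IUPAC_MASK[[m[rowidx[nd], site]]],
                                      c(1L, 2L, 4L, 8L)) > 0L)
        else 1:4
      })
      lik <- 0
      grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE)
      for (c in seq_along(rates)) {
        P <- Plist[[c]]
        for (g in seq_len(nrow(grid))) {
          asn <- as.integer(grid[g, ])
          v <- pi[asn[root]]
          for (e in seq_len(nrow(po$edge)))
            v <- v * P[[e]][asn[po$edge[e, 1]], asn[po$edge[e, 2]]]
          lik <- lik + v / length(rates)
        }
      }
      total <- total + log(lik)
    }
  }
  total
}
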