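#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mitopart, .registration = TRUE
NULL

## IUPAC symbol -> 4-bit state mask over (A, C, G, T).
## Gaps and '?' carry no state information and get the full mask.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  `-` = 15L, `?` = 15L
)

.AMBIGUITY_CODES <- setdiff(names(.IUPAC_MASK), c("A", "C", "G", "T", "U", "-", "?"))

#' MitoAlignment: a multiple sequence alignment of mitogenome sequences
#'
#' Thin S4 container around a character matrix of aligned nucleotide
#' symbols (rows = taxa, columns = sites). Symbols are the four bases,
#' IUPAC ambiguity codes, the gap character \code{-} and missing
#' \code{?}. All sequence operations in the package (site classification,
#' pattern compression, likelihood, parsimony) consume this class.
#'
#' @slot mat character matrix, rownames are unique taxon labels.
#' @exportClass MitoAlignment
setClass("MitoAlignment", representation(mat = "matrix"))

setValidity("MitoAlignment", function(object) {
  m <- object@mat
  if (!is.character(m)) return("alignment matrix must be character")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxon labels must be present and unique")
  bad <- matrix(!(m %in% names(.IUPAC_MASK)), nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("unknown symbol '%s' at taxon '%s', column %d",
                   m[idx[1L], idx[2L]], rownames(m)[idx[1L]], idx[2L]))
  }
  TRUE
})

#' GeneMap: ordered gene annotations on a concatenated alignment
#'
#' Records the gene name, span (1-based inclusive coordinates on the
#' concatenated alignment), gene class (PCG, rRNA or tRNA), reading-frame
#' offset (0..2, PCGs only) and strand for every gene. Spans must be
#' non-overlapping; minus-strand genes are assumed already re-oriented in
#' the concatenated matrix, so strand is bookkeeping only.
#'
#' @slot table data.frame with columns gene, start, end, class, frame,
#'   strand.
#' @exportClass GeneMap
setClass("GeneMap", representation(table = "data.frame"))

setValidity("GeneMap", function(object) {
  tb <- object@table
  need <- c("gene", "start", "end", "class", "frame", "strand")
  if (!all(need %in% names(tb))) return("missing GeneMap columns")
  if (anyDuplicated(tb$gene)) return("gene names must be unique")
  if (!all(tb$class %in% c("PCG", "rRNA", "tRNA")))
    return("gene class must be PCG, rRNA or tRNA")
  if (any(tb$start < 1L) || any(tb$end < tb$start))
    return("invalid gene span")
  pcg <- tb$class == "PCG"
  if (any(is.na(tb$frame[pcg])) || any(!tb$frame[pcg] %in% 0:2))
    return("PCG frame offsets must be 0, 1 or 2")
  if (!all(tb$strand %in% c("+", "-"))) return("strand must be + or -")
  o <- order(tb$start)
  if (any(tb$start[o][-1L] <= tb$end[o][-nrow(tb)]))
    return("gene spans overlap")
  TRUE
})

#' PartitionScheme: named character sets over alignment sites
#'
#' A partitioning strategy's output: disjoint, exhaustive named sets of
#' site indices (1-based) covering every site of a dataset selection.
#'
#' @slot strategyId character, one of PS1..PS12 or "external".
#' @slot charsets named list of integer site-index vectors.
#' @slot nSites integer, number of sites of the partitioned alignment.
#' @exportClass PartitionScheme
setClass("PartitionScheme",
         representation(strategyId = "character", charsets = "list",
                        nSites = "integer"))

setValidity("PartitionScheme", function(object) {
  cs <- object@charsets
  if (length(cs) == 0L) return("scheme must contain at least one charset")
  if (is.null(names(cs)) || anyDuplicated(names(cs)))
    return("charsets must be uniquely named")
  if (any(vapply(cs, length, 1L) == 0L)) return("empty charset")
  all_sites <- sort(unlist(cs, use.names = FALSE))
  if (anyDuplicated(all_sites)) return("charsets overlap")
  if (!identical(all_sites, seq_len(object@nSites)))
    return("charsets do not cover all sites exactly")
  TRUE
})

#' SubstitutionModel: a reversible nucleotide substitution model
#'
#' A member of the GTR family hierarchy, described by six relative
#' exchangeabilities (order AC, AG, AT, CG, CT, GT), stationary base
#' frequencies (A, C, G, T) and an optional discrete-gamma shape for
#' among-site rate variation.
#'
#' @slot family character, one of the recognized family names.
#' @slot rates numeric(6) nonnegative exchangeabilities.
#' @slot freqs numeric(4) frequencies summing to 1.
#' @slot gammaShape numeric, positive shape or NA for no rate variation.
#' @slot nGammaCat integer, number of discrete gamma categories.
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
         representation(family = "character", rates = "numeric",
                        freqs = "numeric", gammaShape = "numeric",
                        nGammaCat = "integer"),
         prototype(family = "GTR", rates = rep(1, 6),
                   freqs = rep(0.25, 4), gammaShape = NA_real_,
                   nGammaCat = 4L))

setValidity("SubstitutionModel", function(object) {
  if (length(object@rates) != 6L || any(object@rates < 0))
    return("rates must be 6 nonnegative values")
  if (length(object@freqs) != 4L || any(object@freqs < 0))
    return("freqs must be 4 nonnegative values")
  if (abs(sum(object@freqs) - 1) > 1e-12)
    return("freqs must sum to 1")
  if (!is.na(object@gammaShape) && object@gammaShape <= 0)
    return("gammaShape must be positive")
  if (object@nGammaCat < 1L) return("nGammaCat must be >= 1")
  TRUE
})

#' PartitionedModel: per-partition substitution models + rate multipliers
#'
#' One SubstitutionModel per charset of a PartitionScheme, plus a
#' positive rate multiplier per partition constrained to a site-weighted
#' mean of 1 (weights = charset sizes).
#'
#' @slot models list of SubstitutionModel, aligned to the scheme.
#' @slot rateMultipliers numeric, one positive value per partition.
#' @slot weights integer, charset sizes used for the mean-1 constraint.
#' @exportClass PartitionedModel
setClass("PartitionedModel",
         representation(models = "list", rateMultipliers = "numeric",
                        weights = "integer"))

setValidity("PartitionedModel", function(object) {
  k <- length(object@models)
  if (length(object@rateMultipliers) != k || length(object@weights) != k)
    return("models, rateMultipliers and weights must have equal length")
  if (!all(vapply(object@models, is, TRUE, "SubstitutionModel")))
    return("models must be SubstitutionModel objects")
  if (any(object@rateMultipliers <= 0))
    return("rate multipliers must be positive")
  wm <- sum(object@weights * object@rateMultipliers) / sum(object@weights)
  if (abs(wm - 1) > 1e-8)
    return("site-weighted mean of rate multipliers must be 1")
  TRUE
})

#' McmcConfig: settings for the Metropolis-coupled MCMC sampler
#'
#' Defaults follow common practice for partitioned mitogenome analyses:
#' eight chains (seven incrementally heated and one cold), samples taken
#' every 100 generations, the first 25\% of samples discarded as burn-in,
#' and runs extended when any monitored effective sample size falls
#' below 100.
#'
#' @slot nChains integer, total chains (cold + heated).
#' @slot heatIncrement numeric, lambda of the heating scheme
#'   beta_r = 1 / (1 + lambda * r).
#' @slot nGenerations integer.
#' @slot sampleEvery integer thinning interval.
#' @slot burninFraction numeric in [0, 1).
#' @slot seed integer RNG seed.
#' @slot essThreshold numeric, minimum acceptable ESS.
#' @slot extensionCap integer, hard cap on total generations when
#'   extending a run that has not reached the ESS threshold.
#' @exportClass McmcConfig
setClass("McmcConfig",
         representation(nChains = "integer", heatIncrement = "numeric",
                        nGenerations = "integer", sampleEvery = "integer",
                        burninFraction = "numeric", seed = "integer",
                        essThreshold = "numeric", extensionCap = "integer"),
         prototype(nChains = 8L, heatIncrement = 0.1,
                   nGenerations = 100000L, sampleEvery = 100L,
                   burninFraction = 0.25, seed = 42L,
                   essThreshold = 100, extensionCap = 400000L))

setValidity("McmcConfig", function(object) {
  if (object@nChains < 1L) return("need at least one chain")
  if (object@heatIncrement <= 0) return("heatIncrement must be positive")
  if (object@burninFraction < 0 || object@burninFraction >= 1)
    return("burninFraction must be in [0, 1)")
  if (object@sampleEvery < 1L) return("sampleEvery must be >= 1")
  TRUE
})

#' PosteriorTrace: cold-chain samples from one MCMC run
#'
#' Stores the sampled generations, log-likelihoods, tree lengths,
#' canonical topology keys, sampled trees and scalar parameter traces,
#' together with the configuration that produced them.
#'
#' @slot samples data.frame with columns generation, lnL, treeLength,
#'   topologyKey plus one column per monitored scalar parameter.
#' @slot trees list of sampled \code{phylo} trees (may be trimmed).
#' @slot config the McmcConfig used.
#' @slot extended logical, TRUE if the run was extended for ESS.
#' @slot cappedWarning logical, TRUE if accepted only because the
#'   extension cap was reached.
#' @exportClass PosteriorTrace
setClass("PosteriorTrace",
         representation(samples = "data.frame", trees = "list",
                        config = "McmcConfig", extended = "logical",
                        cappedWarning = "logical"),
         prototype(extended = FALSE, cappedWarning = FALSE))

setValidity("PosteriorTrace", function(object) {
  g <- object@samples$generation
  if (is.unsorted(g, strictly = TRUE))
    return("generations must be strictly increasing")
  if (any(!is.finite(object@samples$lnL)))
    return("lnL must be finite")
  TRUE
})

#' CredibleSetSummary: credible-set sizes of sampled topologies
#'
#' @slot nDistinct integer, distinct topologies sampled after burn-in.
#' @slot n99 integer, size of the 99\% credible set.
#' @slot n95 integer, size of the 95\% credible set.
#' @exportClass CredibleSetSummary
setClass("CredibleSetSummary",
         representation(nDistinct = "integer", n99 = "integer",
                        n95 = "integer"))

setValidity("CredibleSetSummary", function(object) {
  if (object@n95 > object@n99 || object@n99 > object@nDistinct)
    return("credible-set sizes must satisfy n95 <= n99 <= nDistinct")
  TRUE
})

#' BayesFactorMatrix: pairwise 2lnB10 comparisons between strategies
#'
#' Antisymmetric matrix of twice the log Bayes factor, with the row
#' strategy as model 1 and the column strategy as model 0, plus the
#' Kass-Raftery interpretation of each entry.
#'
#' @slot values numeric matrix of 2lnB10, dimnames are strategy labels.
#' @slot interpretation character matrix of categories.
#' @exportClass BayesFactorMatrix
setClass("BayesFactorMatrix",
         representation(values = "matrix", interpretation = "matrix"))

setValidity("BayesFactorMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(v + t(v))) > 1e-9) return("matrix must be antisymmetric")
  if (max(abs(diag(v))) > 0) return("diagonal must be zero")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "MitoAlignment", function(object) {
  cat(sprintf("MitoAlignment: %d taxa x %d sites\n",
              nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "GeneMap", function(object) {
  tb <- object@table
  cat(sprintf("GeneMap: %d genes (%d PCG, %d rRNA, %d tRNA), span %d..%d\n",
              nrow(tb), sum(tb$class == "PCG"), sum(tb$class == "rRNA"),
              sum(tb$class == "tRNA"), min(tb$start), max(tb$end)))
})

setMethod("show", "PartitionScheme", function(object) {
  cat(sprintf("PartitionScheme %s: %d charsets over %d sites\n",
              object@strategyId, length(object@charsets), object@nSites))
})

setMethod("show", "SubstitutionModel", function(object) {
  g <- if (is.na(object@gammaShape)) "" else
    sprintf("+G(%g, %d cat)", object@gammaShape, object@nGammaCat)
  cat(sprintf("SubstitutionModel %s%s\n", object@family, g))
})

setMethod("show", "PartitionedModel", function(object) {
  cat(sprintf("PartitionedModel: %d partitions, multipliers in [%.3g, %.3g]\n",
              length(object@models), min(object@rateMultipliers),
              max(object@rateMultipliers)))
})

setMethod("show", "PosteriorTrace", function(object) {
  cat(sprintf("PosteriorTrace: %d samples, lnL range [%.2f, %.2f]\n",
              nrow(object@samples), min(object@samples$lnL),
              max(object@samples$lnL)))
})

setMethod("show", "CredibleSetSummary", function(object) {
  cat(sprintf("Credible sets: total %d, 99%% %d, 95%% %d\n",
              object@nDistinct, object@n99, object@n95))
})

setMethod("show", "BayesFactorMatrix", function(object) {
  cat("2lnB10 matrix (row = M1, column = M0):\n")
  print(round(object@values, 2))
})
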