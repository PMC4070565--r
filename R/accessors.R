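## Constructors and accessors for the core classes.

#' Construct a MitoAlignment from a character matrix or vector of strings
#'
#' @param x character matrix (taxa x sites) or named character vector of
#'   equal-length sequence strings.
#' @return a \code{MitoAlignment}.
#' @examples
#' aln <- MitoAlignment(c(t1 = "ACGT", t2 = "ACGA"))
#' nSites(aln)
#' @export
MitoAlignment <- function(x) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
    x <- m
  } else {
    x <- toupper(x)
  }
  if (ncol(x) > 0L) colnames(x) <- NULL
  new("MitoAlignment", mat = x)
}

#' @rdname MitoAlignment
#' @param object a MitoAlignment
#' @export
setGeneric("taxa", function(object) standardGeneric("taxa"))

#' @rdname MitoAlignment
#' @export
setMethod("taxa", "MitoAlignment", function(object) rownames(object@mat))

#' @rdname MitoAlignment
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname MitoAlignment
#' @export
setMethod("nSites", "MitoAlignment", function(object) ncol(object@mat))

#' @rdname MitoAlignment
#' @export
setGeneric("alignmentMatrix", function(object) standardGeneric("alignmentMatrix"))

#' @rdname MitoAlignment
#' @export
setMethod("alignmentMatrix", "MitoAlignment", function(object) object@mat)

#' Construct a GeneMap
#'
#' @param gene character gene names.
#' @param start,end 1-based inclusive spans on the concatenated alignment.
#' @param class gene classes, "PCG", "rRNA" or "tRNA".
#' @param frame reading-frame offset 0..2 for PCGs, NA otherwise.
#' @param strand "+" or "-" (bookkeeping only; the matrix is stored in a
#'   single orientation).
#' @return a \code{GeneMap} ordered by start coordinate.
#' @export
GeneMap <- function(gene, start, end, class,
                    frame = ifelse(class == "PCG", 0L, NA_integer_),
                    strand = "+") {
  tb <- data.frame(gene = as.character(gene), start = as.integer(start),
                   end = as.integer(end), class = as.character(class),
                   frame = as.integer(frame),
                   strand = rep_len(as.character(strand), length(gene)),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$start), , drop = FALSE]
  rownames(tb) <- NULL
  new("GeneMap", table = tb)
}

#' @rdname GeneMap
#' @param object a GeneMap
#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))

#' @rdname GeneMap
#' @export
setMethod("geneTable", "GeneMap", function(object) object@table)

#' @rdname GeneMap
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname GeneMap
#' @export
setMethod("geneNames", "GeneMap", function(object) object@table$gene)

#' Sites covered by each gene of a GeneMap
#'
#' @param object a GeneMap
#' @return named list of integer site-index vectors, in gene order.
#' @export
setGeneric("geneSites", function(object) standardGeneric("geneSites"))

#' @rdname geneSites
#' @export
setMethod("geneSites", "GeneMap", function(object) {
  tb <- object@table
  out <- mapply(function(s, e) s:e, tb$start, tb$end, SIMPLIFY = FALSE)
  names(out) <- tb$gene
  out
})

#' @rdname PartitionScheme-class
#' @param strategyId strategy label.
#' @param charsets named list of integer site-index vectors.
#' @param nSites total site count of the partitioned alignment.
#' @export
PartitionScheme <- function(strategyId, charsets, nSites) {
  new("PartitionScheme", strategyId = strategyId, charsets = charsets,
      nSites = as.integer(nSites))
}

#' @rdname PartitionScheme-class
#' @param object a PartitionScheme
#' @export
setGeneric("charsets", function(object) standardGeneric("charsets"))

#' @rdname PartitionScheme-class
#' @export
setMethod("charsets", "PartitionScheme", function(object) object@charsets)

#' @rdname PartitionScheme-class
#' @export
setGeneric("strategyId", function(object) standardGeneric("strategyId"))

#' @rdname PartitionScheme-class
#' @export
setMethod("strategyId", "PartitionScheme", function(object) object@strategyId)

#' Construct a SubstitutionModel
#'
#' @param family family name (see \code{\link{modelFamilies}}).
#' @param rates six exchangeabilities (AC, AG, AT, CG, CT, GT); must obey
#'   the family's equality constraints.
#' @param freqs stationary base frequencies (A, C, G, T).
#' @param gammaShape discrete-gamma shape, or NA for rate homogeneity.
#' @param nGammaCat number of equal-probability gamma categories.
#' @return a \code{SubstitutionModel}.
#' @examples
#' jc <- SubstitutionModel("JC")
#' gtr <- SubstitutionModel("GTR", rates = c(1, 4, 1, 1, 4, 1),
#'                          freqs = c(.4, .1, .1, .4), gammaShape = 0.5)
#' @export
SubstitutionModel <- function(family = "GTR", rates = NULL, freqs = NULL,
                              gammaShape = NA_real_, nGammaCat = 4L) {
  fam <- .familyDef(family)
  if (is.null(rates)) rates <- rep(1, 6)
  if (is.null(freqs)) freqs <- rep(0.25, 4)
  if (!fam$free_freqs) freqs <- rep(0.25, 4)
  ## enforce family equality constraints by averaging within rate classes
  for (cl in unique(fam$classes))
    rates[fam$classes == cl] <- mean(rates[fam$classes == cl])
  new("SubstitutionModel", family = family, rates = as.numeric(rates),
      freqs = as.numeric(freqs / sum(freqs)),
      gammaShape = as.numeric(gammaShape), nGammaCat = as.integer(nGammaCat))
}

#' @rdname SubstitutionModel
#' @param object a SubstitutionModel
#' @export
setGeneric("baseFreqs", function(object) standardGeneric("baseFreqs"))

#' @rdname SubstitutionModel
#' @export
setMethod("baseFreqs", "SubstitutionModel",
          function(object) setNames(object@freqs, c("A", "C", "G", "T")))

#' @rdname SubstitutionModel
#' @export
setGeneric("exchangeabilities",
           function(object) standardGeneric("exchangeabilities"))

#' @rdname SubstitutionModel
#' @export
setMethod("exchangeabilities", "SubstitutionModel", function(object)
  setNames(object@rates, c("AC", "AG", "AT", "CG", "CT", "GT")))

#' @rdname SubstitutionModel
#' @export
setGeneric("gammaShape", function(object) standardGeneric("gammaShape"))

#' @rdname SubstitutionModel
#' @export
setMethod("gammaShape", "SubstitutionModel", function(object) object@gammaShape)

#' Construct a PartitionedModel
#'
#' @param models list of \code{SubstitutionModel}, one per partition.
#' @param rateMultipliers positive per-partition rate multipliers; they
#'   are rescaled to a site-weighted mean of exactly 1.
#' @param weights charset sizes (site counts) per partition.
#' @return a \code{PartitionedModel}.
#' @export
PartitionedModel <- function(models, rateMultipliers = NULL, weights) {
  if (is(models, "SubstitutionModel")) models <- list(models)
  k <- length(models)
  weights <- as.integer(weights)
  if (is.null(rateMultipliers)) rateMultipliers <- rep(1, k)
  if (any(rateMultipliers <= 0))
    stop("rate multipliers must be positive")
  wm <- sum(weights * rateMultipliers) / sum(weights)
  new("PartitionedModel", models = models,
      rateMultipliers = rateMultipliers / wm, weights = weights)
}

#' @rdname PartitionedModel
#' @param object a PartitionedModel
#' @export
setGeneric("partitionModels", function(object) standardGeneric("partitionModels"))

#' @rdname PartitionedModel
#' @export
setMethod("partitionModels", "PartitionedModel", function(object) object@models)

#' @rdname PartitionedModel
#' @export
setGeneric("rateMultipliers", function(object) standardGeneric("rateMultipliers"))

#' @rdname PartitionedModel
#' @export
setMethod("rateMultipliers", "PartitionedModel",
          function(object) object@rateMultipliers)

#' Construct an McmcConfig
#'
#' @param nChains total number of chains (one cold, the rest heated).
#' @param heatIncrement heating lambda; chain r runs at
#'   beta = 1 / (1 + lambda * r).
#' @param nGenerations number of MCMC generations.
#' @param sampleEvery thinning interval for the cold chain.
#' @param burninFraction fraction of samples discarded before summaries.
#' @param seed RNG seed for the run.
#' @param essThreshold minimum ESS for \code{\link{assessStationarity}}.
#' @param extensionCap maximum total generations across extensions.
#' @return an \code{McmcConfig}.
#' @export
McmcConfig <- function(nChains = 8L, heatIncrement = 0.1,
                       nGenerations = 100000L, sampleEvery = 100L,
                       burninFraction = 0.25, seed = 42L,
                       essThreshold = 100, extensionCap = 4L * nGenerations) {
  new("McmcConfig", nChains = as.integer(nChains),
      heatIncrement = heatIncrement, nGenerations = as.integer(nGenerations),
      sampleEvery = as.integer(sampleEvery), burninFraction = burninFraction,
      seed = as.integer(seed), essThreshold = essThreshold,
      extensionCap = as.integer(extensionCap))
}

#' @rdname PosteriorTrace-class
#' @param object a PosteriorTrace
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))

#' @rdname PosteriorTrace-class
#' @export
setMethod("traceSamples", "PosteriorTrace", function(object) object@samples)

#' Post-burn-in portion of a trace
#'
#' Discards the leading \code{burninFraction} of samples (the fraction
#' recorded in the trace's own config unless overridden).
#'
#' @param object a PosteriorTrace
#' @param burninFraction fraction in [0,1) to discard.
#' @return a data.frame of retained samples.
#' @export
setGeneric("postBurnin",
           function(object, burninFraction = NULL) standardGeneric("postBurnin"))

#' @rdname postBurnin
#' @export
setMethod("postBurnin", "PosteriorTrace", function(object, burninFraction = NULL) {
  if (is.null(burninFraction)) burninFraction <- object@config@burninFraction
  n <- nrow(object@samples)
  drop <- floor(n * burninFraction)
  object@samples[seq.int(drop + 1L, n), , drop = FALSE]
})

#' @rdname BayesFactorMatrix-class
#' @param object a BayesFactorMatrix
#' @export
setGeneric("bfValues", function(object) standardGeneric("bfValues"))

#' @rdname BayesFactorMatrix-class
#' @export
setMethod("bfValues", "BayesFactorMatrix", function(object) object@values)

#' @rdname CredibleSetSummary-class
#' @param object a CredibleSetSummary
#' @export
setGeneric("credibleSetSizes", function(object) standardGeneric("credibleSetSizes"))

#' @rdname CredibleSetSummary-class
#' @export
setMethod("credibleSetSizes", "CredibleSetSummary", function(object)
  c(total = object@nDistinct, n99 = object@n99, n95 = object@n95))
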