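## Synthetic mitogenome-like data: trees, gene-structured alignments
## evolved under partitioned GTR+Gamma models, ambiguity injection, and
## the bundled "nymphalid-mini" study fixture.

#' Simulate an ultrametric birth-death tree
#'
#' @param nTaxa number of tips (>= 4).
#' @param birth,death birth-death rates (birth > death required).
#' @param height target root-to-tip height in expected substitutions per
#'   site; the tree is rescaled to it.
#' @param minInternalFrac internal branches shorter than this fraction
#'   of the height are floored to it, emulating a radiation whose nodes
#'   are resolvable from a mitogenome-length matrix (0 disables).
#' @param labels optional tip labels (default t1..tn).
#' @return a near-ultrametric \code{phylo}.
#' @export
simulateTree <- function(nTaxa, birth = 1, death = 0, height = 0.15,
                         minInternalFrac = 0.05, labels = NULL) {
  stopifnot(nTaxa >= 4L)
  if (birth <= death) stop("birth rate must exceed death rate")
  tr <- ape::rphylo(nTaxa, birth = birth, death = death)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  if (minInternalFrac > 0) {
    internal <- tr$edge[, 2] > nTaxa
    tr$edge.length[internal] <- pmax(tr$edge.length[internal],
                                     minInternalFrac * height)
  }
  tr$tip.label <- if (is.null(labels)) paste0("t", seq_len(nTaxa)) else labels
  tr
}

## simulate states (1..4) down the tree for a set of sites under one
## model; returns ntaxa x nsites integer matrix
.simulatePartition <- function(tree, model, nsites, multiplier) {
  tr <- ape::reorder.phylo(tree, "postorder")
  preorder <- rev(seq_len(nrow(tr$edge)))
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1]
  rates <- discreteGammaRates(model@gammaShape, model@nGammaCat)
  cat_of_site <- sample.int(length(rates), nsites, replace = TRUE)
  states <- matrix(0L, nnode, nsites)
  states[root, ] <- sample.int(4L, nsites, replace = TRUE,
                               prob = model@freqs)
  m0 <- model; m0@gammaShape <- NA_real_; m0@nGammaCat <- 1L
  for (e in preorder) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t <- tr$edge.length[e] * multiplier
    for (c in seq_along(rates)) {
      idx <- which(cat_of_site == c)
      if (!length(idx)) next
      P <- transitionProbabilities(m0, t * rates[c])[[1]]
      ps <- states[p, idx]
      for (s in 1:4) {
        here <- idx[ps == s]
        if (length(here))
          states[ch, here] <- sample.int(4L, length(here), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tr$tip.label
  out
}

#' Simulate an alignment along a tree under a partitioned model
#'
#' Root states are drawn from each partition's stationary frequencies
#' and evolved along branches under the partition's rate matrix,
#' discrete-gamma category rates and rate multiplier.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param scheme a PartitionScheme covering the sites to simulate.
#' @param models a PartitionedModel aligned to the scheme.
#' @return a MitoAlignment of \code{scheme@nSites} columns.
#' @export
simulateAlignment <- function(tree, scheme, models) {
  nt <- length(tree$tip.label)
  mat <- matrix("A", nt, scheme@nSites,
                dimnames = list(tree$tip.label, NULL))
  ms <- partitionModels(models)
  mult <- rateMultipliers(models)
  cs <- charsets(scheme)
  for (k in seq_along(cs)) {
    sim <- .simulatePartition(tree, ms[[k]], length(cs[[k]]), mult[k])
    mat[rownames(sim), cs[[k]]] <- c("A", "C", "G", "T")[sim]
  }
  MitoAlignment(mat)
}

#' Replace cells with compatible IUPAC ambiguity codes
#'
#' Exactly \code{round(rate * nCells)} randomly chosen cells are
#' replaced by an ambiguity code whose state set contains the original
#' state, emulating unresolved sites in assembled mitogenomes.
#'
#' @param aln a MitoAlignment of unambiguous nucleotides.
#' @param rate fraction of cells in [0, 0.01].
#' @param seed RNG seed.
#' @return a MitoAlignment.
#' @export
injectAmbiguities <- function(aln, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 0.01)
  if (rate == 0) return(aln)
  set.seed(seed)
  m <- alignmentMatrix(aln)
  n <- round(rate * length(m))
  if (n == 0L) return(aln)
  cells <- sample.int(length(m), n)
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  amb <- .AMBIGUITY_CODES
  ambMask <- .IUPAC_MASK[amb]
  for (cell in cells) {
    b <- bit[[m[cell]]]
    ok <- amb[bitwAnd(ambMask, b) > 0L]
    m[cell] <- ok[sample.int(length(ok), 1L)]
  }
  MitoAlignment(m)
}

## the mini mitogenome gene table: 13 PCGs, 2 rRNAs, 22 tRNAs in the
## lepidopteran gene order, lengths ~1/10 of the real aligned matrix
## (1134 + 253 + 163 = 1550 sites).
.miniGeneTable <- function() {
  genes <- c("trnM", "trnI", "trnQ", "nad2", "trnW", "trnC", "trnY",
             "cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6",
             "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1",
             "trnE", "trnF", "nad5", "trnH", "nad4", "nad4l", "trnT",
             "trnP", "nad6", "cob", "trnS2", "nad1", "trnL1", "rrnL",
             "trnV", "rrnS")
  cls <- ifelse(grepl("^trn", genes), "tRNA",
                ifelse(grepl("^rrn", genes), "rRNA", "PCG"))
  pcg_len <- c(nad2 = 101, cox1 = 159, cox2 = 69, atp8 = 16, atp6 = 67,
               cox3 = 79, nad3 = 35, nad5 = 185, nad4 = 134, nad4l = 28,
               nad6 = 53, cob = 114, nad1 = 94)          # sums to 1134
  rrn_len <- c(rrnL = 168, rrnS = 85)                     # sums to 253
  trn <- genes[cls == "tRNA"]
  trn_len <- stats::setNames(c(rep(8L, 9), rep(7L, 13)), trn)  # 163
  len <- integer(length(genes))
  len[cls == "PCG"] <- pcg_len[genes[cls == "PCG"]]
  len[cls == "rRNA"] <- rrn_len[genes[cls == "rRNA"]]
  len[cls == "tRNA"] <- trn_len[genes[cls == "tRNA"]]
  minus <- genes %in% c("trnQ", "trnC", "trnY", "nad5", "trnH", "nad4",
                        "nad4l", "nad1", "trnL1", "rrnL", "trnV", "rrnS")
  ends <- cumsum(len)
  GeneMap(genes, ends - len + 1L, ends, cls,
          frame = ifelse(cls == "PCG", 0L, NA_integer_),
          strand = ifelse(minus, "-", "+"))
}

## generating models for the mini fixture: gene-by-codon partitions with
## codon-position rate pattern 1 : 0.4 : 4 (per PCG, scaled by a
## gene-specific factor), slower tRNAs, intermediate rRNAs; AT-rich
## frequencies, stronger at third positions; transition-biased GTR.
.miniModels <- function(scheme, gmap) {
  tb <- geneTable(gmap)
  exch <- c(1, 6, 1.5, 0.8, 10, 1)
  freq_main <- c(A = .39, C = .11, G = .11, T = .39)   # AT 0.78
  freq_pos3 <- c(A = .44, C = .06, G = .06, T = .44)   # AT 0.88
  gene_factor <- stats::setNames(
    rep_len(c(1.6, 0.7, 1.2, 0.9, 1.4, 0.8), nrow(tb)), tb$gene)
  cs <- charsets(scheme)
  models <- vector("list", length(cs))
  mult <- numeric(length(cs))
  for (k in seq_along(cs)) {
    nm <- names(cs)[k]
    gene <- sub("_pos[123]$", "", nm)
    pos <- if (grepl("_pos[123]$", nm)) as.integer(sub("^.*_pos", "", nm))
           else NA_integer_
    cls <- tb$class[tb$gene == gene]
    if (identical(cls, "PCG")) {
      base <- c(1, 0.4, 4)[pos]
      mult[k] <- base * gene_factor[[gene]]
      fr <- if (pos == 3L) freq_pos3 else freq_main
      sh <- c(0.4, 0.3, 0.9)[pos]
    } else if (identical(cls, "rRNA")) {
      mult[k] <- 0.9
      fr <- freq_main
      sh <- 0.4
    } else {
      mult[k] <- 0.6
      fr <- freq_main
      sh <- 0.4
    }
    models[[k]] <- SubstitutionModel("GTR", rates = exch, freqs = fr,
                                     gammaShape = sh)
  }
  PartitionedModel(models, mult, weights = lengths(cs))
}

#' Build the bundled synthetic study fixture
#'
#' The "nymphalid-mini" preset emulates, at one tenth scale, the
#' structure of a concatenated butterfly mitogenome matrix: 12 taxa;
#' 13 protein-coding genes (1,134 sites), 2 rRNAs (253) and 22 tRNAs
#' (163) in the lepidopteran gene order; A+T-rich composition around
#' 0.80 (stronger at third codon positions); strong codon-position rate
#' heterogeneity (third positions fastest, second slowest); rare IUPAC
#' ambiguities. Ground truth (tree, generating scheme and models) is
#' returned for recovery tests.
#'
#' @param preset fixture name; only "nymphalid-mini".
#' @param seed RNG seed controlling tree, alignment and ambiguities.
#' @param ambiguityRate fraction of cells turned into IUPAC codes.
#' @return list(alignment, genemap, tree, scheme, models, seed).
#' @export
makeFixtureStudy <- function(preset = "nymphalid-mini", seed = 1L,
                             ambiguityRate = 2e-4) {
  preset <- match.arg(preset)
  set.seed(seed)
  gmap <- .miniGeneTable()
  tree <- simulateTree(12L, birth = 1, death = 0.3, height = 0.22)
  scheme <- buildPartitionScheme(gmap, "PS4")
  models <- .miniModels(scheme, gmap)
  aln <- simulateAlignment(tree, scheme, models)
  aln <- injectAmbiguities(aln, ambiguityRate, seed = seed + 1L)
  list(alignment = aln, genemap = gmap, tree = tree, scheme = scheme,
       models = models, seed = seed)
}
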