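## Shared builders for small test objects. Everything is generated in
## code; no data files.

## a tiny annotated alignment: 3 PCGs, 1 rRNA, 2 tRNAs over 4 taxa
tinyGeneMap <- function() {
  GeneMap(gene = c("g1", "t1", "g2", "r1", "t2", "g3"),
          start = c(1L, 10L, 14L, 26L, 34L, 40L),
          end = c(9L, 13L, 25L, 33L, 39L, 51L),
          class = c("PCG", "tRNA", "PCG", "rRNA", "tRNA", "PCG"),
          frame = c(0L, NA, 1L, NA, NA, 2L),
          strand = c("+", "+", "-", "+", "+", "+"))
}

tinyAlignment <- function(ntaxa = 4L, nsites = 51L, seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, TRUE),
              ntaxa, nsites, dimnames = list(paste0("s", seq_len(ntaxa)), NULL))
  MitoAlignment(m)
}

## random GeneMap with the requested class counts, contiguous spans
randomGeneMap <- function(nPCG, nrRNA, ntRNA, seed = 1L) {
  set.seed(seed)
  k <- nPCG + nrRNA + ntRNA
  cls <- sample(c(rep("PCG", nPCG), rep("rRNA", nrRNA), rep("tRNA", ntRNA)))
  len <- ifelse(cls == "PCG", sample(9:60, k, TRUE),
                ifelse(cls == "rRNA", sample(20:50, k, TRUE),
                       sample(5:10, k, TRUE)))
  ends <- cumsum(len)
  GeneMap(paste0("gene", seq_len(k)), ends - len + 1L, ends, cls,
          frame = ifelse(cls == "PCG", sample(0:2, k, TRUE), NA_integer_))
}

## unrooted quartet with fixed branch lengths
quartet <- function(len = 0.1) {
  tr <- ape::unroot(ape::read.tree(text = "((a,b),(c,d));"))
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

## random unrooted tree with exponential branch lengths
randomTree <- function(n, seed = 1L, mean = 0.1) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean)
  tr
}

randomModel <- function(seed = 1L, gamma = TRUE) {
  set.seed(seed)
  SubstitutionModel("GTR", rates = stats::runif(6, 0.3, 3),
                    freqs = stats::runif(4, 0.5, 2),
                    gammaShape = if (gamma) stats::runif(1, 0.3, 2)
                                 else NA_real_)
}

singlePartition <- function(n) PartitionScheme("PS1", list(all = seq_len(n)), n)

onePartModel <- function(model, n) PartitionedModel(list(model), weights = n)

## independent Fitch oracle: minimum changes over all internal-state
## assignments, one site at a time
fitchOracle <- function(tree, aln) {
  po <- ape::reorder.phylo(tree, "postorder")
  m <- alignmentMatrix(aln)[po$tip.label, , drop = FALSE]
  ntip <- nrow(m)
  nnode <- max(po$edge)
  masksets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T"),
                   `-` = c("A", "C", "G", "T"), `?` = c("A", "C", "G", "T"))
  total <- 0L
  for (site in seq_len(ncol(m))) {
    states <- lapply(seq_len(nnode), function(nd) {
      if (nd <= ntip) masksets[[m[nd, site]]] else c("A", "C", "G", "T")
    })
    grid <- expand.grid(states, stringsAsFactors = FALSE)
    best <- min(apply(grid, 1, function(asn) {
      sum(asn[po$edge[, 1]] != asn[po$edge[, 2]])
    }))
    total <- total + best
  }
  as.integer(total)
}
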