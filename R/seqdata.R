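## Alignment / annotation I/O, dataset selections, the 12 partitioning
## strategies, and sequence summary statistics.

#' Read an aligned FASTA or NEXUS file
#'
#' FASTA parsing is delegated to ape; NEXUS data blocks are read with
#' \code{ape::read.nexus.data} and any \code{charset} lines in a sets or
#' assumptions block are returned alongside as a \code{PartitionScheme}
#' with strategy id \code{"external"}. NEXUS charset coordinates are
#' 1-based inclusive and may use \code{a-b} ranges and \code{a-b\\3}
#' stepped ranges.
#'
#' @param path file path.
#' @param format "FASTA" or "NEXUS"; guessed from the extension when
#'   missing.
#' @return a \code{MitoAlignment}; for NEXUS files with charsets, the
#'   scheme is attached as attribute \code{"scheme"}.
#' @export
readAlignment <- function(path, format = c("auto", "FASTA", "NEXUS")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "NEXUS" else "FASTA"
  }
  if (format == "FASTA") {
    seqs <- ape::read.FASTA(path)
    chars <- lapply(as.character(seqs), toupper)
    lens <- lengths(chars)
    if (length(unique(lens)) > 1L)
      stop("alignment-shape error: ragged rows (lengths ",
           paste(unique(lens), collapse = ", "), ")")
    m <- do.call(rbind, chars)
    rownames(m) <- names(seqs)
    return(MitoAlignment(m))
  }
  dat <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(dat, function(s) toupper(s)))
  rownames(m) <- names(dat)
  aln <- MitoAlignment(m)
  cs <- .parseNexusCharsets(readLines(path), ncol(m))
  if (length(cs))
    attr(aln, "scheme") <- PartitionScheme("external", cs, ncol(m))
  aln
}

.parseNexusCharsets <- function(lines, n_sites) {
  hits <- grep("^\\s*charset\\s+", lines, ignore.case = TRUE, value = TRUE)
  out <- list()
  for (h in hits) {
    h <- sub(";\\s*$", "", h)
    body <- sub("^\\s*charset\\s+", "", h, ignore.case = TRUE)
    eq <- regmatches(body, regexpr("=", body))
    if (!length(eq)) next
    nm <- trimws(sub("=.*$", "", body))
    spec <- trimws(sub("^[^=]*=", "", body))
    idx <- integer(0)
    for (tok in strsplit(spec, "\\s+")[[1]]) {
      step <- 1L
      if (grepl("\\\\", tok)) {
        step <- as.integer(sub("^.*\\\\", "", tok))
        tok <- sub("\\\\.*$", "", tok)
      }
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        if (ab[2] > n_sites) stop("charset '", nm, "' exceeds alignment length")
        idx <- c(idx, seq.int(ab[1], ab[2], by = step))
      } else {
        idx <- c(idx, as.integer(tok))
      }
    }
    out[[nm]] <- sort(unique(idx))
  }
  out
}

#' Write an alignment as FASTA or NEXUS (optionally with charsets)
#'
#' NEXUS output writes a data block and, when a scheme is supplied, a
#' sets block with 1-based inclusive charset lines; codon-position
#' charsets produced by \code{\link{buildPartitionScheme}} are emitted as
#' stepped ranges (\code{a-b\\3}) where the sites form one, otherwise as
#' explicit range unions.
#'
#' @param aln a MitoAlignment.
#' @param path output file path.
#' @param format "FASTA" or "NEXUS".
#' @param scheme optional PartitionScheme to write into a sets block.
#' @return invisibly, the path.
#' @export
writeAlignment <- function(aln, path, format = c("FASTA", "NEXUS"),
                           scheme = NULL) {
  format <- match.arg(format)
  m <- alignmentMatrix(aln)
  if (format == "FASTA") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(m))) {
      writeLines(paste0(">", rownames(m)[i]), con)
      writeLines(paste(m[i, ], collapse = ""), con)
    }
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  for (i in seq_len(nrow(m)))
    writeLines(sprintf("    %s  %s", rownames(m)[i],
                       paste(m[i, ], collapse = "")), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  if (!is.null(scheme)) {
    writeLines("BEGIN SETS;", con)
    for (nm in names(charsets(scheme)))
      writeLines(sprintf("  charset %s = %s;", nm,
                         .formatSiteSet(charsets(scheme)[[nm]])), con)
    writeLines("END;", con)
  }
  invisible(path)
}

## Compact NEXUS representation of a site set: contiguous runs as a-b,
## arithmetic runs with common step d > 1 as a-b\d.
.formatSiteSet <- function(sites) {
  sites <- sort(sites)
  if (length(sites) >= 2L) {
    d <- unique(diff(sites))
    if (length(d) == 1L && d > 1L)
      return(sprintf("%d-%d\\%d", sites[1], sites[length(sites)], d))
  }
  runs <- split(sites, cumsum(c(1L, diff(sites) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, ""), collapse = " ")
}

#' Read / write a gene-coordinate table
#'
#' Tab-separated with columns gene, start, end, class, frame, strand;
#' coordinates 1-based inclusive on the concatenated alignment.
#'
#' @param path TSV file path.
#' @return a \code{GeneMap}.
#' @export
readGeneMap <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  GeneMap(tb$gene, tb$start, tb$end, tb$class, tb$frame, tb$strand)
}

#' @rdname readGeneMap
#' @param gmap a GeneMap to write.
#' @export
writeGeneMap <- function(gmap, path) {
  utils::write.table(geneTable(gmap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The three dataset selections
#'
#' D37 keeps all genes, D15 the protein-coding and rRNA genes, D13 the
#' protein-coding genes only.
#'
#' @param id "D37", "D15" or "D13".
#' @return character vector of included gene classes.
#' @export
datasetClasses <- function(id = c("D37", "D15", "D13")) {
  switch(match.arg(id),
         D37 = c("PCG", "rRNA", "tRNA"),
         D15 = c("PCG", "rRNA"),
         D13 = "PCG")
}

#' Subset an annotated alignment to a dataset selection
#'
#' Keeps the columns of the genes whose class belongs to the selection,
#' preserving gene order, and remaps the GeneMap onto the new
#' coordinates.
#'
#' @param aln a MitoAlignment.
#' @param gmap the matching GeneMap.
#' @param sel dataset id, "D37", "D15" or "D13".
#' @return list with elements \code{alignment} and \code{genemap}.
#' @export
buildDataset <- function(aln, gmap, sel = c("D37", "D15", "D13")) {
  sel <- match.arg(sel)
  tb <- geneTable(gmap)
  if (max(tb$end) > nSites(aln))
    stop("gene map extends past the alignment")
  keep <- tb[tb$class %in% datasetClasses(sel), , drop = FALSE]
  if (nrow(keep) == 0L) stop("empty-dataset error: selection removes all genes")
  cols <- unlist(mapply(function(s, e) s:e, keep$start, keep$end,
                        SIMPLIFY = FALSE))
  newlen <- cumsum(keep$end - keep$start + 1L)
  gm2 <- GeneMap(keep$gene, c(1L, newlen[-length(newlen)] + 1L), newlen,
                 keep$class, keep$frame, keep$strand)
  list(alignment = MitoAlignment(alignmentMatrix(aln)[, cols, drop = FALSE]),
       genemap = gm2)
}

.STRATEGY_SEL <- c(PS1 = "D37", PS2 = "D37", PS3 = "D37", PS4 = "D37",
                   PS5 = "D15", PS6 = "D15", PS7 = "D15", PS8 = "D15",
                   PS9 = "D13", PS10 = "D13", PS11 = "D13", PS12 = "D13")

#' Dataset selection compatible with a partitioning strategy
#'
#' PS1-PS4 operate on the 37-gene dataset, PS5-PS8 on the 15-gene
#' dataset, PS9-PS12 on the 13-gene dataset.
#'
#' @param strategy "PS1".."PS12".
#' @return dataset id.
#' @export
strategyDataset <- function(strategy) {
  if (!strategy %in% names(.STRATEGY_SEL))
    stop("unknown strategy '", strategy, "'")
  unname(.STRATEGY_SEL[strategy])
}

#' Build one of the 12 partitioning strategies
#'
#' The strategies follow the standard mitogenome partitioning ladder on
#' each dataset selection: no partition (PS1/PS5/PS9); partition by PCG
#' codon position with all RNA genes combined into one extra set where
#' present (PS2/PS6: 4 sets, PS10: 3 sets); partition by gene (PS3: 37,
#' PS7: 15, PS11: 13); partition by both gene and codon position, PCGs
#' split three ways and RNA genes kept whole (PS4: 63, PS8: 41,
#' PS12: 39). Codon position is computed per gene as
#' \code{(site - gene_start - frame) mod 3}, so trailing partial codons
#' keep their computed position. Charsets are emitted in gene order with
#' codon sub-charsets in order 1, 2, 3.
#'
#' @param gmap GeneMap of the dataset-selected alignment (i.e. the
#'   genemap returned by \code{\link{buildDataset}}).
#' @param strategy "PS1".."PS12".
#' @param sel dataset id; must match the strategy's dataset. Defaults to
#'   the strategy's own dataset.
#' @return a \code{PartitionScheme}.
#' @export
buildPartitionScheme <- function(gmap, strategy, sel = strategyDataset(strategy)) {
  if (!identical(sel, strategyDataset(strategy)))
    stop("configuration error: strategy ", strategy,
         " requires dataset ", strategyDataset(strategy), ", got ", sel)
  tb <- geneTable(gmap)
  if (!all(tb$class %in% datasetClasses(sel)))
    stop("configuration error: genemap contains classes outside ", sel)
  n_sites <- max(tb$end)
  kind <- c(PS1 = "none", PS2 = "codon", PS3 = "gene", PS4 = "genecodon",
            PS5 = "none", PS6 = "codon", PS7 = "gene", PS8 = "genecodon",
            PS9 = "none", PS10 = "codon", PS11 = "gene",
            PS12 = "genecodon")[[strategy]]
  cs <- switch(kind,
    none = list(all = seq_len(n_sites)),
    codon = {
      pcg <- tb[tb$class == "PCG", , drop = FALSE]
      pos_sets <- lapply(1:3, function(p) {
        unlist(mapply(function(s, e, f) {
          sites <- s:e
          sites[((sites - s - f) %% 3L) == (p - 1L)]
        }, pcg$start, pcg$end, pcg$frame, SIMPLIFY = FALSE), use.names = FALSE)
      })
      names(pos_sets) <- paste0("pos", 1:3)
      rna <- tb[tb$class != "PCG", , drop = FALSE]
      if (nrow(rna) > 0L)
        pos_sets$RNA <- unlist(mapply(function(s, e) s:e, rna$start, rna$end,
                                      SIMPLIFY = FALSE), use.names = FALSE)
      pos_sets
    },
    gene = {
      out <- geneSites(gmap)
      out
    },
    genecodon = {
      out <- list()
      for (i in seq_len(nrow(tb))) {
        g <- tb[i, ]
        sites <- g$start:g$end
        if (g$class == "PCG") {
          for (p in 1:3)
            out[[sprintf("%s_pos%d", g$gene, p)]] <-
              sites[((sites - g$start - g$frame) %% 3L) == (p - 1L)]
        } else {
          out[[g$gene]] <- sites
        }
      }
      out
    })
  cs <- cs[vapply(cs, length, 1L) > 0L]
  PartitionScheme(strategy, cs, n_sites)
}

## Per-column distinct unambiguous states and their taxon multiplicities.
.columnStates <- function(col) {
  tab <- table(col[col %in% c("A", "C", "G", "T")])
  tab[tab > 0L]
}

#' Classify alignment sites
#'
#' Counts variable (polymorphic) and parsimony-informative sites and the
#' A+T fraction. Only unambiguous nucleotides enter the state counts:
#' gaps, missing data and IUPAC ambiguity codes are excluded, matching
#' DnaSP-style "excluding gaps and missing data" accounting. A site is
#' variable when at least two distinct states occur, and
#' parsimony-informative when at least two states each occur in at least
#' two taxa.
#'
#' @param aln a MitoAlignment (>= 2 taxa for meaningful counts).
#' @return list with nSites, nVariable, nParsimonyInformative, atFraction.
#' @export
classifySites <- function(aln) {
  m <- alignmentMatrix(aln)
  if (ncol(m) == 0L)
    return(list(nSites = 0L, nVariable = 0L, nParsimonyInformative = 0L,
                atFraction = NA_real_))
  isA <- m == "A"; isC <- m == "C"; isG <- m == "G"; isT <- m == "T"
  counts <- rbind(colSums(isA), colSums(isC), colSums(isG), colSums(isT))
  n_states <- colSums(counts > 0L)
  n_ge2 <- colSums(counts >= 2L)
  nv <- sum(n_states >= 2L)
  npi <- sum(n_ge2 >= 2L)
  tot <- sum(counts)
  at <- if (tot == 0L) NA_real_ else sum(counts[c(1L, 4L), ]) / tot
  list(nSites = ncol(m), nVariable = as.integer(nv),
       nParsimonyInformative = as.integer(npi), atFraction = at)
}

#' A+T composition of an alignment
#'
#' (#A + #T) / (#A + #C + #G + #T); gaps, missing and ambiguity codes
#' are excluded.
#'
#' @param aln a MitoAlignment.
#' @return fraction in [0, 1].
#' @export
atFraction <- function(aln) {
  m <- alignmentMatrix(aln)
  n <- sum(m %in% c("A", "C", "G", "T"))
  if (n == 0L) stop("undefined-composition error: no unambiguous nucleotides")
  sum(m %in% c("A", "T")) / n
}

#' Sliding-window polymorphism profile
#'
#' Counts variable sites (as in \code{\link{classifySites}}) in windows
#' of \code{width} sites advanced by \code{step}, the standard
#' DnaSP-style profile of polymorphism along a mitogenome alignment.
#'
#' @param aln a MitoAlignment.
#' @param width window width in sites (default 500).
#' @param step step size in sites (default 2).
#' @return data.frame with columns windowStart (1-based) and nVariable.
#' @export
slidingWindowPolymorphism <- function(aln, width = 500L, step = 2L) {
  stopifnot(width >= 1L, step >= 1L)
  L <- nSites(aln)
  if (L < width)
    stop("empty-series error: alignment length ", L, " < window width ", width)
  m <- alignmentMatrix(aln)
  isVar <- vapply(seq_len(L), function(j) {
    st <- .columnStates(m[, j])
    length(st) >= 2L
  }, TRUE)
  cum <- c(0L, cumsum(isVar))
  starts <- seq.int(1L, L - width + 1L, by = step)
  data.frame(windowStart = starts,
             nVariable = cum[starts + width] - cum[starts])
}

#' Reference class lengths of the emulated concatenated mitogenome matrix
#'
#' The aligned-length budget of a butterfly whole-mitogenome matrix:
#' 11,340 sites from the 13 protein-coding genes, 2,528 from the two
#' rRNAs and 1,627 from the 22 tRNAs. The bundled "nymphalid-mini"
#' fixture scales this structure by one tenth.
#'
#' @return named integer vector with elements PCG, rRNA, tRNA.
#' @export
referenceClassLengths <- function() {
  c(PCG = 11340L, rRNA = 2528L, tRNA = 1627L)
}
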