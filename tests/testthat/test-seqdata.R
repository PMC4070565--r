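test_that("FASTA and NEXUS round-trips preserve the matrix and charsets", {
  aln <- tinyAlignment(seed = 3)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(aln, f, "FASTA")
  expect_identical(alignmentMatrix(readAlignment(f)), alignmentMatrix(aln))

  sch <- buildPartitionScheme(tinyGeneMap(), "PS2")
  nx <- withr::local_tempfile(fileext = ".nex")
  writeAlignment(aln, nx, "NEXUS", scheme = sch)
  back <- readAlignment(nx)
  expect_identical(alignmentMatrix(back), alignmentMatrix(aln))
  sc2 <- attr(back, "scheme")
  expect_s4_class(sc2, "PartitionScheme")
  expect_identical(strategyId(sc2), "external")
  expect_identical(lapply(charsets(sc2), sort),
                   lapply(charsets(sch), function(x) sort(unname(x))))
})

test_that("malformed alignments are rejected with informative errors", {
  f <- withr::local_tempfile()
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(readAlignment(f, "FASTA"), "ragged")
  expect_error(MitoAlignment(c(a = "ACGT", b = "ACZT")), "symbol")
  expect_error(MitoAlignment(c(a = "ACGT", a = "ACGT")), "unique")
})

test_that("a 2-taxon 4-column FASTA parses to a length-4 alignment", {
  f <- withr::local_tempfile()
  writeLines(c(">x", "AC-T", ">y", "ARG?"), f)
  aln <- readAlignment(f, "FASTA")
  expect_equal(nSites(aln), 4L)
  expect_identical(taxa(aln), c("x", "y"))
})

test_that("GeneMap TSV round-trips and validity catches overlaps", {
  gm <- tinyGeneMap()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneMap(gm, f)
  expect_identical(geneTable(readGeneMap(f)), geneTable(gm))
  expect_error(GeneMap(c("a", "b"), c(1L, 5L), c(6L, 9L), c("PCG", "PCG"),
                       c(0L, 0L)), "overlap")
})

test_that("dataset selections subset columns by gene class", {
  aln <- tinyAlignment()
  gm <- tinyGeneMap()
  tb <- geneTable(gm)

  d37 <- buildDataset(aln, gm, "D37")
  expect_identical(alignmentMatrix(d37$alignment), alignmentMatrix(aln))

  d13 <- buildDataset(aln, gm, "D13")
  pcg_len <- sum(tb$end[tb$class == "PCG"] - tb$start[tb$class == "PCG"] + 1L)
  expect_equal(nSites(d13$alignment), pcg_len)
  expect_identical(geneTable(d13$genemap)$class, rep("PCG", 3))

  d15 <- buildDataset(aln, gm, "D15")
  rrna_len <- sum(tb$end[tb$class == "rRNA"] - tb$start[tb$class == "rRNA"] + 1L)
  expect_equal(nSites(d15$alignment), pcg_len + rrna_len)
  ## columns preserve gene order: first gene of D13 is g1's span
  expect_identical(alignmentMatrix(d13$alignment)[, 1:9],
                   alignmentMatrix(aln)[, 1:9])
})

test_that("the twelve strategies produce the documented charset counts", {
  fx <- makeFixtureStudy(seed = 1)
  counts <- c(PS1 = 1L, PS2 = 4L, PS3 = 37L, PS4 = 63L,
              PS5 = 1L, PS6 = 4L, PS7 = 15L, PS8 = 41L,
              PS9 = 1L, PS10 = 3L, PS11 = 13L, PS12 = 39L)
  for (ps in names(counts)) {
    ds <- buildDataset(fx$alignment, fx$genemap, strategyDataset(ps))
    sch <- buildPartitionScheme(ds$genemap, ps)
    expect_identical(length(charsets(sch)), counts[[ps]],
                     label = paste(ps, "charset count"))
  }
  expect_error(buildPartitionScheme(fx$genemap, "PS4", sel = "D13"),
               "configuration error")
})

test_that("every strategy partitions the site set exactly on random gene maps", {
  for (seed in 1:4) {
    gm <- randomGeneMap(5, 2, 4, seed = seed)
    full <- geneTable(gm)
    for (ps in paste0("PS", 1:12)) {
      keep <- full[full$class %in% datasetClasses(strategyDataset(ps)), ]
      ends <- cumsum(keep$end - keep$start + 1L)
      sel_gm <- GeneMap(keep$gene, c(1L, head(ends, -1) + 1L), ends,
                        keep$class, keep$frame, keep$strand)
      sch <- buildPartitionScheme(sel_gm, ps)
      sites <- sort(unlist(charsets(sch), use.names = FALSE))
      expect_identical(sites, seq_len(max(ends)),
                       label = paste("seed", seed, ps, "exact partition"))
    }
    ## expected counts from the structure
    n_pcg <- sum(full$class == "PCG")
    sch4 <- {
      keep <- full  # D37
      sch <- buildPartitionScheme(gm, "PS4")
      expect_length(charsets(sch), 3L * n_pcg + sum(full$class != "PCG"))
    }
  }
})

test_that("codon-position charsets follow the per-gene frame rule", {
  gm <- tinyGeneMap()
  sch <- buildPartitionScheme(gm, "PS2")
  cs <- charsets(sch)
  tb <- geneTable(gm)
  ## g2 spans 14..25 with frame 1: site 14 is position (14-14-1) mod 3 = 2
  ## under 0-based position counting, i.e. codon position 3
  expect_true(14L %in% cs$pos3)
  expect_true(15L %in% cs$pos1)
  ## g1 frame 0: site 1 -> pos1
  expect_true(1L %in% cs$pos1)
  ## RNA set holds every non-PCG site
  rna_sites <- unlist(geneSites(gm)[tb$class != "PCG"], use.names = FALSE)
  expect_setequal(cs$RNA, rna_sites)
  ## charsets emitted in codon order then RNA
  expect_identical(names(cs), c("pos1", "pos2", "pos3", "RNA"))
})

test_that("site classification matches hand-enumerated multiplicities", {
  sameAll <- MitoAlignment(matrix("A", 4, 5,
                                  dimnames = list(paste0("t", 1:4), NULL)))
  cs <- classifySites(sameAll)
  expect_equal(cs$nVariable, 0L)
  expect_equal(cs$nParsimonyInformative, 0L)

  m <- cbind(c("A", "A", "T", "T"), c("A", "A", "A", "T"))
  rownames(m) <- paste0("t", 1:4)
  cs2 <- classifySites(MitoAlignment(m))
  expect_equal(cs2$nVariable, 2L)
  expect_equal(cs2$nParsimonyInformative, 1L)

  ## ambiguities and gaps are excluded from state counts
  m3 <- cbind(c("A", "A", "R", "-"), c("A", "?", "N", "T"))
  rownames(m3) <- paste0("t", 1:4)
  cs3 <- classifySites(MitoAlignment(m3))
  expect_equal(cs3$nVariable, 1L)   # only column 2 has two real states? no:
  ## col1 states {A,A}, col2 states {A,T} -> one variable, none informative
  expect_equal(cs3$nParsimonyInformative, 0L)
})

test_that("site classification is invariant to taxon and column order", {
  aln <- tinyAlignment(6, 40, seed = 9)
  m <- alignmentMatrix(aln)
  perm <- MitoAlignment(m[sample(nrow(m)), sample(ncol(m))])
  a <- classifySites(aln); b <- classifySites(perm)
  expect_equal(a$nVariable, b$nVariable)
  expect_equal(a$nParsimonyInformative, b$nParsimonyInformative)
  expect_equal(a$atFraction, b$atFraction)
})

test_that("AT fraction counts only unambiguous nucleotides", {
  expect_equal(atFraction(MitoAlignment(c(x = "AAAA"))), 1.0)
  expect_equal(atFraction(MitoAlignment(c(x = "ACGT"))), 0.5)
  expect_equal(atFraction(MitoAlignment(c(x = "A-G?"))), 0.5)
  expect_error(atFraction(MitoAlignment(c(x = "--??"))),
               "undefined-composition")
})

test_that("sliding windows count variable sites per window", {
  m <- matrix("A", 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  m[1:2, 3] <- "T"; m[1:2, 8] <- "C"
  aln <- MitoAlignment(m)
  sw <- slidingWindowPolymorphism(aln, width = 4, step = 2)
  expect_equal(sw$windowStart, c(1L, 3L, 5L, 7L))
  expect_equal(sw$nVariable, c(1L, 1L, 1L, 1L))

  ## width = length: one window equal to the total variable count
  sw2 <- slidingWindowPolymorphism(aln, width = 10, step = 1)
  expect_equal(nrow(sw2), 1L)
  expect_equal(sw2$nVariable, classifySites(aln)$nVariable)

  ## step = width tiles the alignment: counts sum to the total
  sw3 <- slidingWindowPolymorphism(aln, width = 5, step = 5)
  expect_equal(sum(sw3$nVariable), classifySites(aln)$nVariable)

  ## invariant alignment
  inv <- MitoAlignment(matrix("G", 3, 8,
                              dimnames = list(paste0("t", 1:3), NULL)))
  expect_true(all(slidingWindowPolymorphism(inv, 4, 2)$nVariable == 0L))

  expect_error(slidingWindowPolymorphism(aln, width = 50), "empty-series")
})
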