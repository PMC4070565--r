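## Study orchestration: datasets x strategies x model settings, report
## emission, and the single-gene suite.

#' Study configuration
#'
#' Validates and normalizes the settings for \code{\link{runStudy}}.
#'
#' @param alignment MitoAlignment (or path readable by
#'   \code{\link{readAlignment}}); ignored when \code{preset} is given.
#' @param genemap GeneMap or TSV path.
#' @param preset fixture preset name passed to
#'   \code{\link{makeFixtureStudy}}.
#' @param strategies character vector of strategy ids (PS1..PS12); each
#'   strategy runs on its own dataset selection.
#' @param modelSetting "GTR_G" (every partition GTR+G) or "best_fit"
#'   (AICc selection per partition, mapped to usable families).
#' @param mcmc an McmcConfig.
#' @param priors a PriorSet.
#' @param seed global seed; per-cell seeds are derived from it.
#' @param outDir optional directory for TSV reports.
#' @return validated config list.
#' @export
studyConfig <- function(alignment = NULL, genemap = NULL, preset = NULL,
                        strategies = c("PS1", "PS2"),
                        modelSetting = c("GTR_G", "best_fit"),
                        mcmc = McmcConfig(), priors = PriorSet(),
                        seed = 1L, outDir = NULL) {
  modelSetting <- match.arg(modelSetting)
  for (s in strategies) strategyDataset(s)  # validates ids
  if (is.null(preset)) {
    if (is.character(alignment)) alignment <- readAlignment(alignment)
    if (is.character(genemap)) genemap <- readGeneMap(genemap)
    if (is.null(alignment) || is.null(genemap))
      stop("supply either a preset or an alignment + genemap")
  }
  list(alignment = alignment, genemap = genemap, preset = preset,
       strategies = strategies, modelSetting = modelSetting, mcmc = mcmc,
       priors = priors, seed = as.integer(seed), outDir = outDir)
}

## derived integer sub-seed, kept inside 32-bit range
.deriveSeed <- function(seed, a, i)
  as.integer((as.numeric(seed) * a + i) %% 214748329)

.cellModels <- function(aln, scheme, modelSetting, nGammaCat = 4L) {
  cs <- charsets(scheme)
  if (modelSetting == "GTR_G") {
    models <- lapply(cs, function(x)
      SubstitutionModel("GTR", gammaShape = 0.5, nGammaCat = nGammaCat))
  } else {
    m <- alignmentMatrix(aln)
    tree <- guideTree(aln)
    models <- lapply(cs, function(sites) {
      block <- MitoAlignment(m[, sites, drop = FALSE])
      sel <- selectModelAICc(block, tree = tree, nGammaCat = nGammaCat)
      fit <- attr(sel, "model")
      mapped <- attr(sel, "mapped")
      if (!identical(mapped, fit@family))
        fit <- SubstitutionModel(mapped, rates = fit@rates,
                                 freqs = fit@freqs,
                                 gammaShape = fit@gammaShape,
                                 nGammaCat = nGammaCat)
      fit
    })
  }
  PartitionedModel(unname(models), weights = lengths(cs))
}

#' Run the full partitioning-strategy study
#'
#' For every requested strategy: build the dataset selection and
#' partition scheme, assign per-partition models (fixed GTR+G or AICc
#' best-fit), run the MCMC, and summarize. Then compare strategies
#' within each dataset by harmonic-mean Bayes factors and report
#' credible sets, free-parameter sums and tree-length statistics — the
#' strategy-comparison tables of a partitioning study.
#'
#' @param config output of \code{\link{studyConfig}}.
#' @return list with elements traces (named by strategy), summary
#'   (data.frame), bf (named list of BayesFactorMatrix per dataset),
#'   consensus (named list of majority-rule trees), failures (named list
#'   of error messages for cells that failed).
#' @export
runStudy <- function(config) {
  if (!is.null(config$preset)) {
    fx <- makeFixtureStudy(config$preset, seed = config$seed)
    aln <- fx$alignment; gmap <- fx$genemap
  } else {
    aln <- config$alignment; gmap <- config$genemap
  }
  traces <- list(); failures <- list()
  rows <- list(); consensus <- list()
  for (i in seq_along(config$strategies)) {
    ps <- config$strategies[i]
    res <- tryCatch({
      sel <- strategyDataset(ps)
      ds <- buildDataset(aln, gmap, sel)
      scheme <- buildPartitionScheme(ds$genemap, ps)
      models <- .cellModels(ds$alignment, scheme, config$modelSetting)
      patterns <- compressPatterns(ds$alignment, scheme)
      cfg <- config$mcmc
      cfg@seed <- .deriveSeed(config$seed, 131L, i)
      trace <- runMcmc(patterns, models, cfg, config$priors)
      list(trace = trace, scheme = scheme, models = models, sel = sel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ps]] <- conditionMessage(res)
      next
    }
    traces[[ps]] <- res$trace
    post <- postBurnin(res$trace)
    cset <- credibleSets(res$trace)
    tls <- treeLengthStats(res$trace)
    keep <- seq.int(nrow(res$trace@samples) - nrow(post) + 1L,
                    nrow(res$trace@samples))
    consensus[[ps]] <- majorityRuleConsensus(res$trace@trees[keep])
    rows[[ps]] <- data.frame(
      strategy = ps, dataset = res$sel,
      nPartitions = length(charsets(res$scheme)),
      freeParameters = countFreeParameters(res$scheme, res$models),
      lnHM = harmonicMeanLnL(post$lnL),
      csetTotal = cset@nDistinct, cset99 = cset@n99, cset95 = cset@n95,
      treeLengthMean = tls[["mean"]], treeLengthSD = tls[["sd"]],
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  bf <- list()
  if (length(traces) >= 2L) {
    byds <- split(names(traces),
                  vapply(names(traces), strategyDataset, ""))
    for (ds in names(byds))
      if (length(byds[[ds]]) >= 2L)
        bf[[ds]] <- bfMatrix(traces[byds[[ds]]])
  }
  out <- list(traces = traces, summary = summary, bf = bf,
              consensus = consensus, failures = failures,
              seed = config$seed)
  if (!is.null(config$outDir)) .writeStudyReports(out, config$outDir)
  out
}

.writeStudyReports <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$summary, file.path(dir, "strategy_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ds in names(study$bf)) {
    v <- bfValues(study$bf[[ds]])
    utils::write.table(data.frame(strategy = rownames(v), v,
                                  check.names = FALSE),
                       file.path(dir, paste0("bayes_factors_", ds, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ps in names(study$consensus))
    ape::write.tree(study$consensus[[ps]],
                    file.path(dir, paste0("consensus_", ps, ".nwk")))
  invisible(dir)
}

#' Single-gene phylogenies and congruence with the concatenated tree
#'
#' Runs an independent Bayesian analysis per major gene (the
#' protein-coding and rRNA genes of the 15-gene selection), summarizes
#' each as a majority-rule consensus, and reports per-gene
#' Robinson-Foulds distance to the reference topology.
#'
#' @param aln concatenated MitoAlignment.
#' @param gmap matching GeneMap.
#' @param reference reference \code{phylo} (e.g. the concatenated-data
#'   consensus).
#' @param mcmc McmcConfig for the per-gene runs.
#' @param priors PriorSet.
#' @param seed base seed; per-gene seeds derive from it.
#' @param minLength genes shorter than this are skipped with a warning.
#' @return list(trees = named list of consensus phylo, report =
#'   congruence data.frame).
#' @export
runSingleGeneSuite <- function(aln, gmap, reference, mcmc = McmcConfig(),
                               priors = PriorSet(), seed = 1L,
                               minLength = 10L) {
  tb <- geneTable(gmap)
  tb <- tb[tb$class %in% c("PCG", "rRNA"), , drop = FALSE]
  m <- alignmentMatrix(aln)
  trees <- list()
  for (i in seq_len(nrow(tb))) {
    g <- tb[i, ]
    if (g$end - g$start + 1L < minLength) {
      warning("gene ", g$gene, " shorter than ", minLength, "; skipped")
      next
    }
    block <- MitoAlignment(m[, g$start:g$end, drop = FALSE])
    models <- PartitionedModel(
      list(SubstitutionModel("GTR", gammaShape = 0.5)),
      weights = nSites(block))
    cfg <- mcmc
    cfg@seed <- .deriveSeed(seed, 977L, i)
    trace <- runMcmc(compressPatterns(block), models, cfg, priors)
    post_n <- nrow(postBurnin(trace))
    keep <- seq.int(length(trace@trees) - post_n + 1L, length(trace@trees))
    trees[[g$gene]] <- majorityRuleConsensus(trace@trees[keep])
  }
  list(trees = trees, report = congruenceReport(trees, reference))
}
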