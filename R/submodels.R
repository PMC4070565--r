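## Substitution-model layer: GTR family hierarchy, rate matrices,
## discrete-gamma transition probabilities, AICc model selection, the
## nearest-over-parameterised substitution rule and free-parameter
## accounting.

## Each family = equality classes on the 6 exchangeabilities
## (order AC, AG, AT, CG, CT, GT) + whether base frequencies are free.
.FAMILIES <- list(
  JC   = list(classes = c(1, 1, 1, 1, 1, 1), free_freqs = FALSE),
  K80  = list(classes = c(1, 2, 1, 1, 2, 1), free_freqs = FALSE),
  HKY  = list(classes = c(1, 2, 1, 1, 2, 1), free_freqs = TRUE),
  TrN  = list(classes = c(1, 2, 1, 1, 3, 1), free_freqs = TRUE),
  TPM1 = list(classes = c(1, 2, 3, 3, 2, 1), free_freqs = TRUE),
  TPM2 = list(classes = c(1, 2, 1, 3, 2, 3), free_freqs = TRUE),
  TPM3 = list(classes = c(1, 2, 3, 1, 2, 3), free_freqs = TRUE),
  TIM1 = list(classes = c(1, 2, 3, 3, 4, 1), free_freqs = TRUE),
  TIM2 = list(classes = c(1, 2, 1, 3, 4, 3), free_freqs = TRUE),
  TIM3 = list(classes = c(1, 2, 3, 1, 4, 3), free_freqs = TRUE),
  TVM  = list(classes = c(1, 2, 3, 4, 2, 5), free_freqs = TRUE),
  SYM  = list(classes = c(1, 2, 3, 4, 5, 6), free_freqs = FALSE),
  GTR  = list(classes = c(1, 2, 3, 4, 5, 6), free_freqs = TRUE)
)

.familyDef <- function(family) {
  def <- .FAMILIES[[family]]
  if (is.null(def)) stop("mapping error: unknown model family '", family, "'")
  def
}

#' Recognized substitution-model family names
#' @return character vector of family names, simplest first.
#' @export
modelFamilies <- function() names(.FAMILIES)

#' Free substitution parameters of a model
#'
#' Counts (number of exchangeability classes - 1) + 3 if frequencies are
#' free + 1 if a gamma shape is estimated, the convention under which a
#' single GTR+G partition carries 9 free parameters.
#'
#' @param model a SubstitutionModel, or a family name (then \code{gamma}
#'   says whether +G applies).
#' @param gamma logical, used only when \code{model} is a family name.
#' @return integer parameter count.
#' @export
nFreeParameters <- function(model, gamma = TRUE) {
  if (is(model, "SubstitutionModel")) {
    fam <- .familyDef(model@family)
    gamma <- !is.na(model@gammaShape)
  } else fam <- .familyDef(model)
  as.integer(max(fam$classes)) - 1L + (if (fam$free_freqs) 3L else 0L) +
    (if (gamma) 1L else 0L)
}

#' Build the normalized rate-matrix generator of a model
#'
#' Q with off-diagonals \code{q_ij = r_ij * pi_j}, rows summing to zero,
#' scaled so the expected substitution rate at stationarity,
#' \code{-sum_i pi_i q_ii}, is 1 (branch lengths are then expected
#' substitutions per site). Detailed balance holds by construction.
#'
#' @param model a SubstitutionModel.
#' @return 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
buildRateMatrix <- function(model) {
  r <- model@rates; p <- model@freqs
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  pair <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (k in 1:6) {
    i <- pair[k,1]; j <- pair[k,2]
    if (r[k] > 0 && (p[i] == 0 || p[j] == 0))
      stop("degenerate-model error: nonzero rate into zero-frequency state")
    Q[i,j] <- r[k] * p[j]
    Q[j,i] <- r[k] * p[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  if (mu <= 0) stop("degenerate-model error: zero total substitution rate")
  Q / mu
}

## Eigen-decomposition of a reversible Q via the symmetrizing similarity
## transform: S = D^{1/2} Q D^{-1/2} is symmetric for reversible Q, so the
## decomposition is numerically stable and eigenvalues are real.
.eigenQ <- function(Q, freqs) {
  d <- sqrt(freqs)
  S <- outer(d, 1/d) * Q          # S_ij = d_i Q_ij / d_j
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / d,         # row-scaled:   U = D^{-1/2} V
       Uinv = t(e$vectors) * rep(d, each = 4))  # V' D^{1/2}
}

#' Discrete-gamma category rates
#'
#' Mean rates of \code{k} equal-probability categories of a Gamma(shape,
#' shape) distribution (mean 1), the standard discretization behind
#' "+G".
#'
#' @param shape positive gamma shape.
#' @param k number of categories.
#' @return numeric(k) rates with mean 1.
#' @export
discreteGammaRates <- function(shape, k = 4L) {
  if (is.na(shape)) return(1)
  if (shape <= 0) stop("gamma shape must be positive")
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = shape, rate = shape)
  ## mean within each slice via the incomplete-gamma identity:
  ## E[X; X<q] under Gamma(a, a) = pgamma(q, a+1, a)
  p <- c(0, stats::pgamma(q, shape = shape + 1, rate = shape), 1)
  r <- k * diff(p)
  r / mean(r)
}

#' Transition-probability matrices per gamma category
#'
#' \code{exp(Q * r_c * t)} for each discrete-gamma category rate
#' \code{r_c}; with no gamma shape a single matrix is returned.
#'
#' @param model a SubstitutionModel.
#' @param t branch length (expected substitutions per site), >= 0.
#' @return list of 4x4 stochastic matrices, one per category.
#' @export
transitionProbabilities <- function(model, t) {
  if (t < 0) stop("domain error: negative branch length")
  Q <- buildRateMatrix(model)
  eg <- .eigenQ(Q, model@freqs)
  rates <- discreteGammaRates(model@gammaShape, model@nGammaCat)
  lapply(rates, function(r) {
    P <- eg$U %*% (exp(eg$values * r * t) * eg$Uinv)
    dimnames(P) <- dimnames(Q)
    pmax(P, 0)
  })
}

#' Map a best-fit family onto the nearest over-parameterised usable family
#'
#' Families whose constraint pattern cannot be represented in the
#' downstream sampler (TVM, TIM1, TIM2, TIM3, TPM3 and TrN) are replaced
#' by GTR, the nearest model with at least as many free parameters; all
#' other recognized families map to themselves.
#'
#' @param family a recognized family name.
#' @return the family actually used downstream.
#' @export
mapToAvailable <- function(family) {
  .familyDef(family)  # errors on unknown names
  if (family %in% c("TVM", "TIM1", "TIM2", "TIM3", "TPM3", "TrN")) "GTR"
  else family
}

## Pack/unpack free parameters of a family for optimization.
## theta = (log rates by class except last class fixed at 1,
##          logit-ish freqs via additive log-ratio, log shape).
.packedLength <- function(fam, gamma) {
  (max(fam$classes) - 1L) + (if (fam$free_freqs) 3L else 0L) +
    (if (gamma) 1L else 0L)
}

.unpackModel <- function(theta, family, gamma, nGammaCat = 4L) {
  fam <- .familyDef(family)
  ncl <- max(fam$classes)
  i <- 0L
  clrates <- rep(1, ncl)
  if (ncl > 1L) {
    clrates[seq_len(ncl - 1L)] <- exp(theta[seq_len(ncl - 1L)])
    i <- ncl - 1L
  }
  rates <- clrates[fam$classes]
  if (fam$free_freqs) {
    z <- exp(c(theta[i + 1:3], 0))
    freqs <- z / sum(z)
    i <- i + 3L
  } else freqs <- rep(0.25, 4)
  shape <- if (gamma) exp(theta[i + 1L]) else NA_real_
  new("SubstitutionModel", family = family, rates = rates, freqs = freqs,
      gammaShape = shape, nGammaCat = as.integer(nGammaCat))
}

## Maximize lnL of one family on a fixed tree for one alignment block.
.fitFamily <- function(block, tree, family, gamma = TRUE, nGammaCat = 4L) {
  fam <- .familyDef(family)
  np <- .packedLength(fam, gamma)
  pat <- compressPatterns(block)
  negll <- function(theta) {
    m <- .unpackModel(theta, family, gamma, nGammaCat)
    ll <- tryCatch(.partitionLnL(tree, m, pat[[1]], 1),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  if (np == 0L) {
    return(list(lnL = -negll(numeric(0)), K = 0L,
                model = .unpackModel(numeric(0), family, gamma, nGammaCat)))
  }
  init <- rep(0, np)
  if (gamma) init[np] <- log(0.5)
  fit <- stats::optim(init, negll, method = "L-BFGS-B",
                      lower = rep(-8, np), upper = rep(8, np),
                      control = list(maxit = 500))
  list(lnL = -fit$value, K = np,
       model = .unpackModel(fit$par, family, gamma, nGammaCat))
}

#' JC-distance neighbor-joining guide tree
#'
#' The fixed topology (and branch lengths) on which candidate models are
#' scored, in the jModelTest fixed-topology tradition.
#'
#' @param aln a MitoAlignment with >= 4 taxa.
#' @return an unrooted \code{phylo} with nonnegative branch lengths.
#' @export
guideTree <- function(aln) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- m[i, ] %in% c("A","C","G","T") & m[j, ] %in% c("A","C","G","T")
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    d <- if (p >= 0.749) 3 else -0.75 * log(1 - 4 * p / 3)
    D[i, j] <- D[j, i] <- d
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  ape::unroot(tr)
}

#' AICc model selection for one partition
#'
#' Fits each candidate family (+G) by maximizing the log-likelihood over
#' its free substitution parameters on a fixed guide tree, scores
#' AICc = -2lnL + 2K + 2K(K+1)/(n-K-1) with n the partition's site
#' count, and returns the argmin together with the family actually used
#' downstream (via \code{\link{mapToAvailable}}).
#'
#' @param block MitoAlignment of the partition's sites (>= 4 taxa).
#' @param candidates character vector of family names to score.
#' @param tree fixed guide tree; defaults to \code{guideTree(block)}.
#' @param gamma logical, add a discrete-gamma shape to every candidate.
#' @param nGammaCat gamma category count.
#' @return data.frame with one row per candidate (family, lnL, K, AICc,
#'   mapped) and attributes \code{best} (family), \code{mapped} and
#'   \code{model} (fitted SubstitutionModel of the best family).
#' @export
selectModelAICc <- function(block, candidates = c("JC", "K80", "HKY",
                                                  "TrN", "SYM", "GTR"),
                            tree = NULL, gamma = TRUE, nGammaCat = 4L) {
  if (nrow(alignmentMatrix(block)) < 4L) stop("need >= 4 taxa")
  if (is.null(tree)) tree <- guideTree(block)
  n <- nSites(block)
  rows <- list()
  fits <- list()
  for (f in candidates) {
    K <- .packedLength(.familyDef(f), gamma)
    if (n <= K + 1L) {
      warning("candidate ", f, " skipped: n <= K + 1")
      next
    }
    fit <- .fitFamily(block, tree, f, gamma, nGammaCat)
    aicc <- -2 * fit$lnL + 2 * fit$K + 2 * fit$K * (fit$K + 1) / (n - fit$K - 1)
    rows[[f]] <- data.frame(family = f, lnL = fit$lnL, K = fit$K,
                            AICc = aicc, mapped = mapToAvailable(f),
                            stringsAsFactors = FALSE)
    fits[[f]] <- fit$model
  }
  if (!length(rows)) stop("selection error: every candidate was skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- out$family[which.min(out$AICc)]
  attr(out, "best") <- best
  attr(out, "mapped") <- mapToAvailable(best)
  attr(out, "model") <- fits[[best]]
  out
}

#' Sum of free substitution-model parameters of a partitioned model
#'
#' Per-partition substitution parameters (9 for GTR+G) summed over
#' partitions, plus k - 1 free rate multipliers when there are k > 1
#' partitions. Branch lengths and topology are shared across partitions
#' and not counted.
#'
#' @param scheme a PartitionScheme.
#' @param models a PartitionedModel aligned to it.
#' @return integer.
#' @export
countFreeParameters <- function(scheme, models) {
  k <- length(charsets(scheme))
  stopifnot(k == length(partitionModels(models)))
  sum(vapply(partitionModels(models), nFreeParameters, 1L)) +
    (if (k > 1L) k - 1L else 0L)
}
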