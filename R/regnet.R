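#' Regulator-target co-expression network
#'
#' @slot regulators regulator symbols present in the network.
#' @slot edges data.frame `gene_a`, `gene_b`, `weight` of retained edges.
#' @slot targets named list: network neighbours of each regulator.
#' @slot beta soft-threshold power applied to |Pearson r|.
#' @slot r2 scale-free topology fit index achieved at `beta`.
#' @slot edgeKeep fraction of candidate edges retained.
#' @export
setClass("RegulatorNetwork", representation(
  regulators = "character", edges = "data.frame", targets = "list",
  beta = "numeric", r2 = "numeric", edgeKeep = "numeric"))

setValidity("RegulatorNetwork", function(object) {
  if (object@beta < 1) return("soft power beta must be >= 1")
  TRUE
})

#' @export
setMethod("show", "RegulatorNetwork", function(object) {
  cat("RegulatorNetwork:", length(object@regulators), "regulators,",
      nrow(object@edges), "retained edges",
      sprintf("(beta = %d, scale-free R^2 = %.3f, keep = %.3f)\n",
              object@beta, object@r2, object@edgeKeep))
})

#' Scale-free topology fit index of a degree distribution
#'
#' R-squared of the regression of `log10(frequency)` on `log10(degree)` over
#' equal-width degree bins — the standard index used to pick a co-expression
#' soft-threshold power.
#'
#' @param degrees numeric vector of (weighted) node degrees.
#' @param nBreaks number of degree bins (default 10).
#' @return R-squared in `[0, 1]`; 0 with a warning when all degrees are
#'   equal (the fit is undefined).
#' @export
scaleFreeFit <- function(degrees, nBreaks = 10) {
  degrees <- degrees[degrees > 0]
  if (length(degrees) < 5)
    stop("need >= 5 nodes with positive degree")
  if (diff(range(degrees)) == 0) {
    warning("all degrees equal; scale-free fit undefined, returning 0")
    return(0)
  }
  cuts <- cut(degrees, nBreaks)
  dk <- tapply(degrees, cuts, mean)
  pk <- tapply(degrees, cuts, length) / length(degrees)
  ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(ok) < 2) {
    warning("fewer than 2 occupied degree bins; returning 0")
    return(0)
  }
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Infer an unsigned co-expression regulator-target network
#'
#' Computes pairwise |Pearson r| over genes, picks the smallest integer soft
#' power `beta` in 1..20 whose weighted-degree distribution reaches a
#' scale-free fit of at least `r2Min` (falling back, with a warning, to the
#' power with the best fit), raises the correlations to that power, and
#' retains the top `edgeKeep` fraction of edges network-wide (exactly
#' `ceiling(edgeKeep * nCandidates)` edges; ties broken by gene symbols).
#' Each regulator's target set is its neighbourhood in the retained graph.
#'
#' @param experiment a [MacrophageExperiment-class] or numeric matrix
#'   (genes x samples); typically restricted to differentially expressed
#'   genes plus the regulators.
#' @param regulators character vector of regulator symbols.
#' @param r2Min minimum scale-free fit index (default 0.85).
#' @param edgeKeep fraction of candidate edges to retain (default 0.05).
#' @param betaGrid integer powers to search (default 1:20).
#' @return A [RegulatorNetwork-class].
#' @export
buildCoexpressionNetwork <- function(experiment, regulators, r2Min = 0.85,
                                     edgeKeep = 0.05, betaGrid = 1:20) {
  y <- if (is(experiment, "MacrophageExperiment")) exprMatrix(experiment)
       else experiment
  if (ncol(y) < 4) stop("network inference needs >= 4 samples")
  constant <- apply(y, 1, function(r) var(r) == 0)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant gene rows")
    y <- y[!constant, , drop = FALSE]
  }
  regulators <- intersect(regulators, rownames(y))
  if (length(regulators) < 2)
    stop("need >= 2 regulators present in the expression matrix")
  r <- abs(cor(t(y)))
  diag(r) <- 0

  r2ByBeta <- vapply(betaGrid, function(b)
    suppressWarnings(scaleFreeFit(rowSums(r^b))), numeric(1))
  hit <- which(r2ByBeta >= r2Min)
  if (length(hit)) {
    beta <- betaGrid[hit[1]]
  } else {
    beta <- betaGrid[which.max(r2ByBeta)]
    warning(sprintf(
      "no power reaches scale-free R^2 >= %.2f; using beta = %d (R^2 = %.3f)",
      r2Min, beta, max(r2ByBeta)))
  }
  w <- r^beta

  ut <- which(upper.tri(w), arr.ind = TRUE)
  cand <- data.frame(gene_a = rownames(w)[ut[, 1]],
                     gene_b = colnames(w)[ut[, 2]],
                     weight = w[ut], stringsAsFactors = FALSE)
  nKeep <- ceiling(edgeKeep * nrow(cand))
  cand <- cand[order(-cand$weight, cand$gene_a, cand$gene_b), , drop = FALSE]
  edges <- cand[seq_len(nKeep), , drop = FALSE]
  rownames(edges) <- NULL

  targets <- lapply(regulators, function(rg) {
    sort(unique(c(edges$gene_b[edges$gene_a == rg],
                  edges$gene_a[edges$gene_b == rg])))
  })
  names(targets) <- regulators
  new("RegulatorNetwork", regulators = regulators, edges = edges,
      targets = targets, beta = beta,
      r2 = r2ByBeta[match(beta, betaGrid)], edgeKeep = edgeKeep)
}

#' @describeIn buildCoexpressionNetwork target sets of each regulator
#' @param network a `RegulatorNetwork`
#' @export
regulatorTargets <- function(network) network@targets

# simple Storey-type q-values: pi0 from the p > 0.5 tail, scaled BH
storeyQ <- function(p) {
  pi0 <- min(1, 2 * mean(p > 0.5))
  pi0 <- max(pi0, 1 / length(p))
  pmin(1, pi0 * adjustBH(p))
}

#' Fisher enrichment of regulator targets among responsive genes
#'
#' For each regulator, a one-sided Fisher exact test of the 2x2 table
#' (gene in targets x gene in `deGenes`) over the `universe`; enrichment
#' direction only. Adjusted p is Benjamini-Hochberg across regulators; q is a
#' Storey-type q-value. A regulator is flagged significant when
#' `p_adj < pAdjCut` and `q < qCut`.
#'
#' @param network a [RegulatorNetwork-class].
#' @param deGenes genes considered responsive (differential p < 0.05 in the
#'   default pipeline).
#' @param universe the gene universe the targets live in.
#' @param pAdjCut,qCut significance cutoffs (defaults 0.05 and 0.2).
#' @return data.frame `regulator`, `nTargets`, `overlap`, `p`, `p_adj`,
#'   `q`, `significant`, `empty`.
#' @export
regulatorEnrichment <- function(network, deGenes, universe,
                                pAdjCut = 0.05, qCut = 0.2) {
  deGenes <- intersect(unique(deGenes), universe)
  rows <- lapply(network@regulators, function(rg) {
    tg <- intersect(network@targets[[rg]], universe)
    if (!all(network@targets[[rg]] %in% universe))
      stop("regulator targets outside the universe for ", rg)
    if (length(tg) == 0)
      return(data.frame(regulator = rg, nTargets = 0L, overlap = 0L,
                        p = 1, empty = TRUE, stringsAsFactors = FALSE))
    a <- length(intersect(tg, deGenes))
    b <- length(tg) - a
    c_ <- length(deGenes) - a
    d <- length(universe) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(regulator = rg, nTargets = length(tg), overlap = a, p = p,
               empty = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjustBH(out$p)
  out$q <- storeyQ(out$p)
  out$significant <- out$p_adj < pAdjCut & out$q < qCut & !out$empty
  rownames(out) <- NULL
  out[, c("regulator", "nTargets", "overlap", "p", "p_adj", "q",
          "significant", "empty")]
}

#' Composite regulator importance score
#'
#' Combines a regulator's own differential-expression evidence with the
#' enrichment of its targets among responsive genes:
#' `score = rankNorm(-log10 p_diff) + rankNorm(-log10 p_enrich)`, where each
#' component is rank-normalized to `[0, 1]` across regulators (average ranks
#' on ties), giving a score in `[0, 2]` that is invariant to strictly
#' monotone transformations of either p-vector.
#'
#' @param differentialP named numeric vector of per-regulator differential
#'   p-values in `(0, 1]`.
#' @param enrichmentP named numeric vector (same names) of enrichment
#'   p-values in `(0, 1]`.
#' @return data.frame `regulator`, `diffComponent`, `enrichComponent`,
#'   `score`, sorted by decreasing score.
#' @export
regenrichScore <- function(differentialP, enrichmentP) {
  stopifnot(length(differentialP) == length(enrichmentP),
            !is.null(names(differentialP)),
            identical(sort(names(differentialP)), sort(names(enrichmentP))))
  enrichmentP <- enrichmentP[names(differentialP)]
  clamp <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(what, " p-values must lie in [0, 1]")
    if (any(p == 0)) {
      warning(what, " p-values of 0 clamped to machine minimum")
      p[p == 0] <- .Machine$double.xmin
    }
    p
  }
  dp <- clamp(differentialP, "differential")
  ep <- clamp(enrichmentP, "enrichment")
  rankNorm <- function(x) {
    n <- length(x)
    if (n == 1) return(1)
    (rank(x, ties.method = "average") - 1) / (n - 1)
  }
  dC <- rankNorm(-log10(dp))
  eC <- rankNorm(-log10(ep))
  out <- data.frame(regulator = names(dp), diffComponent = dC,
                    enrichComponent = eC, score = dC + eC,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top regulators by composite score
#'
#' Deterministic top-k extraction used for the expression heatmap (k = 25)
#' and the score bar chart (k = 20); ties are broken by regulator symbol.
#'
#' @param scores a [regenrichScore()] table.
#' @param k number of regulators to keep.
#' @return subset of `scores`, at most `k` rows.
#' @export
topRegulators <- function(scores, k = 25) {
  scores[seq_len(min(k, nrow(scores))), , drop = FALSE]
}

#' Attribute regulators to enriched pathways by shared target genes
#'
#' A regulator earns one point per gene shared between its target set and a
#' pathway's genes in the DEG-pathway adjacency; the `topK` regulators per
#' pathway are reported (ties broken by composite score, then regulator
#' symbol), Sankey-ready.
#'
#' @param network a [RegulatorNetwork-class].
#' @param adjacency the `adjacency` matrix from [degPathwayAdjacency()]
#'   (genes x pathways, 0/1).
#' @param scores optional [regenrichScore()] table used for tie-breaking.
#' @param topK regulators to keep per pathway (default 5).
#' @return data.frame `pathway`, `regulator`, `points`.
#' @export
attributeRegulatorsToPathways <- function(network, adjacency, scores = NULL,
                                          topK = 5) {
  if (length(adjacency) == 0 || nrow(adjacency) == 0)
    stop("DEG-pathway adjacency is empty")
  scoreOf <- function(rg) {
    if (is.null(scores)) return(0)
    s <- scores$score[scores$regulator == rg]
    if (length(s)) s else 0
  }
  rows <- lapply(colnames(adjacency), function(pw) {
    pwGenes <- rownames(adjacency)[adjacency[, pw] == 1]
    pts <- vapply(network@regulators, function(rg)
      length(intersect(network@targets[[rg]], pwGenes)), integer(1))
    pts <- pts[pts > 0]
    if (length(pts) == 0) return(NULL)
    tieScore <- vapply(names(pts), scoreOf, numeric(1))
    o <- order(-pts, -tieScore, names(pts))
    keep <- o[seq_len(min(topK, length(o)))]
    data.frame(pathway = pw, regulator = names(pts)[keep],
               points = unname(pts[keep]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), regulator = character(),
                      points = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter a protein-protein interaction network by confidence
#'
#' Retains edges whose confidence score meets the minimum (inclusive,
#' default 0.900, the "highest confidence" tier of curated PPI databases).
#'
#' @param network an [InteractionNetwork-class] whose edges carry
#'   confidence scores.
#' @param minConf minimum confidence (default 0.900).
#' @return filtered [InteractionNetwork-class].
#' @export
filterPpiEdges <- function(network, minConf = 0.900) {
  e <- edgeTable(network)
  if (nrow(e) && anyNA(e$confidence))
    stop("edges without a confidence score cannot be filtered")
  InteractionNetwork(e[e$confidence >= minConf, , drop = FALSE])
}
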