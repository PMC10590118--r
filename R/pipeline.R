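#' Pipeline configuration with the study's default thresholds
#'
#' Collects every tunable cutoff of the pipeline. The defaults are the
#' analysis settings of the modelled study: DEG selection at FDR < 0.05 and
#' |logFC| > 0.58 (strict); enrichment input genes at FDR < 0.1; chord
#' filter |logFC| > 2.5; regulator network with scale-free R^2 >= 0.85 and
#' the top 5% of edges; regulator enrichment on genes with differential
#' p < 0.05 at adjusted p < 0.05 and q < 0.2; PPI confidence >= 0.900;
#' top-25 regulators for the heatmap, top-20 for the bar chart, top-5 per
#' pathway for the Sankey attribution.
#'
#' @param fdr,lfc DEG selection cutoffs.
#' @param inputFdr FDR cutoff for enrichment input genes.
#' @param chordLfc absolute logFC filter for the chord adjacency.
#' @param deP differential p cutoff feeding regulator enrichment.
#' @param enrichAdjP,enrichQ regulator enrichment significance cutoffs.
#' @param r2Min,edgeKeep co-expression network parameters.
#' @param ppiMinConf PPI confidence filter.
#' @param topKRegulators,topNHeatmap,topNBar top-k extraction sizes.
#' @param reference reference condition for propensity deltas.
#' @param seed RNG seed for the simulate stage.
#' @param simulate config for the simulate stage (a [SimConfig-class]) or
#'   `NULL` to read inputs from files.
#' @return a validated named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(fdr = 0.05, lfc = 0.58, inputFdr = 0.1,
                           chordLfc = 2.5, deP = 0.05,
                           enrichAdjP = 0.05, enrichQ = 0.2,
                           r2Min = 0.85, edgeKeep = 0.05,
                           ppiMinConf = 0.900, topKRegulators = 5,
                           topNHeatmap = 25, topNBar = 20,
                           reference = "uM", seed = 17,
                           simulate = simConfig(seed = seed)) {
  cfg <- list(fdr = fdr, lfc = lfc, inputFdr = inputFdr,
              chordLfc = chordLfc, deP = deP, enrichAdjP = enrichAdjP,
              enrichQ = enrichQ, r2Min = r2Min, edgeKeep = edgeKeep,
              ppiMinConf = ppiMinConf, topKRegulators = topKRegulators,
              topNHeatmap = topNHeatmap, topNBar = topNBar,
              reference = reference, seed = seed, simulate = simulate)
  probs <- c("fdr", "inputFdr", "deP", "enrichAdjP", "enrichQ",
             "edgeKeep", "ppiMinConf")
  for (nm in probs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")
  if (lfc < 0 || chordLfc < 0) stop("logFC cutoffs must be non-negative")
  if (r2Min < 0 || r2Min > 1) stop("r2Min must lie in [0, 1]")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

configHash <- function(cfg) {
  flat <- cfg[!vapply(cfg, isS4, logical(1))]
  s <- paste(names(flat), vapply(flat, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  if (isS4(cfg$simulate))
    s <- paste(s, paste(vapply(slotNames(cfg$simulate), function(sl)
      paste(format(slot(cfg$simulate, sl), digits = 15), collapse = ","),
      character(1)), collapse = ";"), sep = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load), differential expression on all
#' four design contrasts, matched-background enrichment with theme
#' comparison and chord adjacency, regulator network inference with
#' composite scoring and pathway attribution, and the cell-cell interaction
#' propensity model with reference deltas and driver decomposition. All
#' stage outputs are written as TSV under `outdir` together with a
#' `manifest.tsv` (stage status, seed, config hash, coverage).
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @param inputs optional named list of paths (`expression`, `samples`,
#'   `annotations`, `genesets`, `edges`, `cell_profiles`) used when
#'   `config$simulate` is `NULL`.
#' @return invisible list of all in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, inputs = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  stages <- character()
  msg <- function(...) message("[quiescentome] ", ...)

  # --- stage: simulate or load ------------------------------------------
  if (!is.null(config$simulate)) {
    msg("simulate: seed = ", config$simulate@seed)
    sim <- simulateAll(config$simulate)
    writeSimulation(sim, p("input"))
    stages <- c(stages, "simulate")
  } else {
    need <- c("expression", "samples", "annotations", "genesets", "edges",
              "cell_profiles")
    if (!all(need %in% names(inputs)))
      stop("missing inputs for stage 'load': ",
           paste(setdiff(need, names(inputs)), collapse = ", "))
    sim <- list(
      experiment = readExpression(inputs$expression, inputs$samples),
      annotations = readAnnotations(inputs$annotations),
      geneSets = readGMT(inputs$genesets),
      network = readEdges(inputs$edges),
      cellProfiles = readCellProfiles(inputs$cell_profiles))
    stages <- c(stages, "load")
  }
  exp <- sim$experiment

  # --- stage: differential expression -----------------------------------
  msg("de: FDR < ", config$fdr, ", |logFC| > ", config$lfc,
      " (strict), donor blocking on")
  results <- runDifferentialExpression(exp)
  degs <- lapply(results, selectDEG, fdrCut = config$fdr,
                 lfcCut = config$lfc)
  for (nm in names(results)) {
    writeTsv(results[[nm]], p(paste0("de_", nm, ".tsv")))
    writeTsv(degs[[nm]], p(paste0("deg_", nm, ".tsv")))
  }
  stages <- c(stages, "de")

  # --- stage: enrichment -------------------------------------------------
  msg("enrich: input FDR < ", config$inputFdr, ", chord |logFC| > ",
      config$chordLfc)
  enr <- list(); themeEnr <- list(); themeDeg <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    inputGenes <- res$gene[res$fdr < config$inputFdr]
    if (length(inputGenes)) {
      bg <- matchedBackground(inputGenes, exp)
      enr[[nm]] <- oraHypergeometric(inputGenes, bg, sim$geneSets)
    } else {
      enr[[nm]] <- oraHypergeometric(character(), rownames(exp),
                                     sim$geneSets)[0, ]
    }
    writeTsv(enr[[nm]], p(paste0("enrichment_", nm, ".tsv")))
    deg <- degs[[nm]]
    if (nrow(deg)) {
      bg <- matchedBackground(deg$gene, exp)
      themeEnr[[nm]] <- oraHypergeometric(deg$gene, bg, sim$geneSets)
    } else themeEnr[[nm]] <- enr[[nm]][0, ]
    themeDeg[[nm]] <- deg
  }
  theme <- themeCompare(themeEnr, themeDeg, sim$geneSets, sigCut = 0.1)
  writeTsv(theme, p("theme_comparison.tsv"))
  primary <- "hlf_vs_uM"
  enrichedSets <- enr[[primary]]$set[enr[[primary]]$p_adj < 0.05]
  chord <- degPathwayAdjacency(degs[[primary]], enrichedSets, sim$geneSets,
                               lfcFilter = config$chordLfc)
  writeTsv(chord$edges, p("chord_edges.tsv"))
  stages <- c(stages, "enrich")

  # --- stage: regulator network -----------------------------------------
  msg("regnet: R^2 >= ", config$r2Min, ", keep ", config$edgeKeep,
      " of edges, regulator p < ", config$deP)
  regulators <- sim$annotations$gene[sim$annotations$class == "regulator"]
  res <- results[[primary]]
  deUnion <- unique(unlist(lapply(degs, function(d) d$gene)))
  netGenes <- union(deUnion, regulators)
  net <- buildCoexpressionNetwork(
    exprMatrix(exp)[intersect(rownames(exp), netGenes), , drop = FALSE],
    regulators, r2Min = config$r2Min, edgeKeep = config$edgeKeep)
  responsive <- res$gene[res$p < config$deP]
  fisher <- regulatorEnrichment(net, responsive, rownames(exp),
                                pAdjCut = config$enrichAdjP,
                                qCut = config$enrichQ)
  diffP <- setNames(res$p[match(fisher$regulator, res$gene)],
                    fisher$regulator)
  diffP[is.na(diffP)] <- 1
  scores <- regenrichScore(diffP, setNames(fisher$p, fisher$regulator))
  writeTsv(fisher, p("regulator_enrichment.tsv"))
  writeTsv(scores, p("regulator_scores.tsv"))
  writeTsv(topRegulators(scores, config$topNBar),
           p("regulator_top_bar.tsv"))
  writeTsv(topRegulators(scores, config$topNHeatmap),
           p("regulator_top_heatmap.tsv"))
  sankey <- if (nrow(chord$adjacency))
    attributeRegulatorsToPathways(net, chord$adjacency, scores,
                                  topK = config$topKRegulators)
  else data.frame(pathway = character(), regulator = character(),
                  points = integer())
  writeTsv(sankey, p("regulator_pathway_sankey.tsv"))
  ppi <- filterPpiEdges(sim$network, config$ppiMinConf)
  writeEdges(ppi, p("ppi_high_confidence.tsv"))
  stages <- c(stages, "regnet")

  # --- stage: interactome ------------------------------------------------
  msg("interactome: reference = ", config$reference,
      ", PPI confidence >= ", config$ppiMinConf)
  macroZ <- standardizeExpression(conditionMeans(exp))
  cellZ <- standardizeExpression(sim$cellProfiles)
  prop <- do.call(rbind, lapply(c("physical", "soluble"), function(ch)
    relativeToReference(interactionPropensity(macroZ, cellZ, sim$network,
                                              ch), config$reference)))
  writeTsv(prop, p("propensity.tsv"))
  coverage <- do.call(rbind, lapply(c("physical", "soluble"), function(ch)
    attr(interactionPropensity(macroZ, cellZ, sim$network, ch),
         "coverage")))
  writeTsv(coverage, p("coverage.tsv"))
  drivers <- do.call(rbind, lapply(c("physical", "soluble"), function(ch) {
    d <- interactionDrivers(macroZ, "hlf_LPS", "uM_LPS", cellZ,
                            sim$network, ch,
                            meanExpr = conditionMeans(exp))
    if (nrow(d)) d$channel <- ch else d$channel <- character(0)
    d
  }))
  writeTsv(drivers, p("drivers.tsv"))
  stages <- c(stages, "interactome")

  manifest <- data.frame(
    key = c("stages", "seed", "config_hash", "package_version"),
    value = c(paste(stages, collapse = ","), config$seed,
              configHash(config),
              as.character(utils::packageVersion("quiescentome"))))
  writeTsv(manifest, p("manifest.tsv"))

  invisible(list(experiment = exp, results = results, degs = degs,
                 enrichment = enr, theme = theme, chord = chord,
                 network = net, fisher = fisher, scores = scores,
                 sankey = sankey, propensity = prop, drivers = drivers,
                 coverage = coverage, stages = stages,
                 truth = sim$truth, planted = sim$planted))
}
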