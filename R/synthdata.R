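#' Simulation configuration for the paired 2x2 macrophage design
#'
#' Holds every knob of the synthetic-data generator. The defaults encode the
#' study design the pipeline targets: 4 donors, four conditions (`uM`,
#' `uM_LPS`, `hlf`, `hlf_LPS`) with a shared donor effect (paired design) and
#' condition means that are *identical by construction* for `hlf` and
#' `hlf_LPS`, so the hlf_LPS-vs-hlf contrast is a planted global null.
#'
#' @slot nGenes number of genes.
#' @slot nDonors number of donors (default 4).
#' @slot nDeHlf genes with a planted lactoferrin effect (hlf and hlf_LPS).
#' @slot nDeLps genes with a planted LPS effect in untreated macrophages.
#' @slot effectSizeRange absolute log2-fold-change interval for planted
#'   effects; the lower bound must exceed 0.58 so planted genes are
#'   detectable at the default selection cutoff.
#' @slot donorSd standard deviation of the additive per-gene, per-donor
#'   random effect (log2 units), shared across a donor's four conditions.
#' @slot noiseSd residual standard deviation (log2 units).
#' @slot moduleSd loading of the shared per-module, per-sample latent
#'   factor that induces positively correlated co-expression modules
#'   (log2 units; 0 disables module structure).
#' @slot moduleSize number of genes per co-expression module.
#' @slot baselineMeanRange interval for gene baseline log2 intensity.
#' @slot classFractions named fractions of genes per annotation class
#'   (`cytokine`, `membrane`, `regulator`, `innate`); classes may overlap.
#' @slot nSets,setSizeRange,nPlantedSets,plantedOverlap gene-set generator:
#'   number of sets, set size interval, number of sets enriched for planted
#'   DEG, and the fraction of a planted set drawn from true DEG.
#' @slot nReceptors,nPhysicalEdges,nSolubleEdges,nCellTypes interaction
#'   generator sizes.
#' @slot plantedEdges number of soluble edges planted to shift interaction
#'   propensity towards `plantedCellType` between `plantedConditions`.
#' @slot plantedCellType,plantedConditions target of the planted shift.
#' @slot seed integer RNG seed recorded in all outputs.
#' @export
setClass("SimConfig", representation(
  nGenes = "numeric", nDonors = "numeric",
  nDeHlf = "numeric", nDeLps = "numeric",
  effectSizeRange = "numeric", donorSd = "numeric", noiseSd = "numeric",
  moduleSd = "numeric", moduleSize = "numeric",
  baselineMeanRange = "numeric", classFractions = "numeric",
  nSets = "numeric", setSizeRange = "numeric",
  nPlantedSets = "numeric", plantedOverlap = "numeric",
  nReceptors = "numeric", nPhysicalEdges = "numeric",
  nSolubleEdges = "numeric", nCellTypes = "numeric",
  plantedEdges = "numeric", plantedCellType = "character",
  plantedConditions = "character", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(nGenes = object@nGenes, nDonors = object@nDonors,
              nDeHlf = object@nDeHlf, nDeLps = object@nDeLps,
              nSets = object@nSets, nCellTypes = object@nCellTypes)
  if (any(counts <= 0))
    msg <- c(msg, paste("counts must be positive:",
                        paste(names(counts)[counts <= 0], collapse = ", ")))
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@donorSd < 0) msg <- c(msg, "donorSd must be >= 0")
  if (object@moduleSd < 0) msg <- c(msg, "moduleSd must be >= 0")
  if (object@moduleSize < 1) msg <- c(msg, "moduleSize must be >= 1")
  if (object@effectSizeRange[1] <= 0.58)
    msg <- c(msg, "planted |effect| must exceed 0.58 to be detectable")
  if (diff(object@effectSizeRange) < 0 || diff(object@baselineMeanRange) < 0)
    msg <- c(msg, "ranges must be increasing intervals")
  if (any(object@classFractions < 0) || any(object@classFractions > 1))
    msg <- c(msg, "class fractions must lie in [0, 1]")
  if (object@plantedOverlap < 0 || object@plantedOverlap > 1)
    msg <- c(msg, "plantedOverlap must lie in [0, 1]")
  if (object@setSizeRange[2] > object@nGenes)
    msg <- c(msg, "set sizes cannot exceed the gene universe")
  if (object@nDeHlf + object@nDeLps > object@nGenes)
    msg <- c(msg, "planted DE genes cannot exceed the gene universe")
  if (length(msg)) msg else TRUE
})

#' The four condition labels of the modelled design
#' @return character vector `c("uM", "uM_LPS", "hlf", "hlf_LPS")`.
#' @export
designConditions <- function() c("uM", "uM_LPS", "hlf", "hlf_LPS")

#' The four condition contrasts analysed by the pipeline
#' @return named list of `c(numerator, denominator)` condition pairs.
#' @export
designContrasts <- function() list(
  hlf_vs_uM          = c("hlf", "uM"),
  uM_LPS_vs_uM       = c("uM_LPS", "uM"),
  hlf_LPS_vs_uM_LPS  = c("hlf_LPS", "uM_LPS"),
  hlf_LPS_vs_hlf     = c("hlf_LPS", "hlf"))

#' Construct a SimConfig
#'
#' @param nGenes,nDonors design size (defaults 2000 genes, 4 donors).
#' @param nDeHlf,nDeLps planted DE genes per planted contrast.
#' @param effectSizeRange,donorSd,noiseSd,baselineMeanRange generative model
#'   parameters on the log2 scale.
#' @param classFractions named annotation class fractions.
#' @param nSets,setSizeRange,nPlantedSets,plantedOverlap gene-set generator.
#' @param nReceptors,nPhysicalEdges,nSolubleEdges,nCellTypes,plantedEdges,
#'   plantedCellType,plantedConditions interaction generator.
#' @param seed integer RNG seed (default 17).
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nGenes = 2000, nDonors = 4,
                      nDeHlf = max(1, round(0.04 * nGenes)),
                      nDeLps = max(1, round(0.06 * nGenes)),
                      effectSizeRange = c(1, 3),
                      donorSd = 0.5, noiseSd = 0.2,
                      moduleSd = 0.35, moduleSize = 50,
                      baselineMeanRange = c(4, 12),
                      classFractions = c(cytokine = 0.10, membrane = 0.15,
                                         regulator = 0.10, innate = 0.15),
                      nSets = 50,
                      setSizeRange = c(min(10, max(2, nGenes %/% 10)),
                                       min(60, max(3, nGenes %/% 4))),
                      nPlantedSets = 3, plantedOverlap = 0.8,
                      nReceptors = 40, nPhysicalEdges = 150,
                      nSolubleEdges = 80, nCellTypes = 6,
                      plantedEdges = 8, plantedCellType = "Neutrophil",
                      plantedConditions = c("hlf", "uM"),
                      seed = 17) {
  new("SimConfig", nGenes = nGenes, nDonors = nDonors, nDeHlf = nDeHlf,
      nDeLps = nDeLps, effectSizeRange = effectSizeRange, donorSd = donorSd,
      noiseSd = noiseSd, moduleSd = moduleSd, moduleSize = moduleSize,
      baselineMeanRange = baselineMeanRange,
      classFractions = classFractions, nSets = nSets,
      setSizeRange = setSizeRange, nPlantedSets = nPlantedSets,
      plantedOverlap = plantedOverlap, nReceptors = nReceptors,
      nPhysicalEdges = nPhysicalEdges, nSolubleEdges = nSolubleEdges,
      nCellTypes = nCellTypes, plantedEdges = plantedEdges,
      plantedCellType = plantedCellType,
      plantedConditions = plantedConditions, seed = seed)
}

simGeneNames <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a paired 2x2 expression experiment with planted ground truth
#'
#' Entry model on the log2 scale:
#' `y[g, d, c] = baseline[g] + donorEffect[g, d] + conditionEffect[g, c] +
#' moduleSd * w[module(g), s] + eps` with `eps ~ N(0, noiseSd)` and
#' `donorEffect ~ N(0, donorSd)` shared across the four conditions of a
#' donor (paired design). The per-module, per-sample factor `w ~ N(0, 1)`
#' gives genes of a module positively correlated profiles, the
#' co-expression structure real transcriptomes show (and the network stage
#' exploits); each gene's marginal distribution is unchanged in form.
#' Condition effects are identical for `hlf` and `hlf_LPS`, making
#' hlf_LPS-vs-hlf an exact null.
#'
#' @param config a [SimConfig-class].
#' @return list with `experiment` (a [MacrophageExperiment-class]) and
#'   `truth` (data.frame `gene`, `contrast`, `true_logFC`, `is_de`; one row
#'   per gene and contrast).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 200, seed = 1))
#' dim(exprMatrix(sim$experiment))  # 200 x 16
#' @export
simulateExpression <- function(config) {
  validObject(config)
  set.seed(config@seed)
  conds <- designConditions()
  genes <- simGeneNames(config@nGenes)
  donors <- paste0("D", seq_len(config@nDonors))

  deHlf <- sample(genes, config@nDeHlf)
  deLps <- sample(setdiff(genes, deHlf), config@nDeLps)
  drawEffect <- function(n)
    runif(n, config@effectSizeRange[1], config@effectSizeRange[2]) *
      sample(c(-1, 1), n, replace = TRUE)

  eff <- matrix(0, config@nGenes, 4, dimnames = list(genes, conds))
  ehlf <- drawEffect(config@nDeHlf)
  eff[deHlf, "hlf"] <- ehlf
  eff[deHlf, "hlf_LPS"] <- ehlf     # identical by construction
  eff[deLps, "uM_LPS"] <- drawEffect(config@nDeLps)

  baseline <- runif(config@nGenes, config@baselineMeanRange[1],
                    config@baselineMeanRange[2])
  donorEff <- matrix(rnorm(config@nGenes * config@nDonors, 0, config@donorSd),
                     config@nGenes, config@nDonors,
                     dimnames = list(genes, donors))

  samples <- as.vector(outer(conds, donors, paste, sep = "."))
  condOf <- rep(conds, times = config@nDonors)
  donorOf <- rep(donors, each = 4)
  y <- matrix(0, config@nGenes, length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples))
    y[, j] <- baseline + donorEff[, donorOf[j]] + eff[, condOf[j]]
  if (config@moduleSd > 0) {
    nMod <- max(1, config@nGenes %/% config@moduleSize)
    module <- rep(seq_len(nMod), length.out = config@nGenes)
    w <- matrix(rnorm(nMod * length(samples)), nMod, length(samples))
    y <- y + config@moduleSd * w[module, , drop = FALSE]
  }
  y <- y + matrix(rnorm(length(y), 0, config@noiseSd), nrow(y), ncol(y))

  truth <- do.call(rbind, lapply(names(designContrasts()), function(lbl) {
    pair <- designContrasts()[[lbl]]
    lfc <- eff[, pair[1]] - eff[, pair[2]]
    data.frame(gene = genes, contrast = lbl, true_logFC = unname(lfc),
               is_de = lfc != 0, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  list(experiment = MacrophageExperiment(y, condition = condOf,
                                         donor = donorOf),
       truth = truth)
}

#' Simulate annotation classes over the gene universe
#'
#' Assigns each class (`cytokine`, `membrane`, `regulator`, `innate`) to an
#' exact fraction of genes, drawn independently per class so a gene may carry
#' several classes, mirroring real immune annotation registries.
#'
#' @param config a [SimConfig-class].
#' @param experiment the simulated [MacrophageExperiment-class].
#' @return data.frame with columns `gene`, `class`; (gene, class) unique.
#' @export
simulateAnnotations <- function(config, experiment) {
  validObject(config)
  set.seed(config@seed + 1L)
  genes <- rownames(experiment)
  out <- do.call(rbind, lapply(names(config@classFractions), function(cl) {
    k <- round(config@classFractions[[cl]] * length(genes))
    if (k == 0) return(NULL)
    data.frame(gene = sort(sample(genes, k)), class = cl,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate gene-set collections with planted enrichment
#'
#' The first `nPlantedSets` sets draw a `plantedOverlap` fraction of their
#' members from the true DEG of `contrast`; the remaining sets are uniform
#' draws from the gene universe, so their downstream enrichment p-values are
#' approximately uniform.
#'
#' @param config a [SimConfig-class].
#' @param truth truth table from [simulateExpression()].
#' @param contrast contrast label whose planted DEG seed the planted sets.
#' @return A [GeneSetCollection-class]; planted sets are named
#'   `PLANTED_<i>`, background sets `RANDSET_<i>`.
#' @export
simulateGeneSets <- function(config, truth, contrast = "hlf_vs_uM") {
  validObject(config)
  set.seed(config@seed + 2L)
  genes <- unique(truth$gene)
  de <- truth$gene[truth$contrast == contrast & truth$is_de]
  if (config@setSizeRange[2] > length(genes))
    stop("set size range exceeds the gene universe")
  sets <- list()
  for (i in seq_len(config@nPlantedSets)) {
    sz <- sample(seq(config@setSizeRange[1], config@setSizeRange[2]), 1)
    kDe <- min(round(config@plantedOverlap * sz), length(de))
    sets[[paste0("PLANTED_", i)]] <-
      c(sample(de, kDe), sample(setdiff(genes, de), sz - kDe))
  }
  for (i in seq_len(config@nSets - config@nPlantedSets)) {
    sz <- sample(seq(config@setSizeRange[1], config@setSizeRange[2]), 1)
    sets[[paste0("RANDSET_", i)]] <- sample(genes, sz)
  }
  GeneSetCollection(sets)
}

#' Simulate interaction networks and partner-cell expression profiles
#'
#' Physical edges connect membrane-class genes of the macrophage universe;
#' soluble edges run cytokine -> receptor with the cytokine in the macrophage
#' universe and the receptor among dedicated receptor symbols carried by the
#' partner-cell profile matrix. `plantedEdges` soluble edges are constructed
#' to shift the soluble interaction propensity towards `plantedCellType`
#' between the two `plantedConditions`: their cytokines are genes with a
#' positive planted lactoferrin effect and their receptors are expressed
#' exclusively by the target cell type, which makes the expected per-edge
#' contribution after per-gene standardization a closed form (see the
#' methods vignette).
#'
#' @param config a [SimConfig-class].
#' @param truth truth table from [simulateExpression()].
#' @param annotations annotation table from [simulateAnnotations()].
#' @return list with `network` ([InteractionNetwork-class]), `cellProfiles`
#'   (matrix genes x cell types), and `planted` (data.frame of the planted
#'   soluble edges).
#' @export
simulateInteractions <- function(config, truth, annotations) {
  validObject(config)
  set.seed(config@seed + 3L)
  genes <- unique(truth$gene)
  membrane <- annotations$gene[annotations$class == "membrane"]
  cytokine <- annotations$gene[annotations$class == "cytokine"]
  if (length(membrane) < 2) stop("need >= 2 membrane-class genes")
  receptors <- sprintf("RCPT%03d", seq_len(config@nReceptors))
  cellTypes <- c("Tcell", "Bcell", "NK", "Monocyte", "DC", "Neutrophil",
                 "Basophil", "Plasmablast")[seq_len(config@nCellTypes)]

  phys <- unique(t(replicate(config@nPhysicalEdges,
                             sort(sample(membrane, 2)))))
  physDf <- data.frame(gene_a = phys[, 1], gene_b = phys[, 2],
                       channel = "physical", directed = FALSE,
                       confidence = round(runif(nrow(phys), 0.4, 1), 3),
                       stringsAsFactors = FALSE)

  sol <- data.frame(
    gene_a = sample(cytokine, config@nSolubleEdges, replace = TRUE),
    gene_b = sample(receptors, config@nSolubleEdges, replace = TRUE),
    channel = "soluble", directed = TRUE,
    confidence = round(runif(config@nSolubleEdges, 0.4, 1), 3),
    stringsAsFactors = FALSE)
  sol <- sol[!duplicated(sol[, 1:2]), ]

  # planted soluble edges: positive-effect genes of the planted contrast,
  # one dedicated receptor each, expressed only by the target cell type
  lbl <- paste0(config@plantedConditions[1], "_vs_",
                config@plantedConditions[2])
  if (!lbl %in% truth$contrast)
    lbl <- names(which(vapply(designContrasts(), function(p)
      all(p == config@plantedConditions), logical(1))))[1]
  pool <- truth$gene[truth$contrast == lbl & truth$true_logFC > 0]
  k <- min(config@plantedEdges, length(pool))
  planted <- data.frame(gene_a = character(), gene_b = character(),
                        cell_type = character(), stringsAsFactors = FALSE)
  if (k > 0) {
    pg <- sample(pool, k)
    pr <- sprintf("PRCPT%03d", seq_len(k))
    planted <- data.frame(gene_a = pg, gene_b = pr,
                          cell_type = config@plantedCellType,
                          stringsAsFactors = FALSE)
    sol <- rbind(sol, data.frame(gene_a = pg, gene_b = pr,
                                 channel = "soluble", directed = TRUE,
                                 confidence = 0.95,
                                 stringsAsFactors = FALSE))
  }

  allEdges <- rbind(physDf, sol)
  bad <- !(allEdges$gene_a %in% c(genes, receptors, planted$gene_b)) |
         !(allEdges$gene_b %in% c(genes, receptors, planted$gene_b))
  if (any(bad)) stop("edge references a gene absent from both universes")

  profGenes <- c(membrane, receptors, planted$gene_b)
  prof <- matrix(round(runif(length(profGenes) * length(cellTypes), 2, 10), 3),
                 length(profGenes), length(cellTypes),
                 dimnames = list(profGenes, cellTypes))
  if (nrow(planted)) {
    prof[planted$gene_b, ] <- 0
    prof[cbind(planted$gene_b,
               rep(config@plantedCellType, nrow(planted)))] <- 8
  }

  list(network = InteractionNetwork(allEdges), cellProfiles = prof,
       planted = planted)
}

#' Run the full synthetic-data generator
#'
#' @param config a [SimConfig-class].
#' @return list with `experiment`, `truth`, `annotations`, `geneSets`,
#'   `network`, `cellProfiles`, `planted`, and `config`.
#' @export
simulateAll <- function(config = simConfig()) {
  sim <- simulateExpression(config)
  ann <- simulateAnnotations(config, sim$experiment)
  gs <- simulateGeneSets(config, sim$truth)
  inter <- simulateInteractions(config, sim$truth, ann)
  c(sim, list(annotations = ann, geneSets = gs, network = inter$network,
              cellProfiles = inter$cellProfiles, planted = inter$planted,
              config = config))
}

#' Simulate an expression matrix with a planted hub-regulator module
#'
#' Generates a two-group expression matrix in which one regulator (the hub)
#' drives a module of target genes (`target = hub + noise`), and the hub and
#' its targets additionally carry a group effect so the hub is both
#' co-expression-connected to, and differentially expressed with, its
#' targets. Decoy regulators and background genes are independent noise.
#' Used to verify hub recovery by the network and composite-score stages.
#'
#' @param nRegulators total regulators (hub + decoys).
#' @param nTargets module size.
#' @param nNoise independent background genes.
#' @param nSamples total samples (two equal groups).
#' @param moduleSd residual noise of targets around the hub profile.
#' @param groupEffect group mean shift of hub and targets (log2 units).
#' @param seed RNG seed.
#' @return list with `matrix` (genes x samples), `group` (labels), `hub`,
#'   and `regulators`.
#' @export
simulateRegulatorModule <- function(nRegulators = 8, nTargets = 15,
                                    nNoise = 60, nSamples = 16,
                                    moduleSd = 0.3, groupEffect = 1.5,
                                    seed = 17) {
  set.seed(seed)
  stopifnot(nSamples %% 2 == 0, nRegulators >= 2)
  grp <- rep(c("A", "B"), each = nSamples / 2)
  shift <- ifelse(grp == "B", groupEffect, 0)
  hubProfile <- rnorm(nSamples) + shift
  regs <- sprintf("REG%02d", seq_len(nRegulators))
  hub <- regs[1]
  m <- rbind(
    matrix(hubProfile, 1, nSamples),
    matrix(rnorm((nRegulators - 1) * nSamples), nRegulators - 1, nSamples),
    t(vapply(seq_len(nTargets), function(i)
      hubProfile + rnorm(nSamples, 0, moduleSd), numeric(nSamples))),
    matrix(rnorm(nNoise * nSamples), nNoise, nSamples))
  rownames(m) <- c(regs, sprintf("TGT%03d", seq_len(nTargets)),
                   sprintf("BKG%03d", seq_len(nNoise)))
  colnames(m) <- sprintf("S%02d", seq_len(nSamples))
  list(matrix = m, group = grp, hub = hub, regulators = regs)
}
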