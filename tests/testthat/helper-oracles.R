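# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route (enumeration, closed form, or a reference
# package) and is kept deliberately naive.

# BH step-up by direct definition: adj_(i) = min_{j >= i} p_(j) * n / j
bhBrute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# upper-tail hypergeometric P(X >= k) by direct pmf summation
oraBrute <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) dhyper(i, K, N - K, n), numeric(1)))
}

# one-sided (enrichment) Fisher p by enumeration of all tables with the
# observed margins: P(A >= a)
fisherBrute <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  pOf <- function(x) choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1)
  sum(vapply(a:hi, pOf, numeric(1)))
}

# propensity by brute-force double loop over edges and matrix entries
propensityBrute <- function(macroZ, cellZ, edges, channel) {
  conds <- colnames(macroZ); cells <- colnames(cellZ)
  out <- matrix(0, length(conds), length(cells),
                dimnames = list(conds, cells))
  e <- edges[edges$channel == channel, , drop = FALSE]
  for (ci in conds) for (t in cells) {
    s <- 0
    for (i in seq_len(nrow(e))) {
      a <- e$gene_a[i]; b <- e$gene_b[i]
      if (a %in% rownames(macroZ) && b %in% rownames(cellZ))
        s <- s + macroZ[a, ci] * cellZ[b, t]
      if (channel == "physical" &&
          b %in% rownames(macroZ) && a %in% rownames(cellZ))
        s <- s + macroZ[b, ci] * cellZ[a, t]
    }
    out[ci, t] <- s
  }
  out
}

# random small toy instance for the propensity suites
randomPropensityToy <- function(seed) {
  set.seed(seed)
  nm <- sample(3:6, 1); nc <- sample(2:4, 1)
  npc <- sample(3:6, 1); nt <- sample(2:5, 1)
  macroGenes <- paste0("M", seq_len(nm))
  cellGenes <- paste0("C", seq_len(npc))
  macroZ <- matrix(rnorm(nm * nc), nm, nc,
                   dimnames = list(macroGenes, paste0("cond", seq_len(nc))))
  cellZ <- matrix(rnorm(npc * nt), npc, nt,
                  dimnames = list(cellGenes, paste0("cell", seq_len(nt))))
  ne <- sample(2:8, 1)
  # some edges deliberately reference unknown genes to exercise skipping
  edges <- data.frame(
    gene_a = sample(c(macroGenes, "ABSENT_A"), ne, replace = TRUE),
    gene_b = sample(c(cellGenes, "ABSENT_B"), ne, replace = TRUE),
    channel = sample(c("physical", "soluble"), ne, replace = TRUE),
    stringsAsFactors = FALSE)
  edges$directed <- edges$channel == "soluble"
  edges$confidence <- NA_real_
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  list(macroZ = macroZ, cellZ = cellZ, edges = edges)
}

# small paired-design experiment for unit tests
toyExperiment <- function(nGenes = 50, seed = 1, ...) {
  simulateExpression(simConfig(
    nGenes = nGenes,
    nDeHlf = max(1, nGenes %/% 10), nDeLps = max(1, nGenes %/% 10),
    nSets = 5, setSizeRange = c(2, max(3, nGenes %/% 3)),
    seed = seed, ...))
}

# hand-built RegulatorNetwork with explicit target sets
makeNetwork <- function(targets, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  new("RegulatorNetwork", regulators = names(targets), edges = edges,
      targets = targets, beta = 1, r2 = 1, edgeKeep = 1)
}
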