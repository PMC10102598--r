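# Shared fixtures, memoized so expensive simulations are built once per
# test run. All fixture seeds are fixed literals.

fixtureEnv <- new.env(parent = emptyenv())

withFixture <- function(name, builder) {
  if (!exists(name, envir = fixtureEnv))
    assign(name, builder(), envir = fixtureEnv)
  get(name, envir = fixtureEnv)
}

# hand-built genome: n equal-length genes on one replicon, head-to-tail
# with fixed gaps, so central-region arithmetic is easy to do by hand
toyGenome <- function(n, len = 1000, gap = 200, gc = rep(0.5, n),
                      nonrep = rep(len, n), replicon = "chr") {
  begin <- gap + (seq_len(n) - 1) * (len + gap) + 1
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), replicon = replicon,
    begin = as.integer(begin), end = as.integer(begin + len - 1),
    strand = rep(c("+", "-"), length.out = n), gc = gc,
    nonrepetitive_nt = as.integer(nonrep),
    desc = "toy", stringsAsFactors = FALSE)
  reps <- data.frame(replicon = replicon,
                     length = as.integer(max(genes$end) + gap),
                     is_main = TRUE, stringsAsFactors = FALSE)
  new("GenomeModel", replicons = reps, genes = genes)
}

# pool from explicit positions; gene assignments computed from the genome
toyPool <- function(genome, replicon, pos, n_reads = rep(1L, length(pos))) {
  strains <- data.frame(
    barcode = sprintf("BC%06d", seq_along(pos)), replicon = replicon,
    strand = "+", pos = as.integer(pos), n_reads = as.integer(n_reads),
    gene_id = NA_character_, gene_fraction = NA_real_,
    stringsAsFactors = FALSE)
  mapStrainsToGenes(new("InsertionPool", strains = strains), genome)
}

# GeneFitnessMatrix straight from f and t matrices
makeGfm <- function(f, t) {
  if (is.null(rownames(f))) rownames(f) <- sprintf("g%03d", seq_len(nrow(f)))
  if (is.null(colnames(f))) colnames(f) <- sprintf("e%03d", seq_len(ncol(f)))
  dimnames(t) <- dimnames(f)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fitness = f, t = t))
  new("GeneFitnessMatrix", se)
}

# generic small end-to-end simulation
smallSim <- function() withFixture("smallSim", function() {
  sim <- simulateGenome(200, essentialFraction = 0.12, seed = 101)
  conds <- c("condA", "condB", "condC")
  planted <- geneTable(sim$genome)$gene_id[c(2, 5, 9, 14, 30, 77)]
  truth <- plantEffects(sim$truth, conds,
    effects = data.frame(gene_id = rep(planted, each = 1),
                         condition = "condA",
                         f = c(-3, -2, -1, -0.5, 0.5, 1)),
    seed = 102)
  pool <- simulatePool(sim$genome, truth, 5000, seed = 103)
  design <- makeExperimentDesign(conds, nTime0 = 3)
  counts <- simulateCounts(pool, truth, design, depth = 5e5, seed = 104)
  cfg <- analysisConfig(windowSize = 51)
  list(genome = sim$genome, truth = truth, pool = pool, design = design,
       counts = counts, cfg = cfg, planted = planted)
})

smallFitness <- function() withFixture("smallFitness", function() {
  s <- smallSim()
  runFitnessAnalysis(s$counts, s$pool, s$genome, s$design, s$cfg)
})

# study-scale fixture: genome and insertion-library size matching the
# modeled system (3,400 genes, ~79,700 barcoded strains), 21 Time0
# samples for null comparisons plus one neutral condition, depth 1e6
studyFixture <- function() withFixture("studyFixture", function() {
  sim <- simulateGenome(3400, essentialFraction = 0.12,
                        plasmidGeneFraction = 0.06, seed = 201)
  truth <- sim$truth
  pool <- simulatePool(sim$genome, truth, 79660, seed = 202)
  des <- rbind(
    data.frame(sample = sprintf("T0_%02d", 1:21), role = "Time0",
               time0_group = "grp1", condition = "Time0",
               replicate = 1:21, stringsAsFactors = FALSE),
    data.frame(sample = "neutral_rep1", role = "condition",
               time0_group = "grp1", condition = "neutral",
               replicate = 1, stringsAsFactors = FALSE))
  design <- experimentDesign(des)
  counts <- simulateCounts(pool, truth, design, depth = 1e6, seed = 203)
  list(genome = sim$genome, truth = truth, pool = pool, design = design,
       counts = counts, cfg = analysisConfig())
})

# parameter-recovery fixture: smaller genome at the same per-gene strain
# coverage (median ~15 usable strains/gene), planted effects spanning
# [-3, 1] on a quarter of the genes, depth 1e6
recoveryFixture <- function() withFixture("recoveryFixture", function() {
  sim <- simulateGenome(400, essentialFraction = 0.1, seed = 301)
  g <- geneTable(sim$genome)
  nonEss <- g$gene_id[!essentialGenes(sim$truth)[g$gene_id]]
  set.seed(302)
  planted <- sample(nonEss, 100)
  effects <- data.frame(gene_id = planted, condition = "sel",
                        f = seq(-3, 1, length.out = 100),
                        stringsAsFactors = FALSE)
  truth <- plantEffects(sim$truth, c("sel", "ctrl"), effects = effects,
                        seed = 303)
  pool <- simulatePool(sim$genome, truth, 9400, seed = 304)
  design <- makeExperimentDesign(c("sel", "ctrl"), nTime0 = 3)
  counts <- simulateCounts(pool, truth, design, depth = 1e6, seed = 305)
  cfg <- analysisConfig(windowSize = 51)
  gfm <- runFitnessAnalysis(counts, pool, sim$genome, design, cfg)
  list(genome = sim$genome, truth = truth, pool = pool, design = design,
       counts = counts, cfg = cfg, effects = effects, gfm = gfm)
})

# phenotype-recovery fixture: 32 conditions; four 8-gene cofitness
# modules and 20 planted condition-specific effects (f_true = -2) in
# otherwise-neutral genes
phenoFixture <- function() withFixture("phenoFixture", function() {
  sim <- simulateGenome(400, essentialFraction = 0.1, seed = 401)
  g <- geneTable(sim$genome)
  nonEss <- g$gene_id[!essentialGenes(sim$truth)[g$gene_id]]
  set.seed(402)
  moduleGenes <- sample(nonEss, 32)
  modules <- setNames(rep(sprintf("mod%d", 1:4), each = 8), moduleGenes)
  specGenes <- sample(setdiff(nonEss, moduleGenes), 20)
  conds <- sprintf("c%02d", 1:32)
  specific <- data.frame(gene_id = specGenes,
                         condition = sample(conds, 20, replace = TRUE),
                         stringsAsFactors = FALSE)
  truth <- plantEffects(sim$truth, conds, modules = modules,
                        moduleEffectSd = 1.2, moduleNoiseSd = 0.3,
                        specific = specific, specificEffect = -2,
                        seed = 403)
  pool <- simulatePool(sim$genome, truth, 9400, seed = 404)
  design <- makeExperimentDesign(conds, nTime0 = 3)
  counts <- simulateCounts(pool, truth, design, depth = 1e6, seed = 405)
  cfg <- analysisConfig(windowSize = 51)
  gfm <- runFitnessAnalysis(counts, pool, sim$genome, design, cfg)
  list(genome = sim$genome, truth = truth, modules = modules,
       specific = specific, gfm = gfm, cfg = cfg)
})
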