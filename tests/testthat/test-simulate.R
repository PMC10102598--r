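test_that("essential-gene count follows the rounding rule", {
  sim <- simulateGenome(100, essentialFraction = 0.12, seed = 7)
  expect_equal(sum(essentialGenes(sim$truth)), 12)
  expect_equal(nrow(geneTable(sim$genome)), 100)
  sim2 <- simulateGenome(10, essentialFraction = 0.26, seed = 7)
  expect_equal(sum(essentialGenes(sim2$truth)), 3)
})

test_that("simulation is deterministic for a fixed seed", {
  a <- simulateGenome(60, essentialFraction = 0.1, seed = 11)
  b <- simulateGenome(60, essentialFraction = 0.1, seed = 11)
  expect_identical(a, b)
  pa <- simulatePool(a$genome, a$truth, 500, seed = 12)
  pb <- simulatePool(b$genome, b$truth, 500, seed = 12)
  expect_identical(pa, pb)
  design <- makeExperimentDesign("x", nTime0 = 2)
  ca <- simulateCounts(pa, a$truth, design, depth = 1e4, seed = 13)
  cb <- simulateCounts(pb, b$truth, design, depth = 1e4, seed = 13)
  expect_identical(ca, cb)
})

test_that("generator rejects invalid arguments", {
  expect_error(simulateGenome(0, seed = 1), "empty genome")
  expect_error(simulateGenome(10, essentialFraction = 1.2, seed = 1),
               "fractions")
  sim <- simulateGenome(10, seed = 1)
  expect_error(simulatePool(sim$genome, sim$truth, -1, seed = 1), ">= 0")
  design <- makeExperimentDesign("x", nTime0 = 2)
  pool <- simulatePool(sim$genome, sim$truth, 50, seed = 2)
  expect_error(simulateCounts(pool, sim$truth, design, depth = -5,
                              seed = 1), "negative depth")
  truthB <- plantEffects(sim$truth, "otherCondition", seed = 3)
  expect_error(simulateCounts(pool, truthB, design, depth = 100, seed = 1),
               "without planted truth")
})

test_that("an empty pool and zero depth are handled", {
  sim <- simulateGenome(10, seed = 5)
  empty <- simulatePool(sim$genome, sim$truth, 0, seed = 1)
  expect_equal(nrow(poolStrains(empty)), 0)
  pool <- simulatePool(sim$genome, sim$truth, 100, seed = 1)
  design <- makeExperimentDesign("x", nTime0 = 1)
  counts <- simulateCounts(pool, sim$truth, design, depth = 0, seed = 2)
  expect_true(all(counts == 0))
})

test_that("pool invariants hold across many seeds", {
  sim <- simulateGenome(20, essentialFraction = 0.2, seed = 42)
  rlen <- setNames(repliconTable(sim$genome)$length,
                   repliconTable(sim$genome)$replicon)
  ess <- essentialGenes(sim$truth)
  for (seed in 1:100) {
    pool <- simulatePool(sim$genome, sim$truth, 300, seed = seed)
    s <- poolStrains(pool)
    expect_false(anyDuplicated(s$barcode) > 0)
    expect_true(all(s$pos >= 1 & s$pos <= rlen[s$replicon]))
    # zero leakage: no central insertion in an essential gene
    central <- !is.na(s$gene_id) & s$gene_fraction >= 0.1 &
      s$gene_fraction <= 0.9
    expect_false(any(ess[s$gene_id[central]]))
    # fraction convention
    g <- geneTable(sim$genome)
    hit <- !is.na(s$gene_id)
    idx <- match(s$gene_id[hit], g$gene_id)
    expect_equal(s$gene_fraction[hit],
                 (s$pos[hit] - g$begin[idx] + 1) /
                   (g$end[idx] - g$begin[idx] + 1))
  }
})

test_that("barcodes are fixed-length ACGT strings", {
  sim <- simulateGenome(10, seed = 3)
  pool <- simulatePool(sim$genome, sim$truth, 200, seed = 4)
  bc <- poolStrains(pool)$barcode
  expect_true(all(nchar(bc) == 20))
  expect_true(all(grepl("^[ACGT]+$", bc)))
})

test_that("counts are multinomial at the requested depth", {
  s <- smallSim()
  expect_true(all(colSums(s$counts) == 5e5))
  expect_true(all(s$counts >= 0))
})

test_that("neutral truth gives log2 ratios centered at zero", {
  sim <- simulateGenome(100, essentialFraction = 0, seed = 21)
  pool <- simulatePool(sim$genome, sim$truth, 2000, seed = 22)
  design <- makeExperimentDesign("null", nTime0 = 1)
  counts <- simulateCounts(pool, sim$truth, design, depth = 1e6,
                           seed = 23)
  t0 <- counts[, 1]
  cond <- counts[, 2]
  keep <- t0 >= 50
  lr <- log2(cond[keep] / sum(cond)) - log2(t0[keep] / sum(t0))
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("condition counts match the closed-form multinomial mean", {
  # one central strain with true fitness 1 at relative abundance 1/100
  # among 99 neutral intergenic strains; expected condition count is
  # depth * (0.01 * 2) / (0.99 + 0.01 * 2)
  genome <- toyGenome(1, len = 1000, gap = 200)
  pool <- toyPool(genome, rep("chr", 100),
                  c(700, seq_len(99)))  # strain 1 central, rest intergenic
  truth <- new("SimTruth",
               essential = setNames(FALSE, "g01"),
               fTrue = matrix(1, 1, 1, dimnames = list("g01", "sel")),
               modules = setNames(NA_character_, "g01"),
               specific = data.frame(gene_id = character(),
                                     condition = character()))
  des <- experimentDesign(rbind(
    data.frame(sample = "t0", role = "Time0", time0_group = "g",
               condition = "Time0", replicate = 1),
    data.frame(sample = sprintf("sel_%04d", 1:1000), role = "condition",
               time0_group = "g", condition = "sel",
               replicate = 1:1000)))
  depth <- 1e6
  counts <- simulateCounts(pool, truth, des, depth = depth, seed = 31,
                           abundanceSd = 0)
  p <- (0.01 * 2) / (0.99 + 0.01 * 2)
  expected <- depth * p
  draws <- counts[1, -1]
  se <- sqrt(depth * p * (1 - p) / 1000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("planted truth structures are stored and clipped", {
  sim <- simulateGenome(50, essentialFraction = 0.1, seed = 51)
  g <- names(essentialGenes(sim$truth))
  nonEss <- g[!essentialGenes(sim$truth)]
  truth <- plantEffects(sim$truth, c("a", "b"),
    effects = data.frame(gene_id = nonEss[1], condition = "a", f = -9),
    modules = setNames(rep("m1", 3), nonEss[2:4]),
    specific = data.frame(gene_id = nonEss[5], condition = "b"),
    maxAbsEffect = 3, seed = 52)
  ft <- trueFitness(truth)
  expect_equal(ft[nonEss[1], "a"], -3)  # clipped
  expect_true(all(is.na(ft[essentialGenes(truth), ])))
  expect_equal(unname(geneModules(truth)[nonEss[2]]), "m1")
  expect_equal(specificTruth(truth)$gene_id, nonEss[5])
  expect_equal(ft[nonEss[5], "b"], -2)
})
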