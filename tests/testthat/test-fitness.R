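twoGeneSetup <- function(t0, cond) {
  # 6 strains: 3 central in g01, 2 central in g02, 1 intergenic
  genome <- toyGenome(2, len = 1000, gap = 200)
  g <- geneTable(genome)
  pool <- toyPool(genome, rep("chr", 6),
                  c(g$begin[1] + c(200, 400, 600),
                    g$begin[2] + c(300, 500), 50))
  counts <- cbind(t0 = t0, cond = cond)
  rownames(counts) <- poolStrains(pool)$barcode
  design <- experimentDesign(data.frame(
    sample = c("t0", "cond"), role = c("Time0", "condition"),
    time0_group = "g", condition = c("Time0", "sel"), replicate = 1))
  list(genome = genome, pool = pool, counts = counts, design = design)
}

test_that("strain log ratios follow the stated arithmetic", {
  # equal depths; strain 1 has n_t0 = 3, n_cond = 15 -> log2(16/4) = 2
  s <- twoGeneSetup(t0 = c(3, 97, 100, 50, 150, 100),
                    cond = c(15, 85, 100, 50, 150, 100))
  sf <- strainLogRatios(s$counts, s$design, s$pool)
  expect_equal(sf$ratio[1], 2)
  expect_equal(sf$ratio[3], 0)  # n_cond == n_t0 at equal depth
  expect_true(all(sf$usable[1:5]))
  expect_false(sf$usable[6])    # intergenic
})

test_that("weights are the stated inverse variance", {
  s <- twoGeneSetup(t0 = c(3, 97, 100, 50, 150, 100),
                    cond = c(15, 85, 100, 50, 150, 100))
  sf <- strainLogRatios(s$counts, s$design, s$pool)
  v <- (1 / (sf$n_cond + 1) + 1 / (sf$n_t0 + 1)) / log(2)^2
  expect_equal(sf$weight, 1 / v, tolerance = 1e-12)
})

test_that("doubling condition depth barely moves well-covered strains", {
  set.seed(71)
  n <- 200
  t0 <- rpois(n, 200)
  cond <- rpois(n, 200)
  genome <- toyGenome(1, len = 10 * n + 1000, gap = 200)
  pool <- toyPool(genome, rep("chr", n),
                  geneTable(genome)$begin[1] + 100 + seq_len(n) * 9)
  counts <- cbind(t0 = t0, cond = cond)
  rownames(counts) <- poolStrains(pool)$barcode
  design <- experimentDesign(data.frame(
    sample = c("t0", "cond"), role = c("Time0", "condition"),
    time0_group = "g", condition = c("Time0", "x"), replicate = 1))
  sf1 <- strainLogRatios(counts, design, pool)
  counts2 <- counts
  counts2[, "cond"] <- counts[, "cond"] * 2L
  sf2 <- strainLogRatios(counts2, design, pool)
  keep <- sf1$n_cond >= 50
  expect_lt(max(abs(sf2$ratio[keep] - sf1$ratio[keep])), 0.01)
})

test_that("gene fitness is the weighted average of usable strains", {
  s <- twoGeneSetup(t0 = c(30, 40, 50, 60, 70, 80),
                    cond = c(90, 10, 50, 55, 75, 80))
  sf <- strainLogRatios(s$counts, s$design, s$pool)
  agg <- geneFitnessUnnormalized(sf)
  for (gid in c("g01", "g02")) {
    sub <- sf[sf$usable & sf$gene_id == gid & !is.na(sf$gene_id), ]
    expect_equal(agg$f_raw[agg$gene_id == gid],
                 sum(sub$weight * sub$ratio) / sum(sub$weight),
                 tolerance = 1e-12)
  }
  # single usable strain: fitness equals that strain's ratio
  one <- twoGeneSetup(t0 = c(40, 1, 1, 60, 70, 80),
                      cond = c(90, 1, 1, 55, 75, 80))
  sfo <- strainLogRatios(one$counts, one$design, one$pool)
  aggo <- geneFitnessUnnormalized(sfo, analysisConfig(minGeneT0Reads = 10))
  expect_equal(aggo$f_raw[aggo$gene_id == "g01"],
               sfo$ratio[1])
  expect_equal(aggo$n_strains[aggo$gene_id == "g01"], 1)
})

test_that("equal weights average ratios directly", {
  agg <- geneFitnessUnnormalized(data.frame(
    barcode = c("a", "b"), experiment = "e", gene_id = "g",
    gene_fraction = 0.5, n_cond = c(10, 10), n_t0 = c(100, 100),
    ratio = c(1, 3), weight = c(2, 2), usable = TRUE),
    analysisConfig(minGeneT0Reads = 10))
  expect_equal(agg$f_raw, 2)
})

test_that("genes below the Time0 abundance rule get NA", {
  s <- twoGeneSetup(t0 = c(3, 3, 3, 200, 200, 100),
                    cond = c(5, 5, 5, 200, 200, 100))
  gfm <- runFitnessAnalysis(s$counts, s$pool, s$genome, s$design,
                            analysisConfig(windowSize = 5))
  f <- fitnessScores(gfm)
  expect_true(is.na(f["g01", 1]))   # 9 usable Time0 reads < 30
  expect_false(is.na(f["g02", 1]))
  expect_identical(is.na(fitnessScores(gfm)), is.na(tScores(gfm)))
  expect_equal(unname(fitnessAvailability(gfm)), c(FALSE, TRUE))
})

test_that("running median matches brute force and rejects even windows", {
  set.seed(72)
  x <- rnorm(500)
  rm <- runningMedian(x, 51)
  brute <- sapply(seq_along(x), function(i)
    median(x[max(1, i - 25):min(500, i + 25)]))
  expect_equal(rm, brute)
  expect_error(runningMedian(x, 50), "odd")
  expect_error(positionalNormalize(setNames(x[1:5], sprintf("g%02d", 1:5)),
                                   toyGenome(5),
                                   analysisConfig(windowSize = 4)),
               "odd")
})

test_that("density mode finds the bulk and breaks ties toward zero", {
  set.seed(73)
  x <- c(rnorm(2000, 0, 0.1), rnorm(50, 3, 0.1))
  expect_lt(abs(densityMode(x)), 0.05)
  y <- rnorm(500, 2, 0.1)
  expect_lt(abs(densityMode(y) - 2), 0.05)
})

test_that("positional normalization removes a planted gradient", {
  genome <- toyGenome(400, len = 800, gap = 200)
  g <- geneTable(genome)
  set.seed(74)
  mid <- (g$begin + g$end) / 2
  grad <- 0.5 * mid / 1e6          # 0.5 per Mb
  f <- setNames(grad + rnorm(400, 0, 0.1), g$gene_id)
  cfg <- analysisConfig(windowSize = 51)
  fn <- positionalNormalize(f, genome, cfg)
  # oracle: recompute the running median of the normalized values
  rm <- runningMedian(unname(fn), 51)
  expect_lt(max(abs(rm)), 0.05)
  expect_lt(abs(densityMode(unname(fn))), 0.05)
})

test_that("normalization is idempotent on centered input and removes an
           added constant", {
  genome <- toyGenome(150, len = 800, gap = 200)
  f <- setNames(rep(0, 150), geneTable(genome)$gene_id)
  cfg <- analysisConfig(windowSize = 21)
  expect_lt(max(abs(positionalNormalize(f, genome, cfg))), 1e-9)
  set.seed(75)
  f2 <- setNames(rnorm(150, 0, 0.2), geneTable(genome)$gene_id)
  a <- positionalNormalize(f2, genome, cfg)
  b <- positionalNormalize(f2 + 3, genome, cfg)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("small replicons are centered by their plain median", {
  sim <- simulateGenome(120, essentialFraction = 0,
                        plasmidGeneFraction = 0.15, seed = 76)
  g <- geneTable(sim$genome)
  set.seed(77)
  f <- setNames(rnorm(120, 0, 0.2), g$gene_id)
  f[g$replicon == "plasmid"] <- f[g$replicon == "plasmid"] + 5
  cfg <- analysisConfig(windowSize = 51)
  fn <- positionalNormalize(f, sim$genome, cfg)
  plas <- fn[g$gene_id[g$replicon == "plasmid"]]
  # the +5 plasmid offset is gone up to the chromosome mode shift
  expect_lt(abs(median(plas)), 0.2)
})

test_that("t statistics match the brute-force formula", {
  s <- twoGeneSetup(t0 = c(30, 40, 50, 60, 70, 80),
                    cond = c(90, 10, 50, 55, 75, 80))
  sf <- strainLogRatios(s$counts, s$design, s$pool)
  agg <- geneFitnessUnnormalized(sf)
  f <- setNames(agg$f_raw, agg$gene_id)  # skip normalization: test t only
  t <- tStatistics(f, agg)
  for (gid in c("g01", "g02")) {
    sub <- sf[sf$usable & !is.na(sf$gene_id) & sf$gene_id == gid, ]
    expect_equal(unname(t[gid]),
                 bruteT(unname(f[gid]), sub$ratio, sub$weight),
                 tolerance = 1e-12)
  }
  # f = 0 gives t = 0
  expect_equal(unname(tStatistics(setNames(0, "g01"), agg)[1]), 0)
  # single-strain gene falls back to the count variance alone
  one <- agg[agg$gene_id == "g01", ]
  one$n_strains <- 1; one$v_spread <- NA_real_
  t1 <- tStatistics(setNames(0.5, "g01"), one)
  expect_equal(unname(t1), 0.5 / sqrt(0.1^2 + 1 / one$sum_w),
               tolerance = 1e-12)
})

test_that("more counts give larger |t| when count variance dominates", {
  # tight strain agreement: Vspread ~ 0 so Vg = Vcount = 1/sum(w)
  mkAgg <- function(scale) geneFitnessUnnormalized(data.frame(
    barcode = letters[1:4], experiment = "e", gene_id = "g",
    gene_fraction = 0.5, n_cond = scale * 20, n_t0 = scale * 20,
    ratio = 1, weight = scale * c(5, 6, 7, 8), usable = TRUE),
    analysisConfig(minGeneT0Reads = 10))
  t1 <- tStatistics(setNames(1, "g"), mkAgg(1))
  t10 <- tStatistics(setNames(1, "g"), mkAgg(10))
  expect_gt(abs(t10), abs(t1))
})

test_that("degenerate inputs raise errors", {
  s <- twoGeneSetup(t0 = c(30, 40, 50, 60, 70, 80),
                    cond = c(0, 0, 0, 0, 0, 0))
  expect_error(strainLogRatios(s$counts, s$design, s$pool), "no reads")
  badDesign <- data.frame(
    sample = c("t0", "cond"), role = c("Time0", "condition"),
    time0_group = c("g", "h"), condition = c("Time0", "sel"),
    replicate = 1)
  expect_error(experimentDesign(badDesign), "no Time0 sample")
  expect_error(runFitnessAnalysis(s$counts[, 1, drop = FALSE], s$pool,
                                  s$genome,
                                  experimentDesign(data.frame(
                                    sample = "t0", role = "Time0",
                                    time0_group = "g", condition = "Time0",
                                    replicate = 1)),
                                  analysisConfig(windowSize = 5)),
               "no condition samples")
})

test_that("fitness and t are antisymmetric under role reversal", {
  s <- smallSim()
  counts <- s$counts[, c("T0A_t0_1", "condA_rep1")]
  # keep strains visible from both sides so usability is symmetric
  counts <- counts[apply(counts, 1, min) >= 3, ]
  mkDesign <- function(t0, cond) experimentDesign(data.frame(
    sample = c(t0, cond), role = c("Time0", "condition"),
    time0_group = "g", condition = c("Time0", "x"), replicate = 1))
  dF <- mkDesign("T0A_t0_1", "condA_rep1")
  dR <- mkDesign("condA_rep1", "T0A_t0_1")
  sfF <- strainLogRatios(counts, dF, s$pool, s$cfg)
  sfR <- strainLogRatios(counts, dR, s$pool, s$cfg)
  expect_equal(sfF$ratio, -sfR$ratio, tolerance = 1e-12)
  expect_equal(sfF$weight, sfR$weight, tolerance = 1e-12)
  expect_identical(sfF$usable, sfR$usable)
  # exact antisymmetry of raw gene fitness and t over shared genes
  aggF <- geneFitnessUnnormalized(sfF, s$cfg)
  aggR <- geneFitnessUnnormalized(sfR, s$cfg)
  shared <- intersect(aggF$gene_id[aggF$has_fitness],
                      aggR$gene_id[aggR$has_fitness])
  expect_gt(length(shared), 100)
  fF <- setNames(aggF$f_raw, aggF$gene_id)[shared]
  fR <- setNames(aggR$f_raw, aggR$gene_id)[shared]
  expect_equal(fF, -fR, tolerance = 1e-12)
  tF <- tStatistics(fF, aggF, s$cfg)
  tR <- tStatistics(fR, aggR, s$cfg)
  expect_equal(tF, -tR, tolerance = 1e-12)
  # full pipeline (normalization adds a grid-limited mode shift)
  fwd <- runFitnessAnalysis(counts, s$pool, s$genome, dF, s$cfg)
  rev <- runFitnessAnalysis(counts, s$pool, s$genome, dR, s$cfg)
  ok <- !is.na(fitnessScores(fwd)[, 1]) & !is.na(fitnessScores(rev)[, 1])
  expect_lt(max(abs(fitnessScores(fwd)[ok, 1] +
                    fitnessScores(rev)[ok, 1])), 0.1)
})

test_that("QC flags experiments and reports the stated metrics", {
  gfm <- smallFitness()
  qc <- qcReport(gfm)
  expect_equal(qc$experiment, colnames(gfm))
  expect_true(all(c("gmed", "cor12", "mad12", "pass") %in% names(qc)))
  # condA has planted signal spanning [-3, 1]: half-halves must agree
  expect_gt(qc$cor12[qc$experiment == "condA_rep1"], 0.5)
  expect_true(qc$pass[qc$experiment == "condA_rep1"])
  # an experiment with gmed below threshold fails
  s <- smallSim()
  lowCfg <- analysisConfig(windowSize = 51, qcMinGmed = 1e9)
  gfm2 <- runFitnessAnalysis(s$counts, s$pool, s$genome, s$design, lowCfg)
  expect_false(any(qcReport(gfm2)$pass))
})

test_that("Time0-vs-Time0 comparisons are near-null on small data", {
  s <- smallSim()
  null <- time0NullComparisons(s$counts, s$pool, s$genome, s$design,
                               s$cfg)
  expect_equal(ncol(null), 3)  # leave-one-out over 3 Time0 samples
  f <- fitnessScores(null)
  frac <- mean(abs(f[!is.na(f)]) >= 0.5)
  expect_lt(frac, 0.01)
})
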