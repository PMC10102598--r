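# Synthetic barcoded-library generator. Scales default to the study system
# this package models: a ~3.5 Mb main chromosome plus a ~6% megaplasmid,
# ~80,000 barcoded insertions, a median of ~15 usable (central) insertion
# strains per gene, 4-6 population doublings per assay.

.withSeed <- function(seed, expr) {
  # explicit-seed, no-global-state contract: restore the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-replicon bacterial genome with known essential genes
#'
#' Generates a gene table laid out along a main chromosome and a plasmid,
#' with gene lengths drawn from a gamma distribution, intergenic gaps from
#' an exponential, per-gene GC following an AR(1) process around the genome
#' mean (GC tracks along real chromosomes), and a small fraction of genes
#' carrying repetitive sequence (reduced \code{nonrepetitive_nt}, some
#' below the 100-nt analyzability floor). A fixed fraction of genes is
#' flagged essential in the returned ground truth; the pool simulator
#' rejects central insertions in those genes.
#'
#' @param nGenes number of genes (>= 1).
#' @param essentialFraction fraction of genes planted essential; exactly
#'   \code{round(essentialFraction * nGenes)} genes are flagged.
#' @param plasmidGeneFraction fraction of genes placed on the plasmid.
#' @param seed integer seed; the same arguments and seed reproduce the
#'   output exactly.
#' @param meanGeneLength,sdGeneLength gene length distribution (nt).
#' @param meanGap mean intergenic gap (nt).
#' @param gcMean,gcSd,gcRho GC process: mean, marginal sd, lag-1
#'   autocorrelation along the gene order.
#' @param repeatFraction fraction of genes given a repetitive stretch.
#' @return list with elements \code{genome} (\linkS4class{GenomeModel}) and
#'   \code{truth} (\linkS4class{SimTruth}; no planted condition effects yet,
#'   see \code{\link{plantEffects}}).
#' @examples
#' sim <- simulateGenome(100, essentialFraction = 0.12, seed = 7)
#' sum(essentialGenes(sim$truth))  # 12
#' @export
simulateGenome <- function(nGenes, essentialFraction = 0.12,
                           plasmidGeneFraction = 0.06, seed,
                           meanGeneLength = 780, sdGeneLength = 300,
                           meanGap = 270, gcMean = 0.63, gcSd = 0.05,
                           gcRho = 0.8, repeatFraction = 0.02) {
  if (nGenes < 1) stop("empty genome")
  for (f in c(essentialFraction, plasmidGeneFraction, repeatFraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0,1]")
  if (missing(seed)) stop("seed is required")
  .withSeed(seed, {
    nPlasmid <- round(plasmidGeneFraction * nGenes)
    nMain <- nGenes - nPlasmid
    layout1 <- function(n, repliconId, idOffset) {
      if (n == 0)
        return(list(genes = NULL, length = 10000L))
      shape <- (meanGeneLength / sdGeneLength)^2
      scale <- sdGeneLength^2 / meanGeneLength
      len <- pmax(150L, as.integer(round(rgamma(n, shape, scale = scale))))
      gap <- pmax(20L, as.integer(round(rexp(n + 1, 1 / meanGap))))
      begin <- cumsum(c(0L, len[-n]) + gap[seq_len(n)]) + 1L
      end <- begin + len - 1L
      gc <- numeric(n)
      gc[1] <- gcMean + gcSd * rnorm(1)
      if (n > 1)
        for (i in 2:n)
          gc[i] <- gcMean + gcRho * (gc[i - 1] - gcMean) +
            sqrt(1 - gcRho^2) * gcSd * rnorm(1)
      gc <- pmin(0.9, pmax(0.2, round(gc, 4)))
      hasRepeat <- runif(n) < repeatFraction
      nonrep <- len
      nonrep[hasRepeat] <-
        as.integer(round(runif(sum(hasRepeat), 0, 0.9) * len[hasRepeat]))
      list(genes = data.frame(
             gene_id = sprintf("G%05d", idOffset + seq_len(n)),
             replicon = repliconId, begin = begin, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             gc = gc, nonrepetitive_nt = nonrep,
             desc = paste("simulated gene", idOffset + seq_len(n)),
             stringsAsFactors = FALSE),
           length = end[n] + gap[n + 1])
    }
    main <- layout1(nMain, "chromosome", 0L)
    plas <- layout1(nPlasmid, "plasmid", nMain)
    genes <- rbind(main$genes, plas$genes)
    replicons <- data.frame(
      replicon = c("chromosome", "plasmid"),
      length = as.integer(c(main$length, plas$length)),
      is_main = c(TRUE, FALSE), stringsAsFactors = FALSE)
    genome <- new("GenomeModel", replicons = replicons, genes = genes)
    nEss <- round(essentialFraction * nGenes)
    essential <- setNames(rep(FALSE, nGenes), genes$gene_id)
    essential[sample(nGenes, nEss)] <- TRUE
    truth <- new("SimTruth", essential = essential,
                 fTrue = matrix(numeric(0), nrow = nGenes, ncol = 0,
                                dimnames = list(genes$gene_id, NULL)),
                 modules = setNames(rep(NA_character_, nGenes),
                                    genes$gene_id),
                 specific = data.frame(gene_id = character(),
                                       condition = character(),
                                       stringsAsFactors = FALSE))
    list(genome = genome, truth = truth)
  })
}

#' Plant condition-specific fitness effects and cofitness modules
#'
#' Populates the ground-truth fitness matrix of a simulation. True fitness
#' is the expected final normalized log2 abundance ratio of a disrupted
#' mutant after the assay's growth selection. Three kinds of structure can
#' be planted, alone or together: direct per-(gene, condition) effects;
#' co-regulated modules whose members share a per-condition base effect up
#' to gene-level noise (the structure cofitness analysis should recover);
#' and condition-specific effects for genes that are neutral everywhere
#' else. Essential genes keep \code{NA} (no mutants exist).
#'
#' @param truth a \linkS4class{SimTruth} from \code{\link{simulateGenome}}.
#' @param conditions character vector of condition names.
#' @param effects optional data.frame(gene_id, condition, f) of direct
#'   effects.
#' @param modules optional named character vector gene_id -> module label.
#' @param moduleEffectSd sd of the shared per-(module, condition) base
#'   effect (log2 units).
#' @param moduleNoiseSd sd of gene-level deviation from the module base.
#' @param specific optional data.frame(gene_id, condition) of planted
#'   specific phenotypes.
#' @param specificEffect fitness effect of each planted specific phenotype.
#' @param maxAbsEffect clip bound on |true fitness|.
#' @param seed integer seed.
#' @return the updated \linkS4class{SimTruth}.
#' @export
plantEffects <- function(truth, conditions, effects = NULL, modules = NULL,
                         moduleEffectSd = 1.2, moduleNoiseSd = 0.3,
                         specific = NULL, specificEffect = -2,
                         maxAbsEffect = 3, seed = 1) {
  stopifnot(is(truth, "SimTruth"), length(conditions) >= 1)
  genes <- names(truth@essential)
  .withSeed(seed, {
    f <- matrix(0, nrow = length(genes), ncol = length(conditions),
                dimnames = list(genes, conditions))
    if (!is.null(modules)) {
      stopifnot(all(names(modules) %in% genes))
      truth@modules[names(modules)] <- modules
      for (m in unique(modules)) {
        members <- names(modules)[modules == m]
        base <- rnorm(length(conditions), 0, moduleEffectSd)
        for (g in members)
          f[g, ] <- base + rnorm(length(conditions), 0, moduleNoiseSd)
      }
    }
    if (!is.null(effects)) {
      stopifnot(all(c("gene_id", "condition", "f") %in% names(effects)),
                all(effects$condition %in% conditions),
                all(effects$gene_id %in% genes))
      f[cbind(effects$gene_id, effects$condition)] <- effects$f
    }
    if (!is.null(specific)) {
      stopifnot(all(c("gene_id", "condition") %in% names(specific)),
                all(specific$condition %in% conditions),
                all(specific$gene_id %in% genes))
      f[cbind(specific$gene_id, specific$condition)] <- specificEffect
      truth@specific <- specific[, c("gene_id", "condition")]
    }
    f <- pmin(pmax(f, -maxAbsEffect), maxAbsEffect)
    f[truth@essential, ] <- NA_real_
    truth@fTrue <- f
    validObject(truth)
    truth
  })
}

.assignGenes <- function(replicon, pos, genes) {
  # interval lookup per replicon; genes assumed non-overlapping within a
  # replicon (first by begin wins otherwise)
  geneId <- rep(NA_character_, length(pos))
  frac <- rep(NA_real_, length(pos))
  for (r in unique(replicon)) {
    g <- genes[genes$replicon == r, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$begin), , drop = FALSE]
    sel <- which(replicon == r)
    idx <- findInterval(pos[sel], g$begin)
    hit <- idx >= 1 & pos[sel] <= ifelse(idx >= 1, g$end[pmax(idx, 1)], 0)
    geneId[sel[hit]] <- g$gene_id[idx[hit]]
    glen <- g$end - g$begin + 1
    frac[sel[hit]] <-
      (pos[sel][hit] - g$begin[idx[hit]] + 1) / glen[idx[hit]]
  }
  list(gene_id = geneId, gene_fraction = frac)
}

#' Assign pool strains to genes
#'
#' Fills \code{gene_id} and \code{gene_fraction} for every strain from the
#' genome's gene coordinates. The fraction is the strain's position within
#' the gene measured on the + coordinate direction,
#' \code{(pos - begin + 1) / (end - begin + 1)}, regardless of the gene's
#' strand: the central 10--90\% disruption rule is positional.
#'
#' @param pool an \linkS4class{InsertionPool}.
#' @param genome a \linkS4class{GenomeModel} sharing the pool's replicons.
#' @return the pool with gene assignments recomputed.
#' @export
mapStrainsToGenes <- function(pool, genome) {
  stopifnot(is(pool, "InsertionPool"), is(genome, "GenomeModel"))
  s <- pool@strains
  if (!all(s$replicon %in% genome@replicons$replicon))
    stop("pool references replicon(s) absent from the genome")
  a <- .assignGenes(s$replicon, s$pos, genome@genes)
  s$gene_id <- a$gene_id
  s$gene_fraction <- a$gene_fraction
  new("InsertionPool", strains = s)
}

.randomBarcodes <- function(n, length = 20) {
  draw <- function(k)
    apply(matrix(sample(c("A", "C", "G", "T"), k * length, replace = TRUE),
                 nrow = k), 1, paste, collapse = "")
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Simulate a barcoded transposon insertion pool
#'
#' Draws insertion positions approximately uniformly over the genome
#' (replicons weighted by length). Insertions that would fall in the
#' central 10--90\% of an essential gene are rejected and redrawn --
#' such mutants do not survive library selection -- except with a small
#' configurable leakage probability. Each strain receives a unique random
#' 20-nt ACGT barcode and an overdispersed (negative binomial) Tn-seq read
#' count.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param truth the matching \linkS4class{SimTruth} (essential flags).
#' @param nStrains number of strains (>= 0).
#' @param seed integer seed.
#' @param leakage probability that a central insertion in an essential gene
#'   is retained anyway (default 0).
#' @param barcodeLength barcode length in nt.
#' @param readMu,readSize mean and dispersion of the negative binomial
#'   Tn-seq read count (shifted by +1 so every mapped strain has a read).
#' @return an \linkS4class{InsertionPool} with gene assignments filled in.
#' @export
simulatePool <- function(genome, truth, nStrains, seed, leakage = 0,
                         barcodeLength = 20, readMu = 20, readSize = 1) {
  stopifnot(is(genome, "GenomeModel"), is(truth, "SimTruth"))
  if (nStrains < 0) stop("nStrains must be >= 0")
  if (missing(seed)) stop("seed is required")
  if (leakage < 0 || leakage > 1) stop("leakage must lie in [0,1]")
  emptyPool <- function() new("InsertionPool", strains = data.frame(
    barcode = character(), replicon = character(), strand = character(),
    pos = integer(), n_reads = integer(), gene_id = character(),
    gene_fraction = numeric(), stringsAsFactors = FALSE))
  if (nStrains == 0) return(emptyPool())
  rep <- genome@replicons
  .withSeed(seed, {
    drawPositions <- function(n) {
      ri <- sample.int(nrow(rep), n, replace = TRUE, prob = rep$length)
      data.frame(replicon = rep$replicon[ri],
                 pos = as.integer(ceiling(runif(n) * rep$length[ri])),
                 stringsAsFactors = FALSE)
    }
    d <- drawPositions(nStrains)
    a <- .assignGenes(d$replicon, d$pos, genome@genes)
    repeat {
      centralEss <- !is.na(a$gene_id) & truth@essential[a$gene_id] &
        a$gene_fraction >= 0.1 & a$gene_fraction <= 0.9
      if (leakage > 0)
        centralEss <- centralEss & (runif(length(centralEss)) >= leakage)
      if (!any(centralEss)) break
      redo <- which(centralEss)
      d2 <- drawPositions(length(redo))
      d[redo, ] <- d2
      a2 <- .assignGenes(d2$replicon, d2$pos, genome@genes)
      a$gene_id[redo] <- a2$gene_id
      a$gene_fraction[redo] <- a2$gene_fraction
    }
    strains <- data.frame(
      barcode = .randomBarcodes(nStrains, barcodeLength),
      replicon = d$replicon,
      strand = sample(c("+", "-"), nStrains, replace = TRUE),
      pos = d$pos,
      n_reads = as.integer(rnbinom(nStrains, mu = readMu - 1,
                                   size = readSize) + 1L),
      gene_id = a$gene_id, gene_fraction = a$gene_fraction,
      stringsAsFactors = FALSE)
    new("InsertionPool", strains = strains)
  })
}

#' Build a simple experiment design
#'
#' One Time0 group with \code{nTime0} Time0 samples followed by
#' \code{replicates} condition samples per condition.
#'
#' @param conditions character vector of condition names.
#' @param replicates condition replicates.
#' @param nTime0 number of Time0 samples.
#' @param time0Group group label.
#' @return an \linkS4class{ExperimentDesign}.
#' @export
makeExperimentDesign <- function(conditions, replicates = 1, nTime0 = 3,
                                 time0Group = "T0A") {
  t0 <- data.frame(sample = sprintf("%s_t0_%d", time0Group, seq_len(nTime0)),
                   role = "Time0", time0_group = time0Group,
                   condition = "Time0", replicate = seq_len(nTime0),
                   stringsAsFactors = FALSE)
  cond <- expand.grid(replicate = seq_len(replicates),
                      condition = conditions, stringsAsFactors = FALSE)
  cd <- data.frame(sample = sprintf("%s_rep%d", cond$condition,
                                    cond$replicate),
                   role = "condition", time0_group = time0Group,
                   condition = cond$condition, replicate = cond$replicate,
                   stringsAsFactors = FALSE)
  new("ExperimentDesign", samples = rbind(t0, cd))
}

#' Construct an ExperimentDesign from a sample table
#'
#' @param samples data.frame with columns sample, role, time0_group,
#'   condition, replicate.
#' @return an \linkS4class{ExperimentDesign}.
#' @export
experimentDesign <- function(samples) {
  new("ExperimentDesign", samples = as.data.frame(samples))
}

#' Simulate BarSeq counts for a pooled fitness assay
#'
#' Initial strain abundances are drawn from a log-normal distribution
#' (pooled libraries are strongly uneven) and shared across all samples of
#' a Time0 group. In a condition sample, the abundance of a strain with a
#' central insertion in gene g is proportional to
#' \code{initial * 2^fTrue[g, condition]}; intergenic and non-central
#' strains behave neutrally. Counts per sample are multinomial at the
#' requested sequencing depth (so column sums equal the depth exactly),
#' optionally with Dirichlet-multinomial overdispersion. An optional
#' replication-origin copy-number gradient along the main chromosome,
#' scaled by the number of population doublings, emulates the positional
#' bias that running-median normalization corrects.
#'
#' @param pool an \linkS4class{InsertionPool} with gene assignments.
#' @param truth a \linkS4class{SimTruth} whose planted conditions cover the
#'   design's conditions (unplanted truth means all effects 0).
#' @param design an \linkS4class{ExperimentDesign}.
#' @param depth reads per sample (scalar or named per-sample vector).
#' @param doublings population doublings between Time0 and condition
#'   sampling (4--6 in a typical assay; scales the drift gradient only,
#'   since true fitness is defined as the final log2 ratio).
#' @param seed integer seed.
#' @param abundanceSd log-normal sigma of initial abundances.
#' @param driftPerDoubling log2 copy-number gradient amplitude per doubling
#'   across the main chromosome (default 0).
#' @param dirichletTheta Dirichlet-multinomial overdispersion (0 = pure
#'   multinomial).
#' @return integer matrix of counts, barcodes x samples.
#' @export
simulateCounts <- function(pool, truth, design, depth = 1e6, doublings = 5,
                           seed, abundanceSd = 1, driftPerDoubling = 0,
                           dirichletTheta = 0) {
  stopifnot(is(pool, "InsertionPool"), is(truth, "SimTruth"),
            is(design, "ExperimentDesign"))
  if (doublings <= 0) stop("doublings must be > 0")
  if (missing(seed)) stop("seed is required")
  s <- pool@strains
  des <- design@samples
  if (any(depth < 0)) stop("negative depth")
  depths <- if (length(depth) == 1) setNames(rep(depth, nrow(des)),
                                             des$sample)
            else depth[des$sample]
  if (any(is.na(depths))) stop("depth must cover every sample")
  conds <- unique(des$condition[des$role == "condition"])
  if (length(conds) && ncol(truth@fTrue) == 0) {
    # unplanted truth: neutral everywhere
    truth@fTrue <- matrix(0, nrow = length(truth@essential),
                          ncol = length(conds),
                          dimnames = list(names(truth@essential), conds))
    truth@fTrue[truth@essential, ] <- NA_real_
  }
  missingConds <- setdiff(conds, colnames(truth@fTrue))
  if (length(missingConds))
    stop("condition(s) without planted truth: ",
         paste(missingConds, collapse = ", "))
  .withSeed(seed, {
    counts <- matrix(0L, nrow = nrow(s), ncol = nrow(des),
                     dimnames = list(s$barcode, des$sample))
    central <- !is.na(s$gene_id) & s$gene_fraction >= 0.1 &
      s$gene_fraction <= 0.9
    drift <- rep(0, nrow(s))
    if (driftPerDoubling != 0) {
      # gradient defined on position fraction along each replicon
      for (r in unique(s$replicon)) {
        sel <- s$replicon == r
        x <- s$pos[sel] / max(s$pos[sel])
        drift[sel] <- driftPerDoubling * doublings * (0.5 - x)
      }
    }
    for (grp in unique(des$time0_group)) {
      inGrp <- des$time0_group == grp
      init <- rlnorm(nrow(s), 0, abundanceSd)
      init <- init / sum(init)
      for (j in which(inGrp)) {
        if (des$role[j] == "Time0") {
          prob <- init
        } else {
          fs <- rep(0, nrow(s))
          ft <- setNames(truth@fTrue[, des$condition[j]],
                         rownames(truth@fTrue))
          fs[central] <- ft[s$gene_id[central]]
          fs[is.na(fs)] <- 0   # leaked essential-gene strains: neutral
          prob <- init * 2^(fs + drift)
        }
        prob <- prob / sum(prob)
        if (dirichletTheta > 0) {
          prob <- rgamma(length(prob), shape = prob / dirichletTheta)
          prob <- prob / sum(prob)
        }
        counts[, j] <- rmultinom(1, size = depths[j], prob = prob)[, 1]
      }
    }
    counts
  })
}

#' Write simulation ground truth to a TSV
#'
#' Long format: one row per (gene, condition) plus the essential flag.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  f <- truth@fTrue
  if (ncol(f) == 0)
    f <- matrix(NA_real_, nrow = length(truth@essential), ncol = 1,
                dimnames = list(names(truth@essential), "none"))
  long <- data.frame(
    gene_id = rep(rownames(f), times = ncol(f)),
    essential = rep(unname(truth@essential), times = ncol(f)),
    condition = rep(colnames(f), each = nrow(f)),
    f_true = as.vector(f), stringsAsFactors = FALSE)
  data.table::fwrite(long, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
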