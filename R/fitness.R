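# BarSeq fitness engine: strain log2 ratios vs Time0, inverse-variance
# weighted gene fitness, running-median + mode normalization along the
# chromosome (copy-number correction), and a t-like significance statistic.

#' Centered running median with truncated end windows
#'
#' For element i of x, the median of x over indices
#' \code{max(1, i-h) .. min(n, i+h)} with \code{h = (k-1)/2}; windows are
#' truncated (not shrunk to odd sizes) at the ends.
#'
#' @param x numeric vector.
#' @param k odd window size in elements.
#' @return numeric vector of the same length.
#' @export
runningMedian <- function(x, k) {
  if (k %% 2 == 0) stop("running-median window size must be odd")
  n <- length(x)
  h <- (k - 1) / 2
  vapply(seq_len(n), function(i)
    median(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Mode of a fitness distribution by kernel density
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a regular grid of the given step spanning
#' \code{[min(x) - 0.5, max(x) + 0.5]}; the mode is the grid argmax, with
#' ties broken toward the grid point nearest zero.
#'
#' @param x numeric vector (NAs dropped).
#' @param step grid step.
#' @return the estimated mode (scalar).
#' @export
densityMode <- function(x, step = 0.01) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0)
  if (length(x) == 1) return(x)
  h <- bw.nrd0(x)
  if (!is.finite(h) || h <= 0) return(x[1])
  grid <- seq(min(x) - 0.5, max(x) + 0.5, by = step)
  dens <- vapply(grid, function(g) sum(dnorm((g - x) / h)), numeric(1))
  best <- which(dens == max(dens))
  grid[best[which.min(abs(grid[best]))]]
}

.time0Reference <- function(counts, des) {
  # summed Time0 count vector per Time0 group
  t0 <- des[des$role == "Time0", , drop = FALSE]
  refs <- list()
  for (grp in unique(t0$time0_group)) {
    cols <- t0$sample[t0$time0_group == grp]
    refs[[grp]] <- if (length(cols) == 1) counts[, cols]
                   else rowSums(counts[, cols, drop = FALSE])
  }
  refs
}

.strainRatios1 <- function(nCond, nT0, config) {
  ps <- config@pseudocount
  if (sum(nCond) == 0) stop("no reads in condition sample")
  if (sum(nT0) == 0) stop("no reads in Time0 reference")
  dCond <- sum(nCond) + ps * length(nCond)
  dT0 <- sum(nT0) + ps * length(nT0)
  ratio <- log2((nCond + ps) / dCond) - log2((nT0 + ps) / dT0)
  v <- (1 / (nCond + ps) + 1 / (nT0 + ps)) / log(2)^2
  list(ratio = ratio, weight = 1 / v)
}

#' Strain fitness: normalized log2 ratios versus Time0
#'
#' For every condition sample, the Time0 samples of its group are summed
#' into one reference vector; the strain fitness is
#' \code{log2((n_cond + ps) / D_cond) - log2((n_t0 + ps) / D_t0)} with
#' pseudocount \code{ps} and \code{D} the sample depth plus one pseudocount
#' per strain. The inverse-variance weight is
#' \code{1 / ((1/(n_cond+ps) + 1/(n_t0+ps)) / ln(2)^2)}. A strain is usable
#' for gene fitness when it lies in the central 10--90\% of a gene and has
#' at least \code{minT0Reads} reads in the Time0 reference.
#'
#' @param counts integer matrix, barcodes x samples.
#' @param design an \linkS4class{ExperimentDesign} covering the samples.
#' @param pool the \linkS4class{InsertionPool} (gene assignments used for
#'   usability).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame with one row per (strain, condition sample):
#'   \code{barcode}, \code{experiment}, \code{gene_id},
#'   \code{gene_fraction}, \code{n_cond}, \code{n_t0}, \code{ratio},
#'   \code{weight}, \code{usable}.
#' @export
strainLogRatios <- function(counts, design, pool,
                            config = analysisConfig()) {
  stopifnot(is(design, "ExperimentDesign"), is(pool, "InsertionPool"))
  des <- design@samples
  missing <- setdiff(des$sample, colnames(counts))
  if (length(missing))
    stop("counts lack sample(s): ", paste(missing, collapse = ", "))
  s <- pool@strains[match(rownames(counts), pool@strains$barcode), ,
                    drop = FALSE]
  if (any(is.na(s$barcode)))
    stop("counts contain barcodes absent from the pool")
  refs <- .time0Reference(counts, des)
  central <- !is.na(s$gene_id) & s$gene_fraction >= 0.1 &
    s$gene_fraction <= 0.9
  out <- list()
  for (j in which(des$role == "condition")) {
    grp <- des$time0_group[j]
    if (is.null(refs[[grp]]))
      stop("condition sample ", des$sample[j], " has no Time0 group")
    nT0 <- refs[[grp]]
    nCond <- counts[, des$sample[j]]
    r <- .strainRatios1(nCond, nT0, config)
    out[[des$sample[j]]] <- data.frame(
      barcode = rownames(counts), experiment = des$sample[j],
      gene_id = s$gene_id, gene_fraction = s$gene_fraction,
      n_cond = as.numeric(nCond), n_t0 = as.numeric(nT0),
      ratio = r$ratio, weight = r$weight,
      usable = central & nT0 >= config@minT0Reads,
      stringsAsFactors = FALSE)
  }
  as.data.frame(data.table::rbindlist(out))
}

.geneAggregate <- function(geneId, ratio, weight, nT0, config) {
  # inverse-variance weighted mean per gene plus the pieces of the
  # t-statistic variance model; inputs are usable strains only
  sw <- rowsum(weight, geneId)
  swx <- rowsum(weight * ratio, geneId)
  st0 <- rowsum(nT0, geneId)
  n <- rowsum(rep(1, length(geneId)), geneId)
  fRaw <- swx[, 1] / sw[, 1]
  dev2 <- weight * (ratio - fRaw[geneId])^2
  sdev <- rowsum(dev2, geneId)
  nn <- n[, 1]
  # weighted sample variance of strain ratios about fRaw, divided by n
  vspread <- ifelse(nn > 1, (sdev[, 1] / sw[, 1]) * (nn / (nn - 1)) / nn,
                    NA_real_)
  data.frame(gene_id = rownames(sw), f_raw = fRaw, sum_w = sw[, 1],
             n_strains = nn, t0_reads = st0[, 1], v_spread = vspread,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Unnormalized gene fitness: weighted average over usable strains
#'
#' Gene fitness is the inverse-variance weighted average of the log2
#' ratios of the gene's usable strains. A gene receives a value only when
#' its usable strains carry at least \code{minGeneT0Reads} summed Time0
#' reads -- otherwise the gene's mutants were at insufficient abundance
#' before selection and the estimate would be noise.
#'
#' @param strainFitness output of \code{\link{strainLogRatios}} (one or
#'   more experiments).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame per (gene, experiment): \code{gene_id},
#'   \code{experiment}, \code{f_raw}, \code{sum_w}, \code{n_strains},
#'   \code{t0_reads}, \code{v_spread}, \code{has_fitness}.
#' @export
geneFitnessUnnormalized <- function(strainFitness,
                                    config = analysisConfig()) {
  out <- list()
  for (e in unique(strainFitness$experiment)) {
    sf <- strainFitness[strainFitness$experiment == e &
                        strainFitness$usable, , drop = FALSE]
    if (!nrow(sf)) next
    agg <- .geneAggregate(sf$gene_id, sf$ratio, sf$weight, sf$n_t0, config)
    agg$experiment <- e
    agg$has_fitness <- agg$t0_reads >= config@minGeneT0Reads
    out[[e]] <- agg
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Positional normalization of gene fitness
#'
#' Corrects for copy-number variation along the chromosome in growing
#' cells: on each replicon with enough scored genes (default 100), a
#' centered running median (default window 251 genes, truncated at the
#' ends) over genes ordered by position is subtracted; smaller replicons
#' have their plain median subtracted. Finally the kernel-density mode of
#' the main-chromosome values is subtracted from all genes, putting the
#' typical (no-phenotype) gene at fitness 0.
#'
#' @param f named numeric vector of per-gene fitness (NA allowed), names
#'   are gene_ids.
#' @param genome the \linkS4class{GenomeModel} (gene order and replicons).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return the normalized vector (same names; NAs preserved).
#' @export
positionalNormalize <- function(f, genome, config = analysisConfig()) {
  if (config@windowSize %% 2L == 0L)
    stop("running-median window size must be odd")
  g <- genome@genes
  stopifnot(all(names(f) %in% g$gene_id))
  out <- f
  for (r in unique(g$replicon)) {
    ids <- g$gene_id[g$replicon == r]
    ids <- ids[order(g$begin[match(ids, g$gene_id)])]
    ids <- ids[ids %in% names(f)]
    vals <- f[ids]
    scored <- !is.na(vals)
    if (!any(scored)) next
    if (sum(scored) >= config@minRepliconGenes) {
      rm <- runningMedian(vals[scored], config@windowSize)
      out[ids[scored]] <- vals[scored] - rm
    } else {
      out[ids[scored]] <- vals[scored] - median(vals[scored])
    }
  }
  mainRep <- genome@replicons$replicon[genome@replicons$is_main]
  modeGenes <- if (length(mainRep)) g$gene_id[g$replicon == mainRep]
               else g$gene_id
  m <- densityMode(out[intersect(names(out), modeGenes)],
                   config@modeGridStep)
  out - m
}

#' t-like significance statistic for gene fitness
#'
#' \code{t = f / sqrt(sigma0^2 + max(Vcount, Vspread))} where \code{Vcount
#' = 1 / sum(w)} is the count-based variance of the weighted mean,
#' \code{Vspread} is the weighted sample variance of the gene's strain
#' ratios about the unnormalized gene fitness divided by the number of
#' strains, and \code{sigma0} (default 0.1) is a variance floor that keeps
#' high-count genes from reaching arbitrarily large |t|. Single-strain
#' genes have no spread estimate and use \code{Vcount} alone.
#'
#' @param f named normalized fitness vector.
#' @param geneAgg per-gene aggregate (one experiment) from
#'   \code{\link{geneFitnessUnnormalized}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return named numeric vector of t values (NA where f is NA).
#' @export
tStatistics <- function(f, geneAgg, config = analysisConfig()) {
  idx <- match(names(f), geneAgg$gene_id)
  vcount <- 1 / geneAgg$sum_w[idx]
  vspread <- geneAgg$v_spread[idx]
  vg <- pmax(vcount, ifelse(is.na(vspread), vcount, vspread))
  t <- f / sqrt(config@sigma0^2 + vg)
  t[is.na(f)] <- NA_real_
  t
}

.analyzeOneExperiment <- function(nCond, nT0, strainMeta, genome, config) {
  # full chain for one condition experiment given its Time0 reference
  r <- .strainRatios1(nCond, nT0, config)
  usable <- strainMeta$central & nT0 >= config@minT0Reads
  geneIds <- genome@genes$gene_id
  f <- setNames(rep(NA_real_, length(geneIds)), geneIds)
  empty <- list(f = f, t = f,
                gmed = 0, cor12 = NA_real_, mad12 = NA_real_)
  if (!any(usable)) return(empty)
  agg <- .geneAggregate(strainMeta$gene_id[usable], r$ratio[usable],
                        r$weight[usable], nT0[usable], config)
  agg <- agg[agg$t0_reads >= config@minGeneT0Reads, , drop = FALSE]
  if (!nrow(agg)) return(empty)
  f[agg$gene_id] <- agg$f_raw
  fNorm <- positionalNormalize(f, genome, config)
  t <- tStatistics(fNorm, agg, config)
  # QC: median gene Time0 reads; agreement between fitness computed from
  # first-half (10-50%) vs second-half (50-90%) insertions
  gmed <- median(agg$t0_reads)
  half1 <- usable & strainMeta$gene_fraction < 0.5
  half2 <- usable & strainMeta$gene_fraction >= 0.5
  halfFit <- function(sel) {
    if (!any(sel)) return(NULL)
    a <- .geneAggregate(strainMeta$gene_id[sel], r$ratio[sel],
                        r$weight[sel], nT0[sel], config)
    a[a$t0_reads >= config@minGeneT0Reads / 2, c("gene_id", "f_raw")]
  }
  a1 <- halfFit(half1); a2 <- halfFit(half2)
  cor12 <- NA_real_; mad12 <- NA_real_
  if (!is.null(a1) && !is.null(a2)) {
    shared <- intersect(a1$gene_id, a2$gene_id)
    if (length(shared) >= 10) {
      f1 <- a1$f_raw[match(shared, a1$gene_id)]
      f2 <- a2$f_raw[match(shared, a2$gene_id)]
      cor12 <- cor(f1, f2)
      mad12 <- median(abs(f1 - f2))
    }
  }
  list(f = fNorm, t = t, gmed = gmed, cor12 = cor12, mad12 = mad12)
}

.strainMeta <- function(counts, pool) {
  s <- pool@strains[match(rownames(counts), pool@strains$barcode), ,
                    drop = FALSE]
  if (any(is.na(s$barcode)))
    stop("counts contain barcodes absent from the pool")
  s$central <- !is.na(s$gene_id) & s$gene_fraction >= 0.1 &
    s$gene_fraction <= 0.9
  s
}

.makeGFM <- function(fMat, tMat, genome, colInfo, qc) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fitness = fMat, t = tMat),
    rowData = S4Vectors::DataFrame(genome@genes, row.names =
                                     genome@genes$gene_id),
    colData = S4Vectors::DataFrame(colInfo, row.names = colInfo$experiment))
  md <- S4Vectors::metadata(se)
  md$qc <- qc
  S4Vectors::metadata(se) <- md
  new("GeneFitnessMatrix", se)
}

#' Run the full fitness analysis
#'
#' For every condition sample: strain log2 ratios against the summed Time0
#' reference of its group, weighted gene fitness, running-median and mode
#' normalization, t statistics, and per-experiment QC (gmed: median summed
#' Time0 reads over genes with fitness; cor12/mad12: correlation and median
#' absolute difference between fitness recomputed from first-half vs
#' second-half insertions). Experiments failing QC are flagged, not
#' dropped.
#'
#' @param counts integer matrix, barcodes x samples.
#' @param pool the \linkS4class{InsertionPool}.
#' @param genome the \linkS4class{GenomeModel}.
#' @param design an \linkS4class{ExperimentDesign}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return a \linkS4class{GeneFitnessMatrix}; QC in
#'   \code{qcReport(result)}.
#' @export
runFitnessAnalysis <- function(counts, pool, genome, design,
                               config = analysisConfig()) {
  stopifnot(is(design, "ExperimentDesign"), is(genome, "GenomeModel"))
  validObject(design)
  des <- design@samples
  missing <- setdiff(des$sample, colnames(counts))
  if (length(missing))
    stop("counts lack sample(s): ", paste(missing, collapse = ", "))
  sm <- .strainMeta(counts, pool)
  refs <- .time0Reference(counts, des)
  condIdx <- which(des$role == "condition")
  if (!length(condIdx)) stop("design contains no condition samples")
  geneIds <- genome@genes$gene_id
  fMat <- matrix(NA_real_, length(geneIds), length(condIdx),
                 dimnames = list(geneIds, des$sample[condIdx]))
  tMat <- fMat
  qc <- data.frame(experiment = des$sample[condIdx], gmed = NA_real_,
                   cor12 = NA_real_, mad12 = NA_real_, pass = FALSE,
                   stringsAsFactors = FALSE)
  for (k in seq_along(condIdx)) {
    j <- condIdx[k]
    res <- .analyzeOneExperiment(counts[, des$sample[j]],
                                 refs[[des$time0_group[j]]],
                                 sm, genome, config)
    fMat[, k] <- res$f
    tMat[, k] <- res$t
    qc$gmed[k] <- res$gmed
    qc$cor12[k] <- res$cor12
    qc$mad12[k] <- res$mad12
  }
  qc$pass <- !is.na(qc$gmed) & qc$gmed >= config@qcMinGmed &
    !is.na(qc$cor12) & qc$cor12 >= config@qcMinCor12 &
    !is.na(qc$mad12) & qc$mad12 <= config@qcMaxMad12
  colInfo <- data.frame(experiment = des$sample[condIdx],
                        condition = des$condition[condIdx],
                        time0_group = des$time0_group[condIdx],
                        replicate = des$replicate[condIdx],
                        stringsAsFactors = FALSE)
  .makeGFM(fMat, tMat, genome, colInfo, qc)
}

#' Time0-versus-Time0 null comparisons
#'
#' Within each Time0 group with at least two Time0 samples, each Time0
#' sample in turn is treated as a condition and compared against the sum
#' of the remaining Time0 samples (leave-one-out). No biology separates
#' the two sides, so any significant phenotype here is a false positive;
#' the number of such genes, scaled to the number of condition
#' experiments, gives the empirical FDR of the significance thresholds
#' (see \code{\link{estimateFdr}}).
#'
#' @param counts integer matrix, barcodes x samples.
#' @param pool,genome,config as in \code{\link{runFitnessAnalysis}}.
#' @param design an \linkS4class{ExperimentDesign}; only its Time0 samples
#'   are used.
#' @return a \linkS4class{GeneFitnessMatrix} with one column per
#'   leave-one-out comparison.
#' @export
time0NullComparisons <- function(counts, pool, genome, design,
                                 config = analysisConfig()) {
  des <- design@samples
  t0 <- des[des$role == "Time0", , drop = FALSE]
  sm <- .strainMeta(counts, pool)
  geneIds <- genome@genes$gene_id
  fCols <- list(); tCols <- list(); info <- list()
  for (grp in unique(t0$time0_group)) {
    ss <- t0$sample[t0$time0_group == grp]
    if (length(ss) < 2) next
    for (i in seq_along(ss)) {
      rest <- ss[-i]
      nT0 <- if (length(rest) == 1) counts[, rest]
             else rowSums(counts[, rest, drop = FALSE])
      res <- .analyzeOneExperiment(counts[, ss[i]], nT0, sm, genome,
                                   config)
      id <- paste0(ss[i], "_vs_rest")
      fCols[[id]] <- res$f
      tCols[[id]] <- res$t
      info[[id]] <- data.frame(experiment = id, condition = "Time0null",
                               time0_group = grp, replicate = i,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(fCols))
    stop("no Time0 group with at least two Time0 samples")
  fMat <- do.call(cbind, fCols)
  tMat <- do.call(cbind, tCols)
  rownames(fMat) <- rownames(tMat) <- geneIds
  qc <- data.frame(experiment = names(fCols), gmed = NA_real_,
                   cor12 = NA_real_, mad12 = NA_real_, pass = NA,
                   stringsAsFactors = FALSE)
  .makeGFM(fMat, tMat, genome,
           as.data.frame(data.table::rbindlist(info)), qc)
}
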