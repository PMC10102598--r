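#' Analysis configuration
#'
#' Every tunable threshold of the pipeline in one validated object. The
#' defaults reproduce the analysis conventions of genome-wide RB-TnSeq
#' fitness screens: a pseudocount of 1 on both counts of each log2 ratio,
#' strain usability at >= 3 Time0 reads, gene fitness at >= 30 summed
#' usable-strain Time0 reads, a 251-gene centered running median for
#' copy-number normalization along the chromosome, a kernel-density mode
#' shift, a variance floor sigma0 = 0.1 for the t statistic, essentiality
#' at dens and normreads < 0.2, significant phenotypes at |fitness| > 0.5
#' and |t| > 4, specific phenotypes at |fitness| > 1, |t| > 5, |fitness| < 1
#' in >= 95\% of experiments and |fitness| exceeding the gene's 95th
#' percentile of |fitness| by 0.5, and cofitness at Pearson r >= 0.8.
#'
#' @param pseudocount pseudocount added to condition and Time0 counts.
#' @param minT0Reads minimum (summed) Time0 reads for a strain to be usable.
#' @param minGeneT0Reads minimum summed Time0 reads over a gene's usable
#'   strains for the gene to receive a fitness value.
#' @param windowSize running-median window, in genes; must be odd.
#' @param minRepliconGenes replicons with fewer scored genes than this use a
#'   plain median instead of a running median.
#' @param modeGridStep grid step for the kernel-density mode estimate.
#' @param sigma0 standard-deviation floor of the t statistic.
#' @param essThreshold essentiality threshold on dens and normreads.
#' @param minNonrepetitiveNt minimum non-repetitive nt for a gene to be
#'   analyzable for essentiality.
#' @param sigFitness,sigT significant-phenotype thresholds on |fitness|, |t|.
#' @param specFitness,specT specific-phenotype thresholds on |fitness|, |t|.
#' @param specFraction fraction of experiments in which |fitness| must stay
#'   below 1 for a specific phenotype.
#' @param specMargin margin over the 95th percentile of |fitness|.
#' @param minSpecificExperiments minimum non-NA experiments per gene for
#'   specific-phenotype calling.
#' @param cofitThreshold high-cofitness floor on Pearson r.
#' @param cofitMinOverlap minimum shared non-NA experiments per gene pair.
#' @param qcMinGmed,qcMinCor12,qcMaxMad12 per-experiment QC thresholds on
#'   the median gene Time0 reads, the first/second-half fitness correlation,
#'   and their median absolute difference.
#' @return an \code{AnalysisConfig} object.
#' @examples
#' cfg <- analysisConfig(windowSize = 51)
#' cfg@sigma0
#' @exportClass AnalysisConfig
#' @export
analysisConfig <- function(pseudocount = 1,
                           minT0Reads = 3,
                           minGeneT0Reads = 30,
                           windowSize = 251,
                           minRepliconGenes = 100,
                           modeGridStep = 0.01,
                           sigma0 = 0.1,
                           essThreshold = 0.2,
                           minNonrepetitiveNt = 100,
                           sigFitness = 0.5,
                           sigT = 4,
                           specFitness = 1,
                           specT = 5,
                           specFraction = 0.95,
                           specMargin = 0.5,
                           minSpecificExperiments = 20,
                           cofitThreshold = 0.8,
                           cofitMinOverlap = 50,
                           qcMinGmed = 50,
                           qcMinCor12 = 0.5,
                           qcMaxMad12 = 0.5) {
  new("AnalysisConfig",
      pseudocount = pseudocount, minT0Reads = minT0Reads,
      minGeneT0Reads = minGeneT0Reads, windowSize = as.integer(windowSize),
      minRepliconGenes = as.integer(minRepliconGenes),
      modeGridStep = modeGridStep, sigma0 = sigma0,
      essThreshold = essThreshold,
      minNonrepetitiveNt = as.integer(minNonrepetitiveNt),
      sigFitness = sigFitness, sigT = sigT, specFitness = specFitness,
      specT = specT, specFraction = specFraction, specMargin = specMargin,
      minSpecificExperiments = as.integer(minSpecificExperiments),
      cofitThreshold = cofitThreshold,
      cofitMinOverlap = as.integer(cofitMinOverlap),
      qcMinGmed = qcMinGmed, qcMinCor12 = qcMinCor12,
      qcMaxMad12 = qcMaxMad12)
}

setClass("AnalysisConfig", slots = c(
  pseudocount = "numeric", minT0Reads = "numeric",
  minGeneT0Reads = "numeric", windowSize = "integer",
  minRepliconGenes = "integer", modeGridStep = "numeric",
  sigma0 = "numeric", essThreshold = "numeric",
  minNonrepetitiveNt = "integer", sigFitness = "numeric", sigT = "numeric",
  specFitness = "numeric", specT = "numeric", specFraction = "numeric",
  specMargin = "numeric", minSpecificExperiments = "integer",
  cofitThreshold = "numeric", cofitMinOverlap = "integer",
  qcMinGmed = "numeric", qcMinCor12 = "numeric", qcMaxMad12 = "numeric"))

setValidity("AnalysisConfig", function(object) {
  msgs <- character()
  if (object@windowSize %% 2L == 0L)
    msgs <- c(msgs, "windowSize must be odd")
  pos <- c("pseudocount", "minT0Reads", "minGeneT0Reads", "modeGridStep",
           "sigma0", "essThreshold", "sigFitness", "sigT", "specFitness",
           "specT", "specFraction", "specMargin", "cofitThreshold")
  for (s in pos)
    if (slot(object, s) <= 0) msgs <- c(msgs, paste(s, "must be positive"))
  if (object@specFraction > 1)
    msgs <- c(msgs, "specFraction must be in (0,1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn analysisConfig turn a named list (e.g. parsed from a JSON
#'   config file) into an \code{AnalysisConfig}, starting from defaults.
#' @param overrides named list of fields to override.
#' @export
configFromList <- function(overrides = list()) {
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysisConfig, overrides)
}

#' @describeIn analysisConfig snapshot a config as a named list (used in
#'   run manifests).
#' @param config an \code{AnalysisConfig}.
#' @export
configAsList <- function(config) {
  nm <- slotNames("AnalysisConfig")
  setNames(lapply(nm, function(s) slot(config, s)), nm)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig (|fitness| >", object@sigFitness, ", |t| >",
      object@sigT, "for significance; essentiality <",
      object@essThreshold, ")\n")
})
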