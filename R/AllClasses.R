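#' @import methods
#' @importFrom stats median quantile rbinom rgamma rlnorm rmultinom rnbinom
#'   rnorm runif rexp cor sd dnorm bw.nrd0 setNames
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata DataFrame
NULL

.validStrand <- function(x) all(x %in% c("+", "-"))

#' Genome model for a barcoded transposon library
#'
#' Holds the replicon layout (typically a main chromosome plus a plasmid)
#' and a gene table with 1-based inclusive coordinates, per-gene GC fraction
#' and the number of non-repetitive nucleotides (insertions in repeats
#' cannot be mapped unambiguously, so essentiality statistics are restricted
#' to genes with at least 100 non-repetitive nt).
#'
#' @slot replicons data.frame with columns \code{replicon}, \code{length}
#'   (nt), \code{is_main} (logical; at most one \code{TRUE}).
#' @slot genes data.frame with columns \code{gene_id}, \code{replicon},
#'   \code{begin}, \code{end} (1-based inclusive), \code{strand}
#'   (\code{+}/\code{-}), \code{gc} (fraction in [0,1]),
#'   \code{nonrepetitive_nt}, \code{desc}.
#'
#' @exportClass GenomeModel
setClass("GenomeModel",
  slots = c(replicons = "data.frame", genes = "data.frame"))

setValidity("GenomeModel", function(object) {
  rep <- object@replicons
  g <- object@genes
  msgs <- character()
  need <- c("replicon", "length", "is_main")
  if (!all(need %in% names(rep)))
    return(paste("replicons must have columns:", paste(need, collapse = ", ")))
  needg <- c("gene_id", "replicon", "begin", "end", "strand", "gc",
             "nonrepetitive_nt", "desc")
  if (!all(needg %in% names(g)))
    return(paste("genes must have columns:", paste(needg, collapse = ", ")))
  if (anyDuplicated(rep$replicon)) msgs <- c(msgs, "duplicate replicon ids")
  if (sum(rep$is_main) > 1)
    msgs <- c(msgs, "more than one replicon flagged as main chromosome")
  if (nrow(g)) {
    if (anyDuplicated(g$gene_id)) msgs <- c(msgs, "duplicate gene_ids")
    if (!all(g$replicon %in% rep$replicon))
      msgs <- c(msgs, "gene on unknown replicon")
    if (any(g$begin > g$end)) msgs <- c(msgs, "gene with begin > end")
    if (any(g$begin < 1)) msgs <- c(msgs, "gene begin < 1")
    rlen <- setNames(rep$length, rep$replicon)
    if (any(g$end > rlen[g$replicon]))
      msgs <- c(msgs, "gene extends past replicon end")
    if (!.validStrand(g$strand)) msgs <- c(msgs, "strand must be + or -")
    if (any(g$gc < 0 | g$gc > 1)) msgs <- c(msgs, "gc outside [0,1]")
    if (any(g$nonrepetitive_nt < 0 |
            g$nonrepetitive_nt > g$end - g$begin + 1))
      msgs <- c(msgs, "nonrepetitive_nt outside [0, gene length]")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Ground truth of a simulated library
#'
#' Bookkeeping for simulations: which genes were planted as essential, the
#' true expected fitness (final normalized log2 ratio) per gene and
#' condition, module labels used to plant cofitness structure, and the set
#' of planted condition-specific effects. Essential genes carry \code{NA}
#' true fitness: no viable central-insertion mutants exist for them.
#'
#' @slot essential named logical vector over gene_ids.
#' @slot fTrue numeric matrix, genes x conditions (0 columns until effects
#'   are planted with \code{\link{plantEffects}}).
#' @slot modules named character vector over gene_ids (\code{NA} = none).
#' @slot specific data.frame with columns \code{gene_id}, \code{condition}.
#'
#' @exportClass SimTruth
setClass("SimTruth",
  slots = c(essential = "logical", fTrue = "matrix", modules = "character",
            specific = "data.frame"))

setValidity("SimTruth", function(object) {
  msgs <- character()
  if (is.null(names(object@essential))) return("essential must be named")
  if (ncol(object@fTrue) > 0) {
    if (!identical(rownames(object@fTrue), names(object@essential)))
      msgs <- c(msgs, "fTrue rows must match essential gene_ids")
    ess <- object@essential
    if (any(!is.na(object@fTrue[ess, , drop = FALSE])))
      msgs <- c(msgs, "essential genes must have NA fTrue")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Barcoded transposon insertion pool
#'
#' One row per mutant strain: a unique DNA barcode linked by Tn-seq to an
#' insertion position, plus the number of Tn-seq reads supporting the
#' mapping. \code{gene_id} and \code{gene_fraction} (position within the
#' gene, computed on the + coordinate direction regardless of gene strand)
#' are filled in by \code{\link{mapStrainsToGenes}}; insertions in the
#' central 10--90\% of a gene are assumed to disrupt it.
#'
#' @slot strains data.frame with columns \code{barcode}, \code{replicon},
#'   \code{strand}, \code{pos}, \code{n_reads}, \code{gene_id},
#'   \code{gene_fraction}.
#'
#' @exportClass InsertionPool
setClass("InsertionPool", slots = c(strains = "data.frame"))

setValidity("InsertionPool", function(object) {
  s <- object@strains
  need <- c("barcode", "replicon", "strand", "pos", "n_reads",
            "gene_id", "gene_fraction")
  if (!all(need %in% names(s)))
    return(paste("strains must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(s)) {
    if (anyDuplicated(s$barcode)) msgs <- c(msgs, "duplicate barcodes")
    if (!.validStrand(s$strand)) msgs <- c(msgs, "strand must be + or -")
    if (any(s$pos < 1)) msgs <- c(msgs, "position < 1")
    if (any(s$n_reads < 0)) msgs <- c(msgs, "negative n_reads")
    if (any(is.na(s$gene_id) != is.na(s$gene_fraction)))
      msgs <- c(msgs, "gene_fraction must be defined iff gene_id is")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Experiment design for pooled fitness assays
#'
#' Assigns each BarSeq sample a role: \code{Time0} (aliquot of the pool
#' before growth selection) or \code{condition} (after 4--6 population
#' doublings under selection). Condition samples are compared against the
#' summed Time0 samples of their \code{time0_group}.
#'
#' @slot samples data.frame with columns \code{sample}, \code{role},
#'   \code{time0_group}, \code{condition}, \code{replicate}.
#'
#' @exportClass ExperimentDesign
setClass("ExperimentDesign", slots = c(samples = "data.frame"))

setValidity("ExperimentDesign", function(object) {
  s <- object@samples
  need <- c("sample", "role", "time0_group", "condition", "replicate")
  if (!all(need %in% names(s)))
    return(paste("samples must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(s$sample)) msgs <- c(msgs, "duplicate sample ids")
  if (!all(s$role %in% c("Time0", "condition")))
    msgs <- c(msgs, "role must be Time0 or condition")
  cond <- s[s$role == "condition", , drop = FALSE]
  t0groups <- unique(s$time0_group[s$role == "Time0"])
  bad <- setdiff(unique(cond$time0_group), t0groups)
  if (length(bad))
    msgs <- c(msgs, paste0("condition samples reference Time0 group(s) ",
                           "with no Time0 sample: ",
                           paste(bad, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Gene x experiment fitness matrix
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{fitness}
#' (normalized log2 gene fitness) and \code{t} (t-like significance
#' statistic), one row per gene and one column per condition experiment.
#' Genes whose mutants lacked sufficient Time0 abundance are \code{NA} in
#' both assays. Per-experiment quality control lives in
#' \code{metadata(x)$qc} (see \code{\link{qcReport}}).
#'
#' @exportClass GeneFitnessMatrix
setClass("GeneFitnessMatrix", contains = "SummarizedExperiment")

setValidity("GeneFitnessMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("fitness", "t") %in% an))
    return("assays 'fitness' and 't' are required")
  f <- SummarizedExperiment::assay(object, "fitness")
  t <- SummarizedExperiment::assay(object, "t")
  if (!identical(is.na(f), is.na(t)))
    return("fitness and t must share the same NA mask")
  TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", nrow(object@genes), "genes on",
      nrow(object@replicons), "replicon(s)\n")
  for (i in seq_len(nrow(object@replicons))) {
    r <- object@replicons[i, ]
    cat(sprintf("  %s: %d nt%s, %d genes\n", r$replicon, r$length,
                if (isTRUE(r$is_main)) " (main chromosome)" else "",
                sum(object@genes$replicon == r$replicon)))
  }
})

setMethod("show", "InsertionPool", function(object) {
  s <- object@strains
  cat("InsertionPool:", nrow(s), "barcoded strains;",
      sum(!is.na(s$gene_id)), "within genes\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@essential), "genes,",
      sum(object@essential), "essential,",
      ncol(object@fTrue), "condition(s) with planted effects\n")
})

setMethod("show", "ExperimentDesign", function(object) {
  s <- object@samples
  cat("ExperimentDesign:", nrow(s), "samples (",
      sum(s$role == "Time0"), "Time0,",
      sum(s$role == "condition"), "condition )\n")
})
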