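#' Accessors for rbtnseq data objects
#'
#' Plain-data views of the S4 containers: the gene and replicon tables of a
#' \linkS4class{GenomeModel}, the strain table of an
#' \linkS4class{InsertionPool}, the sample table of an
#' \linkS4class{ExperimentDesign}, and the fitness/t assays and QC table of
#' a \linkS4class{GeneFitnessMatrix}.
#'
#' @param x the object.
#' @return \code{geneTable}, \code{repliconTable}, \code{poolStrains},
#'   \code{designTable} and \code{qcReport} return data.frames;
#'   \code{fitnessScores} and \code{tScores} return numeric matrices
#'   (genes x experiments, \code{NA} where the gene had insufficient Time0
#'   abundance); \code{essentialGenes} returns a named logical vector;
#'   \code{trueFitness} returns the planted gene x condition effect matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setMethod("geneTable", "GenomeModel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("repliconTable", function(x) standardGeneric("repliconTable"))
#' @rdname accessors
#' @export
setMethod("repliconTable", "GenomeModel", function(x) x@replicons)

#' @rdname accessors
#' @export
setGeneric("poolStrains", function(x) standardGeneric("poolStrains"))
#' @rdname accessors
#' @export
setMethod("poolStrains", "InsertionPool", function(x) x@strains)

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setMethod("designTable", "ExperimentDesign", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("essentialGenes", function(x) standardGeneric("essentialGenes"))
#' @rdname accessors
#' @export
setMethod("essentialGenes", "SimTruth", function(x) x@essential)

#' @rdname accessors
#' @export
setGeneric("trueFitness", function(x) standardGeneric("trueFitness"))
#' @rdname accessors
#' @export
setMethod("trueFitness", "SimTruth", function(x) x@fTrue)

#' @rdname accessors
#' @export
setGeneric("geneModules", function(x) standardGeneric("geneModules"))
#' @rdname accessors
#' @export
setMethod("geneModules", "SimTruth", function(x) x@modules)

#' @rdname accessors
#' @export
setGeneric("specificTruth", function(x) standardGeneric("specificTruth"))
#' @rdname accessors
#' @export
setMethod("specificTruth", "SimTruth", function(x) x@specific)

#' @rdname accessors
#' @export
setGeneric("fitnessScores", function(x) standardGeneric("fitnessScores"))
#' @rdname accessors
#' @export
setMethod("fitnessScores", "GeneFitnessMatrix",
  function(x) SummarizedExperiment::assay(x, "fitness"))

#' @rdname accessors
#' @export
setGeneric("tScores", function(x) standardGeneric("tScores"))
#' @rdname accessors
#' @export
setMethod("tScores", "GeneFitnessMatrix",
  function(x) SummarizedExperiment::assay(x, "t"))

#' @rdname accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))
#' @rdname accessors
#' @export
setMethod("qcReport", "GeneFitnessMatrix",
  function(x) S4Vectors::metadata(x)$qc)

#' Which genes have fitness estimates
#'
#' A gene has fitness in an experiment when its usable strains carried
#' sufficient summed Time0 reads. Returns, per gene, whether a fitness
#' value exists in at least one experiment; this flag is the
#' \code{has_fitness} input of \code{\link{callEssentiality}} (a gene whose
#' mutants are measurably present at Time0 is not called essential however
#' sparse its insertion statistics).
#'
#' @param x a \linkS4class{GeneFitnessMatrix}.
#' @return named logical vector over genes.
#' @export
fitnessAvailability <- function(x) {
  stopifnot(is(x, "GeneFitnessMatrix"))
  f <- fitnessScores(x)
  apply(!is.na(f), 1, any)
}
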