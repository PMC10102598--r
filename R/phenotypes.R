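# Downstream phenotype analytics on the gene x experiment fitness matrix:
# significant phenotypes, a Time0-based empirical FDR, condition-specific
# phenotypes, and the cofitness network.

#' Significant phenotypes
#'
#' A (gene, experiment) pair has a significant phenotype when
#' \code{|fitness| > 0.5} and \code{|t| > 4} (defaults). Returns the
#' per-cell calls plus a per-gene summary of whether the gene is
#' significant in at least one experiment.
#'
#' @param matrix a \linkS4class{GeneFitnessMatrix}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{calls} (data.frame gene_id, experiment, f, t,
#'   significant; NA cells omitted) and \code{geneSummary} (data.frame
#'   gene_id, n_significant, any_significant).
#' @export
significantPhenotypes <- function(matrix, config = analysisConfig()) {
  stopifnot(is(matrix, "GeneFitnessMatrix"))
  f <- fitnessScores(matrix)
  t <- tScores(matrix)
  sig <- abs(f) > config@sigFitness & abs(t) > config@sigT
  keep <- which(!is.na(f), arr.ind = TRUE)
  calls <- data.frame(gene_id = rownames(f)[keep[, 1]],
                      experiment = colnames(f)[keep[, 2]],
                      f = f[keep], t = t[keep],
                      significant = sig[keep], stringsAsFactors = FALSE)
  nSig <- rowSums(sig, na.rm = TRUE)
  geneSummary <- data.frame(gene_id = rownames(f), n_significant = nSig,
                            any_significant = nSig > 0,
                            stringsAsFactors = FALSE)
  list(calls = calls, geneSummary = geneSummary)
}

#' Empirical FDR for significant-phenotype gene calls from Time0 nulls
#'
#' Time0-vs-Time0 comparisons share no biological signal, so genes called
#' significant there are false positives. Scaling their count to the
#' number of condition experiments gives the expected number of
#' false-positive genes among the real calls:
#' \code{expected_fp = round(n_fp_time0 * n_condition_experiments /
#' n_time0_comparisons)}, and \code{fdr = expected_fp /
#' n_significant_genes}.
#'
#' @param nFpTime0 genes with a significant phenotype across the Time0
#'   comparisons.
#' @param nTime0Comparisons number of Time0-vs-Time0 comparisons (>= 1).
#' @param nConditionExperiments number of condition experiments.
#' @param nSignificantGenes genes with a significant phenotype in at least
#'   one condition experiment (>= 1).
#' @return list with fields \code{n_fp_time0}, \code{n_time0_comparisons},
#'   \code{n_condition_experiments}, \code{n_significant_genes},
#'   \code{expected_fp}, \code{fdr}.
#' @examples
#' est <- estimateFdr(4, 83, 757, 1137)
#' est$expected_fp  # 36
#' round(100 * est$fdr)  # 3 (percent)
#' @export
estimateFdr <- function(nFpTime0, nTime0Comparisons, nConditionExperiments,
                        nSignificantGenes) {
  args <- c(nFpTime0, nTime0Comparisons, nConditionExperiments,
            nSignificantGenes)
  if (any(args < 0)) stop("counts must be non-negative")
  if (nTime0Comparisons < 1) stop("need at least one Time0 comparison")
  if (nSignificantGenes < 1) stop("need at least one significant gene")
  expectedFp <- round(nFpTime0 * nConditionExperiments / nTime0Comparisons)
  list(n_fp_time0 = nFpTime0, n_time0_comparisons = nTime0Comparisons,
       n_condition_experiments = nConditionExperiments,
       n_significant_genes = nSignificantGenes,
       expected_fp = expectedFp, fdr = expectedFp / nSignificantGenes)
}

#' Condition-specific phenotypes
#'
#' A gene has a specific phenotype in an experiment when the effect is
#' strong (\code{|f| > 1}, \code{|t| > 5}), the gene is near-neutral
#' elsewhere (\code{|f| < 1} in at least 95\% of its non-NA experiments),
#' and the effect stands out from the gene's own profile
#' (\code{|f| > 95th percentile of its |f| values + 0.5}; percentile by
#' linear interpolation between order statistics). Genes with fewer than
#' \code{minSpecificExperiments} non-NA experiments are skipped.
#'
#' @param matrix a \linkS4class{GeneFitnessMatrix}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame: \code{gene_id}, \code{experiment}, \code{f},
#'   \code{t}, \code{pct95_abs_f}.
#' @export
specificPhenotypes <- function(matrix, config = analysisConfig()) {
  stopifnot(is(matrix, "GeneFitnessMatrix"))
  f <- fitnessScores(matrix)
  t <- tScores(matrix)
  out <- list()
  for (i in seq_len(nrow(f))) {
    fi <- f[i, ]
    ok <- !is.na(fi)
    if (sum(ok) < config@minSpecificExperiments) next
    absf <- abs(fi[ok])
    fracBelow <- mean(absf < config@specFitness)
    if (fracBelow < config@specFraction) next
    p95 <- quantile(absf, 0.95, type = 7, names = FALSE)
    hit <- ok & abs(fi) > config@specFitness &
      abs(t[i, ]) > config@specT &
      abs(fi) > p95 + config@specMargin
    if (any(hit, na.rm = TRUE)) {
      j <- which(hit)
      out[[length(out) + 1]] <- data.frame(
        gene_id = rownames(f)[i], experiment = colnames(f)[j],
        f = fi[j], t = t[i, j], pct95_abs_f = p95,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), experiment = character(),
                      f = numeric(), t = numeric(),
                      pct95_abs_f = numeric(), stringsAsFactors = FALSE))
  as.data.frame(data.table::rbindlist(out))
}

#' Cofitness: correlated fitness profiles between genes
#'
#' Pearson correlation of two genes' fitness values over their shared
#' non-NA experiments (pairwise-complete). Genes sharing an operon,
#' pathway or complex tend to have correlated profiles; pairs with
#' \code{r >= 0.8} are flagged as high cofitness. Pairs with fewer than
#' \code{cofitMinOverlap} shared experiments (or fewer than the total
#' number of experiments when that is smaller) are suppressed, as are
#' pairs involving a zero-variance profile.
#'
#' @param matrix a \linkS4class{GeneFitnessMatrix}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param reportFloor report pairs with \code{r >=} this value (default:
#'   the high-cofitness threshold).
#' @return list with \code{pairs} (data.frame gene_a, gene_b, r,
#'   n_overlap, high_cofit; each unordered pair once, gene_a < gene_b) and
#'   \code{topCofit} (data.frame gene_id, partner, r: each gene's
#'   maximum-r partner among pairs passing the overlap rule).
#' @export
cofitness <- function(matrix, config = analysisConfig(),
                      reportFloor = config@cofitThreshold) {
  stopifnot(is(matrix, "GeneFitnessMatrix"))
  f <- fitnessScores(matrix)
  minOv <- min(config@cofitMinOverlap, ncol(f))
  scored <- rowSums(!is.na(f)) >= 2
  f <- f[scored, , drop = FALSE]
  vars <- apply(f, 1, function(x) stats::var(x, na.rm = TRUE))
  keep <- !is.na(vars) & vars > 0
  dropped <- rownames(f)[!keep]
  if (length(dropped))
    message(length(dropped), " zero-variance gene profile(s) excluded ",
            "from cofitness")
  f <- f[keep, , drop = FALSE]
  if (nrow(f) < 2)
    return(list(pairs = data.frame(gene_a = character(),
                                   gene_b = character(), r = numeric(),
                                   n_overlap = integer(),
                                   high_cofit = logical()),
                topCofit = data.frame(gene_id = character(),
                                      partner = character(),
                                      r = numeric())))
  cc <- suppressWarnings(cor(t(f), use = "pairwise.complete.obs"))
  notNa <- !is.na(f)
  nOv <- notNa %*% t(notNa)
  cc[nOv < minOv] <- NA
  diag(cc) <- NA
  # per-gene best partner over all valid pairs
  best <- apply(cc, 1, function(x)
    if (all(is.na(x))) NA_integer_ else which.max(x))
  topCofit <- data.frame(
    gene_id = rownames(cc), partner = colnames(cc)[best],
    r = cc[cbind(seq_len(nrow(cc)), best)], stringsAsFactors = FALSE)
  topCofit <- topCofit[!is.na(topCofit$partner), , drop = FALSE]
  hi <- which(upper.tri(cc) & !is.na(cc) & cc >= reportFloor,
              arr.ind = TRUE)
  pairs <- data.frame(gene_a = rownames(cc)[hi[, 1]],
                      gene_b = colnames(cc)[hi[, 2]],
                      r = cc[hi], n_overlap = as.integer(nOv[hi]),
                      stringsAsFactors = FALSE)
  pairs$high_cofit <- pairs$r >= config@cofitThreshold
  pairs <- pairs[order(-pairs$r), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, topCofit = topCofit)
}
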