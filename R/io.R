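# Stable TSV formats for all pipeline tables. All files are
# tab-separated with a header row, UTF-8, optionally gzipped; coordinates
# are 1-based inclusive everywhere; missing values in matrices are the
# literal "NA". Readers validate and reject, never silently coerce.

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (endsWith(path, ".gz")) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- paste(readLines(con), collapse = "\n")
    return(as.data.frame(data.table::fread(text = txt, sep = "\t",
                                           header = TRUE,
                                           na.strings = "NA")))
  }
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA",
                                  stringsAsFactors = FALSE))
}

.requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " file is missing required column(s): ",
         paste(miss, collapse = ", "))
}

.checkCounts <- function(df, what) {
  for (col in names(df)) {
    x <- df[[col]]
    if (!is.numeric(x) || any(is.na(x)) || any(x != floor(x)))
      stop(what, ": column '", col, "' contains a non-integer count (row ",
           which(is.na(x) | x != floor(x))[1], ")")
    if (any(x < 0))
      stop(what, ": negative count in column '", col, "' (row ",
           which(x < 0)[1], ")")
  }
}

#' Read and write pipeline tables
#'
#' Fixed tab-separated formats. \code{genes}: gene_id, replicon, begin,
#' end, strand, gc, nonrepetitive_nt, desc -- with an optional companion
#' replicons table (replicon, length, is_main); absent that, replicon
#' lengths are inferred from the maximum gene end and the replicon with
#' most genes is taken as the main chromosome. \code{pool}: barcode,
#' replicon, strand, pos, n_reads (gene assignments are recomputed from
#' the genome with \code{\link{mapStrainsToGenes}}). \code{counts}:
#' barcode, then one column per sample. \code{design}: sample, role,
#' time0_group, condition, replicate. Gzipped files are handled
#' transparently.
#'
#' @param path file path (.tsv or .tsv.gz).
#' @param repliconsPath optional path to the replicons table.
#' @param genome,pool,counts,design,x objects to write.
#' @param dir output directory for multi-file writers.
#' @return readers return the corresponding S4 object (counts: an integer
#'   matrix with barcode rownames); writers return the path(s) invisibly.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
readGenes <- function(path, repliconsPath = NULL) {
  g <- .readTsv(path)
  .requireColumns(g, c("gene_id", "replicon", "begin", "end", "strand",
                       "gc", "nonrepetitive_nt", "desc"), "genes")
  if (any(g$end < g$begin))
    stop("genes file: end < begin at row ", which(g$end < g$begin)[1])
  if (!is.null(repliconsPath)) {
    rep <- .readTsv(repliconsPath)
    .requireColumns(rep, c("replicon", "length", "is_main"), "replicons")
    rep$is_main <- as.logical(rep$is_main)
  } else {
    tab <- sort(table(g$replicon), decreasing = TRUE)
    rep <- data.frame(replicon = names(tab),
                      length = as.integer(tapply(g$end, g$replicon,
                                                 max)[names(tab)]),
                      is_main = seq_along(tab) == 1,
                      stringsAsFactors = FALSE)
    message("no replicons table given; inferred lengths from gene ",
            "coordinates and flagged '", rep$replicon[1],
            "' as the main chromosome")
  }
  new("GenomeModel", replicons = rep, genes = g)
}

#' @rdname tsv_io
#' @export
writeGenome <- function(genome, path, repliconsPath = NULL) {
  stopifnot(is(genome, "GenomeModel"))
  data.table::fwrite(genome@genes, path, sep = "\t", na = "NA",
                     quote = FALSE)
  if (!is.null(repliconsPath))
    data.table::fwrite(genome@replicons, repliconsPath, sep = "\t",
                       quote = FALSE)
  invisible(c(path, repliconsPath))
}

#' @rdname tsv_io
#' @export
readPool <- function(path) {
  p <- .readTsv(path)
  .requireColumns(p, c("barcode", "replicon", "strand", "pos", "n_reads"),
                  "pool")
  if (anyDuplicated(p$barcode))
    stop("pool file: duplicate barcode '",
         p$barcode[duplicated(p$barcode)][1], "'")
  .checkCounts(p["n_reads"], "pool")
  if (any(p$pos < 1))
    stop("pool file: position < 1 at row ", which(p$pos < 1)[1])
  if (!.validStrand(p$strand)) stop("pool file: strand must be + or -")
  p$gene_id <- NA_character_
  p$gene_fraction <- NA_real_
  new("InsertionPool",
      strains = p[, c("barcode", "replicon", "strand", "pos", "n_reads",
                      "gene_id", "gene_fraction")])
}

#' @rdname tsv_io
#' @export
writePool <- function(pool, path) {
  stopifnot(is(pool, "InsertionPool"))
  data.table::fwrite(pool@strains[, c("barcode", "replicon", "strand",
                                      "pos", "n_reads")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
readCounts <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, "barcode", "counts")
  if (anyDuplicated(df$barcode))
    stop("counts file: duplicate barcode '",
         df$barcode[duplicated(df$barcode)][1], "'")
  samples <- setdiff(names(df), "barcode")
  if (anyDuplicated(samples)) stop("counts file: duplicate sample ids")
  .checkCounts(df[samples], "counts")
  m <- as.matrix(df[samples])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  m
}

#' @rdname tsv_io
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
readDesign <- function(path) {
  d <- .readTsv(path)
  .requireColumns(d, c("sample", "role", "time0_group", "condition",
                       "replicate"), "design")
  new("ExperimentDesign", samples = d)
}

#' @rdname tsv_io
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "ExperimentDesign"))
  data.table::fwrite(design@samples, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
writeFitnessMatrix <- function(x, dir) {
  stopifnot(is(x, "GeneFitnessMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wmat <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  }
  paths <- file.path(dir, c("fit_logratios.tsv", "fit_t.tsv", "qc.tsv"))
  wmat(fitnessScores(x), paths[1])
  wmat(tScores(x), paths[2])
  data.table::fwrite(qcReport(x), paths[3], sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(paths)
}

#' @rdname tsv_io
#' @export
readFitnessMatrix <- function(dir, genome) {
  rmat <- function(path) {
    df <- .readTsv(path)
    m <- as.matrix(df[setdiff(names(df), "gene_id")])
    rownames(m) <- df$gene_id
    m
  }
  f <- rmat(file.path(dir, "fit_logratios.tsv"))
  t <- rmat(file.path(dir, "fit_t.tsv"))
  qc <- .readTsv(file.path(dir, "qc.tsv"))
  colInfo <- data.frame(experiment = colnames(f),
                        condition = NA_character_,
                        time0_group = NA_character_,
                        replicate = NA_integer_, stringsAsFactors = FALSE)
  .makeGFM(f, t, genome, colInfo, qc)
}
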