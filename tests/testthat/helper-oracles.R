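# Independent brute-force oracles, deliberately naive: per-gene loops and
# explicit formulas, no shared code with the package internals.

# per-gene dens/normreads recomputation
bruteStats <- function(pool, genome, minNonrep = 100) {
  g <- geneTable(genome)
  s <- poolStrains(mapStrainsToGenes(pool, genome))
  n <- nrow(g)
  nPos <- numeric(n); reads <- numeric(n)
  for (i in seq_len(n)) {
    len <- g$end[i] - g$begin[i] + 1
    inGene <- !is.na(s$gene_id) & s$gene_id == g$gene_id[i]
    frac <- (s$pos[inGene] - g$begin[i] + 1) / len
    central <- frac >= 0.1 & frac <= 0.9
    nPos[i] <- length(unique(s$pos[inGene][central]))
    reads[i] <- sum(s$n_reads[inGene][central])
  }
  ana <- g$nonrepetitive_nt >= minNonrep
  rawDens <- ifelse(ana, nPos / g$nonrepetitive_nt, NA)
  rawRpk <- ifelse(ana, reads / (g$nonrepetitive_nt / 1000), NA)
  dens <- rawDens / median(rawDens[ana])
  # same bin convention as the pipeline (a stated design choice); the
  # median and scaling arithmetic below is independent
  bins <- findInterval(g$gc, seq(0, 1, by = 0.05), rightmost.closed = TRUE)
  globalMed <- median(rawRpk[ana])
  corr <- rep(NA_real_, n)
  for (b in unique(bins[ana])) {
    sel <- ana & bins == b
    m <- if (sum(sel) >= 10) median(rawRpk[sel]) else globalMed
    if (m == 0) m <- globalMed
    corr[sel] <- rawRpk[sel] / m
  }
  list(dens = dens, normreads = corr / median(corr[ana]))
}

# t statistic straight from the stated variance model
bruteT <- function(f, ratios, weights, sigma0 = 0.1) {
  n <- length(ratios)
  fRaw <- sum(weights * ratios) / sum(weights)
  vcount <- 1 / sum(weights)
  if (n > 1) {
    wvar <- sum(weights * (ratios - fRaw)^2) / sum(weights) * n / (n - 1)
    vg <- max(vcount, wvar / n)
  } else vg <- vcount
  f / sqrt(sigma0^2 + vg)
}

brutePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
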