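# Shared fixtures and independent oracles.
# Oracles are deliberately coded by a different route than the package
# (explicit sums, svd instead of eigen, all-pairs loops) so agreement is a
# genuine cross-check.

# small random dataset with optional missingness
random_dataset <- function(n1 = 6, n2 = 8, m = 12, n_chrom = 2,
                           missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    chrom <- sort(rep_len(seq_len(n_chrom), m))
    pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
      sort(sample.int(1e6, length(i)))), use.names = FALSE)
    map <- data.frame(
      snp_id = sprintf("rs%03d", seq_len(m)),
      chromosome = chrom, position_bp = pos,
      allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
    d <- matrix(sample(0:2, (n1 + n2) * m, replace = TRUE), n1 + n2, m)
    if (missing_rate > 0) d[runif(length(d)) < missing_rate] <- NA
    rownames(d) <- sprintf("ind_%02d", seq_len(n1 + n2))
    genotype_dataset(map, d, rep(c("A_pop", "B_pop"), c(n1, n2)))
  })
}

# dataset built from explicit per-population dosage columns (one chromosome)
dataset_from_dosages <- function(d1, d2, positions = NULL) {
  d <- rbind(d1, d2)
  m <- ncol(d)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  map <- data.frame(snp_id = sprintf("rs%03d", seq_len(m)),
                    chromosome = 1L, position_bp = positions,
                    allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  rownames(d) <- sprintf("ind_%02d", seq_len(nrow(d)))
  genotype_dataset(map, d, rep(c("A_pop", "B_pop"),
                               c(nrow(d1), nrow(d2))))
}

# brute-force Fst from raw genotype counts, straight from the printed
# equations (independent of fst_per_snp's vectorized path)
oracle_fst <- function(dos1, dos2) {
  n1 <- length(dos1); n2 <- length(dos2)
  f1 <- sum(dos1) / (2 * n1)
  f2 <- sum(dos2) / (2 * n2)
  fp <- (f1 * (2 * n1) + f2 * (2 * n2)) / (2 * (n1 + n2))
  ht <- 2 * fp * (1 - fp)
  hs <- (2 * n1 / (2 * n1 + 2 * n2)) * 2 * f1 * (1 - f1) +
    (2 * n2 / (2 * n1 + 2 * n2)) * 2 * f2 * (1 - f2)
  if (ht == 0) return(NA_real_)
  (ht - hs) / ht
}

# brute-force tricube weighted least squares at every point, via lm()
oracle_lowess <- function(x, y, window, degree = 1) {
  n <- length(x)
  q <- max(min(window, n), degree + 2)
  vapply(seq_len(n), function(i) {
    d_all <- abs(x - x[i])
    idx <- order(d_all)[seq_len(q)]   # nearest q points
    h <- max(d_all[idx])
    w <- if (h > 0) (1 - pmin(d_all[idx] / h, 1)^3)^3 else rep(1, q)
    df <- data.frame(xx = x[idx] - x[i], yy = y[idx])
    if (degree == 0 || h == 0) return(sum(w * df$yy) / sum(w))
    fit <- stats::lm(yy ~ stats::poly(xx, degree, raw = TRUE), data = df,
                     weights = w)
    unname(stats::predict(fit, newdata = data.frame(xx = 0)))
  }, numeric(1))
}

# eigenvalues through svd (PSD correlation matrices), not eigen()
oracle_spectrum <- function(C) {
  sort(svd(C)$d, decreasing = TRUE)
}

oracle_varld_raw <- function(A, B) {
  sum(abs(oracle_spectrum(A) - oracle_spectrum(B)))
}

# Pearson correlation from explicit sums
oracle_cor <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  num <- n * sum(a * b) - sa * sb
  den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
  num / den
}

# all-pairs closed-interval gene/interval intersection
oracle_overlaps <- function(intervals, genes) {
  hits <- list()
  for (i in seq_len(nrow(intervals))) {
    for (g in seq_len(nrow(genes))) {
      if (intervals$chromosome[i] != genes$chromosome[g]) next
      lo <- max(intervals$start_bp[i], genes$start_bp[g])
      hi <- min(intervals$end_bp[i], genes$end_bp[g])
      if (lo <= hi) {
        hits[[length(hits) + 1]] <- data.frame(
          interval = i, gene = genes$gene_id[g], overlap_bp = hi - lo + 1)
      }
    }
  }
  if (length(hits) == 0) return(data.frame(interval = integer(0),
                                           gene = character(0),
                                           overlap_bp = integer(0)))
  do.call(rbind, hits)
}

# write a minimal GFF3 gene file
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$chromosome, genes$start_bp, genes$end_bp,
                     if (!is.null(genes$strand)) genes$strand else "+",
                     genes$gene_id, genes$gene_id))
  writeLines(lines, path)
  path
}
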