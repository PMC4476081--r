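#' Pooled allele frequency of two populations
#'
#' Chromosome-count weighted mean of the two within-population frequencies:
#' `f_p = (f1 * 2*n1 + f2 * 2*n2) / (2 * (n1 + n2))`.
#'
#' @param f1,f2 within-population frequencies of `allele_b`, in \[0, 1\].
#' @param n1,n2 per-population sample (individual) counts, >= 1.
#' @return the pooled frequency, vectorized over loci.
#' @export
pooled_frequency <- function(f1, n1, f2, n2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1),
            all(f1 >= 0 & f1 <= 1), all(f2 >= 0 & f2 <= 1))
  (f1 * 2 * n1 + f2 * 2 * n2) / (2 * (n1 + n2))
}

#' Per-SNP fixation index from pooled heterozygosities
#'
#' For every SNP computes the within-population frequencies, the pooled
#' frequency, the within-population expected heterozygosity
#' `H_s = w1 * 2 f1 (1-f1) + w2 * 2 f2 (1-f2)` (weights `w = 2n / (2n1+2n2)`
#' matching the pooled-frequency weighting, or equal weights on request),
#' the total expected heterozygosity `H_t = 2 f_p (1 - f_p)`, and
#' `Fst = (H_t - H_s) / H_t`. Loci with `H_t = 0` (monomorphic in the pooled
#' sample) get `Fst = NA` and are excluded from downstream smoothing.
#'
#' @param dataset a `GenotypeDataset` with no missing calls (run
#'   [impute_missing()] first).
#' @param hs_weighting `"chromosome_count"` (default) or `"equal"`.
#' @return data.frame of class `fst_track` with one row per SNP: `snp_id`,
#'   `chromosome`, `position_bp`, `f_pop1`, `f_pop2`, `n_pop1`, `n_pop2`,
#'   `f_pooled`, `h_s`, `h_t`, `fst`. Attribute `populations` gives the two
#'   labels in `f_pop1`/`f_pop2` order.
#' @export
fst_per_snp <- function(dataset,
                        hs_weighting = c("chromosome_count", "equal")) {
  hs_weighting <- match.arg(hs_weighting)
  if (length(unique(dataset$populations)) < 2) {
    stop("fst_per_snp needs two populations", call. = FALSE)
  }
  if (anyNA(dataset$dosages)) {
    stop("dataset contains missing calls; run impute_missing() first",
         call. = FALSE)
  }
  rows <- pop_rows(dataset)
  labs <- pop_labels(dataset)
  n1 <- length(rows[[1]]); n2 <- length(rows[[2]])
  f1 <- colSums(dataset$dosages[rows[[1]], , drop = FALSE]) / (2 * n1)
  f2 <- colSums(dataset$dosages[rows[[2]], , drop = FALSE]) / (2 * n2)
  f_p <- pooled_frequency(f1, n1, f2, n2)
  h_t <- 2 * f_p * (1 - f_p)
  if (hs_weighting == "chromosome_count") {
    w1 <- 2 * n1 / (2 * n1 + 2 * n2)
  } else {
    w1 <- 0.5
  }
  w2 <- 1 - w1
  h_s <- w1 * 2 * f1 * (1 - f1) + w2 * 2 * f2 * (1 - f2)
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  track <- data.frame(
    snp_id = dataset$map$snp_id,
    chromosome = dataset$map$chromosome,
    position_bp = dataset$map$position_bp,
    f_pop1 = f1, f_pop2 = f2,
    n_pop1 = n1, n_pop2 = n2,
    f_pooled = f_p, h_s = h_s, h_t = h_t, fst = fst,
    stringsAsFactors = FALSE
  )
  rownames(track) <- NULL
  attr(track, "populations") <- labs
  class(track) <- c("fst_track", "data.frame")
  track
}

#' Genome-wide mean Fst
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' per-SNP Fst over non-NA loci, plus the conventional reading of the mean
#' as the percentage of genetic variation explained by population
#' differences.
#'
#' @param track an `fst_track` from [fst_per_snp()].
#' @return list with `mean`, `sd`, `pct_between` (= 100 * mean) and
#'   `n_loci`.
#' @export
mean_fst <- function(track) {
  v <- track$fst[!is.na(track$fst)]
  if (length(v) < 2) stop("need >= 2 non-NA Fst values", call. = FALSE)
  structure(list(mean = mean(v), sd = stats::sd(v),
                 pct_between = 100 * mean(v), n_loci = length(v)),
            class = "mean_fst")
}

#' @export
print.mean_fst <- function(x, ...) {
  cat(sprintf("mean Fst = %.4f +/- %.4f SD over %d loci\n",
              x$mean, x$sd, x$n_loci))
  cat(sprintf("  (%.2f%% of genetic variation between populations)\n",
              x$pct_between))
  invisible(x)
}

#' Export an Fst track as TSV
#'
#' @param track an `fst_track`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fst_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
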