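#' Windowed genotype-correlation matrix
#'
#' Signed Pearson correlation of unphased dosage columns (composite LD).
#' Columns with zero variance (fixed within the population) contribute 0
#' off-diagonal and 1 on the diagonal, keeping the matrix well defined and
#' the trace equal to the window size.
#'
#' @param dosages numeric matrix, samples x window SNPs, no missing values.
#' @return the k x k correlation matrix.
#' @export
window_correlation <- function(dosages) {
  if (nrow(dosages) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(dosages)) stop("missing dosages; impute first", call. = FALSE)
  k <- ncol(dosages)
  suppressWarnings(C <- stats::cor(dosages))
  C[is.na(C)] <- 0
  diag(C) <- 1
  C
}

#' Raw varLD score: spectral distance between two correlation matrices
#'
#' Eigenvalues of each matrix are sorted in decreasing order and the score
#' is the summed absolute difference,
#' `sum_i |lambda_A(i) - lambda_B(i)|`.
#'
#' @param corr_a,corr_b symmetric correlation matrices of equal size with
#'   unit diagonal.
#' @return non-negative raw score.
#' @export
varld_raw_score <- function(corr_a, corr_b) {
  stopifnot(nrow(corr_a) == ncol(corr_a), nrow(corr_b) == ncol(corr_b),
            nrow(corr_a) == nrow(corr_b))
  if (!isSymmetric(unname(corr_a), tol = 1e-8) ||
      !isSymmetric(unname(corr_b), tol = 1e-8)) {
    stop("correlation matrices must be symmetric", call. = FALSE)
  }
  la <- eigen(corr_a, symmetric = TRUE, only.values = TRUE)$values
  lb <- eigen(corr_b, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(la - lb))  # eigen() returns values in decreasing order
}

#' Sliding-window regional LD comparison (varLD-style)
#'
#' Slides a window of `window_snps` SNPs along each chromosome (never
#' spanning chromosomes), computes each population's genotype-correlation
#' matrix, scores the window by the spectral distance of
#' [varld_raw_score()], standardizes raw scores genome-wide, assigns each
#' window's score to its central SNP (index `ceiling(k/2)` within the
#' window), and flags windows whose standardized score exceeds
#' `threshold_sd` (one-sided: only elevated LD divergence marks
#' differential selection).
#'
#' @param dataset a `GenotypeDataset`, QC'd and imputed.
#' @param window_snps window length in SNPs (default 20, matching the
#'   LOWESS window).
#' @param step_snps step between window starts (default 1).
#' @param threshold_sd significance threshold on the standardized scale
#'   (default 3).
#' @param standardization `"zscore"` (genome-wide (raw - mean)/sd; default)
#'   or `"rank_normal"` (rank-based inverse-normal transform).
#' @return object of class `varld_scan`: data.frame `windows` with columns
#'   `chromosome`, `start_bp`, `end_bp`, `central_snp_id`, `central_bp`,
#'   `raw_score`, `std_score`, `significant`, plus the configuration.
#' @export
varld_scan <- function(dataset, window_snps = 20, step_snps = 1,
                       threshold_sd = 3,
                       standardization = c("zscore", "rank_normal")) {
  standardization <- match.arg(standardization)
  stopifnot(window_snps >= 2, step_snps >= 1)
  if (anyNA(dataset$dosages)) {
    stop("dataset contains missing calls; run impute_missing() first",
         call. = FALSE)
  }
  rows <- pop_rows(dataset)
  map <- dataset$map
  chroms <- sort(unique(map$chromosome[!is.na(map$chromosome)]))
  k <- window_snps
  central_off <- as.integer(ceiling(k / 2)) - 1L  # 0-based offset

  res <- list()
  for (chrom in chroms) {
    snp_idx <- which(!is.na(map$chromosome) & map$chromosome == chrom)
    m <- length(snp_idx)
    if (m < k) {
      warning("chromosome ", chrom, " has ", m, " SNPs < window of ", k,
              "; skipped", call. = FALSE)
      next
    }
    # column-standardized dosages per population: correlation via crossprod
    Z <- lapply(rows, function(r) {
      X <- dataset$dosages[r, snp_idx, drop = FALSE]
      Xc <- scale(X)  # columns with sd 0 become NaN -> set to 0
      Xc[, colSums(is.na(Xc)) > 0] <- 0
      Xc / sqrt(nrow(X) - 1)
    })
    starts <- seq(1L, m - k + 1L, by = step_snps)
    raw <- numeric(length(starts))
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + k - 1L)
      Ca <- crossprod(Z[[1]][, idx]); diag(Ca) <- 1
      Cb <- crossprod(Z[[2]][, idx]); diag(Cb) <- 1
      la <- eigen(Ca, symmetric = TRUE, only.values = TRUE)$values
      lb <- eigen(Cb, symmetric = TRUE, only.values = TRUE)$values
      raw[w] <- sum(abs(la - lb))
    }
    central <- snp_idx[starts + central_off]
    res[[as.character(chrom)]] <- data.frame(
      chromosome = chrom,
      start_bp = map$position_bp[snp_idx[starts]],
      end_bp = map$position_bp[snp_idx[starts + k - 1L]],
      central_snp_id = map$snp_id[central],
      central_bp = map$position_bp[central],
      raw_score = raw,
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0) stop("no chromosome long enough for the window",
                             call. = FALSE)
  windows <- do.call(rbind, res)
  rownames(windows) <- NULL
  windows$std_score <- if (standardization == "zscore") {
    s <- stats::sd(windows$raw_score)
    if (s == 0 || nrow(windows) < 2) {
      rep(0, nrow(windows))  # no spread: nothing can be significant
    } else {
      (windows$raw_score - mean(windows$raw_score)) / s
    }
  } else {
    stats::qnorm((rank(windows$raw_score) - 0.5) / nrow(windows))
  }
  windows$significant <- windows$std_score > threshold_sd
  structure(list(windows = windows,
                 config = list(window_snps = window_snps,
                               step_snps = step_snps,
                               threshold_sd = threshold_sd,
                               standardization = standardization),
                 populations = pop_labels(dataset)),
            class = "varld_scan")
}

#' @export
print.varld_scan <- function(x, ...) {
  cat("varLD scan:", nrow(x$windows), "windows of",
      x$config$window_snps, "SNPs\n")
  cat("  significant (std >", x$config$threshold_sd, "):",
      sum(x$windows$significant), "\n")
  invisible(x)
}

#' Significant central SNPs of a varLD scan
#'
#' @param scan a `varld_scan`.
#' @return data.frame with one row per significant window: `snp_id`
#'   (central SNP), `chromosome`, `position_bp`, `std_score`.
#' @export
varld_significant_snps <- function(scan) {
  w <- scan$windows[scan$windows$significant, , drop = FALSE]
  data.frame(snp_id = w$central_snp_id, chromosome = w$chromosome,
             position_bp = w$central_bp, std_score = w$std_score,
             stringsAsFactors = FALSE)
}
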