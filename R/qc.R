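#' Restrict a dataset to autosomal SNPs
#'
#' @param dataset a `GenotypeDataset`.
#' @param n_autosomes number of autosomes (29 for cattle).
#' @return a `GenotypeDataset` with SNPs on chromosomes 1..`n_autosomes`,
#'   order preserved; attribute `n_removed` counts dropped SNPs.
#' @export
filter_autosomes <- function(dataset, n_autosomes = 29) {
  keep <- !is.na(dataset$map$chromosome) &
    dataset$map$chromosome >= 1 & dataset$map$chromosome <= n_autosomes
  if (!any(keep)) message("filter_autosomes: no autosomal SNPs retained")
  out <- subset_snps(dataset, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

# per-population per-SNP summaries used by several filters
pop_snp_counts <- function(dataset) {
  rows <- pop_rows(dataset)
  d <- dataset$dosages
  lapply(rows, function(r) {
    sub <- d[r, , drop = FALSE]
    nonmiss <- colSums(!is.na(sub))
    list(n_nonmiss = nonmiss, sum_b = colSums(sub, na.rm = TRUE))
  })
}

#' SNP quality-control filters
#'
#' Removes, in order: (1) SNPs monomorphic in *both* populations considered
#' separately (a SNP monomorphic in one but segregating in the other is
#' kept); (2) SNPs with an overall missing-call fraction above
#' `max_missing_rate`; (3) SNPs whose pooled minor allele frequency (both
#' populations together, non-missing calls) is below `min_maf`. Each removed
#' SNP is counted once, under the first filter that triggers.
#'
#' @param dataset a `GenotypeDataset`.
#' @param max_missing_rate maximum tolerated per-SNP missing fraction
#'   (default 0.025, i.e. 2.5\%).
#' @param min_maf minimum pooled minor allele frequency (default 0.01).
#' @return list with elements `dataset` (filtered) and `report`
#'   (a `qc_report`).
#' @export
qc_filter <- function(dataset, max_missing_rate = 0.025, min_maf = 0.01) {
  stopifnot(max_missing_rate >= 0, max_missing_rate < 1,
            min_maf >= 0, min_maf <= 0.5)
  m <- n_snps(dataset)
  n <- n_samples(dataset)
  cnt <- pop_snp_counts(dataset)

  mono_in <- lapply(cnt, function(p) {
    p$n_nonmiss == 0 | p$sum_b == 0 | p$sum_b == 2 * p$n_nonmiss
  })
  mono_both <- mono_in[[1]] & mono_in[[2]]

  n_miss <- colSums(is.na(dataset$dosages))
  high_missing <- (n_miss / n) > max_missing_rate

  n_nonmiss <- cnt[[1]]$n_nonmiss + cnt[[2]]$n_nonmiss
  f_b <- ifelse(n_nonmiss > 0,
                (cnt[[1]]$sum_b + cnt[[2]]$sum_b) / (2 * n_nonmiss), NA)
  maf <- pmin(f_b, 1 - f_b)
  low_maf <- !is.na(maf) & maf < min_maf

  removed_mono <- mono_both
  removed_miss <- high_missing & !removed_mono
  removed_maf <- low_maf & !removed_mono & !removed_miss
  keep <- !(removed_mono | removed_miss | removed_maf)

  report <- structure(list(
    n_input_snps = m,
    n_removed_nonautosomal = 0L,
    n_removed_monomorphic_both = sum(removed_mono),
    n_removed_missingness = sum(removed_miss),
    n_removed_maf = sum(removed_maf),
    n_retained = sum(keep),
    n_imputed_cells = 0L,
    max_missing_rate = max_missing_rate,
    min_maf = min_maf
  ), class = "qc_report")
  list(dataset = subset_snps(dataset, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control report\n")
  cat("  input SNPs:              ", x$n_input_snps, "\n")
  cat("  removed non-autosomal:   ", x$n_removed_nonautosomal, "\n")
  cat("  removed monomorphic-both:", x$n_removed_monomorphic_both, "\n")
  cat(sprintf("  removed missingness >%g%%: %d\n",
              100 * x$max_missing_rate, x$n_removed_missingness))
  cat(sprintf("  removed MAF <%g%%:         %d\n",
              100 * x$min_maf, x$n_removed_maf))
  cat("  retained:                ", x$n_retained, "\n")
  cat("  imputed cells:           ", x$n_imputed_cells, "\n")
  invisible(x)
}

#' Impute missing genotypes with the within-population modal allele
#'
#' Each missing call is replaced by the homozygous dosage (0 or 2) of the
#' allele that is more frequent within that sample's own population at that
#' locus. An exact 50/50 tie imputes `allele_a` (dosage 0), deterministically.
#'
#' @param dataset a `GenotypeDataset`.
#' @return list with elements `dataset` (no missing calls) and `n_imputed`.
#' @export
impute_missing <- function(dataset) {
  d <- dataset$dosages
  rows <- pop_rows(dataset)
  labs <- pop_labels(dataset)
  n_imputed <- 0L
  for (k in 1:2) {
    sub <- d[rows[[k]], , drop = FALSE]
    nonmiss <- colSums(!is.na(sub))
    miss_cols <- which(colSums(is.na(sub)) > 0)
    if (length(miss_cols) == 0) next
    dead <- miss_cols[nonmiss[miss_cols] == 0]
    if (length(dead) > 0) {
      stop("locus ", dataset$map$snp_id[dead[1]],
           " has no non-missing calls in population ", labs[k], call. = FALSE)
    }
    f_b <- colSums(sub[, miss_cols, drop = FALSE], na.rm = TRUE) /
      (2 * nonmiss[miss_cols])
    fill <- ifelse(f_b > 0.5, 2L, 0L)  # tie (f_b == 0.5) -> allele_a
    miss <- which(is.na(sub), arr.ind = TRUE)
    fill_all <- integer(ncol(sub))
    fill_all[miss_cols] <- fill
    sub[miss] <- fill_all[miss[, "col"]]
    d[rows[[k]], ] <- sub
    n_imputed <- n_imputed + nrow(miss)
  }
  out <- dataset
  out$dosages <- d
  validate_genotype_dataset(out)
  list(dataset = out, n_imputed = n_imputed)
}

#' Observed and expected heterozygosity per population
#'
#' Observed heterozygosity is the fraction of heterozygous calls among
#' non-missing calls; expected heterozygosity is the per-SNP mean of
#' `2 f (1 - f)` with `f` the within-population allele frequency. Both are
#' reported per (population, chromosome) and genome-wide (chromosome `NA`).
#'
#' @param dataset a `GenotypeDataset`.
#' @return data.frame of class `het_summary` with columns `population`,
#'   `chromosome` (NA = genome-wide), `n_snps`, `h_obs`, `h_exp`.
#' @export
heterozygosity_summary <- function(dataset) {
  rows <- pop_rows(dataset)
  labs <- pop_labels(dataset)
  map <- dataset$map
  chroms <- sort(unique(map$chromosome[!is.na(map$chromosome)]))
  out <- list()
  for (k in 1:2) {
    sub <- dataset$dosages[rows[[k]], , drop = FALSE]
    het <- colSums(sub == 1L, na.rm = TRUE)
    nonmiss <- colSums(!is.na(sub))
    f_b <- ifelse(nonmiss > 0, colSums(sub, na.rm = TRUE) / (2 * nonmiss), NA)
    h_exp_snp <- 2 * f_b * (1 - f_b)
    groups <- c(as.list(chroms), list(NA))
    for (g in groups) {
      snps <- if (is.na(g[1])) seq_len(nrow(map)) else
        which(!is.na(map$chromosome) & map$chromosome == g)
      calls <- sum(nonmiss[snps])
      out[[length(out) + 1]] <- data.frame(
        population = labs[k],
        chromosome = if (is.na(g[1])) NA_integer_ else as.integer(g),
        n_snps = length(snps),
        h_obs = if (calls > 0) sum(het[snps]) / calls else NA_real_,
        h_exp = mean(h_exp_snp[snps], na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("het_summary", "data.frame")
  res
}

#' Run the full data-editing pipeline
#'
#' Autosome restriction, then the monomorphic/missingness/MAF filters of
#' [qc_filter()], then [impute_missing()]. The heterozygosity summary is
#' computed after filtering but before imputation, so missing calls do not
#' enter its denominators.
#'
#' @param dataset a `GenotypeDataset`.
#' @param n_autosomes passed to [filter_autosomes()].
#' @param max_missing_rate,min_maf passed to [qc_filter()].
#' @param impute replace missing calls (default TRUE)?
#' @return list with `dataset`, `report` (`qc_report` covering all stages)
#'   and `heterozygosity` (`het_summary`).
#' @export
run_qc <- function(dataset, n_autosomes = 29, max_missing_rate = 0.025,
                   min_maf = 0.01, impute = TRUE) {
  n_input <- n_snps(dataset)
  auto <- filter_autosomes(dataset, n_autosomes)
  filt <- qc_filter(auto, max_missing_rate, min_maf)
  het <- heterozygosity_summary(filt$dataset)
  report <- filt$report
  report$n_input_snps <- n_input
  report$n_removed_nonautosomal <- attr(auto, "n_removed")
  ds <- filt$dataset
  if (impute) {
    imp <- impute_missing(ds)
    ds <- imp$dataset
    report$n_imputed_cells <- imp$n_imputed
  }
  list(dataset = ds, report = report, heterozygosity = het)
}
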