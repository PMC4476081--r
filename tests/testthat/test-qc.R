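test_that("autosome filter keeps chromosomes 1..n and preserves order", {
  map <- data.frame(snp_id = paste0("rs", 1:4),
                    chromosome = c(1L, 30L, 29L, NA),
                    position_bp = c(100L, 100L, 100L, 100L),
                    allele_a = "A", allele_b = "G",
                    chrom_label = c("1", "30", "29", "X"),
                    stringsAsFactors = FALSE)
  d <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
  rownames(d) <- paste0("s", 1:4)
  ds <- genotype_dataset(map, d, rep(c("P", "Q"), each = 2))
  out <- filter_autosomes(ds)
  expect_equal(out$map$snp_id, c("rs1", "rs3"))
  expect_equal(attr(out, "n_removed"), 2L)
  # all-autosomal input is untouched
  ds2 <- random_dataset()
  out2 <- filter_autosomes(ds2)
  expect_equal(out2$map, ds2$map)
  expect_equal(out2$dosages, ds2$dosages)
})

test_that("monomorphic-in-both filter spares loci segregating in one
           population", {
  d1 <- cbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 0L, 2L))
  d2 <- cbind(c(0L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L), c(0L, 1L, 1L, 0L))
  ds <- dataset_from_dosages(d1, d2)
  res <- qc_filter(ds, max_missing_rate = 0.5, min_maf = 0)
  # SNP 1 monomorphic in both -> removed; SNP 2 segregates in pop B -> kept
  expect_equal(res$dataset$map$snp_id, c("rs002", "rs003"))
  expect_equal(res$report$n_removed_monomorphic_both, 1L)
  expect_equal(res$report$n_retained, 2L)
})

test_that("missingness and MAF filters trigger in order with reconciling
           counts", {
  n <- 200
  set.seed(5)
  base <- matrix(1L, n, 3)
  # SNP 1: 6/200 = 3% missing (above 2.5%)
  base[1:6, 1] <- NA
  # SNP 2: pooled MAF 0.008 (still polymorphic in one population)
  base[, 2] <- 0L
  base[seq_len(3), 2] <- 1L  # 3/400 = 0.0075 < 0.01
  # SNP 3: clean heterozygous everywhere
  rownames(base) <- sprintf("s%03d", seq_len(n))
  map <- data.frame(snp_id = paste0("rs", 1:3), chromosome = 1L,
                    position_bp = c(10L, 20L, 30L), allele_a = "A",
                    allele_b = "G", stringsAsFactors = FALSE)
  ds <- genotype_dataset(map, base, rep(c("P", "Q"), each = n / 2))
  res <- qc_filter(ds)
  r <- res$report
  expect_equal(r$n_removed_missingness, 1L)
  expect_equal(r$n_removed_maf, 1L)
  expect_equal(r$n_removed_monomorphic_both, 0L)
  expect_equal(r$n_input_snps,
               r$n_retained + r$n_removed_monomorphic_both +
                 r$n_removed_missingness + r$n_removed_maf)
  expect_equal(res$dataset$map$snp_id, "rs3")
})

test_that("qc_filter is idempotent", {
  ds <- random_dataset(n1 = 20, n2 = 20, m = 60, missing_rate = 0.05,
                       seed = 9)
  r1 <- qc_filter(ds)
  r2 <- qc_filter(r1$dataset)
  expect_equal(r2$report$n_retained, r2$report$n_input_snps)
  expect_equal(r2$dataset$dosages, r1$dataset$dosages)
})

test_that("removal counts match brute-force enumeration on random data", {
  ds <- random_dataset(n1 = 15, n2 = 25, m = 120, missing_rate = 0.03,
                       seed = 77)
  res <- qc_filter(ds, max_missing_rate = 0.025, min_maf = 0.05)
  rows <- split(seq_len(n_samples(ds)), ds$populations)
  removed <- c(mono = 0, miss = 0, maf = 0)
  for (j in seq_len(n_snps(ds))) {
    mono <- vapply(rows, function(r) {
      v <- ds$dosages[r, j]; v <- v[!is.na(v)]
      length(v) == 0 || sum(v) == 0 || sum(v) == 2 * length(v)
    }, logical(1))
    if (all(mono)) { removed["mono"] <- removed["mono"] + 1; next }
    if (mean(is.na(ds$dosages[, j])) > 0.025) {
      removed["miss"] <- removed["miss"] + 1; next
    }
    v <- ds$dosages[, j]; v <- v[!is.na(v)]
    f <- sum(v) / (2 * length(v))
    if (min(f, 1 - f) < 0.05) removed["maf"] <- removed["maf"] + 1
  }
  expect_equal(res$report$n_removed_monomorphic_both,
               unname(removed["mono"]))
  expect_equal(res$report$n_removed_missingness, unname(removed["miss"]))
  expect_equal(res$report$n_removed_maf, unname(removed["maf"]))
})

test_that("imputation fills the within-population modal homozygote", {
  d1 <- rbind(c(0L, 2L, 1L),
              c(0L, 2L, 1L),
              c(1L, 1L, 0L),
              c(NA, NA, NA))
  d2 <- rbind(c(2L, 0L, 1L),
              c(2L, 0L, 1L),
              c(2L, 0L, 1L),
              c(2L, 0L, 1L))
  ds <- dataset_from_dosages(d1, d2)
  res <- impute_missing(ds)
  expect_equal(res$n_imputed, 3L)
  # pop A at SNP1: f_b = 1/6 -> 0; SNP2: f_b = 5/6 -> 2
  expect_equal(unname(res$dataset$dosages[4, 1:2]), c(0L, 2L))
  # SNP3: f_b = 2/6 in pop A -> 0
  expect_equal(unname(res$dataset$dosages[4, 3]), 0L)
  expect_false(anyNA(res$dataset$dosages))
})

test_that("an exact 50/50 allele tie imputes allele_a (dosage 0)", {
  d1 <- rbind(c(0L), c(2L), c(1L), c(1L), c(NA))
  d2 <- rbind(c(1L), c(1L), c(1L))
  ds <- dataset_from_dosages(d1, d2)
  res <- impute_missing(ds)
  expect_equal(unname(res$dataset$dosages[5, 1]), 0L)
})

test_that("a locus fully missing within a population is an error", {
  d1 <- rbind(c(NA_integer_), c(NA_integer_), c(NA_integer_))
  d2 <- rbind(c(1L), c(0L), c(1L))
  ds <- dataset_from_dosages(d1, d2)
  expect_error(impute_missing(ds), "rs001.*A_pop")
})

test_that("imputation cannot flip the within-population modal allele", {
  ds <- random_dataset(n1 = 12, n2 = 14, m = 80, missing_rate = 0.15,
                       seed = 3)
  res <- impute_missing(ds)
  rows <- split(seq_len(n_samples(ds)), ds$populations)
  for (pop in names(rows)) {
    before <- colSums(ds$dosages[rows[[pop]], ], na.rm = TRUE) /
      (2 * colSums(!is.na(ds$dosages[rows[[pop]], ])))
    after <- colSums(res$dataset$dosages[rows[[pop]], ]) /
      (2 * length(rows[[pop]]))
    expect_true(all((before > 0.5) == (after > 0.5)))
  }
})

test_that("heterozygosity summary matches hand enumeration", {
  d1 <- rbind(c(0L), c(1L), c(1L), c(2L))
  d2 <- rbind(c(1L), c(1L), c(1L))
  ds <- dataset_from_dosages(d1, d2)
  het <- heterozygosity_summary(ds)
  a_gen <- het[het$population == "A_pop" & is.na(het$chromosome), ]
  expect_equal(a_gen$h_obs, 0.5)
  expect_equal(a_gen$h_exp, 0.5)  # f = 0.5 -> 2 f (1-f) = 0.5
  b_gen <- het[het$population == "B_pop" & is.na(het$chromosome), ]
  expect_equal(b_gen$h_obs, 1)    # all heterozygous
  # identical genotypes give identical summaries
  ds2 <- dataset_from_dosages(d1, d1)
  het2 <- heterozygosity_summary(ds2)
  expect_equal(het2$h_obs[het2$population == "A_pop"],
               het2$h_obs[het2$population == "B_pop"])
})

test_that("missing calls are excluded from heterozygosity denominators", {
  d1 <- rbind(c(1L), c(1L), c(NA), c(NA))
  d2 <- rbind(c(0L), c(0L), c(2L))
  ds <- dataset_from_dosages(d1, d2)
  het <- heterozygosity_summary(ds)
  expect_equal(het$h_obs[het$population == "A_pop" &
                           !is.na(het$chromosome)], 1)
})
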