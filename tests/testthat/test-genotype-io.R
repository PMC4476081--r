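test_that("PED/MAP parsing counts copies of the second-observed allele", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("F1 s1 0 0 0 -9 A A",
               "F1 s2 0 0 0 -9 A G",
               "F2 s3 0 0 0 -9 G G",
               "F2 s4 0 0 0 -9 A G"), ped)
  writeLines("1 rs1 0 100", map)
  ds <- read_plink(ped, map)
  expect_equal(unname(ds$dosages[, 1]), c(0L, 1L, 2L, 1L))
  expect_equal(ds$map$allele_a, "A")
  expect_equal(ds$map$allele_b, "G")
  expect_equal(pop_labels(ds), c("F1", "F2"))
})

test_that("'0 0' genotypes become missing and monomorphic loci dose 0", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("F1 s1 0 0 0 -9 0 0 C C",
               "F1 s2 0 0 0 -9 A G C C",
               "F2 s3 0 0 0 -9 G G C C",
               "F2 s4 0 0 0 -9 G G C C"), ped)
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), map)
  ds <- read_plink(ped, map)
  expect_true(is.na(ds$dosages["s1", "rs1"]))
  expect_equal(unname(ds$dosages[, "rs1"]), c(NA, 1L, 2L, 2L))
  # rs2 monomorphic: single observed allele becomes allele_a, dosage 0
  expect_true(is.na(ds$map$allele_b[2]))
  expect_equal(unname(ds$dosages[, "rs2"]), rep(0L, 4))
})

test_that("PED field-count and allele errors name the offender", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1 rs1 0 100", "1 rs2 0 200"), map)
  writeLines(c("F1 s1 0 0 0 -9 A A C C",
               "F1 s2 0 0 0 -9 A A C"), ped)
  expect_error(read_plink(ped, map), "line 2")
  writeLines(c("F1 s1 0 0 0 -9 A A C C",
               "F1 s2 0 0 0 -9 A G C T",
               "F2 s3 0 0 0 -9 G T C C",
               "F2 s4 0 0 0 -9 A A C C"), ped)
  expect_error(read_plink(ped, map), "rs1")
  # unknown sample in an explicit population mapping
  writeLines(c("F1 s1 0 0 0 -9 A A C C",
               "F2 s2 0 0 0 -9 A G C T"), ped)
  expect_error(read_plink(ped, map, c(s1 = "A_pop")), "s2")
})

test_that("MAP order is stably sorted by chromosome then position", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("2 rs_b 0 500", "1 rs_c 0 900", "chr1 rs_a 0 100"), map)
  writeLines(c("F1 s1 0 0 0 -9 A A C G T T",
               "F1 s2 0 0 0 -9 A G C C T A",
               "F2 s3 0 0 0 -9 G G G G A A",
               "F2 s4 0 0 0 -9 A A C G T A"), ped)
  ds <- read_plink(ped, map)
  expect_equal(ds$map$snp_id, c("rs_a", "rs_c", "rs_b"))
  expect_equal(ds$map$chromosome, c(1L, 1L, 2L))
  # dosage columns follow the SNPs: rs_a was the third genotype pair
  expect_equal(unname(ds$dosages[, "rs_a"]),
               c(0L, 1L, 2L, 1L))
})

test_that("PLINK round-trip reproduces a dataset field-for-field when the
           first sample carries allele_a", {
  map <- data.frame(snp_id = paste0("rs", 1:4), chromosome = c(1L, 1L, 2L, 2L),
                    position_bp = c(100L, 250L, 90L, 400L),
                    allele_a = c("A", "C", "G", "T"),
                    allele_b = c("G", "T", "A", "C"),
                    stringsAsFactors = FALSE)
  d <- rbind(c(0L, 1L, 0L, 1L),
             c(2L, NA, 1L, 0L),
             c(1L, 2L, 2L, 2L),
             c(0L, 0L, 1L, NA))
  rownames(d) <- c("s1", "s2", "s3", "s4")
  ds <- genotype_dataset(map, d, c("P", "P", "Q", "Q"))
  # s1 dosages are 0/1 everywhere, so allele_a is always observed first
  ped <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  write_plink(ds, ped, mapf)
  back <- read_plink(ped, mapf, stats::setNames(ds$populations, ds$samples))
  expect_equal(back$map$allele_a, ds$map$allele_a)
  expect_equal(back$map$allele_b, ds$map$allele_b)
  expect_equal(unname(back$dosages), unname(ds$dosages))
  expect_equal(back$samples, ds$samples)
  expect_equal(back$populations, ds$populations)
})

test_that("PLINK round-trip on simulated data preserves genotypes up to
           allele orientation", {
  sim <- simulate_dataset(sim_config(n_chromosomes = 2,
                                     snps_per_chromosome = 100,
                                     chromosome_length_bp = 1e6,
                                     n_samples = c(25, 25),
                                     missing_rate = 0.05, seed = 42))
  ds <- sim$dataset
  ped <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  write_plink(ds, ped, mapf)
  back <- read_plink(ped, mapf, stats::setNames(ds$populations, ds$samples))
  expect_equal(n_snps(back), n_snps(ds))
  expect_equal(back$map$snp_id, ds$map$snp_id)
  expect_equal(back$map$position_bp, ds$map$position_bp)
  # align orientation: where labels swapped (including loci monomorphic
  # for allele_b, re-read with allele_b as allele_a), dosage reflects 2 - d
  flipped <- !is.na(back$map$allele_a) &
    back$map$allele_a == ds$map$allele_b
  aligned <- back$dosages
  aligned[, flipped] <- 2L - aligned[, flipped]
  expect_equal(unname(aligned), unname(ds$dosages))
  # Fst is invariant to the orientation of each locus (checked on the
  # imputed dataset: the imputation tie-break itself names allele_a, so it
  # is applied before writing)
  imp <- impute_missing(ds)$dataset
  write_plink(imp, ped, mapf)
  back2 <- read_plink(ped, mapf, stats::setNames(imp$populations,
                                                 imp$samples))
  expect_equal(fst_per_snp(back2)$fst, fst_per_snp(imp)$fst,
               tolerance = 1e-12)
})

test_that("VCF GT decoding follows the standard table", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "1|1", "./.", "0/0"), collapse = "\t"),
    paste(c("1", "200", "v2", "C", "T,G", ".", "PASS", ".", "GT",
            "0/1", "0/0", "0/0", "0/2"), collapse = "\t")), vcf)
  pops <- c(s1 = "P", s2 = "P", s3 = "Q", s4 = "Q")
  expect_warning(ds <- read_vcf(vcf, pops), "skipped")
  expect_equal(attr(ds, "n_skipped"), 1)
  expect_equal(n_snps(ds), 1)
  expect_equal(unname(ds$dosages[, "v1"]), c(1L, 2L, NA, 0L))
  expect_equal(ds$map$allele_a, "A")
  expect_equal(ds$map$allele_b, "G")
})

test_that("VCF round-trip reproduces the dosage matrix exactly", {
  sim <- simulate_dataset(sim_config(n_chromosomes = 2,
                                     snps_per_chromosome = 80,
                                     chromosome_length_bp = 1e6,
                                     n_samples = c(20, 22),
                                     missing_rate = 0.03, seed = 7))
  ds <- sim$dataset
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(ds, vcf)
  back <- read_vcf(vcf, stats::setNames(ds$populations, ds$samples))
  expect_equal(unname(back$dosages), unname(ds$dosages))
  expect_equal(back$map$allele_a, ds$map$allele_a)
  expect_equal(back$map$allele_b, ds$map$allele_b)
  expect_equal(back$map$snp_id, ds$map$snp_id)
  expect_equal(back$populations, ds$populations)
})

test_that("empty-SNP dataset writes a valid PED and empty MAP", {
  map <- data.frame(snp_id = character(0), chromosome = integer(0),
                    position_bp = integer(0), allele_a = character(0),
                    allele_b = character(0), stringsAsFactors = FALSE)
  d <- matrix(integer(0), nrow = 4, ncol = 0)
  rownames(d) <- paste0("s", 1:4)
  ds <- genotype_dataset(map, d, rep(c("P", "Q"), each = 2))
  ped <- tempfile(fileext = ".ped"); mapf <- tempfile(fileext = ".map")
  write_plink(ds, ped, mapf)
  expect_equal(length(readLines(mapf)), 0)
  fields <- strsplit(trimws(readLines(ped)), "\\s+")
  expect_true(all(lengths(fields) == 6))
})

test_that("dataset invariants are enforced", {
  map <- data.frame(snp_id = "rs1", chromosome = 1L, position_bp = 100L,
                    allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  d <- matrix(c(0L, 3L, 1L, 2L), 4, 1)
  expect_error(genotype_dataset(map, d, rep(c("P", "Q"), 2)), "dosages")
  d2 <- matrix(0L, 4, 1)
  expect_error(genotype_dataset(map, d2, c("P", "Q", "R", "P")),
               "two population")
  expect_error(genotype_dataset(map, d2, c("P", "P", "P", "Q")),
               "at least 2 samples")
})
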