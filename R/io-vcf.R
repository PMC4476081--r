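#' Read a VCF into a GenotypeDataset
#'
#' Uses \pkg{vcfR} to parse a VCF v4.x file. Only biallelic SNP records are
#' kept: records with more than one ALT allele, or with REF/ALT longer than
#' one base, are skipped and counted. REF becomes `allele_a`, ALT `allele_b`;
#' dosage is the ALT-allele count of the GT field (phased and unphased
#' genotypes treated identically, any GT containing "." is missing).
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param populations named character vector sample id -> population label,
#'   or path to a two-column TSV.
#' @return a `GenotypeDataset`; attribute `n_skipped` counts skipped records.
#' @export
read_vcf <- function(vcf_path, populations) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records", call. = FALSE)
  gt_mat <- vcf@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2) {
    stop("VCF has no genotype columns", call. = FALSE)
  }
  has_gt <- grepl("(^|:)GT(:|$)", gt_mat[, "FORMAT"])
  if (!all(has_gt)) {
    stop("VCF format error: GT key absent from FORMAT at record ",
         which(!has_gt)[1], call. = FALSE)
  }

  alt <- fix$ALT
  alt[is.na(alt)] <- "."
  ref <- fix$REF
  biallelic <- !grepl(",", alt) & nchar(ref) == 1 &
    (alt == "." | nchar(alt) == 1)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0) {
    warning(n_skipped, " non-biallelic-SNP records skipped", call. = FALSE)
  }
  fix <- fix[biallelic, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  samples <- colnames(gt)
  gt_clean <- gsub("\\|", "/", gt)
  dose_of <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dosages <- matrix(dose_of[gt_clean], nrow = nrow(gt), ncol = ncol(gt))
  unknown <- !is.na(gt_clean) & !(gt_clean %in% names(dose_of)) &
    !grepl("\\.", gt_clean)
  if (any(unknown)) {
    stop("unrecognized GT value: ", gt_clean[unknown][1], call. = FALSE)
  }
  dosages <- t(dosages)  # samples x SNPs
  rownames(dosages) <- samples

  snp_id <- fix$ID
  need_id <- is.na(snp_id) | snp_id == "."
  snp_id[need_id] <- paste0(fix$CHROM[need_id], "_", fix$POS[need_id])
  alt_kept <- alt[biallelic]
  map <- data.frame(
    snp_id = snp_id,
    chromosome = parse_chrom(fix$CHROM),
    position_bp = as.integer(fix$POS),
    allele_a = fix$REF,
    allele_b = ifelse(alt_kept == ".", NA_character_, alt_kept),
    chrom_label = fix$CHROM,
    stringsAsFactors = FALSE
  )

  pop <- resolve_populations(populations, samples)
  ord <- map_order(map)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  ds <- genotype_dataset(map, dosages[, ord, drop = FALSE],
                         stats::setNames(pop, samples))
  attr(ds, "n_skipped") <- n_skipped
  ds
}

#' Write a dataset as VCF v4.2
#'
#' Emits a minimal GT-only VCF. `allele_a` is written as REF and `allele_b`
#' as ALT (`.` when the locus is monomorphic), so [read_vcf()] reproduces
#' the dataset exactly, including allele orientation.
#'
#' @param dataset a `GenotypeDataset`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(dataset, path) {
  validate_genotype_dataset(dataset)
  map <- dataset$map
  d <- dataset$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")
  )
  chrom_out <- ifelse(is.na(map$chromosome), map$chrom_label,
                      as.character(map$chromosome))
  body <- vapply(seq_len(nrow(map)), function(j) {
    gt <- rep("./.", nrow(d))
    ok <- !is.na(d[, j])
    gt[ok] <- gt_code[d[ok, j] + 1L]
    paste(c(chrom_out[j], map$position_bp[j], map$snp_id[j],
            map$allele_a[j],
            ifelse(is.na(map$allele_b[j]), ".", map$allele_b[j]),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
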