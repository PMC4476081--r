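#' Read a PLINK text fileset (PED/MAP)
#'
#' Parses whitespace-delimited PED/MAP files into a [genotype_dataset()].
#' Allele orientation is fixed at read time: at each locus the first allele
#' observed in sample order becomes `allele_a`, the second distinct allele
#' becomes `allele_b`, and dosages count copies of `allele_b`. "0 0" encodes
#' a missing genotype. SNPs are stably sorted by (chromosome, position).
#'
#' @param ped_path path to the PED file (6 leading columns + 2 alleles/SNP).
#' @param map_path path to the MAP file (4 columns: chromosome, snp id,
#'   genetic position, bp position).
#' @param populations either a named character vector mapping sample id to
#'   population label, the path of a two-column TSV (sample_id, population),
#'   or the string `"family_id"` to use the PED family id as the label.
#' @return a `GenotypeDataset`.
#' @export
read_plink <- function(ped_path, map_path, populations = "family_id") {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  nf <- lengths(map_fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("MAP format error at line %d: expected 4 fields, found %d",
                 bad, nf[bad]), call. = FALSE)
  }
  m <- length(map_fields)
  map <- data.frame(
    snp_id = vapply(map_fields, `[[`, "", 2L),
    chromosome = parse_chrom(vapply(map_fields, `[[`, "", 1L)),
    position_bp = as.integer(vapply(map_fields, `[[`, "", 4L)),
    chrom_label = vapply(map_fields, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "\\s+")
  expect_n <- 6L + 2L * m
  nf <- lengths(ped_fields)
  if (any(nf != expect_n)) {
    bad <- which(nf != expect_n)[1]
    stop(sprintf("PED format error at line %d: expected %d fields, found %d",
                 bad, expect_n, nf[bad]), call. = FALSE)
  }
  n <- length(ped_fields)
  fam_id <- vapply(ped_fields, `[[`, "", 1L)
  samples <- vapply(ped_fields, `[[`, "", 2L)
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in PED: ",
         samples[duplicated(samples)][1], call. = FALSE)
  }

  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    gt <- ped_fields[[i]][-(1:6)]
    a1[i, ] <- gt[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- gt[seq(2L, 2L * m, by = 2L)]
  }
  valid_codes <- c("A", "C", "G", "T", "1", "2", "0")
  bad_code <- setdiff(unique(c(a1, a2)), valid_codes)
  if (length(bad_code) > 0) {
    stop("invalid allele codes in PED: ",
         paste(bad_code, collapse = ", "), call. = FALSE)
  }

  dosages <- matrix(NA_integer_, n, m)
  allele_a <- character(m)
  allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    if (any((x1 == "0") != (x2 == "0"))) {
      stop("half-missing genotype at SNP ", map$snp_id[j], call. = FALSE)
    }
    # first-observed allele in sample order (first token, then second)
    obs <- as.vector(rbind(x1[!miss], x2[!miss]))
    alleles <- unique(obs)
    if (length(alleles) > 2) {
      stop("more than two alleles at SNP ", map$snp_id[j], ": ",
           paste(alleles, collapse = "/"), call. = FALSE)
    }
    if (length(alleles) == 0) {
      allele_a[j] <- NA_character_
      next
    }
    allele_a[j] <- alleles[1]
    if (length(alleles) == 2) allele_b[j] <- alleles[2]
    d <- rep(NA_integer_, n)
    if (is.na(allele_b[j])) {
      d[!miss] <- 0L
    } else {
      d[!miss] <- (x1[!miss] == allele_b[j]) + (x2[!miss] == allele_b[j])
    }
    dosages[, j] <- d
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  rownames(dosages) <- samples

  pop <- resolve_populations(populations, samples, fam_id)
  ord <- map_order(map)
  dup <- duplicated(map[ord, c("chromosome", "position_bp")]) &
    !is.na(map$chromosome[ord])
  if (any(dup)) {
    warning("duplicate (chromosome, position) pairs in MAP: ",
            sum(dup), " SNPs", call. = FALSE)
  }
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  genotype_dataset(map[, c("snp_id", "chromosome", "position_bp",
                           "allele_a", "allele_b", "chrom_label")],
                   dosages[, ord, drop = FALSE],
                   stats::setNames(pop, samples))
}

resolve_populations <- function(populations, samples, fam_id = NULL) {
  if (is.character(populations) && length(populations) == 1 &&
      is.null(names(populations))) {
    if (populations == "family_id") {
      if (is.null(fam_id)) {
        stop("family-id population rule needs PED input", call. = FALSE)
      }
      return(fam_id)
    }
    populations <- read_population_table(populations)
  }
  if (is.null(names(populations))) {
    stop("population mapping must be named by sample id", call. = FALSE)
  }
  missing <- setdiff(samples, names(populations))
  if (length(missing) > 0) {
    stop("samples absent from population mapping: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  unname(populations[samples])
}

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns sample_id, population (no header required;
#'   a header line `sample_id<TAB>population` is tolerated).
#' @return named character vector, sample id -> population label.
#' @export
read_population_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "population"))
  if (nrow(df) > 0 && identical(tolower(df$sample_id[1]), "sample_id")) {
    df <- df[-1, , drop = FALSE]
  }
  stats::setNames(df$population, df$sample_id)
}

#' Write a dataset as a PLINK text fileset
#'
#' Inverse of [read_plink()]: dosage 0 is written `a a`, 1 `a b`, 2 `b b`,
#' missing `0 0`. Re-reading reproduces the dataset up to allele orientation
#' (exactly, when the first non-missing genotype at every locus carries
#' `allele_a`).
#'
#' @param dataset a `GenotypeDataset`.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink <- function(dataset, ped_path, map_path) {
  validate_genotype_dataset(dataset)
  map <- dataset$map
  if (nrow(map) == 0) {
    writeLines(character(0), map_path)
  } else {
    chrom_out <- ifelse(is.na(map$chromosome), map$chrom_label,
                        as.character(map$chromosome))
    writeLines(paste(chrom_out, map$snp_id, 0L, map$position_bp,
                     sep = "\t"), map_path)
  }

  d <- dataset$dosages
  n <- nrow(d); m <- ncol(d)
  a <- map$allele_a
  b <- ifelse(is.na(map$allele_b), map$allele_a, map$allele_b)
  ped <- character(n)
  g0 <- paste(a, a); g1 <- paste(a, b); g2 <- paste(b, b)
  for (i in seq_len(n)) {
    di <- d[i, ]
    gt <- rep("0 0", m)
    gt[which(di == 0L)] <- g0[which(di == 0L)]
    gt[which(di == 1L)] <- g1[which(di == 1L)]
    gt[which(di == 2L)] <- g2[which(di == 2L)]
    ped[i] <- paste(dataset$populations[i], dataset$samples[i],
                    "0", "0", "0", "-9",
                    if (m > 0) paste(gt, collapse = " ") else NULL,
                    collapse = " ")
  }
  writeLines(ped, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
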