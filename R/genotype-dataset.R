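#' Two-population SNP genotype dataset
#'
#' The central container shared by all analysis steps: an ordered SNP map, a
#' sample-by-SNP dosage matrix, and a two-level population assignment.
#' Dosages count copies of `allele_b` (0, 1, 2) with `NA` for missing calls.
#'
#' @param map data.frame with columns `snp_id`, `chromosome` (integer; `NA`
#'   for non-autosomal or unparseable labels), `position_bp` (1-based),
#'   `allele_a`, `allele_b` (single characters; `allele_b` may be `NA` for a
#'   locus where only one allele was observed). An optional `chrom_label`
#'   column preserves the original chromosome string.
#' @param dosages integer matrix, samples in rows, SNPs in columns, values in
#'   \{0, 1, 2, NA\}. Row names are sample ids, column names SNP ids.
#' @param populations character vector of population labels, one per sample
#'   (exactly two distinct labels, each with at least two samples). May be
#'   named by sample id; otherwise taken in row order.
#'
#' @return An object of class `GenotypeDataset`: a list with elements `map`,
#'   `dosages`, `samples`, `populations`.
#' @export
genotype_dataset <- function(map, dosages, populations) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  samples <- rownames(dosages)
  if (is.null(samples)) {
    samples <- paste0("sample_", seq_len(nrow(dosages)))
    rownames(dosages) <- samples
  }
  if (!is.null(names(populations))) {
    missing <- setdiff(samples, names(populations))
    if (length(missing) > 0) {
      stop("samples absent from population mapping: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    populations <- unname(populations[samples])
  }
  if (is.null(map$chrom_label)) {
    map$chrom_label <- ifelse(is.na(map$chromosome), NA_character_,
                              as.character(map$chromosome))
  }
  map$chromosome <- as.integer(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)
  colnames(dosages) <- map$snp_id
  obj <- structure(
    list(map = map, dosages = dosages, samples = samples,
         populations = as.character(populations)),
    class = "GenotypeDataset"
  )
  validate_genotype_dataset(obj)
  obj
}

#' Validate a GenotypeDataset
#'
#' Checks the structural invariants: matching dimensions, exactly two
#' population labels with >= 2 samples each, dosages in \{0, 1, 2, NA\},
#' and non-decreasing positions within each chromosome.
#'
#' @param x a `GenotypeDataset`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "GenotypeDataset"))
  map <- x$map
  req <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(req %in% names(map))) {
    stop("map lacks required columns: ",
         paste(setdiff(req, names(map)), collapse = ", "), call. = FALSE)
  }
  if (nrow(x$dosages) != length(x$samples) ||
      ncol(x$dosages) != nrow(map)) {
    stop("dosage matrix dimensions do not match samples x SNPs", call. = FALSE)
  }
  if (length(x$populations) != length(x$samples)) {
    stop("population vector length does not match sample count", call. = FALSE)
  }
  tab <- table(x$populations)
  if (length(tab) != 2) {
    stop("exactly two population labels are required, found ",
         length(tab), call. = FALSE)
  }
  if (any(tab < 2)) {
    stop("each population needs at least 2 samples", call. = FALSE)
  }
  rng <- suppressWarnings(range(x$dosages, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (nrow(map) > 1) {
    same_chrom <- map$chromosome[-1] == map$chromosome[-nrow(map)]
    same_chrom[is.na(same_chrom)] <- FALSE
    backwards <- diff(map$position_bp) < 0 & same_chrom
    if (any(backwards)) {
      stop("positions on chromosome ",
           map$chromosome[which(backwards)[1] + 1],
           " are not non-decreasing", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  tab <- table(x$populations)
  chroms <- unique(x$map$chromosome[!is.na(x$map$chromosome)])
  cat("GenotypeDataset:", length(x$samples), "samples x",
      nrow(x$map), "SNPs\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat("  chromosomes:", length(chroms), "numbered,",
      sum(is.na(x$map$chromosome)), "other\n")
  cat("  missing calls:", sum(is.na(x$dosages)), "\n")
  invisible(x)
}

#' Number of SNPs / samples in a dataset
#' @param x a `GenotypeDataset`.
#' @return integer count.
#' @export
n_snps <- function(x) nrow(x$map)

#' @rdname n_snps
#' @export
n_samples <- function(x) length(x$samples)

#' Population labels in order of first appearance
#' @param x a `GenotypeDataset`.
#' @return character vector of length 2.
#' @export
pop_labels <- function(x) unique(x$populations)

# row indices per population, in pop_labels() order
pop_rows <- function(x) {
  labs <- pop_labels(x)
  lapply(labs, function(l) which(x$populations == l))
}

#' Subset a dataset to a set of SNPs
#'
#' @param x a `GenotypeDataset`.
#' @param keep logical or integer index into the SNP map (map order).
#' @return a `GenotypeDataset` with the selected SNPs, order preserved.
#' @export
subset_snps <- function(x, keep) {
  map <- x$map[keep, , drop = FALSE]
  rownames(map) <- NULL
  out <- x
  out$map <- map
  out$dosages <- x$dosages[, keep, drop = FALSE]
  out
}

# stable sort of a map by (chromosome, position_bp); NA chromosomes last
map_order <- function(map) {
  chrom <- map$chromosome
  chrom_key <- ifelse(is.na(chrom), Inf, chrom)
  order(chrom_key, map$position_bp)  # order() is stable
}

# parse chromosome labels: strip optional "chr" prefix, integers kept,
# everything else (X, Y, MT, 0 treated as unplaced => 0 is integer though)
parse_chrom <- function(labels) {
  stripped <- sub("^[Cc][Hh][Rr]", "", as.character(labels))
  suppressWarnings(as.integer(stripped))
}
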