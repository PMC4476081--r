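#' Flanked genomic intervals around significant SNPs
#'
#' Each SNP becomes a closed 1-based interval
#' `[max(1, pos - flank_bp), pos + flank_bp]`; overlapping or book-ended
#' intervals on the same chromosome are merged (seed SNP ids concatenated).
#'
#' @param snps data.frame with columns `snp_id`, `chromosome`,
#'   `position_bp`.
#' @param flank_bp flank on each side (default 250000, i.e. 0.25 Mb).
#' @param merge merge overlapping/adjacent intervals (default TRUE)?
#' @param source optional label recorded in the `source` column.
#' @return data.frame with columns `chromosome`, `start_bp`, `end_bp`,
#'   `n_snps`, `seed_snps` (comma separated), `source`.
#' @export
make_intervals <- function(snps, flank_bp = 250000, merge = TRUE,
                           source = NA_character_) {
  if (nrow(snps) == 0) {
    return(data.frame(chromosome = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      seed_snps = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chromosome),
    ranges = IRanges::IRanges(
      start = pmax(1, snps$position_bp - flank_bp),
      end = snps$position_bp + flank_bp
    ),
    snp_id = snps$snp_id
  )
  if (merge) {
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    hits <- GenomicRanges::findOverlaps(gr, red)
    seeds <- split(gr$snp_id[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits))
    out <- data.frame(
      chromosome = as.integer(as.character(
        GenomicRanges::seqnames(red))),
      start_bp = GenomicRanges::start(red),
      end_bp = GenomicRanges::end(red),
      n_snps = as.integer(lengths(seeds)),
      seed_snps = vapply(seeds, paste, "", collapse = ","),
      source = source,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      chromosome = as.integer(snps$chromosome),
      start_bp = pmax(1, snps$position_bp - flank_bp),
      end_bp = snps$position_bp + flank_bp,
      n_snps = 1L,
      seed_snps = snps$snp_id,
      source = source,
      stringsAsFactors = FALSE
    )
  }
  ord <- order(out$chromosome, out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# read a gene annotation as GRanges; GFF3 keeps type == "gene" when present
read_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    gr <- rtracklayer::import(annotation)
    if (!is.null(gr$type) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
  } else if (methods::is(annotation, "GRanges")) {
    gr <- annotation
  } else {
    stop("annotation must be a GFF3/BED path or a GRanges", call. = FALSE)
  }
  id <- if (!is.null(gr$ID)) gr$ID else if (!is.null(gr$gene_id))
    gr$gene_id else if (!is.null(gr$name)) gr$name else
      paste0("gene_", seq_along(gr))
  nm <- if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$gene_name))
    gr$gene_name else id
  gr$gene_id <- id
  gr$gene_name <- nm
  gr
}

#' Genes overlapping a set of intervals
#'
#' Reports every gene whose span intersects an interval by at least 1 bp
#' (closed 1-based coordinates; strand ignored). Gene models come from a
#' local GFF3 (feature type "gene") or BED file.
#'
#' @param intervals data.frame from [make_intervals()].
#' @param annotation path to a GFF3/BED file, or a `GRanges`.
#' @return data.frame with one row per (gene, interval) pair: `gene_id`,
#'   `gene_name`, `chromosome`, `gene_start`, `gene_end`, `interval_start`,
#'   `interval_end`, `overlap_bp`.
#' @export
overlap_genes <- function(intervals, annotation) {
  empty <- data.frame(gene_id = character(0), gene_name = character(0),
                      chromosome = integer(0), gene_start = integer(0),
                      gene_end = integer(0), interval_start = integer(0),
                      interval_end = integer(0), overlap_bp = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(intervals) == 0) return(empty)
  genes <- read_annotation(annotation)
  norm <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))
  gene_chrom <- norm(GenomicRanges::seqnames(genes))
  int_chrom <- norm(intervals$chromosome)
  unmatched <- setdiff(unique(int_chrom), unique(gene_chrom))
  if (length(unmatched) > 0) {
    stop("chromosome names absent from annotation: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  gr_int <- GenomicRanges::GRanges(
    seqnames = int_chrom,
    ranges = IRanges::IRanges(start = intervals$start_bp,
                              end = intervals$end_bp))
  gr_genes <- GenomicRanges::GRanges(
    seqnames = gene_chrom,
    ranges = IRanges::IRanges(start = GenomicRanges::start(genes),
                              end = GenomicRanges::end(genes)))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_int)
  if (length(hits) == 0) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_genes[qh], gr_int[sh])
  out <- data.frame(
    gene_id = genes$gene_id[qh],
    gene_name = genes$gene_name[qh],
    chromosome = intervals$chromosome[sh],
    gene_start = GenomicRanges::start(gr_genes)[qh],
    gene_end = GenomicRanges::end(gr_genes)[qh],
    interval_start = intervals$start_bp[sh],
    interval_end = intervals$end_bp[sh],
    overlap_bp = GenomicRanges::width(ov),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Per-chromosome concordance between the two detectors
#'
#' Classifies each chromosome carrying at least one significant SNP as
#' `exact` (the two methods share a significant SNP id), `regional`
#' (nearest significant SNPs within `proximity_bp`) or `discordant`.
#'
#' @param chart_snps,varld_snps data.frames with columns `snp_id`,
#'   `chromosome`, `position_bp` (significant SNPs of each method).
#' @param proximity_bp distance defining regional agreement
#'   (default 500000).
#' @return data.frame with columns `chromosome`, `n_chart`, `n_varld`,
#'   `min_distance_bp`, `class`.
#' @export
method_concordance <- function(chart_snps, varld_snps,
                               proximity_bp = 500000) {
  chroms <- sort(unique(c(chart_snps$chromosome, varld_snps$chromosome)))
  rows <- lapply(chroms, function(chrom) {
    a <- chart_snps[chart_snps$chromosome == chrom, , drop = FALSE]
    b <- varld_snps[varld_snps$chromosome == chrom, , drop = FALSE]
    mind <- NA_real_
    if (nrow(a) > 0 && nrow(b) > 0) {
      mind <- min(abs(outer(a$position_bp, b$position_bp, "-")))
    }
    cls <- if (nrow(a) > 0 && nrow(b) > 0 &&
               length(intersect(a$snp_id, b$snp_id)) > 0) "exact"
    else if (!is.na(mind) && mind <= proximity_bp) "regional"
    else "discordant"
    data.frame(chromosome = chrom, n_chart = nrow(a), n_varld = nrow(b),
               min_distance_bp = mind, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chromosome = integer(0), n_chart = integer(0),
                      n_varld = integer(0), min_distance_bp = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as a BED file
#'
#' Internally 1-based closed coordinates are converted to BED's 0-based
#' half-open convention on export.
#'
#' @param intervals data.frame from [make_intervals()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(intervals$chromosome),
    ranges = IRanges::IRanges(start = intervals$start_bp,
                              end = intervals$end_bp),
    name = intervals$seed_snps
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
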