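#' Assemble and validate a pipeline configuration
#'
#' A configuration is a named list; unknown keys are rejected. Input is
#' either a `simulate` block (arguments to [sim_config()]) or file paths
#' (`ped`/`map` or `vcf`, plus `populations`).
#'
#' @param config named list or path to a YAML file with the same structure.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- c("simulate", "ped", "map", "vcf", "populations",
             "n_autosomes", "max_missing_rate", "min_maf",
             "window_snps", "degree", "iterations", "x_axis", "k",
             "scope", "borderline_fraction",
             "varld_window_snps", "varld_step_snps", "varld_threshold_sd",
             "varld_standardization",
             "annotation", "flank_bp", "proximity_bp",
             "out_dir", "seed", "write_plots")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(n_autosomes = 29, max_missing_rate = 0.025,
                   min_maf = 0.01, window_snps = 20, degree = 1,
                   iterations = 0, x_axis = "position_bp", k = 3,
                   scope = "chromosome", borderline_fraction = 0.9,
                   varld_step_snps = 1, varld_threshold_sd = 3,
                   varld_standardization = "zscore",
                   flank_bp = 250000, proximity_bp = 500000,
                   write_plots = FALSE)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$varld_window_snps)) {
    config$varld_window_snps <- config$window_snps
  }
  has_sim <- !is.null(config$simulate)
  has_files <- !is.null(config$vcf) || (!is.null(config$ped) &&
                                          !is.null(config$map))
  if (!has_sim && !has_files) {
    stop("configuration needs a 'simulate' block or input files",
         call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full selection-signature pipeline
#'
#' Loads or simulates genotypes, runs QC (autosome restriction, filters,
#' imputation), the smoothed-Fst/control-chart scan and the varLD-style
#' regional LD scan, builds flanked intervals around significant SNPs,
#' annotates them against a local gene file when provided, computes
#' cross-method concordance, writes every table as TSV into `out_dir`, and
#' records a JSON run manifest with per-stage record counts.
#'
#' @param config a [pipeline_config()], a plain list, or a YAML path.
#' @param out_dir output directory (created if absent; overrides
#'   `config$out_dir`).
#' @return invisibly, the manifest list. Side effects: TSV/BED/JSON files
#'   (and plot PDFs when `write_plots` is TRUE) in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  truth <- NULL
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      dataset <- sim$dataset
      truth <- sim$truth
      if (nrow(truth$sweeps) > 0) {
        write_tsv(truth$sweeps, file.path(out_dir, "truth_sweeps.tsv"))
      }
      if (nrow(truth$ld_divergent) > 0) {
        write_tsv(truth$ld_divergent,
                  file.path(out_dir, "truth_ld_divergent.tsv"))
      }
    } else if (!is.null(config$vcf)) {
      dataset <- read_vcf(config$vcf, config$populations)
    } else {
      dataset <- read_plink(config$ped, config$map,
                            config$populations %||% "family_id")
    }
    n_input <- n_snps(dataset)

    stage <- "qc"
    qc <- run_qc(dataset, n_autosomes = config$n_autosomes,
                 max_missing_rate = config$max_missing_rate,
                 min_maf = config$min_maf, impute = TRUE)
    write_tsv(as.data.frame(unclass(qc$report)[
      c("n_input_snps", "n_removed_nonautosomal",
        "n_removed_monomorphic_both", "n_removed_missingness",
        "n_removed_maf", "n_retained", "n_imputed_cells")]),
      file.path(out_dir, "qc_report.tsv"))
    write_tsv(qc$heterozygosity, file.path(out_dir, "heterozygosity.tsv"))

    stage <- "fst"
    track <- fst_per_snp(qc$dataset)
    write_fst_track(track, file.path(out_dir, "fst_track.tsv"))
    mfst <- mean_fst(track)

    stage <- "scan"
    scan <- fst_scan(track, window_snps = config$window_snps,
                     degree = config$degree,
                     iterations = config$iterations,
                     x_axis = config$x_axis, k = config$k,
                     scope = config$scope,
                     borderline_fraction = config$borderline_fraction)
    write_tsv(scan$snps, file.path(out_dir, "scan_snps.tsv"))
    write_tsv(scan$limits, file.path(out_dir, "scan_limits.tsv"))
    write_tsv(scan$peaks, file.path(out_dir, "scan_peaks.tsv"))

    stage <- "varld"
    varld <- varld_scan(qc$dataset,
                        window_snps = config$varld_window_snps,
                        step_snps = config$varld_step_snps,
                        threshold_sd = config$varld_threshold_sd,
                        standardization = config$varld_standardization)
    write_tsv(varld$windows, file.path(out_dir, "varld_windows.tsv"))

    stage <- "annotate"
    chart_snps <- scan_outlier_snps(scan)
    varld_snps <- varld_significant_snps(varld)
    intervals <- rbind(
      make_intervals(chart_snps, config$flank_bp, source = "control_chart"),
      make_intervals(varld_snps, config$flank_bp, source = "varld"))
    write_tsv(intervals, file.path(out_dir, "intervals.tsv"))
    write_intervals_bed(intervals, file.path(out_dir, "intervals.bed"))
    gene_hits <- NULL
    if (!is.null(config$annotation)) {
      gene_hits <- overlap_genes(intervals, config$annotation)
      write_tsv(gene_hits, file.path(out_dir, "gene_hits.tsv"))
    }
    concord <- method_concordance(chart_snps, varld_snps,
                                  config$proximity_bp)
    write_tsv(concord, file.path(out_dir, "concordance.tsv"))

    if (isTRUE(config$write_plots)) {
      stage <- "plots"
      for (chrom in unique(scan$limits$chromosome)) {
        p <- plot_scan_triptych(scan, track, chrom)
        ggplot2::ggsave(
          file.path(out_dir, sprintf("scan_chr%02d.pdf", chrom)), p,
          width = 8, height = 9)
      }
      ggplot2::ggsave(file.path(out_dir, "varld_manhattan.pdf"),
                      plot_varld_manhattan(varld), width = 10, height = 4)
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("fstscan")),
      seed = config$seed,
      config = unclass(config)[!vapply(config, is.null, TRUE)],
      counts = list(
        n_input_snps = n_input,
        n_retained_snps = n_snps(qc$dataset),
        n_samples = n_samples(qc$dataset),
        n_fst_loci = sum(!is.na(track$fst)),
        n_scan_snps = nrow(scan$snps),
        n_outlier_snps = sum(scan$snps$flag == "outlier_high"),
        n_outlier_peaks = sum(scan$peaks$type == "outlier"),
        n_borderline_peaks = sum(scan$peaks$type == "borderline"),
        n_varld_windows = nrow(varld$windows),
        n_varld_significant = sum(varld$windows$significant),
        n_intervals = nrow(intervals),
        n_gene_hits = if (is.null(gene_hits)) NA else nrow(gene_hits),
        n_concordant_chromosomes =
          sum(concord$class %in% c("exact", "regional"))
      ),
      mean_fst = mfst$mean,
      sd_fst = mfst$sd
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(manifest = manifest, dataset = qc$dataset, qc = qc,
         track = track, scan = scan, varld = varld,
         intervals = intervals, gene_hits = gene_hits,
         concordance = concord, truth = truth)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
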