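#' Configuration for the two-population genotype simulator
#'
#' Defaults emulate a bovine 50K array study: 29 autosomes, ~1,724 SNPs per
#' 100-Mb chromosome (~50K total), 364 + 410 sampled individuals, and drift
#' parameters (`t_gens = 100`, `n_e = 800`) that yield a background
#' genome-wide mean Fst of about 0.03 between the two populations.
#'
#' @param n_chromosomes number of autosomes (default 29).
#' @param snps_per_chromosome SNPs per chromosome (default 1724).
#' @param chromosome_length_bp physical length in bp (default 1e8).
#' @param n_samples integer vector of two per-population sample sizes
#'   (default `c(364, 410)`).
#' @param pop_labels two population labels (default `c("pop1", "pop2")`).
#' @param freq_bounds bounds of the uniform ancestral allele-b frequency
#'   (default `c(0.05, 0.95)`).
#' @param rho target correlation between adjacent haplotype alleles
#'   (first-order Markov LD; default 0.3).
#' @param t_gens generations of independent Wright-Fisher drift in each
#'   population since the split (default 100).
#' @param n_e effective population size per population (default 800;
#'   binomial resampling of 2 * `n_e` chromosomes per generation).
#' @param sweeps optional data.frame of planted sweeps with columns
#'   `chromosome`, `position_bp`, `s` (selection coefficient > 0),
#'   `decay_bp` (hitchhiking decay length), `target_pop` (1 or 2).
#' @param ld_divergent optional data.frame of LD-perturbed regions with
#'   columns `chromosome`, `start_bp`, `end_bp`, `target_pop`, and
#'   optionally `rho` (local coupling in the target population, default 0 =
#'   LD erased; marginal frequencies are untouched either way).
#' @param ld_mode `"attenuate"` (default: local coupling set to
#'   `ld_divergent$rho`) or `"sign_flip"` (coupling sign inverted; note the
#'   windowed correlation spectrum is invariant to pure sign flips, so such
#'   regions are invisible to the eigenvalue statistic).
#' @param missing_rate iid missing-call rate (default 0.002).
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 29, snps_per_chromosome = 1724,
                       chromosome_length_bp = 1e8,
                       n_samples = c(364, 410),
                       pop_labels = c("pop1", "pop2"),
                       freq_bounds = c(0.05, 0.95), rho = 0.3,
                       t_gens = 100, n_e = 800,
                       sweeps = NULL, ld_divergent = NULL,
                       ld_mode = c("attenuate", "sign_flip"),
                       missing_rate = 0.002, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  ld_mode <- match.arg(ld_mode)
  stopifnot(rho >= 0, rho < 1, missing_rate >= 0, missing_rate <= 1,
            length(n_samples) == 2, all(n_samples >= 2),
            freq_bounds[1] > 0, freq_bounds[2] < 1,
            freq_bounds[1] <= freq_bounds[2], t_gens >= 0, n_e >= 1)
  if (!is.null(sweeps)) {
    stopifnot(all(sweeps$s > 0),
              all(sweeps$chromosome %in% seq_len(n_chromosomes)))
    if (any(sweeps$position_bp < 1 |
            sweeps$position_bp > chromosome_length_bp)) {
      stop("sweep position outside chromosome", call. = FALSE)
    }
  }
  if (!is.null(ld_divergent)) {
    stopifnot(all(ld_divergent$chromosome %in% seq_len(n_chromosomes)),
              all(ld_divergent$start_bp <= ld_divergent$end_bp))
    if (is.null(ld_divergent$rho)) ld_divergent$rho <- 0
  }
  structure(list(n_chromosomes = n_chromosomes,
                 snps_per_chromosome = snps_per_chromosome,
                 chromosome_length_bp = chromosome_length_bp,
                 n_samples = as.integer(n_samples),
                 pop_labels = pop_labels,
                 freq_bounds = freq_bounds, rho = rho,
                 t_gens = t_gens, n_e = n_e,
                 sweeps = sweeps, ld_divergent = ld_divergent,
                 ld_mode = ld_mode,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic logistic allele-frequency trajectory of a favored allele
sweep_trajectory <- function(p0, s, t_gens) {
  p <- p0
  for (t in seq_len(t_gens)) p <- p * (1 + s) / (1 + s * p)
  p
}

# emit nh haplotypes along one chromosome as a first-order Markov walk with
# per-SNP marginals p and adjacent-pair correlations rho_j (length m-1).
# Joint probabilities are Frechet-clamped so marginals are exact.
markov_haplotypes <- function(nh, p, rho_adj) {
  m <- length(p)
  H <- matrix(0L, nh, m)
  H[, 1] <- stats::rbinom(nh, 1L, p[1])
  if (m == 1) return(H)
  p1 <- p[-m]; p2 <- p[-1]
  p11 <- p1 * p2 + rho_adj * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- pmin(pmax(p11, pmax(0, p1 + p2 - 1)), pmin(p1, p2))
  cond1 <- ifelse(p1 > 0, p11 / p1, p2)
  cond0 <- ifelse(p1 < 1, (p2 - p11) / (1 - p1), p2)
  cond1 <- pmin(pmax(cond1, 0), 1)
  cond0 <- pmin(pmax(cond0, 0), 1)
  U <- matrix(stats::runif(nh * (m - 1)), nh, m - 1)
  for (j in 2:m) {
    pr <- cond0[j - 1] + (cond1[j - 1] - cond0[j - 1]) * H[, j - 1]
    H[, j] <- (U[, j - 1] < pr) + 0L
  }
  H
}

#' Simulate a two-population SNP-array dataset with known truth
#'
#' The generator (1) draws ancestral allele frequencies uniformly within
#' `freq_bounds`; (2) drifts each population independently for `t_gens`
#' generations of Wright-Fisher binomial resampling of `2 * n_e`
#' chromosomes; (3) at each planted sweep drives the selected allele of the
#' target population along the deterministic logistic trajectory
#' `p' = p (1+s) / (1 + s p)` for `t_gens` generations and pulls flanking
#' SNP frequencies toward the swept frequency with weight
#' `exp(-distance / decay_bp)` (a phenomenological hitchhiking model);
#' (4) emits haplotypes per population by a first-order Markov walk with
#' adjacent-SNP correlation `rho`, two haplotypes per individual summed to
#' dosages; (5) in LD-divergent regions alters the Markov coupling of the
#' target population without changing marginal frequencies; (6) plants iid
#' missing calls. Identical configurations (including seed) give identical
#' output.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `GenotypeDataset`) and `truth` (class
#'   `sim_truth`: `sweeps` and `ld_divergent` data.frames with realized
#'   per-locus values, plus the echoed config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  n1 <- config$n_samples[1]; n2 <- config$n_samples[2]
  nh <- c(2L * n1, 2L * n2)
  m_per <- config$snps_per_chromosome
  L <- config$chromosome_length_bp
  nucs <- c("A", "C", "G", "T")

  maps <- list(); dos <- list()
  sweep_truth <- list(); ld_truth <- list()
  for (chrom in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(L, m_per))
    p0 <- stats::runif(m_per, config$freq_bounds[1], config$freq_bounds[2])
    p_pop <- list(p0, p0)
    for (k in 1:2) {
      p <- p_pop[[k]]
      for (t in seq_len(config$t_gens)) {
        p <- stats::rbinom(m_per, 2L * config$n_e, p) / (2 * config$n_e)
      }
      p_pop[[k]] <- p
    }

    sw <- config$sweeps
    if (!is.null(sw)) sw <- sw[sw$chromosome == chrom, , drop = FALSE]
    if (!is.null(sw) && nrow(sw) > 0) {
      for (i in seq_len(nrow(sw))) {
        tgt <- sw$target_pop[i]
        j_sweep <- which.min(abs(pos - sw$position_bp[i]))
        # the favored variant is the ancestral minor allele: a sweep drives
        # a low-frequency allele toward fixation
        p_anc <- p0[j_sweep]
        p_star <- if (p_anc <= 0.5) {
          sweep_trajectory(p_anc, sw$s[i], config$t_gens)
        } else {
          1 - sweep_trajectory(1 - p_anc, sw$s[i], config$t_gens)
        }
        p <- p_pop[[tgt]]
        w <- exp(-abs(pos - pos[j_sweep]) / sw$decay_bp[i])
        p_pop[[tgt]] <- (1 - w) * p + w * p_star
        sweep_truth[[length(sweep_truth) + 1]] <- data.frame(
          chromosome = chrom, position_bp = pos[j_sweep],
          snp_index = j_sweep, s = sw$s[i], target_pop = tgt,
          swept_freq = p_star,
          freq_diff = abs(p_pop[[tgt]][j_sweep] -
                            p_pop[[-tgt + 3]][j_sweep])
        )
      }
    }

    rho_adj <- list(rep(config$rho, m_per - 1), rep(config$rho, m_per - 1))
    ld <- config$ld_divergent
    if (!is.null(ld)) ld <- ld[ld$chromosome == chrom, , drop = FALSE]
    if (!is.null(ld) && nrow(ld) > 0) {
      for (i in seq_len(nrow(ld))) {
        tgt <- ld$target_pop[i]
        in_region <- which(pos[-m_per] >= ld$start_bp[i] &
                             pos[-1] <= ld$end_bp[i])
        if (length(in_region) == 0) next
        rho_adj[[tgt]][in_region] <- if (config$ld_mode == "attenuate") {
          ld$rho[i]
        } else {
          -rho_adj[[tgt]][in_region]
        }
        ld_truth[[length(ld_truth) + 1]] <- data.frame(
          chromosome = chrom, start_bp = ld$start_bp[i],
          end_bp = ld$end_bp[i], target_pop = tgt,
          n_pairs = length(in_region), mode = config$ld_mode
        )
      }
    }

    d_chrom <- vector("list", 2)
    for (k in 1:2) {
      H <- markov_haplotypes(nh[k], p_pop[[k]], rho_adj[[k]])
      odd <- seq(1L, nh[k], by = 2L)
      d_chrom[[k]] <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
    }
    dos[[chrom]] <- rbind(d_chrom[[1]], d_chrom[[2]])

    allele_pairs <- t(vapply(seq_len(m_per),
                             function(i) sample(nucs, 2), character(2)))
    maps[[chrom]] <- data.frame(
      snp_id = sprintf("snp_%02d_%05d", chrom, seq_len(m_per)),
      chromosome = chrom,
      position_bp = pos,
      allele_a = allele_pairs[, 1],
      allele_b = allele_pairs[, 2],
      stringsAsFactors = FALSE
    )
  }

  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  dosages <- do.call(cbind, dos)
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dosages)) < config$missing_rate
    dosages[miss] <- NA_integer_
  }
  samples <- c(sprintf("%s_%03d", config$pop_labels[1], seq_len(n1)),
               sprintf("%s_%03d", config$pop_labels[2], seq_len(n2)))
  rownames(dosages) <- samples
  populations <- stats::setNames(
    rep(config$pop_labels, c(n1, n2)), samples)
  ds <- genotype_dataset(map, dosages, populations)

  truth <- structure(list(
    sweeps = if (length(sweep_truth) > 0) do.call(rbind, sweep_truth) else
      data.frame(chromosome = integer(0), position_bp = integer(0),
                 snp_index = integer(0), s = numeric(0),
                 target_pop = integer(0), swept_freq = numeric(0),
                 freq_diff = numeric(0)),
    ld_divergent = if (length(ld_truth) > 0) do.call(rbind, ld_truth) else
      data.frame(chromosome = integer(0), start_bp = integer(0),
                 end_bp = integer(0), target_pop = integer(0),
                 n_pairs = integer(0), mode = character(0)),
    config = config
  ), class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' One planted sweep per chromosome
#'
#' Convenience builder for recovery experiments: a sweep at mid-chromosome
#' on every autosome, alternating target population.
#'
#' @param config a [sim_config()].
#' @param s selection coefficient (default 0.1).
#' @param decay_bp hitchhiking decay length (default 500000).
#' @return data.frame suitable for `sim_config(sweeps = ...)`.
#' @export
sweep_per_chromosome <- function(config, s = 0.1, decay_bp = 500000) {
  data.frame(
    chromosome = seq_len(config$n_chromosomes),
    position_bp = round(config$chromosome_length_bp / 2),
    s = s,
    decay_bp = decay_bp,
    target_pop = rep_len(c(1L, 2L), config$n_chromosomes)
  )
}

#' Score detections against simulated truth
#'
#' A detection is a true positive when it lies within `tolerance_bp` of a
#' truth locus (for interval-shaped truths, within the interval extended by
#' the tolerance on both sides).
#'
#' @param detections data.frame with columns `chromosome` and a position
#'   column (`position_bp`, `summit_bp` or `central_bp`; the first present
#'   is used).
#' @param truth data.frame with `chromosome` and either `position_bp` or
#'   `start_bp`/`end_bp`, e.g. `truth$sweeps` or `truth$ld_divergent` from
#'   [simulate_dataset()].
#' @param tolerance_bp matching tolerance (default 500000).
#' @return list with `power` (fraction of truth loci detected), `fdp`
#'   (fraction of detections matching no truth locus), `localization_bp`
#'   (median distance of matched detections to their truth locus),
#'   `n_detections`, `n_truth`.
#' @export
evaluate_detection <- function(detections, truth, tolerance_bp = 500000) {
  pos_col <- intersect(c("position_bp", "summit_bp", "central_bp"),
                       names(detections))[1]
  if (nrow(detections) > 0 && is.na(pos_col)) {
    stop("detections need a position column", call. = FALSE)
  }
  if ("position_bp" %in% names(truth) && !("start_bp" %in% names(truth))) {
    t_start <- truth$position_bp; t_end <- truth$position_bp
  } else {
    t_start <- truth$start_bp; t_end <- truth$end_bp
  }
  n_truth <- nrow(truth)
  n_det <- nrow(detections)
  if (n_truth == 0) {
    return(list(power = NA_real_, fdp = if (n_det > 0) 1 else NA_real_,
                localization_bp = NA_real_,
                n_detections = n_det, n_truth = 0L))
  }
  if (n_det == 0) {
    return(list(power = 0, fdp = NA_real_, localization_bp = NA_real_,
                n_detections = 0L, n_truth = n_truth))
  }
  d_pos <- detections[[pos_col]]
  d_chrom <- detections$chromosome
  truth_hit <- logical(n_truth)
  det_hit <- logical(n_det)
  loc <- numeric(0)
  for (i in seq_len(n_truth)) {
    same <- d_chrom == truth$chromosome[i]
    near <- same & d_pos >= t_start[i] - tolerance_bp &
      d_pos <= t_end[i] + tolerance_bp
    if (any(near)) {
      truth_hit[i] <- TRUE
      det_hit <- det_hit | near
      dist <- pmax(0, pmax(t_start[i] - d_pos[near],
                           d_pos[near] - t_end[i]))
      loc <- c(loc, min(dist))
    }
  }
  list(power = mean(truth_hit),
       fdp = mean(!det_hit),
       localization_bp = if (length(loc) > 0) stats::median(loc) else
         NA_real_,
       n_detections = n_det, n_truth = n_truth)
}
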