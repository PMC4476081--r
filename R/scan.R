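#' Smoothing fraction for a fixed SNP window
#'
#' The LOWESS span `S` is chosen per chromosome so that each local
#' regression draws on a fixed number of SNPs: `S = window_snps / n`.
#'
#' @param chrom_snp_count number of SNPs on the chromosome.
#' @param window_snps target window size (default 20).
#' @return the span `S` in (0, 1\]; if the chromosome carries fewer SNPs
#'   than the window, falls back to `S = 1` with a warning.
#' @export
smoothing_fraction <- function(chrom_snp_count, window_snps = 20) {
  if (chrom_snp_count < window_snps) {
    warning("chromosome has ", chrom_snp_count, " SNPs < window of ",
            window_snps, "; using S = 1", call. = FALSE)
    return(1)
  }
  window_snps / chrom_snp_count
}

#' Locally weighted scatterplot smoothing (LOWESS)
#'
#' Classic tricube-weighted local polynomial regression evaluated at every
#' input point. The neighborhood of a point is its nearest
#' `ceiling(span * n)` points by |x distance| (always a contiguous run on
#' the sorted abscissa). Optional robustness iterations down-weight large
#' residuals with the bisquare function.
#'
#' @param x strictly increasing abscissa (bp positions or SNP ranks).
#' @param y finite response values, same length.
#' @param span fraction of points per local fit, in (0, 1\]. Exactly one of
#'   `span` and `window` must be given.
#' @param window neighborhood size in points (overrides `span`).
#' @param degree local polynomial degree (0, 1 or 2; default 1).
#' @param iterations robustness (bisquare) iterations, default 0.
#' @return numeric vector of fitted values, same length as `x`.
#' @export
lowess_smooth <- function(x, y, span = NULL, window = NULL, degree = 1,
                          iterations = 0) {
  n <- length(x)
  stopifnot(length(y) == n, degree %in% 0:2)
  if (n == 0) return(numeric(0))
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (is.null(window)) {
    if (is.null(span)) stop("give span or window", call. = FALSE)
    window <- ceiling(span * n)
  }
  q <- max(min(window, n), degree + 2)
  if (n < degree + 2) {
    stop("need at least degree + 2 points", call. = FALSE)
  }

  # contiguous nearest-q window per point (two-pointer over sorted x)
  starts <- integer(n)
  s <- 1L
  for (i in seq_len(n)) {
    while (s + q <= n && (x[i] - x[s]) > (x[s + q] - x[i])) s <- s + 1L
    starts[i] <- s
  }

  robust_w <- rep(1, n)
  fitted <- numeric(n)
  for (iter in 0:iterations) {
    for (i in seq_len(n)) {
      idx <- starts[i]:(starts[i] + q - 1L)
      xc <- x[idx] - x[i]
      h <- max(abs(xc))
      w <- if (h > 0) (1 - pmin(abs(xc) / h, 1)^3)^3 else rep(1, q)
      w <- w * robust_w[idx]
      sw <- sum(w)
      if (sw <= 0) {  # all weight killed (robustness edge); fall back
        fitted[i] <- mean(y[idx])
        next
      }
      if (degree == 0 || h == 0) {
        fitted[i] <- sum(w * y[idx]) / sw
      } else if (degree == 1) {
        mx <- sum(w * xc) / sw
        my <- sum(w * y[idx]) / sw
        sxx <- sum(w * (xc - mx)^2)
        if (sxx > 0) {
          b <- sum(w * (xc - mx) * (y[idx] - my)) / sxx
          fitted[i] <- my - b * mx  # value at xc = 0
        } else {
          fitted[i] <- my
        }
      } else {
        X <- cbind(1, xc, xc^2)
        fit <- stats::lm.wfit(X, y[idx], w)
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        fitted[i] <- beta[1]
      }
    }
    if (iter < iterations) {
      r <- y - fitted
      s6 <- 6 * stats::median(abs(r))
      robust_w <- if (s6 > 0) pmax(1 - (r / s6)^2, 0)^2 else rep(1, n)
    }
  }
  fitted
}

#' Control-chart limits and flags for a smoothed track
#'
#' Limits are `mean +/- k * SD` of the supplied values (sample SD, n-1
#' denominator). Flags use strict inequalities: a value exactly on a limit
#' is `normal`.
#'
#' @param smoothed finite smoothed values for one chromosome (>= 2 values).
#' @param k number of standard deviations for the limits (default 3).
#' @return list with `mean`, `sd`, `ucl`, `lcl`, `k` and per-value `flags`
#'   (`"outlier_high"`, `"outlier_low"` or `"normal"`).
#' @export
control_chart <- function(smoothed, k = 3) {
  stopifnot(length(smoothed) >= 2, all(is.finite(smoothed)))
  m <- mean(smoothed)
  s <- stats::sd(smoothed)
  ucl <- m + k * s
  lcl <- m - k * s
  if (s == 0) message("control_chart: zero SD, limits collapse to the mean")
  flags <- rep("normal", length(smoothed))
  flags[smoothed > ucl] <- "outlier_high"
  flags[smoothed < lcl] <- "outlier_low"
  list(mean = m, sd = s, ucl = ucl, lcl = lcl, k = k, flags = flags)
}

#' Collapse flagged SNPs into peaks
#'
#' Contiguous runs of SNPs whose smoothed value exceeds the upper control
#' limit collapse to one outlier peak (summit = maximum smoothed value).
#' Runs that rise above `mean + borderline_fraction * k * sd` without any
#' SNP exceeding the UCL are reported as borderline peaks.
#'
#' @param snps data.frame for one chromosome with columns `snp_id`,
#'   `position_bp`, `smoothed_fst`, in position order.
#' @param chart a [control_chart()] result for the same values.
#' @param borderline_fraction fraction of the mean-to-UCL distance a
#'   borderline run must exceed (default 0.9).
#' @return data.frame with columns `type` (`"outlier"`/`"borderline"`),
#'   `start_bp`, `end_bp`, `n_snps`, `summit_snp_id`, `summit_bp`,
#'   `summit_value`.
#' @export
classify_peaks <- function(snps, chart, borderline_fraction = 0.9) {
  b_thresh <- chart$mean + borderline_fraction * chart$k * chart$sd
  above_b <- snps$smoothed_fst > b_thresh
  peaks <- list()
  if (any(above_b)) {
    runs <- rle(above_b)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      over_ucl <- snps$smoothed_fst[idx] > chart$ucl
      if (any(over_ucl)) {
        idx_peak <- idx[over_ucl]   # peak span = UCL exceedance run(s)
        sub_runs <- rle(over_ucl)
        sub_ends <- cumsum(sub_runs$lengths)
        sub_starts <- sub_ends - sub_runs$lengths + 1L
        for (sr in which(sub_runs$values)) {
          sidx <- idx[sub_starts[sr]:sub_ends[sr]]
          top <- sidx[which.max(snps$smoothed_fst[sidx])]
          peaks[[length(peaks) + 1]] <- data.frame(
            type = "outlier",
            start_bp = min(snps$position_bp[sidx]),
            end_bp = max(snps$position_bp[sidx]),
            n_snps = length(sidx),
            summit_snp_id = snps$snp_id[top],
            summit_bp = snps$position_bp[top],
            summit_value = snps$smoothed_fst[top],
            stringsAsFactors = FALSE
          )
        }
      } else {
        top <- idx[which.max(snps$smoothed_fst[idx])]
        peaks[[length(peaks) + 1]] <- data.frame(
          type = "borderline",
          start_bp = min(snps$position_bp[idx]),
          end_bp = max(snps$position_bp[idx]),
          n_snps = length(idx),
          summit_snp_id = snps$snp_id[top],
          summit_bp = snps$position_bp[top],
          summit_value = snps$smoothed_fst[top],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(peaks) == 0) {
    return(data.frame(type = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      summit_snp_id = character(0), summit_bp = integer(0),
                      summit_value = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, peaks)
}

#' Genome scan: smooth the Fst track and flag control-chart outliers
#'
#' For each chromosome, drops NA-Fst loci, smooths the remaining track with
#' [lowess_smooth()] using a span equivalent to `window_snps` SNPs, then
#' applies a `mean +/- k*SD` control chart (moments per chromosome by
#' default, or pooled over the genome) and collapses exceedances into peaks.
#'
#' @param track an `fst_track` from [fst_per_snp()].
#' @param window_snps SNPs per local regression (default 20).
#' @param degree,iterations passed to [lowess_smooth()].
#' @param x_axis `"position_bp"` (default) or `"snp_index"` regression
#'   abscissa.
#' @param k control-limit width in SDs (default 3).
#' @param scope `"chromosome"` (default): chart moments per chromosome;
#'   `"genome"`: one set of moments for all smoothed values.
#' @param borderline_fraction passed to [classify_peaks()].
#' @return object of class `fst_scan`: list with `snps` (per-SNP table with
#'   `smoothed_fst` and `flag`), `limits` (per-chromosome chart), `peaks`,
#'   and the configuration.
#' @export
fst_scan <- function(track, window_snps = 20, degree = 1, iterations = 0,
                     x_axis = c("position_bp", "snp_index"), k = 3,
                     scope = c("chromosome", "genome"),
                     borderline_fraction = 0.9) {
  x_axis <- match.arg(x_axis)
  scope <- match.arg(scope)
  keep <- !is.na(track$fst) & !is.na(track$chromosome)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("fst_scan: ", n_dropped, " loci with NA Fst or chromosome dropped")
  }
  df <- as.data.frame(track)[keep, , drop = FALSE]
  chroms <- sort(unique(df$chromosome))

  per_chrom <- list()
  for (chrom in chroms) {
    sub <- df[df$chromosome == chrom, , drop = FALSE]
    if (nrow(sub) < degree + 2) {
      warning("chromosome ", chrom, " has too few SNPs; skipped",
              call. = FALSE)
      next
    }
    xs <- if (x_axis == "position_bp") as.numeric(sub$position_bp) else
      as.numeric(seq_len(nrow(sub)))
    ndup <- 0L
    while (any(duplicated(xs))) {  # jitter duplicate positions by +1 bp
      d <- duplicated(xs)
      xs[d] <- xs[d] + 1
      ndup <- ndup + sum(d)
    }
    if (ndup > 0) {
      warning("chromosome ", chrom, ": duplicate positions jittered",
              call. = FALSE)
    }
    sub$smoothed_fst <- lowess_smooth(xs, sub$fst, window = window_snps,
                                      degree = degree,
                                      iterations = iterations)
    per_chrom[[as.character(chrom)]] <- sub
  }
  if (length(per_chrom) == 0) stop("no chromosome could be smoothed",
                                   call. = FALSE)

  all_smoothed <- unlist(lapply(per_chrom, `[[`, "smoothed_fst"))
  genome_chart <- if (scope == "genome") control_chart(all_smoothed, k) else
    NULL

  snp_tabs <- list(); limit_rows <- list(); peak_tabs <- list()
  for (nm in names(per_chrom)) {
    sub <- per_chrom[[nm]]
    chart <- if (scope == "genome") {
      c(genome_chart[c("mean", "sd", "ucl", "lcl", "k")],
        list(flags = {
          f <- rep("normal", nrow(sub))
          f[sub$smoothed_fst > genome_chart$ucl] <- "outlier_high"
          f[sub$smoothed_fst < genome_chart$lcl] <- "outlier_low"
          f
        }))
    } else {
      control_chart(sub$smoothed_fst, k)
    }
    sub$flag <- chart$flags
    peaks <- classify_peaks(sub, chart, borderline_fraction)
    if (nrow(peaks) > 0) {
      peaks <- cbind(chromosome = as.integer(nm), peaks)
      peak_tabs[[nm]] <- peaks
    }
    limit_rows[[nm]] <- data.frame(
      chromosome = as.integer(nm), n_snps = nrow(sub),
      s_param = smoothing_fraction(max(nrow(sub), window_snps), window_snps),
      mean = chart$mean, sd = chart$sd, lcl = chart$lcl, ucl = chart$ucl,
      k = k
    )
    snp_tabs[[nm]] <- sub[, c("snp_id", "chromosome", "position_bp",
                              "fst", "smoothed_fst", "flag")]
  }
  snps <- do.call(rbind, snp_tabs)
  rownames(snps) <- NULL
  limits <- do.call(rbind, limit_rows)
  rownames(limits) <- NULL
  peaks <- if (length(peak_tabs) > 0) do.call(rbind, peak_tabs) else
    data.frame(chromosome = integer(0), type = character(0),
               start_bp = integer(0), end_bp = integer(0),
               n_snps = integer(0), summit_snp_id = character(0),
               summit_bp = integer(0), summit_value = numeric(0))
  rownames(peaks) <- NULL
  structure(list(snps = snps, limits = limits, peaks = peaks,
                 config = list(window_snps = window_snps, degree = degree,
                               iterations = iterations, x_axis = x_axis,
                               k = k, scope = scope,
                               borderline_fraction = borderline_fraction),
                 n_dropped = n_dropped),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  n_out <- sum(x$snps$flag == "outlier_high")
  cat("Fst genome scan:", nrow(x$snps), "SNPs on",
      nrow(x$limits), "chromosomes\n")
  cat("  window:", x$config$window_snps, "SNPs; limits: mean +/-",
      x$config$k, "SD per", x$config$scope, "\n")
  cat("  SNPs above UCL:", n_out, "; peaks:",
      sum(x$peaks$type == "outlier"), "outlier,",
      sum(x$peaks$type == "borderline"), "borderline\n")
  invisible(x)
}

#' Significant SNPs of a scan
#'
#' @param scan an `fst_scan`.
#' @return data.frame of SNPs whose smoothed Fst exceeds the upper control
#'   limit (only upper exceedances count as selection signatures).
#' @export
scan_outlier_snps <- function(scan) {
  scan$snps[scan$snps$flag == "outlier_high", , drop = FALSE]
}
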