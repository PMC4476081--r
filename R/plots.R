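#' Raw / smoothed / control-chart triptych for one chromosome
#'
#' Three stacked panels: the raw per-SNP Fst track, the LOWESS-smoothed
#' track, and the control chart of smoothed values with dashed upper and
#' lower control limits.
#'
#' @param scan an `fst_scan`.
#' @param track the `fst_track` the scan was computed from.
#' @param chromosome chromosome to plot.
#' @return a patchwork/ggplot object.
#' @export
plot_scan_triptych <- function(scan, track, chromosome) {
  raw <- as.data.frame(track)
  raw <- raw[!is.na(raw$chromosome) & raw$chromosome == chromosome &
               !is.na(raw$fst), , drop = FALSE]
  sm <- scan$snps[scan$snps$chromosome == chromosome, , drop = FALSE]
  lim <- scan$limits[scan$limits$chromosome == chromosome, , drop = FALSE]
  mb <- function(x) x / 1e6
  p1 <- ggplot2::ggplot(raw, ggplot2::aes(mb(position_bp), fst)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "raw Fst",
                  title = paste0("BTA", chromosome)) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(sm, ggplot2::aes(mb(position_bp), smoothed_fst)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "smoothed Fst") +
    ggplot2::theme_minimal()
  p3 <- ggplot2::ggplot(sm, ggplot2::aes(mb(position_bp), smoothed_fst)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = lim$mean, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(lim$ucl, lim$lcl),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_point(data = sm[sm$flag != "normal", , drop = FALSE],
                        color = "red", size = 0.8) +
    ggplot2::labs(x = "position (Mb)", y = "smoothed Fst") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, p3, ncol = 1)
}

#' Manhattan-style plot of standardized varLD scores
#'
#' @param varld a `varld_scan`.
#' @return a ggplot object with the significance threshold line.
#' @export
plot_varld_manhattan <- function(varld) {
  w <- varld$windows
  w$chrom_f <- factor(w$chromosome)
  ggplot2::ggplot(w, ggplot2::aes(central_bp / 1e6, std_score,
                                  color = chrom_f)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = varld$config$threshold_sd,
                        linetype = "dashed") +
    ggplot2::facet_grid(~chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "standardized varLD score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
}

utils::globalVariables(c("position_bp", "fst", "smoothed_fst", "flag",
                         "central_bp", "std_score", "chrom_f"))
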