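# ggplot2 views of the window-level results. Each result type gets a
# plot_*() function; autoplot() dispatches on the profile class.

#' Plot the SNP density landscape
#'
#' Heterozygous and homozygous SNP counts per window along each
#' chromosome.
#'
#' @param profile SNP window profile from [profile_snp_windows()].
#' @return A ggplot object.
#' @export
plot_snp_landscape <- function(profile) {
  long <- as_tibble(profile) |>
    select("chrom", "start", "het_count", "hom_count") |>
    tidyr::pivot_longer(c("het_count", "hom_count"),
                        names_to = "metric", values_to = "count") |>
    mutate(metric = ifelse(.data$metric == "het_count",
                           "heterozygous", "homozygous"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6,
                                     y = .data$count,
                                     colour = .data$metric)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "position (Mb)", y = "SNPs per window",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.genarch_snp_profile <- function(object, ...) {
  plot_snp_landscape(object)
}

#' Plot insertion-event counts per window and tier
#'
#' One row per organelle and length tier, mirroring the common
#' multi-track view of nuclear organelle insertions.
#'
#' @param profile Output of [count_events_per_window()].
#' @return A ggplot object.
#' @export
plot_insertion_windows <- function(profile) {
  dat <- as_tibble(profile) |>
    mutate(tier_lab = paste0(">=", ifelse(.data$tier >= 1000,
                                          paste0(.data$tier / 1000, "kb"),
                                          paste0(.data$tier, "bp"))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$start / 1e6, y = .data$n,
                                    fill = .data$organelle)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7, width = 0.1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$tier_lab),
                        cols = ggplot2::vars(.data$chrom),
                        scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insertion events",
                  fill = "organelle") +
    ggplot2::theme_minimal()
}

#' Plot canonical monomer frequency against monomer length
#'
#' The screen used to spot high-frequency tandem repeat families (the
#' telomere motif is typically the most abundant monomer genome-wide).
#'
#' @param monomers Output of [merge_monomer_frequencies()].
#' @param label_top Number of top-frequency monomers to label (default 3).
#' @return A ggplot object.
#' @export
plot_monomer_frequencies <- function(monomers, label_top = 3) {
  dat <- as_tibble(monomers)
  top <- utils::head(dat, label_top)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length,
                                    y = .data$total_frequency)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = .data$canonical),
                       vjust = -0.6, size = 2.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "monomer length (bp)",
                  y = "total copy number (log scale)") +
    ggplot2::theme_minimal()
}
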