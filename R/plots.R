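# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_vline labs facet_wrap theme_bw scale_y_log10 position_dodge
NULL

#' Plot a metagene profile
#'
#' Median normalised ribosome density against offset from the anchored
#' codon.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  anchor <- attr(object, "anchor")
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$median_density)) +
    geom_line(colour = "#b2182b") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = paste0("offset from ", anchor, " codon (nt)"),
         y = "median normalised density",
         title = paste0("Metagene profile at the ", anchor, " codon (n = ",
                        object$n_roi[1], " ROIs)")) +
    theme_bw()
}

#' Plot a triplet phasing table
#'
#' Footprint frame counts per region class, with the matched mRNA frame
#' proportions overlaid as points.
#'
#' @param object A `phasing_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phasing_table <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(c("frame0", "frame1", "frame2"),
                        names_to = "frame", values_to = "count") |>
    mutate(frame = sub("frame", "", .data$frame))
  m <- as_tibble(object) |>
    tidyr::pivot_longer(c("mrna_frame0", "mrna_frame1", "mrna_frame2"),
                        names_to = "frame", values_to = "mrna") |>
    mutate(frame = sub("mrna_frame", "", .data$frame)) |>
    group_by(.data$region) |>
    mutate(mrna_scaled = .data$mrna / sum(.data$mrna)) |>
    ungroup()
  d <- left_join(d, select(m, "region", "frame", "mrna_scaled"),
                 by = c("region", "frame")) |>
    group_by(.data$region) |>
    mutate(fraction = .data$count / max(1, sum(.data$count))) |>
    ungroup()
  ggplot(d, aes(x = .data$frame, y = .data$fraction)) +
    geom_col(fill = "#2166ac") +
    geom_point(aes(y = .data$mrna_scaled), colour = "grey30", shape = 18,
               size = 3) +
    facet_wrap(~region) +
    labs(x = "reading frame (relative to CDS)",
         y = "fraction of 28-mer footprints",
         title = "Triplet phasing (points: mRNA fragment control)") +
    theme_bw()
}

#' Plot Z-curve classifier scores by group
#'
#' @param object A `zcurve_scores` result from [score_extensions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zcurve_scores <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2166ac") +
    facet_wrap(~group, ncol = 1, scales = "free_y") +
    labs(x = "Z-curve discriminant score (coding-positive)", y = "windows",
         title = "Coding character of region groups") +
    theme_bw()
}

#' Plot readthrough rates per candidate
#'
#' Readthrough rate (log scale) per candidate, coloured by score.
#'
#' @param records Scored record tibble from [detect_readthrough()].
#' @return A ggplot.
#' @export
plot_readthrough_rates <- function(records) {
  d <- filter(records, !is.na(.data$rho), .data$rho > 0)
  ggplot(d, aes(x = stats::reorder(.data$gene_id, .data$rho),
                y = .data$rho, colour = .data$score)) +
    geom_point(size = 2) +
    scale_y_log10() +
    labs(x = NULL, y = "readthrough rate (extension / CDS RPKM)",
         colour = "score") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
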