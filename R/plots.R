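# ggplot2 views of the main result types.

#' Plot a stage-conservation (Ptop) profile
#'
#' One panel per species: mean Ptop per developmental stage with standard
#' deviation over the BRI tables as error bars. High Ptop marks stages
#' that recur in the most conserved cross-species stage combinations.
#'
#' @param object A `ptop_result` from [ptop_with_bri()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ptop_result <- function(object, ...) {
  d <- object$summary
  d$stage <- factor(d$stage, levels = unique(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$mean_ptop, group = 1)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(0, .data$mean_ptop - .data$sd_ptop),
        ymax = .data$mean_ptop + .data$sd_ptop
      ),
      width = 0.3
    ) +
    ggplot2::facet_wrap(~species, scales = "free_x") +
    ggplot2::labs(
      x = "developmental stage",
      y = sprintf("Ptop (%% of top %d%% combinations)", round(object$q * 100)),
      title = sprintf("Stage conservation (B = %d BRI tables)", object$B)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pairwise stage-by-stage expression-distance matrix
#'
#' @param data Tibble from [pairwise_stage_matrix()].
#' @param ... Unused.
#' @return A ggplot heatmap of expdist values.
#' @export
plot_stage_matrix <- function(data, ...) {
  data$stage_a <- factor(data$stage_a, levels = unique(data$stage_a))
  data$stage_b <- factor(data$stage_b, levels = unique(data$stage_b))
  ggplot2::ggplot(data, ggplot2::aes(.data$stage_b, .data$stage_a, fill = .data$expdist)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "expdist") +
    ggplot2::labs(x = "species B stage", y = "species A stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a k-mer depth histogram
#'
#' Log-scaled k-mer counts by depth with the detected error valley and
#' coverage peak marked.
#'
#' @param object A `kmer_histogram` from [count_kmers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kmer_histogram <- function(object, ...) {
  vp <- tryCatch(find_error_valley_and_peak(object), error = function(e) NULL)
  p <- ggplot2::ggplot(object$histogram, ggplot2::aes(.data$depth, .data$n_kmers)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "k-mer depth", y = "distinct k-mers",
      title = sprintf("k-mer depth histogram (k = %s)", object$k)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(vp)) {
    p <- p +
      ggplot2::geom_vline(xintercept = vp$valley_depth, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = vp$peak_depth, colour = "red")
  }
  p
}
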