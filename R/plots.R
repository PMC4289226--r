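# ggplot2 visualizations for the main result types.

#' Plot an expression table as a ranked abundance chart
#'
#' @param table Expression table ([abundance_table()] or a published table).
#' @param top_n Number of clusters to show.
#' @return A ggplot object: percent of toxin reads per cluster, colored by
#'   toxin class.
#' @export
plot_abundance <- function(table, top_n = 25L) {
  df <- utils::head(dplyr::arrange(table, .data$rank), top_n)
  df$class <- class_of_cluster(df$cluster_name)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$cluster_name, -.data$pct_toxin_reads),
    y = .data$pct_toxin_reads, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of toxin reads", fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_abundance
#' @param object An `ExpressionRecord` table (class `tbl_df` from
#'   [abundance_table()]); dispatched via [autoplot_abundance()].
#' @export
autoplot_abundance <- function(object, top_n = 25L) plot_abundance(object, top_n)

#' Plot a rate null-distribution analysis
#'
#' Histograms of the nontoxin dN, dS and dN/dS with the 95th-percentile
#' threshold (dashed) and toxin values as a rug.
#'
#' @param object A `vf_rate_null` from [rate_outlier_analysis()].
#' @param ... Unused.
#' @return A ggplot object faceted by statistic.
#' @export
autoplot.vf_rate_null <- function(object, ...) {
  long <- function(df, who) {
    tidyr::pivot_longer(df[, c("dN", "dS", "omega")],
                        dplyr::everything(), names_to = "stat",
                        values_to = "value") |>
      dplyr::mutate(who = who)
  }
  nt <- long(object$nontoxin_rates, "nontoxin")
  tx <- long(object$toxin_rates, "toxin")
  thr <- tibble::tibble(stat = names(object$thresholds),
                        value = unname(object$thresholds))
  ggplot2::ggplot(nt, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = thr, ggplot2::aes(xintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::geom_rug(data = tx, color = "red") +
    ggplot2::facet_wrap(~stat, scales = "free") +
    ggplot2::labs(x = NULL, y = "nontoxin pairs") +
    ggplot2::theme_minimal()
}

#' Plot site-class omegas of a fitted codon model
#'
#' @param object A `vf_site_fit`.
#' @param ... Unused.
#' @return A ggplot object: class proportions vs omega.
#' @export
autoplot.vf_site_fit <- function(object, ...) {
  df <- tidy.vf_site_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$proportion)) +
    ggplot2::geom_col(width = 0.05, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = expression(omega), y = "site-class proportion",
                  title = paste("Model", object$model)) +
    ggplot2::theme_minimal()
}
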