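#' Plot the edits-per-gene histogram
#'
#' @param hist A `tribe_hist` from [edits_per_gene()].
#' @return A ggplot.
#' @export
plot_edits_per_gene <- function(hist) {
  ggplot(as_tibble(hist), aes(x = factor(.data$n_sites), y = .data$n_genes)) +
    geom_col(fill = "grey30") +
    labs(x = "edited sites per gene", y = "target genes",
         title = sprintf("%.0f%% of target genes edited once",
                         100 * attr(hist, "fraction_single"))) +
    theme_bw()
}

#' Plot the mismatch-type spectrum
#'
#' @param spectrum Output of [mismatch_spectrum()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot(spectrum, aes(x = .data$label, y = .data$n_sites)) +
    geom_col(fill = "grey30") +
    labs(x = "substitution (transcript strand)", y = "passing positions") +
    theme_bw()
}

#' Scatter plot of replicate editing percentages at shared sites
#'
#' @param sites_rep1,sites_rep2 `tribe_sites` tibbles.
#' @return A ggplot annotated with the replicate R^2.
#' @export
plot_replicate_scatter <- function(sites_rep1, sites_rep2) {
  shared <- dplyr::inner_join(
    dplyr::select(as_tibble(sites_rep1), "contig", "pos", ep1 = "editing_percent"),
    dplyr::select(as_tibble(sites_rep2), "contig", "pos", ep2 = "editing_percent"),
    by = c("contig", "pos")
  )
  r2 <- replicate_r2(sites_rep1, sites_rep2)
  ggplot(shared, aes(.data$ep1, .data$ep2)) +
    geom_point(alpha = 0.5) +
    geom_abline(linetype = "dashed") +
    labs(x = "editing % (rep 1)", y = "editing % (rep 2)",
         title = sprintf("R² = %.2f over %d shared sites", r2, nrow(shared))) +
    theme_bw()
}

#' @rdname ecdf_compare
#' @param object A `tribe_ecdf`.
#' @export
autoplot.tribe_ecdf <- function(object, ...) {
  ggplot(object$data, aes(.data$value, colour = .data$group)) +
    stat_ecdf() +
    labs(x = "value", y = "cumulative fraction", colour = NULL) +
    theme_bw()
}
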