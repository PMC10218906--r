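#' Classify site positions into 5'UTR / CDS / 3'UTR
#'
#' The region is determined by the position relative to the gene's CDS
#' bounds, oriented by strand: on the plus strand positions left of the CDS
#' are 5'UTR, on the minus strand they are 3'UTR. CDS boundary positions are
#' CDS (inclusive bounds).
#'
#' @param sites A tibble with `gene_id` and `pos` columns (one row per site).
#' @param genes A gene table (see [read_annotation()]).
#' @return A character vector (`"5UTR"`, `"CDS"`, `"3UTR"`), one per site.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", contig = "c", strand = "+",
#'                         tx_start = 1L, tx_end = 300L,
#'                         cds_start = 51L, cds_end = 250L)
#' classify_region(tibble::tibble(gene_id = "g1", pos = c(10L, 51L, 260L)), genes)
#' @export
classify_region <- function(sites, genes) {
  i <- match(sites$gene_id, genes$gene_id)
  if (anyNA(i)) {
    abort(sprintf("site gene_id(s) not in annotation: %s",
                  paste(unique(sites$gene_id[is.na(i)]), collapse = ", ")))
  }
  pos <- sites$pos
  if (any(pos < genes$tx_start[i] | pos > genes$tx_end[i])) {
    abort("site position outside its gene's transcript span (caller bug)")
  }
  left <- pos < genes$cds_start[i]
  right <- pos > genes$cds_end[i]
  plus <- genes$strand[i] == "+"
  dplyr::case_when(
    left & plus ~ "5UTR",
    left & !plus ~ "3UTR",
    right & plus ~ "3UTR",
    right & !plus ~ "5UTR",
    TRUE ~ "CDS"
  )
}

#' Build a target-gene set from called sites
#'
#' A target gene is any gene with at least one passing editing site. The
#' result is a per-gene summary carrying the per-gene site list.
#'
#' @param sites A `tribe_sites` tibble (already filtered).
#' @param label Sample/replicate label.
#' @param threshold Optional [thresholds()]; defaults to the `thresholds`
#'   attribute carried by `sites`.
#' @return A tibble of class `tribe_targets`: `gene_id`, `n_sites`,
#'   `max_editing_percent`, `support` (1 for a single replicate), `sites`
#'   (list-column of per-gene site tibbles sorted by position); attributes
#'   `label` and `thresholds`.
#' @export
build_target_set <- function(sites, label = "sample",
                             threshold = attr(sites, "thresholds")) {
  s <- dplyr::arrange(as_tibble(sites), .data$gene_id, .data$pos)
  if (nrow(s) == 0) {
    out <- tibble(gene_id = character(), n_sites = integer(),
                  max_editing_percent = double(), support = integer(),
                  sites = list())
    attr(out, "label") <- label
    attr(out, "thresholds") <- threshold
    attr(out, "n_replicates") <- 1L
    class(out) <- c("tribe_targets", class(out))
    return(out)
  }
  out <- dplyr::summarise(
    dplyr::group_by(s, .data$gene_id),
    n_sites = dplyr::n(),
    max_editing_percent = max(.data$editing_percent),
    sites = list(dplyr::pick(dplyr::everything())),
    .groups = "drop"
  )
  out$support <- if (nrow(out)) 1L else integer(0)
  out <- dplyr::select(out, "gene_id", "n_sites", "max_editing_percent",
                       "support", "sites")
  attr(out, "label") <- label
  attr(out, "thresholds") <- threshold
  attr(out, "n_replicates") <- 1L
  class(out) <- c("tribe_targets", class(out))
  out
}

#' Combine replicate target sets by union or intersection
#'
#' The union keeps every gene seen in any replicate, with `support` counting
#' the replicates in which it passed; genes present in all replicates form
#' the high-confidence intersection.
#'
#' @param sets A list of `tribe_targets` built at the same thresholds.
#' @param mode `"union"` or `"intersection"`.
#' @return A `tribe_targets` tibble; `n_sites` and `max_editing_percent` are
#'   the per-gene maxima across replicates.
#' @export
combine_replicates <- function(sets, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 1)
  th <- attr(sets[[1]], "thresholds")
  for (s in sets[-1]) {
    th2 <- attr(s, "thresholds")
    if (!is.null(th) && !is.null(th2) && !same_thresholds(th, th2)) {
      abort("replicate target sets were built at different thresholds")
    }
  }
  all <- dplyr::bind_rows(lapply(sets, as_tibble))
  comb <- dplyr::summarise(
    dplyr::group_by(all, .data$gene_id),
    n_sites = max(.data$n_sites),
    max_editing_percent = max(.data$max_editing_percent),
    support = as.integer(sum(.data$support)),
    sites = list(dplyr::bind_rows(.data$sites)),
    .groups = "drop"
  )
  if (mode == "intersection") {
    comb <- dplyr::filter(comb, .data$support == length(sets))
  }
  comb <- dplyr::arrange(comb, .data$gene_id)
  attr(comb, "label") <- paste0(mode, "(",
                                paste(vapply(sets, attr, "", "label"),
                                      collapse = ","), ")")
  attr(comb, "thresholds") <- th
  attr(comb, "n_replicates") <- length(sets)
  class(comb) <- c("tribe_targets", class(comb))
  comb
}

#' Edits-per-gene histogram
#'
#' Tabulates how many target genes carry exactly k edited sites and the
#' fraction of single-site genes (76 percent in the KHD1 experiment this
#' package models).
#'
#' @param ts A `tribe_targets` tibble.
#' @return A tibble of class `tribe_hist` (`n_sites`, `n_genes`) with
#'   attribute `fraction_single`: the proportion of target genes with
#'   exactly one site (`NA` for an empty set).
#' @export
edits_per_gene <- function(ts) {
  h <- dplyr::count(as_tibble(ts), n_sites = .data$n_sites, name = "n_genes")
  h <- dplyr::arrange(h, .data$n_sites)
  attr(h, "fraction_single") <- if (nrow(ts) == 0) NA_real_ else
    sum(ts$n_sites == 1) / nrow(ts)
  class(h) <- c("tribe_hist", class(h))
  h
}

#' Per-region site counts
#'
#' @param sites A `tribe_sites` tibble with a `region` column.
#' @return A tibble `region`, `n_sites` over `5UTR`, `CDS`, `3UTR`.
#' @export
region_counts <- function(sites) {
  counts <- dplyr::count(as_tibble(sites), .data$region, name = "n_sites")
  out <- tibble(region = c("5UTR", "CDS", "3UTR"))
  out <- dplyr::left_join(out, counts, by = "region")
  dplyr::mutate(out, n_sites = dplyr::coalesce(.data$n_sites, 0L))
}

#' Export a target table as TSV
#'
#' @param ts A `tribe_targets` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_targets_tsv <- function(ts, path) {
  readr::write_tsv(dplyr::select(as_tibble(ts), -"sites"), path)
  invisible(path)
}
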