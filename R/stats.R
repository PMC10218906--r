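#' Replicate agreement (R-squared) over shared editing sites
#'
#' Squared Pearson correlation of editing percentages at the sites called in
#' both replicates (matched by contig and position). Published HyperTRIBE
#' replicates in yeast agree at R^2 around 0.6--0.75.
#'
#' @param sites_rep1,sites_rep2 `tribe_sites` tibbles for two replicates.
#' @return A single numeric R^2, or `NA` (with a warning) when fewer than
#'   two sites are shared.
#' @export
replicate_r2 <- function(sites_rep1, sites_rep2) {
  shared <- dplyr::inner_join(
    dplyr::select(as_tibble(sites_rep1), "contig", "pos", ep1 = "editing_percent"),
    dplyr::select(as_tibble(sites_rep2), "contig", "pos", ep2 = "editing_percent"),
    by = c("contig", "pos")
  )
  if (nrow(shared) < 2) {
    warn("fewer than 2 shared sites; R^2 undefined")
    return(NA_real_)
  }
  if (stats::sd(shared$ep1) == 0 || stats::sd(shared$ep2) == 0) {
    warn("no variance in one replicate's editing percentages; R^2 undefined")
    return(NA_real_)
  }
  cor(shared$ep1, shared$ep2)^2
}

#' Signal-to-noise ratio of edited-site counts
#'
#' Ratio of the number of sites called in the fusion sample to the number
#' called in the Hyper-only control under the same thresholds. Published
#' yeast HyperTRIBE experiments report ratios above seven (e.g. 847 fusion
#' vs 106 control sites).
#'
#' @param fusion_sites,control_sites `tribe_sites` tibbles or plain counts.
#' @return A one-row tibble: `n_signal`, `n_noise`, `ratio`, `infinite`
#'   (`TRUE` when the control has zero sites).
#' @export
signal_to_noise <- function(fusion_sites, control_sites) {
  n_sig <- if (is.numeric(fusion_sites)) fusion_sites else nrow(fusion_sites)
  n_noise <- if (is.numeric(control_sites)) control_sites else nrow(control_sites)
  tibble(
    n_signal = n_sig, n_noise = n_noise,
    ratio = if (n_noise == 0) Inf else n_sig / n_noise,
    infinite = n_noise == 0
  )
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' than expected by chance, from the 2x2 table
#' `[[k, |A|-k], [|B|-k, N-|A|-|B|+k]]`. One-sided (enrichment) by default.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe Character vector containing every gene either set could
#'   have drawn from.
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`.
#' @return An object of class `tribe_overlap`: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `expected_overlap`, `odds_ratio` (conditional MLE),
#'   `p_value`, `alternative`. Has [tidy()] and [glance()] methods.
#' @examples
#' overlap_fisher(letters[1:5], letters[3:8], letters)
#' @export
overlap_fisher <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  off_a <- setdiff(set_a, universe)
  off_b <- setdiff(set_b, universe)
  if (length(off_a) + length(off_b) > 0) {
    abort(sprintf(
      "sets are not subsets of the universe; offenders: %s",
      paste(head(c(off_a, off_b), 10), collapse = ", ")
    ))
  }
  n <- length(universe); na <- length(set_a); nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  ft <- fisher_overlap_counts(k, na, nb, n, alternative)
  structure(
    list(n_universe = n, n_a = na, n_b = nb, n_overlap = k,
         expected_overlap = na * nb / n,
         odds_ratio = ft$odds_ratio, p_value = ft$p_value,
         alternative = alternative),
    class = "tribe_overlap"
  )
}

# counts-level core of overlap_fisher (2x2 table [[k, a-k], [b-k, n-a-b+k]])
fisher_overlap_counts <- function(k, na, nb, n, alternative = "greater") {
  tab <- matrix(c(k, na - k, nb - k, n - na - nb + k), nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' @export
print.tribe_overlap <- function(x, ...) {
  cat(sprintf(
    "<tribe_overlap> |A|=%d, |B|=%d, overlap=%d (expected %.2f) of N=%d\n  OR=%.3g, Fisher %s p=%.3g\n",
    x$n_a, x$n_b, x$n_overlap, x$expected_overlap, x$n_universe,
    x$odds_ratio, x$alternative, x$p_value))
  invisible(x)
}

#' @rdname overlap_fisher
#' @param x A `tribe_overlap`.
#' @param ... Unused.
#' @export
tidy.tribe_overlap <- function(x, ...) {
  tibble(n_universe = x$n_universe, n_a = x$n_a, n_b = x$n_b,
         n_overlap = x$n_overlap, expected_overlap = x$expected_overlap,
         estimate = x$odds_ratio, p.value = x$p_value,
         alternative = x$alternative)
}

#' @rdname overlap_fisher
#' @export
glance.tribe_overlap <- function(x, ...) tidy.tribe_overlap(x)

#' Filter a differential-expression table at the study cutoffs
#'
#' Two modes mirroring the two DEG sources the method is validated against:
#' `"microarray"` keeps genes with `p < p_cutoff` and
#' `|log_ratio| > log_ratio_cutoff` (defaults 0.1 and 0.2, the KHD1
#' cutoffs); `"rnaseq"` keeps genes with mean FPKM at or above `fpkm_cutoff`
#' and fold change at least `fold_cutoff` in either direction (defaults 2
#' and 1.5, the BFR1 cutoffs).
#'
#' @param table For `microarray` mode a tibble with columns `gene`,
#'   `log_ratio`, `p`; for `rnaseq` mode columns `gene`, `fpkm_wt`,
#'   `fpkm_mut`.
#' @param mode `"microarray"` or `"rnaseq"`.
#' @param p_cutoff,log_ratio_cutoff Microarray-mode cutoffs.
#' @param fpkm_cutoff,fold_cutoff RNA-seq-mode cutoffs.
#' @return The rows of `table` that pass, as a tibble.
#' @export
deg_filter <- function(table, mode = c("microarray", "rnaseq"),
                       p_cutoff = 0.1, log_ratio_cutoff = 0.2,
                       fpkm_cutoff = 2, fold_cutoff = 1.5) {
  mode <- match.arg(mode)
  table <- as_tibble(table)
  if (mode == "microarray") {
    stopifnot_cols(table, c("gene", "log_ratio", "p"), "DEG table (microarray)")
    dplyr::filter(table, .data$p < p_cutoff,
                  abs(.data$log_ratio) > log_ratio_cutoff)
  } else {
    stopifnot_cols(table, c("gene", "fpkm_wt", "fpkm_mut"), "DEG table (rnaseq)")
    if (any(table$fpkm_wt < 0 | table$fpkm_mut < 0, na.rm = TRUE)) {
      abort("FPKM values must be >= 0")
    }
    ratio <- table$fpkm_mut / table$fpkm_wt
    dplyr::filter(table,
                  (.data$fpkm_wt + .data$fpkm_mut) / 2 >= fpkm_cutoff,
                  ratio >= fold_cutoff | ratio <= 1 / fold_cutoff)
  }
}

#' Compare grouped value distributions (ECDF, KS, Welch t, ANOVA)
#'
#' The generic grouped cumulative-distribution comparison used for
#' target-vs-non-target mRNA abundance ratios and ER-enrichment scores:
#' pairwise two-sample Kolmogorov--Smirnov and Welch two-sample t tests plus
#' a one-way ANOVA across all groups.
#'
#' @param data A data frame with a grouping column and a value column.
#' @param group,value Column names (strings) of group labels and values.
#' @return An object of class `tribe_ecdf`: `data` (tibble of retained
#'   group/value rows), `pairwise` (tibble: `group1`, `group2`, `ks_stat`,
#'   `ks_p`, `t_stat`, `t_p`), `anova_f`, `anova_p`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
ecdf_compare <- function(data, group = "group", value = "value") {
  stopifnot_cols(data, c(group, value), "ecdf data")
  df <- tibble(group = as.character(data[[group]]), value = data[[value]])
  df <- df[!is.na(df$value), ]
  sizes <- table(df$group)
  empty <- setdiff(unique(as.character(data[[group]])), names(sizes))
  if (length(empty) > 0) {
    warn(sprintf("dropping empty group(s): %s", paste(empty, collapse = ", ")))
  }
  groups <- names(sizes)
  if (length(groups) < 2) abort("ecdf_compare needs at least 2 nonempty groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- purrr::map(pairs, function(p) {
    x <- df$value[df$group == p[1]]
    y <- df$value[df$group == p[2]]
    ks <- suppressWarnings(ks.test(x, y))
    tt <- t.test(x, y, var.equal = FALSE)
    tibble(group1 = p[1], group2 = p[2],
           ks_stat = unname(ks$statistic), ks_p = ks$p.value,
           t_stat = unname(tt$statistic), t_p = tt$p.value)
  })
  fit <- summary(aov(value ~ group, data = df))[[1]]
  structure(
    list(data = df, pairwise = dplyr::bind_rows(pw),
         anova_f = fit[["F value"]][1], anova_p = fit[["Pr(>F)"]][1]),
    class = "tribe_ecdf"
  )
}

#' @export
print.tribe_ecdf <- function(x, ...) {
  cat(sprintf("<tribe_ecdf> %d groups, %d values; ANOVA F=%.3g p=%.3g\n",
              length(unique(x$data$group)), nrow(x$data), x$anova_f, x$anova_p))
  print(x$pairwise)
  invisible(x)
}

#' @rdname ecdf_compare
#' @param x A `tribe_ecdf`.
#' @param ... Unused.
#' @export
tidy.tribe_ecdf <- function(x, ...) x$pairwise

#' @rdname ecdf_compare
#' @export
glance.tribe_ecdf <- function(x, ...) {
  tibble(n_groups = length(unique(x$data$group)), n_values = nrow(x$data),
         anova_f = x$anova_f, anova_p = x$anova_p)
}

#' Generic gene-set enrichment by Fisher tests with BH correction
#'
#' One one-sided Fisher overlap test per gene set against the target list,
#' with Benjamini--Hochberg adjusted q-values; a user-supplied replacement
#' for database-backed GO enrichment.
#'
#' @param targets Character vector of target genes.
#' @param collection Named list of gene sets (character vectors), e.g. from
#'   [read_gmt()].
#' @param universe Background gene universe containing all sets and targets.
#' @return A tibble sorted by p-value: `set`, `n_set`, `n_overlap`,
#'   `odds_ratio`, `p_value`, `q_value`.
#' @export
geneset_enrichment <- function(targets, collection, universe) {
  if (length(collection) == 0) {
    return(tibble(set = character(), n_set = integer(), n_overlap = integer(),
                  odds_ratio = double(), p_value = double(), q_value = double()))
  }
  res <- purrr::imap(collection, function(genes, nm) {
    ov <- overlap_fisher(targets, genes, universe)
    tibble(set = nm, n_set = ov$n_b, n_overlap = ov$n_overlap,
           odds_ratio = ov$odds_ratio, p_value = ov$p_value)
  })
  res <- dplyr::bind_rows(res)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, "", 1)
  )
}
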