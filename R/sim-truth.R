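#' Plant ground-truth editing sites and SNPs in a synthetic genome
#'
#' Selects `round(target_fraction * n_genes)` genes as RBP targets and plants
#' edit sites at gene-strand adenosines inside each target's transcript,
#' with per-site true editing fractions drawn uniformly from the configured
#' range. Sites are restricted to the transcript interior (at least one read
#' length from each transcript end) so that simulated coverage at every
#' planted site matches the configured depth. Homozygous SNPs are planted
#' genome-wide at `snp_rate` per bp, never on top of an edit site.
#'
#' @param genome A `tribe_genome` from [generate_genome()].
#' @param config The same [sim_config()] used to build the genome.
#' @return An object of class `tribe_truth`: list with
#'   `edit_sites` (tibble: `contig`, `pos`, `gene_id`, `strand`,
#'   `true_fraction`), `snp_sites` (tibble: `contig`, `pos`, `ref`, `alt`,
#'   forward-strand bases) and `target_genes` (character vector).
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' truth <- plant_truth(generate_genome(cfg), cfg)
#' @export
plant_truth <- function(genome, config) {
  stopifnot(inherits(genome, "tribe_genome"), inherits(config, "sim_config"))
  genes <- genome$genes
  contig_int <- utf8ToInt(as.character(genome$contigs[[config$contig_name]]))

  with_seed(config$seed + 1L, {
    n_targets <- round(config$target_fraction * nrow(genes))
    edit_sites <- tibble(contig = character(), pos = integer(),
                         gene_id = character(), strand = character(),
                         true_fraction = double())
    if (n_targets > 0 && nrow(genes) > 0) {
      ord <- sample(nrow(genes))  # preference order: first n_targets, rest are spares
      ks <- as.integer(names(config$sites_per_gene_prob))
      chosen <- list()
      gi <- 1
      while (length(chosen) < n_targets && gi <= length(ord)) {
        g <- genes[ord[gi], ]
        gi <- gi + 1
        lo <- g$tx_start + config$read_length
        hi <- g$tx_end - config$read_length
        if (lo > hi) { # transcript too short for an interior; use the middle half
          span <- g$tx_end - g$tx_start
          lo <- g$tx_start + span %/% 4
          hi <- g$tx_end - span %/% 4
        }
        want <- if (g$strand == "+") BASE_INT[["A"]] else BASE_INT[["T"]]
        cand <- (lo:hi)[contig_int[lo:hi] == want]
        if (length(cand) == 0) {
          warn(sprintf("gene %s has no %s-strand A in its interior; skipped",
                       g$gene_id, g$strand))
          next
        }
        k <- min(sample(ks, 1, prob = config$sites_per_gene_prob), length(cand))
        pos <- sort(sample(cand, k))
        chosen[[length(chosen) + 1]] <- tibble(
          contig = g$contig, pos = as.integer(pos), gene_id = g$gene_id,
          strand = g$strand,
          true_fraction = runif(k, config$editing_fraction_range[1],
                                config$editing_fraction_range[2])
        )
      }
      if (length(chosen) > 0) edit_sites <- dplyr::bind_rows(chosen)
    }

    n_snp <- rbinom(1, length(contig_int), config$snp_rate)
    snp_pos <- integer(0)
    if (n_snp > 0) {
      avail <- setdiff(seq_along(contig_int), edit_sites$pos)
      snp_pos <- sort(sample(avail, min(n_snp, length(avail))))
    }
    ref <- intToUtf8(contig_int[snp_pos], multiple = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                  USE.NAMES = FALSE)
    snp_sites <- tibble(contig = config$contig_name,
                        pos = as.integer(snp_pos),
                        ref = as.character(ref), alt = as.character(alt))

    structure(
      list(edit_sites = edit_sites, snp_sites = snp_sites,
           target_genes = unique(edit_sites$gene_id)),
      class = "tribe_truth"
    )
  })
}

#' @export
print.tribe_truth <- function(x, ...) {
  cat(sprintf("<tribe_truth> %d edit sites in %d target genes; %d SNPs\n",
              nrow(x$edit_sites), length(x$target_genes), nrow(x$snp_sites)))
  invisible(x)
}

#' Write truth tables as TSV
#'
#' @param truth A `tribe_truth`.
#' @param dir Output directory (created if needed); writes
#'   `truth_edit_sites.tsv`, `truth_snp_sites.tsv`, `truth_target_genes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$edit_sites, file.path(dir, "truth_edit_sites.tsv"))
  readr::write_tsv(truth$snp_sites, file.path(dir, "truth_snp_sites.tsv"))
  readr::write_tsv(tibble(gene_id = truth$target_genes),
                   file.path(dir, "truth_target_genes.tsv"))
  invisible(dir)
}
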