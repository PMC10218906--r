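#' Simulation configuration for synthetic HyperTRIBE libraries
#'
#' Bundles every parameter of the synthetic-data generator: the gene layout
#' of the small reference genome, where and how strongly edits are planted,
#' the SNP and sequencing-error rates, the sequencing depth and the library
#' orientation. Defaults emulate the statistical structure of a yeast
#' HyperTRIBE experiment: a quarter of genes are RBP targets, 76 percent of
#' target genes carry a single edited site, per-site editing fractions are
#' uniform on 0.2--0.8, and libraries follow the dUTP stranded convention.
#'
#' @param n_genes Number of intronless genes to place on the contig.
#' @param target_fraction Fraction of genes selected as RBP targets
#'   (edit sites are planted only in target genes).
#' @param sites_per_gene_prob Named numeric vector; probability that a target
#'   gene carries 1, 2, ... edited sites. Must sum to 1.
#' @param editing_fraction_range Range (length 2, within `[0.01, 0.95]`) from
#'   which per-site true editing fractions are drawn uniformly.
#' @param snp_rate Per-bp probability of a planted homozygous SNP.
#' @param error_rate Per-base uniform sequencing-error probability.
#' @param coverage Mean sequencing depth over transcripts.
#' @param read_length Mean read length (bases); individual read lengths are
#'   jittered by +/- 10 percent so positional duplicate keys rarely collide
#'   between distinct fragments.
#' @param dup_rate Fraction of the library that is exact PCR duplicates.
#' @param strand_protocol Library orientation: `"fr-firststrand"` (dUTP;
#'   read 1 antisense to the transcript), `"fr-secondstrand"`, or
#'   `"unstranded-by-gene"`.
#' @param gene_length_range Range of transcript lengths (bp).
#' @param utr5_length,utr3_length Lengths of the 5' and 3' UTRs flanking the
#'   CDS within each transcript.
#' @param intergenic_gap Gap between consecutive genes (bp).
#' @param contig_name Name of the single synthetic contig.
#' @param seed Root random seed; all stage seeds derive from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 20, coverage = 30, seed = 1)
#' @export
sim_config <- function(n_genes = 200,
                       target_fraction = 0.25,
                       sites_per_gene_prob = c(`1` = 0.76, `2` = 0.18, `3` = 0.06),
                       editing_fraction_range = c(0.2, 0.8),
                       snp_rate = 5e-4,
                       error_rate = 0.005,
                       coverage = 100,
                       read_length = 100,
                       dup_rate = 0.1,
                       strand_protocol = c("fr-firststrand", "fr-secondstrand",
                                           "unstranded-by-gene"),
                       gene_length_range = c(400, 800),
                       utr5_length = 50,
                       utr3_length = 150,
                       intergenic_gap = 100,
                       contig_name = "chrS",
                       seed = 1L) {
  strand_protocol <- match.arg(strand_protocol)
  rates <- c(target_fraction, snp_rate, error_rate, dup_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("target_fraction, snp_rate, error_rate and dup_rate must be in [0, 1]")
  }
  if (coverage <= 0) abort("coverage must be > 0")
  if (read_length < 30) abort("read_length must be >= 30")
  if (abs(sum(sites_per_gene_prob) - 1) > 1e-8) {
    abort("sites_per_gene_prob must sum to 1")
  }
  if (length(editing_fraction_range) != 2 ||
      editing_fraction_range[1] > editing_fraction_range[2] ||
      editing_fraction_range[1] < 0.01 || editing_fraction_range[2] > 0.95) {
    abort("editing_fraction_range must be an increasing pair within [0.01, 0.95]")
  }
  if (n_genes < 0) abort("n_genes must be >= 0")
  structure(
    list(
      n_genes = as.integer(n_genes),
      target_fraction = target_fraction,
      sites_per_gene_prob = sites_per_gene_prob,
      editing_fraction_range = editing_fraction_range,
      snp_rate = snp_rate,
      error_rate = error_rate,
      coverage = coverage,
      read_length = as.integer(read_length),
      dup_rate = dup_rate,
      strand_protocol = strand_protocol,
      gene_length_range = as.integer(gene_length_range),
      utr5_length = as.integer(utr5_length),
      utr3_length = as.integer(utr3_length),
      intergenic_gap = as.integer(intergenic_gap),
      contig_name = contig_name,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d (%.0f%% targets), contig '%s'\n",
              x$n_genes, 100 * x$target_fraction, x$contig_name))
  cat(sprintf("  coverage: %gx, read length ~%d, dup rate %.2f, error rate %.4g\n",
              x$coverage, x$read_length, x$dup_rate, x$error_rate))
  cat(sprintf("  editing fractions U(%.2f, %.2f); snp rate %.2g/bp; %s; seed %d\n",
              x$editing_fraction_range[1], x$editing_fraction_range[2],
              x$snp_rate, x$strand_protocol, x$seed))
  invisible(x)
}
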