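#' Coverage / editing-percentage thresholds
#'
#' HyperTRIBE site calling uses the "rNeM" convention: a site needs at least
#' N reads of coverage and at least M percent editing. `thresholds("r20e10")`
#' and `thresholds("r10e10")` build the two presets used throughout; any
#' combination can be given explicitly.
#'
#' @param preset Optional preset string of the form `"r<reads>e<percent>"`.
#' @param min_reads Minimum coverage (total reads at the position).
#' @param min_editing Minimum editing percentage, in (0, 100].
#' @return A list of class `tribe_thresholds` with `min_reads`,
#'   `min_editing` and a `label`.
#' @examples
#' thresholds("r20e10")
#' thresholds(min_reads = 15, min_editing = 5)
#' @export
thresholds <- function(preset = NULL, min_reads = 20, min_editing = 10) {
  if (!is.null(preset)) {
    m <- regmatches(preset, regexec("^r([0-9]+)e([0-9.]+)$", preset))[[1]]
    if (length(m) != 3) abort("preset must look like 'r20e10'")
    min_reads <- as.numeric(m[2])
    min_editing <- as.numeric(m[3])
  }
  if (min_reads < 1) abort("min_reads must be >= 1")
  if (min_editing <= 0 || min_editing > 100) {
    abort("min_editing must be in (0, 100]")
  }
  structure(
    list(min_reads = min_reads, min_editing = min_editing,
         label = sprintf("r%ge%g", min_reads, min_editing)),
    class = "tribe_thresholds"
  )
}

#' @export
print.tribe_thresholds <- function(x, ...) {
  cat(sprintf("<tribe_thresholds> %s (coverage >= %g, editing >= %g%%)\n",
              x$label, x$min_reads, x$min_editing))
  invisible(x)
}

same_thresholds <- function(a, b) {
  isTRUE(all.equal(a$min_reads, b$min_reads)) &&
    isTRUE(all.equal(a$min_editing, b$min_editing))
}

#' Call candidate A-to-G editing sites from a pileup
#'
#' Emits every genic position whose transcript-strand reference base is `A`,
#' with total coverage at or above the read threshold, at least one `G`
#' read, and editing percentage `100 * G / (A + G)` at or above the editing
#' threshold. The A+G denominator deliberately excludes C/T bases arising
#' from sequencing error, the standard TRIBE convention. Sites are
#' classified into 5'UTR / CDS / 3'UTR from the gene's CDS bounds.
#'
#' @param pileup A `tribe_pileup` from [build_pileup()].
#' @param thresholds A [thresholds()] object (default r20e10).
#' @param annotation Gene models (for region classification); a
#'   `tribe_genome`, gene tibble, or annotation path.
#' @return A tibble of class `tribe_sites`, sorted by (contig, pos):
#'   `contig`, `pos`, `gene_id`, `strand`, `region`, `A_count`, `G_count`,
#'   `coverage`, `editing_percent`, with the thresholds attached as
#'   attribute `thresholds`.
#' @examples
#' # see vignette("hypertribe-analysis") for an end-to-end example
#' @export
call_candidate_sites <- function(pileup, thresholds = tribecall::thresholds("r20e10"),
                                 annotation = NULL) {
  stopifnot_cols(pileup, c("contig", "pos", "gene_id", "strand", "genic",
                           "ref", "A", "G", "coverage"), "pileup")
  sites <- dplyr::filter(
    as_tibble(pileup),
    .data$genic,
    .data$ref == "A",
    .data$coverage >= thresholds$min_reads,
    .data$G >= 1L,
    100 * .data$G / (.data$A + .data$G) >= thresholds$min_editing
  )
  sites <- dplyr::transmute(
    sites,
    contig = .data$contig, pos = .data$pos, gene_id = .data$gene_id,
    strand = .data$strand,
    A_count = .data$A, G_count = .data$G, coverage = .data$coverage,
    editing_percent = 100 * .data$G / (.data$A + .data$G)
  )
  if (!is.null(annotation)) {
    genes <- as_gene_table(annotation)
    sites$region <- classify_region(sites, genes)
  } else {
    sites$region <- NA_character_
  }
  sites <- dplyr::arrange(sites, .data$contig, .data$pos)
  sites <- dplyr::select(sites, "contig", "pos", "gene_id", "strand", "region",
                         "A_count", "G_count", "coverage", "editing_percent")
  attr(sites, "thresholds") <- thresholds
  class(sites) <- c("tribe_sites", class(sites))
  sites
}

#' Subtract Hyper-only background editing
#'
#' Removes called sites at which the negative-control (untethered ADARcd,
#' "Hyper-only") library itself shows editing: by default, control coverage
#' of at least 10 reads, at least 2 control G reads, and control editing
#' percentage of at least 1. The two-read floor keeps a lone
#' sequencing-error G read in a deeply covered control (1/60 reads is
#' already 1.7 percent) from erasing a genuine site.
#'
#' @param sites A `tribe_sites` tibble.
#' @param control_pileup `tribe_pileup` of the Hyper-only library.
#' @param min_coverage,min_percent,min_count The control rule.
#' @return The filtered `tribe_sites` tibble.
#' @export
subtract_background <- function(sites, control_pileup,
                                min_coverage = 10, min_percent = 1,
                                min_count = 2) {
  missing_ctg <- setdiff(unique(sites$contig), unique(control_pileup$contig))
  if (length(missing_ctg) > 0) {
    warn(sprintf("control pileup lacks contig(s) %s; their sites are retained",
                 paste(missing_ctg, collapse = ", ")))
  }
  ctl <- dplyr::select(as_tibble(control_pileup), "contig", "pos",
                       ctl_A = "A", ctl_G = "G", ctl_cov = "coverage")
  merged <- dplyr::left_join(as_tibble(sites), ctl, by = c("contig", "pos"))
  ctl_pct <- 100 * merged$ctl_G / (merged$ctl_A + merged$ctl_G)
  remove <- !is.na(merged$ctl_cov) & merged$ctl_cov >= min_coverage &
    merged$ctl_G >= min_count & !is.na(ctl_pct) & ctl_pct >= min_percent
  out <- sites[!remove, ]
  attr(out, "thresholds") <- attr(sites, "thresholds")
  out
}

#' Exclude genomic SNPs via the wtRNA--RNA approach
#'
#' An apparent edit that is really a homozygous genomic variant shows the
#' alternate allele in the wild-type RNA sample too. A site is dropped when
#' the wild type fails to show the reference allele: its non-reference
#' fraction of coverage (any alternate base, not only G — an A-to-C variant
#' plus one stray error G read would otherwise masquerade as a fully edited
#' site) is at least 0.8 with coverage of at least 10. When no wild-type sample exists, a
#' conservative fallback drops sites edited at >= 95 percent in both the
#' fusion sample and the Hyper-only control (a homozygous variant is at
#' ~100 percent everywhere; genuine hyper-edited sites are not in the
#' control).
#'
#' @param sites A `tribe_sites` tibble.
#' @param wildtype_pileup `tribe_pileup` of the wild-type RNA sample, or
#'   `NULL` to use the fallback.
#' @param min_coverage,min_alt_fraction The wild-type rule.
#' @param control_pileup Required for the fallback when
#'   `wildtype_pileup = NULL`.
#' @return The filtered `tribe_sites` tibble.
#' @export
exclude_snps <- function(sites, wildtype_pileup = NULL,
                         min_coverage = 10, min_alt_fraction = 0.8,
                         control_pileup = NULL) {
  if (!is.null(wildtype_pileup)) {
    wt <- dplyr::select(as_tibble(wildtype_pileup), "contig", "pos",
                        wt_A = "A", wt_cov = "coverage")
    merged <- dplyr::left_join(as_tibble(sites), wt, by = c("contig", "pos"))
    frac <- 1 - merged$wt_A / merged$wt_cov
    remove <- !is.na(merged$wt_cov) & merged$wt_cov >= min_coverage &
      !is.na(frac) & frac >= min_alt_fraction
  } else {
    if (is.null(control_pileup)) {
      abort("exclude_snps needs either a wildtype_pileup or a control_pileup")
    }
    ctl <- dplyr::select(as_tibble(control_pileup), "contig", "pos",
                         ctl_A = "A", ctl_G = "G")
    merged <- dplyr::left_join(as_tibble(sites), ctl, by = c("contig", "pos"))
    ctl_pct <- 100 * merged$ctl_G / (merged$ctl_A + merged$ctl_G)
    remove <- merged$editing_percent >= 95 & !is.na(ctl_pct) & ctl_pct >= 95
  }
  out <- sites[!remove, ]
  attr(out, "thresholds") <- attr(sites, "thresholds")
  out
}

#' Mismatch-type spectrum under the calling thresholds
#'
#' Applies the site-calling rule to all 12 ordered substitution types
#' (reference base to observed base, on the transcript strand): a genic
#' position counts for ref>obs when coverage meets the read threshold, at
#' least one obs read is present, and `100 * obs / (ref + obs)` meets the
#' editing threshold. In a clean HyperTRIBE experiment essentially all mass
#' falls in the A>G bin.
#'
#' @param pileup A `tribe_pileup`.
#' @param thresholds A [thresholds()] object.
#' @return A tibble: `ref`, `obs`, `label` (e.g. `"A>G"`), `n_sites`.
#' @export
mismatch_spectrum <- function(pileup, thresholds = tribecall::thresholds("r20e10")) {
  p <- dplyr::filter(as_tibble(pileup), .data$genic, .data$ref %in% BASES,
                     .data$coverage >= thresholds$min_reads)
  combos <- expand.grid(ref = BASES, obs = BASES, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$obs, ]
  combos <- combos[order(combos$ref, combos$obs), ]
  n <- purrr::map2_int(combos$ref, combos$obs, function(rb, ob) {
    rows <- p[p$ref == rb, ]
    refn <- rows[[rb]]
    obsn <- rows[[ob]]
    sum(obsn >= 1L & 100 * obsn / (refn + obsn) >= thresholds$min_editing)
  })
  tibble(ref = combos$ref, obs = combos$obs,
         label = paste0(combos$ref, ">", combos$obs), n_sites = n)
}

#' Export called sites as TSV
#'
#' @param sites A `tribe_sites` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_sites_tsv <- function(sites, path) {
  readr::write_tsv(as_tibble(sites), path)
  invisible(path)
}

#' Export called sites as BED6
#'
#' Coordinates are converted from the package's 1-based inclusive convention
#' to BED's 0-based half-open intervals; the score column is
#' `editing_percent * 10` (0--1000) and the strand column is the gene strand.
#'
#' @param sites A `tribe_sites` tibble.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$contig,
    start = sites$pos - 1L,
    end = sites$pos,
    name = paste0(sites$gene_id, ":", sites$pos),
    score = round(sites$editing_percent * 10),
    strand = sites$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
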