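#' Extract edit-centred sequence windows
#'
#' For each called site, extracts the window from 100 bp upstream to 100 bp
#' downstream (201 bp total at the default halfwidth) on the transcript
#' strand — minus-strand windows are reverse-complemented. Windows running
#' off a contig end are truncated and flagged. These are the FASTA inputs
#' handed to external motif discovery (MEME/XSTREME); the discovery itself
#' is out of scope here.
#'
#' @param sites A `tribe_sites` tibble (needs `contig`, `pos`, `gene_id`,
#'   `strand`).
#' @param reference Reference sequences (DNAStringSet, `tribe_genome`, or
#'   FASTA path).
#' @param halfwidth Bases on each side of the edited position (default 100).
#' @return A tibble of class `tribe_windows`: `window_id`, `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `truncated`, `seq`,
#'   `provenance = "target"`.
#' @export
extract_windows <- function(sites, reference, halfwidth = 100) {
  contigs <- as_contig_set(reference)
  s <- as_tibble(sites)
  clen <- Biostrings::width(contigs)[match(s$contig, names(contigs))]
  if (anyNA(clen)) {
    abort("site contig(s) missing from reference")
  }
  if (any(s$pos < 1 | s$pos > clen)) {
    abort("site position off its contig (caller bug)")
  }
  start <- pmax(1L, s$pos - as.integer(halfwidth))
  end <- pmin(clen, s$pos + as.integer(halfwidth))
  seqs <- as.character(Biostrings::subseq(contigs[s$contig], start, end))
  flip <- s$strand == "-"
  seqs[flip] <- revcomp(seqs[flip])
  out <- tibble(
    window_id = sprintf("%s:%d:%s", s$contig, s$pos, s$gene_id),
    gene_id = s$gene_id, contig = s$contig,
    start = start, end = end, strand = s$strand,
    truncated = (end - start + 1L) < (2L * as.integer(halfwidth) + 1L),
    seq = unname(seqs), provenance = "target"
  )
  class(out) <- c("tribe_windows", class(out))
  out
}

#' Sample matched background windows from non-target genes
#'
#' Draws `n` windows of exactly `length` bases uniformly from the
#' transcript-strand sequence of genes not in the target set, matched to
#' the target windows in both length (201 bp) and number so that motif
#' discovery compares like with like. Positions are sampled with replacement across genes
#' proportionally to each gene's number of eligible start positions.
#'
#' @param reference Reference sequences.
#' @param annotation Gene models (`tribe_genome`, gene tibble, or path).
#' @param target_genes Character vector of target gene ids to exclude.
#' @param n Number of windows to draw.
#' @param length Window length in bp (default 201).
#' @param seed Random seed (deterministic output per seed).
#' @return A `tribe_windows` tibble with `provenance = "background"`.
#' @export
sample_background <- function(reference, annotation, target_genes, n,
                              length = 201, seed = 1) {
  contigs <- as_contig_set(reference)
  genes <- as_gene_table(annotation)
  pool <- genes[!genes$gene_id %in% target_genes, ]
  pool <- pool[pool$tx_end - pool$tx_start + 1L >= length, ]
  if (nrow(pool) == 0) {
    abort(sprintf(
      "no non-target gene has a transcript of >= %d bp to sample %d background windows from",
      length, n))
  }
  n_starts <- pool$tx_end - pool$tx_start + 1L - as.integer(length) + 1L
  with_seed(seed, {
    gi <- sample.int(nrow(pool), n, replace = TRUE, prob = n_starts)
    off <- as.integer(floor(runif(n) * n_starts[gi]))
    start <- pool$tx_start[gi] + off
    end <- start + as.integer(length) - 1L
    seqs <- as.character(Biostrings::subseq(contigs[pool$contig[gi]], start, end))
    flip <- pool$strand[gi] == "-"
    seqs[flip] <- revcomp(seqs[flip])
    out <- tibble(
      window_id = sprintf("bg%05d_%s", seq_len(n), pool$gene_id[gi]),
      gene_id = pool$gene_id[gi], contig = pool$contig[gi],
      start = start, end = end, strand = pool$strand[gi],
      truncated = FALSE, seq = unname(seqs), provenance = "background"
    )
    class(out) <- c("tribe_windows", class(out))
    out
  })
}

#' Test k-mers for enrichment in target vs background windows
#'
#' Counts the windows containing each k-mer at least once in each group and
#' applies a one-sided Fisher's exact test for enrichment in the target
#' group. An internal sanity check on candidate motifs (default: the CAACAA
#' / CAUCAU elements recognized by KH domains); `U` is accepted and stored
#' as `T`.
#'
#' @param target_windows,background_windows `tribe_windows` tibbles.
#' @param kmers Character vector of motifs (DNA or RNA alphabet).
#' @return A tibble: `kmer`, `n_target`, `target_with`, `n_background`,
#'   `background_with`, `odds_ratio`, `p_value`.
#' @export
kmer_enrichment <- function(target_windows, background_windows,
                            kmers = c("CAACAA", "CATCAT")) {
  stopifnot(length(kmers) > 0)
  kmers <- toupper(chartr("Uu", "Tt", kmers))
  tgt <- Biostrings::DNAStringSet(target_windows$seq)
  bg <- Biostrings::DNAStringSet(background_windows$seq)
  min_w <- min(Biostrings::width(tgt), Biostrings::width(bg))
  res <- purrr::map(kmers, function(k) {
    if (nchar(k) > min_w) {
      warn(sprintf("k-mer %s is longer than the shortest window; skipped", k))
      return(NULL)
    }
    t_with <- sum(Biostrings::vcountPattern(k, tgt, fixed = TRUE) > 0)
    b_with <- sum(Biostrings::vcountPattern(k, bg, fixed = TRUE) > 0)
    tab <- matrix(c(t_with, length(tgt) - t_with,
                    b_with, length(bg) - b_with), nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "greater")
    tibble(kmer = k, n_target = length(tgt), target_with = t_with,
           n_background = length(bg), background_with = b_with,
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  dplyr::bind_rows(res)
}

#' Write windows to FASTA
#'
#' Output is directly usable as MEME/XSTREME input.
#'
#' @param windows A `tribe_windows` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  x <- Biostrings::DNAStringSet(setNames(windows$seq, windows$window_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
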