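# shared fixtures: all synthetic, built in code at test time

tiny_cfg <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_genes = 12, coverage = 60, gene_length_range = c(300, 500),
         snp_rate = 2e-3, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

sim_triple <- function(cfg) {
  g <- generate_genome(cfg)
  tr <- plant_truth(g, cfg)
  list(
    genome = g, truth = tr,
    fusion = simulate_reads(g, tr, cfg, "fusion"),
    control = simulate_reads(g, tr, cfg, "hyper_only"),
    wildtype = simulate_reads(g, tr, cfg, "wildtype")
  )
}

# hand-built pileup rows for caller unit tests
make_pileup <- function(...) {
  rows <- list(...)
  defaults <- list(contig = "c1", pos = 1L, gene_id = "g1", strand = "+",
                   genic = TRUE, ref = "A", A = 0L, C = 0L, G = 0L, T = 0L)
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    r <- modifyList(defaults, r)
    tibble::as_tibble(r)
  }))
  out$coverage <- out$A + out$C + out$G + out$T
  out
}

# coordinate mirror: reverse-complement the genome and flip every strand
mirror_genome <- function(genome) {
  L <- Biostrings::width(genome$contigs)
  contigs <- Biostrings::reverseComplement(genome$contigs)
  names(contigs) <- names(genome$contigs)
  len <- L[match(genome$genes$contig, names(genome$contigs))]
  genes <- dplyr::mutate(
    genome$genes,
    new_tx_start = len - tx_end + 1L,
    new_tx_end = len - tx_start + 1L,
    new_cds_start = len - cds_end + 1L,
    new_cds_end = len - cds_start + 1L,
    strand = ifelse(strand == "+", "-", "+")
  )
  genes$tx_start <- genes$new_tx_start
  genes$tx_end <- genes$new_tx_end
  genes$cds_start <- genes$new_cds_start
  genes$cds_end <- genes$new_cds_end
  genes <- dplyr::select(genes, -dplyr::starts_with("new_"))
  structure(list(contigs = contigs, genes = genes), class = "tribe_genome")
}

mirror_reads <- function(reads, contig_len) {
  flip <- function(s) ifelse(s == "+", "-", "+")
  dplyr::mutate(
    reads,
    new_start = contig_len - end + 1L,
    end = contig_len - start + 1L,
    start = new_start,
    seq = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq))),
    read_strand = flip(read_strand),
    library_strand = flip(library_strand),
    flag = bitwXor(flag, 16L)
  ) |> dplyr::select(-"new_start")
}

# brute-force hypergeometric tail oracle for the Fisher overlap test
brute_fisher_p <- function(k, na, nb, n, alternative = "greater") {
  kk <- max(0, na + nb - n):min(na, nb)
  probs <- stats::dhyper(kk, na, n - na, nb)
  if (alternative == "greater") {
    sum(probs[kk >= k])
  } else if (alternative == "less") {
    sum(probs[kk <= k])
  } else {
    pk <- probs[kk == k]
    sum(probs[probs <= pk * (1 + 1e-7)])
  }
}

random_windows <- function(n, len = 201) {
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  big <- paste(chars, collapse = "")
  off <- (seq_len(n) - 1L) * len + 1L
  tibble::tibble(
    window_id = sprintf("w%04d", seq_len(n)),
    seq = substring(big, off, off + len - 1L)
  )
}
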