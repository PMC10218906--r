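#' Simulate a stranded, pre-aligned HyperTRIBE library
#'
#' Emits reads already aligned to the synthetic genome (SAM; no indels, no
#' splicing) for one of the three library roles of a HyperTRIBE experiment:
#' the RBP--ADARcd `fusion` sample carries the planted A-to-G edits (each
#' read covering an edit site shows G on the gene strand with probability
#' `true_fraction`), the `hyper_only` negative control and the `wildtype`
#' RNA sample carry none. All three carry planted homozygous SNP alleles
#' with probability 1, uniform per-base sequencing errors, and a configured
#' fraction of exact PCR duplicates. Read counts per gene are
#' `coverage * transcript_length / read_length`; read strand follows the
#' configured library orientation (dUTP `fr-firststrand` by default: the
#' read aligns antisense to the transcript).
#'
#' @param genome A `tribe_genome`.
#' @param truth The matching `tribe_truth`.
#' @param config The [sim_config()] used throughout.
#' @param sample_kind One of `"fusion"`, `"hyper_only"`, `"wildtype"`.
#' @param path Optional SAM output path; when `NULL` no file is written.
#' @param seed Seed for this library's randomness. Defaults to a
#'   sample-kind-specific offset of `config$seed`; pass distinct seeds to
#'   simulate independent replicates of the same truth.
#' @return Invisibly, a tibble of the emitted reads (`qname`, `flag`,
#'   `contig`, `start`, `end`, `read_strand`, `library_strand` — the
#'   transcript strand — and `seq`) with attributes
#'   `n_primary`, `n_duplicates` and `n_unique_primary_keys` (the number of
#'   distinct positional duplicate-keys among primary reads — the exact
#'   expected post-deduplication read count).
#' @examples
#' cfg <- sim_config(n_genes = 5, coverage = 20, seed = 1)
#' g <- generate_genome(cfg)
#' tr <- plant_truth(g, cfg)
#' reads <- simulate_reads(g, tr, cfg, "fusion")
#' @export
simulate_reads <- function(genome, truth, config,
                           sample_kind = c("fusion", "hyper_only", "wildtype"),
                           path = NULL, seed = NULL) {
  sample_kind <- match.arg(sample_kind)
  stopifnot(inherits(genome, "tribe_genome"), inherits(truth, "tribe_truth"))
  if (is.null(seed)) {
    seed <- config$seed +
      c(fusion = 101L, hyper_only = 102L, wildtype = 103L)[[sample_kind]]
  }
  genes <- genome$genes
  contig_name <- config$contig_name
  contig_int <- utf8ToInt(as.character(genome$contigs[[contig_name]]))
  # homozygous SNPs are present in every library
  if (nrow(truth$snp_sites) > 0) {
    contig_int[truth$snp_sites$pos] <-
      BASE_INT[truth$snp_sites$alt]
  }

  if (nrow(genes) == 0) {
    empty <- tibble(qname = character(), flag = integer(), contig = character(),
                    start = integer(), end = integer(), read_strand = character(),
                    library_strand = character(), seq = character(),
                    gene_id = character())
    attr(empty, "n_primary") <- 0L
    attr(empty, "n_duplicates") <- 0L
    attr(empty, "n_unique_primary_keys") <- 0L
    if (!is.null(path)) write_sam(empty, genome, path)
    return(invisible(empty))
  }

  reads <- with_seed(seed, {
    tx_len <- genes$tx_end - genes$tx_start + 1L
    n_per_gene <- pmax(1L, as.integer(round(config$coverage * tx_len /
                                              config$read_length)))
    gene_idx <- rep(seq_len(nrow(genes)), n_per_gene)
    n_reads <- length(gene_idx)
    jit <- as.integer(round(config$read_length * 0.1))
    len <- sample(seq(config$read_length - jit, config$read_length + jit),
                  n_reads, replace = TRUE)
    len <- pmax(30L, pmin(len, tx_len[gene_idx]))
    start <- genes$tx_start[gene_idx] +
      as.integer(floor(runif(n_reads) * (tx_len[gene_idx] - len + 1L)))
    end <- start + len - 1L

    seqs <- substring(intToUtf8(contig_int), start, end)

    # plant edits in the fusion library, per read, at probability true_fraction
    if (sample_kind == "fusion" && nrow(truth$edit_sites) > 0) {
      gene_of_read <- genes$gene_id[gene_idx]
      for (i in seq_len(nrow(truth$edit_sites))) {
        s <- truth$edit_sites[i, ]
        idx <- which(gene_of_read == s$gene_id & start <= s$pos & end >= s$pos)
        if (length(idx) == 0) next
        sel <- idx[runif(length(idx)) < s$true_fraction]
        if (length(sel) == 0) next
        edited <- if (s$strand == "+") "G" else "C"  # forward-strand base
        off <- s$pos - start[sel] + 1L
        substr(seqs[sel], off, off) <- rep(edited, length(sel))
      }
    }

    # uniform sequencing errors over all emitted bases
    if (config$error_rate > 0) {
      cumw <- cumsum(len)
      v <- utf8ToInt(paste(seqs, collapse = ""))
      idx <- which(runif(length(v)) < config$error_rate)
      if (length(idx) > 0) {
        others <- rbind(A = BASE_INT[c("C", "G", "T")],
                        C = BASE_INT[c("A", "G", "T")],
                        G = BASE_INT[c("A", "C", "T")],
                        T = BASE_INT[c("A", "C", "G")])
        bi <- match(v[idx], BASE_INT)
        pick <- sample.int(3L, length(idx), replace = TRUE)
        v[idx] <- others[cbind(bi, pick)]
      }
      seqs <- substring(intToUtf8(v), c(0L, head(cumw, -1)) + 1L, cumw)
    }

    ts <- genes$strand[gene_idx]
    read_strand <- switch(config$strand_protocol,
      "fr-firststrand" = other_strand(ts),
      "fr-secondstrand" = ts,
      "unstranded-by-gene" = sample(c("+", "-"), n_reads, replace = TRUE)
    )

    primary <- tibble(
      qname = sprintf("%s_%07d", sample_kind, seq_len(n_reads)),
      flag = ifelse(read_strand == "-", 16L, 0L),
      contig = contig_name, start = start, end = end,
      read_strand = read_strand, library_strand = ts, seq = seqs,
      gene_id = genes$gene_id[gene_idx]
    )

    n_dup <- round(config$dup_rate * n_reads)
    out <- primary
    if (n_dup > 0) {
      di <- sample.int(n_reads, n_dup, replace = TRUE)
      dup <- primary[di, ]
      dup$qname <- sprintf("%s_dup%07d", sample_kind, seq_len(n_dup))
      out <- dplyr::bind_rows(primary, dup)
    }
    out <- dplyr::arrange(out, .data$contig, .data$start, .data$end, .data$qname)
    attr(out, "n_primary") <- n_reads
    attr(out, "n_duplicates") <- n_dup
    attr(out, "n_unique_primary_keys") <- nrow(dplyr::distinct(
      primary, .data$contig, .data$start, .data$end, .data$read_strand))
    out
  })

  if (!is.null(path)) {
    write_sam(reads, genome, path)
  }
  invisible(reads)
}

# write a reads tibble as coordinate-sorted SAM
write_sam <- function(reads, genome, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$contigs),
            Biostrings::width(genome$contigs))
  )
  if (nrow(reads) > 0) {
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                    reads$qname, reads$flag, reads$contig, reads$start,
                    reads$end - reads$start + 1L, reads$seq)
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
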