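#' Generate a synthetic reference genome with intronless gene models
#'
#' Lays out `n_genes` non-overlapping intronless genes on a single contig of
#' uniform random sequence, separated by fixed intergenic gaps. Each gene has
#' a transcript span, a CDS, and 5'/3' UTRs oriented by a randomly drawn
#' strand; on the minus strand the 5' UTR sits at the high-coordinate end.
#' Output is deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `tribe_genome`: a list with `contigs`
#'   (a [Biostrings::DNAStringSet]) and `genes`, a tibble with columns
#'   `gene_id`, `contig`, `strand`, `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end` (1-based inclusive genomic coordinates).
#' @examples
#' g <- generate_genome(sim_config(n_genes = 5, seed = 1))
#' g$genes
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  utr_total <- config$utr5_length + config$utr3_length
  if (config$n_genes > 0 && min(config$gene_length_range) <= utr_total) {
    abort("gene_length_range minimum must exceed utr5_length + utr3_length")
  }
  with_seed(config$seed, {
    gap <- config$intergenic_gap
    if (config$n_genes > 0) {
      lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                     config$n_genes, replace = TRUE)
      strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
      tx_start <- gap + c(0L, cumsum(lens + gap))[seq_len(config$n_genes)] + 1L
      tx_end <- tx_start + lens - 1L
      cds_start <- ifelse(strand == "+", tx_start + config$utr5_length,
                          tx_start + config$utr3_length)
      cds_end <- ifelse(strand == "+", tx_end - config$utr3_length,
                        tx_end - config$utr5_length)
      genes <- tibble(
        gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
        contig = config$contig_name,
        strand = strand,
        tx_start = as.integer(tx_start),
        tx_end = as.integer(tx_end),
        cds_start = as.integer(cds_start),
        cds_end = as.integer(cds_end)
      )
      contig_len <- max(tx_end) + gap
    } else {
      genes <- tibble(
        gene_id = character(), contig = character(), strand = character(),
        tx_start = integer(), tx_end = integer(),
        cds_start = integer(), cds_end = integer()
      )
      contig_len <- 1000L
    }
    seq <- paste(sample(BASES, contig_len, replace = TRUE), collapse = "")
    contigs <- Biostrings::DNAStringSet(setNames(seq, config$contig_name))
    structure(list(contigs = contigs, genes = genes), class = "tribe_genome")
  })
}

#' @export
print.tribe_genome <- function(x, ...) {
  cat(sprintf("<tribe_genome> %d contig(s), %d bp total, %d genes\n",
              length(x$contigs), sum(Biostrings::width(x$contigs)),
              nrow(x$genes)))
  invisible(x)
}

#' Write a synthetic genome to FASTA
#'
#' @param genome A `tribe_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$contigs, path)
  invisible(path)
}

#' Write synthetic gene models to GFF3
#'
#' Emits one `gene` feature per gene plus `five_prime_UTR`, `CDS` and
#' `three_prime_UTR` child features oriented by strand (zero-length UTRs are
#' omitted).
#'
#' @param genome A `tribe_genome`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  g <- genome$genes
  feats <- purrr::pmap(g, function(gene_id, contig, strand, tx_start, tx_end,
                                    cds_start, cds_end) {
    utr_lo <- c(tx_start, cds_start - 1L)   # left flank
    utr_hi <- c(cds_end + 1L, tx_end)       # right flank
    left_type <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
    right_type <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
    rows <- tibble(
      type = c("gene", left_type, "CDS", right_type),
      start = c(tx_start, utr_lo[1], cds_start, utr_hi[1]),
      end = c(tx_end, utr_lo[2], cds_end, utr_hi[2]),
      contig = contig, strand = strand, gene_id = gene_id
    )
    dplyr::filter(rows, .data$start <= .data$end)
  })
  feats <- dplyr::bind_rows(feats)
  if (nrow(feats) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = feats$contig,
      ranges = IRanges::IRanges(feats$start, feats$end),
      strand = feats$strand,
      type = feats$type,
      phase = ifelse(feats$type == "CDS", 0L, NA_integer_),
      ID = ifelse(feats$type == "gene", feats$gene_id,
                  paste0(feats$gene_id, ":", feats$type)),
      Parent = ifelse(feats$type == "gene", NA_character_, feats$gene_id)
    )
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED12
#'
#' Converts an annotation file into the flat gene table the pileup and
#' calling functions use. GFF3 input needs `gene` features carrying an `ID`
#' (or `gene_id`) attribute; CDS bounds are taken from `CDS` children when
#' present, otherwise the CDS is the full transcript span (zero-length UTRs).
#' BED12 input uses the thick range as the CDS.
#'
#' @param path Annotation file (`.gff3`/`.gff` or `.bed`).
#' @param extend_utr Length-2 numeric `c(five, three)`: for genes whose CDS
#'   equals the transcript span (no annotated UTRs), extend the transcript
#'   span by this many bases on the 5' and 3' sides so UTR regions exist.
#'   Default adds nothing.
#' @return A tibble with columns `gene_id`, `contig`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end`.
#' @export
read_annotation <- function(path, extend_utr = c(0, 0)) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(path, format = "bed")
    genes <- tibble(
      gene_id = gr$name %||% as.character(seq_along(gr)),
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      tx_start = GenomicRanges::start(gr),
      tx_end = GenomicRanges::end(gr),
      cds_start = if (!is.null(gr$thick)) IRanges::start(gr$thick) else GenomicRanges::start(gr),
      cds_end = if (!is.null(gr$thick)) IRanges::end(gr$thick) else GenomicRanges::end(gr)
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    is_gene <- meta$type == "gene"
    ids <- as.character(meta$ID)
    if (!is.null(meta$gene_id)) {
      ids <- ifelse(is.na(ids), as.character(meta$gene_id), ids)
    }
    genes <- tibble(
      gene_id = ids[is_gene],
      contig = as.character(GenomicRanges::seqnames(gr))[is_gene],
      strand = as.character(GenomicRanges::strand(gr))[is_gene],
      tx_start = GenomicRanges::start(gr)[is_gene],
      tx_end = GenomicRanges::end(gr)[is_gene]
    )
    parent_of <- if (is.null(meta$Parent)) {
      rep(NA_character_, length(gr))
    } else {
      # Parent is a CharacterList with zero or more entries per feature
      vapply(as.list(meta$Parent),
             function(x) if (length(x)) as.character(x[1]) else NA_character_,
             character(1))
    }
    cds <- tibble(
      parent = parent_of[meta$type == "CDS"],
      start = GenomicRanges::start(gr)[meta$type == "CDS"],
      end = GenomicRanges::end(gr)[meta$type == "CDS"]
    )
    cds <- dplyr::summarise(dplyr::group_by(cds, .data$parent),
                            cds_start = min(.data$start),
                            cds_end = max(.data$end), .groups = "drop")
    genes <- dplyr::left_join(genes, cds, by = c(gene_id = "parent"))
    genes <- dplyr::mutate(
      genes,
      cds_start = dplyr::coalesce(.data$cds_start, .data$tx_start),
      cds_end = dplyr::coalesce(.data$cds_end, .data$tx_end)
    )
  }
  no_utr <- genes$cds_start == genes$tx_start & genes$cds_end == genes$tx_end
  if (any(no_utr) && any(extend_utr > 0)) {
    plus <- genes$strand == "+"
    genes$tx_start[no_utr] <- pmax(1L, genes$tx_start[no_utr] -
      as.integer(ifelse(plus[no_utr], extend_utr[1], extend_utr[2])))
    genes$tx_end[no_utr] <- genes$tx_end[no_utr] +
      as.integer(ifelse(plus[no_utr], extend_utr[2], extend_utr[1]))
  }
  dplyr::mutate(genes, dplyr::across(c("tx_start", "tx_end", "cds_start", "cds_end"),
                                     as.integer))
}

# coerce genome / tibble into a gene table
as_gene_table <- function(annotation) {
  if (inherits(annotation, "tribe_genome")) {
    return(annotation$genes)
  }
  if (is.character(annotation) && length(annotation) == 1) {
    return(read_annotation(annotation))
  }
  stopifnot_cols(annotation,
                 c("gene_id", "contig", "strand", "tx_start", "tx_end",
                   "cds_start", "cds_end"),
                 "gene annotation")
  as_tibble(annotation)
}
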