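#' Load aligned reads from SAM or BAM
#'
#' Reads a coordinate-sorted SAM/BAM through Rsamtools, drops unmapped,
#' secondary and supplementary records, and resolves each read's library
#' strand (the transcript strand implied by its alignment orientation) from
#' the FLAG bits and the library protocol: under `fr-firststrand` (dUTP)
#' read 1 aligns antisense to the transcript, under `fr-secondstrand` sense;
#' `unstranded-by-gene` leaves the library strand `NA` and the pileup
#' assigns strand from the overlapping gene instead.
#'
#' @param path SAM or BAM file.
#' @param strand_protocol `"fr-firststrand"` (default), `"fr-secondstrand"`
#'   or `"unstranded-by-gene"`.
#' @param min_mapq Drop reads below this mapping quality (default 0: keep
#'   all; uniqueness filtering is normally the aligner's job).
#' @return A tibble with one row per retained alignment: `qname`, `flag`,
#'   `contig`, `start`, `end` (1-based inclusive reference span), `mapq`,
#'   `cigar`, `library_strand`, `mate` (0 unpaired, 1 first, 2 second),
#'   `mpos`, `seq`.
#' @export
load_alignments <- function(path,
                            strand_protocol = c("fr-firststrand",
                                                "fr-secondstrand",
                                                "unstranded-by-gene"),
                            min_mapq = 0) {
  strand_protocol <- match.arg(strand_protocol)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mpos", "seq")
    )
  )[[1]]
  keep <- !is.na(res$pos) &
    bitwAnd(res$flag, 0x4) == 0 &     # unmapped
    bitwAnd(res$flag, 0x100) == 0 &   # secondary
    bitwAnd(res$flag, 0x800) == 0     # supplementary
  if (min_mapq > 0) keep <- keep & !is.na(res$mapq) & res$mapq >= min_mapq
  flag <- res$flag[keep]
  cigar <- res$cigar[keep]
  pos <- res$pos[keep]
  read_strand <- ifelse(bitwAnd(flag, 0x10) > 0, "-", "+")
  mate <- ifelse(bitwAnd(flag, 0x40) > 0, 1L,
                 ifelse(bitwAnd(flag, 0x80) > 0, 2L, 0L))
  library_strand <- switch(strand_protocol,
    "fr-firststrand" = ifelse(mate == 2L, read_strand, other_strand(read_strand)),
    "fr-secondstrand" = ifelse(mate == 2L, other_strand(read_strand), read_strand),
    "unstranded-by-gene" = rep(NA_character_, length(flag))
  )
  tibble(
    qname = res$qname[keep],
    flag = flag,
    contig = as.character(res$rname[keep]),
    start = pos,
    end = pos + cigar_ref_width(cigar) - 1L,
    mapq = res$mapq[keep],
    cigar = cigar,
    library_strand = library_strand,
    mate = mate,
    mpos = res$mpos[keep],
    seq = as.character(res$seq[keep])
  )
}

#' Remove PCR duplicates by positional key
#'
#' Keeps exactly one representative per duplicate key
#' `(contig, start, end, library_strand, mate, mate position)` — the
#' convention for libraries without UMIs. Retention is deterministic: the
#' first record in `(contig, start, end, qname)` order survives. Idempotent.
#'
#' @param reads A read tibble from [load_alignments()] (or
#'   [simulate_reads()], whose columns are a subset).
#' @return The deduplicated tibble.
#' @export
dedup_reads <- function(reads) {
  stopifnot_cols(reads, c("contig", "start", "end", "qname"), "reads")
  if (!"library_strand" %in% names(reads)) {
    reads$library_strand <- reads$read_strand
  }
  if (!"mate" %in% names(reads)) reads$mate <- 0L
  if (!"mpos" %in% names(reads)) reads$mpos <- NA_integer_
  reads <- dplyr::arrange(reads, .data$contig, .data$start, .data$end,
                          .data$qname)
  dplyr::distinct(reads, .data$contig, .data$start, .data$end,
                  .data$library_strand, .data$mate, .data$mpos,
                  .keep_all = TRUE)
}

#' Build a strand-resolved per-position base pileup
#'
#' Tallies, for every covered reference position, the A/C/G/T counts on the
#' transcript strand. Reads contribute at a genic position only when their
#' library strand matches the gene's strand (all reads contribute under an
#' unstranded protocol); counts and the reference base are
#' reverse-complemented for minus-strand genes so that an A-to-G edit always
#' reads as reference `A`, observed `G`. Positions outside any gene are
#' reported on the forward strand with `genic = FALSE` and can never become
#' editing sites.
#'
#' @param reads Deduplicated read tibble.
#' @param reference Reference sequences: a [Biostrings::DNAStringSet], a
#'   `tribe_genome`, or a FASTA path.
#' @param annotation Gene models: a `tribe_genome`, a gene tibble, or a
#'   GFF3/BED12 path (see [read_annotation()]).
#' @param count_mode `"fragment"` (default) counts a position once per
#'   fragment when paired mates overlap it; `"read"` counts every aligned
#'   base of every read.
#' @return A tibble of class `tribe_pileup`: `contig`, `pos`, `gene_id`,
#'   `strand`, `genic`, `ref`, `A`, `C`, `G`, `T`, `coverage`, all on the
#'   transcript strand for genic rows.
#' @export
build_pileup <- function(reads, reference, annotation,
                         count_mode = c("fragment", "read")) {
  count_mode <- match.arg(count_mode)
  contigs <- as_contig_set(reference)
  genes <- as_gene_table(annotation)
  if (!"library_strand" %in% names(reads) && "read_strand" %in% names(reads)) {
    reads$library_strand <- reads$read_strand
  }
  bad <- setdiff(unique(reads$contig), names(contigs))
  if (length(bad) > 0) {
    abort(sprintf("read contig(s) absent from reference: %s",
                  paste(bad, collapse = ", ")))
  }

  out <- vector("list", length(names(contigs)))
  names(out) <- names(contigs)
  for (ctg in unique(reads$contig)) {
    r <- reads[reads$contig == ctg, ]
    if (nrow(r) == 0) next
    expanded <- expand_bases(r, count_mode)
    clen <- Biostrings::width(contigs)[match(ctg, names(contigs))]
    bi <- match(expanded$base, BASE_INT)  # non-ACGT read bases (N) drop out
    ok <- !is.na(bi) & expanded$pos >= 1L & expanded$pos <= clen
    pos <- expanded$pos[ok]
    bi <- bi[ok]
    plus <- is.na(expanded$strand[ok]) | expanded$strand[ok] == "+"
    # counts per (position, strand, base) via tabulate on a packed index
    code <- (pos - 1L) * 8L + (!plus) * 4L + bi
    counts <- tabulate(code, nbins = 8L * clen)
    covered <- which(tabulate(pos, nbins = clen) > 0L)

    cnt <- function(p, strandbit, b) counts[(p - 1L) * 8L + strandbit * 4L + b]
    mat_plus <- vapply(1:4, function(b) cnt(covered, 0L, b), integer(length(covered)))
    mat_minus <- vapply(1:4, function(b) cnt(covered, 1L, b), integer(length(covered)))
    if (length(covered) == 1) {
      mat_plus <- matrix(mat_plus, nrow = 1)
      mat_minus <- matrix(mat_minus, nrow = 1)
    }

    g <- genes[genes$contig == ctg, ]
    hit <- rep(NA_integer_, length(covered))
    if (nrow(g) > 0) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(covered, covered),
        IRanges::IRanges(g$tx_start, g$tx_end),
        select = "first"
      )
      hit <- as.integer(ov)
    }
    gene_strand <- ifelse(is.na(hit), NA_character_, g$strand[hit])
    unstranded <- all(is.na(expanded$strand))

    # genic rows: counts from reads matching the gene strand
    use_minus <- !is.na(gene_strand) & gene_strand == "-" & !unstranded
    use_plus_only <- !is.na(gene_strand) & gene_strand == "+" & !unstranded
    raw <- mat_plus + mat_minus           # unstranded / intergenic tally
    sel <- raw
    sel[use_plus_only, ] <- mat_plus[use_plus_only, , drop = FALSE]
    sel[use_minus, ] <- mat_minus[use_minus, , drop = FALSE]

    ref_fwd <- intToUtf8(utf8ToInt(as.character(contigs[[ctg]]))[covered],
                         multiple = TRUE)
    flip <- !is.na(gene_strand) & gene_strand == "-"
    # complement counts and reference onto the transcript strand
    A <- ifelse(flip, sel[, 4L], sel[, 1L])
    C <- ifelse(flip, sel[, 3L], sel[, 2L])
    G <- ifelse(flip, sel[, 2L], sel[, 3L])
    T_ <- ifelse(flip, sel[, 1L], sel[, 4L])
    ref <- ifelse(flip, comp_base(ref_fwd), ref_fwd)

    out[[ctg]] <- tibble(
      contig = ctg, pos = covered,
      gene_id = ifelse(is.na(hit), NA_character_, g$gene_id[hit]),
      strand = ifelse(is.na(gene_strand), "+", gene_strand),
      genic = !is.na(hit),
      ref = ref, A = A, C = C, G = G, T = T_,
      coverage = A + C + G + T_
    )
  }
  res <- dplyr::bind_rows(out)
  res <- res[res$coverage > 0, ]
  class(res) <- c("tribe_pileup", class(res))
  res
}

# expand reads into per-base (pos, base utf8 int, library strand) vectors;
# fragment mode counts a (qname, pos) pair once when mates overlap
expand_bases <- function(r, count_mode) {
  if ("cigar" %in% names(r)) {
    simple <- grepl("^[0-9]+M$", r$cigar)
  } else {
    simple <- rep(TRUE, nrow(r))
  }

  expand_simple <- function(rr) {
    w <- rr$end - rr$start + 1L
    list(pos = sequence(w, from = rr$start),
         base = utf8ToInt(paste(rr$seq, collapse = "")),
         strand = rep(rr$library_strand, w),
         qname = NULL, w = w)
  }
  expand_cigar <- function(rr) {
    res <- purrr::pmap(list(rr$cigar, rr$seq, rr$start), function(cg, sq, st) {
      ops <- cigar_ops(cg)
      rpos <- st
      qpos <- 1L
      ps <- integer(0); bs <- integer(0)
      for (i in seq_along(ops$op)) {
        len <- ops$len[i]
        op <- ops$op[i]
        if (op %in% c("M", "=", "X")) {
          ps <- c(ps, rpos:(rpos + len - 1L))
          bs <- c(bs, utf8ToInt(substr(sq, qpos, qpos + len - 1L)))
          rpos <- rpos + len; qpos <- qpos + len
        } else if (op %in% c("I", "S")) {
          qpos <- qpos + len
        } else if (op %in% c("D", "N")) {
          rpos <- rpos + len
        }
      }
      list(pos = ps, base = bs)
    })
    w <- vapply(res, function(x) length(x$pos), integer(1))
    list(pos = unlist(lapply(res, `[[`, "pos")),
         base = unlist(lapply(res, `[[`, "base")),
         strand = rep(rr$library_strand, w),
         w = w)
  }

  parts <- list()
  idx_order <- integer(0)
  if (any(simple)) parts <- c(parts, list(c(expand_simple(r[simple, ]),
                                            list(rows = which(simple)))))
  if (any(!simple)) parts <- c(parts, list(c(expand_cigar(r[!simple, ]),
                                             list(rows = which(!simple)))))
  pos <- unlist(lapply(parts, `[[`, "pos"))
  base <- unlist(lapply(parts, `[[`, "base"))
  strand <- unlist(lapply(parts, `[[`, "strand"))
  rowid <- unlist(lapply(parts, function(p) rep(p$rows, p$w)))

  if (count_mode == "fragment" && anyDuplicated(r$qname) > 0) {
    qn <- r$qname[rowid]
    dupq <- unique(r$qname[duplicated(r$qname)])
    affected <- qn %in% dupq
    if (any(affected)) {
      key <- paste(qn[affected], pos[affected])
      drop <- duplicated(key)
      keep <- rep(TRUE, length(pos))
      keep[which(affected)[drop]] <- FALSE
      pos <- pos[keep]; base <- base[keep]; strand <- strand[keep]
    }
  }
  list(pos = pos, base = base, strand = strand)
}
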