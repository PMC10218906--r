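test_that("SAM loading skips unusable records and resolves library strand", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:100",
    "r1\t0\tc1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t16\tc1\t5\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*",          # unmapped
    "r4\t256\tc1\t7\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",    # secondary
    "r5\t2048\tc1\t9\t60\t5M5S\t*\t0\t0\tACGTACGTAC\t*"   # supplementary
  ), sam)
  reads <- load_alignments(sam, "fr-firststrand")
  expect_equal(reads$qname, c("r1", "r2"))
  expect_equal(reads$end, c(10L, 14L))
  # dUTP single-end: library strand is the opposite of the read strand
  expect_equal(reads$library_strand, c("-", "+"))
  reads2 <- load_alignments(sam, "fr-secondstrand")
  expect_equal(reads2$library_strand, c("+", "-"))

  # header-only file: empty stream
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:c1\tLN:100"),
             file.path(d, "empty.sam"))
  expect_equal(nrow(load_alignments(file.path(d, "empty.sam"))), 0)
})

test_that("a simulated SAM round-trips through the loader", {
  cfg <- tiny_cfg(seed = 11, dup_rate = 0.15)
  g <- generate_genome(cfg)
  tr <- plant_truth(g, cfg)
  d <- withr::local_tempdir()
  sam <- file.path(d, "fusion.sam")
  sim <- simulate_reads(g, tr, cfg, "fusion", path = sam)
  loaded <- load_alignments(sam, cfg$strand_protocol)
  expect_equal(nrow(loaded), nrow(sim))
  expect_equal(nrow(loaded),
               attr(sim, "n_primary") + attr(sim, "n_duplicates"))
  key <- function(x) paste(x$contig, x$start, x$end, x$library_strand)
  expect_setequal(key(loaded), key(sim))
  # and the loader-derived library strand agrees with the simulator's truth
  m <- match(loaded$qname, sim$qname)
  expect_equal(loaded$library_strand, sim$library_strand[m])
})

test_that("deduplication keeps one read per positional key and is idempotent", {
  r <- tibble::tibble(
    qname = c("a", "b", "c"), flag = 0L, contig = "c1",
    start = c(10L, 10L, 20L), end = c(60L, 60L, 70L),
    library_strand = "+", seq = strrep("A", 51)
  )
  d1 <- dedup_reads(r)
  expect_equal(nrow(d1), 2)
  expect_true(all(c("a", "c") %in% d1$qname))  # first in sorted order survives
  expect_identical(dedup_reads(d1), d1)

  all_unique <- dplyr::mutate(r, start = c(10L, 11L, 20L), end = start + 50L)
  expect_equal(nrow(dedup_reads(all_unique)), 3)
})

test_that("dedup recovers the simulator's unique primary key count", {
  cfg <- tiny_cfg(seed = 13, dup_rate = 0.2)
  g <- generate_genome(cfg)
  tr <- plant_truth(g, cfg)
  reads <- simulate_reads(g, tr, cfg, "fusion")
  expect_equal(nrow(dedup_reads(reads)), attr(reads, "n_unique_primary_keys"))
})

test_that("pileup counts one read's bases, complementing on minus-strand genes", {
  contigs <- Biostrings::DNAStringSet(c(c1 = "AATTCCTGAA"))
  genes <- tibble::tibble(gene_id = c("gp", "gm"), contig = "c1",
                          strand = c("+", "-"),
                          tx_start = c(1L, 6L), tx_end = c(5L, 10L),
                          cds_start = c(1L, 6L), cds_end = c(5L, 10L))
  read_p <- tibble::tibble(qname = "r1", flag = 0L, contig = "c1",
                           start = 1L, end = 5L, library_strand = "+",
                           seq = "AATTC")
  p <- build_pileup(read_p, contigs, genes)
  expect_equal(nrow(p), 5)
  expect_equal(p$A, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(p$T, c(0L, 0L, 1L, 1L, 0L))
  expect_equal(p$C, c(0L, 0L, 0L, 0L, 1L))

  # forward T->C mismatch inside a minus-strand gene = transcript A->G
  read_m <- tibble::tibble(qname = "r2", flag = 16L, contig = "c1",
                           start = 6L, end = 10L, library_strand = "-",
                           seq = "CCGAA")  # reference window is CTGAA; pos 7 T -> C
  pm <- build_pileup(read_m, contigs, genes)
  row7 <- pm[pm$pos == 7, ]
  expect_equal(row7$ref, "A")   # forward T complemented
  expect_equal(row7$G, 1L)      # forward C observed => transcript G
  expect_equal(row7$strand, "-")
})

test_that("pileup conserves aligned bases and only reads matching the gene strand count", {
  cfg <- tiny_cfg(seed = 15, dup_rate = 0)
  x <- sim_triple(cfg)
  p <- build_pileup(x$fusion, x$genome, x$genome)
  expect_equal(sum(p$coverage), sum(x$fusion$end - x$fusion$start + 1))

  # an antisense read contributes nothing at a stranded genic position
  g1 <- x$genome$genes[1, ]
  anti <- tibble::tibble(
    qname = "anti", flag = 0L, contig = g1$contig,
    start = g1$tx_start, end = g1$tx_start + 9L,
    library_strand = ifelse(g1$strand == "+", "-", "+"),
    seq = strrep("A", 10)
  )
  pa <- build_pileup(anti, x$genome, x$genome)
  expect_equal(nrow(pa[pa$genic & pa$coverage > 0, ]), 0)
})

test_that("overlapping mates count once per fragment, twice in read mode", {
  contigs <- Biostrings::DNAStringSet(c(c1 = strrep("A", 30)))
  genes <- tibble::tibble(gene_id = "g", contig = "c1", strand = "+",
                          tx_start = 1L, tx_end = 30L,
                          cds_start = 1L, cds_end = 30L)
  pair <- tibble::tibble(
    qname = "frag1", flag = c(0L, 0L), contig = "c1",
    start = c(1L, 6L), end = c(10L, 15L), library_strand = "+",
    seq = c(strrep("A", 10), strrep("A", 10)), mate = c(1L, 2L)
  )
  frag <- build_pileup(pair, contigs, genes, count_mode = "fragment")
  expect_equal(frag$coverage[frag$pos == 8], 1L)
  perread <- build_pileup(pair, contigs, genes, count_mode = "read")
  expect_equal(perread$coverage[perread$pos == 8], 2L)
  # non-overlapping flanks identical in both modes
  expect_equal(frag$coverage[frag$pos == 2], perread$coverage[perread$pos == 2])
})

test_that("pileup refuses reads on contigs missing from the reference", {
  contigs <- Biostrings::DNAStringSet(c(c1 = strrep("A", 30)))
  genes <- tibble::tibble(gene_id = "g", contig = "c1", strand = "+",
                          tx_start = 1L, tx_end = 30L,
                          cds_start = 1L, cds_end = 30L)
  bad <- tibble::tibble(qname = "r", flag = 0L, contig = "cX",
                        start = 1L, end = 5L, library_strand = "+",
                        seq = "AAAAA")
  expect_error(build_pileup(bad, contigs, genes), "cX")
})

test_that("error-free fusion pileup mismatches occur only at planted positions", {
  cfg <- tiny_cfg(error_rate = 0, seed = 21)
  x <- sim_triple(cfg)
  p <- build_pileup(dedup_reads(x$fusion), x$genome, x$genome)
  ref_count <- vapply(seq_len(nrow(p)), function(i) p[[p$ref[i]]][i], integer(1))
  mism <- p[p$coverage > ref_count, ]
  planted <- c(x$truth$edit_sites$pos, x$truth$snp_sites$pos)
  expect_true(all(mism$pos %in% planted))
})
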