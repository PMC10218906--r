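test_that("candidate calling applies the r/e thresholds on the A+G denominator", {
  p <- make_pileup(
    list(pos = 1L, A = 20L, G = 5L),                 # 5/25 = 20% of A+G, cov 25
    list(pos = 2L, A = 18L, G = 1L),                 # cov 19 < 20
    list(pos = 3L, A = 85L, G = 9L, C = 6L),         # 9/94 = 9.57% < 10
    list(pos = 4L, A = 90L, G = 10L),                # 10% exactly: emitted
    list(pos = 5L, ref = "C", A = 0L, C = 20L, G = 20L),  # ref not A
    list(pos = 6L, A = 20L, G = 5L, genic = FALSE, gene_id = NA)
  )
  s <- call_candidate_sites(p, thresholds("r20e10"))
  expect_equal(s$pos, c(1L, 4L))
  expect_equal(s$editing_percent, c(20, 10))
  expect_s3_class(s, "tribe_sites")
})

test_that("raising thresholds never adds sites (r20e10 subset of r10e10)", {
  cfg <- tiny_cfg(seed = 31, editing_fraction_range = c(0.05, 0.8))
  x <- sim_triple(cfg)
  p <- build_pileup(dedup_reads(x$fusion), x$genome, x$genome)
  s20 <- call_candidate_sites(p, thresholds("r20e10"))
  s10 <- call_candidate_sites(p, thresholds("r10e10"))
  key <- function(s) paste(s$contig, s$pos)
  expect_true(all(key(s20) %in% key(s10)))
  expect_true(all(unique(s20$gene_id) %in% unique(s10$gene_id)))
})

test_that("background subtraction follows the control rule", {
  sites <- call_candidate_sites(
    make_pileup(list(pos = 10L, A = 50L, G = 30L),
                list(pos = 20L, A = 50L, G = 30L),
                list(pos = 30L, A = 50L, G = 30L)),
    thresholds("r20e10")
  )
  control <- make_pileup(
    list(pos = 10L, A = 45L, G = 5L),   # 10% in control: removed
    list(pos = 30L, A = 50L, G = 1L)    # one stray G read: retained
  )
  out <- subtract_background(sites, control)
  expect_equal(out$pos, c(20L, 30L))    # absent from control: retained too

  missing_ctg <- make_pileup(list(pos = 10L, contig = "other", A = 45L, G = 5L))
  expect_warning(out2 <- subtract_background(sites, missing_ctg), "retained")
  expect_equal(nrow(out2), 3)
})

test_that("SNP exclusion drops homozygous variants but keeps real edits", {
  sites <- call_candidate_sites(
    make_pileup(list(pos = 10L, A = 0L, G = 60L),    # SNP: 100% G everywhere
                list(pos = 20L, A = 36L, G = 24L),   # real 40% edit
                list(pos = 30L, A = 0L, G = 1L, C = 59L)),  # A->C SNP + error G
    thresholds("r20e10")
  )
  wt <- make_pileup(
    list(pos = 10L, A = 0L, G = 55L),
    list(pos = 20L, A = 58L, G = 0L),
    list(pos = 30L, A = 0L, C = 57L)
  )
  out <- exclude_snps(sites, wt)
  expect_equal(out$pos, 20L)

  # fallback without wild type: ~100% sites also ~100% in control are dropped
  ctl <- make_pileup(list(pos = 10L, A = 0L, G = 40L))
  out2 <- exclude_snps(sites, NULL, control_pileup = ctl)
  expect_false(10L %in% out2$pos)
  expect_true(20L %in% out2$pos)
  expect_error(exclude_snps(sites, NULL), "control_pileup")
})

test_that("background subtraction and SNP exclusion commute", {
  cfg <- tiny_cfg(seed = 33)
  x <- sim_triple(cfg)
  pf <- build_pileup(dedup_reads(x$fusion), x$genome, x$genome)
  pc <- build_pileup(dedup_reads(x$control), x$genome, x$genome)
  pw <- build_pileup(dedup_reads(x$wildtype), x$genome, x$genome)
  cand <- call_candidate_sites(pf, thresholds("r20e10"))
  ab <- exclude_snps(subtract_background(cand, pc), pw)
  ba <- subtract_background(exclude_snps(cand, pw), pc)
  expect_equal(as.data.frame(ab), as.data.frame(ba))
})

test_that("full filtering removes every planted SNP from the final site list", {
  cfg <- tiny_cfg(seed = 35, snp_rate = 5e-3)
  x <- sim_triple(cfg)
  res <- call_editing(x$fusion, x$control, x$wildtype, x$genome, x$genome)
  expect_length(intersect(res$sites$pos, x$truth$snp_sites$pos), 0)
  # stage bookkeeping is monotone
  expect_true(res$stage_counts["final"] <= res$stage_counts["after_background"])
  expect_true(res$stage_counts["after_background"] <= res$stage_counts["candidates"])
})

test_that("the mismatch spectrum isolates planted substitution types", {
  # only A>G planted, no errors, no SNPs: all 11 other bins empty
  cfg <- tiny_cfg(error_rate = 0, snp_rate = 0, seed = 37)
  x <- sim_triple(cfg)
  p <- build_pileup(dedup_reads(x$fusion), x$genome, x$genome)
  sp <- mismatch_spectrum(p, thresholds("r20e10"))
  expect_equal(sum(sp$n_sites[sp$label != "A>G"]), 0)
  expect_gt(sp$n_sites[sp$label == "A>G"], 0)

  # planted C->T contamination lands only in the C>T bin
  pc <- make_pileup(list(pos = 1L, ref = "C", C = 40L, T = 20L),
                    list(pos = 2L, ref = "C", C = 40L, T = 20L))
  spc <- mismatch_spectrum(pc, thresholds("r20e10"))
  expect_equal(spc$n_sites[spc$label == "C>T"], 2L)
  expect_equal(sum(spc$n_sites), 2L)
})

test_that("symmetric random errors spread the spectrum evenly over the 12 bins", {
  # multinomial oracle: equal-probability substitutions at fixed depth
  withr::local_seed(99)
  n_pos <- 2400
  refs <- sample(c("A", "C", "G", "T"), n_pos, replace = TRUE)
  rows <- lapply(seq_len(n_pos), function(i) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), refs[i]), 1)
    r <- list(pos = i, ref = refs[i], A = 0L, C = 0L, G = 0L, T = 0L)
    r[[refs[i]]] <- 30L
    r[[alt]] <- 10L   # 25% of ref+alt, passes e=10
    r
  })
  p <- do.call(make_pileup, rows)
  sp <- mismatch_spectrum(p, thresholds("r20e10"))
  expect_equal(sum(sp$n_sites), n_pos)
  gof <- chisq.test(sp$n_sites)
  expect_gt(gof$p.value, 1e-4)
})

test_that("site exports carry the documented coordinate conventions", {
  sites <- call_candidate_sites(
    make_pileup(list(pos = 100L, A = 30L, G = 30L)), thresholds("r20e10"))
  d <- withr::local_tempdir()
  export_sites_bed(sites, file.path(d, "s.bed"))
  bed <- readr::read_tsv(file.path(d, "s.bed"), col_names = FALSE,
                         show_col_types = FALSE)
  expect_equal(bed$X2, 99)            # 0-based start
  expect_equal(bed$X3, 100)           # half-open end
  expect_equal(bed$X5, 500)           # editing percent x 10
  expect_equal(bed$X6, "+")
})
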