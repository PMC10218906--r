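mk_sites <- function(pos, ep, gene = "g") {
  tibble::tibble(contig = "c1", pos = as.integer(pos), gene_id = gene,
                 strand = "+", region = "CDS", A_count = 10L, G_count = 10L,
                 coverage = 20L, editing_percent = ep)
}

test_that("replicate R^2 matches least squares and its invariances", {
  a <- mk_sites(1:5, c(10, 25, 40, 60, 85))
  b <- mk_sites(1:5, c(12, 22, 45, 58, 80))
  expected <- summary(lm(b$editing_percent ~ a$editing_percent))$r.squared
  expect_equal(replicate_r2(a, b), expected, tolerance = 1e-12)

  # order swap and joint affine rescale leave R^2 unchanged
  expect_equal(replicate_r2(b, a), replicate_r2(a, b))
  b2 <- dplyr::mutate(b, editing_percent = 0.5 * editing_percent + 3)
  a2 <- dplyr::mutate(a, editing_percent = 0.5 * editing_percent + 3)
  expect_equal(replicate_r2(a2, b2), replicate_r2(a, b))

  # identical and anti-correlated replicates both give R^2 = 1
  expect_equal(replicate_r2(a, a), 1.0)
  flip <- dplyr::mutate(a, editing_percent = 100 - editing_percent)
  expect_equal(replicate_r2(a, flip), 1.0)

  # fewer than two shared sites: missing
  expect_warning(r <- replicate_r2(a[1, ], b), "undefined")
  expect_true(is.na(r))
})

test_that("signal-to-noise reproduces the published site-count ratio", {
  sn <- signal_to_noise(847, 106)
  expect_equal(sn$ratio, 847 / 106, tolerance = 1e-12)
  expect_gt(sn$ratio, 7)
  expect_equal(signal_to_noise(50, 50)$ratio, 1.0)
  z <- signal_to_noise(10, 0)
  expect_true(is.infinite(z$ratio) && z$infinite)
})

test_that("overlap Fisher test equals brute-force hypergeometric enumeration", {
  u <- sprintf("gene%02d", 1:20)
  a <- u[1:5]
  b <- u[c(1:4, 6)]   # overlap 4
  ov <- overlap_fisher(a, b, u)
  expect_equal(ov$n_overlap, 4)
  expect_equal(ov$p_value, brute_fisher_p(4, 5, 5, 20), tolerance = 1e-12)

  ov2 <- overlap_fisher(a, b, u, alternative = "two.sided")
  expect_equal(ov2$p_value, brute_fisher_p(4, 5, 5, 20, "two.sided"),
               tolerance = 1e-10)

  # identical sets: the smallest p the margins allow
  self <- overlap_fisher(a, a, u)
  expect_equal(self$p_value, brute_fisher_p(5, 5, 5, 20), tolerance = 1e-12)
  expect_lt(self$p_value, ov$p_value)

  # overlap at the independence expectation: odds ratio near 1
  u2 <- sprintf("g%03d", 1:100)
  a2 <- u2[1:20]
  b2 <- c(u2[1:4], u2[21:36])  # |A||B|/N = 4 = k
  ind <- overlap_fisher(a2, b2, u2)
  expect_equal(ind$odds_ratio, 1, tolerance = 0.15)

  expect_error(overlap_fisher(c(a, "offworld"), b, u), "offworld")
  td <- tidy(ov)
  expect_equal(td$n_overlap, 4)
  expect_equal(td$p.value, ov$p_value)
})

test_that("DEG filtering applies the microarray and RNA-seq cutoffs", {
  ma <- tibble::tibble(
    gene = sprintf("g%d", 1:6),
    log_ratio = c(0.3, 0.15, -0.25, 0.5, -0.19, 0.21),
    p = c(0.05, 0.05, 0.09, 0.2, 0.01, 0.099)
  )
  kept <- deg_filter(ma, "microarray")
  manual <- ma[ma$p < 0.1 & abs(ma$log_ratio) > 0.2, ]
  expect_equal(kept, manual)
  expect_setequal(kept$gene, c("g1", "g3", "g6"))

  rs <- tibble::tibble(
    gene = sprintf("r%d", 1:6),
    fpkm_wt = c(10, 1.9, 4, 8, 1.8, 4),
    fpkm_mut = c(16, 4, 5, 4, 2.0, 1.5)
  )
  kept2 <- deg_filter(rs, "rnaseq")
  ratio <- rs$fpkm_mut / rs$fpkm_wt
  manual2 <- rs[(rs$fpkm_wt + rs$fpkm_mut) / 2 >= 2 &
                  (ratio >= 1.5 | ratio <= 1 / 1.5), ]
  expect_equal(kept2, manual2)
  expect_false("r5" %in% kept2$gene)   # mean FPKM 1.9 dropped despite ratio
  expect_true("r6" %in% kept2$gene)    # down-regulation counts symmetrically

  # stricter cutoffs select subsets
  stricter <- deg_filter(ma, "microarray", p_cutoff = 0.05, log_ratio_cutoff = 0.25)
  expect_true(all(stricter$gene %in% kept$gene))
  expect_error(deg_filter(ma[, 1:2], "microarray"), "missing")
})

test_that("ECDF comparison recovers known distribution relationships", {
  same <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                         value = rep(seq(0, 1, length.out = 50), 2))
  cmp <- ecdf_compare(same)
  expect_equal(cmp$pairwise$ks_stat, 0)

  # shift of a uniform by delta: maximal CDF gap equals delta (width 1)
  withr::local_seed(1)
  n <- 4000
  shifted <- tibble::tibble(
    group = rep(c("a", "b"), each = n),
    value = c(runif(n), runif(n) + 0.25)
  )
  cmp2 <- ecdf_compare(shifted)
  expect_lt(abs(cmp2$pairwise$ks_stat - 0.25), 0.05)
  expect_lt(cmp2$pairwise$t_p, 1e-10)
  expect_lt(cmp2$anova_p, 1e-10)

  g <- glance(cmp2)
  expect_equal(g$n_groups, 2)
  expect_s3_class(autoplot(cmp2), "ggplot")
  expect_error(ecdf_compare(same[same$group == "a", ]), "2 nonempty groups")
})

test_that("one-way ANOVA in the grouped comparison holds its nominal size", {
  withr::local_seed(7)
  nsim <- 300
  rej <- 0L
  for (i in seq_len(nsim)) {
    df <- tibble::tibble(group = rep(c("a", "b", "c"), each = 40),
                         value = rnorm(120))
    rej <- rej + (ecdf_compare(df)$anova_p < 0.05)
  }
  expect_lt(rej / nsim, 0.09)
  expect_gt(rej / nsim, 0.015)
})

test_that("gene-set enrichment ranks a planted set first with valid BH q-values", {
  u <- sprintf("g%03d", 1:200)
  targets <- u[1:30]
  coll <- list(
    planted = u[1:25],
    partial = c(u[20:35], u[100:120]),
    unrelated = u[150:180]
  )
  res <- geneset_enrichment(targets, coll, u)
  expect_equal(res$set[1], "planted")
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(all(res$q_value >= res$p_value))
  expect_true(!is.unsorted(res$p_value))
  expect_equal(nrow(geneset_enrichment(targets, list(), u)), 0)
})

test_that("GMT round trip preserves set membership", {
  d <- withr::local_tempdir()
  path <- file.path(d, "sets.gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4")))
})
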