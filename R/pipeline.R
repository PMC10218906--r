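#' Call, filter and annotate editing sites for one replicate
#'
#' The core per-replicate pipeline stage: load and deduplicate the three
#' libraries, build pileups, call candidate A-to-G sites in the fusion
#' sample, subtract Hyper-only background, and exclude SNPs via the
#' wild-type sample (or the fallback rule when none is given).
#'
#' @param fusion,control,wildtype SAM/BAM paths or read tibbles (wildtype
#'   may be `NULL`).
#' @param reference Reference sequences (DNAStringSet, `tribe_genome`, or
#'   FASTA path).
#' @param annotation Gene models (`tribe_genome`, gene tibble, or path).
#' @param thresholds A [thresholds()] object.
#' @param strand_protocol Library orientation for SAM/BAM inputs.
#' @param control_rule List with `min_coverage`, `min_percent`, `min_count` for
#'   [subtract_background()].
#' @param snp_rule List with `min_coverage`, `min_alt_fraction` for
#'   [exclude_snps()].
#' @return A list: `sites` (final `tribe_sites`), `candidates`,
#'   `after_background`, `pileups` (named list), `stage_counts`.
#' @export
call_editing <- function(fusion, control, wildtype = NULL,
                         reference, annotation,
                         thresholds = tribecall::thresholds("r20e10"),
                         strand_protocol = "fr-firststrand",
                         control_rule = list(min_coverage = 10, min_percent = 1, min_count = 2),
                         snp_rule = list(min_coverage = 10, min_alt_fraction = 0.8)) {
  get_reads <- function(x) {
    if (is.character(x)) load_alignments(x, strand_protocol) else x
  }
  pile <- function(x) {
    build_pileup(dedup_reads(get_reads(x)), reference, annotation)
  }
  p_fus <- pile(fusion)
  p_ctl <- pile(control)
  p_wt <- if (!is.null(wildtype)) pile(wildtype) else NULL

  cand <- call_candidate_sites(p_fus, thresholds, annotation)
  after_bg <- subtract_background(cand, p_ctl,
                                  min_coverage = control_rule$min_coverage,
                                  min_percent = control_rule$min_percent,
                                  min_count = control_rule$min_count %||% 2)
  final <- exclude_snps(after_bg, p_wt,
                        min_coverage = snp_rule$min_coverage,
                        min_alt_fraction = snp_rule$min_alt_fraction,
                        control_pileup = p_ctl)
  list(
    sites = final, candidates = cand, after_background = after_bg,
    pileups = list(fusion = p_fus, control = p_ctl, wildtype = p_wt),
    stage_counts = c(candidates = nrow(cand),
                     after_background = nrow(after_bg),
                     final = nrow(final))
  )
}

#' Run the full synthetic HyperTRIBE pipeline
#'
#' End-to-end orchestration at desk scale: simulate a genome with planted
#' truth, emit fusion/Hyper-only/wild-type libraries for each replicate,
#' call and filter editing sites, build per-replicate and combined target
#' sets, compute replicate agreement, signal-to-noise, edits-per-gene
#' histograms, region and mismatch-spectrum tables, and write motif-window
#' FASTAs with matched background. All outputs and the machine-readable
#' summary are written under `outdir` when given; reruns with the same
#' configuration are identical.
#'
#' @param sim A [sim_config()]; its seed drives every random draw.
#' @param n_replicates Number of fusion/control replicate pairs (default 2).
#' @param threshold_preset Thresholds preset label (default `"r20e10"`).
#' @param control_rule,snp_rule Filtering rules, as in [call_editing()].
#' @param outdir Output directory, or `NULL` to skip file output.
#' @return An object of class `tribe_run`: a list with `replicates`
#'   (per-replicate results), `targets_union`, `targets_intersection`,
#'   `histogram`, `spectrum`, `region_counts`, `stats` (replicate R^2,
#'   signal-to-noise, venn counts), `windows`, `truth`, `config`, `summary`.
#' @export
run_pipeline <- function(sim = sim_config(),
                         n_replicates = 2,
                         threshold_preset = "r20e10",
                         control_rule = list(min_coverage = 10, min_percent = 1, min_count = 2),
                         snp_rule = list(min_coverage = 10, min_alt_fraction = 0.8),
                         outdir = NULL) {
  th <- thresholds(threshold_preset)
  inform(sprintf("[simulate] %d genes, %d replicate(s), seed %d",
                 sim$n_genes, n_replicates, sim$seed))
  genome <- generate_genome(sim)
  truth <- plant_truth(genome, sim)

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    base <- sim$seed + 1000L * r
    fus <- simulate_reads(genome, truth, sim, "fusion", seed = base + 1L)
    ctl <- simulate_reads(genome, truth, sim, "hyper_only", seed = base + 2L)
    wt <- simulate_reads(genome, truth, sim, "wildtype", seed = base + 3L)
    res <- call_editing(fus, ctl, wt, genome, genome, th,
                        control_rule = control_rule, snp_rule = snp_rule)
    res$targets <- build_target_set(res$sites, label = sprintf("rep%d", r))
    inform(sprintf(
      "[call] rep%d: %d candidates -> %d after background -> %d final sites in %d genes",
      r, res$stage_counts["candidates"], res$stage_counts["after_background"],
      res$stage_counts["final"], nrow(res$targets)))
    reps[[r]] <- res
  }

  sets <- lapply(reps, `[[`, "targets")
  uni <- combine_replicates(sets, "union")
  int <- combine_replicates(sets, "intersection")
  hist <- edits_per_gene(uni)
  spectrum <- mismatch_spectrum(reps[[1]]$pileups$fusion, th)
  regions <- region_counts(reps[[1]]$sites)

  r2 <- if (n_replicates >= 2) replicate_r2(reps[[1]]$sites, reps[[2]]$sites)
        else NA_real_
  ctl_cand <- call_candidate_sites(reps[[1]]$pileups$control, th, genome)
  sn <- signal_to_noise(reps[[1]]$candidates, ctl_cand)

  venn <- list(
    per_replicate_genes = vapply(sets, nrow, integer(1)),
    union_genes = nrow(uni),
    intersection_genes = nrow(int),
    per_replicate_sites = vapply(reps, function(x) nrow(x$sites), integer(1))
  )

  windows <- extract_windows(reps[[1]]$sites, genome)
  background <- if (nrow(windows) > 0) {
    sample_background(genome, genome, uni$gene_id, n = nrow(windows),
                      seed = sim$seed + 77L)
  } else windows
  enr <- if (nrow(windows) > 0) kmer_enrichment(windows, background) else NULL

  summary <- list(
    threshold = th$label,
    n_replicates = n_replicates,
    seed = sim$seed,
    stage_counts = lapply(reps, `[[`, "stage_counts"),
    venn = venn,
    replicate_r2 = r2,
    signal_to_noise = sn$ratio,
    fraction_single_site = attr(hist, "fraction_single"),
    n_truth_sites = nrow(truth$edit_sites),
    n_truth_genes = length(truth$target_genes)
  )

  run <- structure(
    list(replicates = reps, targets_union = uni, targets_intersection = int,
         histogram = hist, spectrum = spectrum, region_counts = regions,
         stats = list(replicate_r2 = r2, signal_to_noise = sn, venn = venn,
                      kmer_enrichment = enr),
         windows = list(target = windows, background = background),
         truth = truth, genome = genome,
         config = list(sim = sim, threshold = th, control_rule = control_rule,
                       snp_rule = snp_rule),
         summary = summary),
    class = "tribe_run"
  )
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(run$genome, file.path(outdir, "reference.fa"))
  write_genome_gff3(run$genome, file.path(outdir, "genes.gff3"))
  write_truth_tables(run$truth, outdir)
  for (r in seq_along(run$replicates)) {
    rep <- run$replicates[[r]]
    export_sites_tsv(rep$sites, file.path(outdir, sprintf("sites_rep%d.tsv", r)))
    export_sites_bed(rep$sites, file.path(outdir, sprintf("sites_rep%d.bed", r)))
    export_targets_tsv(rep$targets,
                       file.path(outdir, sprintf("targets_rep%d.tsv", r)))
  }
  export_targets_tsv(run$targets_union, file.path(outdir, "targets_union.tsv"))
  export_targets_tsv(run$targets_intersection,
                     file.path(outdir, "targets_intersection.tsv"))
  readr::write_tsv(as_tibble(run$histogram),
                   file.path(outdir, "edits_per_gene.tsv"))
  readr::write_tsv(run$spectrum, file.path(outdir, "mismatch_spectrum.tsv"))
  readr::write_tsv(run$region_counts, file.path(outdir, "region_counts.tsv"))
  jsonlite::write_json(run$stats$venn, file.path(outdir, "venn.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(run$windows$target) > 0) {
    write_windows_fasta(run$windows$target,
                        file.path(outdir, "windows_target.fa"))
    write_windows_fasta(run$windows$background,
                        file.path(outdir, "windows_background.fa"))
  }
  if (!is.null(run$stats$kmer_enrichment)) {
    readr::write_tsv(run$stats$kmer_enrichment,
                     file.path(outdir, "kmer_enrichment.tsv"))
  }
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.tribe_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<tribe_run> threshold %s, %d replicate(s), seed %d\n",
              s$threshold, s$n_replicates, s$seed))
  cat(sprintf("  genes: union %d, intersection %d (truth: %d targets)\n",
              s$venn$union_genes, s$venn$intersection_genes, s$n_truth_genes))
  cat(sprintf("  replicate R^2 %.3f, signal/noise %.2f, single-site fraction %.2f\n",
              s$replicate_r2, s$signal_to_noise, s$fraction_single_site))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `tribe_run`.
#' @param ... Unused.
#' @export
glance.tribe_run <- function(x, ...) {
  s <- x$summary
  tibble(
    threshold = s$threshold, n_replicates = s$n_replicates, seed = s$seed,
    union_genes = s$venn$union_genes,
    intersection_genes = s$venn$intersection_genes,
    replicate_r2 = s$replicate_r2, signal_to_noise = s$signal_to_noise,
    fraction_single_site = s$fraction_single_site,
    n_truth_sites = s$n_truth_sites, n_truth_genes = s$n_truth_genes
  )
}
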