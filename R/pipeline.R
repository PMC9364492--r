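#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()], with every tunable
#' threshold of the underlying modules surfaced under its standard default:
#' 100 bp discordance bins, the strict > 0.9 high-UCR bin rule, the
#' heterozygous AF window 0.25-0.75 at depth >= 5, and the 2 percent
#' short-read mismatch acceptance rule.  The genome defaults describe the
#' synthetic study conditions: 150 kb subgenomes with alternating 5 kb
#' conserved / 5 kb divergent blocks at 5 percent local divergence and
#' 0.22 percent heterozygosity; ONT-like reads at 30x with the 17.5 percent
#' mismatch / 7.5 percent gap preset, CCS-like and NGS-like reads at 20x.
#' The divergence-UCR correlation windows are scaled to the synthetic genome
#' (5 kb windows over blocks >= 20 kb).
#'
#' @param ... Overrides of any listed key (unknown keys are an error).
#' @return A named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    subgenome_length = 150000L,
    n_subgenomes = 2L,
    divergence = 0.05,
    heterozygosity = 0.0022,
    conserved_len = 5000L,
    divergent_len = 5000L,
    ont_depth = 30,
    ont_length = c(mean = 10000, min = 1000),
    ont_profile = ont_profile(),
    ccs_depth = 20,
    ngs_depth = 20,
    correction = TRUE,
    cross_subgenome = TRUE,
    min_overlap = 2000L,
    min_support = 3L,
    anchor_min = 500L,
    polish_rounds = 1L,
    map_k = 21L,
    max_mismatch_rate = 0.02,
    map_ties = "random",
    bin_size = 100L,
    ucr_bin_threshold = 0.9,
    min_depth = 5L,
    af_lo = 0.25,
    af_hi = 0.75,
    cor_block_min = 20000L,
    cor_bin = 5000L,
    seed = 42L,
    verbose = TRUE,
    out_dir = NULL)
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("config overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the end-to-end experiment
#'
#' Simulate -> (optionally) self-correct -> assemble -> polish -> evaluate:
#' builds the genome, simulates ONT-like, CCS-like and NGS-like reads,
#' corrects the long reads by overlap-cluster majority vote, builds
#' coordinate-preserving consensus assemblies from the raw, corrected and
#' CCS-like reads (plus a CCS-polished corrected assembly), maps the
#' short reads to every assembly with the seed-and-extend mapper, and
#' computes the full evaluation battery: coverage at depth thresholds, UCR
#' intervals, per-bin discordance with high-UCR classification, site calls
#' with complete-discordance statistics inside and outside the UCR, the
#' divergence-UCR correlation, the heterozygosity estimate on the CCS
#' assembly, and the removed/retained/introduced correction account.
#'
#' All randomness flows from `config$seed` (stage seeds are derived from it),
#' so a rerun with an identical config reproduces every output.
#'
#' @param config A [pipeline_config()] list.
#' @return A `ucr_pipeline` object; when `config$out_dir` is set the full
#'   report bundle (FASTA/FASTQ/TSV/BED/JSON plus a run manifest) is written
#'   there as well.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  say <- function(fmt, ...) if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))

  genome <- make_subgenomes(cfg$subgenome_length, cfg$divergence,
                            c(cfg$conserved_len, cfg$divergent_len),
                            n_subgenomes = cfg$n_subgenomes, seed = cfg$seed)
  if (cfg$heterozygosity > 0)
    genome <- add_heterozygosity(genome, cfg$heterozygosity,
                                 seed = cfg$seed + 1L)
  say("genome: %d subgenome(s) x %d bp, %d divergent + %d heterozygous sites",
      cfg$n_subgenomes, cfg$subgenome_length,
      sum(genome$truth$class == "divergent"),
      sum(genome$truth$class == "heterozygous"))

  ont <- simulate_long_reads(genome, cfg$ont_depth, cfg$ont_length,
                             cfg$ont_profile, seed = cfg$seed + 2L)
  ccs <- simulate_ccs_reads(genome, cfg$ccs_depth, seed = cfg$seed + 3L)
  ngs <- simulate_ngs_reads(genome, cfg$ngs_depth, seed = cfg$seed + 4L)
  say("reads: %d ONT-like (%d error events), %d CCS-like, %d NGS-like",
      nrow(ont$reads), nrow(ont$ledger), nrow(ccs$reads), nrow(ngs$reads))

  overlaps <- NULL
  corrected <- NULL
  account <- NULL
  if (isTRUE(cfg$correction)) {
    overlaps <- find_overlaps(ont, genome, min_overlap = cfg$min_overlap,
                              cross_subgenome = cfg$cross_subgenome,
                              anchor_min = cfg$anchor_min)
    corrected <- correct_reads(ont, genome, overlaps,
                               min_support = cfg$min_support)
    account <- correction_accounting(ont, corrected, genome)
    say("correction: %d overlap edges (%d cross-subgenome), %d errors introduced",
        nrow(overlaps), sum(overlaps$cross),
        sum(account$summary$introduced))
  }

  assemblies <- list(
    "ont-raw-consensus" = consensus_assembly(ont, genome),
    "ccs-consensus" = consensus_assembly(ccs, genome))
  if (isTRUE(cfg$correction)) {
    assemblies[["ont-corrected-consensus"]] <-
      consensus_assembly(corrected, genome)
    assemblies[["ont-corrected-polished"]] <-
      polish(assemblies[["ont-corrected-consensus"]], ccs, genome,
             rounds = cfg$polish_rounds)
  }

  evaluation <- purrr::imap(assemblies, function(asm, label) {
    set.seed(cfg$seed + 5L)
    aln <- seed_extend_map(ngs, asm, k = cfg$map_k,
                           max_mismatch_rate = cfg$max_mismatch_rate,
                           ties = cfg$map_ties)
    depth <- depth_profile(aln)
    ucr <- ucr_intervals(depth, asm)
    say("evaluate %s: %.2f%% NGS coverage, %s bp UCR", label,
        100 * mean(unlist(purrr::map2(depth, non_n_masks(depth, asm),
                                      function(d, m) d[m] > 0))),
        format(sum(ucr$end - ucr$start), big.mark = ","))
    list(aln = aln, depth = depth,
         coverage = coverage_at_thresholds(depth, asm),
         ucr = ucr,
         summary = summarize_assembly(asm, aln, nrow(ngs$reads), label))
  })
  table1 <- purrr::map_dfr(evaluation, "summary")

  focal <- if (isTRUE(cfg$correction)) "ont-corrected-consensus"
           else "ont-raw-consensus"
  focal_asm <- assemblies[[focal]]
  focal_ucr <- evaluation[[focal]]$ucr
  ont_on_focal <- oracle_place(ont, genome, target_seqs = focal_asm)
  bins <- classify_high_ucr(
    bin_discordance(ont_on_focal, focal_asm, bin_size = cfg$bin_size,
                    ngs_depth = evaluation[[focal]]$depth),
    cfg$ucr_bin_threshold)

  ccs_on_focal <- oracle_place(ccs, genome, target_seqs = focal_asm)
  calls <- call_sites(build_pileup(ccs_on_focal, focal_asm),
                      min_depth = cfg$min_depth, af_lo = cfg$af_lo,
                      af_hi = cfg$af_hi)
  cd_inside <- if (nrow(focal_ucr)) {
    ucr_complete_discordance_fraction(calls, focal_ucr)
  } else NA_real_  # no UCR at all: the density inside is undefined
  covered_iv <- complement_intervals(
    focal_ucr, setNames(nchar(focal_asm), names(focal_asm)))
  cd_outside <- ucr_complete_discordance_fraction(calls, covered_iv)

  diffs <- assembly_truth_diffs(focal_asm, genome)
  correlation <- tryCatch(
    divergence_ucr_correlation(diffs, focal_ucr, focal_asm,
                               block_min = cfg$cor_block_min,
                               bin = cfg$cor_bin),
    error = function(e) NULL)

  ccs_asm <- assemblies[["ccs-consensus"]]
  ccs_on_ccs <- oracle_place(ccs, genome, target_seqs = ccs_asm)
  het_calls <- call_sites(build_pileup(ccs_on_ccs, ccs_asm),
                          min_depth = cfg$min_depth, af_lo = cfg$af_lo,
                          af_hi = cfg$af_hi)
  het_est <- heterozygosity(het_calls)
  say("heterozygosity estimate %.4f%%; CD density %.3g in UCR vs %.3g outside",
      100 * het_est, cd_inside, cd_outside)

  res <- structure(list(
    config = cfg, genome = genome,
    reads = list(ont = ont, ccs = ccs, ngs = ngs, corrected = corrected),
    overlaps = overlaps, account = account,
    assemblies = assemblies, evaluation = evaluation, table1 = table1,
    focal_assembly = focal, bins = bins, calls = calls,
    cd_fraction = list(inside_ucr = cd_inside, outside_ucr = cd_outside),
    discordance = discordance_split(calls),
    correlation = correlation,
    heterozygosity = het_est), class = "ucr_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline(res, cfg$out_dir)
  res
}

#' @export
print.ucr_pipeline <- function(x, ...) {
  cat("<ucr_pipeline>\n")
  print(dplyr::select(x$table1, "assembly", "coverage_1x", "coverage_5x",
                      "ucr_fraction"))
  if (!is.null(x$account)) {
    cat(sprintf("introduced errors: %d (rate %.3g per template base)\n",
                sum(x$account$summary$introduced),
                sum(x$account$summary$introduced) / x$account$template_bases))
  }
  cat(sprintf("heterozygosity %.4f%%; CD density inside UCR %.3g, outside %.3g\n",
              100 * x$heterozygosity, x$cd_fraction$inside_ucr,
              x$cd_fraction$outside_ucr))
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

# Write the full report bundle plus a manifest that reproduces it.
write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_genome_fasta(res$genome, p("genome.fasta"))
  write_truth_tsv(res$genome, p("truth_sites.tsv"))
  write_genome_json(res$genome, p("genome_params.json"))
  write_reads_fastq(res$reads$ont, p("ont_reads.fastq"))
  write_ledger_tsv(res$reads$ont, p("ont_ledger.tsv"))
  write_origins_tsv(res$reads$ont, p("ont_origins.tsv"))
  if (!is.null(res$reads$corrected)) {
    write_reads_fastq(res$reads$corrected, p("corrected_reads.fastq"))
    write_account_json(res$account, p("correction_account.json"))
    write_overlaps_tsv(res$overlaps, p("overlap_graph.tsv"))
  }
  for (label in names(res$assemblies)) {
    write_assembly_fasta(res$assemblies[[label]],
                         p(sprintf("%s.fasta", label)))
    write_ucr_bed(res$evaluation[[label]]$ucr,
                  p(sprintf("%s.ucr.bed", label)))
  }
  readr::write_tsv(res$table1, p("assembly_summary.tsv"))
  write_bins_tsv(res$bins, p("bin_discordance.tsv"))
  write_calls_tsv(res$calls, p("site_calls.tsv"))
  stats_json <- list(
    heterozygosity = res$heterozygosity,
    cd_fraction = res$cd_fraction,
    discordance_split = res$discordance,
    correlation = if (!is.null(res$correlation))
      list(r = res$correlation$estimate, p = res$correlation$p.value,
           n_bins = res$correlation$n_bins) else NULL)
  jsonlite::write_json(stats_json, p("statistics.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- res$config
  manifest$ont_profile <- unclass(manifest$ont_profile)
  manifest$package_version <- as.character(utils::packageVersion("ucrsim"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Analysis-only mode on an existing assembly and alignments
#'
#' Runs the evaluation battery (depth, coverage at thresholds, UCR,
#' per-bin discordance, pileup site calls) on a user-provided assembly FASTA
#' and coordinate-sorted SAM/BAM (or an in-memory `alignment_set`).
#' Non-primary records are dropped first, mirroring a 0x900 flag filter.
#'
#' @param assembly Named character vector of sequences, or a FASTA path.
#' @param alignments An `alignment_set`, or a SAM/BAM path.
#' @param bin_size Discordance bin width (bp).
#' @param min_depth Depth filter for site calls.
#' @param cap Depth cap.
#' @return List with `alignments`, `depth`, `coverage`, `ucr`, `bins`,
#'   `calls`.
#' @export
analyze_alignments <- function(assembly, alignments, bin_size = 100,
                               min_depth = 5, cap = 200) {
  if (is.character(assembly) && length(assembly) == 1L &&
      nchar(assembly) < 4096 && file.exists(assembly))
    assembly <- read_assembly_fasta(assembly)
  aln <- if (inherits(alignments, "alignment_set")) alignments
         else read_alignments(alignments, assembly)
  aln <- filter_primary(aln)
  depth <- depth_profile(aln, cap = cap)
  ucr <- ucr_intervals(depth, assembly)
  bins <- bin_discordance(aln, assembly, bin_size = bin_size,
                          ngs_depth = depth)
  calls <- call_sites(build_pileup(aln, assembly), min_depth = min_depth)
  list(alignments = aln, depth = depth,
       coverage = coverage_at_thresholds(depth, assembly),
       ucr = ucr, bins = bins, calls = calls)
}
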