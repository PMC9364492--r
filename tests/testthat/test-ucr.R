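make_aln <- function(records, L = 100L) {
  codes <- lapply(seq_len(nrow(records)), function(i) {
    rep(0L, records$tend[i] - records$tstart[i])
  })
  ucrsim:::new_alignment_set(
    records, codes,
    tibble::tibble(rec = integer(), query_id = character(),
                   tpos = integer(), code = integer()),
    setNames(rep(L, length(unique(records$target))), unique(records$target)))
}

test_that("depth profile matches interval stabbing on trivial and simulated input", {
  rec <- tibble::tibble(query_id = "q1", target = "t", tstart = 10L,
                        tend = 20L, strand = "+", is_primary = TRUE,
                        aligned_query_bases = 10L)
  d <- depth_profile(make_aln(rec))
  expect_equal(sum(d$t), 10)
  expect_true(all(d$t[11:20] == 1L))
  g <- small_tetraploid(5000, seed = 1)
  r <- simulate_long_reads(g, depth = 5,
                           length_dist = c(mean = 1100, min = 1000), seed = 2)
  aln <- oracle_place(r, g)
  d2 <- depth_profile(aln)
  for (tn in names(d2)) {
    expect_equal(d2[[tn]], pmin(naive_depth(aln$records, tn, 5000), 200L))
  }
})

test_that("coverage fractions are hand-countable and non-increasing in the threshold", {
  depth <- list(t = c(0L, 4L, 5L, 20L))
  cov <- coverage_at_thresholds(depth)
  expect_equal(cov$fraction, c(0.75, 0.5, 0.25, 0.25))
  set.seed(3)
  for (i in 1:20) {
    d <- list(t = sample(0:30, 200, replace = TRUE))
    fr <- coverage_at_thresholds(d, thresholds = c(1, 2, 5, 8, 13, 21))$fraction
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("UCR intervals are maximal zero-depth runs and partition the non-N assembly", {
  expect_equal(nrow(ucr_intervals(list(t = rep(3L, 10)))), 0L)
  u <- ucr_intervals(list(t = c(1L, 0L, 0L, 1L)))
  expect_equal(u$start, 1L)
  expect_equal(u$end, 3L)
  # partition property with Ns
  asm <- setNames(paste(c(rep("A", 40), rep("N", 10), rep("A", 50)),
                        collapse = ""), "t")
  set.seed(4)
  depth <- list(t = sample(0:2, 100, replace = TRUE))
  ucr <- ucr_intervals(depth, asm)
  covered <- complement_intervals(ucr, c(t = 100L))
  ucr_len <- sum(ucr$end - ucr$start)
  non_n <- strsplit(asm, "")[[1]] != "N"
  # UCR plus depth-covered non-N positions tile the non-N assembly
  expect_equal(ucr_len + sum(depth$t > 0 & non_n), sum(non_n))
  # the complement is exact: no overlap, total length L
  expect_equal(ucr_len + sum(covered$end - covered$start), 100L)
  # no N position falls inside a UCR interval
  in_ucr <- logical(100)
  for (k in seq_len(nrow(ucr))) in_ucr[(ucr$start[k] + 1):ucr$end[k]] <- TRUE
  expect_true(all(non_n[in_ucr]))
})

test_that("bin discordance matches hand arithmetic and a per-base recount", {
  g <- make_subgenomes(10000, 0, c(2000, 2000), n_subgenomes = 1, seed = 5)
  clean <- simulate_long_reads(g, depth = 3, profile = error_profile(),
                               seed = 6)
  aln <- oracle_place(clean, g)
  bins <- bin_discordance(aln, subgenome_seq(g), bin_size = 100)
  expect_true(all(bins$mismatch_rate[bins$aligned_read_bases > 0] == 0))
  expect_true(all(bins$gap_rate[bins$aligned_read_bases > 0] == 0))

  noisy <- simulate_long_reads(g, depth = 5, profile = ont_profile(),
                               seed = 7)
  aln2 <- oracle_place(noisy, g)
  bins2 <- bin_discordance(aln2, subgenome_seq(g), bin_size = 100)
  # per-base recount oracle
  counts <- naive_allele_counts(aln2, "A", 10000)
  ref <- ucrsim:::dna_encode(subgenome_seq(g, "A")[[1]])
  ins <- aln2$ins
  for (b in sample(nrow(bins2), 10)) {
    span <- (bins2$start[b] + 1L):bins2$end[b]
    aligned <- sum(counts[1:4, span])
    mism <- aligned - sum(counts[cbind(ref[span] + 1L, span)])
    gap <- sum(counts[5L, span]) +
      sum(ins$tpos %in% (span - 1L))
    expect_equal(bins2$aligned_read_bases[b], aligned)
    expect_equal(bins2$mismatched_bases[b], mism)
    expect_equal(bins2$gap_length[b], gap)
  }
  # conservation across bins: aligned bin bases match total match/mismatch bases
  expect_equal(sum(bins2$aligned_read_bases), sum(counts[1:4, ]))
})

test_that("a single-read bin with 10 mismatches in 100 bases has rate 0.10", {
  target <- setNames(strrep("A", 100), "t")
  codes <- rep(0L, 100)
  codes[seq(5, 95, by = 10)] <- 1L  # 10 read bases disagree with the reference
  aln <- ucrsim:::new_alignment_set(
    tibble::tibble(query_id = "q", target = "t", tstart = 0L, tend = 100L,
                   strand = "+", is_primary = TRUE,
                   aligned_query_bases = 100L),
    list(codes),
    tibble::tibble(rec = integer(), query_id = character(),
                   tpos = integer(), code = integer()),
    c(t = 100L))
  bins <- bin_discordance(aln, target, bin_size = 100)
  expect_equal(bins$mismatch_rate, 0.10)
  expect_equal(bins$gap_rate, 0)
})

test_that("high-UCR classification is strict and exhaustive", {
  bins <- tibble::tibble(ucr_fraction = c(1, 0.9, 0.95, 0, NA))
  out <- classify_high_ucr(bins, threshold = 0.9)
  expect_equal(out$ucr_class,
               c("high-UCR", "non-UCR", "high-UCR", "non-UCR", NA))
  expect_equal(sum(out$ucr_class == "high-UCR", na.rm = TRUE) +
                 sum(out$ucr_class == "non-UCR", na.rm = TRUE),
               sum(!is.na(bins$ucr_fraction)))
})

test_that("divergence-UCR correlation recovers exact r on constructed windows", {
  # perfectly linear: ucr bases per window equal diff count per window
  L <- 10000L
  asm <- setNames(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""), "t")
  set.seed(8)
  n_diff <- sample(5:50, 10)
  diffs <- purrr::map_dfr(seq_len(10), function(w) {
    tibble::tibble(target = "t",
                   pos = (w - 1L) * 1000L + sort(sample(0:999, n_diff[w])))
  })
  ucr <- purrr::map_dfr(seq_len(10), function(w) {
    tibble::tibble(target = "t", start = (w - 1L) * 1000L,
                   end = (w - 1L) * 1000L + n_diff[w])
  })
  res <- divergence_ucr_correlation(diffs, ucr, asm, block_min = 1000,
                                    bin = 1000)
  expect_false(res$degenerate)
  expect_equal(res$estimate, 1.0, tolerance = 1e-12)
  # closed-form check on the same windows
  expect_equal(res$estimate,
               naive_pearson(res$bins$divergence, res$bins$ucr_ratio),
               tolerance = 1e-12)

  # constant divergence -> flagged degenerate
  diffs_c <- purrr::map_dfr(seq_len(10), function(w) {
    tibble::tibble(target = "t", pos = (w - 1L) * 1000L + 0:9)
  })
  res_c <- divergence_ucr_correlation(diffs_c, ucr[0, ], asm,
                                      block_min = 1000, bin = 1000)
  expect_true(res_c$degenerate)
  expect_true(is.na(res_c$estimate))
  expect_error(divergence_ucr_correlation(diffs, ucr, asm,
                                          block_min = 1e6, bin = 1000),
               "fewer than 3")
})

test_that("correlation on hand-written windows equals the covariance formula", {
  L <- 20000L
  asm <- setNames(strrep("G", L), "t")
  set.seed(9)
  n_diff <- sample(0:80, 20)
  ucr_len <- sample(0:500, 20)
  diffs <- purrr::map_dfr(seq_len(20), function(w) {
    if (n_diff[w] == 0) return(NULL)
    tibble::tibble(target = "t",
                   pos = (w - 1L) * 1000L + sort(sample(0:999, n_diff[w])))
  })
  ucr <- purrr::map_dfr(seq_len(20), function(w) {
    if (ucr_len[w] == 0) return(NULL)
    tibble::tibble(target = "t", start = (w - 1L) * 1000L,
                   end = (w - 1L) * 1000L + ucr_len[w])
  })
  res <- divergence_ucr_correlation(diffs, ucr, asm, block_min = 1000,
                                    bin = 1000)
  expect_equal(res$estimate, naive_pearson(n_diff / 1000, ucr_len / 1000),
               tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(td$estimate, res$estimate)
  expect_equal(td$n_bins, 20L)
})
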