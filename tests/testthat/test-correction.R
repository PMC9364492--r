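test_that("reads from disjoint regions share no overlap edge", {
  g <- small_tetraploid(30000, seed = 1)
  r <- simulate_long_reads(g, depth = 2,
                           length_dist = c(mean = 3000, min = 2000), seed = 2)
  ov <- find_overlaps(r, g, min_overlap = 2000)
  info <- read_info(r)
  expect_gt(nrow(ov), 0)
  # every reported edge really shares >= min_overlap bases; no disjoint pair
  # ever appears
  for (k in seq_len(nrow(ov))) {
    i <- match(ov$id1[k], info$id)
    j <- match(ov$id2[k], info$id)
    shared <- min(info$end[i], info$end[j]) - max(info$start[i], info$start[j])
    expect_gte(shared, 2000)
  }
})

test_that("truth-mode overlap edges equal all-pairs interval enumeration", {
  g <- small_tetraploid(20000, divergence = 0.05, seed = 3)
  r <- simulate_long_reads(g, depth = 3,
                           length_dist = c(mean = 3000, min = 1500), seed = 4)
  expect_lte(nrow(read_info(r)), 60)
  ov <- find_overlaps(r, g, min_overlap = 2000, anchor_min = 500)
  oracle <- naive_overlaps(r, g, min_overlap = 2000, anchor_min = 500)
  oracle_keys <- sort(vapply(oracle, paste, character(1), collapse = "|"))
  expect_identical(edge_key_set(ov), oracle_keys)
})

test_that("anchor-kmer overlap detection finds truth overlaps on clean reads", {
  g <- make_subgenomes(12000, 0, c(2000, 2000), n_subgenomes = 1, seed = 5)
  r <- simulate_long_reads(g, depth = 1.2,
                           length_dist = c(mean = 3000, min = 2500),
                           profile = error_profile(), seed = 6)
  ov_truth <- find_overlaps(r, g, min_overlap = 1000)
  ov_kmer <- find_overlaps(r, g, mode = "anchor-kmer", k = 15, t = 10)
  # every substantial truth overlap is recovered by shared k-mers
  expect_true(all(edge_key_set(ov_truth) %in% edge_key_set(ov_kmer)))
})

test_that("unanimous clusters leave reads unchanged", {
  # identical subgenomes: every voting column is unanimous for error-free reads
  g <- small_tetraploid(20000, divergence = 0, seed = 7)
  r <- simulate_long_reads(g, depth = 3, profile = error_profile(), seed = 8)
  cr <- correct_reads(r, g, min_overlap = 2000)
  expect_identical(read_info(cr)$seq, read_info(r)$seq)
  expect_equal(nrow(error_ledger(cr)), 0L)
})

test_that("a diploid cluster removes an isolated sequencing error", {
  g <- make_subgenomes(12000, 0, c(2000, 2000), n_subgenomes = 1, seed = 9)
  set.seed(10)
  repeat {
    r <- simulate_long_reads(g, depth = 6,
                             length_dist = c(mean = 6000, min = 5000),
                             profile = error_profile(0.0005, 0, 0),
                             seed = sample.int(1e6, 1))
    if (nrow(error_ledger(r)) >= 1) break
  }
  cr <- correct_reads(r, g, min_overlap = 2000, min_support = 3)
  acc <- correction_accounting(r, cr, g)
  expect_gte(sum(acc$summary$removed), 1)
  expect_equal(sum(acc$summary$introduced), 0)
})

test_that("removed plus retained equals the raw error count, exactly", {
  g <- small_tetraploid(30000, seed = 11)
  g <- add_heterozygosity(g, 0.0022, seed = 11)
  r <- simulate_long_reads(g, depth = 6, seed = 12)
  cr <- correct_reads(r, g)
  acc <- correction_accounting(r, cr, g)
  expect_equal(sum(acc$summary$removed) + sum(acc$summary$retained),
               acc$raw_error_count)
})

test_that("introduced complete flips land only on divergent sites in truth mode at high support", {
  g <- small_tetraploid(30000, divergence = 0.05, seed = 13)
  r <- simulate_long_reads(g, depth = 8, seed = 14)
  cr <- correct_reads(r, g)
  acc <- correction_accounting(r, cr, g)
  divpos <- truth_table(g)$pos[truth_table(g)$class == "divergent"]
  frac_div <- mean(acc$introduced_sites$pos %in% divpos)
  expect_gte(frac_div, 0.8)
})

test_that("diploid introduced-error rate decreases with coverage", {
  g <- make_subgenomes(80000, 0, c(5000, 5000), n_subgenomes = 1, seed = 15)
  rates <- vapply(c(10, 20, 40), function(d) {
    r <- simulate_long_reads(g, depth = d, seed = 16)
    acc <- correction_accounting(r, correct_reads(r, g), g)
    glance(acc)$introduced_rate
  }, numeric(1))
  # monotone decreasing within simulation noise: strictly so from the
  # low-coverage regime, non-increasing beyond it
  expect_gt(rates[1], rates[2])
  expect_gte(rates[2], rates[3])
})

test_that("correction is deterministic and preserves origins", {
  g <- small_tetraploid(20000, seed = 17)
  r <- simulate_long_reads(g, depth = 4, seed = 18)
  c1 <- correct_reads(r, g)
  c2 <- correct_reads(r, g)
  expect_identical(read_info(c1), read_info(c2))
  expect_identical(read_info(c1)[, c("id", "subgenome", "start", "end")],
                   read_info(r)[, c("id", "subgenome", "start", "end")])
})

test_that("refusing cross-subgenome edges suppresses introduced errors (phasing counterfactual)", {
  g <- small_tetraploid(30000, divergence = 0.05, seed = 19)
  r <- simulate_long_reads(g, depth = 20, seed = 20)
  with_cross <- correction_accounting(
    r, correct_reads(r, g, cross_subgenome = TRUE), g)
  without_cross <- correction_accounting(
    r, correct_reads(r, g, cross_subgenome = FALSE), g)
  expect_gt(sum(with_cross$summary$introduced),
            10 * sum(without_cross$summary$introduced))
})
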