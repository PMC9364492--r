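pileup_row <- function(ref, A = 0L, C = 0L, G = 0L, T = 0L, del = 0L,
                       pos = 0L) {
  tibble::tibble(target = "t", pos = pos, ref = ref,
                 depth = A + C + G + T + del,
                 A = A, C = C, G = G, T = T, del = del, ins_len = 0L)
}

test_that("site classification follows the depth and AF rules", {
  p <- dplyr::bind_rows(
    pileup_row("A", A = 2L, G = 2L, pos = 0L),            # depth 4: low-depth
    pileup_row("A", A = 5L, G = 5L, pos = 1L),            # AF 0.5: heterozygous
    pileup_row("A", G = 8L, pos = 2L),                    # all non-ref: CD
    pileup_row("A", A = 1L, G = 9L, pos = 3L),            # AF 0.9: homozygous-alt
    pileup_row("A", A = 9L, G = 1L, pos = 4L),            # AF 0.1: homozygous-ref
    pileup_row("C", C = 5L, del = 5L, pos = 5L),          # deletion allele het
    pileup_row("A", A = 2L, C = 2L, G = 2L, T = 2L, pos = 6L))
  calls <- call_sites(p, min_depth = 5)
  expect_equal(calls$class,
               c("low-depth", "heterozygous", "complete-discordance",
                 "homozygous-alt", "homozygous-ref", "heterozygous",
                 "heterozygous"))
  expect_equal(calls$alt[6], "-")
  # exactly one class per eligible site
  expect_true(all(table(calls$pos) == 1))
  # AF window boundaries are inclusive
  p2 <- dplyr::bind_rows(pileup_row("A", A = 6L, G = 2L, pos = 0L),  # AF 0.25
                         pileup_row("A", A = 2L, G = 6L, pos = 1L),  # AF 0.75
                         pileup_row("A", A = 7L, G = 1L, pos = 2L))  # AF 0.125
  expect_equal(call_sites(p2)$class,
               c("heterozygous", "heterozygous", "homozygous-ref"))
})

test_that("complete-discordance rules differ only on mixed non-reference sites", {
  p <- dplyr::bind_rows(
    pileup_row("A", G = 8L, pos = 0L),
    pileup_row("A", G = 5L, T = 3L, pos = 1L))
  default_rule <- call_sites(p, cd_rule = "any-nonref")
  strict_rule <- call_sites(p, cd_rule = "same-allele")
  expect_equal(default_rule$class,
               c("complete-discordance", "complete-discordance"))
  expect_equal(strict_rule$class[1], "complete-discordance")
  expect_false(strict_rule$class[2] == "complete-discordance")
})

test_that("summed AF mode aggregates non-reference alleles", {
  p <- pileup_row("A", A = 5L, G = 3L, T = 2L, pos = 0L)
  lead <- call_sites(p, af_mode = "leading")
  summed <- call_sites(p, af_mode = "summed")
  expect_equal(lead$af, 0.3)
  expect_equal(summed$af, 0.5)
  expect_equal(summed$class, "heterozygous")
})

test_that("heterozygosity arithmetic and denominators behave", {
  calls <- tibble::tibble(class = c(rep("heterozygous", 22),
                                    rep("homozygous-ref", 9978)))
  expect_equal(heterozygosity(calls), 0.0022)
  expect_equal(heterozygosity(calls, eligible = 20000), 0.0011)
  expect_error(heterozygosity(calls[0, ]), "eligible")
  expect_equal(heterozygosity(tibble::tibble(class = rep("homozygous-ref", 10))), 0)
})

test_that("heterozygosity is recovered from error-free reads on a diploid genome", {
  g <- make_subgenomes(200000, 0, c(5000, 5000), n_subgenomes = 1, seed = 1)
  g <- add_heterozygosity(g, 0.0022, seed = 2)
  r <- simulate_accurate_reads(g, depth = 30, read_len = c(10000, 15000),
                               error_rate = 0, seed = 3)
  aln <- oracle_place(r, g)
  calls <- call_sites(build_pileup(aln, subgenome_seq(g)), min_depth = 5)
  est <- heterozygosity(calls)
  expect_lt(abs(est - 0.0022) / 0.0022, 0.15)
  # per-site power: every deep truth het site should be called het with
  # probability given by the exact binomial AF window; check the aggregate
  tt <- truth_table(g)
  het_pos <- tt$pos[tt$class == "heterozygous"]
  called <- calls[calls$class == "heterozygous", ]
  deep <- calls$pos[calls$depth >= 20 & calls$pos %in% het_pos]
  if (length(deep) > 50) {
    p_call <- mean(deep %in% called$pos)
    # exact binomial power at n = 20 is the lowest in this depth range
    p_min <- sum(stats::dbinom(5:15, 20, 0.5))
    expect_gte(p_call, p_min - 3 * sqrt(p_min * (1 - p_min) / length(deep)))
  }
})

test_that("complete-discordance density in intervals is exact on hand-built input", {
  calls <- tibble::tibble(
    target = "t", pos = c(5L, 10L, 15L, 50L),
    class = c("complete-discordance", "complete-discordance",
              "heterozygous", "complete-discordance"))
  ucr <- tibble::tibble(target = "t", start = 0L, end = 100L)
  expect_equal(ucr_complete_discordance_fraction(calls, ucr), 3 / 100)
  narrow <- tibble::tibble(target = "t", start = 0L, end = 20L)
  expect_equal(ucr_complete_discordance_fraction(calls, narrow), 2 / 20)
  expect_warning(out <- ucr_complete_discordance_fraction(calls, ucr[0, ]),
                 "undefined")
  expect_true(is.na(out))
  none <- calls[calls$class == "heterozygous", ]
  expect_equal(ucr_complete_discordance_fraction(none, ucr), 0)
})

test_that("discordance split matches a brute-force recount on random pileups", {
  set.seed(4)
  n <- 300
  p <- tibble::tibble(
    target = "t", pos = seq_len(n) - 1L, ref = sample(c("A", "C", "G", "T"), n, TRUE),
    A = sample(0:6, n, TRUE), C = sample(0:6, n, TRUE),
    G = sample(0:6, n, TRUE), T = sample(0:6, n, TRUE),
    del = sample(0:2, n, TRUE), ins_len = 0L)
  p$depth <- p$A + p$C + p$G + p$T + p$del
  calls <- call_sites(p, min_depth = 5)
  split_out <- discordance_split(calls)
  # brute force over the same call table
  naive <- list(mismatch = c(0L, 0L), gap = c(0L, 0L))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (row$class == "low-depth" || row$alt_count == 0) next
    key <- if (row$alt == "-") "gap" else "mismatch"
    naive[[key]][1] <- naive[[key]][1] + 1L
    if (row$ref_count == 0) naive[[key]][2] <- naive[[key]][2] + 1L
  }
  expect_equal(split_out$n_sites, c(naive$mismatch[1], naive$gap[1]))
  expect_equal(split_out$n_complete, c(naive$mismatch[2], naive$gap[2]))
  # hand case: one complete mismatch site of two mismatch sites
  hand <- dplyr::bind_rows(pileup_row("A", G = 8L, pos = 0L),
                           pileup_row("A", A = 4L, G = 4L, pos = 1L))
  hs <- discordance_split(call_sites(hand))
  expect_equal(hs$fraction[hs$type == "mismatch"], 0.5)
})

test_that("VCF-like output is 1-based with the expected columns", {
  p <- pileup_row("A", A = 5L, G = 5L, pos = 41L)
  calls <- call_sites(p)
  path <- tempfile(fileext = ".tsv")
  write_calls_tsv(calls, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("CHROM", "POS", "REF", "ALT", "DP", "AF", "CLASS"))
  expect_equal(back$POS, 42)
  unlink(path)
})
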