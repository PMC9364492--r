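#' Per-base depth profile of an alignment set
#'
#' Depth at a position counts the primary-mapped reads whose target-consuming
#' operations span it (deleted positions still count as spanned).  Depths are
#' capped at `cap` (200 by default, matching the convention of genome-coverage
#' counting tools).
#'
#' @param x An `alignment_set`; non-primary records are ignored.
#' @param cap Maximum reported depth.
#' @return Named list of integer vectors, one per target.
#' @export
depth_profile <- function(x, cap = 200L) {
  stopifnot(inherits(x, "alignment_set"))
  x <- filter_primary(x)
  lapply(setNames(nm = names(x$target_lengths)), function(tn) {
    L <- as.integer(x$target_lengths[[tn]])
    idx <- which(x$records$target == tn)
    if (!length(idx)) return(integer(L))
    inc <- tabulate(x$records$tstart[idx] + 1L, nbins = L)
    dec <- tabulate(x$records$tend[idx] + 1L, nbins = L)
    pmin(as.integer(cumsum(inc - dec)), as.integer(cap))
  })
}

#' Fraction of assembly positions covered at depth thresholds
#'
#' Fraction of non-N assembly positions with depth at least `t`, for each
#' threshold; non-increasing in `t` by construction.
#'
#' @param depth A [depth_profile()] list.
#' @param assembly Optional named character vector of assembly sequences; when
#'   supplied, N positions are excluded from the denominator.
#' @param thresholds Depth thresholds.
#' @return Tibble `threshold`, `covered_bases`, `eligible_bases`, `fraction`.
#' @export
coverage_at_thresholds <- function(depth, assembly = NULL,
                                   thresholds = c(1, 5, 10, 20)) {
  masks <- non_n_masks(depth, assembly)
  eligible <- sum(vapply(masks, sum, numeric(1)))
  purrr::map_dfr(thresholds, function(t) {
    covered <- sum(vapply(names(depth), function(tn) {
      sum(depth[[tn]] >= t & masks[[tn]])
    }, numeric(1)))
    tibble::tibble(threshold = t, covered_bases = covered,
                   eligible_bases = eligible,
                   fraction = if (eligible > 0) covered / eligible else NA_real_)
  })
}

non_n_masks <- function(depth, assembly) {
  lapply(setNames(nm = names(depth)), function(tn) {
    if (is.null(assembly)) rep(TRUE, length(depth[[tn]]))
    else dna_encode(assembly[[tn]]) >= 0L
  })
}

#' Uncovered-region (UCR) intervals
#'
#' Maximal intervals of zero-depth non-N positions, 0-based half-open.  The
#' union of the UCR and the covered intervals tiles the non-N assembly.
#'
#' @inheritParams coverage_at_thresholds
#' @return Tibble `target`, `start`, `end`.
#' @export
ucr_intervals <- function(depth, assembly = NULL) {
  masks <- non_n_masks(depth, assembly)
  purrr::map_dfr(names(depth), function(tn) {
    zero <- depth[[tn]] == 0L & masks[[tn]]
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    tibble::tibble(target = tn, start = starts[keep], end = ends[keep])
  })
}

#' Per-bin discordance statistics
#'
#' Splits each target into `bin_size` bp bins and tallies, from the pileup of
#' the supplied alignments: the aligned read bases consumed in the bin
#' (match + mismatch bases, attributed to the bin containing their target
#' position), the mismatched bases among them, and the gap length (deleted
#' reference positions in the bin plus insertion lengths attached to
#' positions in the bin).  `mismatch_rate` and `gap_rate` divide by the
#' aligned bases and are `NA` (flagged) for bins with none.  When an NGS
#' depth profile is supplied, `ucr_fraction` is the fraction of the bin's
#' non-N bases at zero depth.  Bases aligned over assembly N positions count
#' as aligned but never as mismatched (no reference to disagree with); the
#' final partial bin is kept and flagged.
#'
#' @param x An `alignment_set` of the reads whose discordance is being
#'   measured (e.g. raw long reads on an assembly).
#' @param target_seqs Named character vector of assembly sequences.
#' @param bin_size Bin width in bp.
#' @param ngs_depth Optional [depth_profile()] of mapped short reads, used to
#'   populate `ucr_fraction`.
#' @return Tibble of bins with the columns described above.
#' @export
bin_discordance <- function(x, target_seqs, bin_size = 100, ngs_depth = NULL) {
  stopifnot(inherits(x, "alignment_set"))
  if (bin_size <= 0) stop("`bin_size` must be positive")
  bin_size <- as.integer(bin_size)
  purrr::map_dfr(names(target_seqs), function(tn) {
    L <- nchar(target_seqs[[tn]])
    rc <- dna_encode(target_seqs[[tn]])
    idx <- which(x$records$target == tn)
    counts <- .pileup_counts_cpp(x$records$tstart[idx], x$codes[idx], L)
    base_cov <- colSums(counts[1:4, , drop = FALSE])
    ref_match <- numeric(L)
    ok <- rc >= 0L
    ref_match[ok] <- counts[cbind(rc[ok] + 1L, which(ok))]
    mism <- base_cov - ref_match
    mism[!ok] <- 0
    gap <- counts[5L, ]
    ins <- x$ins[x$ins$rec %in% idx, , drop = FALSE]
    if (nrow(ins)) {
      tab <- table(ins$tpos)
      gap[as.integer(names(tab)) + 1L] <- gap[as.integer(names(tab)) + 1L] +
        as.integer(tab)
    }
    bin <- (seq_len(L) - 1L) %/% bin_size
    ucr <- if (!is.null(ngs_depth)) {
      zero <- as.numeric(ngs_depth[[tn]] == 0L & ok)
      n_ok <- as.numeric(rowsum_by(as.numeric(ok), bin))
      z <- as.numeric(rowsum_by(zero, bin))
      ifelse(n_ok > 0, z / n_ok, NA_real_)
    } else NA_real_
    starts <- unique(bin) * bin_size
    aligned <- as.numeric(rowsum_by(base_cov, bin))
    out <- tibble::tibble(
      target = tn, start = starts, end = pmin(starts + bin_size, L),
      n_N = as.integer(rowsum_by(as.numeric(!ok), bin)),
      aligned_read_bases = aligned,
      mismatched_bases = as.numeric(rowsum_by(mism, bin)),
      gap_length = as.numeric(rowsum_by(gap, bin)),
      ucr_fraction = ucr)
    out$mismatch_rate <- ifelse(out$aligned_read_bases > 0,
                                out$mismatched_bases / out$aligned_read_bases,
                                NA_real_)
    out$gap_rate <- ifelse(out$aligned_read_bases > 0,
                           out$gap_length / out$aligned_read_bases, NA_real_)
    out$partial <- (out$end - out$start) < bin_size
    out
  })
}

rowsum_by <- function(v, g) {
  as.vector(rowsum(v, g, reorder = TRUE))
}

#' Classify bins into high-UCR and non-UCR
#'
#' A bin is high-UCR when strictly more than `threshold` of its bases are
#' uncovered by short reads.
#'
#' @param bins Tibble from [bin_discordance()] with `ucr_fraction` populated.
#' @param threshold UCR fraction above which a bin is high-UCR.
#' @return `bins` with an added `ucr_class` column
#'   (`"high-UCR"`/`"non-UCR"`).
#' @export
classify_high_ucr <- function(bins, threshold = 0.9) {
  bins$ucr_class <- ifelse(is.na(bins$ucr_fraction), NA_character_,
                           ifelse(bins$ucr_fraction > threshold,
                                  "high-UCR", "non-UCR"))
  bins
}

#' Correlation between assembly-truth divergence and UCR ratio
#'
#' Selects contiguous non-N assembly blocks of at least `block_min` bp, cuts
#' them into `bin` bp windows, and correlates per-window divergence (truth
#' diffs per non-N base) with per-window UCR ratio (zero-short-read-coverage
#' bases per window base), reporting Pearson's r and its t-based p-value.
#' Windows with constant divergence or UCR make the correlation undefined
#' and are flagged degenerate.
#'
#' @param diffs Tibble from [assembly_truth_diffs()] (or any per-position
#'   difference table with `target`, `pos`).
#' @param ucr UCR interval tibble from [ucr_intervals()].
#' @param assembly Named character vector of assembly sequences.
#' @param block_min Minimum block size in bp.
#' @param bin Window size in bp.
#' @return A `div_ucr_cor` object (supports [tidy()], [glance()],
#'   [autoplot()]); `$bins` holds the per-window table.
#' @export
divergence_ucr_correlation <- function(diffs, ucr, assembly,
                                       block_min = 200000, bin = 100000) {
  bins <- purrr::map_dfr(names(assembly), function(tn) {
    codes <- dna_encode(assembly[[tn]])
    ok <- codes >= 0L
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= block_min
    if (!any(keep)) return(NULL)
    ucr_mask <- logical(length(codes))
    uv <- ucr[ucr$target == tn, , drop = FALSE]
    for (k in seq_len(nrow(uv)))
      ucr_mask[(uv$start[k] + 1L):uv$end[k]] <- TRUE
    diff_mask <- logical(length(codes))
    dv <- diffs$pos[diffs$target == tn]
    diff_mask[dv + 1L] <- TRUE
    purrr::map2_dfr(starts[keep], ends[keep], function(bs, be) {
      ws <- seq.int(bs, be - 1L, by = bin)
      we <- pmin(ws + bin, be)
      tibble::tibble(
        target = tn, start = ws, end = we,
        n_diff = vapply(seq_along(ws), function(q)
          sum(diff_mask[(ws[q] + 1L):we[q]]), numeric(1)),
        non_n = vapply(seq_along(ws), function(q)
          sum(ok[(ws[q] + 1L):we[q]]), numeric(1)),
        ucr_bases = vapply(seq_along(ws), function(q)
          sum(ucr_mask[(ws[q] + 1L):we[q]]), numeric(1)))
    })
  })
  if (is.null(bins) || nrow(bins) < 3)
    stop("fewer than 3 usable windows; enlarge the assembly or shrink `bin`")
  bins$divergence <- ifelse(bins$non_n > 0, bins$n_diff / bins$non_n, NA_real_)
  bins$ucr_ratio <- bins$ucr_bases / (bins$end - bins$start)
  use <- !is.na(bins$divergence)
  degenerate <- stats::sd(bins$divergence[use]) == 0 ||
    stats::sd(bins$ucr_ratio[use]) == 0
  if (degenerate) {
    ht <- NULL
    est <- NA_real_
    pval <- NA_real_
    df <- sum(use) - 2L
  } else {
    ht <- cor.test(bins$divergence[use], bins$ucr_ratio[use],
                   method = "pearson")
    est <- unname(ht$estimate)
    pval <- ht$p.value
    df <- unname(ht$parameter)
  }
  structure(list(estimate = est, p.value = pval, df = df,
                 n_bins = sum(use), bin_size = bin, block_min = block_min,
                 degenerate = degenerate, bins = bins),
            class = "div_ucr_cor")
}

#' @export
print.div_ucr_cor <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<div_ucr_cor> degenerate (constant input) over %d windows\n",
                x$n_bins))
  } else {
    cat(sprintf("<div_ucr_cor> Pearson r = %.3f (p = %.3g) over %d windows of %s bp\n",
                x$estimate, x$p.value, x$n_bins,
                format(x$bin_size, big.mark = ",")))
  }
  invisible(x)
}

#' Table-1-shaped assembly summary
#'
#' Size, non-N size, short-read mapped rate, mean depth and coverage at the
#' standard thresholds for one assembly.
#'
#' @param assembly Named character vector of assembly sequences.
#' @param ngs_aln `alignment_set` of short reads mapped to this assembly.
#' @param n_reads_total Total short reads attempted (mapped + unmapped).
#' @param label Assembly label for the output row.
#' @return One-row tibble.
#' @export
summarize_assembly <- function(assembly, ngs_aln, n_reads_total,
                               label = "assembly") {
  depth <- depth_profile(ngs_aln)
  cov <- coverage_at_thresholds(depth, assembly)
  ucr <- ucr_intervals(depth, assembly)
  size <- sum(nchar(assembly))
  non_n <- cov$eligible_bases[1]
  tibble::tibble(
    assembly = label, size_bp = size, non_n_bp = non_n,
    ngs_mapped_rate = nrow(ngs_aln$records) / n_reads_total,
    mean_depth = sum(vapply(depth, function(d) sum(as.numeric(d)),
                            numeric(1))) / non_n,
    coverage_1x = cov$fraction[cov$threshold == 1],
    coverage_5x = cov$fraction[cov$threshold == 5],
    coverage_10x = cov$fraction[cov$threshold == 10],
    coverage_20x = cov$fraction[cov$threshold == 20],
    ucr_fraction = sum(ucr$end - ucr$start) / non_n)
}

#' Write UCR intervals as BED
#' @param ucr Tibble from [ucr_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ucr_bed <- function(ucr, path) {
  readr::write_tsv(ucr[, c("target", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write bin statistics as TSV
#' @param bins Tibble from [bin_discordance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins_tsv <- function(bins, path) {
  readr::write_tsv(bins, path)
  invisible(path)
}
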