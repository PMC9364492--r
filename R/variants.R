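#' Classify pileup sites from allele frequencies
#'
#' Implements the pileup-derived site classes: positions with depth below
#' `min_depth` are `low-depth`; positions where every covering read carries a
#' non-reference allele are `complete-discordance`; otherwise the allele
#' frequency AF of the leading (most frequent) non-reference allele --
#' deletion pseudo-allele included -- classifies the site as `heterozygous`
#' when `af_lo <= AF <= af_hi`, `homozygous-alt` when `AF > af_hi`, and
#' `homozygous-ref` below.  Insertions never create calls (they have no
#' reference position).  Reference-N positions are dropped.
#'
#' `af_mode = "summed"` uses the summed frequency of all non-reference
#' alleles instead of the leading one (sensitivity analysis).  `cd_rule =
#' "same-allele"` additionally requires all reads to agree on one allele for
#' a complete discordance; the default only requires that no read supports
#' the reference.
#'
#' @param pileup Tibble from [build_pileup()] (primary-only alignments).
#' @param min_depth Depth filter.
#' @param af_lo,af_hi Heterozygous AF window.
#' @param af_mode `"leading"` or `"summed"`.
#' @param cd_rule `"any-nonref"` or `"same-allele"`.
#' @return Tibble `target`, `pos`, `ref`, `depth`, `ref_count`, `alt`,
#'   `alt_count`, `af`, `class`.
#' @export
call_sites <- function(pileup, min_depth = 5, af_lo = 0.25, af_hi = 0.75,
                       af_mode = c("leading", "summed"),
                       cd_rule = c("any-nonref", "same-allele")) {
  af_mode <- match.arg(af_mode)
  cd_rule <- match.arg(cd_rule)
  p <- pileup[pileup$ref %in% c(.BASES, "-"), , drop = FALSE]
  counts <- as.matrix(p[, c("A", "C", "G", "T", "del")])
  ref_idx <- match(p$ref, c(.BASES, "-"))
  ref_count <- counts[cbind(seq_len(nrow(p)), ref_idx)]
  nonref <- counts
  nonref[cbind(seq_len(nrow(p)), ref_idx)] <- -1L
  lead_idx <- max.col(nonref, ties.method = "first")
  lead_count <- nonref[cbind(seq_len(nrow(p)), lead_idx)]
  lead_count[lead_count < 0L] <- 0L
  af <- if (af_mode == "leading") lead_count / p$depth
        else (p$depth - ref_count) / p$depth
  is_cd <- if (cd_rule == "any-nonref") ref_count == 0L
           else ref_count == 0L & lead_count == p$depth
  class <- dplyr::case_when(
    p$depth < min_depth ~ "low-depth",
    is_cd ~ "complete-discordance",
    af >= af_lo & af <= af_hi ~ "heterozygous",
    af > af_hi ~ "homozygous-alt",
    TRUE ~ "homozygous-ref")
  tibble::tibble(target = p$target, pos = p$pos, ref = p$ref,
                 depth = p$depth, ref_count = as.integer(ref_count),
                 alt = c(.BASES, "-")[lead_idx],
                 alt_count = as.integer(lead_count), af = af, class = class)
}

#' Genome heterozygosity from site calls
#'
#' Heterozygous calls divided by the depth-eligible positions.  By default
#' the denominator is the number of calls passing the depth filter (the
#' depth-eligible convention); supply `eligible` to use another denominator,
#' e.g. all assembly positions.
#'
#' @param calls Tibble from [call_sites()].
#' @param eligible Denominator; default `sum(calls$class != "low-depth")`.
#' @return Heterozygosity as a fraction.
#' @export
heterozygosity <- function(calls, eligible = NULL) {
  eligible <- eligible %||% sum(calls$class != "low-depth")
  if (eligible == 0) stop("no depth-eligible positions")
  sum(calls$class == "heterozygous") / eligible
}

#' Complete-discordance density within an interval set
#'
#' The number of complete-discordance calls falling inside the intervals
#' divided by the total interval length.  Computed from long-read or
#' CCS-like pileups, since UCR by definition has no short-read coverage.
#'
#' @param calls Tibble from [call_sites()].
#' @param intervals Interval tibble (`target`, `start`, `end`), e.g.
#'   [ucr_intervals()] output or its [complement_intervals()].
#' @return Fraction; `NA` (with a warning) when the intervals are empty.
#' @export
ucr_complete_discordance_fraction <- function(calls, intervals) {
  total <- sum(intervals$end - intervals$start)
  if (total == 0) {
    warning("empty interval set; fraction undefined")
    return(NA_real_)
  }
  cd <- calls[calls$class == "complete-discordance", , drop = FALSE]
  n_in <- sum(vapply(unique(intervals$target), function(tn) {
    iv <- intervals[intervals$target == tn, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    pos <- cd$pos[cd$target == tn]
    if (!length(pos) || !nrow(iv)) return(0L)
    k <- findInterval(pos, iv$start)
    sum(k >= 1L & pos < iv$end[pmax(k, 1L)])
  }, integer(1)))
  n_in / total
}

#' Fraction of discordant sites that are complete discordances, by type
#'
#' Among depth-eligible sites with any non-reference support, the fraction
#' where no read supports the reference, split by whether the leading
#' non-reference allele is a base (mismatch) or the deletion pseudo-allele
#' (gap).
#'
#' @param calls Tibble from [call_sites()].
#' @return Tibble `type` (mismatch, gap), `n_sites`, `n_complete`,
#'   `fraction` (`NA` when no sites of the type exist).
#' @export
discordance_split <- function(calls) {
  d <- calls[calls$class != "low-depth" & calls$alt_count > 0, , drop = FALSE]
  d$type <- ifelse(d$alt == "-", "gap", "mismatch")
  purrr::map_dfr(c("mismatch", "gap"), function(ty) {
    sub <- d[d$type == ty, , drop = FALSE]
    tibble::tibble(type = ty, n_sites = nrow(sub),
                   n_complete = sum(sub$ref_count == 0L),
                   fraction = if (nrow(sub)) sum(sub$ref_count == 0L) / nrow(sub)
                              else NA_real_)
  })
}

#' Write site calls as a VCF-like TSV
#'
#' Minimal columns CHROM, POS (1-based, VCF parity), REF, ALT, DP, AF,
#' CLASS.
#'
#' @param calls Tibble from [call_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(
    tibble::tibble(CHROM = calls$target, POS = calls$pos + 1L,
                   REF = calls$ref, ALT = calls$alt, DP = calls$depth,
                   AF = calls$af, CLASS = calls$class),
    path)
  invisible(path)
}
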