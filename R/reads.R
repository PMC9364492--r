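#' Per-base error profile for read simulation
#'
#' Rates are per template base: a base is deleted with probability
#' `deletion`, otherwise substituted with probability `mismatch`; an
#' independent length-1 insertion follows each base with probability
#' `insertion`.  Expected ledger fractions therefore equal the profile rates.
#'
#' @param mismatch,insertion,deletion Rates, each in `[0, 0.3]` with sum
#'   below 0.5.
#' @return An `error_profile` object.
#' @export
error_profile <- function(mismatch = 0, insertion = 0, deletion = 0) {
  vals <- c(mismatch = mismatch, insertion = insertion, deletion = deletion)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 0.3))
    stop("error rates must each be in [0, 0.3]")
  if (sum(vals) >= 0.5)
    stop("total error rate must be below 0.5")
  structure(as.list(vals), class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> mismatch %.4g, insertion %.4g, deletion %.4g\n",
              x$mismatch, x$insertion, x$deletion))
  invisible(x)
}

#' ONT-like error preset: 17.5 percent mismatch, 7.5 percent gap
#'
#' The gap rate is split evenly between insertions and deletions (3.75
#' percent each); the aggregate gap rate is what is empirically anchored.
#'
#' @return An [error_profile()].
#' @export
ont_profile <- function() error_profile(0.175, 0.0375, 0.0375)

new_read_set <- function(reads, ledger, het, profile, corrected = FALSE) {
  structure(list(reads = reads, ledger = ledger, het = het,
                 profile = profile, corrected = corrected),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set>%s %d reads, %s template bp, %d ledger error events\n",
              if (isTRUE(x$corrected)) " (corrected)" else "",
              nrow(x$reads), format(sum(x$reads$tpl_len), big.mark = ","),
              nrow(x$ledger)))
  invisible(x)
}

#' Read origin and sequence table
#' @param x A `read_set`.
#' @return Tibble with columns `id`, `subgenome`, `start`, `end`, `strand`,
#'   `tpl_len`, `seq` (sequence stored in forward genome orientation).
#' @export
read_info <- function(x) {
  stopifnot(inherits(x, "read_set"))
  x$reads
}

#' Per-base error ledger
#' @param x A `read_set`.
#' @return Tibble with one row per injected (or, for corrected reads,
#'   effective) error: `id`, `tpl_off` (0-based offset in the error-free
#'   template), `tpos` (genome position), `type`, `true_base`, `emitted_base`.
#' @export
error_ledger <- function(x) {
  stopifnot(inherits(x, "read_set"))
  x$ledger
}

#' Haplotype choices made at heterozygous sites
#' @param x A `read_set`.
#' @return Tibble `id`, `subgenome`, `pos`, `allele`.
#' @export
haplotype_choices <- function(x) {
  stopifnot(inherits(x, "read_set"))
  x$het
}

#' Simulate noisy long reads
#'
#' Reads are drawn uniformly from all subgenomes until the total template
#' length reaches `depth` times the total genome length.  Lengths follow a
#' truncated geometric distribution with the stated mean and minimum; reads
#' are clipped at the subgenome end.  Per-base errors are injected at the
#' profile rates and every event is recorded in the ledger, so the truth
#' needed for removed/retained/introduced accounting travels with the reads.
#' At heterozygous sites each read draws one allele of the pair with
#' probability 1/2.
#'
#' @param genome A [make_subgenomes()] genome.
#' @param depth Target fold-coverage of the whole genome (all subgenomes).
#' @param length_dist `c(mean, min)` read length in bp; mean must be >= 1 kb.
#' @param profile An [error_profile()]; default the ONT preset.
#' @param seed Integer seed.
#' @return A `read_set`.
#' @examples
#' g <- make_subgenomes(30000, divergence = 0, seed = 1)
#' r <- simulate_long_reads(g, depth = 2, profile = ont_profile(), seed = 1)
#' error_ledger_summary(r)
#' @export
simulate_long_reads <- function(genome, depth,
                                length_dist = c(mean = 10000, min = 1000),
                                profile = ont_profile(), seed = 42) {
  stopifnot(inherits(genome, "polyploid_genome"))
  if (!is.numeric(depth) || depth <= 0) stop("`depth` must be positive")
  mean_len <- as.integer(length_dist[[1]])
  min_len <- as.integer(length_dist[[2]])
  if (mean_len < 1000L) stop("mean read length must be at least 1 kb")
  set.seed(seed)
  origins <- draw_origins(genome, depth, function(nb) {
    min_len + rgeom(nb, 1 / (mean_len - min_len + 1))
  }, mean_len, prefix = "lr")
  het <- draw_haplotypes(origins, genome)
  emit_reads(origins, het, genome, profile, seed = seed)
}

#' Simulate accurate reads (CCS-like or NGS-like)
#'
#' Fixed-length (or uniform-in-range) single-end reads with mismatch-only
#' errors at `error_rate`.  Presets: CCS-like reads are 10-15 kb at error
#' 0.002; NGS-like reads are 150 bp at error 0.002 (see
#' [simulate_ccs_reads()], [simulate_ngs_reads()]).
#'
#' @inheritParams simulate_long_reads
#' @param read_len Read length in bp: a scalar, or a length-2 range for
#'   uniform sampling.
#' @param error_rate Per-base mismatch rate.
#' @param paired Must be `FALSE`: reads are modeled single-end (coverage, not
#'   pairing, defines the statistics here).
#' @return A `read_set`.
#' @export
simulate_accurate_reads <- function(genome, depth, read_len,
                                    error_rate = 0.002, paired = FALSE,
                                    seed = 42) {
  stopifnot(inherits(genome, "polyploid_genome"))
  if (!is.numeric(depth) || depth <= 0) stop("`depth` must be positive")
  if (isTRUE(paired))
    stop("paired simulation is not supported; reads are modeled single-end")
  read_len <- as.integer(read_len)
  if (any(read_len > genome$params$length))
    stop("`read_len` exceeds the subgenome length")
  if (any(read_len < 1L)) stop("`read_len` must be positive")
  profile <- error_profile(mismatch = error_rate)
  set.seed(seed)
  mean_len <- mean(read_len)
  origins <- draw_origins(genome, depth, function(nb) {
    if (length(read_len) == 1L) rep(read_len, nb)
    else sample(seq.int(read_len[1], read_len[2]), nb, replace = TRUE)
  }, mean_len, prefix = "ar")
  het <- draw_haplotypes(origins, genome)
  emit_reads(origins, het, genome, profile, seed = seed)
}

#' @rdname simulate_accurate_reads
#' @export
simulate_ccs_reads <- function(genome, depth = 20, seed = 42) {
  simulate_accurate_reads(genome, depth, read_len = c(10000L, 15000L),
                          error_rate = 0.002, seed = seed)
}

#' @rdname simulate_accurate_reads
#' @export
simulate_ngs_reads <- function(genome, depth = 20, seed = 42) {
  simulate_accurate_reads(genome, depth, read_len = 150L,
                          error_rate = 0.002, seed = seed)
}

# Draw read origins until total template bases >= depth * genome size.
# `len_fun(nb)` draws nb read lengths.  Uses the current RNG stream.
draw_origins <- function(genome, depth, len_fun, mean_len, prefix) {
  L <- genome$params$length
  subs <- names(genome$codes)
  total_target <- depth * L * length(subs)
  acc <- list()
  tot <- 0
  min_keep <- 50L
  while (tot < total_target) {
    nb <- max(100L, ceiling((total_target - tot) / mean_len))
    len <- len_fun(nb)
    sub <- sample(subs, nb, replace = TRUE)
    # reads may overhang either end and are clipped, so marginal coverage is
    # uniform along the genome (no edge ramp)
    start_raw <- as.integer(floor(runif(nb) * (L + len - 1)) - (len - 1L))
    start <- pmax(start_raw, 0L)
    end <- as.integer(pmin(start_raw + len, L))
    tpl_len <- end - start
    keep <- tpl_len >= pmin(min_keep, len)
    batch <- tibble::tibble(subgenome = sub[keep], start = start[keep],
                            end = end[keep], tpl_len = tpl_len[keep])
    acc[[length(acc) + 1L]] <- batch
    tot <- tot + sum(batch$tpl_len)
  }
  reads <- dplyr::bind_rows(acc)
  m <- which(cumsum(reads$tpl_len) >= total_target)[1L]
  reads <- reads[seq_len(m), , drop = FALSE]
  reads$strand <- sample(c("+", "-"), m, replace = TRUE)
  reads$id <- sprintf("%s%06d", prefix, seq_len(m))
  dplyr::relocate(reads, "id")
}

# 50/50 allele draw per (read, covered heterozygous site)
draw_haplotypes <- function(reads, genome) {
  empty <- tibble::tibble(id = character(), subgenome = character(),
                          pos = integer(), allele = character())
  het_sites <- genome$truth[genome$truth$class == "heterozygous", , drop = FALSE]
  if (!nrow(het_sites)) return(empty)
  out <- purrr::map_dfr(split(het_sites, het_sites$subgenome), function(hs) {
    sub <- hs$subgenome[1]
    ri <- which(reads$subgenome == sub)
    if (!length(ri)) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(hs$pos + 1L, hs$pos + 1L),
      IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri]))
    if (!length(hits)) return(NULL)
    si <- S4Vectors::queryHits(hits)
    rj <- S4Vectors::subjectHits(hits)
    pick_alt <- runif(length(si)) < 0.5
    tibble::tibble(id = reads$id[ri][rj], subgenome = sub, pos = hs$pos[si],
                   allele = ifelse(pick_alt, hs$alt_allele[si], hs$ref_allele[si]))
  })
  if (!nrow(out)) empty else dplyr::arrange(out, .data$id, .data$pos)
}

# Inject errors per read and build emitted sequences plus the ledger.
emit_reads <- function(origins, het, genome, profile, seed) {
  p_del <- profile$deletion
  p_mm <- profile$mismatch
  p_ins <- profile$insertion
  n <- nrow(origins)
  het_by_read <- split(het, factor(het$id, levels = origins$id))
  seqs <- character(n)
  led <- vector("list", n)
  for (i in seq_len(n)) {
    s <- origins$start[i]
    tpl <- genome$codes[[origins$subgenome[i]]][(s + 1L):origins$end[i]]
    hb <- het_by_read[[i]]
    if (!is.null(hb) && nrow(hb))
      tpl[hb$pos - s + 1L] <- match(hb$allele, .BASES) - 1L
    len <- length(tpl)
    if (p_del > 0 || p_mm > 0) {
      u <- runif(len)
      del <- u < p_del
      mm <- !del & u < p_del + p_mm
    } else {
      del <- mm <- logical(len)
    }
    ins_idx <- if (p_ins > 0) which(runif(len) < p_ins) else integer(0)
    emitted <- tpl
    mm_idx <- which(mm)
    if (length(mm_idx)) emitted[mm_idx] <- mutate_codes(tpl[mm_idx])
    ins_codes <- if (length(ins_idx)) sample(0:3, length(ins_idx), replace = TRUE)
                 else integer(0)
    if (any(del) || length(ins_idx)) {
      keep <- which(!del)
      ord <- order(c(keep - 1, ins_idx - 1 + 0.5))
      seqs[i] <- dna_decode(c(emitted[keep], ins_codes)[ord])
    } else {
      seqs[i] <- dna_decode(emitted)
    }
    del_idx <- which(del)
    led[[i]] <- tibble::tibble(
      tpl_off = c(mm_idx, ins_idx, del_idx) - 1L,
      type = rep(c("mismatch", "insertion", "deletion"),
                 c(length(mm_idx), length(ins_idx), length(del_idx))),
      true_base = c(.BASES[tpl[mm_idx] + 1L], rep(NA_character_, length(ins_idx)),
                    .BASES[tpl[del_idx] + 1L]),
      emitted_base = c(.BASES[emitted[mm_idx] + 1L], .BASES[ins_codes + 1L],
                       rep(NA_character_, length(del_idx))))
  }
  n_events <- vapply(led, nrow, integer(1))
  ledger <- dplyr::bind_rows(led)
  ledger$id <- rep(origins$id, n_events)
  ledger$tpos <- rep(origins$start, n_events) + ledger$tpl_off
  ledger <- dplyr::arrange(
    dplyr::relocate(ledger, "id"), .data$id, .data$tpl_off)
  origins$seq <- seqs
  new_read_set(origins, ledger, het, profile)
}

#' Tally the error ledger of a read set
#'
#' Exact counts over all ledgers divided by the total number of emitted
#' bases.
#'
#' @param x A `read_set`.
#' @return Tibble with columns `type` (mismatch, insertion, deletion), `n`,
#'   `fraction`.
#' @export
error_ledger_summary <- function(x) {
  stopifnot(inherits(x, "read_set"))
  n_emitted <- sum(nchar(x$reads$seq))
  counts <- table(factor(x$ledger$type,
                         levels = c("mismatch", "insertion", "deletion")))
  tibble::tibble(type = names(counts), n = as.integer(counts),
                 fraction = as.integer(counts) / n_emitted)
}

# Truth template codes (heterozygous alleles applied) per read, as a list of
# integer vectors aligned with read_info(x) rows.
read_template_codes <- function(x, genome) {
  het_by_read <- split(x$het, factor(x$het$id, levels = x$reads$id))
  purrr::map(seq_len(nrow(x$reads)), function(i) {
    s <- x$reads$start[i]
    tpl <- genome$codes[[x$reads$subgenome[i]]][(s + 1L):x$reads$end[i]]
    hb <- het_by_read[[i]]
    if (!is.null(hb) && nrow(hb))
      tpl[hb$pos - s + 1L] <- match(hb$allele, .BASES) - 1L
    tpl
  })
}

# Target-space emitted allele codes (0..4) per read, derived from the ledger,
# plus insertion events.  This is the exact alignment implied by the truth.
aligned_codes <- function(x, genome) {
  tpl <- read_template_codes(x, genome)
  led_by_read <- split(x$ledger, factor(x$ledger$id, levels = x$reads$id))
  codes <- vector("list", length(tpl))
  ins <- vector("list", length(tpl))
  for (i in seq_along(tpl)) {
    cv <- tpl[[i]]
    lb <- led_by_read[[i]]
    if (!is.null(lb) && nrow(lb)) {
      is_mm <- lb$type == "mismatch"
      if (any(is_mm))
        cv[lb$tpl_off[is_mm] + 1L] <- match(lb$emitted_base[is_mm], .BASES) - 1L
      is_del <- lb$type == "deletion"
      if (any(is_del)) cv[lb$tpl_off[is_del] + 1L] <- 4L
      is_ins <- lb$type == "insertion"
      if (any(is_ins)) {
        ins[[i]] <- tibble::tibble(
          rec = i, query_id = lb$id[is_ins], tpos = lb$tpos[is_ins],
          code = match(lb$emitted_base[is_ins], .BASES) - 1L)
      }
    }
    codes[[i]] <- cv
  }
  ins_tb <- dplyr::bind_rows(ins)
  if (!nrow(ins_tb))
    ins_tb <- tibble::tibble(rec = integer(), query_id = character(),
                             tpos = integer(), code = integer())
  list(codes = codes, ins = ins_tb)
}

#' Write reads as FASTQ
#'
#' Sequences are emitted in sequencing orientation (minus-strand reads are
#' reverse-complemented on output) with constant placeholder quality "I".
#'
#' @param x A `read_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(x, path) {
  stopifnot(inherits(x, "read_set"))
  out <- x$reads$seq
  neg <- x$reads$strand == "-"
  if (any(neg)) out[neg] <- vapply(out[neg], revcomp, character(1), USE.NAMES = FALSE)
  # written record-by-record: long-read records exceed the line-buffer limit
  # of the usual FASTQ serializers
  lines <- as.vector(rbind(paste0("@", x$reads$id), out,
                           "+", strrep("I", nchar(out))))
  writeLines(lines, path)
  invisible(path)
}

#' Write the error ledger as TSV
#' @inheritParams write_reads_fastq
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(x, path) {
  readr::write_tsv(error_ledger(x), path)
  invisible(path)
}

#' Write read origins (the oracle truth) as TSV
#' @inheritParams write_reads_fastq
#' @return `path`, invisibly.
#' @export
write_origins_tsv <- function(x, path) {
  readr::write_tsv(dplyr::select(read_info(x), "id", "subgenome", "start",
                                 "end", "strand"), path)
  invisible(path)
}
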