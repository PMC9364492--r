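new_alignment_set <- function(records, codes, ins, target_lengths,
                              unmapped = character(0)) {
  structure(list(records = records, codes = codes, ins = ins,
                 target_lengths = target_lengths, unmapped = unmapped),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d records on %d target(s)%s\n",
              nrow(x$records), length(x$target_lengths),
              if (length(x$unmapped))
                sprintf(", %d unmapped queries", length(x$unmapped)) else ""))
  invisible(x)
}

#' Alignment record table
#' @param x An `alignment_set`.
#' @return Tibble of records: `query_id`, `target`, `tstart`, `tend` (0-based
#'   half-open target span), `strand`, `is_primary`, `aligned_query_bases`.
#' @export
alignment_records <- function(x) {
  stopifnot(inherits(x, "alignment_set"))
  x$records
}

#' Place simulated reads on their targets using the simulation truth
#'
#' The alignment of a simulated read is fully determined by its origin and
#' error ledger, so no alignment search is needed: each ledger mismatch
#' becomes a mismatch operation, each deletion a deletion, each insertion an
#' insertion, and everything else a match.  Corrected reads carry an
#' effective ledger against the same origin, so they are placed at their
#' original origin even when correction moved their content toward the other
#' subgenome -- this is exactly the error-propagation channel under study.
#'
#' @param x A `read_set`.
#' @param genome The [make_subgenomes()] genome the reads came from.
#' @param target_seqs Optional named character vector of target sequences the
#'   reads are being placed on (defaults to the subgenome sequences).  Targets
#'   must be colinear with the subgenomes; names must cover the read origins.
#' @return An `alignment_set` (all records primary).
#' @export
oracle_place <- function(x, genome, target_seqs = NULL) {
  stopifnot(inherits(x, "read_set"), inherits(genome, "polyploid_genome"))
  if (is.null(target_seqs)) {
    target_lengths <- setNames(rep(genome$params$length, length(genome$codes)),
                               names(genome$codes))
  } else {
    target_lengths <- setNames(nchar(target_seqs), names(target_seqs))
  }
  missing_t <- setdiff(unique(x$reads$subgenome), names(target_lengths))
  if (length(missing_t))
    stop("read origins not on the supplied targets: ",
         paste(missing_t, collapse = ", "))
  if (any(x$reads$end > target_lengths[x$reads$subgenome]))
    stop("read span extends past the target end")
  ac <- aligned_codes(x, genome)
  n_ins <- vapply(split(ac$ins$rec, factor(ac$ins$rec, levels = seq_len(nrow(x$reads)))),
                  length, integer(1))
  n_del <- vapply(ac$codes, function(cv) sum(cv == 4L), integer(1))
  records <- tibble::tibble(
    query_id = x$reads$id, target = x$reads$subgenome,
    tstart = x$reads$start, tend = x$reads$end, strand = x$reads$strand,
    is_primary = TRUE,
    aligned_query_bases = x$reads$tpl_len - n_del + as.integer(n_ins))
  new_alignment_set(records, ac$codes, ac$ins, target_lengths)
}

#' Ordered operation list of an alignment record
#'
#' Expands a record into its run-length operation list (match, mismatch,
#' insertion, deletion) against the target sequence, in target order with
#' insertions attached after the target position they follow.
#'
#' @param x An `alignment_set`.
#' @param target_seqs Named character vector of target sequences.
#' @param which Record indices (default all).
#' @return Tibble `query_id`, `op`, `length`.
#' @export
alignment_operations <- function(x, target_seqs, which = NULL) {
  stopifnot(inherits(x, "alignment_set"))
  which <- which %||% seq_len(nrow(x$records))
  tcodes <- lapply(target_seqs, dna_encode)
  purrr::map_dfr(which, function(i) {
    rec <- x$records[i, ]
    cv <- x$codes[[i]]
    ref <- tcodes[[rec$target]][(rec$tstart + 1L):rec$tend]
    cls <- ifelse(cv == 4L, 4L, ifelse(cv == ref, 1L, 2L))  # 1=match 2=mism 4=del
    ins <- x$ins[x$ins$rec == i, , drop = FALSE]
    key <- c(seq_along(cls) - 1, ins$tpos - rec$tstart + 0.5)
    vals <- c(cls, rep(3L, nrow(ins)))                      # 3=insertion
    ord <- order(key)
    r <- rle(vals[ord])
    tibble::tibble(query_id = rec$query_id,
                   op = c("match", "mismatch", "insertion", "deletion")[r$values],
                   length = r$lengths)
  })
}

#' Map reads onto targets with a gapless seed-and-extend mapper
#'
#' A stand-in for a short-read aligner: every k-mer of the read is looked up
#' in an exact k-mer index of the targets, each candidate end-to-end gapless
#' placement is scored by mismatch count, and the read is mapped iff its best
#' placement has `mismatches / length <= max_mismatch_rate` (default 2
#' percent -- the empirical boundary below which mapped short reads fall).
#' Equal-scoring placements are resolved to the lowest target coordinate, and
#' only that placement is reported (primary).  Reads shorter than `k` are
#' unmapped.
#'
#' @param x A `read_set` or a character vector of read sequences (optionally
#'   named).
#' @param target_seqs Named character vector of target sequences (may contain
#'   N; k-mers and matches involving N never count as identical).
#' With `ties = "lowest"` (the default) equal-scoring placements are resolved
#' deterministically to the lowest target coordinate.  `ties = "random"`
#' instead picks uniformly among the equal-best placements (seeded through
#' the R RNG), which is how production short-read mappers place multireads
#' and is what coverage statistics over repetitive or homologous sequence
#' assume; the pipeline uses this mode.
#'
#' @param k Seed length.
#' @param max_mismatch_rate Acceptance threshold on mismatches/length.
#' @param ties `"lowest"` or `"random"` (see Details).
#' @return An `alignment_set`; queries with no acceptable placement are
#'   listed in its `unmapped` field.
#' @export
seed_extend_map <- function(x, target_seqs, k = 21, max_mismatch_rate = 0.02,
                            ties = c("lowest", "random")) {
  ties <- match.arg(ties)
  if (inherits(x, "read_set")) {
    seqs <- setNames(x$reads$seq, x$reads$id)
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- sprintf("q%06d", seq_along(seqs))
  }
  stopifnot(is.character(target_seqs), !is.null(names(target_seqs)))
  hit <- .seed_extend_cpp(unname(target_seqs), unname(seqs), as.integer(k),
                          max_mismatch_rate, ties == "random")
  mapped <- !is.na(hit$target)
  lens <- nchar(seqs)
  records <- tibble::tibble(
    query_id = names(seqs)[mapped],
    target = names(target_seqs)[hit$target[mapped]],
    tstart = hit$tstart[mapped],
    tend = hit$tstart[mapped] + lens[mapped],
    strand = "+",
    is_primary = TRUE,
    aligned_query_bases = as.integer(lens[mapped]),
    n_mismatch = hit$n_mismatch[mapped])
  codes <- lapply(seqs[mapped], dna_encode)
  names(codes) <- NULL
  new_alignment_set(records, codes,
                    tibble::tibble(rec = integer(), query_id = character(),
                                   tpos = integer(), code = integer()),
                    setNames(nchar(target_seqs), names(target_seqs)),
                    unmapped = names(seqs)[!mapped])
}

#' Keep only primary alignment records
#'
#' The in-memory analogue of dropping secondary/supplementary records by SAM
#' flag mask 0x900.
#'
#' @param x An `alignment_set`.
#' @return The filtered `alignment_set`.
#' @export
filter_primary <- function(x) {
  stopifnot(inherits(x, "alignment_set"))
  keep <- which(x$records$is_primary)
  subset_alignment(x, keep)
}

subset_alignment <- function(x, keep) {
  ins <- x$ins[x$ins$rec %in% keep, , drop = FALSE]
  ins$rec <- match(ins$rec, keep)
  new_alignment_set(x$records[keep, , drop = FALSE], x$codes[keep], ins,
                    x$target_lengths, x$unmapped)
}

#' Build a pileup from alignment records
#'
#' One row per covered target position, with per-allele read counts: the four
#' bases, a deletion pseudo-allele (each deleted position of a spanning read
#' contributes one deletion count), and the total inserted length attached to
#' the position (pileup convention: an insertion accrues to the preceding
#' consumed target position).  The allele counts (including deletions) sum to
#' the depth.
#'
#' @param x An `alignment_set` (use [filter_primary()] first when secondary
#'   records may be present).
#' @param target_seqs Named character vector of target sequences.
#' @return Tibble `target`, `pos` (0-based), `ref`, `depth`, `A`, `C`, `G`,
#'   `T`, `del`, `ins_len`.
#' @export
build_pileup <- function(x, target_seqs) {
  stopifnot(inherits(x, "alignment_set"))
  purrr::map_dfr(names(target_seqs), function(tn) {
    idx <- which(x$records$target == tn)
    L <- nchar(target_seqs[[tn]])
    if (!length(idx)) return(NULL)
    counts <- .pileup_counts_cpp(x$records$tstart[idx], x$codes[idx], L)
    depth <- colSums(counts)
    ins <- x$ins[x$ins$rec %in% idx, , drop = FALSE]
    ins_len <- integer(L)
    if (nrow(ins)) {
      tab <- table(ins$tpos)
      ins_len[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    covered <- which(depth > 0L | ins_len > 0L)
    ref <- strsplit(target_seqs[[tn]], "", fixed = TRUE)[[1]]
    tibble::tibble(target = tn, pos = covered - 1L, ref = ref[covered],
                   depth = as.integer(depth[covered]),
                   A = counts[1L, covered], C = counts[2L, covered],
                   G = counts[3L, covered], T = counts[4L, covered],
                   del = counts[5L, covered],
                   ins_len = ins_len[covered])
  })
}

#' Read alignments from SAM/BAM (real-data mode)
#'
#' Ingests a coordinate-sorted SAM or BAM file into an `alignment_set`.
#' CIGAR M/=/X runs are resolved against the reference sequence (M without an
#' MD tag is resolved by direct base comparison, which is exact here because
#' the reference is supplied); I and D map to insertion/deletion operations;
#' soft-clipped bases are ignored.  Records with flag bits 0x100 or 0x800 are
#' marked non-primary.
#'
#' @param path Path to a SAM or BAM file.
#' @param target_seqs Named character vector of reference sequences.
#' @return An `alignment_set`.
#' @export
read_alignments <- function(path, target_seqs) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("Rsamtools and GenomicAlignments are required to read SAM/BAM")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "seq", "flag")))
  mc <- S4Vectors::mcols(ga)
  n <- length(ga)
  df <- as.data.frame(ga)
  tname <- as.character(df$seqnames)
  tstart <- df$start - 1L
  cig_ops <- GenomicAlignments::explodeCigarOps(df$cigar)
  cig_len <- GenomicAlignments::explodeCigarOpLengths(df$cigar)
  seqs <- as.character(mc$seq)
  codes_l <- vector("list", n)
  ins_l <- vector("list", n)
  for (i in seq_len(n)) {
    q <- dna_encode(seqs[i])
    ops <- cig_ops[[i]]
    lens <- cig_len[[i]]
    cv <- integer(0)
    ins_pos <- integer(0)
    ins_code <- integer(0)
    qoff <- 0L
    tpos <- tstart[i]
    for (j in seq_along(ops)) {
      len <- lens[j]
      op <- ops[j]
      if (op %in% c("M", "=", "X")) {
        cv <- c(cv, q[(qoff + 1L):(qoff + len)])
        qoff <- qoff + len
        tpos <- tpos + len
      } else if (op %in% c("D", "N")) {
        cv <- c(cv, rep(4L, len))
        tpos <- tpos + len
      } else if (op == "I") {
        ins_pos <- c(ins_pos, rep(tpos - 1L, len))
        ins_code <- c(ins_code, q[(qoff + 1L):(qoff + len)])
        qoff <- qoff + len
      } else if (op == "S") {
        qoff <- qoff + len
      }
    }
    codes_l[[i]] <- cv
    if (length(ins_pos))
      ins_l[[i]] <- tibble::tibble(rec = i, query_id = mc$qname[i],
                                   tpos = ins_pos, code = ins_code)
  }
  ins_tb <- dplyr::bind_rows(ins_l)
  if (!nrow(ins_tb))
    ins_tb <- tibble::tibble(rec = integer(), query_id = character(),
                             tpos = integer(), code = integer())
  records <- tibble::tibble(
    query_id = as.character(mc$qname), target = tname, tstart = tstart,
    tend = tstart + vapply(codes_l, length, integer(1)),
    strand = ifelse(bitwAnd(mc$flag, 16L) > 0L, "-", "+"),
    is_primary = bitwAnd(mc$flag, 0x900L) == 0L,
    aligned_query_bases = vapply(seq_len(n), function(i) {
      sum(codes_l[[i]] != 4L) + sum(ins_tb$rec == i)
    }, integer(1)))
  new_alignment_set(records, codes_l, ins_tb,
                    setNames(nchar(target_seqs), names(target_seqs)))
}

#' Write an alignment set as SAM
#'
#' Minimal single-end SAM export (flag 0 for primary, 0x100 for secondary;
#' strand information is carried in the record table, sequences are emitted
#' in target orientation).  Match and mismatch runs are written as M.
#'
#' @param x An `alignment_set`.
#' @param target_seqs Named character vector of reference sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, target_seqs, path) {
  stopifnot(inherits(x, "alignment_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (tn in names(target_seqs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tn, nchar(target_seqs[[tn]])), con)
  ord <- order(match(x$records$target, names(target_seqs)), x$records$tstart)
  for (i in ord) {
    rec <- x$records[i, ]
    cv <- x$codes[[i]]
    ins <- x$ins[x$ins$rec == i, , drop = FALSE]
    # sequence and cigar in target order with insertions interleaved
    key <- c(seq_along(cv) - 1, ins$tpos - rec$tstart + 0.5)
    vals <- c(cv, ins$code)
    is_ins <- c(rep(FALSE, length(cv)), rep(TRUE, nrow(ins)))
    ord2 <- order(key)
    vals <- vals[ord2]
    is_ins <- is_ins[ord2]
    opc <- ifelse(is_ins, "I", ifelse(vals == 4L, "D", "M"))
    r <- rle(opc)
    cigar <- paste0(r$lengths, r$values, collapse = "")
    seq_out <- dna_decode(vals[vals != 4L | is_ins])
    flag <- if (rec$is_primary) 0L else 256L
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       rec$query_id, flag, rec$target, rec$tstart + 1L, cigar,
                       seq_out, strrep("I", nchar(seq_out))), con)
  }
  invisible(path)
}
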