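#' Find overlaps between long reads for self-correction
#'
#' In `truth` mode two reads overlap when their origin intervals -- projected
#' onto the shared coordinate system of the colinear subgenomes -- intersect
#' by at least `min_overlap` bases.  Because subgenome divergence is
#' substitution-only, positions align 1:1 across subgenomes and the
#' projection is the identity; a cross-subgenome overlap is accepted only
#' when the shared span includes at least `anchor_min` bases of conserved
#' blocks (the homologous anchor that makes chimeric clusters form in a real
#' all-vs-all aligner).  Setting `cross_subgenome = FALSE` gives the
#' counterfactual of a perfectly phasing-aware corrector: with truth-mode
#' overlaps, subgenome identity is the phase, so refusing cross-subgenome
#' edges is exactly a cluster split at divergent sites.
#'
#' In `anchor-kmer` mode (intended for small read sets) two reads overlap
#' when they share at least `t` exact k-mers on a consistent diagonal
#' (within a 100 bp band).
#'
#' @param x A `read_set`.
#' @param genome The genome the reads came from (supplies conserved blocks).
#' @param min_overlap Minimum shared bases.
#' @param mode `"truth"` or `"anchor-kmer"`.
#' @param cross_subgenome Allow cross-subgenome edges (truth mode)?
#' @param anchor_min Minimum conserved bases within a cross-subgenome shared
#'   span.
#' @param k,t Anchor k-mer length and count (anchor-kmer mode).
#' @return Edge tibble `id1`, `id2`, `offset` (start2 - start1), `overlap`,
#'   `cross` (one row per unordered pair).
#' @export
find_overlaps <- function(x, genome, min_overlap = 2000,
                          mode = c("truth", "anchor-kmer"),
                          cross_subgenome = TRUE, anchor_min = 500,
                          k = 15, t = 10) {
  stopifnot(inherits(x, "read_set"))
  mode <- match.arg(mode)
  if (mode == "anchor-kmer") {
    return(find_overlaps_kmer(x, k = k, t = t, min_kmers = t))
  }
  rd <- x$reads
  ir <- IRanges::IRanges(rd$start + 1L, rd$end)
  hits <- IRanges::findOverlaps(ir, minoverlap = as.integer(min_overlap),
                                drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  if (!length(i)) {
    return(tibble::tibble(id1 = character(), id2 = character(),
                          offset = integer(), overlap = integer(),
                          cross = logical()))
  }
  ov_start <- pmax(rd$start[i], rd$start[j])
  ov_end <- pmin(rd$end[i], rd$end[j])
  cross <- rd$subgenome[i] != rd$subgenome[j]
  keep <- !cross
  if (cross_subgenome && any(cross)) {
    cons_cum <- conserved_cumulative(genome)
    cons_in_span <- cons_cum[ov_end + 1L] - cons_cum[ov_start + 1L]
    keep <- keep | (cross & cons_in_span >= anchor_min)
  }
  tibble::tibble(id1 = rd$id[i][keep], id2 = rd$id[j][keep],
                 offset = (rd$start[j] - rd$start[i])[keep],
                 overlap = (ov_end - ov_start)[keep],
                 cross = cross[keep])
}

# cumulative count of conserved-block bases; element p+1 = conserved bases in [0, p)
conserved_cumulative <- function(genome) {
  L <- genome$params$length
  cons <- logical(L)
  cb <- genome$blocks[genome$blocks$class == "conserved", , drop = FALSE]
  for (r in seq_len(nrow(cb))) cons[(cb$start[r] + 1L):cb$end[r]] <- TRUE
  c(0L, cumsum(cons))
}

# anchor-kmer overlap detection on emitted sequences (small sets)
find_overlaps_kmer <- function(x, k, t, min_kmers, band = 100L) {
  rd <- x$reads
  km <- purrr::map_dfr(seq_len(nrow(rd)), function(i) {
    s <- rd$seq[i]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    tibble::tibble(read = i, qoff = seq_len(n) - 1L,
                   kmer = substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
  pairs <- dplyr::inner_join(km, km, by = "kmer", relationship = "many-to-many",
                             suffix = c("1", "2"))
  pairs <- pairs[pairs$read1 < pairs$read2, , drop = FALSE]
  if (!nrow(pairs)) {
    return(tibble::tibble(id1 = character(), id2 = character(),
                          offset = integer(), overlap = integer(),
                          cross = logical()))
  }
  pairs$diag <- pairs$qoff2 - pairs$qoff1
  out <- pairs |>
    dplyr::group_by(.data$read1, .data$read2) |>
    dplyr::summarise(n_banded = max_banded_count(.data$diag, band),
                     offset = as.integer(stats::median(.data$diag)),
                     .groups = "drop") |>
    dplyr::filter(.data$n_banded >= t)
  tibble::tibble(id1 = rd$id[out$read1], id2 = rd$id[out$read2],
                 offset = -out$offset,
                 overlap = NA_integer_,
                 cross = rd$subgenome[out$read1] != rd$subgenome[out$read2])
}

# largest number of values within any window of width `band`
max_banded_count <- function(v, band) {
  v <- sort(v)
  max(vapply(seq_along(v), function(a) {
    sum(v <= v[a] + band) - a + 1L
  }, integer(1)))
}

#' Correct reads by column-wise majority vote over their overlap clusters
#'
#' For each read (the cluster target), every overlapping read votes at each
#' target column with its allele there (a base, or the deletion
#' pseudo-allele).  Columns with at least `min_support` votes adopt the
#' plurality allele; ties and under-supported columns keep the target's
#' original allele.  An insertion survives (or is adopted) at a junction only
#' when a strict majority of covering members carries one.  The corrected
#' read keeps its origin metadata, and its ledger is recomputed as the
#' *effective* errors against the haplotype-resolved truth, so downstream
#' accounting and placement work exactly as for raw reads.
#'
#' @param x A `read_set`.
#' @param genome The source genome.
#' @param overlaps Edge tibble from [find_overlaps()]; computed with defaults
#'   when `NULL`.
#' @param min_support Minimum votes for a column to be corrected.
#' @param ... Passed to [find_overlaps()] when `overlaps` is `NULL`.
#' @return A corrected `read_set`.
#' @export
correct_reads <- function(x, genome, overlaps = NULL, min_support = 3, ...) {
  stopifnot(inherits(x, "read_set"))
  if (is.null(overlaps)) overlaps <- find_overlaps(x, genome, ...)
  rd <- x$reads
  n <- nrow(rd)
  idx <- setNames(seq_len(n), rd$id)
  e1 <- idx[overlaps$id1]
  e2 <- idx[overlaps$id2]
  members <- lapply(seq_len(n), function(i) i)
  if (length(e1)) {
    adj <- split(c(e2, e1), c(e1, e2))
    for (nm in names(adj))
      members[[as.integer(nm)]] <- c(as.integer(nm), unname(adj[[nm]]))
  }
  ac <- aligned_codes(x, genome)
  ins_by_rec <- split(ac$ins, factor(ac$ins$rec, levels = seq_len(n)))
  ins_pos <- lapply(ins_by_rec, function(d) if (is.null(d)) integer(0) else d$tpos)
  ins_code <- lapply(ins_by_rec, function(d) if (is.null(d)) integer(0) else d$code)
  res <- .correct_reads_cpp(rd$start, ac$codes, ins_pos, ins_code, members,
                            as.integer(min_support))
  rebuild_read_set(x, genome, res$codes, res$ins_pos, res$ins_code)
}

# Build a read_set from corrected target-space codes: new emitted sequences
# plus the effective ledger relative to the haplotype truth.
rebuild_read_set <- function(x, genome, codes, ins_pos, ins_code) {
  tpl <- read_template_codes(x, genome)
  n <- nrow(x$reads)
  seqs <- character(n)
  led <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- codes[[i]]
    tv <- tpl[[i]]
    s <- x$reads$start[i]
    ip <- ins_pos[[i]]
    ic <- ins_code[[i]]
    if (length(ip)) {
      keep <- which(cv != 4L)
      ord <- order(c(keep - 1, ip - s + 0.5))
      seqs[i] <- dna_decode(c(cv[keep], ic)[ord])
    } else {
      seqs[i] <- dna_decode(cv[cv != 4L])
    }
    mm_idx <- which(cv != tv & cv != 4L)
    del_idx <- which(cv == 4L)
    led[[i]] <- tibble::tibble(
      tpl_off = c(mm_idx - 1L, ip - s, del_idx - 1L),
      type = rep(c("mismatch", "insertion", "deletion"),
                 c(length(mm_idx), length(ip), length(del_idx))),
      true_base = c(.BASES[tv[mm_idx] + 1L], rep(NA_character_, length(ip)),
                    .BASES[tv[del_idx] + 1L]),
      emitted_base = c(.BASES[cv[mm_idx] + 1L], .BASES[ic + 1L],
                       rep(NA_character_, length(del_idx))))
  }
  n_events <- vapply(led, nrow, integer(1))
  ledger <- dplyr::bind_rows(led)
  ledger$id <- rep(x$reads$id, n_events)
  ledger$tpos <- rep(x$reads$start, n_events) + ledger$tpl_off
  ledger <- dplyr::arrange(dplyr::relocate(ledger, "id"),
                           .data$id, .data$tpl_off)
  reads <- x$reads
  reads$seq <- seqs
  new_read_set(reads, ledger, x$het, x$profile, corrected = TRUE)
}

#' Account for removed, retained and introduced errors after correction
#'
#' Compares each raw/corrected read pair against the haplotype-resolved truth
#' of its origin.  Per position: a raw error that the corrected read no
#' longer carries is *removed*; one it still carries is *retained* (counted
#' by the raw error's type); a position that was correct in the raw read but
#' wrong after correction is *introduced* (counted by the corrected state's
#' type).  Insertion junctions are handled the same way.  The identity
#' `removed + retained = raw error count` holds exactly on every run.
#'
#' @param raw,corrected Paired `read_set`s (same reads, same order).
#' @param genome The source genome.
#' @return A `correction_account`: summary counts by type, the genome
#'   positions of introduced errors (for joining against [truth_table()]),
#'   and totals.
#' @export
correction_accounting <- function(raw, corrected, genome) {
  stopifnot(inherits(raw, "read_set"), inherits(corrected, "read_set"))
  if (!identical(raw$reads$id, corrected$reads$id))
    stop("raw and corrected read sets are not paired (ids differ)")
  tpl <- read_template_codes(raw, genome)
  raw_ac <- aligned_codes(raw, genome)
  cor_ac <- aligned_codes(corrected, genome)
  counts <- matrix(0, nrow = 2, ncol = 3,
                   dimnames = list(c("mismatch", "gap"),
                                   c("removed", "retained", "introduced")))
  intro <- vector("list", nrow(raw$reads))
  raw_ins_by <- split(raw_ac$ins$tpos, factor(raw_ac$ins$rec,
                                              levels = seq_along(tpl)))
  cor_ins_by <- split(cor_ac$ins$tpos, factor(cor_ac$ins$rec,
                                              levels = seq_along(tpl)))
  for (i in seq_along(tpl)) {
    tv <- tpl[[i]]
    rv <- raw_ac$codes[[i]]
    cv <- cor_ac$codes[[i]]
    s <- raw$reads$start[i]
    raw_err <- rv != tv
    cor_err <- cv != tv
    raw_gap <- rv == 4L
    counts["mismatch", "removed"] <- counts["mismatch", "removed"] +
      sum(raw_err & !raw_gap & !cor_err)
    counts["gap", "removed"] <- counts["gap", "removed"] +
      sum(raw_gap & !cor_err)
    counts["mismatch", "retained"] <- counts["mismatch", "retained"] +
      sum(raw_err & !raw_gap & cor_err)
    counts["gap", "retained"] <- counts["gap", "retained"] +
      sum(raw_gap & cor_err)
    intro_idx <- which(!raw_err & cor_err)
    if (length(intro_idx)) {
      counts["mismatch", "introduced"] <- counts["mismatch", "introduced"] +
        sum(cv[intro_idx] != 4L)
      counts["gap", "introduced"] <- counts["gap", "introduced"] +
        sum(cv[intro_idx] == 4L)
      intro[[i]] <- tibble::tibble(
        id = raw$reads$id[i], subgenome = raw$reads$subgenome[i],
        pos = s + intro_idx - 1L,
        type = ifelse(cv[intro_idx] == 4L, "gap", "mismatch"))
    }
    # insertion junctions
    rip <- raw_ins_by[[i]] %||% integer(0)
    cip <- cor_ins_by[[i]] %||% integer(0)
    counts["gap", "removed"] <- counts["gap", "removed"] +
      length(setdiff(rip, cip))
    counts["gap", "retained"] <- counts["gap", "retained"] +
      length(intersect(rip, cip))
    new_ins <- setdiff(cip, rip)
    if (length(new_ins)) {
      counts["gap", "introduced"] <- counts["gap", "introduced"] +
        length(new_ins)
      intro[[i]] <- dplyr::bind_rows(
        intro[[i]],
        tibble::tibble(id = raw$reads$id[i],
                       subgenome = raw$reads$subgenome[i],
                       pos = as.integer(new_ins), type = "gap"))
    }
  }
  introduced_sites <- dplyr::bind_rows(intro)
  if (!nrow(introduced_sites))
    introduced_sites <- tibble::tibble(id = character(), subgenome = character(),
                                       pos = integer(), type = character())
  structure(list(
    summary = tibble::tibble(type = rownames(counts),
                             removed = counts[, "removed"],
                             retained = counts[, "retained"],
                             introduced = counts[, "introduced"]),
    introduced_sites = introduced_sites,
    raw_error_count = nrow(raw$ledger),
    corrected_error_count = nrow(corrected$ledger),
    template_bases = sum(raw$reads$tpl_len),
    n_reads = nrow(raw$reads)),
    class = "correction_account")
}

#' @export
print.correction_account <- function(x, ...) {
  cat(sprintf("<correction_account> %d reads, %s template bp\n", x$n_reads,
              format(x$template_bases, big.mark = ",")))
  print(x$summary)
  g <- glance(x)
  cat(sprintf("  removed fraction %.3f, introduced per base %.3g\n",
              g$removed_fraction, g$introduced_rate))
  invisible(x)
}

#' Write a correction account as JSON
#' @param x A `correction_account`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_account_json <- function(x, path) {
  stopifnot(inherits(x, "correction_account"))
  jsonlite::write_json(
    list(summary = x$summary, raw_error_count = x$raw_error_count,
         corrected_error_count = x$corrected_error_count,
         template_bases = x$template_bases, n_reads = x$n_reads),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write an overlap graph as TSV
#' @param overlaps Edge tibble from [find_overlaps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlaps_tsv <- function(overlaps, path) {
  readr::write_tsv(overlaps, path)
  invisible(path)
}
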