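# Independent brute-force oracles and small fixture builders.  Everything
# here recomputes quantities from first principles (per-base loops, all-pairs
# enumeration, closed forms) so the implementation under test is never on
# both sides of an assertion.

# 5 x L allele-count matrix by per-base loop over records of one target
naive_allele_counts <- function(aln, target, target_len) {
  counts <- matrix(0L, 5L, target_len)
  for (i in which(aln$records$target == target)) {
    cv <- aln$codes[[i]]
    s <- aln$records$tstart[i]
    for (j in seq_along(cv)) {
      counts[cv[j] + 1L, s + j] <- counts[cv[j] + 1L, s + j] + 1L
    }
  }
  counts
}

# depth by interval stabbing
naive_depth <- function(records, target, target_len) {
  d <- integer(target_len)
  for (i in which(records$target == target)) {
    span <- (records$tstart[i] + 1L):records$tend[i]
    d[span] <- d[span] + 1L
  }
  d
}

# all-offset, all-target gapless mapping: best = fewest mismatches, ties to
# lowest target then lowest offset; NULL when no placement passes
naive_map <- function(read, targets, max_mm_rate = 0.02) {
  rb <- strsplit(read, "")[[1]]
  len <- length(rb)
  best <- NULL
  for (ti in seq_along(targets)) {
    tb <- strsplit(targets[[ti]], "")[[1]]
    L <- length(tb)
    if (L < len) next
    for (off in 0:(L - len)) {
      seg <- tb[(off + 1L):(off + len)]
      mm <- sum(seg != rb | seg == "N")
      if (mm <= max_mm_rate * len + 1e-9 &&
          (is.null(best) || mm < best$mm)) {
        best <- list(ti = ti, off = off, mm = mm)
      }
    }
  }
  best
}

# all-pairs interval overlap with conserved-anchor rule
naive_overlaps <- function(x, genome, min_overlap, anchor_min = 500) {
  rd <- x$reads
  cons <- logical(genome$params$length)
  cb <- genome$blocks[genome$blocks$class == "conserved", ]
  for (r in seq_len(nrow(cb))) cons[(cb$start[r] + 1L):cb$end[r]] <- TRUE
  out <- list()
  n <- nrow(rd)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- max(rd$start[i], rd$start[j])
      e <- min(rd$end[i], rd$end[j])
      if (e - s < min_overlap) next
      if (rd$subgenome[i] != rd$subgenome[j] &&
          sum(cons[(s + 1L):e]) < anchor_min) next
      out[[length(out) + 1L]] <- sort(c(rd$id[i], rd$id[j]))
    }
  }
  out
}

edge_key_set <- function(edges) {
  sort(vapply(seq_len(nrow(edges)), function(k) {
    paste(sort(c(edges$id1[k], edges$id2[k])), collapse = "|")
  }, character(1)))
}

# closed-form Pearson correlation
naive_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# undo the ledger edits of one read: rebuild the haplotype template from the
# emitted sequence
reverse_ledger <- function(seq, led, tpl_len) {
  em <- strsplit(seq, "")[[1]]
  del <- led$tpl_off[led$type == "deletion"]
  ins <- led$tpl_off[led$type == "insertion"]
  out <- character(tpl_len)
  ei <- 1L
  for (o in 0:(tpl_len - 1L)) {
    if (o %in% del) {
      out[o + 1L] <- NA_character_
    } else {
      out[o + 1L] <- em[ei]
      ei <- ei + 1L
    }
    ei <- ei + sum(ins == o)
  }
  mm <- led[led$type == "mismatch", ]
  out[mm$tpl_off + 1L] <- mm$true_base
  dl <- led[led$type == "deletion", ]
  out[dl$tpl_off + 1L] <- dl$true_base
  paste(out, collapse = "")
}

# haplotype-resolved template of read i as a string
read_truth_seq <- function(x, genome, i) {
  s <- x$reads$start[i]
  cv <- genome$codes[[x$reads$subgenome[i]]][(s + 1L):x$reads$end[i]]
  hb <- x$het[x$het$id == x$reads$id[i], ]
  if (nrow(hb)) cv[hb$pos - s + 1L] <- match(hb$allele, c("A", "C", "G", "T")) - 1L
  paste(c("A", "C", "G", "T")[cv + 1L], collapse = "")
}

small_tetraploid <- function(length = 30000, divergence = 0.05, seed = 11) {
  blk <- max(500L, as.integer(length %/% 6))
  make_subgenomes(length, divergence, block_model = c(blk, blk), seed = seed)
}
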