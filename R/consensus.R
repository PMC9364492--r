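#' Coordinate-preserving consensus assembly from reads
#'
#' Builds one pseudo-assembly sequence per subgenome by placing every read at
#' its original origin (see [oracle_place()]) and emitting, per position, the
#' plurality base over the covering reads (ties resolved to the first base in
#' reference order A<C<G<T; deletion votes carry no emittable base).
#' Zero-coverage positions emit N.  The assembly stays colinear with the
#' truth, so every downstream statistic can be joined back to the truth
#' table -- the phenomenon under study lives in base-level error density, not
#' contig topology.
#'
#' Corrected reads are placed at their original origin even when correction
#' moved their content toward the other subgenome; that is the channel
#' through which chimeric-cluster errors reach the assembly.
#'
#' @param x A `read_set` (raw or corrected).
#' @param genome The source genome.
#' @return Named character vector of assembly sequences (one per subgenome).
#' @export
consensus_assembly <- function(x, genome) {
  stopifnot(inherits(x, "read_set"))
  if (!nrow(x$reads)) stop("empty read set")
  ac <- aligned_codes(x, genome)
  L <- genome$params$length
  out <- vapply(names(genome$codes), function(sub) {
    idx <- which(x$reads$subgenome == sub)
    if (!length(idx)) return(strrep("N", L))
    counts <- .pileup_counts_cpp(x$reads$start[idx], ac$codes[idx], L)
    dna_decode(.consensus_call_cpp(counts))
  }, character(1))
  setNames(out, names(genome$codes))
}

#' Polish an assembly by per-position plurality re-vote
#'
#' Places the polishing read set on the assembly (reads and assembly share
#' the truth coordinate system) and replaces each position covered by at
#' least one base vote with the plurality base of the polishing reads; N and
#' uncovered positions are left untouched.  Re-polishing with the same read
#' set is idempotent.
#'
#' @param assembly Named character vector from [consensus_assembly()].
#' @param x The polishing `read_set` (e.g. CCS-like reads).
#' @param genome The source genome (supplies read origins).
#' @param rounds Number of polishing rounds.
#' @return The polished assembly (named character vector).
#' @export
polish <- function(assembly, x, genome, rounds = 1) {
  stopifnot(inherits(x, "read_set"))
  ac <- aligned_codes(x, genome)
  for (r in seq_len(rounds)) {
    assembly <- setNames(vapply(names(assembly), function(sub) {
      old <- dna_encode(assembly[[sub]])
      idx <- which(x$reads$subgenome == sub)
      if (!length(idx)) return(assembly[[sub]])
      counts <- .pileup_counts_cpp(x$reads$start[idx], ac$codes[idx],
                                   length(old))
      voted <- .consensus_call_cpp(counts)
      keep <- voted < 0L
      voted[keep] <- old[keep]
      dna_decode(voted)
    }, character(1)), names(assembly))
  }
  assembly
}

#' Per-position differences between an assembly and the genome truth
#'
#' Positions where the assembly carries a base (not N) different from the
#' subgenome truth sequence.  These are the assembly's residual errors;
#' joining them to [truth_table()] shows where they sit relative to
#' subgenome-divergent sites.
#'
#' @param assembly Named character vector of assembly sequences.
#' @param genome The source genome.
#' @return Tibble `target`, `pos` (0-based), `assembly_base`, `truth_base`.
#' @export
assembly_truth_diffs <- function(assembly, genome) {
  purrr::map_dfr(names(assembly), function(sub) {
    av <- dna_encode(assembly[[sub]])
    tv <- genome$codes[[sub]]
    stopifnot(length(av) == length(tv))
    d <- which(av != tv & av >= 0L)
    tibble::tibble(target = sub, pos = d - 1L,
                   assembly_base = .BASES[av[d] + 1L],
                   truth_base = .BASES[tv[d] + 1L])
  })
}

#' Write an assembly as FASTA
#' @param assembly Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(assembly), path,
                              width = 80L)
  invisible(path)
}

#' Read an assembly (or any FASTA) as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_assembly_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}
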