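#' Generate subgenomes with block-structured divergence
#'
#' Builds an allotetraploid model genome: two subgenomes ("A" and "B") of
#' equal length whose sequence alternates between conserved blocks (identical
#' between subgenomes) and divergent blocks, where subgenome B differs from
#' subgenome A by substitutions placed uniformly at random at the requested
#' per-base rate.  With `n_subgenomes = 1` a diploid control genome (single
#' subgenome, no divergence) is produced.  Every difference is recorded in an
#' exhaustive truth table so that downstream error accounting can be joined
#' back to site classes.
#'
#' All coordinates in the package are 0-based, half-open.  Divergence is
#' substitution-only: the two subgenomes stay colinear base-for-base, which
#' keeps every downstream coordinate joinable to the truth.
#'
#' @param length Subgenome length in bp.
#' @param divergence Per-base substitution rate inside divergent blocks
#'   (the ~5 percent local divergence regime of homoeologous regions).
#'   Must be in `[0, 0.25]`.
#' @param block_model Numeric vector of two block lengths in bp,
#'   `c(conserved = ..., divergent = ...)`; blocks alternate deterministically
#'   along the genome starting with a conserved block.
#' @param n_subgenomes 2 (allotetraploid) or 1 (diploid control).
#' @param seed Integer seed; the genome is fully deterministic given it.
#' @return An object of class `polyploid_genome`.
#' @seealso [add_heterozygosity()], [truth_table()], [subgenome_seq()]
#' @examples
#' g <- make_subgenomes(40000, divergence = 0.05,
#'                      block_model = c(conserved = 5000, divergent = 5000),
#'                      seed = 1)
#' g
#' @export
make_subgenomes <- function(length, divergence = 0.05,
                            block_model = c(conserved = 5000, divergent = 5000),
                            n_subgenomes = 2, seed = 42) {
  length <- as.integer(length)
  if (base::length(block_model) != 2L)
    stop("`block_model` must give two block lengths (conserved, divergent)")
  conserved_len <- as.integer(block_model[[1]])
  divergent_len <- as.integer(block_model[[2]])
  if (!n_subgenomes %in% c(1L, 2L))
    stop("`n_subgenomes` must be 1 (diploid control) or 2 (allotetraploid)")
  if (is.na(divergence) || divergence < 0 || divergence > 0.25)
    stop("`divergence` must be in [0, 0.25]; beyond that the substitution-only model breaks down")
  if (length < 2L * (conserved_len + divergent_len))
    stop("`length` must cover at least two full conserved+divergent block cycles")

  set.seed(seed)
  blocks <- block_map(length, conserved_len, divergent_len)
  codes_a <- sample(0:3, length, replace = TRUE)

  truth <- empty_truth()
  if (n_subgenomes == 2L) {
    codes_b <- codes_a
    div_blocks <- blocks[blocks$class == "divergent", , drop = FALSE]
    div_positions <- unlist(purrr::map2(div_blocks$start, div_blocks$end,
                                        function(s, e) seq.int(s, e - 1L)))
    hit <- div_positions[runif(base::length(div_positions)) < divergence]
    if (base::length(hit)) {
      alt <- mutate_codes(codes_a[hit + 1L])
      codes_b[hit + 1L] <- alt
      truth <- tibble::tibble(
        subgenome = "A", pos = as.integer(hit), class = "divergent",
        ref_allele = .BASES[codes_a[hit + 1L] + 1L],
        alt_allele = .BASES[alt + 1L])
    }
    codes <- list(A = codes_a, B = codes_b)
  } else {
    codes <- list(A = codes_a)
  }

  new_polyploid_genome(
    codes, blocks, truth,
    params = list(length = length, divergence = divergence,
                  heterozygosity = 0,
                  conserved_len = conserved_len, divergent_len = divergent_len,
                  n_subgenomes = as.integer(n_subgenomes), seed = seed))
}

new_polyploid_genome <- function(codes, blocks, truth, params) {
  structure(list(codes = codes, blocks = blocks,
                 truth = dplyr::arrange(truth, .data$subgenome, .data$pos),
                 params = params),
            class = "polyploid_genome")
}

empty_truth <- function() {
  tibble::tibble(subgenome = character(), pos = integer(), class = character(),
                 ref_allele = character(), alt_allele = character())
}

block_map <- function(length, conserved_len, divergent_len) {
  cycle <- conserved_len + divergent_len
  cycle_starts <- seq.int(0L, length - 1L, by = cycle)
  starts <- as.vector(rbind(cycle_starts, cycle_starts + conserved_len))
  ends <- pmin(c(starts[-1L], Inf), length)
  keep <- starts < length & ends > starts
  tibble::tibble(start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]),
                 class = rep(c("conserved", "divergent"),
                             length.out = base::length(starts))[keep])
}

#' Add within-subgenome heterozygosity
#'
#' Assigns a diploid allele pair to randomly chosen positions of each
#' subgenome at per-base rate `h`.  Heterozygous positions are drawn from
#' sites that are not subgenome-divergent (collisions are re-drawn), so the
#' heterozygous and divergent truth-site sets are disjoint.  Read simulation
#' later draws each read's allele from the pair with probability 1/2.
#'
#' @param genome A [make_subgenomes()] genome.
#' @param h Heterozygosity rate in `[0, 0.01]` (the study regime is 0.0022,
#'   i.e. 0.22 percent).
#' @param seed Integer seed.
#' @return The genome with heterozygous truth sites added.
#' @export
add_heterozygosity <- function(genome, h, seed = 42) {
  stopifnot(inherits(genome, "polyploid_genome"))
  if (is.na(h) || h < 0 || h > 0.01)
    stop("`h` must be in [0, 0.01]")
  if (h == 0) return(genome)
  set.seed(seed)
  L <- genome$params$length
  new_rows <- purrr::map_dfr(names(genome$codes), function(sub) {
    taken <- divergent_positions(genome)
    taken <- c(taken, genome$truth$pos[genome$truth$subgenome == sub &
                                         genome$truth$class == "heterozygous"])
    n_het <- rbinom(1L, L, h)
    candidates <- setdiff(seq.int(0L, L - 1L), taken)
    pos <- sort(sample(candidates, min(n_het, base::length(candidates))))
    ref <- genome$codes[[sub]][pos + 1L]
    tibble::tibble(subgenome = sub, pos = as.integer(pos),
                   class = "heterozygous",
                   ref_allele = .BASES[ref + 1L],
                   alt_allele = .BASES[mutate_codes(ref) + 1L])
  })
  genome$truth <- dplyr::arrange(dplyr::bind_rows(genome$truth, new_rows),
                                 .data$subgenome, .data$pos)
  genome$params$heterozygosity <- h
  genome
}

# positions (0-based) where the subgenomes differ
divergent_positions <- function(genome) {
  genome$truth$pos[genome$truth$class == "divergent"]
}

#' Exhaustive site-class truth table
#'
#' One row per divergent position (recorded once, with subgenome A's base as
#' `ref_allele` and subgenome B's as `alt_allele`) and one row per
#' heterozygous position per subgenome (`ref_allele` is the base present in
#' the subgenome sequence, `alt_allele` the second allele of the pair).
#' Positions are 0-based.
#'
#' @param genome A [make_subgenomes()] genome.
#' @return A tibble with columns `subgenome`, `pos`, `class`, `ref_allele`,
#'   `alt_allele`, sorted by subgenome then position.
#' @export
truth_table <- function(genome) {
  stopifnot(inherits(genome, "polyploid_genome"))
  genome$truth
}

#' Subgenome sequence as a character string
#'
#' @param genome A [make_subgenomes()] genome.
#' @param subgenome Subgenome name ("A" or "B"); default all, as a named
#'   character vector.
#' @return Named character vector of sequences.
#' @export
subgenome_seq <- function(genome, subgenome = NULL) {
  stopifnot(inherits(genome, "polyploid_genome"))
  nm <- subgenome %||% names(genome$codes)
  setNames(vapply(nm, function(s) dna_decode(genome$codes[[s]]), character(1)), nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.polyploid_genome <- function(x, ...) {
  p <- x$params
  cat(sprintf("<polyploid_genome> %d subgenome(s) x %s bp\n",
              p$n_subgenomes, format(p$length, big.mark = ",")))
  cat(sprintf("  blocks: %d bp conserved / %d bp divergent (alternating)\n",
              p$conserved_len, p$divergent_len))
  n_div <- sum(x$truth$class == "divergent")
  n_het <- sum(x$truth$class == "heterozygous")
  cat(sprintf("  divergence %.3g (%d divergent sites), heterozygosity %.4g (%d het sites)\n",
              p$divergence, n_div, p$heterozygosity, n_het))
  invisible(x)
}

#' Write subgenomes as FASTA
#'
#' One record per subgenome, 80-column wrapped.
#'
#' @param genome A [make_subgenomes()] genome.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(subgenome_seq(genome))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write the truth table as TSV
#'
#' @inheritParams write_genome_fasta
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(genome, path) {
  readr::write_tsv(truth_table(genome), path)
  invisible(path)
}

#' Write genome parameters as a JSON sidecar
#'
#' @inheritParams write_genome_fasta
#' @return `path`, invisibly.
#' @export
write_genome_json <- function(genome, path) {
  jsonlite::write_json(genome$params, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
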