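# Internal DNA helpers.  Allele codes: 0=A 1=C 2=G 3=T, 4=deletion
# pseudo-allele (alignment/pileup space only), -1 = N/unknown.

.BASES <- c("A", "C", "G", "T")

.CODE_LUT <- local({
  lut <- rep(-1L, 127L)
  for (i in seq_along(.BASES)) {
    lut[utf8ToInt(.BASES[i])] <- i - 1L
    lut[utf8ToInt(tolower(.BASES[i]))] <- i - 1L
  }
  lut
})

dna_encode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(integer(0))
  .CODE_LUT[utf8ToInt(x)]
}

dna_decode <- function(codes) {
  if (!length(codes)) return("")
  idx <- codes + 1L
  idx[is.na(idx) | idx < 1L | idx > 4L] <- 5L
  intToUtf8(utf8ToInt("ACGTN")[idx])
}

# single-character allele labels for code vectors ("-" = deletion)
code_to_char <- function(codes) {
  c(.BASES, "-", "N")[ifelse(is.na(codes) | codes < 0L | codes > 4L, 6L, codes + 1L)]
}

revcomp_codes <- function(codes) {
  out <- 3L - codes
  out[codes < 0L | codes > 3L] <- -1L
  rev(out)
}

revcomp <- function(x) dna_decode(revcomp_codes(dna_encode(x)))

# draw a substitution different from the template base, uniformly
mutate_codes <- function(codes, n_alt = NULL) {
  shift <- sample.int(3L, length(codes), replace = TRUE)
  (codes + shift) %% 4L
}

#' Complement of an interval set over whole targets
#'
#' Returns the maximal intervals not covered by `intervals`, per target.
#' Intervals are 0-based half-open, as everywhere in the package.
#'
#' @param intervals A tibble with columns `target`, `start`, `end`
#'   (non-overlapping within each target).
#' @param target_lengths Named integer vector of target lengths.
#' @return A tibble with columns `target`, `start`, `end`.
#' @export
complement_intervals <- function(intervals, target_lengths) {
  purrr::map_dfr(names(target_lengths), function(tn) {
    L <- as.integer(target_lengths[[tn]])
    iv <- intervals[intervals$target == tn, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    starts <- c(0L, iv$end)
    ends <- c(iv$start, L)
    keep <- ends > starts
    tibble::tibble(target = tn, start = as.integer(starts[keep]),
                   end = as.integer(ends[keep]))
  })
}
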