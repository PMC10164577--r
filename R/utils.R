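#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' ACGTN). Thin wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert a helical length in Angstrom to base pairs of B-form duplex
#'
#' B-form DNA rises ~3.3 Angstrom per base pair, so a protein domain spanning
#' 145 Angstrom covers ~44 bp of duplex. Used to relate the CAF-1 KER helix
#' length to the DNA footprint it can accommodate.
#'
#' @param angstrom Length in Angstrom.
#' @param rise_per_bp Helical rise per base pair in Angstrom (default 3.3).
#' @return Duplex length in base pairs (not rounded).
#' @examples
#' helix_span_bp(145) # ~44 bp
#' @export
helix_span_bp <- function(angstrom, rise_per_bp = 3.3) {
  stopifnot(angstrom >= 0, rise_per_bp > 0)
  angstrom / rise_per_bp
}

#' @rdname helix_span_bp
#' @param bp Duplex length in base pairs.
#' @export
helix_span_angstrom <- function(bp, rise_per_bp = 3.3) {
  stopifnot(bp >= 0, rise_per_bp > 0)
  bp * rise_per_bp
}

## Number of mismatches between the first `n` characters of each element of
## `reads` and the length-n string `index`. Vectorised over reads; n is small
## (an adapter index), so a per-position scan is fine.
prefix_mismatches <- function(reads, index) {
  n <- nchar(index)
  mm <- integer(length(reads))
  for (k in seq_len(n)) {
    mm <- mm + (substr(reads, k, k) != substr(index, k, k))
  }
  mm[nchar(reads) < n] <- NA_integer_
  mm
}

## Deterministic child seeds so one user-facing seed can drive several
## independent generator stages without reusing streams.
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% .Machine$integer.max
}
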