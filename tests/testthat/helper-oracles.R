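# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package paths
# they verify.

# Brute-force window mean: literal loop definition of the truncated boxcar.
oracle_blur <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# All-positions, all-rotations scan of a read against a reference set.
# Returns every (ref, strand, start0) at which the read matches exactly,
# scanning each rotation of circular references directly.
oracle_scan_read <- function(read, refs) {
  hits <- list()
  n <- nchar(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    L <- nchar(ref$sequence)
    scan_seq <- if (ref$circular) paste0(ref$sequence, ref$sequence)
                else ref$sequence
    starts <- if (ref$circular) seq_len(L) else seq_len(max(L - n + 1L, 0L))
    if (length(starts) == 0L) next
    windows <- substring(scan_seq, starts, starts + n - 1L)
    for (s0 in starts[windows == read]) {
      hits[[length(hits) + 1L]] <- list(ref = nm, strand = "+",
                                        start0 = s0 - 1L)
    }
    for (s0 in starts[windows == rc]) {
      hits[[length(hits) + 1L]] <- list(ref = nm, strand = "-",
                                        start0 = s0 - 1L)
    }
  }
  hits
}

# Brute-force pair mapping: both mates scanned independently; a fragment is
# reported only for a unique proper-orientation same-reference combination.
oracle_map_pair <- function(r1, r2, refs, max_fragment = 1000L) {
  h1 <- oracle_scan_read(r1, refs)
  h2 <- oracle_scan_read(r2, refs)
  if (length(h1) != 1L || length(h2) != 1L) return(NULL)
  a <- h1[[1L]]; b <- h2[[1L]]
  if (a$ref != b$ref || a$strand == b$strand) return(NULL)
  L <- nchar(refs[[a$ref]]$sequence)
  plus <- if (a$strand == "+") a else b
  minus <- if (a$strand == "+") b else a
  minus_len <- nchar(if (a$strand == "+") r2 else r1)
  start0 <- plus$start0
  end0 <- minus$start0 + minus_len
  if (end0 <= start0) end0 <- end0 + L
  len <- end0 - start0
  if (len > max_fragment) return(NULL)
  list(reference = a$ref, start = start0, end = end0, length = len)
}

# Exhaustive composition assignment used as the independent enumeration.
oracle_assign <- function(mass, M1, M2, amax, bmax, tol) {
  best <- NULL
  for (a in 0:amax) for (b in 0:bmax) {
    if (a + b == 0L) next
    r <- abs(mass - a * M1 - b * M2)
    if (is.null(best) || r < best$r - 1e-12 ||
        (abs(r - best$r) <= 1e-12 &&
         (a + b < best$a + best$b ||
          (a + b == best$a + best$b && a < best$a)))) {
      best <- list(a = a, b = b, r = r)
    }
  }
  if (best$r > tol) return(list(a = NA_integer_, b = NA_integer_))
  list(a = best$a, b = best$b)
}

# Shared small fixture: deterministic references reused across test files.
test_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_references(101, c(1500L, 1500L, 207L))
    cache
  }
})
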