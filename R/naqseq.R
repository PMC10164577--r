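## NAQ-seq plasmid read pipeline: dual-index demultiplexing, 5' index
## trimming, unique-best mapping to small (circular) references, nucleosomal
## fragment-length selection and the percent-nicked / coverage summaries.

#' Sample index table for demultiplexing
#'
#' @param indices Named character vector: sample name -> index sequence. All
#'   indices must share one length and be pairwise distinct at >= 2
#'   mismatches, so a single-mismatch read cannot be ambiguous.
#' @return An `IndexTable` object.
#' @export
index_table <- function(indices) {
  if (length(indices) == 0L || is.null(names(indices))) {
    stop("indices must be a named, non-empty character vector")
  }
  indices <- toupper(indices)
  if (any(grepl("[^ACGT]", indices))) stop("index alphabet must be ACGT")
  if (length(unique(nchar(indices))) != 1L) {
    stop("all indices must have the same length")
  }
  n <- length(indices)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d <- sum(strsplit(indices[[i]], "")[[1L]] !=
                   strsplit(indices[[j]], "")[[1L]])
        if (d < 2L) {
          stop("indices '", indices[[i]], "' and '", indices[[j]],
               "' differ at fewer than 2 positions")
        }
      }
    }
  }
  structure(list(indices = indices, width = nchar(indices[[1L]])),
            class = "IndexTable")
}

#' Demultiplex read pairs on a 5' adapter index present in both mates
#'
#' A pair is assigned to a sample only when BOTH mates begin with that
#' sample's index within `max_mismatch`; pairs matching no sample, or whose
#' mates match different samples, are discarded.
#'
#' @param pairs A `ReadPairs` data.frame (columns `id`, `r1`, `r2`).
#' @param table An [index_table()].
#' @param max_mismatch Allowed mismatches per mate index (default 0).
#' @return List with `samples` (named list of `ReadPairs` subsets) and
#'   `discarded` (a `ReadPairs` subset). Assigned plus discarded partition
#'   the input.
#' @export
demultiplex <- function(pairs, table, max_mismatch = 0L) {
  stopifnot(inherits(table, "IndexTable"))
  n <- nrow(pairs)
  assign <- rep(NA_character_, n)
  n_hits <- integer(n)
  if (n > 0L) {
    for (sm in names(table$indices)) {
      idx <- table$indices[[sm]]
      hit <- prefix_mismatches(pairs$r1, idx) <= max_mismatch &
        prefix_mismatches(pairs$r2, idx) <= max_mismatch
      hit[is.na(hit)] <- FALSE
      assign[hit] <- sm
      n_hits <- n_hits + hit
    }
    assign[n_hits != 1L] <- NA_character_   # ambiguous pairs are discarded
  }
  keep_class <- function(df) {
    class(df) <- c("ReadPairs", "data.frame")
    df
  }
  samples <- lapply(names(table$indices), function(sm) {
    keep_class(pairs[which(assign == sm), , drop = FALSE])
  })
  names(samples) <- names(table$indices)
  list(samples = samples,
       discarded = keep_class(pairs[is.na(assign), , drop = FALSE]))
}

#' Trim the 5' adapter index off both mates
#'
#' @param pairs A `ReadPairs` subset assigned to one sample.
#' @param index_length Index length in nt.
#' @return The pairs with `index_length` bases removed from the 5' end of
#'   each mate. Errors if any mate would become empty.
#' @export
trim_index <- function(pairs, index_length) {
  stopifnot(index_length >= 1L)
  if (nrow(pairs) > 0L &&
      any(nchar(pairs$r1) <= index_length | nchar(pairs$r2) <= index_length)) {
    stop("read shorter than or equal to the index length; already trimmed?")
  }
  pairs$r1 <- substring(pairs$r1, index_length + 1L)
  pairs$r2 <- substring(pairs$r2, index_length + 1L)
  pairs
}

# ---------------------------------------------------------------------------
# Unique-best exact-seed mapper
#
# BWA-grade alignment is unnecessary at plasmid scale: references are a few
# kb and k-mer disjoint by construction. The mapper hashes every k-mer of
# each reference (doubled for circular molecules, both strands), looks up the
# read's 5' k-mer and verifies the full read by ungapped comparison. A mate
# maps only when exactly one reference location matches (unique best hit, the
# stand-in for a MAPQ filter).

#' Build a k-mer index over a reference set
#'
#' @param refs A `ReferenceSet`.
#' @param k Seed length (default 31); reads shorter than `k` cannot map.
#' @return A `RefIndex` object used by [map_pairs()].
#' @export
build_ref_index <- function(refs, k = 31L) {
  stopifnot(inherits(refs, "ReferenceSet"), k >= 8L)
  env <- new.env(parent = emptyenv(), size = 65536L)
  meta <- list()
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    L <- nchar(ref$sequence)
    scan_fwd <- if (ref$circular) paste0(ref$sequence, ref$sequence)
                else ref$sequence
    rc <- revcomp(ref$sequence)
    scan_rev <- if (ref$circular) paste0(rc, rc) else rc
    n_start <- if (ref$circular) L else max(L - k + 1L, 0L)
    starts <- seq_len(n_start)
    add <- function(scan_seq, strand) {
      kmers <- substring(scan_seq, starts, starts + k - 1L)
      full <- nchar(kmers) == k
      for (i in which(full)) {
        key <- kmers[i]
        hit <- list(ref = nm, strand = strand, pos = starts[i])
        env[[key]] <- c(env[[key]], list(hit))
      }
    }
    add(scan_fwd, "+")
    add(scan_rev, "-")
    meta[[nm]] <- list(length = L, circular = ref$circular,
                       fwd = scan_fwd, rev = scan_rev)
  }
  structure(list(env = env, k = k, meta = meta,
                 roles = reference_roles(refs)),
            class = "RefIndex")
}

## Map one set of reads (character vector) -> data.frame of unique hits.
## strand is the strand of the indexed sequence the read matched.
map_reads_unique <- function(reads, index) {
  k <- index$k
  seeds <- substr(reads, 1L, k)
  cand <- mget(seeds, envir = index$env, ifnotfound = list(NULL))
  ref <- rep(NA_character_, length(reads))
  strand <- rep(NA_character_, length(reads))
  start1 <- rep(NA_integer_, length(reads))    # 1-based on the scanned strand
  for (i in seq_along(reads)) {
    hits <- cand[[i]]
    if (is.null(hits) || nchar(reads[i]) < k) next
    rd <- reads[i]; n <- nchar(rd)
    locs <- list()
    for (h in hits) {
      m <- index$meta[[h$ref]]
      scan_seq <- if (h$strand == "+") m$fwd else m$rev
      if (h$pos + n - 1L > nchar(scan_seq)) next
      if (substr(scan_seq, h$pos, h$pos + n - 1L) == rd) {
        canon <- if (m$circular) ((h$pos - 1L) %% m$length) else (h$pos - 1L)
        locs[[length(locs) + 1L]] <- list(ref = h$ref, strand = h$strand,
                                          canon = canon)
      }
    }
    if (length(locs) == 0L) next
    key <- vapply(locs, function(l) paste(l$ref, l$strand, l$canon),
                  character(1))
    locs <- locs[!duplicated(key)]
    if (length(locs) != 1L) next               # not unique -> unmapped
    ref[i] <- locs[[1L]]$ref
    strand[i] <- locs[[1L]]$strand
    start1[i] <- locs[[1L]]$canon + 1L
  }
  data.frame(ref = ref, strand = strand, start1 = start1,
             len = nchar(reads), stringsAsFactors = FALSE)
}

#' Map trimmed read pairs to the reference set
#'
#' Each mate is placed by exact k-mer seed plus full ungapped verification
#' against the doubled circular sequence and its reverse complement. A
#' `Fragment` is emitted only when both mates map uniquely to the same
#' reference in proper (convergent) orientation; the fragment is the outer
#' span of the two mates, with circular wrap resolved so `end > start`.
#'
#' @param pairs Trimmed `ReadPairs`.
#' @param index A [build_ref_index()].
#' @param max_fragment Longest plausible fragment (guards against spurious
#'   pairings on circular molecules; default 1000 bp).
#' @return data.frame of class `Fragments` with columns `reference`, `start`,
#'   `end` (0-based half-open; `end` may exceed the reference length when the
#'   fragment wraps the origin), `length`, `unique` (always `TRUE` for
#'   emitted fragments). Unmapped pair count is attached as attribute
#'   `n_unmapped`.
#' @export
map_pairs <- function(pairs, index, max_fragment = 1000L) {
  stopifnot(inherits(index, "RefIndex"))
  m1 <- map_reads_unique(pairs$r1, index)
  m2 <- map_reads_unique(pairs$r2, index)
  ok <- !is.na(m1$ref) & !is.na(m2$ref) & m1$ref == m2$ref &
    m1$strand != m2$strand
  out <- data.frame(reference = character(0), start = integer(0),
                    end = integer(0), length = integer(0),
                    unique = logical(0), stringsAsFactors = FALSE)
  rows <- which(ok)
  if (length(rows) > 0L) {
    ref <- m1$ref[rows]
    L <- vapply(ref, function(nm) index$meta[[nm]]$length, numeric(1))
    # orient: the '+' mate gives the fragment 5' start on the reference
    plus_is_1 <- m1$strand[rows] == "+"
    p_start1 <- ifelse(plus_is_1, m1$start1[rows], m2$start1[rows])
    p_len <- ifelse(plus_is_1, m1$len[rows], m2$len[rows])
    minus_start1 <- ifelse(plus_is_1, m2$start1[rows], m1$start1[rows])
    minus_len <- ifelse(plus_is_1, m2$len[rows], m1$len[rows])
    # minus-strand mate position was recorded on the reverse-complement
    # scan; convert to forward coordinates of its 5'-most base
    minus_fwd_start1 <- L - (minus_start1 - 1L) - minus_len + 1L
    minus_fwd_start1 <- ((minus_fwd_start1 - 1L) %% L) + 1L
    start0 <- p_start1 - 1L
    end0 <- minus_fwd_start1 - 1L + minus_len
    wrap <- end0 <= start0
    end0[wrap] <- end0[wrap] + L[wrap]
    len <- end0 - start0
    good <- len >= pmax(p_len, minus_len) & len <= max_fragment
    out <- data.frame(reference = ref[good], start = as.integer(start0[good]),
                      end = as.integer(end0[good]),
                      length = as.integer(len[good]),
                      unique = rep(TRUE, sum(good)),
                      stringsAsFactors = FALSE)
    rows <- rows[good]
  }
  class(out) <- c("Fragments", "data.frame")
  attr(out, "n_unmapped") <- nrow(pairs) - nrow(out)
  attr(out, "pair_rows") <- rows
  out
}

#' Select fragments in a nucleosomal length window
#'
#' Keeps fragments with `lo <= length <= hi` (closed interval), preserving
#' input order. The default 125-160 bp window selects mononucleosome-
#' protected MNase products.
#'
#' @param fragments A `Fragments` data.frame.
#' @param lo,hi Window bounds in bp.
#' @return Filtered `Fragments`.
#' @export
length_select <- function(fragments, lo = 125L, hi = 160L) {
  if (lo > hi) stop("lo must not exceed hi")
  out <- fragments[fragments$length >= lo & fragments$length <= hi, ,
                   drop = FALSE]
  class(out) <- c("Fragments", "data.frame")
  out
}

#' Percentage of fragments on the nicked plasmid
#'
#' `100 * n_nicked / (n_nicked + n_supercoiled)`; loading-control fragments
#' are excluded from both numerator and denominator.
#'
#' @param fragments Length-selected `Fragments`.
#' @param roles Named character vector role -> reference name, e.g. from
#'   [reference_roles()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_nicked <- function(fragments, roles) {
  n_nick <- sum(fragments$reference == roles[["nicked"]])
  n_super <- sum(fragments$reference == roles[["supercoiled"]])
  if (n_nick + n_super == 0L) {
    stop("no fragments on the nicked or supercoiled plasmid")
  }
  100 * n_nick / (n_nick + n_super)
}

#' Loading-control-normalized per-bp coverage
#'
#' Per-bp fragment depth on one reference divided by the loading-control
#' fragment count, making coverage comparable across samples with different
#' recovery.
#'
#' @param fragments `Fragments` on the reference of interest (wrapped
#'   circular fragments allowed).
#' @param ref_length Reference length in bp.
#' @param control_count Loading-control fragment count (> 0).
#' @return Numeric vector of length `ref_length` (normalized depth per bp).
#' @export
control_normalized_coverage <- function(fragments, ref_length, control_count) {
  if (control_count <= 0) stop("control_count must be > 0")
  cov <- numeric(ref_length)
  for (i in seq_len(nrow(fragments))) {
    pos <- seq.int(fragments$start[i], fragments$end[i] - 1L) %% ref_length
    cov[pos + 1L] <- cov[pos + 1L] + 1
  }
  cov / control_count
}

#' Nucleosome band normalized to the in-lane loading control
#'
#' Ratio of the nucleosomal band intensity (the ~140-160 bp protected
#' species) to the loading-control band in the same lane; lane-wise exposure
#' cancels.
#'
#' @param nucleosome_band_intensity,control_band_intensity Band intensities.
#' @return Normalized nucleosome signal.
#' @export
gel_band_quant <- function(nucleosome_band_intensity,
                           control_band_intensity) {
  if (any(control_band_intensity <= 0)) stop("control intensity must be > 0")
  nucleosome_band_intensity / control_band_intensity
}

#' Percent of histone fluorescence on the nicked plasmid
#'
#' `100 * nicked / (nicked + supercoiled)` from per-plasmid fluorescence
#' intensities of one reaction.
#'
#' @param nicked_intensity,supercoiled_intensity Nonnegative intensities.
#' @return Percentage in `[0, 100]`.
#' @export
fluorescence_fraction_nicked <- function(nicked_intensity,
                                         supercoiled_intensity) {
  if (any(nicked_intensity < 0) || any(supercoiled_intensity < 0)) {
    stop("intensities must be >= 0")
  }
  tot <- nicked_intensity + supercoiled_intensity
  if (any(tot <= 0)) stop("total intensity must be > 0")
  100 * nicked_intensity / tot
}

#' Full NAQ-seq pipeline for multiplexed read pairs
#'
#' Demultiplexes, trims, maps, length-selects and summarises each sample.
#'
#' @param pairs `ReadPairs` (multiplexed).
#' @param refs A `ReferenceSet`.
#' @param table An [index_table()].
#' @param lo,hi Fragment-length window (default 125-160 bp).
#' @param max_mismatch Index mismatches allowed in demultiplexing.
#' @return data.frame with one row per sample: `sample`, `n_pairs`,
#'   `n_mapped`, `n_selected`, `n_control`, `percent_nicked`.
#' @export
naq_pipeline <- function(pairs, refs, table, lo = 125L, hi = 160L,
                         max_mismatch = 0L) {
  idx <- build_ref_index(refs)
  roles <- reference_roles(refs)
  dm <- demultiplex(pairs, table, max_mismatch)
  rows <- lapply(names(dm$samples), function(sm) {
    sp <- trim_index(dm$samples[[sm]], table$width)
    frags <- map_pairs(sp, idx)
    sel <- length_select(frags, lo, hi)
    n_ctrl <- sum(sel$reference == roles[["loading_control"]])
    pn <- if (sum(sel$reference %in%
                  c(roles[["nicked"]], roles[["supercoiled"]])) > 0L) {
      percent_nicked(sel, roles)
    } else NA_real_
    data.frame(sample = sm, n_pairs = nrow(dm$samples[[sm]]),
               n_mapped = nrow(frags), n_selected = nrow(sel),
               n_control = n_ctrl, percent_nicked = pn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write fragments as BED
#'
#' 0-based half-open intervals; fragments wrapping a circular origin are
#' written with `end` clipped to the reference length and flagged in the
#' name field.
#'
#' @param fragments `Fragments`.
#' @param ref_lengths Named vector of reference lengths.
#' @param file Output BED path.
#' @export
write_fragments_bed <- function(fragments, ref_lengths, file) {
  L <- ref_lengths[fragments$reference]
  wrap <- fragments$end > L
  bed <- data.frame(chrom = fragments$reference,
                    start = fragments$start,
                    end = pmin(fragments$end, L),
                    name = ifelse(wrap, "wrapped", "frag"))
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
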