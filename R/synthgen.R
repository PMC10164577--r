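## Synthetic-data generators. Every pipeline stage in the package has a
## generator here that produces inputs with known ground truth, so the whole
## analysis is testable by parameter recovery.

#' Plasmid reference sequence with an experimental role
#'
#' @param name Unique reference name.
#' @param sequence DNA string (ACGT only, non-empty).
#' @param circular Is the molecule circular?
#' @param role One of `"nicked"`, `"supercoiled"`, `"loading_control"`. The
#'   nicked/supercoiled identity is experiment metadata (which plasmid was
#'   nicked), not something inferred from the data.
#' @return A `PlasmidReference` object.
#' @export
plasmid_reference <- function(name, sequence,
                              circular = TRUE,
                              role = c("nicked", "supercoiled",
                                       "loading_control")) {
  role <- match.arg(role)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) stop("sequence alphabet must be ACGT")
  structure(list(name = as.character(name), sequence = sequence,
                 circular = isTRUE(circular), role = role),
            class = "PlasmidReference")
}

#' Bundle plasmid references into a validated NAQ reference set
#'
#' @param ... `PlasmidReference` objects, exactly one per role.
#' @return A named list of class `ReferenceSet`.
#' @export
reference_set <- function(...) {
  refs <- list(...)
  if (length(refs) == 1L && is.list(refs[[1L]]) &&
      !inherits(refs[[1L]], "PlasmidReference")) {
    refs <- refs[[1L]]
  }
  if (length(refs) == 0L) stop("reference set must not be empty")
  ok <- vapply(refs, inherits, logical(1), "PlasmidReference")
  if (!all(ok)) stop("all elements must be PlasmidReference objects")
  nm <- vapply(refs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("reference names must be unique")
  roles <- vapply(refs, `[[`, character(1), "role")
  need <- c("nicked", "supercoiled", "loading_control")
  if (!setequal(roles, need) || length(roles) != 3L) {
    stop("a NAQ reference set needs exactly one reference per role: ",
         paste(need, collapse = ", "))
  }
  names(refs) <- nm
  structure(refs, class = "ReferenceSet")
}

#' Look up reference names by role
#' @param refs A `ReferenceSet`.
#' @return Named character vector role -> reference name.
#' @export
reference_roles <- function(refs) {
  stopifnot(inherits(refs, "ReferenceSet"))
  roles <- vapply(refs, `[[`, character(1), "role")
  stats::setNames(names(refs), roles)
}

## All k-mers of a reference on both strands; circular molecules contribute
## origin-spanning k-mers via sequence doubling.
ref_kmers <- function(ref, k) {
  s <- ref$sequence
  L <- nchar(s)
  scan_seq <- if (ref$circular) paste0(s, substr(s, 1L, k - 1L)) else s
  n <- nchar(scan_seq) - k + 1L
  if (n < 1L) return(character(0))
  fwd <- substring(scan_seq, seq_len(n), seq_len(n) + k - 1L)
  unique(c(fwd, revcomp(fwd)))
}

#' Generate synthetic plasmid references with disjoint k-mer content
#'
#' Draws three random sequences (nicked plasmid, supercoiled plasmid, linear
#' loading-control amplicon) and verifies that no 31-mer is shared between
#' any two of them on either strand, so a nucleosomal-length read always maps
#' uniquely to its reference. Redraws on collision, up to `max_tries`.
#'
#' @param seed Integer RNG seed; output is deterministic for a fixed seed.
#' @param lengths Lengths (bp) of the nicked plasmid, supercoiled plasmid and
#'   loading control. Plasmids must be at least 500 bp.
#' @param k Seed k-mer length used for the disjointness check (default 31).
#' @param max_tries Redraw budget before giving up.
#' @return A `ReferenceSet`.
#' @export
gen_references <- function(seed, lengths = c(3000L, 3000L, 207L), k = 31L,
                           max_tries = 25L) {
  stopifnot(length(lengths) == 3L)
  if (any(lengths[1:2] < 500L)) stop("plasmid lengths must be >= 500 bp")
  if (lengths[3L] < 2L * k) stop("loading control too short for unique mapping")
  set.seed(as.integer(seed))
  draw <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = "")
  for (try in seq_len(max_tries)) {
    refs <- reference_set(
      plasmid_reference("pNick",  draw(lengths[1L]), circular = TRUE,
                        role = "nicked"),
      plasmid_reference("pSuper", draw(lengths[2L]), circular = TRUE,
                        role = "supercoiled"),
      plasmid_reference("ctrl",   draw(lengths[3L]), circular = FALSE,
                        role = "loading_control"))
    km <- lapply(refs, ref_kmers, k = k)
    shared <- length(intersect(km[[1L]], km[[2L]])) +
      length(intersect(km[[1L]], km[[3L]])) +
      length(intersect(km[[2L]], km[[3L]]))
    if (shared == 0L) return(refs)
  }
  stop("could not draw k-mer-disjoint references in ", max_tries, " tries")
}

#' Write a reference set as FASTA
#' @param refs A `ReferenceSet`.
#' @param file Output FASTA path.
#' @export
write_reference_fasta <- function(refs, file) {
  stopifnot(inherits(refs, "ReferenceSet"))
  seqs <- Biostrings::DNAStringSet(vapply(refs, `[[`, character(1), "sequence"))
  names(seqs) <- names(refs)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Read a reference set from FASTA plus a role table
#' @param fasta FASTA path.
#' @param roles Named character vector reference name -> role, or a TSV path
#'   with columns `name`, `role`, `circular`.
#' @export
read_reference_fasta <- function(fasta, roles) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  circ <- NULL
  if (is.character(roles) && length(roles) == 1L && file.exists(roles)) {
    tab <- utils::read.delim(roles, stringsAsFactors = FALSE)
    circ <- stats::setNames(as.logical(tab$circular), tab$name)
    roles <- stats::setNames(tab$role, tab$name)
  }
  refs <- lapply(names(seqs), function(nm) {
    plasmid_reference(nm, as.character(seqs[[nm]]),
                      circular = if (is.null(circ)) roles[[nm]] != "loading_control"
                                 else circ[[nm]],
                      role = roles[[nm]])
  })
  reference_set(refs)
}

# ---------------------------------------------------------------------------
# NAQ-seq read-pair simulation

#' Ground truth for a simulated NAQ-seq library
#'
#' @param p_nicked Probability that a (non-control) nucleosomal fragment
#'   derives from the nicked plasmid, in `[0, 1]`.
#' @param n_pairs Number of read pairs to simulate.
#' @param index 5' adapter index sequence carried by both mates.
#' @param sample Sample name.
#' @param fraglen_mean,fraglen_sd Fragment length distribution (bp); lengths
#'   are truncated to `[50, 250]`. Defaults Normal(145, 10), a stand-in for a
#'   mononucleosomal MNase library centred in the 125-160 bp selection window.
#' @param control_fraction Fraction of pairs drawn from the loading control.
#' @param read_length Bases of insert sequence per mate after the index.
#' @param seed Integer RNG seed.
#' @return A `NaqSimTruth` object.
#' @export
naq_sim_truth <- function(p_nicked, n_pairs, index, sample = "S1",
                          fraglen_mean = 145, fraglen_sd = 10,
                          control_fraction = 0.05, read_length = 75L,
                          seed = 1L) {
  if (p_nicked < 0 || p_nicked > 1) stop("p_nicked must be in [0, 1]")
  if (n_pairs < 1L) stop("n_pairs must be positive")
  if (fraglen_mean < 100 || fraglen_mean > 200) {
    stop("fraglen_mean outside the plausible nucleosomal range (100-200 bp)")
  }
  if (fraglen_sd <= 0) stop("fraglen_sd must be > 0")
  if (grepl("[^ACGT]", index)) stop("index alphabet must be ACGT")
  structure(list(p_nicked = p_nicked, n_pairs = as.integer(n_pairs),
                 index = toupper(index), sample = as.character(sample),
                 fraglen_mean = fraglen_mean, fraglen_sd = fraglen_sd,
                 control_fraction = control_fraction,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "NaqSimTruth")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- round(stats::rnorm(n, mean, sd))
  pmin(pmax(x, lo), hi)
}

#' Simulate paired NAQ-seq reads with known origin
#'
#' Each pair derives from an MNase-protected fragment placed uniformly on the
#' nicked plasmid with probability `p_nicked`, otherwise on the supercoiled
#' plasmid; a `control_fraction` of pairs comes from the linear loading
#' control. Fragment lengths are Normal(mean, sd) truncated to `[50, 250]`
#' bp (and to the control length on the control). Both mates carry the
#' sample's index at the 5' end followed by insert sequence; mate 2 is the
#' reverse complement of the fragment's 3' end. Circular plasmids wrap: the
#' fragment may span the sequence origin.
#'
#' @param truth A `NaqSimTruth`, or a list of them (one per sample; reads are
#'   pooled and shuffled as in a multiplexed run).
#' @param refs A `ReferenceSet`.
#' @return A data.frame of class `ReadPairs` with columns `id`, `r1`, `r2`,
#'   and a `truth` attribute (data.frame: `sample`, `reference`, `start`,
#'   `length`) giving each pair's origin (0-based start).
#' @export
sim_naq_readpairs <- function(truth, refs) {
  if (!inherits(refs, "ReferenceSet")) stop("refs must be a ReferenceSet")
  truths <- if (inherits(truth, "NaqSimTruth")) list(truth) else truth
  stopifnot(all(vapply(truths, inherits, logical(1), "NaqSimTruth")))
  roles <- reference_roles(refs)
  chunks <- lapply(truths, function(tr) {
    set.seed(tr$seed)
    n <- tr$n_pairs
    is_ctrl <- stats::runif(n) < tr$control_fraction
    on_nick <- stats::runif(n) < tr$p_nicked
    ref_name <- ifelse(is_ctrl, roles[["loading_control"]],
                       ifelse(on_nick, roles[["nicked"]], roles[["supercoiled"]]))
    len <- rtrunc_norm(n, tr$fraglen_mean, tr$fraglen_sd, 50L, 250L)
    start <- integer(n)
    insert <- character(n)
    for (nm in unique(ref_name)) {
      idx <- which(ref_name == nm)
      ref <- refs[[nm]]
      L <- nchar(ref$sequence)
      if (ref$circular) {
        start[idx] <- sample.int(L, length(idx), replace = TRUE) - 1L
        doubled <- paste0(ref$sequence, ref$sequence)
        insert[idx] <- substring(doubled, start[idx] + 1L, start[idx] + len[idx])
      } else {
        len[idx] <- pmin(len[idx], L)
        start[idx] <- vapply(L - len[idx] + 1L,
                             function(m) sample.int(m, 1L), integer(1)) - 1L
        insert[idx] <- substring(ref$sequence, start[idx] + 1L,
                                 start[idx] + len[idx])
      }
    }
    rl <- pmin(tr$read_length, len)
    r1 <- paste0(tr$index, substring(insert, 1L, rl))
    r2 <- paste0(tr$index, revcomp(substring(insert, len - rl + 1L, len)))
    list(r1 = r1, r2 = r2,
         truth = data.frame(sample = tr$sample, reference = ref_name,
                            start = start, length = len,
                            stringsAsFactors = FALSE))
  })
  r1 <- unlist(lapply(chunks, `[[`, "r1")); r2 <- unlist(lapply(chunks, `[[`, "r2"))
  tru <- do.call(rbind, lapply(chunks, `[[`, "truth"))
  if (length(truths) > 1L) {           # interleave samples like a pooled run
    set.seed(child_seed(truths[[1L]]$seed, 991L))
    ord <- sample.int(length(r1))
    r1 <- r1[ord]; r2 <- r2[ord]; tru <- tru[ord, , drop = FALSE]
  }
  pairs <- data.frame(id = sprintf("read%06d", seq_along(r1)),
                      r1 = r1, r2 = r2, stringsAsFactors = FALSE)
  class(pairs) <- c("ReadPairs", "data.frame")
  attr(pairs, "truth") <- tru
  pairs
}

#' Write read pairs as a pair of FASTQ files
#'
#' Four-line FASTQ records with constant Phred+33 quality (`I` = Q40).
#'
#' @param pairs A `ReadPairs` data.frame.
#' @param r1_file,r2_file Output FASTQ paths for mate 1 / mate 2.
#' @export
write_fastq_pairs <- function(pairs, r1_file, r2_file) {
  wr <- function(seqs, ids, path) {
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  }
  wr(pairs$r1, pairs$id, r1_file)
  wr(pairs$r2, pairs$id, r2_file)
  invisible(c(r1_file, r2_file))
}

#' Read paired FASTQ files into a `ReadPairs` table
#' @param r1_file,r2_file FASTQ paths (mate order must match).
#' @export
read_fastq_pairs <- function(r1_file, r2_file) {
  s1 <- Biostrings::readDNAStringSet(r1_file, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_file, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  pairs <- data.frame(id = names(s1), r1 = as.character(s1),
                      r2 = as.character(s2), stringsAsFactors = FALSE)
  class(pairs) <- c("ReadPairs", "data.frame")
  pairs
}

# ---------------------------------------------------------------------------
# SCAR-seq track simulation

#' Ground truth for simulated SCAR-seq samples
#'
#' @param n_bins Number of bins in the track.
#' @param bin_width Bin width in bp (default 1000).
#' @param iz_positions Bin indices (0-based) of initiation zones.
#' @param partition_amplitude Injected asymmetry amplitude `a` in `[-1, 1]`:
#'   the expected forward-read fraction at signed offset `d` bins from the
#'   nearest initiation zone is `0.5 * (1 + a * s(d))` with
#'   `s(d) = sign(d) * exp(-|d| / decay_bins)`.
#' @param decay_bins Exponential decay length of the asymmetry profile, in
#'   bins (default 300, i.e. 300 kb at 1 kb bins — the scale over which
#'   strand bias relaxes around mammalian initiation zones).
#' @param depth Expected total (F + R) pulldown reads per bin for a sample
#'   with scale factor 1.
#' @param enrichment Pulldown-over-input CPM enrichment on the simulated
#'   region: the input library is modelled as spreading
#'   `enrichment`-fold more reads genome-wide than land in the region, so
#'   after CPM normalization the local input signal is `1/enrichment` of the
#'   pulldown's.
#' @param spikein_fraction Exogenous spike-in reads as a fraction of the
#'   scale-1 target depth; the spike-in count is constant across samples.
#' @param sample_scale_factors Named positive scale factors, one per sample;
#'   each sample's expected target read total is scaled by its factor.
#' @param iz_orientations Optional +1/-1 per initiation zone (default all +1).
#' @param seed Integer RNG seed.
#' @return A `ScarSimTruth` object.
#' @export
scar_sim_truth <- function(n_bins = 4000L, bin_width = 1000L,
                           iz_positions = seq(400L, 3600L, by = 800L),
                           partition_amplitude = 0.4, decay_bins = 300L,
                           depth = 50, enrichment = 10,
                           spikein_fraction = 0.05,
                           sample_scale_factors = c(A = 1),
                           iz_orientations = NULL, seed = 1L) {
  if (abs(partition_amplitude) > 1) stop("|partition_amplitude| must be <= 1")
  if (depth <= 0) stop("depth must be > 0")
  if (spikein_fraction <= 0 || spikein_fraction >= 1) {
    stop("spikein_fraction must be in (0, 1)")
  }
  if (any(sample_scale_factors <= 0)) stop("scale factors must be > 0")
  if (is.null(names(sample_scale_factors))) {
    stop("sample_scale_factors must be named")
  }
  if (any(iz_positions < 0 | iz_positions >= n_bins)) {
    stop("iz_positions out of track bounds")
  }
  if (is.null(iz_orientations)) iz_orientations <- rep(1L, length(iz_positions))
  stopifnot(length(iz_orientations) == length(iz_positions),
            all(iz_orientations %in% c(-1L, 1L)))
  structure(list(n_bins = as.integer(n_bins), bin_width = as.integer(bin_width),
                 iz_positions = as.integer(iz_positions),
                 partition_amplitude = partition_amplitude,
                 decay_bins = as.integer(decay_bins), depth = depth,
                 enrichment = enrichment, spikein_fraction = spikein_fraction,
                 sample_scale_factors = sample_scale_factors,
                 iz_orientations = as.integer(iz_orientations),
                 seed = as.integer(seed)),
            class = "ScarSimTruth")
}

## Expected forward-strand fraction per bin implied by the truth.
scar_expected_forward_fraction <- function(truth) {
  bins <- seq_len(truth$n_bins) - 1L
  offs <- outer(bins, truth$iz_positions, `-`)
  nearest <- apply(abs(offs), 1L, which.min)
  d <- offs[cbind(seq_along(bins), nearest)]
  ori <- truth$iz_orientations[nearest]
  s <- ori * sign(d) * exp(-abs(d) / truth$decay_bins)
  0.5 * (1 + truth$partition_amplitude * s)
}

#' Simulate SCAR-seq pulldown/input samples with spike-in
#'
#' Per-bin counts are Poisson. The pulldown splits its per-bin depth between
#' strands according to the injected asymmetry profile; the input has no
#' strand asymmetry. Each sample's expected target totals are scaled by its
#' scale factor while the spike-in count stays constant, emulating a fixed
#' exogenous (dm6) spike-in against a varying target (mm10) library.
#'
#' @param truth A `ScarSimTruth`.
#' @return Named list (one element per sample), each with `pulldown` and
#'   `input` (`StrandedBinTrack`s in counts), `pulldown_total` and
#'   `input_total` (library totals for CPM: the input total includes the
#'   genome-wide reads implied by `enrichment`), `spikein` (spike-in read
#'   count) and `target_total` (target-genome pulldown reads). The truth's
#'   initiation zones are attached as attribute `izs`.
#' @export
sim_scar_samples <- function(truth) {
  stopifnot(inherits(truth, "ScarSimTruth"))
  set.seed(truth$seed)
  f <- scar_expected_forward_fraction(truth)
  spikein <- round(truth$spikein_fraction * truth$depth * truth$n_bins)
  out <- lapply(names(truth$sample_scale_factors), function(sm) {
    sc <- truth$sample_scale_factors[[sm]]
    mu <- truth$depth * sc
    pd_f <- stats::rpois(truth$n_bins, mu * f)
    pd_r <- stats::rpois(truth$n_bins, mu * (1 - f))
    in_f <- stats::rpois(truth$n_bins, mu / 2)
    in_r <- stats::rpois(truth$n_bins, mu / 2)
    pulldown <- stranded_bin_track("synth", truth$bin_width, pd_f, pd_r,
                                   units = "counts")
    input <- stranded_bin_track("synth", truth$bin_width, in_f, in_r,
                                units = "counts")
    list(pulldown = pulldown, input = input,
         pulldown_total = sum(pd_f) + sum(pd_r),
         input_total = round(truth$enrichment * (sum(in_f) + sum(in_r))),
         spikein = spikein,
         target_total = sum(pd_f) + sum(pd_r))
  })
  names(out) <- names(truth$sample_scale_factors)
  attr(out, "izs") <- data.frame(reference = "synth",
                                 center_bin = truth$iz_positions,
                                 orientation = truth$iz_orientations)
  out
}

# ---------------------------------------------------------------------------
# Gel-lane simulation

#' Lambda/HindIII ladder fragment sizes (bp)
#' @return Integer vector of the eight digest fragment sizes.
#' @export
lambda_hindiii_sizes <- function() {
  c(23130L, 9416L, 6557L, 4361L, 2322L, 2027L, 564L, 125L)
}

#' Simulate a molecular-weight ladder lane
#'
#' Band positions follow the log-linear migration model
#' `log10(size) = slope * Rf + intercept` with `Rf = position / lane_length`.
#'
#' @param calib Numeric `c(slope, intercept)` with slope < 0.
#' @param sizes Band sizes in bp (default lambda/HindIII digest).
#' @param lane_length Total migration span (arbitrary units, e.g. mm).
#' @return data.frame with columns `size`, `position` (bands with Rf outside
#'   `[0, 1]` are dropped).
#' @export
sim_gel_ladder <- function(calib = c(slope = -2.5, intercept = 4.5),
                           sizes = lambda_hindiii_sizes(), lane_length = 100) {
  slope <- calib[[1L]]; intercept <- calib[[2L]]
  stopifnot(slope < 0, lane_length > 0)
  rf <- (log10(sizes) - intercept) / slope
  keep <- rf >= 0 & rf <= 1
  data.frame(size = sizes[keep], position = rf[keep] * lane_length)
}

#' Simulate one gel lane with a product front at a known size
#'
#' The lane holds a smeared distribution of replication products up to a
#' maximum size `front_bp`. Intensity is zero on the high-molecular-weight
#' side of the front, ramps up linearly over `ramp_width` migration units to
#' a flat plateau of `plateau_width`, then decays toward smaller products.
#' The ramp is placed so that the 5%-of-peak crossing (the default front
#' threshold of [detect_front()]) sits exactly at the migration position of
#' `front_bp` under `calib`; the detected front is therefore analytically
#' exact on noiseless lanes.
#'
#' @param front_bp True maximum product size in bp.
#' @param calib Numeric `c(slope, intercept)` of the migration model.
#' @param noise_sd Gaussian intensity noise SD (0 for a noiseless lane).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param lane_length,n_positions Lane geometry.
#' @param ramp_width Width of the front edge in migration units.
#' @param plateau_width Width of the flat maximum behind the front.
#' @param peak Peak intensity.
#' @param baseline Constant background added to the whole lane.
#' @return A [lane_profile()].
#' @export
sim_gel_lane <- function(front_bp, calib = c(slope = -2.5, intercept = 4.5),
                         noise_sd = 0, seed = 1L, lane_length = 100,
                         n_positions = 1000L, ramp_width = 5,
                         plateau_width = 2, peak = 1000, baseline = 0) {
  stopifnot(front_bp > 0)
  slope <- calib[[1L]]; intercept <- calib[[2L]]
  rf_front <- (log10(front_bp) - intercept) / slope
  if (rf_front < 0 || rf_front > 1) stop("front_bp outside the calibrated range")
  x <- seq(0, lane_length, length.out = n_positions)
  x_front <- rf_front * lane_length
  x0 <- x_front - 0.05 * ramp_width            # 5%-of-peak crossing == x_front
  ramp <- pmin(pmax((x - x0) / ramp_width, 0), 1)
  xp <- x0 + ramp_width + plateau_width        # decay starts past the plateau
  decay <- ifelse(x > xp, exp(-(x - xp) / (0.25 * lane_length)), 1)
  intensity <- peak * ramp * decay + baseline
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    intensity <- pmax(intensity + stats::rnorm(n_positions, 0, noise_sd), 0)
  }
  lane_profile(x, intensity, lane_length = lane_length)
}

# ---------------------------------------------------------------------------
# Titration and mass-photometry simulation

#' Paired concentration/response observations from a binding titration
#'
#' @param concentration Nonnegative concentrations (molar units of choice).
#' @param response Matched responses (percent bound or polarization).
#' @param response_kind `"percent_bound"` or `"polarization"`.
#' @return A `TitrationCurve` object.
#' @export
titration_curve <- function(concentration, response,
                            response_kind = c("percent_bound",
                                              "polarization")) {
  response_kind <- match.arg(response_kind)
  if (length(concentration) != length(response)) {
    stop("concentration and response lengths differ")
  }
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  structure(list(concentration = as.numeric(concentration),
                 response = as.numeric(response),
                 response_kind = response_kind),
            class = "TitrationCurve")
}

#' One-site Hill binding model
#'
#' `response = baseline + amplitude * c^h / (Kd^h + c^h)`.
#'
#' @param conc Concentrations.
#' @param Kd Dissociation constant (> 0), same units as `conc`.
#' @param h Hill coefficient (> 0).
#' @param amplitude,baseline Response scale and offset.
#' @return Model responses.
#' @export
hill_response <- function(conc, Kd, h = 1, amplitude = 100, baseline = 0) {
  stopifnot(Kd > 0, h > 0)
  ch <- conc^h
  baseline + amplitude * ch / (Kd^h + ch)
}

#' Simulate a binding titration
#'
#' @param model `"one_site_hill"` (EMSA percent-bound) or `"fp_one_site"`
#'   (fluorescence polarization; Hill coefficient forced to 1).
#' @param params List with `Kd`, `h`, `amplitude`, `baseline`.
#' @param concentrations Concentration series.
#' @param noise_sd Gaussian response noise: the SD in response units when
#'   `noise_model = "additive"`, or the relative SD (fraction of the
#'   expected response) when `noise_model = "proportional"`. Densitometry
#'   errors scale with band intensity, so the proportional model is the
#'   realistic one for gel-derived percent-bound readouts.
#' @param noise_model Noise structure; default additive.
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return A [titration_curve()]; ground truth attached as attribute `truth`.
#' @export
sim_titration <- function(model = c("one_site_hill", "fp_one_site"), params,
                          concentrations, noise_sd = 0,
                          noise_model = c("additive", "proportional"),
                          seed = 1L) {
  model <- match.arg(model)
  noise_model <- match.arg(noise_model)
  h <- if (model == "fp_one_site") 1 else params$h %||% 1
  resp <- hill_response(concentrations, params$Kd, h,
                        params$amplitude %||% 100, params$baseline %||% 0)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    eps <- stats::rnorm(length(resp), 0, noise_sd)
    resp <- if (noise_model == "proportional") resp * (1 + eps)
            else resp + eps
  }
  curve <- titration_curve(concentrations, resp,
                           response_kind = if (model == "fp_one_site")
                             "polarization" else "percent_bound")
  attr(curve, "truth") <- list(model = model, Kd = params$Kd, h = h,
                               amplitude = params$amplitude %||% 100,
                               baseline = params$baseline %||% 0)
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate mass-photometry landing events
#'
#' Draws single-molecule masses from a Gaussian mixture.
#'
#' @param components data.frame with columns `mass` (kDa) and `weight`
#'   (mixture weights summing to 1).
#' @param sigma_kDa Common component SD in kDa (> 0).
#' @param n Number of events.
#' @param seed RNG seed.
#' @return Numeric vector of event masses (kDa).
#' @export
sim_mass_events <- function(components, sigma_kDa, n, seed = 1L) {
  stopifnot(is.data.frame(components), sigma_kDa > 0, n > 0)
  if (abs(sum(components$weight) - 1) > 1e-8) stop("weights must sum to 1")
  set.seed(as.integer(seed))
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$weight)
  stats::rnorm(n, mean = components$mass[comp], sd = sigma_kDa)
}

#' Write a simulation truth manifest as TSV
#' @param truth Any of the `*SimTruth` objects (a named list).
#' @param file Output path.
#' @export
write_truth_manifest <- function(truth, file) {
  flat <- vapply(truth, function(v) paste(format(v, trim = TRUE),
                                          collapse = ","), character(1))
  utils::write.table(data.frame(field = names(flat), value = flat),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
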