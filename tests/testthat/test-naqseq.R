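pairs_df <- function(r1, r2) {
  df <- data.frame(id = sprintf("p%d", seq_along(r1)), r1 = r1, r2 = r2,
                   stringsAsFactors = FALSE)
  class(df) <- c("ReadPairs", "data.frame")
  df
}

test_that("index tables enforce pairwise-distinct indices", {
  expect_s3_class(index_table(c(A = "AACCGGTT", B = "TTGGCCAA")), "IndexTable")
  expect_error(index_table(c(A = "AACCGGTT", B = "AACCGGTA")), "fewer than 2")
  expect_error(index_table(c(A = "AACC", B = "TTGGCCAA")), "same length")
  expect_error(index_table(character(0)), "non-empty")
})

test_that("demultiplexing requires the index on both mates and partitions input", {
  tab <- index_table(c(A = "AAAACCCC", B = "GGGGTTTT"))
  p <- pairs_df(
    r1 = c("AAAACCCCGATTACA", "AAAACCCCGATTACA", "GGGGTTTTGATTACA",
           "CCCCCCCCGATTACA"),
    r2 = c("AAAACCCCTGTAATC", "GGGGTTTTTGTAATC", "GGGGTTTTTGTAATC",
           "CCCCCCCCTGTAATC"))
  dm <- demultiplex(p, tab)
  expect_equal(dm$samples$A$id, "p1")        # both mates carry A
  expect_equal(dm$samples$B$id, "p3")
  expect_setequal(dm$discarded$id, c("p2", "p4"))  # mixed mates / no index
  n_assigned <- sum(vapply(dm$samples, nrow, integer(1)))
  expect_equal(n_assigned + nrow(dm$discarded), nrow(p))
  # one mismatch tolerated when requested
  p1 <- pairs_df("AAAACCCGGATTACA", "AAAACCCCTGTAATC")
  expect_equal(nrow(demultiplex(p1, tab, 0L)$samples$A), 0L)
  expect_equal(nrow(demultiplex(p1, tab, 1L)$samples$A), 1L)
  # empty input stays empty
  dm0 <- demultiplex(p[0, ], tab)
  expect_equal(nrow(dm0$discarded), 0L)
})

test_that("index trimming removes the 5' prefix and rejects short reads", {
  p <- pairs_df(strrep("A", 75), strrep("C", 75))
  out <- trim_index(p, 8L)
  expect_equal(nchar(out$r1), 67L)
  expect_equal(nchar(out$r2), 67L)
  expect_error(trim_index(pairs_df("ACGTACGT", "ACGTACGTA"), 8L), "shorter")
  # trimming twice on minimum-length reads errors rather than truncating
  expect_error(trim_index(trim_index(pairs_df(strrep("A", 16), strrep("C", 16)),
                                     8L), 8L), "shorter")
})

test_that("the mapper reproduces simulated fragment coordinates", {
  refs <- test_refs()
  tr <- naq_sim_truth(0.5, 400, index = "ACGTACGT", seed = 19,
                      control_fraction = 0.1)
  pairs <- sim_naq_readpairs(tr, refs)
  tru <- attr(pairs, "truth")
  idx <- build_ref_index(refs)
  frags <- map_pairs(trim_index(pairs, 8L), idx)
  rows <- attr(frags, "pair_rows")
  expect_gt(nrow(frags), 380)      # error-free reads map almost completely
  expect_equal(frags$reference, tru$reference[rows])
  expect_equal(frags$start, tru$start[rows])
  expect_equal(frags$length, tru$length[rows])
  expect_true(all(frags$end > frags$start))
})

test_that("mates from different references are rejected", {
  refs <- test_refs()
  tr <- naq_sim_truth(1, 20, index = "ACGTACGT", seed = 4,
                      control_fraction = 0)
  trS <- naq_sim_truth(0, 20, index = "ACGTACGT", seed = 4,
                       control_fraction = 0)
  pN <- trim_index(sim_naq_readpairs(tr, refs), 8L)
  pS <- trim_index(sim_naq_readpairs(trS, refs), 8L)
  chimera <- pairs_df(pN$r1, pS$r2)
  idx <- build_ref_index(refs)
  expect_equal(nrow(map_pairs(chimera, idx)), 0L)
})

test_that("origin-spanning fragments resolve with correct wrapped length", {
  refs <- test_refs()
  nick <- refs[[reference_roles(refs)[["nicked"]]]]
  L <- nchar(nick$sequence)
  doubled <- paste0(nick$sequence, nick$sequence)
  start0 <- L - 60L                      # fragment crosses the origin
  len <- 140L
  insert <- substr(doubled, start0 + 1L, start0 + len)
  r1 <- substr(insert, 1, 75)
  r2 <- revcomp(substr(insert, len - 74L, len))
  idx <- build_ref_index(refs)
  fr <- map_pairs(pairs_df(r1, r2), idx)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, start0)
  expect_equal(fr$length, len)
  expect_equal(fr$end, start0 + len)     # end past L marks the wrap
  # brute-force all-rotations oracle agrees
  oracle <- oracle_map_pair(r1, r2, refs)
  expect_equal(oracle$start, fr$start)
  expect_equal(oracle$length, fr$length)
})

test_that("mapper agrees with the brute-force scan on random error-free pairs", {
  refs <- test_refs()
  tr <- naq_sim_truth(0.4, 500, index = "ACGTACGT", seed = 77,
                      control_fraction = 0.1)
  pairs <- trim_index(sim_naq_readpairs(tr, refs), 8L)
  idx <- build_ref_index(refs)
  frags <- map_pairs(pairs, idx)
  rows <- attr(frags, "pair_rows")
  mapped <- setNames(vector("list", nrow(pairs)), NULL)
  for (j in seq_along(rows)) mapped[[rows[j]]] <- frags[j, ]
  for (i in seq_len(nrow(pairs))) {
    oracle <- oracle_map_pair(pairs$r1[i], pairs$r2[i], refs)
    got <- mapped[[i]]
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$reference, oracle$reference)
      expect_equal(got$start, oracle$start)
      expect_equal(got$length, oracle$length)
    }
  }
})

test_that("length selection keeps the closed 125-160 bp interval", {
  fr <- data.frame(reference = "x", start = 0L, end = 1L,
                   length = c(120L, 125L, 160L, 161L), unique = TRUE)
  sel <- length_select(fr)
  expect_equal(sel$length, c(125L, 160L))
  expect_equal(nrow(length_select(fr[0, ])), 0L)
  expect_error(length_select(fr, 200, 100), "lo")
  # composing windows equals intersecting them
  set.seed(12)
  fr2 <- data.frame(reference = "x", start = 0L, end = 1L,
                    length = sample(100:200, 200, replace = TRUE),
                    unique = TRUE)
  expect_equal(length_select(length_select(fr2, 110, 180), 125, 160)$length,
               length_select(fr2, 125, 160)$length)
  # widening the window never removes a fragment
  expect_true(all(length_select(fr2, 125, 160)$length %in%
                    length_select(fr2, 120, 170)$length))
})

test_that("percent nicked excludes the loading control", {
  roles <- c(nicked = "pN", supercoiled = "pS", loading_control = "lc")
  fr <- data.frame(reference = c(rep("pN", 50), rep("pS", 50), rep("lc", 30)))
  expect_equal(percent_nicked(fr, roles), 50)
  expect_equal(percent_nicked(fr[fr$reference != "lc", , drop = FALSE],
                              roles), 50)
  fr0 <- data.frame(reference = c("pS", rep("lc", 5)))
  expect_equal(percent_nicked(fr0, roles), 0)
  expect_error(percent_nicked(data.frame(reference = "lc"), roles),
               "no fragments")
})

test_that("control-normalized coverage is scale invariant and near uniform", {
  refs <- test_refs()
  roles <- reference_roles(refs)
  tr <- naq_sim_truth(1, 4000, index = "ACGTACGT", seed = 55,
                      control_fraction = 0)
  tru <- attr(sim_naq_readpairs(tr, refs), "truth")
  fr <- data.frame(reference = tru$reference, start = tru$start,
                   end = tru$start + tru$length, length = tru$length)
  L <- nchar(refs[[roles[["nicked"]]]]$sequence)
  cov1 <- control_normalized_coverage(fr, L, 100)
  cov2 <- control_normalized_coverage(rbind(fr, fr), L, 200)
  expect_equal(cov1, cov2)                       # doubling everything cancels
  expect_equal(control_normalized_coverage(fr[0, ], L, 10), numeric(L))
  # uniform placement -> flat coverage (CV small at this depth)
  expect_lt(sd(cov1) / mean(cov1), 0.2)
  expect_error(control_normalized_coverage(fr, L, 0), "control_count")
})

test_that("lane ratios behave as simple normalizations", {
  expect_equal(gel_band_quant(30, 60), 0.5)
  expect_equal(gel_band_quant(60, 60), 1)
  expect_equal(gel_band_quant(3 * 30, 3 * 60), 0.5)     # exposure cancels
  expect_error(gel_band_quant(1, 0), "control")
  expect_equal(fluorescence_fraction_nicked(1, 1), 50)
  expect_equal(fluorescence_fraction_nicked(1, 4), 20)
  expect_equal(fluorescence_fraction_nicked(0, 2), 0)
  expect_error(fluorescence_fraction_nicked(0, 0), "total")
})

test_that("the multiplexed pipeline summarises each sample correctly", {
  refs <- test_refs()
  tab <- index_table(c(S1 = "AACCGGTT", S2 = "TTGGCCAA"))
  truths <- list(
    naq_sim_truth(0.8, 800, index = "AACCGGTT", sample = "S1", seed = 61),
    naq_sim_truth(0.2, 800, index = "TTGGCCAA", sample = "S2", seed = 62))
  pairs <- sim_naq_readpairs(truths, refs)
  res <- naq_pipeline(pairs, refs, tab)
  expect_equal(res$sample, c("S1", "S2"))
  expect_equal(res$n_pairs, c(800L, 800L))
  expect_lt(abs(res$percent_nicked[1] - 80), 6)
  expect_lt(abs(res$percent_nicked[2] - 20), 6)
})
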