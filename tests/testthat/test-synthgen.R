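test_that("reference generation is deterministic, k-mer disjoint and validated", {
  refs1 <- gen_references(1, c(3000L, 3000L, 207L))
  refs2 <- gen_references(1, c(3000L, 3000L, 207L))
  expect_identical(vapply(refs1, `[[`, character(1), "sequence"),
                   vapply(refs2, `[[`, character(1), "sequence"))
  expect_setequal(vapply(refs1, `[[`, character(1), "role"),
                  c("nicked", "supercoiled", "loading_control"))

  # independent 31-mer disjointness check (both strands, circular wrap)
  kmers <- function(ref) {
    s <- if (ref$circular) paste0(ref$sequence, substr(ref$sequence, 1, 30))
         else ref$sequence
    n <- nchar(s) - 30L
    fwd <- substring(s, seq_len(n), seq_len(n) + 30L)
    c(fwd, as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd))))
  }
  sets <- lapply(refs1, kmers)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_length(intersect(sets[[1]], sets[[3]]), 0)
  expect_length(intersect(sets[[2]], sets[[3]]), 0)

  expect_error(gen_references(1, c(100L, 3000L, 207L)), "500")
  expect_error(plasmid_reference("x", "ACGN"), "alphabet")
  expect_error(reference_set(refs1[[1]], refs1[[2]]), "role")
})

test_that("simulated NAQ read pairs hit the requested nicked fraction", {
  refs <- test_refs()
  roles <- reference_roles(refs)
  tr <- naq_sim_truth(0.5, 20000, index = "ACGTACGT", seed = 7,
                      control_fraction = 0.05)
  pairs <- sim_naq_readpairs(tr, refs)
  tru <- attr(pairs, "truth")
  plasmid <- tru$reference != roles[["loading_control"]]
  frac <- mean(tru$reference[plasmid] == roles[["nicked"]])
  se <- sqrt(0.25 / sum(plasmid))
  expect_lt(abs(frac - 0.5), 3 * se)

  # boundary fractions
  tr0 <- naq_sim_truth(0, 2000, index = "ACGTACGT", seed = 3)
  tru0 <- attr(sim_naq_readpairs(tr0, refs), "truth")
  expect_equal(sum(tru0$reference == roles[["nicked"]]), 0)
  tr1 <- naq_sim_truth(1, 2000, index = "ACGTACGT", seed = 3)
  tru1 <- attr(sim_naq_readpairs(tr1, refs), "truth")
  non_ctrl <- tru1$reference != roles[["loading_control"]]
  expect_true(all(tru1$reference[non_ctrl] == roles[["nicked"]]))

  # bit-reproducible under a fixed seed
  p1 <- sim_naq_readpairs(tr, refs)
  expect_identical(p1$r1, pairs$r1)
  expect_identical(p1$r2, pairs$r2)
})

test_that("simulated reads carry the index and read back through FASTQ", {
  refs <- test_refs()
  tr <- naq_sim_truth(0.5, 200, index = "TTGGCCAA", seed = 9)
  pairs <- sim_naq_readpairs(tr, refs)
  expect_true(all(startsWith(pairs$r1, "TTGGCCAA")))
  expect_true(all(startsWith(pairs$r2, "TTGGCCAA")))
  # mate lengths: index + min(read_length, fragment length)
  tru <- attr(pairs, "truth")
  expect_equal(nchar(pairs$r1), 8L + pmin(75L, tru$length))

  r1f <- tempfile(fileext = ".fastq"); r2f <- tempfile(fileext = ".fastq")
  write_fastq_pairs(pairs, r1f, r2f)
  back <- read_fastq_pairs(r1f, r2f)
  expect_equal(back$r1, pairs$r1)
  expect_equal(back$r2, pairs$r2)
})

test_that("SCAR simulation obeys depth, scaling and symmetry contracts", {
  truth <- scar_sim_truth(n_bins = 2000L, iz_positions = c(500L, 1500L),
                          partition_amplitude = 0, depth = 50,
                          sample_scale_factors = c(A = 1, B = 0.5),
                          seed = 21)
  sim <- sim_scar_samples(truth)
  a <- sim$A; b <- sim$B
  # per-bin totals Poisson at the stated mean
  tot <- a$pulldown$F + a$pulldown$R
  expect_lt(abs(mean(tot) - 50), 3 * sqrt(50 / 2000))
  expect_lt(abs(var(tot) / mean(tot) - 1), 0.15)
  # constant spike-in, scaled target totals -> normalized ratio A/B = 2
  expect_identical(a$spikein, b$spikein)
  norm <- spikein_normalize(list(A = c(a$target_total, a$spikein),
                                 B = c(b$target_total, b$spikein)), "B")
  expect_lt(abs(norm[["A"]] - 2), 0.1)
  # zero asymmetry: F and R exchangeable in aggregate
  z <- (sum(a$pulldown$F) - sum(a$pulldown$R)) /
    sqrt(sum(a$pulldown$F) + sum(a$pulldown$R))
  expect_lt(abs(z), 4)
})

test_that("titration simulation matches the closed-form model", {
  conc <- c(0, 10^seq(-2, 1, length.out = 9))
  cv <- sim_titration("one_site_hill",
                      list(Kd = 0.5, h = 2, amplitude = 80, baseline = 10),
                      conc, noise_sd = 0)
  expect_equal(cv$response, 10 + 80 * conc^2 / (0.5^2 + conc^2))
  expect_equal(cv$response[1], 10)                       # c = 0 -> baseline
  half <- sim_titration("one_site_hill",
                        list(Kd = 0.5, h = 2, amplitude = 80, baseline = 10),
                        c(0.5, 0.5, 0.5, 1, 2), noise_sd = 0)
  expect_equal(half$response[1], 10 + 40)                # half-saturation
  # FP model forces h = 1
  fp <- sim_titration("fp_one_site", list(Kd = 5, h = 3, amplitude = 100,
                                          baseline = 50), conc)
  expect_equal(attr(fp, "truth")$h, 1)
  # proportional noise scales with the expected response
  noisy <- sim_titration("one_site_hill",
                         list(Kd = 0.5, h = 1, amplitude = 100, baseline = 0),
                         conc, noise_sd = 0.05,
                         noise_model = "proportional", seed = 4)
  expect_equal(noisy$response[1], 0)                     # zero signal stays zero
})

test_that("mass-photometry event simulation recovers mixture weights", {
  tight <- sim_mass_events(data.frame(mass = 190, weight = 1),
                           sigma_kDa = 1e-6, n = 50, seed = 2)
  expect_true(all(abs(tight - 190) < 1e-3))
  ev <- sim_mass_events(data.frame(mass = c(190, 430), weight = c(0.7, 0.3)),
                        sigma_kDa = 10, n = 5000, seed = 8)
  w_hat <- mean(ev < 310)
  expect_lt(abs(w_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 5000))
  expect_identical(ev, sim_mass_events(data.frame(mass = c(190, 430),
                                                  weight = c(0.7, 0.3)),
                                       sigma_kDa = 10, n = 5000, seed = 8))
  expect_error(sim_mass_events(data.frame(mass = 1, weight = 0.5), 1, 10),
               "sum to 1")
})

test_that("simulated gel lanes place the product front analytically", {
  calib <- c(slope = -2.5, intercept = 4.5)
  lane <- sim_gel_lane(3000, calib, noise_sd = 0)
  x_expected <- (log10(3000) - 4.5) / -2.5 * 100
  expect_equal(detect_front(lane), x_expected, tolerance = 1e-8)
  # monotone: larger products migrate less (smaller front position)
  f2 <- detect_front(sim_gel_lane(2000, calib))
  f4 <- detect_front(sim_gel_lane(4000, calib))
  expect_gt(f2, f4)
  # seeded noise: recovered within one ladder-interpolation step
  noisy <- sim_gel_lane(3000, calib, noise_sd = 10, seed = 5)
  clean <- subtract_background_minprofile(noisy)
  lad <- sim_gel_ladder(calib)
  cal <- fit_ladder(lad$position, lad$size, 100)
  bp_hat <- position_to_bp(cal, detect_front(clean))
  neighbours <- sort(abs(lad$size - 3000))
  expect_lt(abs(bp_hat - 3000), neighbours[2])
})
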