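# Context profiler: incorporated-base counting, position probability
# matrices, amino-acid sampling, primer anchoring, replicate concordance.

test_that("incorporated bases are hand-countable: sense G tallies as cDNA C", {
  tr <- toy_template()  # GACG, one annotated adenine in GAC
  reads <- reads_of(rep("GGCG", 3), rep("GACG", 7))
  prof <- count_incorporations(reads, tr)
  expect_equal(unname(prof$frequencies["GAC", "C"]), 0.30)
  expect_equal(unname(prof$frequencies["GAC", "T"]), 0.70)
  expect_equal(unname(prof$totals["GAC"]), 10)
  expect_equal(prof$pooled_rate, 0.30)
})

test_that("zero-error reads give 100% cognate T incorporation everywhere", {
  tr <- design_nan_template(1)
  rs <- simulate_cdna_reads(tr, misincorporation_model(p = 0), 100, seed = 1)
  prof <- count_incorporations(rs, tr)
  expect_true(all(prof$frequencies[, "T"] == 1))
  expect_equal(prof$pooled_rate, 0)
})

test_that("counts are conserved and the sense-space view is an involution", {
  tr <- design_nan_template(1)
  rs <- simulate_cdna_reads(tr, misincorporation_model(0.4), 500, seed = 2)
  prof <- count_incorporations(rs, tr)
  census <- context_census(tr)
  expect_equal(unname(prof$totals[names(census)]), unname(census) * 500)
  expect_equal(rowSums(prof$frequencies), rep(1, nrow(prof$frequencies)),
               ignore_attr = TRUE)
  round_trip <- as_sense_profile(as_sense_profile(prof))
  expect_equal(round_trip$counts, prof$counts)
  expect_error(count_incorporations(reads_of("ACGTACGT"), tr), "length-matched")
})

test_that("per-context model parameters are recovered within binomial error", {
  tr <- design_nan_template(1)
  n <- 20000
  spec <- c(C = 0.593, G = 0.264, A = 0.143)
  m <- misincorporation_model(0.3065, spec)
  prof <- count_incorporations(simulate_cdna_reads(tr, m, n, seed = 5), tr)
  n_obs <- sum(prof$counts)
  sigma_rate <- sqrt(0.3065 * (1 - 0.3065) / n_obs)
  expect_lt(abs(prof$pooled_rate - 0.3065), 3 * sigma_rate)
  shares <- misincorporation_spectrum(prof)
  n_mis <- sum(prof$counts[, c("A", "C", "G")])
  for (b in names(spec)) {
    sigma <- sqrt(spec[b] * (1 - spec[b]) / n_mis)
    expect_lt(abs(shares[b] - spec[b]), 3 * sigma)
  }
})

test_that("position probability matrix rows are unit simplices", {
  tr <- design_nan_template(1)
  one <- reads_of(tr$sequence)
  ppm1 <- position_ppm(one, tr)
  expect_true(all(apply(ppm1, 1, max) == 1))  # unit vectors
  rs <- simulate_cdna_reads(tr, misincorporation_model(0.3065), 5000, seed = 3)
  ppm <- position_ppm(rs, tr)
  expect_equal(rowSums(ppm), rep(1, nrow(ppm)), ignore_attr = TRUE,
               tolerance = 1e-9)
  # adenine rows stay A with probability ~ 1 - p
  offs <- as.integer(names(tr$contexts))
  pa <- ppm[as.character(offs), "A"]
  sigma <- sqrt(0.6935 * 0.3065 / 5000)
  expect_true(all(abs(pa - 0.6935) < 4 * sigma))
  expect_error(position_ppm(reads_of("ACGT"), tr), "length-matched")
})

test_that("amino-acid sampling translates observed codons correctly", {
  tr <- template_repeat("GGAACGG", id = "frame")  # AAC codon at offset 2
  unmut <- reads_of(rep("GGAACGG", 10))
  sp <- aa_sampling(unmut, tr, frame_offset = 2)
  expect_identical(names(sp$by_codon), "AAC")
  expect_equal(unname(sp$by_codon$AAC["N"]), 1)  # Asn
  forced <- reads_of(rep("GGTACGG", 10))  # AAC -> TAC
  sp2 <- aa_sampling(forced, tr, frame_offset = 2)
  expect_equal(unname(sp2$by_codon$AAC["Y"]), 1)  # Tyr
  expect_error(aa_sampling(unmut, tr, frame_offset = 0), "no in-frame AAN")
})

test_that("stop-codon sampling at an AAA codon matches the analytic rate", {
  tr <- template_repeat("GGAAAGG", id = "stopframe")
  n <- 20000
  rs <- simulate_cdna_reads(tr, misincorporation_model(0.3065), n, seed = 11)
  sp <- aa_sampling(rs, tr, frame_offset = 2)
  p_stop <- stop_conversion("AAA", 0.3065)
  got <- sp$by_codon$AAA["*"]
  sigma <- sqrt(p_stop * (1 - p_stop) / n)
  expect_lt(abs(got - p_stop), 3 * sigma)
})

test_that("primer anchoring trims exactly and rejects with reasons", {
  tr <- toy_template()
  fwd <- "TTCCGGAA"
  rev <- "CCTTGGAA"  # appears in read as its reverse complement
  good <- paste0(fwd, tr$sequence, dna_revcomp_for_tests(rev))
  hit <- anchor_and_trim(good, tr, c(fwd, rev))
  expect_identical(hit$status, "ok")
  expect_identical(hit$segment, tr$sequence)
  no_f <- anchor_and_trim(paste0("GGGGGGGG", tr$sequence,
                                 dna_revcomp_for_tests(rev)),
                          tr, c(fwd, rev), max_mismatch = 0)
  expect_identical(no_f$status, "no_anchor")
  del <- paste0(fwd, substr(tr$sequence, 1, 2), substr(tr$sequence, 4, 4),
                dna_revcomp_for_tests(rev))  # 1-nt deletion
  expect_identical(anchor_and_trim(del, tr, c(fwd, rev))$status,
                   "length_mismatch")
  set <- read_set(c(good, del, "AAAATTTTCCCCGGGG"))
  res <- anchor_and_trim_set(set, tr, c(fwd, rev))
  expect_equal(length(res$reads), 1)
  expect_equal(unname(res$rejections["length_mismatch"]), 1)
  expect_equal(unname(res$rejections["no_anchor"]), 1)
})

test_that("replicate profiles concord and deliberate contrasts are flagged", {
  tr <- design_nan_template(1)
  m <- misincorporation_model(0.3065)
  p1 <- count_incorporations(simulate_cdna_reads(tr, m, 20000, seed = 1), tr)
  p2 <- count_incorporations(simulate_cdna_reads(tr, m, 20000, seed = 2), tr)
  expect_true(all(profile_concordance(list(p1, p1)) == 0))
  dev <- profile_concordance(list(p1, p2))
  expect_lt(max(dev), 0.02)
  # shift one context's p drastically in a third profile
  p_ctx <- stats::setNames(rep(0.3065, 16), nan_contexts())
  p_ctx["GAC"] <- 0.9
  m3 <- misincorporation_model(p_ctx)
  p3 <- count_incorporations(simulate_cdna_reads(tr, m3, 20000, seed = 3), tr)
  dev3 <- profile_concordance(list(p1, p3))
  expect_identical(names(which.max(dev3)), "GAC")
  bad <- p1
  rownames(bad$frequencies) <- rev(rownames(bad$frequencies))
  expect_error(profile_concordance(list(p1, structure(list(
    frequencies = p1$frequencies[1:4, ]), class = "context_profile"))),
    "identical context keys")
})

test_that("subsampled frequency estimates track the full set", {
  tr <- design_nan_template(1)
  rs <- simulate_cdna_reads(tr, misincorporation_model(0.3065), 20000, seed = 4)
  half <- subsample(rs, 10000, seed = 1)
  full_rate <- count_incorporations(rs, tr)$pooled_rate
  half_rate <- count_incorporations(half, tr)$pooled_rate
  n_obs <- sum(context_census(tr)) * 10000
  sigma <- sqrt(full_rate * (1 - full_rate) / n_obs)
  expect_lt(abs(half_rate - full_rate), 3 * sigma)
})
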