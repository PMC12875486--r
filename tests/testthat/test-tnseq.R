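# Tn-seq processing and enrichment: trimming, mapping, RPM, Mann-Whitney,
# hit calling, origin recentering, orientation preference.

test_that("read preprocessing trims the junction and counts rejections", {
  junction <- "AAGAGACAG"
  genomic30 <- strrep("ACGTA", 6)
  genomic24 <- substr(genomic30, 1, 24)
  rs <- read_set(c(
    paste0("TTT", junction, genomic30),            # kept, 30 nt
    paste0(junction, genomic24),                   # too short: 24 nt
    paste0("CCCC", genomic30),                     # no junction
    paste0("TT", junction, genomic30, strrep("G", 12))  # poly-G stripped
  ))
  res <- preprocess_reads(rs)
  expect_equal(length(res$reads), 2)
  expect_identical(res$reads$sequences, c(genomic30, genomic30))
  expect_equal(unname(res$rejections["too_short"]), 1)
  expect_equal(unname(res$rejections["no_junction"]), 1)
  # a 25-nt remainder is exactly long enough
  res25 <- preprocess_reads(read_set(paste0(junction, substr(genomic30, 1, 25))))
  expect_equal(length(res25$reads), 1)
})

test_that("the exact-prefix mapper keeps unique hits and discards ambiguity", {
  left <- strrep("ACGT", 250)
  uniq1 <- "GATCCATTACGGATCCAGTTCAGGA"   # 25 nt, unique
  mid <- strrep("TTGCA", 40)
  dup <- "CCATGGTACCATGGAATTCCTGCAG"     # 25 nt, planted twice
  genome_seq <- paste0(left, uniq1, mid, dup, strrep("GA", 100), dup,
                       strrep("CT", 60))
  g <- tn_genome(nchar(genome_seq), oric = 0,
                 genes = data.frame(name = "g1", start = 0, end = 100,
                                    strand = "+"),
                 sequence = genome_seq)
  pos_uniq <- nchar(left)  # 0-based
  reads <- read_set(c(uniq1, uniq1, dna_revcomp_for_tests(uniq1), dup,
                      "AAAAACCCCCGGGGGTTTTTAAAAA"))
  lib <- map_insertions(reads, g)
  expect_equal(nrow(lib$sites), 2)
  plus <- lib$sites[lib$sites$strand == "+", ]
  minus <- lib$sites[lib$sites$strand == "-", ]
  expect_equal(plus$position, pos_uniq)
  expect_equal(plus$count, 2L)    # duplicate reads aggregate
  expect_equal(minus$position, pos_uniq)  # rc maps to same leftmost coordinate
  expect_error(map_insertions(read_set("ACGT"), g), "at least k")
  g_noseq <- tn_genome(1000, 0, data.frame(name = "g", start = 0, end = 10,
                                           strand = "+"))
  expect_error(map_insertions(reads, g_noseq), "no sequence")
})

test_that("simulated libraries round-trip through reads, trimming and mapping", {
  g <- toy_tn_genome(length = 50000, n_genes = 5, gene_length = 5000,
                     sequence_seed = 2)
  sim <- simulate_tnseq(g, selection_model(), 200, 5000, seed = 5)
  for (lib in list(sim$input, sim$output)) {
    pp <- preprocess_reads(tnseq_reads(lib, g))
    expect_equal(sum(pp$rejections), 0)
    mapped <- map_insertions(pp$reads, g, label = lib$label)
    want <- lib$sites[lib$sites$count > 0, ]
    want <- want[order(want$position, want$strand), ]
    got <- mapped$sites[order(mapped$sites$position, mapped$sites$strand), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("SAM ingestion keeps primary MAPQ-60 records only", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq25 <- strrep("ACGTA", 5)
  qual <- strrep("I", 25)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:toy\tLN:1000",
    sprintf("r1\t0\ttoy\t101\t60\t25M\t*\t0\t0\t%s\t%s", seq25, qual),
    sprintf("r2\t16\ttoy\t201\t60\t25M\t*\t0\t0\t%s\t%s", seq25, qual),
    sprintf("r3\t0\ttoy\t301\t30\t25M\t*\t0\t0\t%s\t%s", seq25, qual),
    sprintf("r4\t256\ttoy\t401\t60\t25M\t*\t0\t0\t*\t*"),
    sprintf("r5\t0\ttoy\t101\t60\t25M\t*\t0\t0\t%s\t%s", seq25, qual)
  ), sam)
  lib <- read_sam_insertions(sam, mapq = 60, genome_length = 1000)
  expect_equal(lib$total_reads, 3L)
  expect_equal(nrow(lib$sites), 2)
  plus <- lib$sites[lib$sites$strand == "+", ]
  expect_equal(plus$position, 100L)  # SAM 1-based -> 0-based
  expect_equal(plus$count, 2L)
  expect_equal(lib$sites$position[lib$sites$strand == "-"], 200L)
})

test_that("RPM normalisation is exact and scale invariant", {
  lib <- insertion_library(c(10, 20, 30), c("+", "-", "+"), c(1, 1, 2))
  rpm <- normalize_rpm(lib)$sites$rpm
  expect_equal(rpm, c(250000, 250000, 500000))
  expect_equal(sum(rpm), 1e6)
  lib10 <- insertion_library(c(10, 20, 30), c("+", "-", "+"), c(10, 10, 20))
  expect_equal(normalize_rpm(lib10)$sites$rpm, rpm)
  single <- insertion_library(5, "+", 7)
  expect_equal(normalize_rpm(single)$sites$rpm, 1e6)
  empty <- insertion_library(integer(0), character(0), integer(0))
  expect_error(normalize_rpm(empty), "zero total")
})

test_that("Mann-Whitney U and exact p match exhaustive enumeration (n+m <= 12)", {
  set.seed(42)  # test-local case generation only
  for (N in 2:12) {
    for (n in 1:(N - 1)) {
      m <- N - n
      # tie-free case: exact p path
      x <- sample(seq_len(100), n)
      y <- sample(setdiff(seq_len(100), x), m)
      got <- mw_test(x, y)
      oracle <- mw_oracle(x, y)
      expect_equal(got$u, oracle$u)
      expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
      # tied case: U must still match pair counting
      xt <- sample(1:3, n, replace = TRUE)
      yt <- sample(1:3, m, replace = TRUE)
      expect_equal(mw_test(xt, yt, exact = FALSE)$u, mw_oracle(xt, yt)$u)
    }
  }
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(7)
  x <- rnorm(15)
  y <- rnorm(20, 0.5)
  got <- mw_test(x, y, exact = FALSE)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  gote <- mw_test(x, y, exact = TRUE)
  refe <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(gote$p_value, refe$p.value, tolerance = 1e-12)
})

test_that("gene enrichment reproduces a hand-built contrast", {
  g <- tn_genome(1000, 0,
                 genes = data.frame(name = "gA", start = 0, end = 500,
                                    strand = "+"))
  pos <- c(10, 110, 210, 310, 410)
  input <- insertion_library(pos, rep("+", 5), rep(10, 5), "Input", 1000)
  output <- insertion_library(pos, rep("+", 5), rep(105, 5), "Output", 1000)
  enr <- gene_enrichment(input, output, g, min_sites = 5)
  # both libraries RPM-normalise to 1e6, so pooled RPM is equal and the
  # smoothed fold change is 1 by construction of a single-gene genome
  expect_equal(enr$fold_change, 1, tolerance = 1e-12)
  # a second, neutral gene makes the contrast visible
  g2 <- tn_genome(1000, 0,
                  genes = data.frame(name = c("gA", "gB"),
                                     start = c(0, 500), end = c(500, 1000),
                                     strand = c("+", "+")))
  pos_b <- c(510, 610, 710, 810, 910)
  input2 <- insertion_library(c(pos, pos_b), rep("+", 10), rep(10, 10),
                              "Input", 1000)
  output2 <- insertion_library(c(pos, pos_b), rep("+", 10),
                               c(rep(105, 5), rep(10, 5)), "Output", 1000)
  enr2 <- gene_enrichment(input2, output2, g2, min_sites = 5)
  a <- enr2[enr2$gene == "gA", ]
  # Input gA RPM: 5e5; Output gA RPM: 105/115 * 1e6
  expect_equal(a$fold_change, (105 / 115 * 1e6 + 0.5) / (5e5 + 0.5),
               tolerance = 1e-12)
  expect_equal(a$u_stat, 25)  # all output sites exceed all input sites
  expect_lt(a$p_value, 0.05)
})

test_that("identical libraries are null: fold change 1, p near 1", {
  g <- toy_tn_genome(length = 1e5, n_genes = 10, gene_length = 5000)
  sim <- simulate_tnseq(g, selection_model(), 300, 30000, seed = 4)
  enr <- gene_enrichment(sim$input, sim$input, g)
  expect_equal(enr$fold_change, rep(1, nrow(enr)), tolerance = 1e-12)
  expect_true(all(enr$p_value >= 0.99))
})

test_that("hit calling applies fold-change and p thresholds jointly", {
  enr <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    fold_change = c(10.5, 1.9, 4.0, 0.4, 3.0),
                    p_value = c(0.003, 0.001, 0.06, 0.01, 0.02),
                    eligible = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  got <- call_hits(enr)
  expect_identical(got$hit, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  up_only <- call_hits(enr, direction = "up")
  expect_identical(up_only$hit, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  stringent <- call_hits(data.frame(gene = "x", fold_change = 3,
                                    p_value = 0.001, eligible = TRUE),
                         preset = "stringent")
  expect_false(stringent$hit)  # 3-fold misses the 4-fold line
  expect_error(call_hits(enr, fc_threshold = -1), "positive")
})

test_that("origin recentering is the stated signed offset and a bijection", {
  g <- tn_genome(4000000, oric = 3900000,
                 genes = data.frame(name = "g", start = 0, end = 10,
                                    strand = "+"))
  rc <- recenter_oric(100000, "+", g)
  expect_equal(rc$d, 200000)  # wraps across the linearisation point
  expect_equal(recenter_oric(3900000, "+", g)$d, 0)
  expect_equal(recenter_oric(3900000, "-", g)$d, 0)
  # modular-arithmetic oracle on a 1000-bp toy genome: bijective onto
  # [-L/2, L/2)
  toy <- tn_genome(1000, oric = 313,
                   genes = data.frame(name = "g", start = 0, end = 10,
                                      strand = "+"))
  all_pos <- 0:999
  d <- recenter_oric(all_pos, rep("+", 1000), toy)$d
  expect_equal(sort(d), seq(-500, 499))
  expect_equal(length(unique(d)), 1000)
  oracle <- ((all_pos - 313 + 500) %% 1000) - 500
  expect_equal(d, oracle)
  # orientation classes by definition
  expect_identical(recenter_oric(313, "+", toy)$orientation, "away")
  expect_identical(recenter_oric(350, "+", toy)$orientation, "away")
  expect_identical(recenter_oric(350, "-", toy)$orientation, "toward")
  expect_identical(recenter_oric(300, "-", toy)$orientation, "away")
  expect_identical(recenter_oric(300, "+", toy)$orientation, "toward")
  expect_error(recenter_oric(1000, "+", toy), "positions")
})

test_that("orientation preference separates orientation from copy number", {
  g <- toy_tn_genome(length = 2e5, n_genes = 10, gene_length = 5000)
  # copy gradient only: enrichment falls with |d| but away/toward ratio ~ 1
  sim_cg <- simulate_tnseq(g, selection_model(copy_gradient = 4), 1000, 1e5,
                           seed = 6)
  op_cg <- orientation_preference(sim_cg$input, sim_cg$output, g, n_bins = 4)
  ratios <- op_cg$bins$away_toward_ratio
  expect_true(all(abs(log(ratios)) < log(1.5)))
  expect_false(op_cg$summary$strand_flips)
  inner <- op_cg$bins$away_enrichment[2:3]
  outer_bins <- op_cg$bins$away_enrichment[c(1, 4)]
  expect_gt(mean(inner), mean(outer_bins))
  # orientation factor only: away preferred in every bin, strand flips at oriC
  sim_or <- simulate_tnseq(g, selection_model(orientation_factor = 5), 1000,
                           1e5, seed = 7)
  op_or <- orientation_preference(sim_or$input, sim_or$output, g, n_bins = 4)
  expect_true(all(op_or$bins$away_toward_ratio > 1))
  expect_true(op_or$summary$strand_flips)
  expect_error(orientation_preference(sim_or$input, sim_or$output, g, 3),
               "even")
})

test_that("insertion CSV and gene TSV round trips preserve content", {
  lib <- insertion_library(c(5, 100), c("+", "-"), c(3, 9), "Input")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_insertions(lib, csv)
  back <- read_insertions(csv, label = "Input")
  expect_equal(back$sites, lib$sites)
  expect_equal(back$total_reads, lib$total_reads)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  genes <- data.frame(name = c("a", "b"), start = c(0, 50), end = c(10, 99),
                      strand = c("+", "-"))
  write.table(genes, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_gene_table(tsv), genes)
})
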