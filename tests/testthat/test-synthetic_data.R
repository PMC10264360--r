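test_that("genome truth is a pure, structurally valid function of its seed", {
  t1 <- gen_genome_truth(n_chrom = 4, seed = 5)
  t2 <- gen_genome_truth(n_chrom = 4, seed = 5)
  expect_identical(t1$units, t2$units)
  expect_identical(t1$chrom_lengths, t2$chrom_lengths)
  expect_false(identical(t1$units, gen_genome_truth(n_chrom = 4,
                                                    seed = 6)$units))
  # per-chromosome unit counts inside the configured range
  counts <- table(t1$units$chrom)
  expect_true(all(counts >= 7 & counts <= 11))
  # unit lengths within the truncation bounds
  lens <- t1$units$end - t1$units$start
  expect_true(all(lens >= 0.24e6 & lens <= 4.46e6))
  # units are sorted and disjoint per chromosome
  expect_equal(as_domain_set(t1$units)[, c("chrom", "start", "end")],
               t1$units[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
})

test_that("degenerate distributions give exact chromosome arithmetic", {
  t0 <- gen_genome_truth(n_chrom = 3, units_per_chrom = c(4, 4),
                         unit_len_mean = 2e6, unit_len_sdlog = 0,
                         unit_len_range = c(1e6, 3e6),
                         gap_mean = 8e6, gap_sd = 0, seed = 1)
  # k units of L with (k+1) gaps of G -> chrom length kL + (k+1)G
  expect_true(all(t0$chrom_lengths == 4 * 2e6 + 5 * 8e6))
  lens <- t0$units$end - t0$units$start
  expect_true(all(lens == 2e6))
  gaps <- unit_stats(t0$units, t0$chrom_lengths)$gaps
  expect_true(all(gaps == 8e6))
})

test_that("sample means approach the configured means for large n", {
  t1 <- gen_genome_truth(n_chrom = 120, seed = 31)
  lens <- t1$units$end - t1$units$start
  st <- unit_stats(t1$units, t1$chrom_lengths)
  # ~1000 units: means within 10% of the configured regime
  expect_gt(length(lens), 800)
  expect_equal(mean(lens), 1.89e6, tolerance = 0.1)
  expect_equal(mean(st$gaps), 9.97e6, tolerance = 0.1)
})

test_that("fragmentation is recoverable by construction", {
  truth <- gen_genome_truth(n_chrom = 3, seed = 8)
  # zero break rate: raw equals truth
  raw0 <- fragment_truth(truth, break_rate = 0, seed = 9)
  expect_equal(raw0, truth$units, ignore_attr = TRUE)
  # seeded fragmentation: all interruptions below the merge threshold,
  # all pieces at least 1 kb, and the caller recovers the truth exactly
  raw <- fragment_truth(truth, break_rate = 3, seed = 10)
  expect_identical(raw, fragment_truth(truth, break_rate = 3, seed = 10))
  expect_true(all(raw$end - raw$start >= 1000))
  recovered <- call_units(raw)
  expect_equal(recovered, truth$units, ignore_attr = TRUE)
  # interruption gaps are all below 500 kb
  for (ch in unique(raw$chrom)) {
    r <- raw[raw$chrom == ch, ]
    tr <- truth$units[truth$units$chrom == ch, ]
    gaps <- r$start[-1] - r$end[-nrow(r)]
    # gaps inside units < 500 kb; gaps between units are the truth gaps
    small <- gaps[gaps < 5e5]
    expect_equal(length(small), nrow(r) - nrow(tr))
  }
  # infeasible parameters are rejected
  expect_error(fragment_truth(truth, interruption_len = c(1e3, 6e5)),
               "recoverable")
  expect_error(fragment_truth(truth, min_piece = 100), "recoverable")
})

test_that("two-caller noise model honours its intersection guarantees", {
  truth <- gen_genome_truth(n_chrom = 2, seed = 12)
  raw <- fragment_truth(truth, break_rate = 1, seed = 13)
  # zero noise: both callers equal the raw set
  cl0 <- gen_two_callers(raw, truth$chrom_lengths, seed = 14)
  expect_equal(cl0$a, raw, ignore_attr = TRUE)
  expect_equal(cl0$b, raw, ignore_attr = TRUE)
  # false positives only: caller-specific, so the intersection is still raw
  clfp <- gen_two_callers(raw, truth$chrom_lengths, fp_rate = 1, seed = 15)
  expect_gt(nrow(clfp$a), nrow(raw))
  expect_equal(intersect_callers(clfp$a, clfp$b), raw, ignore_attr = TRUE)
  # reproducible under seed
  clfp2 <- gen_two_callers(raw, truth$chrom_lengths, fp_rate = 1, seed = 15)
  expect_identical(clfp$a, clfp2$a)
  # with jitter and drop-outs the callers genuinely differ
  cln <- gen_two_callers(raw, truth$chrom_lengths, boundary_jitter = 2000,
                         fn_rate = 0.1, seed = 16)
  expect_false(identical(cln$a, cln$b))
})

test_that("genes stay clear of units by the configured offset", {
  truth <- gen_genome_truth(n_chrom = 2, seed = 18)
  g <- gen_genes(truth, density = 5, min_offset = 2e4, seed = 19)
  expect_gt(nrow(g), 0)
  st <- unit_stats(truth$units, truth$chrom_lengths, genes = g)
  expect_gte(st$mean_nearest_gene_distance, 2e4)
  # per-gene check against every unit
  gr_dist <- function(a, b) {
    if (a$end <= b$start) b$start - a$end else
      if (b$end <= a$start) a$start - b$end else 0
  }
  for (r in seq_len(min(nrow(g), 40))) {
    for (u in seq_len(nrow(truth$units))) {
      if (g$chrom[r] != truth$units$chrom[u]) next
      expect_gte(gr_dist(g[r, ], truth$units[u, ]), 2e4)
    }
  }
  # density 0 -> empty
  expect_equal(nrow(gen_genes(truth, density = 0, seed = 20)), 0)
  # min_offset 0 allows abutting genes
  g0 <- gen_genes(truth, density = 5, min_offset = 0, seed = 21)
  expect_gt(nrow(g0), 0)
})

test_that("planted dyads round-trip through the scanner", {
  m <- gen_monomer_with_dyads(40, planted = list(c(4, 2, 6)), seed = 22)
  d <- find_dyads(m, min_arm = 4, max_loop = 4)
  expect_true(any(d$left_start == 6 & d$arm_len == 4 & d$loop_len == 2))
  # junction arm: the dimer carries a junction dyad of exactly that arm
  mj <- gen_monomer_with_dyads(28, junction_arm = 8, seed = 23)
  dj <- dimer_hairpin(mj, arm_len = 8, max_loop = 4)
  expect_true(any(dj$arm_len == 8 & dj$loop_len == 0))
  # single-letter alphabet: no dyads anywhere
  ma <- gen_monomer_with_dyads(30, alphabet = "A", seed = 24)
  expect_equal(nrow(find_dyads(ma, min_arm = 2, max_loop = 6)), 0)
  # generators are pure functions of (parameters, seed)
  expect_identical(gen_monomer_with_dyads(40, planted = list(c(4, 2, 6)),
                                          seed = 22), m)
})

test_that("the fixture tree materialises in standard formats", {
  dir <- file.path(tempdir(), "holosim-fixtures")
  make_fixtures(dir, seed = 2, n_chrom = 2)
  expect_true(file.exists(file.path(dir, "truth_units.bed")))
  truth <- read_bed(file.path(dir, "truth_units.bed"))
  raw <- read_bed(file.path(dir, "raw_peaks.bed"))
  a <- read_bed(file.path(dir, "caller_a.bed"))
  b <- read_bed(file.path(dir, "caller_b.bed"))
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(call_units(intersect_callers(a, b)), truth,
               ignore_attr = TRUE)
  expect_true(all(unique(truth$chrom) %in% names(sizes)))
  fa <- Biostrings::readDNAStringSet(file.path(dir,
                                               "monomers_synthetic.fasta"))
  expect_equal(length(fa), 2)
  expect_equal(as.integer(Biostrings::width(fa)), c(23, 28))
})
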