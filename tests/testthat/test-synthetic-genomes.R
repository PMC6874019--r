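test_that("ancestor simulation honours length, determinism and GC", {
  cfg <- sim_config(ancestor_length = 1000, gc_fraction = 0.5, n_deletions = 0,
                    seed = 1)
  a1 <- simulate_ancestor(cfg)
  expect_equal(assembly_length(a1), 1000)
  expect_true(grepl("^[ACGT]+$", a1$seqs[[1]]))
  a2 <- simulate_ancestor(cfg)
  expect_identical(a1$seqs, a2$seqs)

  # GC within a binomial 3-sigma bound at 1e6 bp: sd = sqrt(p(1-p)/L)
  cfg2 <- sim_config(ancestor_length = 1e6, gc_fraction = 0.42, n_deletions = 0,
                     seed = 7)
  a3 <- simulate_ancestor(cfg2)
  gc <- sum(strsplit(a3$seqs[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  tol <- 3 * sqrt(0.42 * 0.58 / 1e6)
  expect_lt(abs(gc - 0.42), tol)
})

test_that("reference derivation conserves length and records exact truth", {
  cfg <- sim_config(ancestor_length = 1e5, n_deletions = 10,
                    deletion_length_range = c(400, 1000), seed = 3)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  seg <- der$truth$segments
  expect_equal(assembly_length(anc),
               assembly_length(der$reference) + sum(seg$length))
  # non-overlapping, away from ends
  expect_true(all(seg$anc_start[-1] > seg$anc_end[-nrow(seg)]))
  expect_true(all(seg$anc_start >= 2000 & seg$anc_end <= 1e5 - 2000))
  # planted sequences are exactly the bases absent from the reference:
  # reinserting each at its ancestor coordinate rebuilds the ancestor
  rebuilt <- der$reference$seqs[[1]]
  for (i in order(seg$anc_start)) {
    expect_identical(seg$sequence[i],
                     substring(anc$seqs[[1]], seg$anc_start[i] + 1, seg$anc_end[i]))
    rebuilt <- paste0(substr(rebuilt, 1, seg$anc_start[i]), seg$sequence[i],
                      substring(rebuilt, seg$anc_start[i] + 1))
  }
  expect_identical(rebuilt, anc$seqs[[1]])
})

test_that("zero deletions reproduce the ancestor", {
  cfg <- sim_config(ancestor_length = 5000, n_deletions = 0, seed = 2)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  expect_identical(der$reference$seqs[[1]], anc$seqs[[1]])
  expect_equal(nrow(der$truth$segments), 0)
})

test_that("donor divergence plants the configured substitution rate", {
  cfg <- sim_config(ancestor_length = 1e6, n_deletions = 0, seed = 4)
  anc <- simulate_ancestor(cfg)
  d0 <- derive_donor(anc, 0, seed = 10)
  expect_identical(d0$assembly$seqs[[1]], anc$seqs[[1]])
  d1 <- derive_donor(anc, 0.01, seed = 11)
  n <- nrow(d1$divergence_sites)
  expect_lt(abs(n - 10000), 300) # binomial 3 sigma
  # substitutions never keep the same base, and truth matches the sequences
  expect_true(all(d1$divergence_sites$from != d1$divergence_sites$to))
  idx <- sample.int(n, 50)
  pos <- d1$divergence_sites$pos[idx]
  expect_identical(substring(d1$assembly$seqs[[1]], pos + 1, pos + 1),
                   d1$divergence_sites$to[idx])
  expect_identical(substring(anc$seqs[[1]], pos + 1, pos + 1),
                   d1$divergence_sites$from[idx])
})

test_that("cohort genotypes follow population frequencies", {
  cfg <- sim_config(ancestor_length = 2e5, n_deletions = 8,
                    deletion_length_range = c(400, 800), seed = 5)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  # frequency 1 and 0 are deterministic
  ch <- simulate_individuals(der$truth, list(list(size = 10, freq = 1)), seed = 1)
  expect_true(all(ch$genotypes == 2))
  ch0 <- simulate_individuals(der$truth, list(list(size = 10, freq = 0)), seed = 1)
  expect_true(all(ch0$genotypes == 0))
  # frequency 0.5 with 100 haplotypes: 50 +/- 15 carriers (binomial 3 sigma)
  ch5 <- simulate_individuals(der$truth, list(list(size = 50, freq = 0.5)), seed = 2)
  carriers <- colSums(ch5$hap1) + colSums(ch5$hap2)
  expect_true(all(abs(carriers - 50) <= 15))
})

test_that("individual genomes reinsert present segments at their junctions", {
  cfg <- sim_config(ancestor_length = 5e4, n_deletions = 3,
                    deletion_length_range = c(400, 600), seed = 6)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  nseg <- nrow(der$truth$segments)
  g_all <- individual_genome(der$reference, der$truth, rep(1L, nseg), rep(0L, nseg))
  expect_identical(unname(g_all["hap1"]), anc$seqs[[1]]) # all present = ancestor
  expect_identical(unname(g_all["hap2"]), der$reference$seqs[[1]]) # none = reference
})

test_that("read simulation honours count, purity and depth", {
  genome <- c(h1 = random_dna(5e4, seed = 21), h2 = random_dna(5e4))
  rs <- simulate_reads(genome, coverage = 10, read_length = 100,
                       error_rate = 0, seed = 1)
  expect_equal(length(rs$reads), round(10 * 1e5 / 100))
  # error-free reads are exact substrings of their haplotype at the truth position
  idx <- sample(length(rs$reads), 30)
  expect_identical(rs$reads[idx],
                   substring(genome[rs$truth$hap[idx]], rs$truth$start[idx] + 1,
                             rs$truth$start[idx] + 100))
  # mean depth near the nominal coverage
  depth <- sum(nchar(rs$reads)) / sum(nchar(genome))
  expect_lt(abs(depth - 10), 0.5)
  expect_error(simulate_reads(c(h1 = "ACGT"), 1, 100), "read_length")
})

test_that("substream seeds are deterministic and name-sensitive", {
  expect_identical(substream_seed(1, "reads3"), substream_seed(1, "reads3"))
  expect_false(substream_seed(1, "reads3") == substream_seed(1, "reads4"))
  expect_false(substream_seed(1, "reads3") == substream_seed(2, "reads3"))
})
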