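# exhaustive chaining oracle: best collinear subset of anchors under the
# same monotonicity and max_gap rules, by subset enumeration
brute_force_chain_score <- function(qpos, tpos, max_gap) {
  n <- length(qpos)
  ord <- order(qpos)
  qpos <- qpos[ord]; tpos <- tpos[ord]
  best <- 0
  for (mask in 1:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      for (j in 2:length(members)) {
        a <- members[j - 1]; b <- members[j]
        if (qpos[b] <= qpos[a] || tpos[b] <= tpos[a] ||
            qpos[b] - qpos[a] > max_gap || tpos[b] - tpos[a] > max_gap) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, length(members))
  }
  best
}

test_that("anchors cover a self-comparison and vanish without shared k-mers", {
  s <- random_dna(400, seed = 31)
  a <- find_anchors(c(t = s), s, k = 15)
  # unique k-mers of a random 400-mer: essentially all positions anchor
  expect_gt(nrow(a), 380 * 0.95)
  expect_true(all(a$qpos == a$tpos))
  b <- find_anchors(c(t = random_dna(400)), random_dna(400), k = 15)
  expect_equal(nrow(b), 0)
})

test_that("anchor density on a diverged pair tracks the unbroken k-mer rate", {
  s <- random_dna(50000, seed = 32)
  q <- mutate_dna(s, 0.01)
  a <- find_anchors(c(t = s), q, k = 15)
  # expected intact k-mer fraction (1-p)^k, generous band for uniqueness losses
  expected <- (1 - 0.01)^15
  expect_gt(nrow(a) / (50000 - 14), expected - 0.05)
})

test_that("chaining matches the exhaustive collinear-subset oracle", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    qpos <- sample.int(500, n)
    tpos <- sample.int(500, n)
    max_gap <- sample(c(100, 200, 500), 1)
    chains <- chain_anchors(data.frame(qpos = qpos, tpos = tpos), max_gap)
    top <- max(vapply(chains, `[[`, numeric(1), "score"))
    expect_equal(top, brute_force_chain_score(qpos, tpos, max_gap))
  }
})

test_that("collinear anchors form one chain; distant groups split", {
  a <- data.frame(qpos = c(0, 20, 40), tpos = c(0, 20, 40))
  ch <- chain_anchors(a, max_gap = 100)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$score, 3)
  b <- data.frame(qpos = c(0, 20, 5000, 5020), tpos = c(0, 20, 5000, 5020))
  ch2 <- chain_anchors(b, max_gap = 100)
  expect_length(ch2, 2)
})

test_that("chain extension computes exact column and match counts", {
  s <- random_dna(10000, seed = 34)
  aln <- align_assemblies(c(t = s), c(q = s))
  expect_equal(nrow(aln$blocks), 1)
  expect_equal(aln$blocks$identity, 1.0)
  expect_equal(aln$total_length, 10000)
  # a single substitution costs exactly one match
  q <- paste0(substr(s, 1, 4999),
              chartr("ACGT", "CATG", substr(s, 5000, 5000)),
              substring(s, 5001))
  aln2 <- align_assemblies(c(t = s), c(q = q))
  expect_equal(aln2$total_length, 10000)
  expect_equal(aln2$divergent_sites, 1)
})

test_that("block identity on a diverged pair matches planted truth", {
  asm <- genome_assembly(c(c1 = random_dna(20000, seed = 35)), "A.sp")
  don <- derive_donor(asm, 0.01, seed = 36)
  aln <- align_assemblies(asm, don$assembly)
  expect_equal(aln$divergent_sites, nrow(don$divergence_sites))
})

test_that("1:1 filtering keeps non-overlapping blocks and drops duplicates", {
  blocks <- data.frame(q_start = c(0, 2000), q_end = c(1000, 3000),
                       t_start = c(0, 2000), t_end = c(1000, 3000),
                       n_columns = c(1000, 1000), n_matches = c(990, 980),
                       n_gapcols = c(0, 0), identity = c(0.99, 0.98))
  kept <- one_to_one_filter(blocks)
  expect_equal(nrow(kept$blocks), 2)
  dup <- blocks[c(1, 1), ]
  kept2 <- one_to_one_filter(dup)
  expect_equal(nrow(kept2$blocks), 1)
})

test_that("1:1 filtering is near the exhaustive non-overlapping optimum", {
  set.seed(37)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    st <- sample.int(5000, n)
    len <- sample(200:800, n, replace = TRUE)
    blocks <- data.frame(q_start = st, q_end = st + len,
                         t_start = st, t_end = st + len,
                         n_columns = len, n_matches = round(len * runif(n, 0.9, 1)),
                         n_gapcols = 0)
    blocks$identity <- blocks$n_matches / blocks$n_columns
    kept <- one_to_one_filter(blocks, min_columns = 1)
    # exhaustive search over non-overlapping (untrimmed) subsets
    best <- 0
    for (mask in 1:(2^n - 1)) {
      m <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(m) > 1) {
        o <- order(blocks$q_start[m])
        mm <- m[o]
        if (any(blocks$q_start[mm][-1] < blocks$q_end[mm][-length(mm)])) next
      }
      best <- max(best, sum(blocks$n_matches[m]))
    }
    # trimming can only add matches relative to the drop-only optimum
    expect_gte(sum(kept$blocks$n_matches), best * 0.95)
  }
})

test_that("divergence is zero on self and monotone in the substitution rate", {
  asm <- genome_assembly(c(c1 = random_dna(50000, seed = 38)), "A.sp")
  self <- align_assemblies(asm, asm)
  expect_equal(genomic_divergence(self), 0)
  d1 <- derive_donor(asm, 0.002, seed = 40)
  d2 <- derive_donor(asm, 0.02, seed = 40)
  v1 <- genomic_divergence(align_assemblies(asm, d1$assembly))
  v2 <- genomic_divergence(align_assemblies(asm, d2$assembly))
  expect_lt(v1, v2)
})

test_that("block coverage and unaligned segments partition each query contig", {
  cfg <- sim_config(ancestor_length = 1e5, n_deletions = 4,
                    deletion_length_range = c(500, 2000),
                    donor_divergences = 0.01, seed = 41)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  don <- derive_donor(anc, 0.01, seed = 42)
  aln <- align_assemblies(der$reference, don$assembly)
  segs <- unaligned_segments(don$assembly, aln, min_len = 1)
  covered <- sum(aln$blocks$q_end - aln$blocks$q_start) + sum(segs$end - segs$start)
  expect_equal(covered, assembly_length(don$assembly))
})

test_that("unaligned segments recover a planted novel segment; 399 bp is excluded", {
  set.seed(43)
  base <- random_dna(20000)
  novel1k <- random_dna(1000)
  novel399 <- random_dna(399)
  query <- paste0(substr(base, 1, 8000), novel1k,
                  substring(base, 8001, 15000), novel399, substring(base, 15001))
  aln <- align_assemblies(c(t = base), c(q = query))
  segs <- unaligned_segments(genome_assembly(c(q = query), "Q.sp", "donor"), aln)
  expect_equal(nrow(segs), 1)
  ov <- interval_overlap(segs$start, segs$end, 8000, 9000)
  expect_gte(ov, 900)                       # >= 90% of planted bases
  expect_lte(abs(segs$start - 8000), 100)   # boundaries within 100 bp
  expect_lte(abs(segs$end - 9000), 100)
  # fully aligned query: nothing unaligned
  aln2 <- align_assemblies(c(t = base), c(q = base))
  expect_equal(nrow(unaligned_segments(genome_assembly(c(q = base), "Q.sp", "donor"),
                                       aln2)), 0)
})

test_that("banded identity agrees with a full global alignment oracle", {
  set.seed(44)
  for (rate in c(0.005, 0.02)) {
    a <- random_dna(2000)
    b <- mutate_dna(a, rate)
    aln <- align_assemblies(c(t = a), c(q = b))
    mine <- sum(aln$blocks$n_matches) / sum(aln$blocks$n_columns)
    pa <- Biostrings::pairwiseAlignment(b, a, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 0, gapExtension = 2)
    oracle <- Biostrings::nmatch(pa) / oracle_columns(pa)
    expect_lt(abs(mine - oracle), 0.005)
  }
})

test_that("PAF and BED writers emit well-formed rows", {
  s <- random_dna(5000, seed = 45)
  aln <- align_assemblies(c(t = s), c(q = s))
  paf <- withr::local_tempfile(fileext = ".paf")
  write_paf(aln, c(q = 5000), c(t = 5000), paf)
  row <- strsplit(readLines(paf), "\t")[[1]]
  expect_equal(row[1:12], c("q", "5000", "0", "5000", "+", "t", "5000", "0",
                            "5000", "5000", "5000", "255"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(c = "q", s = 10, e = 20, n = "x"), bed)
  expect_equal(readLines(bed), "q\t10\t20\tx")
})
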