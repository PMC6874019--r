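test_that("shredding tiles sequences and preserves every base", {
  seg <- data.frame(source_species = "S", source_contig = "c", start = 0L,
                    end = 10000L, sequence = random_dna(10000, seed = 51))
  fr <- shred(seg, 1000)
  expect_equal(nrow(fr), 10)
  expect_true(all(fr$end - fr$start == 1000))
  expect_identical(paste(fr$sequence, collapse = ""), seg$sequence)
  seg$end <- 10500L
  seg$sequence <- paste0(seg$sequence, random_dna(500))
  fr2 <- shred(seg, 1000)
  expect_equal(nrow(fr2), 11)
  expect_equal(fr2$end[11] - fr2$start[11], 500)
  expect_identical(paste(fr2$sequence, collapse = ""), seg$sequence)
})

test_that("cascade filter removes known sequence and keeps novel sequence", {
  base <- c(chr = random_dna(30000, seed = 52))
  idx <- kmer_index(base, k = 15)
  copies <- data.frame(source_species = "S", source_contig = "c",
                       start = c(0L, 1000L), end = c(1000L, 2000L),
                       sequence = c(substr(base, 5001, 6000), random_dna(1000)))
  kept <- cascade_filter(copies, idx)
  expect_equal(nrow(kept), 1)          # verbatim copy removed, novel kept
  expect_equal(kept$start, 1000L)
  expect_equal(kept$best_identity, 0)  # novel fragment had no hit
})

test_that("a 96%-identity paralog is removed by the cascade", {
  set.seed(53)
  base_core <- random_dna(1000)
  base <- c(chr = paste0(random_dna(5000), base_core, random_dna(5000)))
  paralog <- mutate_dna(base_core, 0.04)
  # independent oracle: full local alignment confirms the planted identity
  orc <- oracle_local_stats(paralog, base_core)
  expect_gt(orc$identity, 0.95)
  frag <- data.frame(source_species = "S", source_contig = "c", start = 0L,
                     end = 1000L, sequence = paralog)
  kept <- cascade_filter(frag, kmer_index(base, k = 15))
  expect_equal(nrow(kept), 0)
  # at 15% divergence (identity well below 90%) the paralog survives the cascade
  far <- mutate_dna(base_core, 0.15)
  frag2 <- data.frame(source_species = "S", source_contig = "c", start = 0L,
                      end = 1000L, sequence = far)
  expect_equal(nrow(cascade_filter(frag2, kmer_index(base, k = 15))), 1)
})

test_that("merging requires strict contiguity and the 400 bp floor", {
  s3k <- random_dna(3000, seed = 54)
  fr <- data.frame(source_species = "S", source_contig = "c",
                   start = c(0L, 1000L, 2000L, 5000L),
                   end = c(1000L, 2000L, 3000L, 5350L),
                   sequence = c(substring(s3k, c(1, 1001, 2001), c(1000, 2000, 3000)),
                                random_dna(350)))
  m <- merge_fragments(fr)
  expect_equal(nrow(m), 1)             # 350 bp leftover dropped
  expect_equal(m$start, 0L)
  expect_equal(m$end, 3000L)
  expect_equal(nchar(m$sequence), 3000)
  # a gap breaks the merge
  fr2 <- fr[c(1, 3), ]
  m2 <- merge_fragments(fr2)
  expect_equal(nrow(m2), 2)
})

test_that("greedy dedupe matches an exhaustive all-pairs oracle", {
  set.seed(55)
  for (rep in 1:3) {
    templates <- replicate(3, random_dna(sample(500:900, 1)))
    segs <- list()
    for (t in templates) {
      segs <- c(segs, t)
      if (runif(1) < 0.8) segs <- c(segs, mutate_dna(t, 0.02))   # redundant twin
      if (runif(1) < 0.5) segs <- c(segs, mutate_dna(t, 0.12))   # distinct relative
    }
    segs <- unlist(segs)
    df <- data.frame(source_species = "S", source_contig = paste0("c", seq_along(segs)),
                     start = 0L, end = nchar(segs), sequence = segs,
                     stringsAsFactors = FALSE)
    reps <- dedupe(df)
    clusters <- attr(reps, "clusters")
    # oracle: same greedy rule with Biostrings local alignment statistics
    ord <- order(-nchar(segs), paste0("c", seq_along(segs)))
    o_cluster <- integer(length(segs)); o_reps <- integer(0)
    for (i in ord) {
      hit <- 0
      for (ri in seq_along(o_reps)) {
        st <- oracle_local_stats(segs[o_reps[ri]], segs[i])
        if (st$identity >= 0.95 && st$coverage >= 0.80) { hit <- ri; break }
      }
      if (hit) o_cluster[i] <- hit
      else { o_reps <- c(o_reps, i); o_cluster[i] <- length(o_reps) }
    }
    expect_equal(clusters, o_cluster)
    expect_equal(nrow(reps), length(o_reps))
  }
})

test_that("dedupe keeps identical pairs once and 90%-identity pairs twice", {
  s <- random_dna(1000, seed = 56)
  df <- data.frame(source_species = "S", source_contig = c("a", "b"),
                   start = 0L, end = 1000L, sequence = c(s, s))
  expect_equal(nrow(dedupe(df)), 1)
  df2 <- df
  df2$sequence[2] <- mutate_dna(s, 0.10)
  expect_equal(nrow(dedupe(df2)), 2)
})

test_that("iterative build recovers planted segments and ignores duplicate donors", {
  cfg <- sim_config(ancestor_length = 2e5, n_deletions = 6,
                    deletion_length_range = c(500, 3000),
                    donor_divergences = 0.01, seed = 57)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  don <- derive_donor(anc, 0.01, seed = 58)$assembly
  pg <- iterative_build(der$reference, list(don))
  planted <- der$truth$segments
  rec <- sum(vapply(seq_len(nrow(planted)), function(i)
    interval_overlap(pg$provenance$start, pg$provenance$end,
                     planted$anc_start[i], planted$anc_end[i]), numeric(1)))
  expect_gte(rec / sum(planted$length), 0.90)
  # donor coordinates equal ancestor coordinates (no indels): false-positive
  # bases are those outside every planted interval
  fp <- sum(pg$provenance$length) - rec
  expect_lt(fp / sum(pg$provenance$length), 0.01)
  # a second identical donor contributes nothing
  don2 <- don; don2$species <- "Donor2.sp"
  pg2 <- iterative_build(der$reference, list(don, don2))
  expect_equal(pg2$build_history$new_bases[2], 0)
  expect_true(all(diff(pg2$build_history$cumulative_bases) >= 0))
})

test_that("anchoring by flanks finds the true junction and rejects lost flanks", {
  cfg <- sim_config(ancestor_length = 1e5, n_deletions = 4,
                    deletion_length_range = c(500, 2000),
                    donor_divergences = 0.005, seed = 59)
  anc <- simulate_ancestor(cfg)
  der <- derive_reference(anc, cfg)
  don <- derive_donor(anc, 0.005, seed = 60)$assembly
  pg <- iterative_build(der$reference, list(don))
  anchors <- anchor_pansequences(pg, setNames(list(don), don$species))
  expect_true(all(anchors$anchored))
  # each anchor sits at the reference junction of its planted segment
  seg <- der$truth$segments
  for (i in seq_len(nrow(anchors))) {
    prov <- pg$provenance[i, ]
    truth_row <- seg[which.min(abs(seg$anc_start - prov$start)), ]
    expect_lte(abs(anchors$position[i] - truth_row$ref_pos), 10)
  }
  # flanks hitting nothing (novel context) anchor nowhere
  idx <- kmer_index(der$reference$seqs, k = 15)
  fake_donor <- genome_assembly(c(cX = random_dna(6000)), "Fake.sp", "donor")
  prov <- data.frame(id = "x", species = "Fake.sp", contig = "cX",
                     start = 2500L, end = 3500L, donor = "Fake.sp", length = 1000L)
  expect_null(anchor_by_flanks(prov, fake_donor, idx))
})

test_that("homolog search applies the identity and coverage thresholds", {
  set.seed(61)
  ps <- setNames(random_dna(2000), "ps1")
  og_exact <- genome_assembly(
    c(o = paste0(random_dna(3000), ps, random_dna(3000))), "Out.sp", "donor")
  og_random <- genome_assembly(c(o = random_dna(8000)), "Out.sp", "donor")
  res <- homolog_search(ps, list(og_exact))
  expect_true(res$flags$flagged[1])
  expect_equal(res$fraction, 1)
  res2 <- homolog_search(ps, list(og_random))
  expect_false(res2$flags$flagged[1])
  # 5% divergence: well above 80% identity, flagged
  og5 <- genome_assembly(c(o = mutate_dna(ps, 0.05)), "Out.sp", "donor")
  expect_true(homolog_search(ps, list(og5))$flags$flagged[1])
  # 25% divergence: below the identity threshold (and unalignable), not flagged
  og25 <- genome_assembly(c(o = mutate_dna(ps, 0.25)), "Out.sp", "donor")
  expect_false(homolog_search(ps, list(og25))$flags$flagged[1])
})
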