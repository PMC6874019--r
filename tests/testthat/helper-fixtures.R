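# Shared fixtures and independent oracles for the test suite.

.fixture_env <- new.env(parent = emptyenv())

# The standard synthetic study: 1 Mb ancestor, 30 planted deletions of
# 0.5-20 kb, one donor at 1% divergence, 20 diploid individuals at 10x
# coverage with per-segment frequencies drawn from {0.1, 0.5, 0.9}, 1%
# read error. Built once per test run and shared by the end-to-end tests.
standard_fixture <- function() {
  if (!is.null(.fixture_env$std)) return(.fixture_env$std)
  cfg <- sim_config(seed = 1)
  dir <- file.path(tempdir(), "panrecover-standard-fixture")
  res <- run_pipeline(pipeline_config(sim = cfg), dir)
  res$config <- cfg
  res$dir <- dir
  .fixture_env$std <- res
  res
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a fraction of positions (substitutions only), base R, independent
# of the package's C++ mutation kernel
mutate_dna <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(chars)) < rate)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# alignment columns (matches + mismatches + gap columns) of a
# PairwiseAlignments object
oracle_columns <- function(pa) {
  ni <- Biostrings::nindel(pa)
  Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
    sum(Biostrings::insertion(ni)[, "WidthSum"]) +
    sum(Biostrings::deletion(ni)[, "WidthSum"])
}

# independent alignment oracle: identity and shorter-sequence coverage from
# a Biostrings local alignment
oracle_local_stats <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
                                      gapOpening = 0, gapExtension = 2)
  cols <- oracle_columns(pa)
  span_a <- Biostrings::width(Biostrings::pattern(pa))
  span_b <- Biostrings::width(Biostrings::subject(pa))
  shorter <- min(nchar(a), nchar(b))
  span_shorter <- if (nchar(a) <= nchar(b)) span_a else span_b
  list(identity = if (cols > 0) Biostrings::nmatch(pa) / cols else 0,
       coverage = span_shorter / shorter)
}

# bases of [s1, e1) overlapping any interval in (s2, e2) vectors
interval_overlap <- function(s1, e1, s2, e2) {
  sum(pmax(0, pmin(e1, e2) - pmax(s1, s2)))
}

# best two-group label agreement over the two possible label matchings
label_agreement <- function(pred, truth) {
  acc <- mean(pred == truth)
  max(acc, 1 - acc)
}
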