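#' Find unique k-mer anchors between two sequence sets
#'
#' Anchors are exact k-mer matches at positions where the k-mer occurs
#' exactly once in the whole target set and exactly once in the query.
#' Coordinates are 0-based. k-mers containing `N` are skipped.
#'
#' @param target Named character vector of target sequences (or a
#'   [genome_assembly]).
#' @param query A single query sequence.
#' @param k k-mer size, at least 12 for genome-scale uniqueness.
#' @return Data frame with columns `target` (contig name), `qpos`, `tpos`.
#' @export
find_anchors <- function(target, query, k = 15) {
  if (inherits(target, "genome_assembly")) target <- target$seqs
  if (k < 12) stop("k must be >= 12")
  if (any(nchar(target) < k) || nchar(query) < k)
    stop("k larger than a sequence")
  a <- .find_anchors_cpp(target, query, as.integer(k))
  a$target <- names(target)[a$target]
  a
}

#' Chain anchors into maximal collinear chains
#'
#' Anchors are chained by a longest-increasing-subsequence style dynamic
#' program: a chain is strictly monotone in both coordinates and the gap
#' between consecutive anchor start positions is at most `max_gap` on both
#' axes. The chain score is the number of anchors it contains; on small
#' instances the top score equals the exhaustive optimum. Chains are
#' returned in decreasing score order.
#'
#' @param anchors Data frame with `qpos` and `tpos` (one target).
#' @param max_gap Maximum per-axis gap between consecutive anchors, bp.
#' @return List of chains, each a list with `runs` (matrix of collapsed
#'   same-diagonal runs: `q_start`, `t_start`, `n_anchors`) and `score`.
#' @export
chain_anchors <- function(anchors, max_gap = 2000) {
  if (nrow(anchors) == 0) return(list())
  .chain_anchors_cpp(as.integer(anchors$qpos), as.integer(anchors$tpos),
                     as.integer(max_gap))
}

#' Extend a chain into alignment blocks
#'
#' Anchored runs contribute exact-match columns; the gaps between
#' consecutive runs are closed by banded global alignment (match +1,
#' mismatch -1, gap -2). Where the gap length difference exceeds the band
#' the chain is split into separate blocks. Identity is
#' `n_matches / n_columns` with gap columns counted in `n_columns`.
#'
#' @param chain One chain from [chain_anchors()].
#' @param target,query The two sequences (characters).
#' @param k k-mer size used for the anchors.
#' @param band Alignment band half-width, bp.
#' @return Data frame of blocks: `q_start`, `q_end`, `t_start`, `t_end`
#'   (0-based half-open), `n_columns`, `n_matches`, `n_gapcols`, `identity`.
#' @export
extend_chain <- function(chain, target, query, k = 15, band = 200) {
  m <- .extend_chain_cpp(target, query, chain$runs, as.integer(k), as.integer(band))
  b <- as.data.frame(m)
  b$identity <- ifelse(b$n_columns > 0, b$n_matches / b$n_columns, 0)
  b
}

#' Greedy 1:1 filtering of alignment blocks
#'
#' Blocks are taken in decreasing `n_matches` order; a block is kept if it
#' does not overlap any kept block on either the query or the target axis.
#' A partially overlapping block is trimmed to its largest overlap-free
#' remainder (both axes trimmed together, assuming near-diagonal blocks)
#' and kept if at least `min_columns` columns remain; its column counts are
#' scaled proportionally.
#'
#' @param blocks Data frame of blocks as from [extend_chain()], with
#'   additional columns `query_contig` and `target_contig` (single values
#'   are filled in if missing).
#' @param min_columns Minimum surviving columns after trimming.
#' @return An object of class `one_to_one_alignment`: list with `blocks`,
#'   `total_length` (sum of columns) and `divergent_sites` (mismatch
#'   columns, gap columns excluded).
#' @export
one_to_one_filter <- function(blocks, min_columns = 50) {
  if (is.null(blocks$query_contig)) blocks$query_contig <- "query"
  if (is.null(blocks$target_contig)) blocks$target_contig <- "target"
  blocks <- blocks[order(-blocks$n_matches), , drop = FALSE]
  kept <- blocks[0, , drop = FALSE]
  # per-contig lists of kept intervals
  qiv <- list(); tiv <- list()
  subtract <- function(s, e, ivs) {
    # pieces of [s, e) not covered by intervals in `ivs` (matrix cols s, e)
    pieces <- matrix(c(s, e), ncol = 2)
    if (is.null(ivs)) return(pieces)
    for (r in seq_len(nrow(ivs))) {
      out <- matrix(numeric(0), ncol = 2)
      for (p in seq_len(nrow(pieces))) {
        ps <- pieces[p, 1]; pe <- pieces[p, 2]
        os <- max(ps, ivs[r, 1]); oe <- min(pe, ivs[r, 2])
        if (os >= oe) out <- rbind(out, pieces[p, , drop = FALSE])
        else {
          if (ps < os) out <- rbind(out, c(ps, os))
          if (oe < pe) out <- rbind(out, c(oe, pe))
        }
      }
      pieces <- out
      if (!nrow(pieces)) break
    }
    pieces
  }
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    qp <- subtract(b$q_start, b$q_end, qiv[[b$query_contig]])
    if (!nrow(qp)) next
    # try query-free pieces from largest; map to target by diagonal offset
    qp <- qp[order(qp[, 2] - qp[, 1], decreasing = TRUE), , drop = FALSE]
    placed <- FALSE
    for (p in seq_len(nrow(qp))) {
      lt <- qp[p, 1] - b$q_start          # left trim on query
      rt <- b$q_end - qp[p, 2]            # right trim on query
      ts <- b$t_start + lt; te <- b$t_end - rt
      if (te <= ts) next
      tp <- subtract(ts, te, tiv[[b$target_contig]])
      if (!nrow(tp)) next
      tp <- tp[order(tp[, 2] - tp[, 1], decreasing = TRUE), , drop = FALSE]
      lt2 <- tp[1, 1] - ts; rt2 <- te - tp[1, 2]
      nb <- b
      nb$q_start <- qp[p, 1] + lt2; nb$q_end <- qp[p, 2] - rt2
      nb$t_start <- tp[1, 1];       nb$t_end <- tp[1, 2]
      if (nb$q_end - nb$q_start <= 0) next
      frac <- (nb$q_end - nb$q_start) / (b$q_end - b$q_start)
      nb$n_columns <- round(b$n_columns * frac)
      nb$n_matches <- min(round(b$n_matches * frac), nb$n_columns)
      nb$n_gapcols <- min(round(b$n_gapcols * frac), nb$n_columns - nb$n_matches)
      nb$identity <- if (nb$n_columns > 0) nb$n_matches / nb$n_columns else 0
      if (nb$n_columns < min_columns) next
      kept <- rbind(kept, nb)
      qiv[[b$query_contig]] <- rbind(qiv[[b$query_contig]], c(nb$q_start, nb$q_end))
      tiv[[b$target_contig]] <- rbind(tiv[[b$target_contig]], c(nb$t_start, nb$t_end))
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  rownames(kept) <- NULL
  structure(list(blocks = kept,
                 total_length = sum(kept$n_columns),
                 divergent_sites = sum(kept$n_columns - kept$n_matches - kept$n_gapcols)),
            class = "one_to_one_alignment")
}

#' @export
print.one_to_one_alignment <- function(x, ...) {
  cat(sprintf("<one_to_one_alignment> %d block(s), %s columns, %s divergent sites (%.4f%%)\n",
              nrow(x$blocks), format(x$total_length, big.mark = ","),
              format(x$divergent_sites, big.mark = ","),
              if (x$total_length > 0) 100 * x$divergent_sites / x$total_length else NA))
  invisible(x)
}

#' Align two assemblies with seed-chain-extend and 1:1 filtering
#'
#' Every query contig is anchored against all target contigs at once
#' (anchors must be unique across the whole target set), chained, extended,
#' and the resulting blocks filtered to a 1:1 alignment. Forward strand
#' only.
#'
#' @param target Target [genome_assembly] (or named character vector).
#' @param query Query [genome_assembly] (or named character vector).
#' @param k Anchor k-mer size.
#' @param max_gap Chaining gap bound, bp.
#' @param band Extension band half-width, bp.
#' @param min_chain_anchors Chains with fewer anchors are discarded as
#'   noise.
#' @return A `one_to_one_alignment`.
#' @export
align_assemblies <- function(target, query, k = 15, max_gap = 2000, band = 200,
                             min_chain_anchors = 3) {
  tseqs <- if (inherits(target, "genome_assembly")) target$seqs else target
  qseqs <- if (inherits(query, "genome_assembly")) query$seqs else query
  all_blocks <- NULL
  for (qc in names(qseqs)) {
    anchors <- find_anchors(tseqs, qseqs[[qc]], k)
    for (tc in unique(anchors$target)) {
      sub <- anchors[anchors$target == tc, ]
      chains <- chain_anchors(sub, max_gap)
      for (ch in chains) {
        if (ch$score < min_chain_anchors) next
        b <- extend_chain(ch, tseqs[[tc]], qseqs[[qc]], k, band)
        if (!nrow(b)) next
        b$query_contig <- qc
        b$target_contig <- tc
        all_blocks <- rbind(all_blocks, b)
      }
    }
  }
  if (is.null(all_blocks))
    all_blocks <- data.frame(q_start = numeric(0), q_end = numeric(0),
                             t_start = numeric(0), t_end = numeric(0),
                             n_columns = numeric(0), n_matches = numeric(0),
                             n_gapcols = numeric(0), identity = numeric(0),
                             query_contig = character(0),
                             target_contig = character(0))
  one_to_one_filter(all_blocks)
}

#' Genomic divergence of a 1:1 alignment
#'
#' The fraction of divergent (mismatch) aligned sites over the total 1:1
#' alignment length.
#'
#' @param alignment A `one_to_one_alignment`.
#' @return Divergence as a fraction in `[0, 1]`.
#' @export
genomic_divergence <- function(alignment) {
  stopifnot(inherits(alignment, "one_to_one_alignment"))
  if (alignment$total_length <= 0) stop("empty alignment")
  alignment$divergent_sites / alignment$total_length
}

#' Extract unaligned query segments
#'
#' The per-contig complement of the query-axis block coverage, filtered to
#' a minimum length (the 400 bp floor is inclusive).
#'
#' @param query_assembly The query [genome_assembly].
#' @param alignment A `one_to_one_alignment` of that query against the
#'   current pan-genome.
#' @param min_len Minimum segment length in bp, inclusive.
#' @return Data frame of candidate segments: `source_species`,
#'   `source_contig`, `start`, `end` (0-based half-open), `sequence`,
#'   `stage = "raw"`.
#' @export
unaligned_segments <- function(query_assembly, alignment, min_len = 400) {
  out <- NULL
  for (qc in names(query_assembly$seqs)) {
    L <- nchar(query_assembly$seqs[[qc]])
    b <- alignment$blocks[alignment$blocks$query_contig == qc, , drop = FALSE]
    if (nrow(b)) {
      b <- b[order(b$q_start), ]
      # union of block intervals
      us <- b$q_start[1]; ue <- b$q_end[1]
      merged <- NULL
      for (i in seq_len(nrow(b))[-1]) {
        if (b$q_start[i] <= ue) ue <- max(ue, b$q_end[i])
        else { merged <- rbind(merged, c(us, ue)); us <- b$q_start[i]; ue <- b$q_end[i] }
      }
      merged <- rbind(merged, c(us, ue))
      gs <- c(0, merged[, 2]); ge <- c(merged[, 1], L)
    } else {
      gs <- 0; ge <- L
    }
    keep <- (ge - gs) >= min_len
    if (!any(keep)) next
    out <- rbind(out, data.frame(
      source_species = query_assembly$species, source_contig = qc,
      start = as.integer(gs[keep]), end = as.integer(ge[keep]),
      sequence = substring(query_assembly$seqs[[qc]], gs[keep] + 1, ge[keep]),
      stage = "raw", stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(source_species = character(0), source_contig = character(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stage = character(0))
  rownames(out) <- NULL
  out
}

#' Pairwise alignment statistics between two sequences
#'
#' Convenience wrapper running the seed-chain-extend aligner on a single
#' sequence pair and summarising identity and per-sequence aligned
#' coverage over the kept 1:1 blocks. Used by the redundancy clustering and
#' homolog search.
#'
#' @param a,b Character sequences (`a` is the target axis).
#' @param k,max_gap,band Aligner parameters.
#' @return List with `identity` (matches / columns over all kept blocks; 0
#'   if nothing aligns), `cov_a`, `cov_b` (aligned fraction of each
#'   sequence), and `n_columns`.
#' @export
pair_align_stats <- function(a, b, k = 15, max_gap = 1000, band = 200) {
  if (nchar(a) < k || nchar(b) < k)
    return(list(identity = 0, cov_a = 0, cov_b = 0, n_columns = 0))
  aln <- align_assemblies(c(a_seq = a), c(b_seq = b), k = k,
                          max_gap = max_gap, band = band)
  if (!nrow(aln$blocks) || aln$total_length == 0)
    return(list(identity = 0, cov_a = 0, cov_b = 0, n_columns = 0))
  bl <- aln$blocks
  list(identity = sum(bl$n_matches) / sum(bl$n_columns),
       cov_a = sum(bl$t_end - bl$t_start) / nchar(a),
       cov_b = sum(bl$q_end - bl$q_start) / nchar(b),
       n_columns = aln$total_length)
}

#' Write alignment blocks as PAF
#'
#' Standard 12-column PAF (forward strand only) with the block identity in
#' an `id:f` tag and gap columns in `gc:i`.
#'
#' @param alignment A `one_to_one_alignment`.
#' @param query_lengths,target_lengths Named integer vectors of contig
#'   lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignment, query_lengths, target_lengths, path) {
  b <- alignment$blocks
  lines <- vapply(seq_len(nrow(b)), function(i) {
    paste(b$query_contig[i], query_lengths[[b$query_contig[i]]],
          format(b$q_start[i], scientific = FALSE), format(b$q_end[i], scientific = FALSE),
          "+",
          b$target_contig[i], target_lengths[[b$target_contig[i]]],
          format(b$t_start[i], scientific = FALSE), format(b$t_end[i], scientific = FALSE),
          format(b$n_matches[i], scientific = FALSE),
          format(b$n_columns[i], scientific = FALSE),
          255,
          sprintf("id:f:%.6f", b$identity[i]),
          sprintf("gc:i:%d", as.integer(b$n_gapcols[i])),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df Data frame with contig/start/end in its first three columns
#'   (plus optional name column used as the BED name field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- df[, 1:min(4, ncol(df))]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
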