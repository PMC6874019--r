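#' Pan-genome container
#'
#' The base assembly plus an ordered set of pan-sequences with provenance.
#'
#' @param base The base [genome_assembly].
#' @return An object of class `pangenome` with empty pan-sequence set.
#' @export
pangenome <- function(base) {
  stopifnot(inherits(base, "genome_assembly"))
  structure(list(base = base,
                 pansequences = setNames(character(0), character(0)),
                 provenance = data.frame(id = character(0), species = character(0),
                                         contig = character(0), start = integer(0),
                                         end = integer(0), donor = character(0),
                                         length = integer(0), stringsAsFactors = FALSE),
                 build_history = data.frame(donor = character(0),
                                            new_sequences = integer(0),
                                            new_bases = integer(0),
                                            cumulative_bases = integer(0),
                                            stringsAsFactors = FALSE)),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> base %s (%s bp) + %d pan-sequence(s), %s bp\n",
              x$base$species, format(assembly_length(x$base), big.mark = ","),
              length(x$pansequences),
              format(sum(nchar(x$pansequences)), big.mark = ",")))
  invisible(x)
}

#' All sequences of a pan-genome (base contigs then pan-sequences)
#' @param pg A [pangenome].
#' @return Named character vector.
#' @export
pangenome_seqs <- function(pg) c(pg$base$seqs, pg$pansequences)

#' Shred sequences into fixed-size fragments
#'
#' Non-overlapping tiling into `fragment_size` pieces (terminal fragment may
#' be shorter); source coordinates are retained so surviving fragments can
#' later be merged back into contiguous segments.
#'
#' @param segments Data frame of candidate segments (as from
#'   [unaligned_segments()]) or a [genome_assembly].
#' @param fragment_size Fragment size in bp.
#' @return Data frame of fragments with provenance columns
#'   `source_species`, `source_contig`, `start`, `end`, `sequence`.
#' @export
shred <- function(segments, fragment_size = 1000) {
  stopifnot(fragment_size > 0)
  if (inherits(segments, "genome_assembly"))
    segments <- data.frame(source_species = segments$species,
                           source_contig = names(segments$seqs),
                           start = 0L, end = nchar(segments$seqs),
                           sequence = unname(segments$seqs),
                           stringsAsFactors = FALSE)
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    len <- segments$end[i] - segments$start[i]
    fs <- seq(0L, max(len - 1L, 0L), by = fragment_size)
    fe <- pmin(fs + fragment_size, len)
    out[[i]] <- data.frame(
      source_species = segments$source_species[i],
      source_contig = segments$source_contig[i],
      start = segments$start[i] + fs,
      end = segments$start[i] + fe,
      sequence = substring(segments$sequence[i], fs + 1, fe),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a k-mer index over sequences
#'
#' @param seqs Named character vector.
#' @param k k-mer size (up to 31).
#' @param max_occ k-mers occurring more often are treated as repetitive and
#'   skipped at query time.
#' @return An opaque index handle of class `kmer_index`.
#' @export
kmer_index <- function(seqs, k = 15, max_occ = 8) {
  ptr <- .build_kmer_index_cpp(seqs, as.integer(k), as.integer(max_occ))
  structure(list(ptr = ptr, names = names(seqs), lengths = nchar(seqs),
                 seqs = seqs, k = k),
            class = "kmer_index")
}

# best-hit lookup of `query` against an index: returns top vote entries
query_hits <- function(index, query, max_hits = 5) {
  h <- .query_hits_cpp(index$ptr, query, as.integer(max_hits))
  h$target <- index$names[h$target]
  h
}

# extract the target region implied by a (target, diag) hit, padded
hit_region <- function(index, hit, qlen, pad = 200) {
  tlen <- index$lengths[[hit$target]]
  s <- max(0, hit$diag - pad)
  e <- min(tlen, hit$diag + qlen + pad)
  list(seq = substr(index$seqs[[hit$target]], s + 1, e),
       target = hit$target, start = s, end = e)
}

#' Two-stage identity filter cascade
#'
#' Stage 1 ("fast"): fragments with a strong k-mer hit (at least
#' `stage1_min_votes` shared k-mer votes on one diagonal) are aligned
#' banded-globally to the implied pan-genome region and removed when
#' identity is at least `id_stage1`. Stage 2 ("sensitive"): surviving
#' fragments with any hit at all are re-checked by exact local alignment
#' against the padded best-hit region and removed when the aligned-region
#' identity reaches `id_stage2` and the alignment covers at least
#' `stage2_min_cov` of the fragment. Fragments with no hit are kept
#' outright.
#'
#' @param fragments Data frame of fragments from [shred()].
#' @param pg_index A [kmer_index] over the current pan-genome sequences.
#' @param id_stage1,id_stage2 Identity thresholds of the two stages.
#' @param stage1_min_votes Votes needed to count as a stage-1 hit.
#' @param stage2_min_cov Minimum fragment coverage of the stage-2 local
#'   alignment for a removal decision.
#' @param band Stage-1 band half-width.
#' @return The kept fragments (same columns, `stage = "filtered"`), with a
#'   `best_identity` column recording the highest identity seen.
#' @export
cascade_filter <- function(fragments, pg_index, id_stage1 = 0.90, id_stage2 = 0.95,
                           stage1_min_votes = 10, stage2_min_cov = 0.5, band = 200) {
  keep <- logical(nrow(fragments))
  best_id <- numeric(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    frag <- fragments$sequence[i]
    hits <- query_hits(pg_index, frag, max_hits = 3)
    if (!nrow(hits)) { keep[i] <- TRUE; next }  # no hit at all
    # stage 1: banded identity against the best strong hit
    drop <- FALSE
    if (hits$votes[1] >= stage1_min_votes) {
      reg <- hit_region(pg_index, hits[1, ], nchar(frag), pad = band)
      st <- .banded_global_cpp(frag, reg$seq, as.integer(band + abs(nchar(frag) - nchar(reg$seq))))
      # global-vs-padded-region alignment: discount the pad gap columns
      cols <- st[["n_columns"]] - (nchar(reg$seq) - nchar(frag))
      idv <- if (cols > 0) st[["n_matches"]] / cols else 0
      best_id[i] <- max(best_id[i], idv)
      if (idv >= id_stage1) drop <- TRUE
    }
    # stage 2: exact local alignment against the padded best hit
    if (!drop) {
      reg <- hit_region(pg_index, hits[1, ], nchar(frag), pad = 200)
      la <- .local_align_cpp(frag, reg$seq)
      idv <- if (la$n_columns > 0) la$n_matches / la$n_columns else 0
      cov <- (la$a_end - la$a_start) / nchar(frag)
      best_id[i] <- max(best_id[i], idv)
      if (idv >= id_stage2 && cov >= stage2_min_cov) drop <- TRUE
    }
    keep[i] <- !drop
  }
  out <- fragments[keep, , drop = FALSE]
  out$stage <- rep("filtered", nrow(out))
  out$best_identity <- best_id[keep]
  rownames(out) <- NULL
  out
}

#' Merge kept fragments back into contiguous segments
#'
#' Fragments from the same donor contig with strictly contiguous
#' coordinates (gap 0) merge into one segment; merged segments shorter than
#' `min_len` are dropped. Strict contiguity avoids chimeric segments
#' bridging dropped fragments.
#'
#' @param kept Data frame of fragments surviving [cascade_filter()].
#' @param min_len Minimum merged segment length, inclusive.
#' @return Data frame of merged segments (`stage = "merged"`).
#' @export
merge_fragments <- function(kept, min_len = 400) {
  if (!nrow(kept))
    return(data.frame(source_species = character(0), source_contig = character(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stage = character(0)))
  kept <- kept[order(kept$source_species, kept$source_contig, kept$start), ]
  key <- paste(kept$source_species, kept$source_contig)
  new_run <- c(TRUE, key[-1] != key[-nrow(kept)] |
                 kept$start[-1] != kept$end[-nrow(kept)])
  grp <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(seq_len(nrow(kept)), grp), function(ix) {
    data.frame(source_species = kept$source_species[ix[1]],
               source_contig = kept$source_contig[ix[1]],
               start = kept$start[ix[1]], end = kept$end[ix[length(ix)]],
               sequence = paste(kept$sequence[ix], collapse = ""),
               stage = "merged", stringsAsFactors = FALSE)
  }))
  out <- out[(out$end - out$start) >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy redundancy clustering (identity/coverage rule)
#'
#' Segments are considered longest-first (ties broken by identifier); a
#' segment joins an existing representative when their alignment identity
#' is at least `identity` and the alignment covers at least
#' `short_coverage` of the shorter sequence; otherwise it founds a new
#' cluster. One representative (the longest member) is returned per
#' cluster.
#'
#' @param segments Data frame of segments with `sequence` and provenance
#'   columns (as from [merge_fragments()]).
#' @param identity Identity threshold.
#' @param short_coverage Minimum aligned coverage of the shorter sequence.
#' @param k,max_gap,band Parameters of the pairwise aligner used for the
#'   comparisons.
#' @return The representative rows, with a `cluster` column on the full
#'   input attached as attribute `"clusters"` (integer cluster id per input
#'   row).
#' @export
dedupe <- function(segments, identity = 0.95, short_coverage = 0.80,
                   k = 15, max_gap = 1000, band = 200) {
  n <- nrow(segments)
  if (!n) {
    attr(segments, "clusters") <- integer(0)
    return(segments)
  }
  ids <- name_pansequence(segments$source_contig, segments$start, segments$end,
                          segments$source_species)
  lens <- segments$end - segments$start
  ord <- order(-lens, ids)
  cluster <- integer(n)
  reps <- integer(0) # row indices of representatives
  for (i in ord) {
    assigned <- FALSE
    for (ri in seq_along(reps)) {
      r <- reps[ri]
      st <- pair_align_stats(segments$sequence[r], segments$sequence[i],
                             k = k, max_gap = max_gap, band = band)
      shorter_cov <- if (lens[i] <= lens[r]) st$cov_b else st$cov_a
      if (st$identity >= identity && shorter_cov >= short_coverage) {
        cluster[i] <- ri
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  out <- segments[reps, , drop = FALSE]
  out$stage <- "deduped"
  rownames(out) <- NULL
  attr(out, "clusters") <- cluster
  out
}

#' Canonical pan-sequence identifier
#'
#' `"{contig}_{start}_{end}-{Species}"` with 0-based half-open coordinates,
#' so that the sequence length equals `end - start`.
#'
#' @param contig,start,end,species Provenance fields (vectorized).
#' @return Character vector of identifiers.
#' @export
name_pansequence <- function(contig, start, end, species) {
  stopifnot(all(start < end))
  sprintf("%s_%d_%d-%s", contig, as.integer(start), as.integer(end), species)
}

#' Parse a pan-sequence identifier
#'
#' The rightmost two `_`-separated numeric fields before the `-Species`
#' suffix are taken as start and end, so contig names that themselves
#' contain underscores (accession-style names) parse correctly.
#'
#' @param id Character vector of identifiers.
#' @return Data frame with `contig`, `start`, `end`, `species`, `length`.
#' @export
parse_pansequence_id <- function(id) {
  out <- lapply(id, function(x) {
    dash <- regexpr("-", x, fixed = TRUE)
    if (dash < 0) stop("malformed pan-sequence id (no species suffix): ", x)
    species <- substring(x, dash + 1)
    head_part <- substring(x, 1, dash - 1)
    fields <- strsplit(head_part, "_", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("malformed pan-sequence id (too few fields): ", x)
    nf <- length(fields)
    start <- suppressWarnings(as.numeric(fields[nf - 1]))
    end <- suppressWarnings(as.numeric(fields[nf]))
    if (is.na(start) || is.na(end)) stop("malformed pan-sequence id (non-numeric coordinates): ", x)
    if (start >= end) stop("malformed pan-sequence id (start >= end): ", x)
    contig <- paste(fields[1:(nf - 2)], collapse = "_")
    data.frame(contig = contig, start = start, end = end, species = species,
               length = end - start, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Iteratively build the pan-genome from donor assemblies
#'
#' For each donor in order (by convention the most distant donor first):
#' align the donor to the current pan-genome, extract unaligned segments,
#' shred to fragments, run the identity filter cascade, merge survivors,
#' deduplicate against the existing pan-sequences, and append what remains.
#'
#' @param base The base [genome_assembly].
#' @param donors List of donor [genome_assembly] objects, in addition
#'   order.
#' @param min_len Minimum segment length (bp, inclusive).
#' @param fragment_size Shredding fragment size (bp).
#' @param id_stage1,id_stage2 Cascade identity thresholds.
#' @param dedupe_identity,dedupe_coverage Redundancy clustering thresholds.
#' @param k,max_gap,band Aligner parameters.
#' @param verbose Print per-donor progress.
#' @return A [pangenome] with provenance and build history filled in.
#' @export
iterative_build <- function(base, donors, min_len = 400, fragment_size = 1000,
                            id_stage1 = 0.90, id_stage2 = 0.95,
                            dedupe_identity = 0.95, dedupe_coverage = 0.80,
                            k = 15, max_gap = 2000, band = 200, verbose = FALSE) {
  stopifnot(length(donors) >= 1)
  pg <- pangenome(base)
  for (d in donors) {
    seqs <- pangenome_seqs(pg)
    aln <- align_assemblies(seqs, d, k = k, max_gap = max_gap, band = band)
    segs <- unaligned_segments(d, aln, min_len = min_len)
    new_seqs <- character(0)
    if (nrow(segs)) {
      frags <- shred(segs, fragment_size)
      idx <- kmer_index(seqs, k = k)
      kept <- cascade_filter(frags, idx, id_stage1 = id_stage1, id_stage2 = id_stage2,
                             band = band)
      merged <- merge_fragments(kept, min_len = min_len)
      if (nrow(merged)) {
        # dedupe within the donor's contribution, then against existing
        # pan-sequences (existing representatives always win)
        new <- dedupe(merged, identity = dedupe_identity,
                      short_coverage = dedupe_coverage, k = k, band = band)
        if (nrow(new) && length(pg$pansequences)) {
          redundant <- vapply(seq_len(nrow(new)), function(i) {
            for (ex in pg$pansequences) {
              st <- pair_align_stats(ex, new$sequence[i], k = k,
                                     max_gap = max_gap, band = band)
              shorter_cov <- if (nchar(new$sequence[i]) <= nchar(ex)) st$cov_b else st$cov_a
              if (st$identity >= dedupe_identity && shorter_cov >= dedupe_coverage)
                return(TRUE)
            }
            FALSE
          }, logical(1))
          new <- new[!redundant, , drop = FALSE]
        }
        if (nrow(new)) {
          ids <- name_pansequence(new$source_contig, new$start, new$end, new$source_species)
          new_seqs <- setNames(new$sequence, ids)
          pg$pansequences <- c(pg$pansequences, new_seqs)
          pg$provenance <- rbind(pg$provenance, data.frame(
            id = ids, species = new$source_species, contig = new$source_contig,
            start = new$start, end = new$end, donor = d$species,
            length = new$end - new$start, stringsAsFactors = FALSE))
        }
      }
    }
    pg$build_history <- rbind(pg$build_history, data.frame(
      donor = d$species, new_sequences = length(new_seqs),
      new_bases = sum(nchar(new_seqs)),
      cumulative_bases = sum(nchar(pg$pansequences)),
      stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("donor %s: +%d sequences, +%s bp (cumulative %s bp)",
                      d$species, length(new_seqs),
                      format(sum(nchar(new_seqs)), big.mark = ","),
                      format(sum(nchar(pg$pansequences)), big.mark = ",")))
  }
  pg
}

#' Anchor a pan-sequence on the base assembly by its flanks
#'
#' Both donor flanks of the pan-sequence are located on the base assembly
#' by k-mer votes; an anchor is assigned when both flanks hit the same base
#' contig, in order, within a span slack (default twice the pan-sequence
#' length). The insertion position is the end of the left-flank hit.
#'
#' @param prov One provenance row (id, contig, start, end, donor
#'   coordinates refer to the donor assembly).
#' @param donor The donor [genome_assembly] the pan-sequence came from.
#' @param base_index A [kmer_index] over the base assembly.
#' @param flank_len Flank length in bp (flanks truncated below 200 bp
#'   report no anchor).
#' @param span_slack_mult Maximum base-axis gap between the flank hits, as
#'   a multiple of the pan-sequence length.
#' @return A list `(contig, position, left_votes, right_votes)` or `NULL`.
#' @export
anchor_by_flanks <- function(prov, donor, base_index, flank_len = 1000,
                             span_slack_mult = 2) {
  ctg <- donor$seqs[[prov$contig]]
  if (is.null(ctg)) return(NULL)
  L <- nchar(ctg)
  ls <- max(0, prov$start - flank_len)
  left <- substr(ctg, ls + 1, prov$start)
  re <- min(L, prov$end + flank_len)
  right <- substr(ctg, prov$end + 1, re)
  if (nchar(left) < 200 || nchar(right) < 200) return(NULL)
  lh <- query_hits(base_index, left, 1)
  rh <- query_hits(base_index, right, 1)
  if (!nrow(lh) || !nrow(rh)) return(NULL)
  if (lh$target[1] != rh$target[1]) return(NULL)
  left_end <- lh$diag[1] + nchar(left)
  gap <- rh$diag[1] - left_end
  len <- prov$end - prov$start
  if (gap < -50 || gap > span_slack_mult * len) return(NULL)
  list(contig = lh$target[1], position = left_end,
       left_votes = lh$votes[1], right_votes = rh$votes[1])
}

#' Anchor all pan-sequences of a pan-genome
#'
#' @param pg A [pangenome].
#' @param donors Named list of donor assemblies (names = species labels
#'   recorded in provenance `donor`).
#' @param flank_len,span_slack_mult See [anchor_by_flanks()].
#' @return Data frame `id`, `anchored`, `contig`, `position`.
#' @export
anchor_pansequences <- function(pg, donors, flank_len = 1000, span_slack_mult = 2) {
  idx <- kmer_index(pg$base$seqs, k = 15)
  rows <- lapply(seq_len(nrow(pg$provenance)), function(i) {
    prov <- pg$provenance[i, ]
    donor <- donors[[prov$donor]]
    a <- if (is.null(donor)) NULL
         else anchor_by_flanks(prov, donor, idx, flank_len, span_slack_mult)
    if (is.null(a))
      data.frame(id = prov$id, anchored = FALSE, contig = NA_character_,
                 position = NA_integer_, stringsAsFactors = FALSE)
    else
      data.frame(id = prov$id, anchored = TRUE, contig = a$contig,
                 position = a$position, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Search outgroup assemblies for homologs of pan-sequences
#'
#' A pan-sequence is flagged when some alignment against an outgroup
#' assembly reaches both the identity and the pan-sequence coverage
#' thresholds.
#'
#' @param pansequences Named character vector of pan-sequences.
#' @param outgroups List of outgroup [genome_assembly] objects.
#' @param min_identity,min_coverage Thresholds (identity of the aligned
#'   region; coverage of the pan-sequence).
#' @param k,max_gap,band Aligner parameters.
#' @return List with `flags` (data frame id/flagged/best identity and
#'   coverage) and `fraction` flagged.
#' @export
homolog_search <- function(pansequences, outgroups, min_identity = 0.80,
                           min_coverage = 0.50, k = 15, max_gap = 2000, band = 200) {
  flags <- data.frame(id = names(pansequences), flagged = FALSE,
                      identity = 0, coverage = 0, stringsAsFactors = FALSE)
  for (og in outgroups) {
    ogseq <- og$seqs
    for (i in seq_along(pansequences)) {
      if (flags$flagged[i]) next
      aln <- align_assemblies(ogseq, setNames(pansequences[i], "ps"),
                              k = k, max_gap = max_gap, band = band)
      if (!nrow(aln$blocks)) next
      idv <- sum(aln$blocks$n_matches) / sum(aln$blocks$n_columns)
      cov <- sum(aln$blocks$q_end - aln$blocks$q_start) / nchar(pansequences[i])
      flags$identity[i] <- max(flags$identity[i], idv)
      flags$coverage[i] <- max(flags$coverage[i], cov)
      if (idv >= min_identity && cov >= min_coverage) flags$flagged[i] <- TRUE
    }
  }
  list(flags = flags, fraction = mean(flags$flagged))
}
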