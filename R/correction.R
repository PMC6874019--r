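#' Pileup of placed reads over one pan-sequence
#'
#' Per-position base counts (A, C, G, T) from reads placed on the
#' sequence; no realignment, substitution columns only.
#'
#' @param reads Character vector of reads (the full read set the
#'   placements index into).
#' @param placements Data frame from [naive_map()].
#' @param sequence_id Pan-genome sequence name.
#' @param seq_len Length of that sequence in bp.
#' @return A 4 x L integer matrix with rows A, C, G, T.
#' @export
pileup <- function(reads, placements, sequence_id, seq_len) {
  p <- placements[placements$target == sequence_id, , drop = FALSE]
  .pileup_cpp(as.integer(seq_len), reads[p$read], as.integer(p$start))
}

#' Correct a sequence from pileup majority
#'
#' At every position with depth at least `min_depth`, the majority base
#' replaces the current base when it differs and its fraction exceeds
#' `min_majority` (strict); ties and shallow positions keep the current
#' base. Substitution-only: the sequence length never changes.
#'
#' @param sequence Character sequence.
#' @param counts 4 x L pileup matrix from [pileup()].
#' @param min_depth Minimum depth to consider a position.
#' @param min_majority Majority fraction that must be strictly exceeded.
#' @return List with `sequence` (corrected) and `changes` (data frame
#'   `pos` 0-based, `old`, `new`, `depth`, `majority_fraction`).
#' @export
correct_sequence <- function(sequence, counts, min_depth = 1, min_majority = 0.5) {
  L <- nchar(sequence)
  stopifnot(ncol(counts) == L)
  depth <- colSums(counts)
  bases <- rownames(counts)
  maxc <- apply(counts, 2, max)
  eligible <- which(depth >= min_depth & maxc / pmax(depth, 1) > min_majority &
                      maxc > depth - maxc) # strict majority over all alternatives
  if (!length(eligible))
    return(list(sequence = sequence,
                changes = data.frame(pos = integer(0), old = character(0),
                                     new = character(0), depth = integer(0),
                                     majority_fraction = numeric(0))))
  cur <- strsplit(sequence, "")[[1]]
  maj <- bases[apply(counts[, eligible, drop = FALSE], 2, which.max)]
  diff <- eligible[maj != cur[eligible]]
  maj <- maj[maj != cur[eligible]]
  changes <- data.frame(pos = diff - 1L, old = cur[diff], new = maj,
                        depth = depth[diff],
                        majority_fraction = maxc[diff] / depth[diff])
  cur[diff] <- maj
  list(sequence = paste(cur, collapse = ""), changes = changes)
}

#' Iterative per-individual correction of pan-sequences
#'
#' Applies pileup-majority correction for each individual in cohort order,
#' each round operating on the previous round's output, and repeats passes
#' over the cohort until a complete pass makes no changes (or `max_rounds`
#' passes). Because corrections are substitutions only, read placements
#' stay valid across rounds.
#'
#' @param pansequences Named character vector of pan-sequences.
#' @param individuals List of per-individual data: each a list with
#'   `reads` (character vector) and `placements` (data frame from
#'   [naive_map()] against the pan-genome).
#' @param min_depth,min_majority See [correct_sequence()].
#' @param max_rounds Maximum passes over the cohort.
#' @return List with `pansequences` (corrected), `log` (cumulative change
#'   log with `individual` and `sequence_id` columns) and `converged`.
#' @export
iterate_correction <- function(pansequences, individuals, min_depth = 1,
                               min_majority = 0.5, max_rounds = 2) {
  stopifnot(length(individuals) >= 1)
  log <- NULL
  converged <- FALSE
  ind_names <- names(individuals)
  if (is.null(ind_names)) ind_names <- paste0("ind", seq_along(individuals))
  for (round in seq_len(max_rounds)) {
    n_changes <- 0L
    for (ii in seq_along(individuals)) {
      ind <- individuals[[ii]]
      for (sid in names(pansequences)) {
        counts <- pileup(ind$reads, ind$placements, sid, nchar(pansequences[[sid]]))
        res <- correct_sequence(pansequences[[sid]], counts, min_depth, min_majority)
        if (nrow(res$changes)) {
          pansequences[[sid]] <- res$sequence
          n_changes <- n_changes + nrow(res$changes)
          log <- rbind(log, cbind(individual = ind_names[ii], sequence_id = sid,
                                  round = round, res$changes))
        }
      }
    }
    if (n_changes == 0L) { converged <- TRUE; break }
  }
  if (is.null(log))
    log <- data.frame(individual = character(0), sequence_id = character(0),
                      round = integer(0), pos = integer(0), old = character(0),
                      new = character(0), depth = integer(0),
                      majority_fraction = numeric(0))
  list(pansequences = pansequences, log = log, converged = converged)
}
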