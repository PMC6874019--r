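#' Map reads to a pan-genome by k-mer votes
#'
#' Each read is placed at the (target, offset) gathering the most shared
#' k-mer votes; reads whose best vote count is tied between different
#' targets are discarded as ambiguous, ties within one target take the
#' leftmost offset. Reads with fewer than `min_votes` votes stay unplaced.
#'
#' @param reads Character vector of reads.
#' @param index A [kmer_index] over the pan-genome sequences (`k = 21` by
#'   default fits 100 bp reads at percent-scale divergence), or a named
#'   character vector of sequences from which an index is built.
#' @param k k-mer size (used only when `index` is a sequence vector).
#' @param min_votes Minimum votes for a placement.
#' @return Data frame of placements: `read` (index into `reads`), `target`
#'   (sequence name), `start` (0-based, may be negative when a read
#'   overhangs the target start), `votes`, `len`.
#' @export
naive_map <- function(reads, index, k = 21, min_votes = 2) {
  if (!inherits(index, "kmer_index")) index <- kmer_index(index, k = k)
  pl <- .map_reads_cpp(index$ptr, reads, as.integer(min_votes))
  pl$target <- index$names[pl$target]
  pl
}

# per-base coverage of one target from placements (clipped to [0, L))
coverage_vector <- function(L, starts, ends) {
  s <- pmax(pmin(starts, L), 0)
  e <- pmax(pmin(ends, L), 0)
  d <- tabulate(s + 1, nbins = L + 1) - tabulate(e + 1, nbins = L + 1)
  cumsum(d)[seq_len(L)]
}

# sliding window starts/ends for a sequence of length L:
# full windows at `step` offsets; a tail window (>= step bp) covers the
# remainder; a sub-step tail extends the last window instead.
window_bounds <- function(L, window = 200, step = 100) {
  if (L <= window) return(data.frame(start = 0L, end = as.integer(L)))
  starts <- seq(0L, L - window, by = step)
  ends <- starts + window
  tail_start <- starts[length(starts)] + step
  if (L > ends[length(ends)]) {
    if (L - tail_start >= step) {
      starts <- c(starts, tail_start)
      ends <- c(ends, L)
    } else {
      ends[length(ends)] <- L
    }
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Windowed depth profile for one individual
#'
#' Mean per-base coverage in sliding windows (200 bp window, 100 bp step by
#' default) over every pan-genome sequence, plus the genome-wide median
#' window depth computed over the base-assembly windows only. The median is
#' on the diploid-coverage scale, so a segment present on both haplotypes
#' has normalized depth near 1.
#'
#' @param placements Data frame from [naive_map()].
#' @param seq_lengths Named integer vector of pan-genome sequence lengths.
#' @param base_names Names of the base-assembly contigs (used for the
#'   genome median).
#' @param window,step Window size and step in bp.
#' @return An object of class `depth_profile`: list with `windows` (named
#'   list of per-sequence data frames start/end/depth) and `genome_median`.
#' @export
window_depth <- function(placements, seq_lengths, base_names,
                         window = 200, step = 100) {
  wins <- list()
  for (nm in names(seq_lengths)) {
    L <- seq_lengths[[nm]]
    wb <- window_bounds(L, window, step)
    p <- placements[placements$target == nm, , drop = FALSE]
    if (nrow(p)) {
      cov <- coverage_vector(L, p$start, p$start + p$len)
      cs <- c(0, cumsum(cov))
      wb$depth <- (cs[wb$end + 1] - cs[wb$start + 1]) / (wb$end - wb$start)
    } else {
      wb$depth <- 0
    }
    wins[[nm]] <- wb
  }
  base_depths <- unlist(lapply(intersect(base_names, names(wins)),
                               function(nm) wins[[nm]]$depth))
  structure(list(windows = wins,
                 genome_median = if (length(base_depths)) median(base_depths) else NA_real_,
                 window = window, step = step),
            class = "depth_profile")
}

#' Normalized read depth (NRD) of a sequence for one individual
#'
#' The median of the sequence's window depths divided by the individual's
#' genome-wide median window depth. On this scale a segment present on both
#' haplotypes sits near 1, a heterozygous segment near 0.5, and an absent
#' one near 0.
#'
#' @param profile A `depth_profile` from [window_depth()].
#' @param sequence_id Name of the pan-genome sequence.
#' @return Non-negative NRD value.
#' @export
nrd <- function(profile, sequence_id) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!is.finite(profile$genome_median) || profile$genome_median <= 0)
    stop("genome median depth is zero: individual has no usable coverage")
  w <- profile$windows[[sequence_id]]
  if (is.null(w)) stop("unknown sequence: ", sequence_id)
  median(w$depth) / profile$genome_median
}

#' Classify an NRD value into a presence call
#'
#' Present when NRD >= `present` (inclusive), absent when NRD <= `absent`
#' (inclusive), ambiguous in between (the intermediate zone contains
#' heterozygotes and divergent alleles).
#'
#' @param nrd_value Non-negative NRD value(s).
#' @param present,absent Thresholds.
#' @return Character vector of `"present"`, `"absent"` or `"ambiguous"`.
#' @export
classify_presence <- function(nrd_value, present = 0.4, absent = 0.2) {
  if (any(nrd_value < 0)) stop("NRD must be non-negative")
  ifelse(nrd_value >= present, "present",
         ifelse(nrd_value <= absent, "absent", "ambiguous"))
}

#' Cohort retention rule and presence/absence matrix
#'
#' A pan-sequence is retained when at least `min_individuals` cohort
#' members call it present. Calls become the PAV matrix: present = 1,
#' absent = 0, ambiguous = NA (ambiguous evidence is not conflated with
#' absence).
#'
#' @param nrd_matrix Individuals x pan-sequences matrix of NRD values.
#' @param min_individuals Retention threshold (inclusive).
#' @param present,absent NRD thresholds, see [classify_presence()].
#' @return List with `retained` (pan-sequence ids), `pav` (individuals x
#'   retained pan-sequences matrix in \{0, 1, NA\}) and `frequency` (mean of
#'   non-NA entries per retained pan-sequence).
#' @export
retain_pansequences <- function(nrd_matrix, min_individuals = 2,
                                present = 0.4, absent = 0.2) {
  if (!nrow(nrd_matrix)) stop("empty cohort")
  calls <- matrix(classify_presence(nrd_matrix, present, absent),
                  nrow = nrow(nrd_matrix), dimnames = dimnames(nrd_matrix))
  n_present <- colSums(calls == "present")
  retained <- colnames(nrd_matrix)[n_present >= min_individuals]
  pav <- matrix(NA_real_, nrow(nrd_matrix), length(retained),
                dimnames = list(rownames(nrd_matrix), retained))
  pav[calls[, retained, drop = FALSE] == "present"] <- 1
  pav[calls[, retained, drop = FALSE] == "absent"] <- 0
  list(retained = retained, pav = pav,
       frequency = colMeans(pav, na.rm = TRUE))
}

#' Cohort NRD matrix from per-individual depth profiles
#'
#' @param profiles Named list of `depth_profile` objects (one per
#'   individual).
#' @param sequence_ids Pan-sequence ids to evaluate.
#' @return Individuals x pan-sequences numeric matrix of NRD values.
#' @export
nrd_matrix <- function(profiles, sequence_ids) {
  m <- matrix(0, length(profiles), length(sequence_ids),
              dimnames = list(names(profiles), sequence_ids))
  for (i in seq_along(profiles))
    for (j in seq_along(sequence_ids))
      m[i, j] <- nrd(profiles[[i]], sequence_ids[j])
  m
}
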