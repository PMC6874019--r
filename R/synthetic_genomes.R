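#' Simulation configuration
#'
#' Defines the synthetic study: an ancestral genome, a reference derived
#' from it by deleting segments (the planted "missing sequences"), donor
#' assemblies carrying i.i.d. point substitutions, and a diploid cohort with
#' per-segment presence/absence genotypes sequenced at uniform coverage.
#' Donor divergence defaults span the range observed between closely related
#' Caprini genomes (0.21\% to 2.18\% per site).
#'
#' @param ancestor_length Ancestral genome length in bp.
#' @param gc_fraction GC content of the ancestor, in `[0, 1]`.
#' @param n_deletions Number of segments deleted from the reference.
#' @param deletion_length_range Two-element bp range; the minimum must be at
#'   least 400 bp so every planted segment passes the pipeline's minimum
#'   length filter.
#' @param donor_divergences Per-site substitution rate for each donor
#'   assembly, each in `[0, 0.05]`.
#' @param populations List of populations, each a list with `size` (number
#'   of diploid individuals) and `freq` (per-segment presence frequency: a
#'   single value recycled to all segments, a vector of one frequency per
#'   segment, or a pool from which per-segment frequencies are drawn).
#' @param coverage Diploid fold coverage of the simulated reads.
#' @param read_length Read length in bp.
#' @param read_error_rate Per-base substitution error rate of the reads.
#' @param seed Master seed; every random draw derives from it via
#'   [substream_seed()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(ancestor_length = 1e6,
                       gc_fraction = 0.42,
                       n_deletions = 30,
                       deletion_length_range = c(500, 20000),
                       donor_divergences = c(0.01),
                       populations = list(list(size = 20, freq = c(0.1, 0.5, 0.9))),
                       coverage = 10,
                       read_length = 100,
                       read_error_rate = 0.01,
                       seed = 1L) {
  stopifnot(ancestor_length > 0, gc_fraction >= 0, gc_fraction <= 1,
            n_deletions >= 0, length(deletion_length_range) == 2,
            deletion_length_range[1] <= deletion_length_range[2],
            all(donor_divergences >= 0), all(donor_divergences <= 1),
            coverage > 0, read_length > 0,
            read_error_rate >= 0, read_error_rate <= 1)
  if (n_deletions > 0 && deletion_length_range[1] < 400)
    stop("deletion lengths must be >= 400 bp so planted truth passes the minimum length filter")
  for (p in populations)
    stopifnot(p$size >= 1, all(p$freq >= 0), all(p$freq <= 1))
  structure(list(ancestor_length = as.integer(ancestor_length),
                 gc_fraction = gc_fraction,
                 n_deletions = as.integer(n_deletions),
                 deletion_length_range = as.integer(deletion_length_range),
                 donor_divergences = donor_divergences,
                 populations = populations,
                 coverage = coverage,
                 read_length = as.integer(read_length),
                 read_error_rate = read_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_sequence <- function(length, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate the ancestral genome
#'
#' A single contig of i.i.d. bases at the configured GC fraction,
#' deterministic under the master seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_assembly] with role `"base"` and one contig `"chr1"`.
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "ancestor"), {
    seqs <- setNames(random_sequence(config$ancestor_length, config$gc_fraction), "chr1")
  })
  genome_assembly(seqs, species = "Ancestor.sp", role = "base")
}

#' Derive the reference by deleting planted segments
#'
#' Non-overlapping segments, placed at least 2 kb from contig ends so that
#' flanking sequence exists for later anchoring, are removed from the
#' ancestor. The reference plays the role of the incomplete base assembly;
#' the deleted segments are the ground-truth missing sequences.
#'
#' @param ancestor The ancestral [genome_assembly].
#' @param config A [sim_config()].
#' @return A list with `reference` (a [genome_assembly], species
#'   `"Focal.sp"`) and `truth`, a list holding `segments` (data frame with
#'   the ancestor coordinates `anc_start`/`anc_end` 0-based half-open, the
#'   insertion point `ref_pos` on the reference, and each segment's
#'   sequence).
#' @export
derive_reference <- function(ancestor, config) {
  anc <- ancestor$seqs[[1]]
  L <- nchar(anc)
  n <- config$n_deletions
  margin <- 2000L
  truth_seg <- data.frame(segment = character(0), anc_start = integer(0),
                          anc_end = integer(0), length = integer(0),
                          ref_pos = integer(0), sequence = character(0),
                          stringsAsFactors = FALSE)
  if (n > 0) {
    with_seed(substream_seed(config$seed, "deletions"), {
      lens <- as.integer(round(runif(n, config$deletion_length_range[1],
                                     config$deletion_length_range[2])))
      # spacing construction: distribute the free (non-deleted) interior
      # uniformly between segments, which always yields a non-overlapping,
      # strictly separated placement when the segments fit at all
      free <- L - margin * 2L - sum(lens) - (n + 1L)
      if (free <= 0) stop("deletions cannot fit inside the ancestor")
      cuts <- sort(sample.int(free, n))
      starts <- as.integer(margin + cuts + seq_len(n) + c(0L, cumsum(lens[-n])))
      ends <- starts + lens
    })
    # reference position of each deletion start, after removing preceding segments
    ref_pos <- starts - c(0L, cumsum(lens)[-n])
    truth_seg <- data.frame(
      segment = sprintf("seg%03d", seq_len(n)),
      anc_start = starts, anc_end = ends, length = lens, ref_pos = ref_pos,
      sequence = substring(anc, starts + 1, ends),
      stringsAsFactors = FALSE)
    keep_starts <- c(0L, ends)
    keep_ends <- c(starts, L)
    ref <- paste(substring(anc, keep_starts + 1, keep_ends), collapse = "")
  } else {
    ref <- anc
  }
  reference <- genome_assembly(setNames(ref, names(ancestor$seqs)),
                               species = "Focal.sp", role = "base")
  list(reference = reference,
       truth = list(segments = truth_seg, ancestor_length = L))
}

#' Derive a diverged donor assembly
#'
#' The donor is the ancestor with i.i.d. substitutions at `rate` per site
#' (never to the same base); it therefore retains every planted segment, in
#' diverged form.
#'
#' @param ancestor The ancestral [genome_assembly].
#' @param divergence_rate Per-site substitution rate in `[0, 0.05]`.
#' @param seed Integer seed for this donor's substream.
#' @param species Species label for the donor.
#' @return A list with `assembly` (a donor [genome_assembly]) and
#'   `divergence_sites`, a data frame of (contig, pos 0-based, from, to).
#' @export
derive_donor <- function(ancestor, divergence_rate, seed, species = "Donor.sp") {
  stopifnot(divergence_rate >= 0, divergence_rate <= 0.05)
  seqs <- ancestor$seqs
  sites <- NULL
  with_seed(seed, {
    for (ctg in names(seqs)) {
      m <- .mutate_sequence_cpp(seqs[[ctg]], divergence_rate)
      seqs[[ctg]] <- m$seq
      s <- as.data.frame(m$sites)
      if (nrow(s)) sites <- rbind(sites, cbind(contig = ctg, s))
    }
  })
  if (is.null(sites))
    sites <- data.frame(contig = character(0), pos = integer(0),
                        from = character(0), to = character(0))
  list(assembly = genome_assembly(seqs, species = species, role = "donor"),
       divergence_sites = sites)
}

#' Simulate diploid genotypes for a cohort
#'
#' Each haplotype carries each planted segment independently with its
#' population's per-segment presence frequency.
#'
#' @param truth Truth list from [derive_reference()].
#' @param populations Populations as in [sim_config()].
#' @param seed Integer seed.
#' @return A list with `genotypes` (individuals x segments matrix of copy
#'   numbers 0/1/2), haplotype indicator matrices `hap1`/`hap2`,
#'   `population` labels per individual, and `freq` (population x segment
#'   matrix of configured presence frequencies).
#' @export
simulate_individuals <- function(truth, populations, seed) {
  nseg <- nrow(truth$segments)
  sizes <- vapply(populations, function(p) as.integer(p$size), integer(1))
  n_ind <- sum(sizes)
  hap1 <- hap2 <- matrix(0L, n_ind, nseg)
  freq <- matrix(0, length(populations), max(nseg, 1))
  pop_lab <- rep(seq_along(populations), sizes)
  with_seed(seed, {
    for (pi in seq_along(populations)) {
      f <- populations[[pi]]$freq
      f <- if (length(f) == nseg) f
           else if (length(f) == 1) rep(f, nseg)
           else sample(f, nseg, replace = TRUE)
      if (nseg > 0) freq[pi, seq_len(nseg)] <- f
      rows <- which(pop_lab == pi)
      for (si in seq_len(nseg)) {
        hap1[rows, si] <- rbinom(length(rows), 1, f[si])
        hap2[rows, si] <- rbinom(length(rows), 1, f[si])
      }
    }
  })
  geno <- hap1 + hap2
  ind_ids <- sprintf("ind%03d", seq_len(n_ind))
  dimnames(geno) <- dimnames(hap1) <- dimnames(hap2) <-
    list(ind_ids, truth$segments$segment)
  list(genotypes = geno, hap1 = hap1, hap2 = hap2,
       population = setNames(pop_lab, ind_ids), freq = freq)
}

#' Materialize one diploid individual genome
#'
#' Each haplotype is the reference with the individual's present segments
#' reinserted at their original junctions (with focal, i.e. ancestral,
#' alleles).
#'
#' @param reference The reference [genome_assembly].
#' @param truth Truth list from [derive_reference()].
#' @param hap1,hap2 Integer 0/1 vectors of per-segment presence, one entry
#'   per planted segment.
#' @return Character vector of two haplotype sequences.
#' @export
individual_genome <- function(reference, truth, hap1, hap2) {
  ref <- reference$seqs[[1]]
  seg <- truth$segments
  build <- function(pres) {
    if (!nrow(seg) || !any(pres == 1)) return(ref)
    ins <- seg[pres == 1, ]
    ins <- ins[order(ins$ref_pos), ]
    cuts <- c(0L, ins$ref_pos)
    pieces <- substring(ref, cuts + 1, c(ins$ref_pos, nchar(ref)))
    out <- character(2 * nrow(ins) + 1)
    out[seq(1, length(out), by = 2)] <- pieces
    out[seq(2, length(out) - 1, by = 2)] <- ins$sequence
    paste(out, collapse = "")
  }
  c(hap1 = build(hap1), hap2 = build(hap2))
}

#' Simulate uniform single-end reads from a (haploid or diploid) genome
#'
#' Reads start uniformly over each haplotype (haplotypes weighted by
#' length); per-base substitution errors are applied at `error_rate`. The
#' read count is `round(coverage * total_length / read_length)`.
#'
#' @param genome Character vector of haplotype sequences.
#' @param coverage Fold coverage over the summed haplotype length.
#' @param read_length Read length in bp.
#' @param error_rate Per-base error rate.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return A list with `reads` (character vector) and `truth` (data frame
#'   of haplotype index and 0-based start per read).
#' @export
simulate_reads <- function(genome, coverage, read_length, error_rate = 0, seed = NULL) {
  lens <- nchar(genome)
  if (any(lens < read_length)) stop("read_length exceeds a contig length")
  n_reads <- as.integer(round(coverage * sum(lens) / read_length))
  with_seed(seed, {
    hap <- sample.int(length(genome), n_reads, replace = TRUE, prob = lens)
    start <- floor(runif(n_reads) * (lens[hap] - read_length + 1))
    reads <- substring(genome[hap], start + 1, start + read_length)
    if (error_rate > 0) reads <- .inject_errors_cpp(reads, error_rate)
  })
  list(reads = reads,
       truth = data.frame(hap = hap, start = as.integer(start)))
}
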