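#' Partial harmonic sum
#'
#' `a(n) = 1 + 1/2 + 1/3 + ... + 1/n`, by direct summation (no asymptotic
#' approximation). This is the coefficient of the transformed Watterson
#' pan-genome size estimator.
#'
#' @param n Positive integer.
#' @return The harmonic number `H_n`.
#' @export
harmonic_a <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  sum(1 / seq_len(n))
}

#' Transformed Watterson pan-genome size estimate
#'
#' `K = thetaL * a(n)` where `thetaL` is the average individual-specific
#' sequence amount between two genomes (bp) and `n` is the effective
#' population size. By default the harmonic coefficient is `H_n` exactly as
#' the estimator is usually written in this transformed form; classic
#' Watterson theory sums to `n - 1` over sampled chromosomes, available via
#' `convention = "n-1"`.
#'
#' @param thetaL Pairwise individual-specific sequence amount, bp.
#' @param n Effective population size.
#' @param convention `"n"` (default) or `"n-1"`.
#' @return An object of class `size_model`: list `(thetaL, n, a, K)`.
#' @export
pansize_K <- function(thetaL, n, convention = c("n", "n-1")) {
  convention <- match.arg(convention)
  stopifnot(thetaL > 0, n >= 1)
  a <- harmonic_a(if (convention == "n") n else max(n - 1, 1))
  structure(list(thetaL = thetaL, n = as.integer(n), a = a, K = thetaL * a,
                 convention = convention),
            class = "size_model")
}

#' @export
print.size_model <- function(x, ...) {
  cat(sprintf("<size_model> thetaL = %s bp, n = %s, a = %.4f (%s), K = %s bp\n",
              format(x$thetaL, big.mark = ","), format(x$n, big.mark = ","),
              x$a, x$convention, format(round(x$K), big.mark = ",")))
  invisible(x)
}

#' Expected discovery curve of cumulative novel sequence
#'
#' `curve(n) = thetaL * a(n)`; the increment from adding the n-th genome is
#' exactly `thetaL / n`.
#'
#' @param thetaL Pairwise individual-specific sequence amount, bp.
#' @param n_max Number of genomes.
#' @param convention Harmonic convention, see [pansize_K()].
#' @return Data frame `n`, `cumulative`, `increment`.
#' @export
discovery_curve <- function(thetaL, n_max, convention = c("n", "n-1")) {
  convention <- match.arg(convention)
  stopifnot(n_max >= 1)
  n <- seq_len(n_max)
  if (convention == "n") {
    inc <- thetaL / n
  } else {
    inc <- c(0, thetaL / pmax(n[-1] - 1, 1))
  }
  data.frame(n = n, cumulative = cumsum(inc), increment = inc)
}

#' Observed discovery curve from a pan-genome build
#'
#' The non-decreasing step curve of total deduplicated pan-sequence bases
#' after each donor was added.
#'
#' @param pg A [pangenome] with build history.
#' @return Data frame `donor`, `n`, `new_bases`, `cumulative`.
#' @export
observed_discovery_curve <- function(pg) {
  h <- pg$build_history
  data.frame(donor = h$donor, n = seq_len(nrow(h)),
             new_bases = h$new_bases, cumulative = h$cumulative_bases)
}

#' Frequency spectrum of pan-sequences
#'
#' Counts of pan-sequences per presence-frequency bin. Default bins follow
#' the common reporting convention: (0, 0.01], (0.01, 0.1], (0.1, 0.5],
#' (0.5, 0.9], (0.9, 1].
#'
#' @param pav Individuals x pan-sequences PAV matrix (entries 0/1/NA).
#' @param bins Increasing break points starting at 0 and ending at 1.
#' @return Data frame `bin`, `count`.
#' @export
frequency_spectrum <- function(pav, bins = c(0, 0.01, 0.1, 0.5, 0.9, 1)) {
  stopifnot(ncol(pav) > 0)
  freq <- colMeans(pav, na.rm = TRUE)
  cutv <- cut(freq, breaks = bins, include.lowest = FALSE)
  data.frame(bin = levels(cutv), count = as.integer(table(cutv)))
}

#' Unsupervised clustering of individuals from PAV profiles
#'
#' NA entries are imputed to the column presence frequency; individuals are
#' clustered by average-linkage hierarchical clustering on pairwise
#' presence-profile distances and the tree is cut to `n_groups`. The
#' default distance is simple matching (mean per-segment disagreement),
#' which counts shared absences as agreement and therefore keeps
#' low-frequency populations cohesive; Jaccard (shared absences ignored)
#' is available but cannot separate a low-frequency group whose members
#' share few presences. With all-identical profiles a single group is
#' reported.
#'
#' @param pav Individuals x pan-sequences PAV matrix.
#' @param n_groups Number of groups to cut.
#' @param linkage Agglomeration method, `"average"` (default) or
#'   `"complete"`.
#' @param distance `"hamming"` (simple matching, default) or `"jaccard"`.
#' @return Integer vector of group labels named by individual.
#' @export
cluster_individuals <- function(pav, n_groups = 2, linkage = c("average", "complete"),
                                distance = c("hamming", "jaccard")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  stopifnot(nrow(pav) >= 2)
  colf <- colMeans(pav, na.rm = TRUE)
  colf[is.nan(colf)] <- 0
  for (j in seq_len(ncol(pav))) pav[is.na(pav[, j]), j] <- colf[j]
  if (all(apply(pav, 2, function(x) length(unique(x)) == 1))) {
    warning("degenerate PAV matrix: all individuals identical; single group")
    return(setNames(rep(1L, nrow(pav)), rownames(pav)))
  }
  d <- if (distance == "jaccard") vegan::vegdist(pav, method = "jaccard")
       else stats::dist(pav, method = "manhattan") / ncol(pav)
  hc <- hclust(d, method = linkage)
  cutree(hc, k = n_groups)
}
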