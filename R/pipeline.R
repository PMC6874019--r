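#' Pipeline configuration
#'
#' Collects every stage parameter with the standard defaults: the 400 bp
#' minimum segment length, the 0.90/0.95 cascade identities, 0.95/0.80
#' redundancy clustering thresholds, 200/100 bp depth windows, 0.4/0.2 NRD
#' thresholds with 2-individual retention, and pileup correction at minimum
#' depth 1.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param k Anchor k-mer size for assembly comparison.
#' @param map_k Read-mapping k-mer size.
#' @param max_gap,band Aligner parameters.
#' @param min_len Minimum pan-sequence length, bp.
#' @param fragment_size Shredding size, bp.
#' @param id_stage1,id_stage2 Cascade identity thresholds.
#' @param dedupe_identity,dedupe_coverage Redundancy thresholds.
#' @param window,step Depth window size and step, bp.
#' @param nrd_present,nrd_absent NRD call thresholds.
#' @param min_individuals Cohort retention threshold.
#' @param min_depth,min_majority Correction parameters.
#' @param thetaL,ne Size-model inputs (pairwise individual-specific bp and
#'   effective population size).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            k = 15, map_k = 21, max_gap = 2000, band = 200,
                            min_len = 400, fragment_size = 1000,
                            id_stage1 = 0.90, id_stage2 = 0.95,
                            dedupe_identity = 0.95, dedupe_coverage = 0.80,
                            window = 200, step = 100,
                            nrd_present = 0.4, nrd_absent = 0.2,
                            min_individuals = 2,
                            min_depth = 1, min_majority = 0.5,
                            thetaL = 6.4e6, ne = 11574) {
  stopifnot(window >= step,
            id_stage1 >= 0, id_stage1 <= 1, id_stage2 >= 0, id_stage2 <= 1,
            dedupe_identity >= 0, dedupe_identity <= 1,
            dedupe_coverage >= 0, dedupe_coverage <= 1,
            nrd_present >= 0, nrd_present <= 1, nrd_absent >= 0,
            nrd_absent <= nrd_present)
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic study
#'
#' Executes simulate, align, build, validate, correct and analyze in order
#' and writes every artifact (FASTA, BED, TSV, JSON) plus a checksum
#' manifest into `out_dir`. All randomness derives from the master seed of
#' `config$sim`, so a rerun with the same configuration reproduces every
#' file byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the main in-memory results (`truth`,
#'   `pangenome`, `nrd`, `retention`, `corrected`, `spectrum`,
#'   `size_model`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  say <- function(...) if (verbose) message(sprintf(...))

  # --- simulate -------------------------------------------------------------
  say("[simulate] ancestor, reference, donors, cohort")
  ancestor <- simulate_ancestor(sim)
  der <- derive_reference(ancestor, sim)
  reference <- der$reference; truth <- der$truth
  donors <- list()
  for (i in seq_along(sim$donor_divergences)) {
    d <- derive_donor(ancestor, sim$donor_divergences[i],
                      seed = substream_seed(sim$seed, paste0("donor", i)),
                      species = sprintf("Donor%d.sp", i))
    donors[[d$assembly$species]] <- d
  }
  cohort <- simulate_individuals(truth, sim$populations,
                                 seed = substream_seed(sim$seed, "genotypes"))
  write_fasta(reference, file.path(out_dir, "reference.fa"))
  for (nm in names(donors))
    write_fasta(donors[[nm]]$assembly, file.path(out_dir, paste0(nm, ".fa")))
  write_bed(data.frame(contig = names(ancestor$seqs)[1],
                       start = truth$segments$anc_start,
                       end = truth$segments$anc_end,
                       name = truth$segments$segment),
            file.path(out_dir, "planted_segments.bed"))
  write_tsv(as.data.frame(cohort$genotypes), file.path(out_dir, "genotypes.tsv"),
            meta = "truth diploid copy number per planted segment")
  jsonlite::write_json(unclass(sim), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- build ----------------------------------------------------------------
  say("[build] iterative pan-genome construction from %d donor(s)", length(donors))
  pg <- iterative_build(reference, lapply(donors, `[[`, "assembly"),
                        min_len = config$min_len, fragment_size = config$fragment_size,
                        id_stage1 = config$id_stage1, id_stage2 = config$id_stage2,
                        dedupe_identity = config$dedupe_identity,
                        dedupe_coverage = config$dedupe_coverage,
                        k = config$k, max_gap = config$max_gap, band = config$band,
                        verbose = verbose)
  if (!length(pg$pansequences)) stop("pipeline aborted at stage 'build': no pan-sequences recovered")
  write_fasta(pangenome_seqs(pg), file.path(out_dir, "pangenome.fa"))
  write_tsv(pg$provenance, file.path(out_dir, "provenance.tsv"),
            meta = "pan-sequence provenance (donor coordinates, 0-based half-open)")

  # --- validate -------------------------------------------------------------
  say("[validate] mapping %d individuals, NRD genotyping", nrow(cohort$genotypes))
  pg_seqs <- pangenome_seqs(pg)
  idx <- kmer_index(pg_seqs, k = config$map_k)
  seq_lengths <- setNames(nchar(pg_seqs), names(pg_seqs))
  profiles <- list()
  for (i in seq_len(nrow(cohort$genotypes))) {
    g <- individual_genome(reference, truth, cohort$hap1[i, ], cohort$hap2[i, ])
    rs <- simulate_reads(g, sim$coverage, sim$read_length, sim$read_error_rate,
                         seed = substream_seed(sim$seed, paste0("reads", i)))
    pl <- naive_map(rs$reads, idx)
    profiles[[rownames(cohort$genotypes)[i]]] <-
      window_depth(pl, seq_lengths, names(pg$base$seqs),
                   window = config$window, step = config$step)
  }
  nrdm <- nrd_matrix(profiles, names(pg$pansequences))
  ret <- retain_pansequences(nrdm, min_individuals = config$min_individuals,
                             present = config$nrd_present, absent = config$nrd_absent)
  write_tsv(as.data.frame(nrdm), file.path(out_dir, "nrd.tsv"),
            meta = "NRD per individual (rows) and pan-sequence (columns)")
  write_tsv(as.data.frame(ret$pav), file.path(out_dir, "pav_matrix.tsv"),
            meta = "presence/absence calls (1 present, 0 absent, NA ambiguous)")

  # --- correct --------------------------------------------------------------
  say("[correct] pileup-majority correction of %d retained pan-sequence(s)",
      length(ret$retained))
  retained_seqs <- pg$pansequences[ret$retained]
  individuals <- list()
  for (i in seq_len(nrow(cohort$genotypes))) {
    g <- individual_genome(reference, truth, cohort$hap1[i, ], cohort$hap2[i, ])
    rs <- simulate_reads(g, sim$coverage, sim$read_length, sim$read_error_rate,
                         seed = substream_seed(sim$seed, paste0("reads", i)))
    pl <- naive_map(rs$reads, idx)
    pl <- pl[pl$target %in% ret$retained, , drop = FALSE]
    individuals[[rownames(cohort$genotypes)[i]]] <- list(reads = rs$reads, placements = pl)
  }
  corr <- iterate_correction(retained_seqs, individuals,
                             min_depth = config$min_depth,
                             min_majority = config$min_majority)
  write_fasta(c(pg$base$seqs, corr$pansequences),
              file.path(out_dir, "pangenome_corrected.fa"))
  write_tsv(corr$log, file.path(out_dir, "correction_log.tsv"),
            meta = "pileup-majority substitutions (pos 0-based)")

  # --- analyze --------------------------------------------------------------
  say("[analyze] spectrum, clustering, size model")
  spectrum <- frequency_spectrum(ret$pav)
  write_tsv(spectrum, file.path(out_dir, "spectrum.tsv"))
  groups <- tryCatch(cluster_individuals(ret$pav),
                     warning = function(w) setNames(rep(1L, nrow(ret$pav)),
                                                    rownames(ret$pav)))
  write_tsv(data.frame(individual = names(groups), group = unname(groups),
                       population = unname(cohort$population)),
            file.path(out_dir, "clusters.tsv"))
  sm <- pansize_K(config$thetaL, config$ne)
  jsonlite::write_json(unclass(sm), file.path(out_dir, "size_model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv(observed_discovery_curve(pg), file.path(out_dir, "discovery_observed.tsv"))

  # --- manifest -------------------------------------------------------------
  files <- setdiff(list.files(out_dir), "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), digits = NA)

  invisible(list(truth = truth, cohort = cohort, pangenome = pg, nrd = nrdm,
                 retention = ret, corrected = corr, spectrum = spectrum,
                 size_model = sm, manifest = manifest, profiles = profiles,
                 ancestor = ancestor, reference = reference, donors = donors))
}
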