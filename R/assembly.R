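#' Genome assembly container
#'
#' A light S3 wrapper around a named character vector of contig sequences,
#' with a species label and a role (`"base"` for the guiding reference,
#' `"donor"` for assemblies contributing candidate pan-sequences).
#'
#' @param seqs Named character vector of upper-case contig sequences.
#' @param species Species label used in pan-sequence identifiers, e.g.
#'   `"Ovis.aries"`.
#' @param role `"base"` or `"donor"`.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(seqs, species = "Unknown.sp", role = c("base", "donor")) {
  role <- match.arg(role)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("contig sequences must have unique names")
  seqs <- toupper(unname(vapply(seqs, as.character, character(1))) |>
                    setNames(names(seqs)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("illegal characters in contig(s): ", paste(names(seqs)[bad], collapse = ", "))
  structure(list(seqs = seqs, species = species, role = role),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s (%s): %d contig(s), %s bp total\n",
              x$species, x$role, length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Total assembly length in bp
#' @param assembly A [genome_assembly].
#' @return Integer total length.
#' @export
assembly_length <- function(assembly) sum(nchar(assembly$seqs))

#' Read a FASTA file into a genome assembly
#'
#' Sequences are upper-cased; `N` is allowed (and excluded from k-mer
#' indexing downstream), any other non-ACGT character is an error, as are
#' duplicate or empty records. Only the first whitespace-delimited token of
#' each header is kept as the contig name.
#'
#' @param path FASTA file path.
#' @inheritParams genome_assembly
#' @return A [genome_assembly].
#' @export
read_fasta <- function(path, species = "Unknown.sp", role = c("base", "donor")) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[anyDuplicated(ids)])
  if (any(width(ss) == 0)) stop("empty FASTA record in ", path)
  genome_assembly(setNames(toupper(as.character(ss)), ids), species, role)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param x A [genome_assembly] or a named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "genome_assembly")) x$seqs else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}

# width() generic without attaching Biostrings
width <- function(x) Biostrings::width(x)
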