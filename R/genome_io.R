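#' Read a (possibly gzipped, possibly soft-masked) genome FASTA
#'
#' Sequences are uppercase-normalised for all matching operations. When
#' \code{keep_case = TRUE} the raw case is returned as a \code{BStringSet}
#' instead, which preserves the soft-masking (lowercase) used by the probe
#' repeat filter.
#'
#' @param path FASTA file, \code{.gz} allowed.
#' @param keep_case Return a case-preserving \code{BStringSet}.
#' @return A named \code{DNAStringSet} (or \code{BStringSet}); contig names
#'   are truncated at the first whitespace.
#' @export
read_genome <- function(path, keep_case = FALSE) {
  if (keep_case) {
    x <- Biostrings::readBStringSet(path)
  } else {
    x <- Biostrings::readDNAStringSet(path)
  }
  names(x) <- sub("\\s.*$", "", names(x))
  if (!keep_case) {
    # readDNAStringSet keeps IUPAC case; force uppercase for exact matching
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  x
}

#' Write a genome FASTA
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param path Output path (\code{.gz} allowed).
#' @export
write_genome <- function(genome, path) {
  if (!inherits(genome, "XStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
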