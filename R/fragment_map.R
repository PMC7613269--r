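#' Digest a genome into a restriction-fragment map
#'
#' Tiles every contig gaplessly into restriction fragments at the enzyme's
#' cut positions. Coordinates are 0-based half-open (BED-compatible)
#' throughout the package. Fragment ids are consecutive integers assigned in
#' (contig order, coordinate order), so identical genomes always produce
#' identical maps.
#'
#' @param genome A named \code{Biostrings::DNAStringSet} or a named character
#'   vector of contig sequences.
#' @param enzyme An \code{\link{enzyme_spec}}.
#' @param genome_id Free-text identifier recorded in the map.
#' @return A \code{fragment_map}: list with \code{enzyme}, \code{genome_id},
#'   \code{fragments} (data.table: fragment_id, chrom, start, end) and
#'   \code{seqlengths}.
#' @examples
#' g <- c(chrA = "AAGATCCCGATCTT")
#' digest_genome(g, enzyme_spec("DpnII"))
#' @export
digest_genome <- function(genome, enzyme, genome_id = "genome") {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  nms <- names(genome)
  if (is.null(nms) || anyNA(nms) || any(!nzchar(nms)))
    stop("all contigs must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicate contig name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  lens <- Biostrings::width(genome)
  frags <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    L <- lens[i]
    cuts <- find_cut_sites(genome[[i]], enzyme)
    cuts <- cuts[cuts > 0L & cuts < L]
    bounds <- c(0L, cuts, L)
    frags[[i]] <- data.table::data.table(
      chrom = nms[i],
      start = bounds[-length(bounds)],
      end   = bounds[-1L]
    )
  }
  fragments <- data.table::rbindlist(frags)
  fragments[, fragment_id := seq_len(nrow(fragments))]
  data.table::setcolorder(fragments, c("fragment_id", "chrom", "start", "end"))
  data.table::setkey(fragments, chrom, start)
  structure(
    list(enzyme = enzyme, genome_id = genome_id, fragments = fragments,
         seqlengths = stats::setNames(as.integer(lens), nms)),
    class = "fragment_map"
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map> %s | %s (%s) | %d contigs, %d fragments\n",
              x$genome_id, x$enzyme$name, x$enzyme$recognition,
              length(x$seqlengths), nrow(x$fragments)))
  invisible(x)
}

#' Locate the restriction fragment covering a genomic position
#'
#' Binary-search lookup under the half-open convention: returns the unique
#' fragment with \code{start <= position < end}; a position equal to a
#' fragment end therefore falls in the next fragment.
#'
#' @param map A \code{fragment_map}.
#' @param chrom Contig name.
#' @param position 0-based position (vectorised).
#' @return Integer vector of fragment ids.
#' @export
locate_fragment <- function(map, chrom, position) {
  stopifnot(inherits(map, "fragment_map"))
  if (length(chrom) == 1L) chrom <- rep(chrom, length(position))
  out <- integer(length(position))
  for (ch in unique(chrom)) {
    if (!ch %in% names(map$seqlengths))
      stop("unknown contig: ", ch, call. = FALSE)
    sel <- chrom == ch
    pos <- position[sel]
    L <- map$seqlengths[[ch]]
    if (any(pos < 0L | pos >= L))
      stop("position out of range for contig ", ch, " (length ", L, ")",
           call. = FALSE)
    sub <- map$fragments[chrom == ch]
    idx <- findInterval(pos, sub$start)
    out[sel] <- sub$fragment_id[idx]
  }
  out
}

#' Write a fragment map as 4-column BED
#'
#' Emits \code{chrom, start, end, fragment_id} preceded by a single header
#' line recording the enzyme, recognition motif, split convention and genome
#' id, so the map round-trips with \code{\link{read_fragment_map}}.
#'
#' @param map A \code{fragment_map}.
#' @param path Output file.
#' @export
write_fragment_map <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  header <- sprintf("#enzyme=%s recognition=%s convention=%s genome=%s",
                    map$enzyme$name, map$enzyme$recognition,
                    map$enzyme$split_convention, map$genome_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  bed <- map$fragments[, .(chrom, start, end, fragment_id)]
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment map written by \code{\link{write_fragment_map}}
#'
#' @param path BED file with the sidecar header line.
#' @return A \code{fragment_map}.
#' @export
read_fragment_map <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#enzyme="))
    stop("not a fragment-map BED (missing #enzyme= header): ", path,
         call. = FALSE)
  kv <- strsplit(sub("^#", "", header), " ")[[1]]
  kv <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  enz <- enzyme_spec(kv[["enzyme"]], kv[["recognition"]], kv[["convention"]])
  bed <- data.table::fread(path, skip = 1L, header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "fragment_id"))
  fragments <- bed[, .(fragment_id = as.integer(fragment_id), chrom,
                       start = as.integer(start), end = as.integer(end))]
  data.table::setkey(fragments, chrom, start)
  sl <- fragments[, .(len = max(end)), by = chrom]
  structure(
    list(enzyme = enz, genome_id = kv[["genome"]], fragments = fragments,
         seqlengths = stats::setNames(sl$len, sl$chrom)),
    class = "fragment_map"
  )
}

#' Extract fragment sequences from the genome
#'
#' @param map A \code{fragment_map}.
#' @param genome The genome the map was built from.
#' @param fragment_ids Fragments to extract (default all).
#' @return A character vector named by fragment id.
#' @keywords internal
fragment_sequences <- function(map, genome, fragment_ids = NULL) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  fr <- map$fragments
  if (!is.null(fragment_ids)) fr <- fr[fragment_id %in% fragment_ids]
  out <- character(nrow(fr))
  for (ch in unique(fr$chrom)) {
    sel <- fr$chrom == ch
    ir <- IRanges::IRanges(start = fr$start[sel] + 1L, end = fr$end[sel])
    out[sel] <- as.character(Biostrings::extractAt(genome[[ch]], ir))
  }
  stats::setNames(out, fr$fragment_id)
}
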