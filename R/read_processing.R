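#' Read paired FASTQ files into a pair table
#'
#' @param r1_path,r2_path FASTQ files (gzip allowed). Mates must be in the
#'   same order; read ids are truncated at the first whitespace.
#' @return data.table with columns \code{read_id, r1_seq, r2_seq, r1_qual,
#'   r2_qual}.
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files differ in record count (", length(r1), " vs ",
         length(r2), ")", call. = FALSE)
  ids1 <- sub("\\s.*$", "", names(r1))
  ids2 <- sub("\\s.*$", "", names(r2))
  ids1 <- sub("/1$", "", ids1); ids2 <- sub("/2$", "", ids2)
  if (!identical(ids1, ids2))
    stop("mate read ids do not match; files must be sorted identically",
         call. = FALSE)
  data.table::data.table(
    read_id = ids1,
    r1_seq = as.character(r1),
    r2_seq = as.character(r2),
    r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
    r2_qual = as.character(S4Vectors::mcols(r2)$qualities)
  )
}

#' Write a pair table back to paired FASTQ
#' @param pairs Pair table as returned by \code{\link{read_paired_fastq}}.
#' @param r1_path,r2_path Output files; \code{.gz} triggers compression.
#' @export
write_paired_fastq <- function(pairs, r1_path, r2_path) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
  }
  write_one(pairs$r1_seq, pairs$r1_qual, pairs$read_id, r1_path)
  write_one(pairs$r2_seq, pairs$r2_qual, pairs$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Remove exact PCR duplicates at the FASTQ level
#'
#' Retains the first occurrence of every exact \code{(r1_seq, r2_seq)}
#' combination. Deeply sequenced capture libraries typically lose 25-50\% of
#' pairs here (up to 90\% at extreme depth); the removed fraction is a core
#' QC metric.
#'
#' @param pairs Pair table.
#' @return list with \code{pairs} (deduplicated, input order preserved),
#'   \code{removed} (count) and \code{removed_fraction}.
#' @export
dedup_fastq <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, removed = 0L, removed_fraction = 0))
  key <- paste(pairs$r1_seq, pairs$r2_seq, sep = "\x01")
  dup <- duplicated(key)
  list(pairs = pairs[!dup],
       removed = sum(dup),
       removed_fraction = mean(dup))
}

#' Merge overlapping paired-end mates into single fragment sequences
#'
#' Reconstructs the sonication fragment from a read pair when the mates
#' overlap, in the manner of FLASh. All alignments of the 3' end of R1
#' against the reverse complement of R2 are scanned; the longest overlap of
#' at least \code{min_overlap} bases with a mismatch rate of at most
#' \code{max_mismatch_rate} is accepted (ties broken towards the longer,
#' then leftmost overlap). Disagreements within the overlap resolve to the
#' higher-quality base. Pairs without a qualifying overlap are returned
#' unmerged with both mates preserved.
#'
#' @param pairs Pair table.
#' @param min_overlap Minimum acceptable overlap (bp).
#' @param max_mismatch_rate Maximum fraction of mismatching bases within the
#'   overlap.
#' @return data.table: \code{read_id, merged} (logical), \code{seq},
#'   \code{qual} (merged sequence, NA when unmerged), plus the original mate
#'   columns.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_rate = 0.25) {
  if (nrow(pairs) == 0L)
    return(data.table::data.table(
      read_id = character(), merged = logical(), seq = character(),
      qual = character(), r1_seq = character(), r2_seq = character(),
      r1_qual = character(), r2_qual = character()))
  rc2 <- revcomp(pairs$r2_seq)
  q2r <- vapply(pairs$r2_qual,
                function(q) intToUtf8(rev(utf8ToInt(q))), "",
                USE.NAMES = FALSE)
  res <- overlap_merge_cpp(pairs$r1_seq, rc2, pairs$r1_qual, q2r,
                           as.integer(min_overlap), max_mismatch_rate)
  o <- res$overlap
  l2 <- nchar(rc2)
  qual <- ifelse(res$ok,
                 paste0(pairs$r1_qual, substr(q2r, o + 1L, l2)),
                 NA_character_)
  data.table::data.table(
    read_id = pairs$read_id,
    merged = res$ok,
    seq = res$merged,
    qual = qual,
    r1_seq = pairs$r1_seq, r2_seq = pairs$r2_seq,
    r1_qual = pairs$r1_qual, r2_qual = pairs$r2_qual
  )
}

#' In-silico digestion of chimeric read sequences
#'
#' Splits each sequence at every recognition-motif occurrence using the same
#' boundary convention as the reference map (\code{before_site}: boundary at
#' motif start; \code{after_site}: at motif end), so that junction-regenerated
#' motifs are assigned to slices exactly as reference fragments are. A read
#' without a motif yields a single slice: sonication fragments wholly
#' contained within the viewpoint fragment legitimately carry no site.
#'
#' @param seqs Character vector of read sequences.
#' @param enzyme \code{\link{enzyme_spec}}.
#' @param read_ids Optional ids (default index).
#' @param mate Mate label recorded per slice (\code{"flashed"}, \code{"r1"}
#'   or \code{"r2"}).
#' @param min_mappable Slices shorter than this are flagged unmappable but
#'   still emitted, keeping the reconstruction invariant exact.
#' @return data.table: \code{read_id, mate, slice_index} (0-based,
#'   contiguous per read/mate), \code{seq, has_upstream_site,
#'   has_downstream_site, mappable}.
#' @export
digest_reads <- function(seqs, enzyme, read_ids = NULL, mate = "flashed",
                         min_mappable = 18L) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (is.null(read_ids)) read_ids <- as.character(seq_along(seqs))
  if (length(seqs) == 0L)
    return(empty_slice_table())
  dss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(enzyme$recognition, dss, fixed = TRUE)
  off <- if (enzyme$split_convention == "before_site") -1L
         else nchar(enzyme$recognition) - 1L
  lens <- nchar(seqs)
  # flatten match starts; matches are ascending within each sequence
  grp <- rep(seq_along(seqs), S4Vectors::elementNROWS(m))
  cut <- BiocGenerics::start(unlist(m)) + off      # 0-based within the read
  keep <- cut > 0L & cut < lens[grp]
  cut <- cut[keep]; grp <- grp[keep]
  n_cuts <- tabulate(grp, nbins = length(seqs))
  ns <- n_cuts + 1L
  ridx <- rep(seq_along(seqs), ns)
  slice_index <- sequence(ns) - 1L
  is_first <- slice_index == 0L
  is_last <- slice_index == ns[ridx] - 1L
  slice_start <- integer(length(ridx))
  slice_start[!is_first] <- cut
  slice_end <- integer(length(ridx))
  slice_end[is_last] <- lens[ridx[is_last]]
  slice_end[!is_last] <- cut
  slices <- data.table::data.table(
    read_id = read_ids[ridx], mate = mate,
    slice_index = slice_index,
    seq = substring(seqs[ridx], slice_start + 1L, slice_end),
    has_upstream_site = !is_first,
    has_downstream_site = !is_last
  )
  slices[, mappable := nchar(seq) >= min_mappable]
  slices[]
}

empty_slice_table <- function() {
  data.table::data.table(
    read_id = character(), mate = character(), slice_index = integer(),
    seq = character(), has_upstream_site = logical(),
    has_downstream_site = logical(), mappable = logical())
}

#' Trim exact adapter prefixes/suffixes
#'
#' Minimal adapter handling: an exact match of any adapter (or its first 10+
#' bases at the read 3' end) is clipped. Default adapters are the standard
#' Illumina TruSeq pair.
#' @param seqs Character vector of read sequences.
#' @param adapters Character vector of adapter sequences.
#' @return list(seqs, n_trimmed)
#' @export
trim_adapters <- function(seqs,
                          adapters = c(
                            "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                            "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")) {
  n_trimmed <- 0L
  for (ad in adapters) {
    for (k in rev(seq(10L, nchar(ad)))) {
      probe <- substr(ad, 1L, k)
      hit <- endsWith(seqs, probe)
      if (any(hit)) {
        seqs[hit] <- substr(seqs[hit], 1L, nchar(seqs[hit]) - k)
        n_trimmed <- n_trimmed + sum(hit)
      }
    }
  }
  list(seqs = seqs, n_trimmed = n_trimmed)
}

#' Full FASTQ-to-slices stage: dedup, merge, in-silico digest
#'
#' Composes \code{\link{dedup_fastq}}, \code{\link{merge_pairs}} and
#' \code{\link{digest_reads}}. Unmerged pairs are digested per mate and kept
#' as paired-end (PE) read groups downstream. With 150-bp reads and typical
#' sonication, around 90\% of pairs merge and roughly 70\% of molecules carry
#' at least one DpnII site.
#'
#' @param pairs Pair table.
#' @param enzyme \code{\link{enzyme_spec}}.
#' @param min_overlap,max_mismatch_rate Passed to \code{\link{merge_pairs}}.
#' @param dedup Set \code{FALSE} to skip FASTQ-level deduplication (used when
#'   exercising coordinate-level deduplication on its own).
#' @return list with \code{slices} (slice table) and \code{stats}: input
#'   pairs, duplicates removed, merged fraction, fraction of molecules with
#'   at least one site, slice-count histogram.
#' @export
process_reads <- function(pairs, enzyme, min_overlap = 10L,
                          max_mismatch_rate = 0.25, dedup = TRUE) {
  n_input <- nrow(pairs)
  if (n_input == 0L) {
    return(list(slices = empty_slice_table(),
                stats = list(input_pairs = 0L, duplicates_removed = 0L,
                             duplicate_fraction = 0,
                             merged_fraction = 0,
                             with_site_fraction = 0,
                             slice_histogram = table(integer()))))
  }
  if (dedup) {
    dd <- dedup_fastq(pairs)
    pairs <- dd$pairs
    removed <- dd$removed
  } else removed <- 0L
  mg <- merge_pairs(pairs, min_overlap, max_mismatch_rate)
  flashed <- mg[merged == TRUE]
  pe <- mg[merged == FALSE]
  sl <- list(
    digest_reads(flashed$seq, enzyme, flashed$read_id, mate = "flashed"),
    digest_reads(pe$r1_seq, enzyme, pe$read_id, mate = "r1"),
    digest_reads(pe$r2_seq, enzyme, pe$read_id, mate = "r2")
  )
  slices <- data.table::rbindlist(sl)
  # keep input pair order (first-seen semantics downstream), mates adjacent
  slices <- slices[order(match(read_id, pairs$read_id), mate, slice_index)]
  per_mol <- slices[, .(n_slices = .N), by = read_id]
  with_site <- slices[, .(any_site = any(has_upstream_site |
                                           has_downstream_site)),
                      by = read_id]
  stats <- list(
    input_pairs = n_input,
    duplicates_removed = removed,
    duplicate_fraction = removed / n_input,
    merged_fraction = mean(mg$merged),
    with_site_fraction = mean(with_site$any_site),
    slice_histogram = table(per_mol$n_slices)
  )
  list(slices = slices, stats = stats)
}

#' Write slices as FASTQ with structured names
#'
#' Read names follow \code{origId|mate|sliceIndex} so that slice identity
#' survives an external aligner round-trip.
#' @param slices Slice table.
#' @param path Output FASTQ (\code{.gz} allowed).
#' @export
write_slices_fastq <- function(slices, path) {
  x <- Biostrings::DNAStringSet(slices$seq)
  names(x) <- paste(slices$read_id, slices$mate, slices$slice_index,
                    sep = "|")
  quals <- Biostrings::BStringSet(strrep("F", nchar(slices$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
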