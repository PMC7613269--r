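#' Probe filter configuration
#'
#' Thresholds applied when filtering candidate capture oligonucleotides,
#' following standard capture-design practice: at most 2 genome-wide exact
#' duplicates, sequence-similarity density at most 40, GC content at most
#' 60\%, and no repeat-masked bases unless explicitly allowed. Probe length
#' must lie in 70-120 bp.
#'
#' @param probe_length Oligonucleotide length in bp (70-120).
#' @param max_duplicates Maximum genome-wide exact occurrences (both
#'   strands).
#' @param max_density Maximum similarity-density score (see
#'   \code{\link{filter_probes}}).
#' @param max_gc_percent Maximum GC percentage.
#' @param allow_repeats Accept probes overlapping soft-masked repeats.
#' @return \code{probe_filter_config} list.
#' @export
probe_filter_config <- function(probe_length = 120L, max_duplicates = 2L,
                                max_density = 40, max_gc_percent = 60,
                                allow_repeats = FALSE) {
  stopifnot(probe_length >= 70L, probe_length <= 120L,
            max_duplicates >= 0, max_density >= 0, max_gc_percent >= 0)
  structure(list(probe_length = as.integer(probe_length),
                 max_duplicates = as.integer(max_duplicates),
                 max_density = max_density,
                 max_gc_percent = max_gc_percent,
                 allow_repeats = isTRUE(allow_repeats)),
            class = "probe_filter_config")
}

#' Select the viewpoint restriction fragment for a target coordinate
#'
#' Returns the fragment overlapping the single-bp target, or the nearest
#' fragment with its edge distance. Warnings (returned, not raised) flag a
#' target further than 2 kb from the chosen fragment and fragment lengths
#' outside the optimal 250-1,000 bp band: short fragments show elevated
#' trans noise, long ones put probes far from the element of interest.
#'
#' @param map \code{fragment_map}.
#' @param chrom,position Target coordinate (0-based).
#' @return list(fragment = one-row data.table, distance, warnings).
#' @export
select_viewpoint_fragment <- function(map, chrom, position) {
  if (!chrom %in% names(map$seqlengths))
    stop("unknown contig: ", chrom, call. = FALSE)
  sub <- map$fragments[map$fragments$chrom == chrom]
  dist <- pmax(sub$start - position, position - (sub$end - 1L), 0L)
  i <- which.min(dist)
  frag <- sub[i]
  d <- dist[i]
  warnings <- character()
  if (d >= 2000L)
    warnings <- c(warnings, sprintf(
      "target is %d bp from the nearest restriction fragment (>= 2 kb)", d))
  len <- frag$end - frag$start
  if (len < 250L)
    warnings <- c(warnings, sprintf(
      "fragment length %d bp < 250 bp: expect elevated trans interactions",
      len))
  if (len > 1000L)
    warnings <- c(warnings, sprintf(
      "fragment length %d bp > 1000 bp: probes will sit far from the target",
      len))
  list(fragment = frag, distance = d, warnings = warnings)
}

#' Design capture probes for a viewpoint fragment or tiled region
#'
#' Three layouts, all on the + strand:
#' \itemize{
#'   \item \code{capture}: two probes per fragment, one flush with each
#'     fragment end, so each overlaps a restriction digestion site;
#'   \item \code{tri}: a single probe centred on the fragment (Tri-C
#'     viewpoints sit on short ~150-250 bp fragments, so a central probe
#'     covers most of the fragment);
#'   \item \code{tiled}: the capture-layout pair for every fragment contained
#'     in the region; fragments shorter than the probe are skipped with a
#'     warning.
#' }
#'
#' @param target For capture/tri: a one-row fragment (data.table with chrom,
#'   start, end, fragment_id). For tiled: list(chrom, start, end) region.
#' @param genome Named \code{DNAStringSet}.
#' @param map \code{fragment_map}.
#' @param mode \code{"capture"}, \code{"tri"} or \code{"tiled"}.
#' @param config \code{probe_filter_config}.
#' @param viewpoint_name Name stem for probe ids.
#' @return data.table of probes: viewpoint_name, probe id, chrom, start,
#'   end, strand, sequence (filter columns added by
#'   \code{\link{filter_probes}}).
#' @export
design_probes <- function(target, genome, map,
                          mode = c("capture", "tri", "tiled"),
                          config = probe_filter_config(),
                          viewpoint_name = "viewpoint") {
  mode <- match.arg(mode)
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  L <- config$probe_length
  pair_for_fragment <- function(chrom, s, e) {
    data.table::data.table(chrom = chrom, start = c(s, e - L),
                           end = c(s + L, e))
  }
  if (mode %in% c("capture", "tri")) {
    frag <- data.table::as.data.table(target)
    stopifnot(nrow(frag) == 1L)
    flen <- frag$end - frag$start
    if (mode == "capture") {
      if (flen < L)
        stop("fragment (", flen, " bp) is shorter than the probe (", L,
             " bp)", call. = FALSE)
      probes <- pair_for_fragment(frag$chrom, frag$start, frag$end)
    } else {
      if (flen < L)
        stop("fragment (", flen, " bp) is shorter than the probe (", L,
             " bp)", call. = FALSE)
      if (flen < 150L || flen > 250L)
        warning("Tri-C viewpoint fragment is ", flen,
                " bp; ~150-250 bp recommended")
      off <- frag$start + (flen - L) %/% 2L
      probes <- data.table::data.table(chrom = frag$chrom, start = off,
                                       end = off + L)
    }
  } else {
    region <- as.list(target)
    frs <- map$fragments[chrom == region$chrom & start >= region$start &
                           end <= region$end]
    if (!nrow(frs))
      stop("tiled region contains no restriction fragments", call. = FALSE)
    short <- frs[end - start < L]
    if (nrow(short))
      warning(nrow(short), " fragment(s) shorter than the probe skipped")
    frs <- frs[end - start >= L]
    probes <- frs[, pair_for_fragment(chrom, start, end),
                  by = fragment_id][, fragment_id := NULL]
  }
  probes[, `:=`(viewpoint_name = viewpoint_name,
                probe = paste0(viewpoint_name, "_probe", seq_len(.N)),
                strand = "+")]
  seqs <- character(nrow(probes))
  for (ch in unique(probes$chrom)) {
    sel <- probes$chrom == ch
    seqs[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = probes$start[sel] + 1L,
                       end = probes$end[sel])))
  }
  probes[, sequence := seqs]
  data.table::setcolorder(probes, c("viewpoint_name", "probe", "chrom",
                                    "start", "end", "strand", "sequence"))
  probes[]
}

#' Score and filter candidate probes
#'
#' Computes, per probe:
#' \itemize{
#'   \item \code{gc_percent}: 100 (G+C)/length;
#'   \item \code{duplicate_count}: exact genome-wide occurrences of the
#'     probe sequence counting both strands;
#'   \item \code{density_score}: a sequence-similarity density proxy --
#'     total bases of all maximal exact matches of probe 20-mers elsewhere
#'     in the genome (both strands, the probe's own locus excluded),
#'     divided by probe length. Penalises dispersed similarity the way a
#'     BLAT-hit density filter does, without an external aligner;
#'   \item \code{repeat_fraction}: fraction of soft-masked (lowercase)
#'     reference bases under the probe; 0 with a caveat when no masked
#'     genome is supplied.
#' }
#' \code{pass} requires all four thresholds of \code{config} to hold.
#'
#' @param probes Probe table from \code{\link{design_probes}}.
#' @param genome Named \code{DNAStringSet} (uppercase).
#' @param config \code{probe_filter_config}.
#' @param masked_genome Optional case-preserving \code{BStringSet} of the
#'   same genome (from \code{read_genome(path, keep_case = TRUE)}).
#' @param kmer Seed length for the density proxy.
#' @return The probe table with score columns and \code{pass} appended.
#' @export
filter_probes <- function(probes, genome, config = probe_filter_config(),
                          masked_genome = NULL, kmer = 20L) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  probes <- data.table::as.data.table(probes)
  n <- nrow(probes)
  gc <- vapply(probes$sequence, function(s) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
    100 * sum(f) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  dup <- integer(n); dens <- numeric(n); repfrac <- numeric(n)
  for (i in seq_len(n)) {
    sq <- probes$sequence[i]
    # consistency: the stated coordinates must reproduce the sequence
    ref <- as.character(Biostrings::extractAt(
      genome[[probes$chrom[i]]],
      IRanges::IRanges(probes$start[i] + 1L, probes$end[i])))
    if (!identical(toupper(ref), toupper(sq)))
      stop("probe ", probes$probe[i],
           " sequence does not match the reference at its coordinates",
           call. = FALSE)
    dup[i] <- sum(Biostrings::vcountPattern(sq, genome, fixed = TRUE)) +
      sum(Biostrings::vcountPattern(revcomp(sq), genome, fixed = TRUE))
    dens[i] <- probe_density_score(sq, probes$chrom[i], probes$start[i],
                                   probes$end[i], genome, kmer)
    if (!is.null(masked_genome)) {
      sub <- substr(as.character(masked_genome[[probes$chrom[i]]]),
                    probes$start[i] + 1L, probes$end[i])
      repfrac[i] <- mean(grepl("[a-z]", strsplit(sub, "")[[1]]))
    }
  }
  if (is.null(masked_genome))
    message("no soft-masked genome supplied; repeat_fraction set to 0")
  probes[, `:=`(gc_percent = gc, duplicate_count = dup,
                density_score = dens, repeat_fraction = repfrac)]
  probes[, pass := gc_percent <= config$max_gc_percent &
           duplicate_count <= config$max_duplicates &
           density_score <= config$max_density &
           (config$allow_repeats | repeat_fraction == 0)]
  probes[]
}

# total bases of maximal exact k-mer match runs elsewhere in the genome,
# per probe length; the probe's own locus (and its - strand image) excluded
probe_density_score <- function(seq, chrom, start0, end0, genome, kmer) {
  L <- nchar(seq)
  if (L < kmer) return(0)
  starts <- seq_len(L - kmer + 1L)
  kmers <- substring(seq, starts, starts + kmer - 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unique(kmers)))
  pd_rc <- Biostrings::PDict(Biostrings::DNAStringSet(
    revcomp(unique(kmers))))
  total <- 0
  for (ci in seq_along(genome)) {
    subj <- genome[[ci]]
    own <- names(genome)[ci] == chrom
    for (p in list(pd, pd_rc)) {
      m <- Biostrings::matchPDict(p, subj)
      st <- BiocGenerics::start(unlist(m))
      if (!length(st)) next
      ir <- IRanges::reduce(IRanges::IRanges(start = st, width = kmer))
      if (own) {
        self <- IRanges::IRanges(start = start0 + 1L, end = end0)
        ir <- IRanges::setdiff(ir, self)
      }
      total <- total + sum(IRanges::width(ir))
    }
  }
  total / L
}

#' Flag co-captured viewpoint pairs
#'
#' Simultaneously enriching two nearby viewpoints whose mutual interactions
#' are of interest biases the observed contact frequency between them; such
#' pairs should be split into separate capture pools. Every same-contig
#' pair closer than \code{min_cis_separation} is flagged. Tiled designs are
#' exempt: contiguous tiling enriches all in-region fragments equally.
#'
#' @param viewpoints \code{viewpoint_set} (capture or tri mode).
#' @param min_cis_separation Minimum separation in bp (default 5 Mb).
#' @return data.table of flagged pairs (name_a, name_b, chrom, separation).
#' @export
check_cocapture <- function(viewpoints, min_cis_separation = 5e6) {
  stopifnot(inherits(viewpoints, "viewpoint_set"))
  if (viewpoints$mode == "tiled")
    stop("co-capture bias does not apply to tiled designs", call. = FALSE)
  e <- viewpoints$entries
  out <- list()
  if (nrow(e) >= 2L) {
    cmb <- utils::combn(nrow(e), 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (e$chrom[i] != e$chrom[j]) next
      sep <- max(e$start[i], e$start[j]) - min(e$end[i], e$end[j])
      sep <- max(sep, 0L)
      if (sep < min_cis_separation)
        out[[length(out) + 1L]] <- data.table::data.table(
          name_a = e$name[i], name_b = e$name[j], chrom = e$chrom[i],
          separation = sep)
    }
  }
  if (length(out)) data.table::rbindlist(out)
  else data.table::data.table(name_a = character(), name_b = character(),
                              chrom = character(), separation = integer())
}

#' Write probes as FASTA and 6-column BED, with a per-filter report TSV
#' @param probes Filtered probe table.
#' @param prefix Output path prefix; writes \code{<prefix>.fa},
#'   \code{<prefix>.bed} and \code{<prefix>_report.tsv}.
#' @export
write_probes <- function(probes, prefix) {
  x <- Biostrings::DNAStringSet(probes$sequence)
  names(x) <- probes$probe
  Biostrings::writeXStringSet(x, paste0(prefix, ".fa"))
  bed <- probes[, .(chrom, start, end, probe, score = 0L, strand)]
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(probes, paste0(prefix, "_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
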