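#' Built-in exact-match slice mapper
#'
#' Maps slice sequences to the genome by unique exact match: a slice is
#' mapped only when its sequence (on either strand) occurs exactly once in
#' the genome; ambiguous (multi-hit) and absent sequences are returned
#' unmapped. Matching is seed-and-verify: the first \code{seed_width} bases
#' of every unique sequence are matched genome-wide with an Aho-Corasick
#' dictionary, and full-length identity is verified at each seed hit.
#' Intended for simulated/synthetic data; production data goes through the
#' external aligner adapter.
#'
#' @param seqs Character vector of slice sequences.
#' @param genome Named \code{DNAStringSet}.
#' @param seed_width Seed length; sequences shorter than this are unmapped.
#' @return data.table aligned with \code{seqs}: \code{chrom, start, end}
#'   (0-based half-open), \code{strand, mapped, nhits}.
#' @export
exact_match_mapper <- function(seqs, genome, seed_width = 20L) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  useq <- unique(seqs)
  n <- length(useq)
  lens <- nchar(useq)
  eligible <- lens >= seed_width & grepl("^[ACGT]+$", useq)
  hits <- data.table::data.table(uidx = integer(), chrom = character(),
                                 start = integer(), strand = character())
  collect <- function(query, strand_label) {
    # query: full sequences to search on the + strand of the genome
    idx <- which(eligible)
    if (!length(idx)) return(NULL)
    seeds <- substr(query[idx], 1L, seed_width)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    out <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      subj <- genome[[ci]]
      m <- Biostrings::matchPDict(pd, subj)
      nh <- S4Vectors::elementNROWS(m)
      if (!sum(nh)) next
      qi <- rep(seq_along(idx), nh)
      p1 <- BiocGenerics::start(unlist(m))       # 1-based seed start
      full_len <- lens[idx][qi]
      ok <- p1 + full_len - 1L <= length(subj)
      qi <- qi[ok]; p1 <- p1[ok]; full_len <- full_len[ok]
      if (!length(qi)) next
      cand <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(start = p1, width = full_len)))
      verified <- cand == query[idx][qi]
      if (!any(verified)) next
      out[[ci]] <- data.table::data.table(
        uidx = idx[qi[verified]],
        chrom = names(genome)[ci],
        start = p1[verified] - 1L,
        strand = strand_label)
    }
    data.table::rbindlist(out)
  }
  fwd <- collect(useq, "+")
  rev <- collect(revcomp(useq), "-")
  hits <- data.table::rbindlist(list(fwd, rev))
  res <- data.table::data.table(
    useq = useq, len = lens,
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_, mapped = FALSE, nhits = 0L)
  if (nrow(hits)) {
    counts <- hits[, .N, by = uidx]
    res$nhits[counts$uidx] <- counts$N
    uniq <- hits[uidx %in% counts[N == 1L, uidx]]
    res$chrom[uniq$uidx] <- uniq$chrom
    res$start[uniq$uidx] <- uniq$start
    res$end[uniq$uidx] <- uniq$start + res$len[uniq$uidx]
    res$strand[uniq$uidx] <- uniq$strand
    res$mapped[uniq$uidx] <- TRUE
  }
  res[match(seqs, useq),
      .(chrom, start, end, strand, mapped, nhits)]
}

#' Align slices to the genome
#'
#' Attaches genomic coordinates to a slice table, using either the built-in
#' exact-match mapper or an external aligner adapter (see
#' \code{\link{make_external_aligner}}). Unmapped slices are retained with
#' \code{mapped = FALSE} so that downstream statistics can account for them.
#'
#' @param slices Slice table from \code{\link{digest_reads}} /
#'   \code{\link{process_reads}}.
#' @param genome Named \code{DNAStringSet} (built-in mapper) or an index
#'   prefix understood by the external aligner.
#' @param aligner \code{"builtin"} or a function returned by
#'   \code{\link{make_external_aligner}}.
#' @param min_mapq External alignments below this MAPQ are treated as
#'   unmapped (multi-mapping guard).
#' @return The slice table with \code{chrom, start, end, strand, mapped,
#'   mapq} columns appended.
#' @export
align_slices <- function(slices, genome, aligner = "builtin",
                         min_mapq = 30L) {
  if (is.function(aligner)) {
    aln <- aligner(slices, genome)
    aln[mapq < min_mapq, mapped := FALSE]
    return(aln)
  }
  if (!identical(aligner, "builtin"))
    stop("aligner must be 'builtin' or an adapter function", call. = FALSE)
  res <- exact_match_mapper(slices$seq, genome)
  res[slices$mappable == FALSE, `:=`(mapped = FALSE, chrom = NA_character_,
                                     start = NA_integer_, end = NA_integer_,
                                     strand = NA_character_)]
  cbind(slices, res[, .(chrom, start, end, strand, mapped)],
        data.table::data.table(mapq = ifelse(res$mapped, 60L, 0L)))
}

#' External aligner adapter
#'
#' Wraps a command-line short-read aligner as a slice-mapping function. The
#' command template is expanded with \code{{fastq}}, \code{{index}} and
#' \code{{sam}} placeholders and must write SAM to \code{{sam}} (e.g.
#' \code{"bwa mem -k 15 -T 15 {index} {fastq} > {sam}"}). Only the read
#' name, flag, reference, position and CIGAR-derived end are consumed.
#' Parsing uses Rsamtools.
#'
#' @param cmd_template Shell command with placeholders.
#' @return A function \code{(slices, index)} returning the aligned slice
#'   table in the same layout as \code{\link{align_slices}}.
#' @export
make_external_aligner <- function(cmd_template) {
  force(cmd_template)
  function(slices, index) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required for external aligner support",
           call. = FALSE)
    td <- tempfile("aln"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    fq <- file.path(td, "slices.fastq")
    sam <- file.path(td, "slices.sam")
    write_slices_fastq(slices, fq)
    cmd <- gsub("{fastq}", fq, cmd_template, fixed = TRUE)
    cmd <- gsub("{index}", index, cmd, fixed = TRUE)
    cmd <- gsub("{sam}", sam, cmd, fixed = TRUE)
    status <- system(paste(cmd, "2>", file.path(td, "stderr.log")))
    if (status != 0L)
      stop("aligner failed (exit ", status, "): ",
           paste(readLines(file.path(td, "stderr.log")), collapse = "\n"),
           call. = FALSE)
    bam <- Rsamtools::asBam(sam, file.path(td, "slices"),
                            indexDestination = FALSE)
    rec <- Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar", "mapq")))[[1]]
    secondary <- bitwAnd(rec$flag, 256L) > 0L |
      bitwAnd(rec$flag, 2048L) > 0L
    keep <- !secondary
    qname <- rec$qname[keep]
    aln <- data.table::data.table(
      name = qname,
      chrom = as.character(rec$rname)[keep],
      pos = rec$pos[keep],
      cigar = rec$cigar[keep],
      mapq = rec$mapq[keep],
      unmapped = bitwAnd(rec$flag[keep], 4L) > 0L,
      minus = bitwAnd(rec$flag[keep], 16L) > 0L)
    rw <- rep(NA_integer_, nrow(aln))
    has_cig <- !is.na(aln$cigar) & !aln$unmapped
    if (any(has_cig))
      rw[has_cig] <- cigar_ref_width(aln$cigar[has_cig])
    aln[, `:=`(start = pos - 1L, end = pos - 1L + rw)]
    key <- paste(slices$read_id, slices$mate, slices$slice_index, sep = "|")
    idx <- match(key, aln$name)
    out <- cbind(
      slices,
      data.table::data.table(
        chrom = aln$chrom[idx], start = aln$start[idx], end = aln$end[idx],
        strand = ifelse(aln$minus[idx], "-", "+"),
        mapped = !is.na(idx) & !aln$unmapped[idx],
        mapq = ifelse(is.na(idx), 0L, aln$mapq[idx])))
    out[mapped == FALSE, `:=`(chrom = NA_character_, start = NA_integer_,
                              end = NA_integer_, strand = NA_character_)]
    out[]
  }
}

# reference-consumed width of a CIGAR string (M/D/N/=/X advance the ref)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
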