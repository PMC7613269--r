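#' Count unique reporters per viewpoint
#'
#' For every deduplicated informative read group and every viewpoint whose
#' capture fragment the group contains, each reporter slice increments the
#' count of its restriction fragment by one. Reporters on the viewpoint
#' contig are cis, all others trans; the cis fraction is a core library
#' quality metric (>60\% expected for a good library).
#'
#' @param annotated Annotated slice table (all slices).
#' @param groups Deduplicated informative group table (from
#'   \code{\link{group_and_filter}} + \code{\link{dedup_groups}}).
#' @param viewpoints \code{viewpoint_set}.
#' @param map \code{fragment_map}.
#' @return Named list of \code{reporter_profile} objects, one per viewpoint:
#'   list(viewpoint, counts = data.table(fragment_id, chrom, start, end,
#'   count, cis), cis_total, trans_total, normalised).
#' @export
count_reporters <- function(annotated, groups, viewpoints, map) {
  vp <- resolve_viewpoints(viewpoints, map)
  ann <- data.table::as.data.table(annotated)
  keep <- groups[informative == TRUE, read_id]
  ann <- ann[read_id %in% keep]
  caps <- unique(ann[cls == "capture",
                     .(read_id, viewpoint)])
  reps <- ann[cls == "reporter", .(read_id, fragment_id)]
  hits <- merge(caps, reps, by = "read_id", allow.cartesian = TRUE)
  fr <- map$fragments
  out <- list()
  for (nm in unique(vp$name)) {
    vchrom <- vp[name == nm, chrom][1]
    h <- hits[viewpoint == nm]
    counts <- h[, .(count = .N), by = fragment_id]
    counts <- merge(counts, fr, by = "fragment_id")
    counts[, cis := chrom == vchrom]
    data.table::setorder(counts, chrom, start)
    out[[nm]] <- structure(
      list(viewpoint = nm, viewpoint_chrom = vchrom,
           counts = counts[, .(fragment_id, chrom, start, end, count, cis)],
           cis_total = counts[cis == TRUE, sum(count)],
           trans_total = counts[cis == FALSE, sum(count)],
           normalised = NULL, scale = NULL),
      class = "reporter_profile")
  }
  out
}

#' @export
print.reporter_profile <- function(x, ...) {
  cat(sprintf("<reporter_profile> %s: %d cis + %d trans reporters over %d fragments\n",
              x$viewpoint, x$cis_total, x$trans_total, nrow(x$counts)))
  invisible(x)
}

#' Normalise a reporter profile to a fixed number of cis reporters
#'
#' Interaction counts are normalised in cis rather than to total
#' interactions, because differing trans (noise) levels between samples
#' would otherwise distort proximal signal. Each cis fragment gets
#' \code{count * scale / cis_total}; trans fragments are excluded from the
#' track but retained in the statistics.
#'
#' @param profile \code{reporter_profile}.
#' @param scale Reporters-per-so-many cis reporters (default 100,000).
#' @return The profile with a \code{normalised} table
#'   (fragment_id, chrom, start, end, signal) attached.
#' @export
normalise_cis <- function(profile, scale = 1e5) {
  stopifnot(inherits(profile, "reporter_profile"))
  if (profile$cis_total == 0) {
    warning("viewpoint ", profile$viewpoint,
            ": no cis reporters; empty normalised track")
    profile$normalised <- profile$counts[0, .(fragment_id, chrom, start,
                                              end, signal = numeric(0))]
    profile$scale <- scale
    return(profile)
  }
  cis <- profile$counts[cis == TRUE]
  profile$normalised <- cis[, .(fragment_id, chrom, start, end,
                                signal = count * scale / profile$cis_total)]
  profile$scale <- scale
  profile
}

#' Mean of replicate normalised profiles
#'
#' Per-fragment arithmetic mean of the normalised signal; a fragment absent
#' from a replicate contributes zero.
#'
#' @param replicates List of normalised \code{reporter_profile}s for the
#'   same viewpoint.
#' @return data.table(fragment_id, chrom, start, end, signal).
#' @export
mean_profiles <- function(replicates) {
  vps <- unique(vapply(replicates, `[[`, "", "viewpoint"))
  if (length(vps) != 1L)
    stop("replicates mix viewpoints: ", paste(vps, collapse = ", "),
         call. = FALSE)
  n <- length(replicates)
  all <- data.table::rbindlist(lapply(replicates, function(p) {
    if (is.null(p$normalised))
      stop("profiles must be normalised first (normalise_cis)",
           call. = FALSE)
    p$normalised
  }))
  all[, .(signal = sum(signal) / n),
      by = .(fragment_id, chrom, start, end)][order(chrom, start)]
}

#' Difference track between two mean profiles
#'
#' Per-fragment signed difference \code{a - b}; used to compare cell types
#' or genetic models after cis normalisation.
#'
#' @param mean_a,mean_b Mean tracks from \code{\link{mean_profiles}} (or
#'   single normalised tables).
#' @return data.table(fragment_id, chrom, start, end, signal = a - b).
#' @export
subtract_profiles <- function(mean_a, mean_b) {
  m <- merge(mean_a, mean_b, by = c("fragment_id", "chrom", "start", "end"),
             all = TRUE, suffixes = c("_a", "_b"))
  m[is.na(signal_a), signal_a := 0]
  m[is.na(signal_b), signal_b := 0]
  m[, .(fragment_id, chrom, start, end,
        signal = signal_a - signal_b)][order(chrom, start)]
}

#' Consolidated pipeline QC report
#'
#' Gathers per-stage statistics into one report annotated with the expected
#' ranges for a successful experiment: FASTQ duplicates 25-50\% (up to 90\%
#' at extreme depth), ~90\% merged for 150-bp reads, ~70\% of molecules with
#' a DpnII site, capture fraction 80-98\% of mapped reads, reporters in
#' 60-80\% of capture-containing groups, cis fraction >60\%, and at least
#' 20,000 unique cis reporters per viewpoint for a high-quality track.
#'
#' @param read_stats Stats from \code{\link{process_reads}}.
#' @param group_stats Stats from \code{\link{group_and_filter}}.
#' @param dedup_removed Groups removed by \code{\link{dedup_groups}}.
#' @param profiles List of \code{reporter_profile}s.
#' @return \code{qc_report} list; see \code{\link{write_qc_report}}.
#' @export
build_qc_report <- function(read_stats, group_stats, dedup_removed = 0L,
                            profiles = list()) {
  per_vp <- lapply(profiles, function(p) {
    tot <- p$cis_total + p$trans_total
    list(cis = p$cis_total, trans = p$trans_total,
         cis_fraction = if (tot > 0) p$cis_total / tot else 0,
         high_quality = p$cis_total >= 20000)
  })
  report <- list(
    raw_pairs = read_stats$input_pairs,
    fastq_duplicates = read_stats$duplicates_removed,
    fastq_duplicate_fraction = read_stats$duplicate_fraction,
    merged_fraction = read_stats$merged_fraction,
    with_site_fraction = read_stats$with_site_fraction,
    total_groups = group_stats$total_groups,
    capture_groups = group_stats$capture_groups,
    capture_fraction = group_stats$capture_fraction,
    reporter_given_capture = group_stats$reporter_given_capture,
    informative_groups = group_stats$informative_groups,
    coordinate_duplicates = dedup_removed,
    unique_groups = group_stats$total_groups - dedup_removed,
    viewpoints = per_vp,
    expectations = list(
      fastq_duplicate_fraction = "0.25-0.50 (deep sequencing up to 0.90)",
      merged_fraction = "~0.90 for 150-bp paired reads",
      with_site_fraction = "~0.70 for DpnII at 150-bp reads",
      capture_fraction = "0.80-0.98 of mapped reads",
      reporter_given_capture = "0.60-0.80",
      cis_fraction = ">0.60",
      cis_reporters = ">=20,000 per viewpoint for high quality")
  )
  class(report) <- "qc_report"
  report
}

#' Write a QC report as JSON (and optionally TSV)
#' @param report \code{qc_report}.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Sequencing-depth planner
#'
#' Computes reads available per viewpoint per 3C library and compares with
#' the per-method minimum: 100,000 read pairs for Capture-C (100,000-500,000
#' recommended to reach ~20,000 unique reporters), 1,000,000 for Tri-C, and
#' for Tiled-C 3,000,000 reads per Mb of tiled region. A 20M-read MiSeq run
#' covers 5-25 Capture-C viewpoints across six libraries.
#'
#' @param platform_reads Total read pairs produced by the platform/run.
#' @param n_libraries Number of multiplexed 3C libraries.
#' @param n_viewpoints Number of viewpoints (tiled: number of regions).
#' @param method \code{"capture"}, \code{"tri"} or \code{"tiled"}.
#' @param region_mb Tiled region size in Mb (tiled mode only).
#' @return \code{sequencing_plan} list with
#'   \code{reads_per_viewpoint_per_library} and \code{sufficient}.
#' @export
plan_sequencing <- function(platform_reads, n_libraries, n_viewpoints,
                            method = c("capture", "tri", "tiled"),
                            region_mb = 1) {
  method <- match.arg(method)
  stopifnot(platform_reads > 0, n_libraries > 0, n_viewpoints > 0)
  rpv <- floor(platform_reads / (n_libraries * n_viewpoints))
  minimum <- switch(method,
                    capture = 1e5,
                    tri = 1e6,
                    tiled = 3e6 * region_mb)
  structure(
    list(platform_reads = platform_reads, n_libraries = n_libraries,
         n_viewpoints = n_viewpoints, method = method,
         reads_per_viewpoint_per_library = rpv,
         required_minimum = minimum,
         sufficient = rpv >= minimum),
    class = "sequencing_plan")
}

#' @export
print.sequencing_plan <- function(x, ...) {
  cat(sprintf(
    "<sequencing_plan> %s: %s reads / (%d libraries x %d viewpoints) = %s per viewpoint per library [%s]\n",
    x$method, format(x$platform_reads, big.mark = ","), x$n_libraries,
    x$n_viewpoints, format(x$reads_per_viewpoint_per_library,
                           big.mark = ","),
    if (x$sufficient) "sufficient" else "insufficient"))
  invisible(x)
}

#' Write a fragment-resolution track as bedGraph
#'
#' One interval per restriction fragment carrying the normalised (or
#' difference) signal.
#' @param track data.table(chrom, start, end, signal) or a normalised
#'   \code{reporter_profile}.
#' @param path Output bedGraph.
#' @param name Track name for the header line.
#' @export
write_bedgraph <- function(track, path, name = "capture3C") {
  if (inherits(track, "reporter_profile")) track <- track$normalised
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(track[, .(chrom, start, end, signal)], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Emit UCSC track-hub stanzas
#'
#' Writes \code{hub.txt}, \code{genomes.txt} and \code{trackDb.txt} (relative
#' paths only) describing the bedGraph tracks of a run. Serving the files is
#' the user's concern.
#'
#' @param dir Public directory to write into.
#' @param hub_name Hub label.
#' @param genome_id Genome assembly name.
#' @param track_files Character vector of bedGraph filenames (relative).
#' @export
write_ucsc_hub <- function(dir, hub_name, genome_id, track_files) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    sprintf("hub %s", hub_name),
    sprintf("shortLabel %s", hub_name),
    sprintf("longLabel %s capture3C tracks", hub_name),
    "genomesFile genomes.txt",
    "email nobody@example.org"), file.path(dir, "hub.txt"))
  writeLines(c(sprintf("genome %s", genome_id),
               sprintf("trackDb %s/trackDb.txt", genome_id)),
             file.path(dir, "genomes.txt"))
  gdir <- file.path(dir, genome_id)
  dir.create(gdir, showWarnings = FALSE)
  stanzas <- unlist(lapply(track_files, function(f) {
    nm <- tools::file_path_sans_ext(basename(f))
    c(sprintf("track %s", nm),
      "type bedGraph",
      sprintf("bigDataUrl %s", f),
      sprintf("shortLabel %s", nm),
      sprintf("longLabel %s", nm),
      "visibility full", "")
  }))
  writeLines(stanzas, file.path(gdir, "trackDb.txt"))
  invisible(dir)
}
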