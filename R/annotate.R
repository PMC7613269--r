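#' Viewpoint set
#'
#' Reads a 4-column viewpoint BED (chromosome, fragment start, fragment
#' stop, viewpoint name) into a validated set. For \code{capture} and
#' \code{tri} experiments each entry is a single restriction fragment; for
#' \code{tiled} each entry is an extended region spanning at least two
#' contiguous fragments.
#'
#' @param path 4-column tab-separated BED file.
#' @param mode Experiment type: \code{"capture"}, \code{"tri"} or
#'   \code{"tiled"}.
#' @return A \code{viewpoint_set}: list(entries = data.table(chrom, start,
#'   end, name), mode).
#' @export
read_viewpoints <- function(path, mode = c("capture", "tri", "tiled")) {
  mode <- match.arg(mode)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) != 4L)
    stop("viewpoint BED must have exactly 4 columns, found ", ncol(dt),
         call. = FALSE)
  data.table::setnames(dt, c("chrom", "start", "end", "name"))
  problems <- character()
  if (!is.numeric(dt$start) || !is.numeric(dt$end))
    problems <- c(problems, "non-integer coordinates")
  if (anyDuplicated(dt$name))
    problems <- c(problems,
                  paste("duplicate viewpoint names:",
                        paste(unique(dt$name[duplicated(dt$name)]),
                              collapse = ", ")))
  if (is.numeric(dt$start) && is.numeric(dt$end) && any(dt$start >= dt$end))
    problems <- c(problems, "start >= end in one or more entries")
  if (length(problems))
    stop("invalid viewpoint BED: ", paste(problems, collapse = "; "),
         call. = FALSE)
  viewpoint_set(dt, mode)
}

#' @rdname read_viewpoints
#' @param entries data.frame/data.table with chrom, start, end, name.
#' @export
viewpoint_set <- function(entries, mode = c("capture", "tri", "tiled")) {
  mode <- match.arg(mode)
  entries <- data.table::as.data.table(entries)
  entries[, `:=`(start = as.integer(start), end = as.integer(end),
                 name = as.character(name))]
  structure(list(entries = entries, mode = mode), class = "viewpoint_set")
}

#' @export
print.viewpoint_set <- function(x, ...) {
  cat(sprintf("<viewpoint_set> mode=%s, %d entries\n", x$mode,
              nrow(x$entries)))
  invisible(x)
}

# resolve each viewpoint entry against the fragment map; errors list every
# offending entry rather than the first
resolve_viewpoints <- function(viewpoints, map) {
  stopifnot(inherits(viewpoints, "viewpoint_set"),
            inherits(map, "fragment_map"))
  e <- data.table::copy(viewpoints$entries)
  fr <- map$fragments
  if (viewpoints$mode %in% c("capture", "tri")) {
    m <- merge(e, fr, by = c("chrom", "start", "end"), all.x = TRUE)
    bad <- m[is.na(fragment_id), name]
    if (length(bad))
      stop("viewpoint entries do not coincide with restriction fragments: ",
           paste(bad, collapse = ", "), call. = FALSE)
    m[, .(chrom, start, end, name, fragment_id)]
  } else {
    # tiled: collect all fragments fully contained in each region
    out <- vector("list", nrow(e))
    for (i in seq_len(nrow(e))) {
      sub <- fr[chrom == e$chrom[i] & start >= e$start[i] & end <= e$end[i]]
      if (nrow(sub) < 2L)
        stop("tiled region '", e$name[i],
             "' spans fewer than 2 restriction fragments", call. = FALSE)
      out[[i]] <- data.table::data.table(
        chrom = e$chrom[i], start = e$start[i], end = e$end[i],
        name = e$name[i], fragment_id = sub$fragment_id)
    }
    data.table::rbindlist(out)
  }
}

#' Annotate aligned slices with fragments and reporter classes
#'
#' Assigns each mapped slice to the restriction fragment with the largest
#' overlap (ties resolved to the fragment containing the slice midpoint) and
#' classifies it:
#' \itemize{
#'   \item \code{capture} - the slice's fragment is a viewpoint fragment
#'     (capture/tri) or lies inside a tiled region (tiled);
#'   \item \code{exclusion} - not capture, but overlapping a viewpoint
#'     fragment extended by \code{exclusion_window} bp on each side: these
#'     are religation artefacts in the capture-adjacent fragments;
#'   \item \code{reporter} - mapped and neither of the above;
#'   \item \code{unmapped} - everything else.
#' }
#' Tiled mode never produces the exclusion class.
#'
#' @param alignments Aligned slice table from \code{\link{align_slices}}.
#' @param map \code{fragment_map}.
#' @param viewpoints \code{viewpoint_set}.
#' @param exclusion_window Religation-exclusion window in bp around the
#'   viewpoint fragment.
#' @return Annotated slice table: input columns plus \code{fragment_id,
#'   viewpoint, cls}.
#' @export
annotate_slices <- function(alignments, map, viewpoints,
                            exclusion_window = 1000L) {
  vp <- resolve_viewpoints(viewpoints, map)
  ann <- data.table::as.data.table(alignments)
  ann[, fragment_id := NA_integer_]
  ann[, viewpoint := NA_character_]
  ann[, cls := "unmapped"]
  mp <- which(ann$mapped)
  if (length(mp)) {
    gr_sl <- GenomicRanges::GRanges(
      ann$chrom[mp], IRanges::IRanges(start = ann$start[mp] + 1L,
                                      end = ann$end[mp]))
    fr <- map$fragments
    gr_fr <- GenomicRanges::GRanges(
      fr$chrom, IRanges::IRanges(start = fr$start + 1L, end = fr$end))
    ov <- GenomicRanges::findOverlaps(gr_sl, gr_fr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_sl)[qh], IRanges::ranges(gr_fr)[sh]))
    # largest overlap; ties -> fragment containing the slice midpoint
    mid <- (ann$start[mp] + ann$end[mp]) %/% 2L
    contains_mid <- fr$start[sh] <= mid[qh] & mid[qh] < fr$end[sh]
    o <- order(qh, -w, -contains_mid)
    first <- !duplicated(qh[o])
    assign_q <- qh[o][first]; assign_s <- sh[o][first]
    ann$fragment_id[mp[assign_q]] <- fr$fragment_id[assign_s]
  }
  # capture class: slice's fragment is a viewpoint fragment / in-region
  cap_idx <- match(ann$fragment_id, vp$fragment_id)
  is_cap <- !is.na(cap_idx) & ann$mapped
  ann$cls[is_cap] <- "capture"
  ann$viewpoint[is_cap] <- vp$name[cap_idx[is_cap]]
  if (viewpoints$mode != "tiled") {
    # exclusion: overlap of viewpoint fragment +/- window, not capture
    vfr <- map$fragments[fragment_id %in% vp$fragment_id]
    vfr <- merge(vfr, vp[, .(fragment_id, name)], by = "fragment_id")
    cand <- which(ann$mapped & ann$cls != "capture")
    if (length(cand) && nrow(vfr)) {
      gr_c <- GenomicRanges::GRanges(
        ann$chrom[cand], IRanges::IRanges(start = ann$start[cand] + 1L,
                                          end = ann$end[cand]))
      gr_x <- GenomicRanges::GRanges(
        vfr$chrom,
        IRanges::IRanges(start = pmax(0L, vfr$start - exclusion_window) + 1L,
                         end = vfr$end + exclusion_window))
      ovx <- GenomicRanges::findOverlaps(gr_c, gr_x, select = "first")
      hit <- !is.na(ovx)
      ann$cls[cand[hit]] <- "exclusion"
      ann$viewpoint[cand[hit]] <- vfr$name[ovx[hit]]
    }
    rep_idx <- ann$mapped & !(ann$cls %in% c("capture", "exclusion"))
    ann$cls[rep_idx] <- "reporter"
  } else {
    ann$cls[ann$mapped & ann$cls != "capture"] <- "reporter"
  }
  ann[]
}

#' Group annotated slices into read groups and flag informative ones
#'
#' One read group holds all slices of one sequenced molecule (flashed read or
#' both mates of a PE pair). A group is informative in capture/tri mode when
#' it carries at least one capture slice and at least one reporter slice; in
#' tiled mode when it touches at least two distinct in-region fragments.
#'
#' @param annotated Annotated slice table.
#' @param mode Experiment type.
#' @return list(groups = per-read table with counts, informative flag and
#'   dedup key; stats = filtering counts).
#' @export
group_and_filter <- function(annotated, mode = c("capture", "tri", "tiled")) {
  mode <- match.arg(mode)
  ann <- data.table::as.data.table(annotated)
  coord <- ifelse(ann$mapped,
                  paste0(ann$chrom, ":", ann$start, "-", ann$end), NA)
  ann[, .coord := coord]
  groups <- ann[, .(
    n_slices = .N,
    n_capture = sum(cls == "capture"),
    n_reporter = sum(cls == "reporter"),
    n_exclusion = sum(cls == "exclusion"),
    n_capture_fragments = data.table::uniqueN(fragment_id[cls == "capture"]),
    viewpoints = paste(sort(unique(viewpoint[cls == "capture"])),
                       collapse = ","),
    dedup_key = paste(sort(.coord[!is.na(.coord)]), collapse = ";")
  ), by = read_id]
  ann[, .coord := NULL]
  if (mode == "tiled") {
    groups[, informative := n_capture_fragments >= 2L]
  } else {
    groups[, informative := n_capture >= 1L & n_reporter >= 1L]
  }
  stats <- list(
    total_groups = nrow(groups),
    capture_groups = sum(groups$n_capture >= 1L),
    capture_with_reporter = sum(groups$n_capture >= 1L &
                                  groups$n_reporter >= 1L),
    informative_groups = sum(groups$informative),
    capture_fraction = if (nrow(groups)) mean(groups$n_capture >= 1L) else 0,
    reporter_given_capture = if (any(groups$n_capture >= 1L))
      mean(groups$n_reporter[groups$n_capture >= 1L] >= 1L) else 0
  )
  list(groups = groups, stats = stats)
}

#' Coordinate-based PCR-duplicate removal on read groups
#'
#' Two molecules are PCR duplicates when every mapped slice coordinate
#' matches: the dedup key is the order-invariant sorted tuple of
#' \code{(chrom, start, end)} over all mapped slices of the group. Identical
#' fragments ligated at different sonication ends produce different
#' coordinates and are kept (the sonication-end principle). First occurrence
#' wins; groups with no mapped slice are never collapsed.
#'
#' @param groups Group table from \code{\link{group_and_filter}}.
#' @return list(groups = kept groups in input order, removed = count).
#' @export
dedup_groups <- function(groups) {
  g <- data.table::as.data.table(groups)
  has_key <- nzchar(g$dedup_key)
  dup <- logical(nrow(g))
  dup[has_key] <- duplicated(g$dedup_key[has_key])
  list(groups = g[!dup], removed = sum(dup))
}

#' Write annotated slices as a TSV for downstream tools and debugging
#' @param annotated Annotated slice table.
#' @param path Output TSV.
#' @export
write_annotated_tsv <- function(annotated, path) {
  cols <- c("read_id", "mate", "slice_index", "chrom", "start", "end",
            "strand", "fragment_id", "viewpoint", "cls")
  utils::write.table(annotated[, cols, with = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
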