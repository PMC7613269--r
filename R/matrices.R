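#' Contact-matrix specification
#'
#' Defines the binning of a genomic region for Tri-C or Tiled-C contact
#' matrices. Bins are half-open intervals aligned to the region start; a
#' final partial bin is kept and flagged.
#'
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param bin_size Bin width in bp: Tiled-C default 5,000 (the resolution
#'   the recommended sequencing depth supports), Tri-C default 1,000.
#' @return \code{matrix_spec} list with a \code{bins} table.
#' @export
matrix_spec <- function(chrom, start, end, bin_size = 5000L) {
  stopifnot(bin_size > 0, end - start >= bin_size)
  starts <- seq(start, end - 1L, by = bin_size)
  ends <- pmin(starts + bin_size, end)
  bins <- data.table::data.table(
    bin = seq_along(starts), chrom = chrom, start = starts, end = ends,
    partial = (ends - starts) < bin_size)
  structure(list(chrom = chrom, start = start, end = end,
                 bin_size = as.integer(bin_size), bins = bins,
                 normalisation = "raw"),
            class = "matrix_spec")
}

# map positions (fragment midpoints) to bin index; NA outside the region
bin_of <- function(spec, chrom, pos) {
  b <- ifelse(chrom == spec$chrom & pos >= spec$start & pos < spec$end,
              (pos - spec$start) %/% spec$bin_size + 1L, NA_integer_)
  as.integer(b)
}

new_contact_matrix <- function(spec, values, total_pairs,
                               normalisation = "raw") {
  structure(list(spec = spec, values = values, total_pairs = total_pairs,
                 normalisation = normalisation),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s:%d-%d @ %d bp | %d bins | %s | %d pairs\n",
              x$spec$chrom, x$spec$start, x$spec$end, x$spec$bin_size,
              nrow(x$spec$bins), x$normalisation, x$total_pairs))
  invisible(x)
}

# shared pair-accumulation core: takes (read_id, bin) slice assignments,
# one row per counted reporter slice (tri) or distinct fragment (tiled)
accumulate_pairs <- function(assign, nbins) {
  values <- matrix(0, nbins, nbins)
  total <- 0L
  if (nrow(assign)) {
    pairs <- assign[, {
      k <- .N
      if (k >= 2L) {
        cmb <- utils::combn(bin, 2L)
        list(i = pmin(cmb[1, ], cmb[2, ]), j = pmax(cmb[1, ], cmb[2, ]))
      } else list(i = integer(0), j = integer(0))
    }, by = read_id]
    if (nrow(pairs)) {
      tab <- pairs[, .N, by = .(i, j)]
      for (r in seq_len(nrow(tab))) {
        values[tab$i[r], tab$j[r]] <- values[tab$i[r], tab$j[r]] + tab$N[r]
        if (tab$i[r] != tab$j[r])
          values[tab$j[r], tab$i[r]] <- values[tab$i[r], tab$j[r]]
      }
      total <- sum(tab$N)
    }
  }
  list(values = values, total = total)
}

#' Tri-C multi-way reporter-pair matrix
#'
#' Reads with multiple ligation junctions witness multi-way proximity at
#' single alleles. For each unique read group containing the viewpoint's
#' capture slice and at least two in-region reporter slices, every unordered
#' pair of reporter slices increments its bin pair once (k reporters give
#' choose(k, 2) increments; two reporters in the same bin land on the
#' diagonal). Exclusion-class and out-of-region slices are ignored.
#'
#' @param annotated Annotated slice table (deduplicated informative groups).
#' @param groups Deduplicated group table.
#' @param viewpoint Viewpoint name the matrix is for.
#' @param spec \code{matrix_spec}; the region must be in cis with the
#'   viewpoint.
#' @param map \code{fragment_map}.
#' @param viewpoints \code{viewpoint_set} (to locate the viewpoint fragment).
#' @return \code{contact_matrix}.
#' @export
tri_c_matrix <- function(annotated, groups, viewpoint, spec, map,
                         viewpoints) {
  vp <- resolve_viewpoints(viewpoints, map)
  vrow <- vp[name == viewpoint]
  if (!nrow(vrow))
    stop("unknown viewpoint: ", viewpoint, call. = FALSE)
  if (vrow$chrom[1] != spec$chrom)
    stop("matrix region is on ", spec$chrom, " but viewpoint ", viewpoint,
         " is on ", vrow$chrom[1], call. = FALSE)
  ann <- data.table::as.data.table(annotated)
  keep <- groups[informative == TRUE & grepl(viewpoint, viewpoints,
                                             fixed = TRUE), read_id]
  rep_slices <- ann[read_id %in% keep & cls == "reporter"]
  fr <- map$fragments
  mids <- (fr$start + fr$end) %/% 2L
  rep_slices[, fmid := mids[match(fragment_id, fr$fragment_id)]]
  rep_slices[, fchrom := fr$chrom[match(fragment_id, fr$fragment_id)]]
  rep_slices[, bin := bin_of(spec, fchrom, fmid)]
  assign <- rep_slices[!is.na(bin), .(read_id, bin)]
  acc <- accumulate_pairs(assign, nrow(spec$bins))
  new_contact_matrix(spec, acc$values, acc$total)
}

#' Tiled-C binned contact matrix
#'
#' Hi-C-like semantics over a tiled region: per unique read group, every
#' unordered pair of distinct in-region fragments increments its bin pair
#' once. A group entirely within one fragment contributes nothing.
#'
#' @param annotated Annotated slice table (tiled mode, deduplicated).
#' @param groups Deduplicated group table.
#' @param spec \code{matrix_spec}.
#' @param map \code{fragment_map}.
#' @return \code{contact_matrix}.
#' @export
tiled_c_matrix <- function(annotated, groups, spec, map) {
  ann <- data.table::as.data.table(annotated)
  keep <- groups[informative == TRUE, read_id]
  cap <- unique(ann[read_id %in% keep & cls == "capture",
                    .(read_id, fragment_id)])
  fr <- map$fragments
  mids <- (fr$start + fr$end) %/% 2L
  cap[, fmid := mids[match(fragment_id, fr$fragment_id)]]
  cap[, fchrom := fr$chrom[match(fragment_id, fr$fragment_id)]]
  cap[, bin := bin_of(spec, fchrom, fmid)]
  assign <- cap[!is.na(bin), .(read_id, bin)]
  acc <- accumulate_pairs(assign, nrow(spec$bins))
  new_contact_matrix(spec, acc$values, acc$total)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Balances the matrix so every unmasked bin has the same marginal
#' (iterative proportional fitting). Bins with a zero raw marginal are
#' masked and stay zero. Raw matrices should always be kept alongside.
#'
#' @param mat \code{contact_matrix} (raw).
#' @param max_iter Maximum iterations.
#' @param tol Convergence: maximum relative deviation of unmasked row sums
#'   from their mean.
#' @return Normalised \code{contact_matrix} (\code{normalisation = "ice"}).
#' @export
ice_normalise <- function(mat, max_iter = 100L, tol = 1e-5) {
  stopifnot(inherits(mat, "contact_matrix"))
  W <- mat$values
  if (all(W == 0)) {
    warning("all-zero matrix; returned unchanged")
    return(new_contact_matrix(mat$spec, W, mat$total_pairs, "ice"))
  }
  masked <- rowSums(W) == 0
  idx <- which(!masked)
  V <- W[idx, idx, drop = FALSE]
  for (it in seq_len(max_iter)) {
    s <- rowSums(V)
    s <- s / mean(s)
    if (max(abs(s - 1)) < tol) break
    V <- V / outer(s, s)
  }
  out <- matrix(0, nrow(W), ncol(W))
  out[idx, idx] <- V
  new_contact_matrix(mat$spec, out, mat$total_pairs, "ice")
}

#' Write / read a contact matrix as sparse TSV triplets
#'
#' Upper-triangle triplets \code{(bin_i, bin_j, value)} with a bin-table
#' sidecar; the round-trip is exact.
#'
#' @param mat \code{contact_matrix}.
#' @param path Triplet TSV path; the bin table goes to \code{<path>.bins}.
#' @export
write_contact_matrix <- function(mat, path) {
  ut <- which(upper.tri(mat$values, diag = TRUE) & mat$values != 0,
              arr.ind = TRUE)
  trip <- data.table::data.table(bin_i = ut[, 1], bin_j = ut[, 2],
                                 value = mat$values[ut])
  data.table::setorder(trip, bin_i, bin_j)
  header <- sprintf("#chrom=%s start=%d end=%d bin_size=%d normalisation=%s total_pairs=%d",
                    mat$spec$chrom, mat$spec$start, mat$spec$end,
                    mat$spec$bin_size, mat$normalisation, mat$total_pairs)
  con <- file(path, "w"); writeLines(header, con)
  utils::write.table(format(trip, scientific = FALSE, trim = TRUE,
                            digits = 17),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(mat$spec$bins, paste0(path, ".bins"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- strsplit(sub("^#", "", header), " ")[[1]]
  kv <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  spec <- matrix_spec(kv[["chrom"]], as.integer(kv[["start"]]),
                      as.integer(kv[["end"]]),
                      as.integer(kv[["bin_size"]]))
  trip <- data.table::fread(path, skip = 1L, header = FALSE,
                            col.names = c("bin_i", "bin_j", "value"))
  n <- nrow(spec$bins)
  values <- matrix(0, n, n)
  values[cbind(trip$bin_i, trip$bin_j)] <- trip$value
  values[cbind(trip$bin_j, trip$bin_i)] <- trip$value
  new_contact_matrix(spec, values, as.integer(kv[["total_pairs"]]),
                     kv[["normalisation"]])
}
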