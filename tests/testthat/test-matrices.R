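test_that("matrix binning tiles the region half-open with a flagged partial bin", {
  spec <- matrix_spec("chrA", 1000L, 12500L, 5000L)
  expect_equal(nrow(spec$bins), 3L)
  expect_equal(spec$bins$start, c(1000L, 6000L, 11000L))
  expect_equal(spec$bins$end, c(6000L, 11000L, 12500L))
  expect_equal(spec$bins$partial, c(FALSE, FALSE, TRUE))
  expect_error(matrix_spec("chrA", 0L, 100L, 5000L))
})

# Tri-C fixture: a genome whose viewpoint is a short fragment, simulated
# in tri mode so reads carry multiple junctions
tri_fixture <- function(seed = 61, n = 1000) {
  fx <- small_sim(seed = seed, n = n, method = "tri",
                  duplicate_rate = 0)
  out <- run_capture_pipeline(fx)
  c(fx, out)
}

test_that("Tri-C matrices count reporter pairs combinatorially", {
  fx <- tri_fixture()
  v <- fx$vp$entries
  spec <- matrix_spec(v$chrom, max(0L, v$start - 50000L),
                      v$end + 50000L, 1000L)
  mat <- tri_c_matrix(fx$annotated, fx$dedup$groups, "VP1", spec, fx$map,
                      fx$vp)
  # symmetry and integer raw counts
  expect_true(isSymmetric(mat$values))
  expect_true(all(mat$values >= 0))
  expect_true(all(mat$values == round(mat$values)))
  # total_pairs = sum over groups of choose(k, 2) with k = in-region
  # reporter count; upper triangle + diagonal sums to total_pairs
  keep <- fx$dedup$groups[informative == TRUE, read_id]
  fr <- fx$map$fragments
  ann <- fx$annotated[read_id %in% keep & cls == "reporter"]
  ann[, mid := (fr$start[match(fragment_id, fr$fragment_id)] +
                  fr$end[match(fragment_id, fr$fragment_id)]) %/% 2L]
  ann[, fchr := fr$chrom[match(fragment_id, fr$fragment_id)]]
  inreg <- ann[fchr == spec$chrom & mid >= spec$start & mid < spec$end]
  k <- inreg[, .N, by = read_id]
  expect_equal(mat$total_pairs, sum(choose(k$N, 2)))
  expect_equal(sum(mat$values[upper.tri(mat$values, diag = TRUE)]),
               mat$total_pairs)
  # brute-force pair enumeration reproduces every cell
  brute <- matrix(0, nrow(spec$bins), nrow(spec$bins))
  for (rid in unique(inreg$read_id)) {
    bins <- (inreg[read_id == rid, mid] - spec$start) %/% 1000L + 1L
    if (length(bins) >= 2) {
      cmb <- utils::combn(bins, 2)
      for (cc in seq_len(ncol(cmb))) {
        i <- min(cmb[, cc]); j <- max(cmb[, cc])
        brute[i, j] <- brute[i, j] + 1
        if (i != j) brute[j, i] <- brute[i, j]
      }
    }
  }
  expect_equal(mat$values, brute)
  # a region on another contig is rejected
  expect_error(tri_c_matrix(fx$annotated, fx$dedup$groups, "VP1",
                            matrix_spec("chrS2", 0L, 50000L, 1000L),
                            fx$map, fx$vp), "chrS2")
})

test_that("Tri-C runs carry multiple reporters per read as designed", {
  fx <- tri_fixture(seed = 62, n = 2000)
  keep <- fx$dedup$groups[informative == TRUE]
  # pipeline-observed reporter slices agree with the simulator's own
  # visibility bookkeeping read-by-read
  got <- mean(keep$n_reporter)
  truth <- fx$truth$molecules[match(keep$read_id, read_id),
                              reporter_slices_visible]
  expect_lt(abs(got - mean(truth)), 0.1)
  # concatemers carry the configured multi-way degree on average
  expect_equal(mean(fx$truth$molecules$k_reporters), 2.5, tolerance = 0.05)
  # and the longer Tri-C sonication exposes more reporters per read than
  # the capture-mode geometry does
  fc <- small_sim(seed = 62, n = 2000, method = "capture",
                  duplicate_rate = 0)
  oc <- run_capture_pipeline(fc)
  cap_mean <- mean(oc$dedup$groups[informative == TRUE, n_reporter])
  expect_gt(got, cap_mean + 0.3)
  expect_gt(got, 1.5)
})

test_that("Tiled-C matrices count distinct fragment pairs per read group", {
  set.seed(63)
  cuts <- seq(400, 19600, by = 400)
  g <- c(chrA = planted_genome(20000, cuts))
  map <- digest_genome(g, enzyme_spec("DpnII"))
  vp <- viewpoint_set(data.table::data.table(
    chrom = "chrA", start = 2000L, end = 18000L, name = "tile"), "tiled")
  fr <- map$fragments
  mk_slice <- function(rid, pos) data.table::data.table(
    read_id = rid, mate = "flashed", slice_index = 0L, seq = "A",
    has_upstream_site = FALSE, has_downstream_site = FALSE,
    mappable = TRUE, chrom = "chrA", start = pos, end = pos + 60L,
    strand = "+", mapped = TRUE, mapq = 60L)
  aln <- data.table::rbindlist(list(
    mk_slice("two_frag", 2100L), mk_slice("two_frag", 6100L),
    mk_slice("one_frag", 9000L), mk_slice("one_frag", 9040L),
    mk_slice("three", 2500L), mk_slice("three", 10500L),
    mk_slice("three", 17000L)))
  ann <- annotate_slices(aln, map, vp)
  gf <- group_and_filter(ann, "tiled")
  spec <- matrix_spec("chrA", 2000L, 18000L, 4000L)
  mat <- tiled_c_matrix(ann, gf$groups, spec, map)
  # 2 distinct fragments -> 1 increment; 1 fragment -> 0; 3 -> 3
  expect_equal(mat$total_pairs, 1L + 0L + 3L)
  # brute force over distinct fragments per group
  brute <- matrix(0, 4, 4)
  for (rid in c("two_frag", "three")) {
    fids <- unique(ann[read_id == rid & cls == "capture", fragment_id])
    mids <- (fr$start[match(fids, fr$fragment_id)] +
               fr$end[match(fids, fr$fragment_id)]) %/% 2L
    bins <- (mids - 2000L) %/% 4000L + 1L
    cmb <- utils::combn(bins, 2)
    for (cc in seq_len(ncol(cmb))) {
      i <- min(cmb[, cc]); j <- max(cmb[, cc])
      brute[i, j] <- brute[i, j] + 1
      if (i != j) brute[j, i] <- brute[i, j]
    }
  }
  expect_equal(mat$values, brute)
})

test_that("binning is translation-consistent", {
  set.seed(64)
  cuts <- seq(400, 19600, by = 400)
  g <- c(chrA = planted_genome(20000, cuts))
  map <- digest_genome(g, enzyme_spec("DpnII"))
  vp <- viewpoint_set(data.table::data.table(
    chrom = "chrA", start = 2000L, end = 18000L, name = "tile"), "tiled")
  aln <- data.table::data.table(
    read_id = rep("g", 2), mate = "flashed", slice_index = 0:1, seq = "A",
    has_upstream_site = FALSE, has_downstream_site = FALSE,
    mappable = TRUE, chrom = "chrA", start = c(4100L, 12100L),
    end = c(4160L, 12160L), strand = "+", mapped = TRUE, mapq = 60L)
  ann <- annotate_slices(aln, map, vp)
  gf <- group_and_filter(ann, "tiled")
  m1 <- tiled_c_matrix(ann, gf$groups,
                       matrix_spec("chrA", 2000L, 18000L, 2000L), map)
  m2 <- tiled_c_matrix(ann, gf$groups,
                       matrix_spec("chrA", 4000L, 18000L, 2000L), map)
  w1 <- which(m1$values > 0, arr.ind = TRUE)
  w2 <- which(m2$values > 0, arr.ind = TRUE)
  expect_equal(w1 - 1L, w2)   # one-bin shift of the region start
})

test_that("iterative correction equalises unmasked marginals", {
  set.seed(65)
  # random positive symmetric 100x100 with a few zeroed (masked) bins
  A <- matrix(stats::runif(100 * 100, 0.1, 5), 100)
  W <- (A + t(A)) / 2
  W[5, ] <- 0; W[, 5] <- 0; W[77, ] <- 0; W[, 77] <- 0
  mat <- structure(list(spec = matrix_spec("c", 0L, 100000L, 1000L),
                        values = W, total_pairs = 0L,
                        normalisation = "raw"), class = "contact_matrix")
  out <- ice_normalise(mat, tol = 1e-5)
  rs <- rowSums(out$values)
  unmasked <- setdiff(seq_len(100), c(5, 77))
  expect_lt(max(abs(rs[unmasked] / mean(rs[unmasked]) - 1)), 1e-5)
  expect_true(all(rs[c(5, 77)] == 0))
  expect_true(isSymmetric(out$values))
  # an already-balanced matrix is a fixed point
  U <- matrix(1, 10, 10)
  matu <- structure(list(spec = matrix_spec("c", 0L, 10000L, 1000L),
                         values = U, total_pairs = 0L,
                         normalisation = "raw"), class = "contact_matrix")
  expect_equal(ice_normalise(matu)$values, U)
  # all-zero input returned unchanged with a warning
  z <- matu; z$values <- matrix(0, 10, 10)
  expect_warning(zz <- ice_normalise(z), "all-zero")
  expect_equal(zz$values, z$values)
})

test_that("triplet serialization round-trips bit-exactly", {
  set.seed(66)
  spec <- matrix_spec("chrA", 0L, 20000L, 2000L)
  n <- nrow(spec$bins)
  V <- matrix(0, n, n)
  idx <- which(upper.tri(V, diag = TRUE))
  vals <- sample(0:9, length(idx), replace = TRUE)
  V[idx] <- vals
  V <- pmax(V, t(V))
  mat <- structure(list(spec = spec, values = V,
                        total_pairs = sum(V[upper.tri(V, diag = TRUE)]),
                        normalisation = "raw"), class = "contact_matrix")
  f <- tempfile(fileext = ".tsv")
  write_contact_matrix(mat, f)
  back <- read_contact_matrix(f)
  expect_equal(back$values, mat$values)
  expect_equal(back$total_pairs, mat$total_pairs)
  expect_equal(back$spec$bins, mat$spec$bins)
})
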