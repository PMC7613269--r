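# minimal two-contig fixture with a known viewpoint fragment
quant_fixture <- function(seed = 51) {
  set.seed(seed)
  cuts_a <- seq(400, 4400, by = 400)
  g <- c(chrA = planted_genome(5000, cuts_a),
         chrB = planted_genome(3000, c(1000, 2000)))
  map <- digest_genome(g, enzyme_spec("DpnII"))
  vp <- viewpoint_set(data.table::data.table(
    chrom = "chrA", start = 2000L, end = 2400L, name = "VP"), "capture")
  list(map = map, vp = vp)
}

fake_annotated <- function(read_id, chrom, start, end, cls, viewpoint,
                           fragment_id) {
  data.table::data.table(
    read_id = read_id, mate = "flashed",
    slice_index = seq_along(read_id) - 1L, seq = "A",
    has_upstream_site = FALSE, has_downstream_site = FALSE,
    mappable = TRUE, chrom = chrom, start = start, end = end,
    strand = "+", mapped = TRUE, mapq = 60L,
    fragment_id = fragment_id, viewpoint = viewpoint, cls = cls)
}

fake_groups <- function(read_ids) {
  data.table::data.table(read_id = read_ids, n_slices = 3L,
                         n_capture = 1L, n_reporter = 2L,
                         n_exclusion = 0L, n_capture_fragments = 1L,
                         viewpoints = "VP", dedup_key = read_ids,
                         informative = TRUE)
}

test_that("reporter counting tallies per slice with cis/trans bookkeeping", {
  fx <- quant_fixture()
  fr <- fx$map$fragments
  f1 <- fr[chrom == "chrA" & start == 800L, fragment_id]
  f2 <- fr[chrom == "chrA" & start == 4000L, fragment_id]
  ftrans <- fr[chrom == "chrB"][1, fragment_id]
  ann <- fake_annotated(
    read_id = rep("g1", 4),
    chrom = c("chrA", "chrA", "chrA", "chrB"),
    start = c(2100L, 850L, 4010L, 100L),
    end = c(2160L, 910L, 4070L, 160L),
    cls = c("capture", "reporter", "reporter", "reporter"),
    viewpoint = c("VP", NA, NA, NA),
    fragment_id = c(fr[chrom == "chrA" & start == 2000L, fragment_id],
                    f1, f2, ftrans))
  prof <- count_reporters(ann, fake_groups("g1"), fx$vp, fx$map)
  p <- prof$VP
  expect_equal(p$counts[fragment_id == f1, count], 1L)
  expect_equal(p$counts[fragment_id == f2, count], 1L)
  expect_equal(p$cis_total, 2L)
  expect_equal(p$trans_total, 1L)
  expect_equal(p$cis_total + p$trans_total, sum(p$counts$count))
})

test_that("reporter totals equal a flat-file recount of the annotated TSV", {
  fx <- small_sim(seed = 52, n = 800)
  out <- run_capture_pipeline(fx)
  p <- out$profiles$VP1
  tsv <- tempfile(fileext = ".tsv")
  write_annotated_tsv(out$annotated, tsv)
  flat <- data.table::fread(tsv)
  keep <- out$dedup$groups[informative == TRUE, read_id]
  recount <- flat[read_id %in% keep & cls == "reporter", .N,
                  by = fragment_id]
  m <- merge(p$counts, recount, by = "fragment_id", all = TRUE)
  expect_equal(m$count, m$N)
  expect_equal(sum(p$counts$count), sum(recount$N))
})

test_that("cis normalisation scales, conserves and survives count scaling", {
  fx <- quant_fixture()
  fr <- fx$map$fragments
  mk <- function(counts) {
    structure(list(
      viewpoint = "VP", viewpoint_chrom = "chrA",
      counts = data.table::data.table(
        fragment_id = fr$fragment_id[seq_along(counts)],
        chrom = "chrA", start = fr$start[seq_along(counts)],
        end = fr$end[seq_along(counts)], count = counts, cis = TRUE),
      cis_total = sum(counts), trans_total = 0L,
      normalised = NULL, scale = NULL), class = "reporter_profile")
  }
  # cis_total 50 with count 5 -> 10,000 per 100,000
  p <- mk(c(5L, 45L))
  n <- normalise_cis(p)
  expect_equal(n$normalised$signal[1], 10000)
  # tripling all counts leaves the normalised track unchanged
  n3 <- normalise_cis(mk(c(15L, 135L)))
  expect_equal(n3$normalised$signal, n$normalised$signal)
  # conservation: normalised sums to the scale constant
  set.seed(53)
  for (i in 1:100) {
    cnt <- sample.int(50, sample(2:8, 1))
    expect_equal(sum(normalise_cis(mk(cnt))$normalised$signal), 1e5)
  }
  # zero cis reporters: empty track plus a warning
  empty <- structure(list(viewpoint = "VP", viewpoint_chrom = "chrA",
                          counts = mk(1L)$counts[0], cis_total = 0L,
                          trans_total = 3L, normalised = NULL,
                          scale = NULL), class = "reporter_profile")
  expect_warning(ne <- normalise_cis(empty), "no cis")
  expect_equal(nrow(ne$normalised), 0L)
})

test_that("replicate means and subtraction tracks obey their algebra", {
  fx <- quant_fixture()
  fr <- fx$map$fragments
  mk <- function(sig, ids = fr$fragment_id[seq_along(sig)]) {
    structure(list(viewpoint = "VP", viewpoint_chrom = "chrA",
                   normalised = data.table::data.table(
                     fragment_id = ids, chrom = "chrA",
                     start = fr$start[match(ids, fr$fragment_id)],
                     end = fr$end[match(ids, fr$fragment_id)],
                     signal = sig)), class = "reporter_profile")
  }
  a <- mk(c(10, 20)); b <- mk(c(0, 40))
  m <- mean_profiles(list(a, b))
  expect_equal(m$signal, c(5, 30))
  # identical replicates -> mean equals each
  expect_equal(mean_profiles(list(a, a))$signal, c(10, 20))
  # absent fragments count as zero
  c2 <- mk(6, ids = fr$fragment_id[3])
  m2 <- mean_profiles(list(a, c2))
  expect_equal(m2[fragment_id == fr$fragment_id[3], signal], 3)
  expect_equal(m2[fragment_id == fr$fragment_id[1], signal], 5)
  # random profiles match recomputation from raw sums
  set.seed(54)
  ps <- lapply(1:3, function(i) mk(stats::runif(5, 0, 100)))
  m3 <- mean_profiles(ps)
  want <- Reduce(`+`, lapply(ps, function(p) p$normalised$signal)) / 3
  expect_equal(m3$signal, want)
  # subtraction: zero on equal inputs, antisymmetric otherwise
  expect_true(all(subtract_profiles(m, m)$signal == 0))
  d1 <- subtract_profiles(mean_profiles(list(a)), mean_profiles(list(b)))
  d2 <- subtract_profiles(mean_profiles(list(b)), mean_profiles(list(a)))
  expect_equal(d1$signal, -d2$signal)
  # planted differential fragment carries the extreme value
  hi <- mk(c(10, 10, 80)); lo <- mk(c(10, 10, 5))
  d3 <- subtract_profiles(mean_profiles(list(hi)),
                          mean_profiles(list(lo)))
  expect_equal(d3[which.max(abs(signal)), fragment_id],
               fr$fragment_id[3])
  bad <- mk(c(1)); bad$viewpoint <- "other"
  expect_error(mean_profiles(list(a, bad)), "mix viewpoints")
})

test_that("the QC report degrades gracefully and keeps counts monotone", {
  empty_stats <- process_reads(
    data.table::data.table(read_id = character(), r1_seq = character(),
                           r2_seq = character(), r1_qual = character(),
                           r2_qual = character()),
    enzyme_spec("DpnII"))$stats
  rep0 <- build_qc_report(empty_stats,
                          list(total_groups = 0L, capture_groups = 0L,
                               capture_with_reporter = 0L,
                               informative_groups = 0L,
                               capture_fraction = 0,
                               reporter_given_capture = 0))
  expect_equal(rep0$raw_pairs, 0L)
  expect_false(is.nan(rep0$capture_fraction))
  fx <- small_sim(seed = 55, n = 500)
  out <- run_capture_pipeline(fx)
  qc <- build_qc_report(out$read_stats, out$group_stats,
                        out$dedup$removed, out$profiles)
  # counts never increase along the pipeline
  expect_lte(qc$total_groups, qc$raw_pairs - qc$fastq_duplicates)
  expect_lte(qc$capture_groups, qc$total_groups)
  expect_lte(qc$informative_groups, qc$capture_groups)
  expect_lte(qc$unique_groups, qc$total_groups)
  f <- tempfile(fileext = ".json")
  write_qc_report(qc, f)
  expect_equal(jsonlite::read_json(f)$raw_pairs, qc$raw_pairs)
})

test_that("the sequencing-depth planner applies per-method minima linearly", {
  p <- plan_sequencing(2e7, 6, 25, "capture")
  expect_equal(p$reads_per_viewpoint_per_library, 133333)
  expect_true(p$sufficient)
  p2 <- plan_sequencing(2e7, 6, 40, "capture")
  expect_equal(p2$reads_per_viewpoint_per_library, 83333)
  expect_false(p2$sufficient)
  # doubling platform reads doubles depth (floor effects aside)
  p3 <- plan_sequencing(4e7, 6, 25, "capture")
  expect_equal(p3$reads_per_viewpoint_per_library,
               2 * p$reads_per_viewpoint_per_library)
  expect_true(plan_sequencing(6.1e6, 2, 3, "tri")$sufficient)
  expect_false(plan_sequencing(5.9e6, 2, 3, "tri")$sufficient)
  expect_true(plan_sequencing(2e7, 3, 1, "tiled", region_mb = 2)$sufficient)
  expect_false(plan_sequencing(1.7e7, 3, 1, "tiled",
                               region_mb = 2)$sufficient)
})

test_that("tracks and hub stanzas are written in browser-ready form", {
  fx <- small_sim(seed = 56, n = 400)
  out <- run_capture_pipeline(fx)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(out$profiles$VP1, f, name = "VP1")
  lines <- readLines(f)
  expect_match(lines[1], "^track type=bedGraph")
  body <- data.table::fread(text = lines[-1])
  expect_equal(ncol(body), 4L)
  expect_true(all(body$V2 < body$V3))
  hub <- tempfile("hub"); dir.create(hub)
  write_ucsc_hub(hub, "testhub", "simgenome", basename(f))
  expect_true(file.exists(file.path(hub, "hub.txt")))
  expect_true(file.exists(file.path(hub, "genomes.txt")))
  expect_true(any(grepl("bedGraph",
                        readLines(file.path(hub, "simgenome",
                                            "trackDb.txt")))))
})
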