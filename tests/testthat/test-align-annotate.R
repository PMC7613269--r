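# fabricate an aligned-slice table directly (coordinates 0-based half-open)
fake_aln <- function(read_id, chrom, start, end, mate = "flashed",
                     mapped = TRUE) {
  n <- length(read_id)
  data.table::data.table(
    read_id = read_id, mate = mate,
    slice_index = unlist(lapply(table(read_id)[unique(read_id)],
                                function(k) seq_len(k) - 1L))[
                                  order(order(read_id))],
    seq = strrep("A", 30), has_upstream_site = FALSE,
    has_downstream_site = FALSE, mappable = TRUE,
    chrom = chrom, start = start, end = end,
    strand = "+", mapped = mapped, mapq = ifelse(mapped, 60L, 0L))
}

annotate_fixture <- function(seed = 41) {
  set.seed(seed)
  # fragment boundaries at known cut positions; viewpoint = [2000, 2600)
  cuts <- c(400, 1000, 1600, 2000, 2600, 3200, 3900, 4500)
  g <- c(chrA = planted_genome(5000, cuts), chrB = planted_genome(2000, 1000))
  map <- digest_genome(g, enzyme_spec("DpnII"))
  vp <- viewpoint_set(data.table::data.table(
    chrom = "chrA", start = 2000L, end = 2600L, name = "VP"), "capture")
  list(genome = Biostrings::DNAStringSet(g), raw = g, map = map, vp = vp)
}

test_that("the exact mapper maps unique sequences and rejects ambiguous ones", {
  set.seed(42)
  g <- Biostrings::DNAStringSet(c(u1 = random_dna(3000),
                                  u2 = random_dna(2000)))
  # unique slice copied verbatim from a known location
  sl <- as.character(Biostrings::extractAt(
    g[[1]], IRanges::IRanges(501, 580)))
  res <- exact_match_mapper(sl, g)
  expect_true(res$mapped)
  expect_equal(res$chrom, "u1")
  expect_equal(res$start, 500L)
  expect_equal(res$end, 580L)
  expect_equal(res$strand, "+")
  # its reverse complement maps to the same locus on the minus strand
  res_rc <- exact_match_mapper(oracle_revcomp(sl), g)
  expect_true(res_rc$mapped)
  expect_equal(res_rc$start, 500L)
  expect_equal(res_rc$strand, "-")
  # a duplicated locus is ambiguous -> unmapped with 2 hits
  dup <- random_dna(60)
  g2 <- Biostrings::DNAStringSet(c(d1 = paste0(random_dna(500), dup,
                                               random_dna(500), dup,
                                               random_dna(200))))
  res2 <- exact_match_mapper(dup, g2)
  expect_false(res2$mapped)
  expect_equal(res2$nhits, 2L)
  # absent and too-short sequences stay unmapped
  res3 <- exact_match_mapper(c(random_dna(40), "ACGT"), g)
  expect_false(any(res3$mapped))
})

test_that("simulated slices map back to their origins almost completely", {
  fx <- small_sim(seed = 43, n = 500)
  pr <- process_reads(fx$pairs, fx$cfg$enzyme)
  mappable <- pr$slices[mappable == TRUE & nchar(seq) >= 20]
  al <- align_slices(pr$slices, fx$genome)
  rate <- mean(al[mappable == TRUE & nchar(seq) >= 20, mapped])
  expect_gte(rate, 0.99)
  # spot-verify mapped coordinates reproduce the slice sequence
  m <- al[mapped == TRUE][1:50]
  for (i in seq_len(nrow(m))) {
    ref <- as.character(Biostrings::extractAt(
      fx$genome[[m$chrom[i]]],
      IRanges::IRanges(m$start[i] + 1L, m$end[i])))
    if (m$strand[i] == "-") ref <- oracle_revcomp(ref)
    expect_equal(ref, m$seq[i])
  }
})

test_that("slice classification matches brute-force interval arithmetic", {
  fx <- annotate_fixture()
  aln <- fake_aln(
    read_id = c("r1", "r2", "r2", "r3"),
    chrom = "chrA",
    start = c(2100L, 1650L, 100L, 700L),
    end = c(2180L, 1700L, 180L, 760L))
  ann <- annotate_slices(aln, fx$map, fx$vp, exclusion_window = 1000L)
  # exclusion zone is [2000,2600) +- 1000 = [1000, 3600): the slice at
  # [1650,1700) falls in it, [700,760) is clear of it
  expect_equal(ann$cls, c("capture", "exclusion", "reporter", "reporter"))
})

test_that("classification table equals an interval oracle on simulated slices", {
  fx <- small_sim(seed = 44, n = 500)
  pr <- process_reads(fx$pairs, fx$cfg$enzyme)
  al <- align_slices(pr$slices, fx$genome)
  ann <- annotate_slices(al, fx$map, fx$vp, exclusion_window = 1000L)
  # every mapped slice gets exactly one class; classes partition
  expect_true(all(ann[mapped == TRUE, cls] %in%
                    c("capture", "exclusion", "reporter")))
  expect_true(all(ann[mapped == FALSE, cls] == "unmapped"))
  v <- fx$vp$entries
  fr <- fx$map$fragments
  sub <- ann[mapped == TRUE][1:500]
  for (i in seq_len(nrow(sub))) {
    s <- sub[i]
    ovl <- fr[chrom == s$chrom & start < s$end & end > s$start]
    w <- pmin(ovl$end, s$end) - pmax(ovl$start, s$start)
    best <- ovl[which.max(w)]   # ties absent in this fixture check
    if (max(w) == sort(w, decreasing = TRUE)[1] &&
        sum(w == max(w)) == 1) {
      expect_equal(s$fragment_id, best$fragment_id)
    }
    in_vp <- s$chrom == v$chrom && best$start == v$start &&
      best$end == v$end
    in_excl <- s$chrom == v$chrom && s$start < v$end + 1000 &&
      s$end > v$start - 1000
    want <- if (in_vp) "capture" else if (in_excl) "exclusion"
            else "reporter"
    expect_equal(s$cls, want)
  }
})

test_that("viewpoints that do not coincide with fragments are rejected with names", {
  fx <- annotate_fixture()
  bad <- viewpoint_set(data.table::data.table(
    chrom = "chrA", start = 2001L, end = 2600L, name = "offByOne"),
    "capture")
  expect_error(annotate_slices(fake_aln("r", "chrA", 10L, 40L),
                               fx$map, bad), "offByOne")
})

test_that("read groups and informative flags follow the mode rules", {
  fx <- annotate_fixture()
  aln <- fake_aln(
    read_id = c("capOnly", "good", "good", "good", "repOnly"),
    chrom = "chrA",
    start = c(2100L, 2100L, 4000L, 4600L, 4000L),
    end = c(2160L, 2160L, 4060L, 4660L, 4060L))
  ann <- annotate_slices(aln, fx$map, fx$vp)
  gf <- group_and_filter(ann, "capture")
  g <- gf$groups[order(read_id)]
  expect_equal(g[read_id == "capOnly", informative], FALSE)
  expect_equal(g[read_id == "good", informative], TRUE)
  expect_equal(g[read_id == "good", n_reporter], 2L)
  expect_equal(g[read_id == "repOnly", informative], FALSE)
  expect_equal(gf$stats$total_groups, 3L)
  expect_equal(gf$stats$capture_groups, 2L)
  expect_equal(gf$stats$capture_with_reporter, 1L)
})

test_that("coordinate deduplication keys on sonication ends, order-invariantly", {
  fx <- annotate_fixture()
  aln <- fake_aln(
    read_id = c("a", "a", "b", "b", "c", "c"),
    chrom = "chrA",
    # b repeats a's coordinates in swapped slice order; c shifts one end
    start = c(2100L, 4000L, 4000L, 2100L, 2100L, 4003L),
    end = c(2160L, 4060L, 4060L, 2160L, 2160L, 4060L))
  ann <- annotate_slices(aln, fx$map, fx$vp)
  gf <- group_and_filter(ann, "capture")
  dd <- dedup_groups(gf$groups)
  expect_equal(dd$removed, 1L)
  expect_setequal(dd$groups$read_id, c("a", "c"))   # first-seen kept
  # idempotent
  dd2 <- dedup_groups(dd$groups)
  expect_equal(dd2$removed, 0L)
})

test_that("injected coordinate-level duplicates are removed without touching real molecules", {
  fx <- small_sim(seed = 45, n = 1500, duplicate_rate = 0.25,
                  duplicate_mode = "coordinate")
  # skip FASTQ dedup so identical-sequence copies reach the coordinate stage
  pr <- process_reads(fx$pairs, fx$cfg$enzyme, dedup = FALSE)
  al <- align_slices(pr$slices, fx$genome)
  ann <- annotate_slices(al, fx$map, fx$vp)
  gf <- group_and_filter(ann, fx$vp$mode)
  dd <- dedup_groups(gf$groups)
  injected <- fx$truth$duplicates$read_id
  kept <- dd$groups$read_id
  # every injected duplicate whose parent is present must be gone
  expect_length(intersect(kept, injected), 0L)
  # no informative original molecule may be lost to a key collision
  informative_orig <- gf$groups[informative == TRUE &
                                  !read_id %in% injected, read_id]
  expect_setequal(intersect(kept, informative_orig), informative_orig)
})

test_that("tiled mode never produces the exclusion class and needs two fragments", {
  set.seed(46)
  cuts <- seq(400, 4400, by = 400)
  g <- c(chrA = planted_genome(5000, cuts))
  map <- digest_genome(g, enzyme_spec("DpnII"))
  vp <- viewpoint_set(data.table::data.table(
    chrom = "chrA", start = 800L, end = 2800L, name = "tile"), "tiled")
  aln <- fake_aln(
    read_id = c("one", "one", "two"),
    chrom = "chrA",
    start = c(900L, 2500L, 1300L), end = c(960L, 2560L, 1360L))
  ann <- annotate_slices(aln, map, vp)
  expect_false(any(ann$cls == "exclusion"))
  expect_equal(ann$cls[1:2], c("capture", "capture"))
  gf <- group_and_filter(ann, "tiled")
  g2 <- gf$groups[order(read_id)]
  expect_true(g2[read_id == "one", informative])     # 2 distinct fragments
  expect_false(g2[read_id == "two", informative])    # only 1
})

test_that("the external aligner adapter drives bwa through SAM to coordinates", {
  set.seed(47)
  g <- Biostrings::DNAStringSet(c(ref = random_dna(50000)))
  td <- tempfile("bwa"); dir.create(td)
  fa <- file.path(td, "ref.fa")
  write_genome(g, fa)
  system(paste("bwa index", fa, "2>/dev/null"))
  starts <- sample(1000:48000, 25)
  slices <- data.table::data.table(
    read_id = sprintf("s%02d", seq_along(starts)), mate = "flashed",
    slice_index = 0L,
    seq = vapply(starts, function(s) as.character(Biostrings::extractAt(
      g[[1]], IRanges::IRanges(s, s + 79))), ""),
    has_upstream_site = FALSE, has_downstream_site = FALSE,
    mappable = TRUE)
  aligner <- make_external_aligner(
    "bwa mem -v 1 {index} {fastq} > {sam}")
  al <- align_slices(slices, fa, aligner = aligner)
  expect_true(all(al$mapped))
  expect_equal(al$start, starts - 1L)
  expect_equal(al$end, starts + 79L)
})
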