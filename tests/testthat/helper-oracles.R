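# Independent brute-force oracles and fixture builders. These deliberately
# use naive algorithms (window scans, all-offset searches, linear scans)
# so they cannot share a defect with the implementation.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# naive window scan over every offset; cut at motif start or end
oracle_cut_sites <- function(seq, motif, convention) {
  w <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - w + 1L)) {
    if (substr(seq, i, i + w - 1L) == motif) hits <- c(hits, i - 1L)
  }
  if (convention == "after_site") hits <- hits + w
  hits
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# all-offset brute-force overlap merge; mirrors the documented contract:
# longest overlap >= min_overlap with mismatch count <= floor(rate * o)
oracle_merge <- function(r1, r2, min_overlap = 10, rate = 0.25) {
  b <- oracle_revcomp(r2)
  la <- nchar(r1); lb <- nchar(b)
  for (o in seq(min(la, lb), min_overlap)) {
    x <- substr(r1, la - o + 1L, la)
    y <- substr(b, 1L, o)
    mism <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (mism <= floor(rate * o))
      return(paste0(r1, substr(b, o + 1L, lb)))
  }
  NA_character_
}

# genome with motif instances planted at given 0-based positions and no
# accidental occurrences elsewhere: accidental motifs are destroyed by
# mutating their first base, then the wanted copies are planted
planted_genome <- function(length, positions, motif = "GATC") {
  s <- strsplit(random_dna(length), "")[[1]]
  w <- nchar(motif)
  repeat {
    seq <- paste(s, collapse = "")
    found <- oracle_cut_sites(seq, motif, "before_site")
    stray <- setdiff(found, as.integer(positions))
    if (!length(stray)) break
    for (p in stray)
      s[p + 1L] <- setdiff(c("A", "C", "G", "T"), s[p + 1L])[1]
  }
  for (p in positions)
    s[(p + 1):(p + w)] <- strsplit(motif, "")[[1]]
  seq <- paste(s, collapse = "")
  stopifnot(identical(oracle_cut_sites(seq, motif, "before_site"),
                      as.integer(sort(positions))))
  seq
}

# a small simulated capture experiment shared by several tests
small_sim <- function(seed = 11, n = 2000, method = "capture", ...) {
  cfg <- simulation_config(seed = seed, method = method, n_molecules = n,
                           ...)
  sim <- simulate_genome(cfg)
  vp <- pick_viewpoints(sim$map, cfg$method)
  rd <- simulate_reads(sim$genome, sim$map, cfg, vp)
  list(cfg = cfg, genome = sim$genome, map = sim$map, vp = vp,
       pairs = rd$pairs, truth = rd$truth)
}

run_capture_pipeline <- function(fx, dedup = TRUE) {
  pr <- process_reads(fx$pairs, fx$cfg$enzyme, dedup = dedup)
  al <- align_slices(pr$slices, fx$genome)
  ann <- annotate_slices(al, fx$map, fx$vp)
  gf <- group_and_filter(ann, fx$vp$mode)
  dd <- dedup_groups(gf$groups)
  profiles <- count_reporters(ann, dd$groups, fx$vp, fx$map)
  list(read_stats = pr$stats, slices = pr$slices, aligned = al,
       annotated = ann, groups = gf$groups, group_stats = gf$stats,
       dedup = dd, profiles = lapply(profiles, normalise_cis))
}
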