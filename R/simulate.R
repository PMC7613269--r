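#' Simulation configuration
#'
#' Bundles every parameter of the synthetic 3C read generator. The defaults
#' describe the experimental conditions the protocol targets: 150-bp
#' paired-end reads, sonication to a mean of 200 bp for capture experiments
#' (450 bp for Tri-C, whose longer fragments carry multiple ligation
#' junctions), PCR-duplicate content of 30\% of reads (deep capture
#' libraries typically show 25-50\%), a 20\% trans-ligation noise rate
#' (keeping the cis fraction comfortably above the 60\% quality bar), and a
#' genomic-distance decay P(d) proportional to 1/d for cis reporter
#' sampling. Tri-C uses NlaIII (smaller median fragment size), the other
#' methods DpnII.
#'
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @param method \code{"capture"}, \code{"tri"} or \code{"tiled"}.
#' @param contig_lengths Named contig lengths of the synthetic genome.
#' @param gc GC content of the synthetic genome.
#' @param n_molecules Ligation concatemers to simulate.
#' @param decay_exponent Cis distance-decay exponent.
#' @param trans_rate Probability a reporter is trans-chromosomal.
#' @param multiway_mean Expected reporters per concatemer (shifted Poisson,
#'   minimum 1).
#' @param sonication_mean,sonication_sd Sonication fragment size (bp).
#' @param read_length Read length (bp).
#' @param duplicate_rate Fraction of emitted read pairs that are PCR
#'   duplicates.
#' @param duplicate_mode \code{"fastq"}: duplicates are exact copies of the
#'   final reads (caught by FASTQ-level dedup); \code{"coordinate"}:
#'   duplicates re-sequence the same sonication fragment with independent
#'   errors, so only coordinate-level dedup can catch them.
#' @param error_rate Per-base substitution rate.
#' @param reporter_gap Cis fragments within this distance of the viewpoint
#'   fragment are ineligible as reporters (they would fall in the pipeline's
#'   religation-exclusion window).
#' @param min_reporter_len Fragments shorter than this are ineligible as
#'   reporters: a fragment must be at least as long as a mappable slice to
#'   be recoverable at all, so the planted truth profile is defined over
#'   fragments the assay can in principle observe.
#' @param enzyme Override the method's default enzyme.
#' @return \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              method = c("capture", "tri", "tiled"),
                              contig_lengths = c(chrS1 = 5e5, chrS2 = 3e5,
                                                 chrS3 = 2e5),
                              gc = 0.5,
                              n_molecules = 10000L,
                              decay_exponent = 1.0,
                              trans_rate = 0.2,
                              multiway_mean = NULL,
                              sonication_mean = NULL,
                              sonication_sd = NULL,
                              read_length = 150L,
                              duplicate_rate = 0.3,
                              duplicate_mode = c("fastq", "coordinate"),
                              error_rate = 0,
                              reporter_gap = 1000L,
                              min_reporter_len = 30L,
                              enzyme = NULL) {
  method <- match.arg(method)
  duplicate_mode <- match.arg(duplicate_mode)
  if (is.null(multiway_mean))
    multiway_mean <- if (method == "tri") 2.5 else 1.2
  if (is.null(sonication_mean))
    sonication_mean <- if (method == "tri") 450 else 200
  if (is.null(sonication_sd))
    sonication_sd <- if (method == "tri") 80 else 50
  if (is.null(enzyme))
    enzyme <- enzyme_spec(if (method == "tri") "NlaIII" else "DpnII")
  stopifnot(trans_rate >= 0, trans_rate <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            error_rate >= 0, error_rate <= 1,
            multiway_mean >= 1, gc > 0, gc < 1)
  structure(list(seed = as.integer(seed), method = method,
                 contig_lengths = contig_lengths, gc = gc,
                 n_molecules = as.integer(n_molecules),
                 decay_exponent = decay_exponent, trans_rate = trans_rate,
                 multiway_mean = multiway_mean,
                 sonication_mean = sonication_mean,
                 sonication_sd = sonication_sd,
                 read_length = as.integer(read_length),
                 duplicate_rate = duplicate_rate,
                 duplicate_mode = duplicate_mode,
                 error_rate = error_rate,
                 reporter_gap = as.integer(reporter_gap),
                 min_reporter_len = as.integer(min_reporter_len),
                 enzyme = enzyme),
            class = "simulation_config")
}

# run expr with a private RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded synthetic genome and its restriction map
#'
#' Random i.i.d. sequence at the configured GC content; at GC 0.5 a 4-base
#' motif occurs every 256 bp in expectation, giving realistic 4-cutter
#' fragment sizes. Reproducible: the same config yields byte-identical
#' sequence.
#'
#' @param config \code{simulation_config}.
#' @return list(genome = DNAStringSet, map = fragment_map).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- with_seed(config$seed, {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(config$contig_lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, "")
    Biostrings::DNAStringSet(seqs)
  })
  names(genome) <- names(config$contig_lengths)
  map <- digest_genome(genome, config$enzyme,
                       genome_id = sprintf("sim_seed%d", config$seed))
  list(genome = genome, map = map)
}

#' Pick simulator viewpoints appropriate for the method
#'
#' Capture: the fragment with length in 250-1,000 bp closest to the middle
#' of the first contig. Tri: likewise with 150-250 bp. Tiled: the run of
#' contiguous fragments covering ~\code{region_width} bp around the middle
#' of the first contig, snapped to fragment boundaries.
#'
#' @param map \code{fragment_map}.
#' @param method Experiment type.
#' @param region_width Tiled region width (bp).
#' @return \code{viewpoint_set}.
#' @export
pick_viewpoints <- function(map, method = c("capture", "tri", "tiled"),
                            region_width = 100000L) {
  method <- match.arg(method)
  fr <- map$fragments
  ch1 <- names(map$seqlengths)[1]
  mid <- map$seqlengths[[1]] %/% 2L
  sub <- fr[chrom == ch1]
  internal <- sub[seq(2L, .N - 1L)]
  if (method == "tiled") {
    lo <- internal[start >= mid - region_width %/% 2L]
    sel <- lo[cumsum(end - start) <= region_width]
    if (nrow(sel) < 2L) sel <- lo[1:2]
    return(viewpoint_set(data.table::data.table(
      chrom = ch1, start = min(sel$start), end = max(sel$end),
      name = "tile1"), mode = "tiled"))
  }
  band <- if (method == "tri") c(150L, 250L) else c(250L, 1000L)
  cand <- internal[(end - start) >= band[1] & (end - start) <= band[2]]
  if (!nrow(cand))
    stop("no fragment with length in [", band[1], ", ", band[2],
         "] bp on ", ch1, call. = FALSE)
  pickd <- abs((cand$start + cand$end) %/% 2L - mid)
  v <- cand[which.min(pickd)]
  viewpoint_set(data.table::data.table(
    chrom = v$chrom, start = v$start, end = v$end, name = "VP1"),
    mode = if (method == "tri") "tri" else "capture")
}

# oriented ligation units: sequences that start (before_site) or end
# (after_site) with the intact recognition motif in both orientations, so
# religation junctions regenerate exactly one motif and in-silico digestion
# splits at the constructed position
ligation_units <- function(map, genome, fragment_ids) {
  fr <- map$fragments[fragment_id %in% fragment_ids]
  w <- nchar(map$enzyme$recognition)
  before <- map$enzyme$split_convention == "before_site"
  fwd <- character(nrow(fr)); rev <- character(nrow(fr))
  for (ch in unique(fr$chrom)) {
    sel <- fr$chrom == ch
    s <- fr$start[sel]; e <- fr$end[sel]
    fwd[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(s + 1L, e)))
    if (before) {
      rev[sel] <- revcomp(as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(s + w + 1L, e + w))))
    } else {
      rev[sel] <- revcomp(as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(s - w + 1L, e - w))))
    }
  }
  list(fwd = stats::setNames(fwd, fr$fragment_id),
       rev = stats::setNames(rev, fr$fragment_id))
}

# internal (non-terminal) fragments per contig: only these have motif
# boundaries on both sides and can act as ligation units
internal_fragments <- function(map) {
  fr <- map$fragments
  fr[, {
    if (.N > 2L) .SD[seq(2L, .N - 1L)] else .SD[0]
  }, by = chrom][, .(fragment_id, chrom, start, end)]
}

#' Simulate Capture-C / Tri-C / Tiled-C paired-end reads with ground truth
#'
#' Per molecule: a ligation concatemer is built from the viewpoint fragment
#' plus K reporters (K shifted-Poisson with mean \code{multiway_mean}); each
#' reporter is trans with probability \code{trans_rate}, otherwise drawn in
#' cis with probability proportional to genomic distance to the power
#' \code{-decay_exponent}. Units take random orientations; religated
#' junctions regenerate the recognition motif per the enzyme convention. A
#' sonication window (Normal, truncated) covering the viewpoint junction is
#' drawn and a read pair emitted from its two ends, with optional
#' substitution errors, then PCR duplicates are appended at
#' \code{duplicate_rate}.
#'
#' @param genome,map From \code{\link{simulate_genome}}.
#' @param config \code{simulation_config}.
#' @param viewpoints \code{viewpoint_set}; defaults to
#'   \code{\link{pick_viewpoints}}.
#' @return list(pairs = FASTQ pair table, truth = list(probs per viewpoint,
#'   molecules table, duplicates table, config)).
#' @export
simulate_reads <- function(genome, map, config, viewpoints = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(viewpoints))
    viewpoints <- pick_viewpoints(map, config$method)
  vp <- resolve_viewpoints(viewpoints, map)
  if (viewpoints$mode == "tiled") {
    vp_frag_ids <- vp$fragment_id
  } else {
    vp_frag_ids <- vp$fragment_id
  }
  intern <- internal_fragments(map)
  intern <- intern[end - start >= config$min_reporter_len]
  fr <- map$fragments
  with_seed(config$seed + 1L, {
    n <- config$n_molecules
    # anchor (capture) fragment per molecule: round-robin over viewpoints
    # (tiled: uniform over in-region fragments)
    if (viewpoints$mode == "tiled") {
      anchor_pool <- intersect(vp_frag_ids, intern$fragment_id)
      anchor <- sample(anchor_pool, n, replace = TRUE)
      anchor_name <- rep(vp$name[1], n)
    } else {
      vp_cycle <- rep_len(seq_len(nrow(vp)), n)
      anchor <- vp$fragment_id[vp_cycle]
      anchor_name <- vp$name[vp_cycle]
    }
    # reporter eligibility and truth probabilities per anchor fragment
    mids <- (fr$start + fr$end) / 2
    names(mids) <- fr$fragment_id
    eligibility <- function(afid) {
      arow <- fr[fragment_id == afid]
      same <- intern[chrom == arow$chrom]
      d <- abs(mids[as.character(same$fragment_id)] -
                 mids[[as.character(afid)]])
      gap_lo <- arow$start - config$reporter_gap
      gap_hi <- arow$end + config$reporter_gap
      cis_ok <- same[!(same$end > gap_lo & same$start < gap_hi)]
      d_ok <- abs(mids[as.character(cis_ok$fragment_id)] -
                    mids[[as.character(afid)]])
      p_cis <- d_ok^(-config$decay_exponent)
      p_cis <- p_cis / sum(p_cis)
      trans_pool <- intern[chrom != arow$chrom]
      list(cis_ids = cis_ok$fragment_id, p_cis = p_cis,
           trans_ids = trans_pool$fragment_id)
    }
    elig <- lapply(stats::setNames(unique(anchor), unique(anchor)),
                   eligibility)
    # truth probabilities per viewpoint (mixture of cis decay and uniform
    # trans)
    probs <- lapply(stats::setNames(unique(anchor), unique(anchor)),
                    function(a) {
      e <- elig[[as.character(a)]]
      data.table::data.table(
        fragment_id = c(e$cis_ids, e$trans_ids),
        prob = c((1 - config$trans_rate) * e$p_cis,
                 rep(config$trans_rate / length(e$trans_ids),
                     length(e$trans_ids))))
    })
    # reporters per molecule
    K <- 1L + stats::rpois(n, config$multiway_mean - 1)
    mol_of_rep <- rep(seq_len(n), K)
    R <- length(mol_of_rep)
    is_trans <- stats::runif(R) < config$trans_rate
    rep_frag <- integer(R)
    for (a in unique(anchor)) {
      e <- elig[[as.character(a)]]
      sel <- anchor[mol_of_rep] == a
      n_cis <- sum(sel & !is_trans); n_tr <- sum(sel & is_trans)
      rep_frag[sel & !is_trans] <-
        sample(e$cis_ids, n_cis, replace = TRUE, prob = e$p_cis)
      rep_frag[sel & is_trans] <-
        sample(e$trans_ids, n_tr, replace = TRUE)
    }
    # oriented unit sequences
    need <- unique(c(anchor, rep_frag))
    units <- ligation_units(map, genome, need)
    flip_anchor <- stats::runif(n) < 0.5
    flip_rep <- stats::runif(R) < 0.5
    u_anchor <- ifelse(flip_anchor, units$rev[as.character(anchor)],
                       units$fwd[as.character(anchor)])
    u_rep <- ifelse(flip_rep, units$rev[as.character(rep_frag)],
                    units$fwd[as.character(rep_frag)])
    rep_tail <- vapply(split(u_rep, mol_of_rep),
                       paste, "", collapse = "")
    rep_tail <- rep_tail[as.character(seq_len(n))]
    concat <- paste0(u_anchor, rep_tail)
    j1 <- nchar(u_anchor)                 # viewpoint junction position
    ML <- nchar(concat)
    # sonication window covering the viewpoint junction
    margin <- 25L
    L <- pmin(pmax(round(stats::rnorm(n, config$sonication_mean,
                                      config$sonication_sd)), 60L), ML)
    lo <- pmax(0L, j1 - L + margin)
    hi <- pmin(ML - L, j1 - margin)
    bad <- hi < lo
    lo[bad] <- pmax(0L, j1[bad] - L[bad] + 1L)
    hi[bad] <- pmin(ML[bad] - L[bad], j1[bad] - 1L)
    hi <- pmax(hi, lo)
    a0 <- lo + floor(stats::runif(n) * (hi - lo + 1L))
    window <- substring(concat, a0 + 1L, a0 + L)
    rl <- config$read_length
    r1_clean <- substring(window, 1L, pmin(rl, L))
    r2_clean <- revcomp(substring(window, pmax(1L, L - rl + 1L), L))
    r1 <- r1_clean; r2 <- r2_clean
    if (config$error_rate > 0) {
      r1 <- inject_errors(r1, config$error_rate)
      r2 <- inject_errors(r2, config$error_rate)
    }
    read_id <- sprintf("mol%07d", seq_len(n))
    pairs <- data.table::data.table(
      read_id = read_id, r1_seq = r1, r2_seq = r2,
      r1_qual = strrep("F", nchar(r1)), r2_qual = strrep("F", nchar(r2)))
    # PCR duplicates: duplicate_rate is the duplicate fraction of the
    # final read pool, so n_dup / (n + n_dup) = rate
    n_dup <- round(n * config$duplicate_rate / (1 - config$duplicate_rate))
    dup_tab <- data.table::data.table(read_id = character(),
                                      parent = character())
    if (n_dup > 0) {
      src <- sample(n, n_dup, replace = TRUE)
      dup <- pairs[src]
      dup[, read_id := sprintf("dup%07d_%s", seq_len(n_dup),
                               pairs$read_id[src])]
      if (config$duplicate_mode == "coordinate" && config$error_rate > 0) {
        # re-sequence the same sonication fragment with fresh errors
        dup[, r1_seq := inject_errors(r1_clean[src], config$error_rate)]
        dup[, r2_seq := inject_errors(r2_clean[src], config$error_rate)]
      }
      dup_tab <- data.table::data.table(read_id = dup$read_id,
                                        parent = pairs$read_id[src])
      pairs <- data.table::rbindlist(list(pairs, dup))
    }
    # per-molecule truth: a reporter unit yields a mappable slice for every
    # sequenced segment it overlaps by >= 20 bp (the mapper seed). Merged
    # windows (mates overlap by >= 10) are one segment; longer windows are
    # sequenced only at the two read ends.
    ulen <- nchar(u_rep)
    cum <- unlist(lapply(split(ulen, mol_of_rep), function(x)
      cumsum(c(0, x[-length(x)]))), use.names = FALSE)
    rep_start <- j1[mol_of_rep] + cum                 # concatemer coords
    rs <- rep_start - a0[mol_of_rep]                  # window coords
    re <- rs + ulen
    Lm <- L[mol_of_rep]
    rlm <- pmin(rl, Lm)
    merged_mol <- L <= 2L * pmin(rl, L) - 10L
    seg1_end <- ifelse(merged_mol[mol_of_rep], Lm, rlm)
    ov1 <- pmin(re, seg1_end) - pmax(rs, 0L)
    ov2 <- pmin(re, Lm) - pmax(rs, Lm - rlm)
    n_vis <- (ov1 >= 20L) +
      ifelse(merged_mol[mol_of_rep], 0L, (ov2 >= 20L))
    in_window <- n_vis > 0L
    mol_truth <- data.table::data.table(
      read_id = read_id,
      viewpoint = anchor_name,
      anchor_fragment = anchor,
      k_reporters = K,
      window_start = a0, window_len = L, junction = j1)
    mol_truth[, reporters_in_window :=
                tabulate(mol_of_rep[in_window], nbins = n)]
    mol_truth[, reporter_slices_visible := {
      v <- numeric(n); agg <- tapply(n_vis, mol_of_rep, sum)
      v[as.integer(names(agg))] <- agg; as.integer(v)
    }]
    rep_truth <- data.table::data.table(
      read_id = read_id[mol_of_rep],
      fragment_id = rep_frag,
      trans = is_trans,
      in_window = in_window,
      n_visible_slices = n_vis)
    names(probs) <- vapply(as.integer(names(probs)), function(a)
      anchor_name[match(a, anchor)], "")
    truth <- list(probs = probs, molecules = mol_truth,
                  reporters = rep_truth, duplicates = dup_tab,
                  viewpoints = viewpoints, config = config)
    list(pairs = pairs, truth = truth)
  })
}

# independent per-base substitutions at the given rate
inject_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample(lens[i], n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Score recovery of a reporter profile (or matrix) against simulator truth
#'
#' Profiles: Spearman correlation between the estimated per-fragment signal
#' and the truth sampling probability, over the truth support restricted to
#' the viewpoint contig (the normalised track is cis-only); fragments the
#' estimate missed count as zero. A bootstrap over fragments gives a
#' confidence interval. Matrices: Pearson correlation of log1p counts over
#' the upper triangle.
#'
#' @param estimated A normalised \code{reporter_profile} or a
#'   \code{contact_matrix}.
#' @param truth Truth list from \code{\link{simulate_reads}} (profiles) or
#'   a reference \code{contact_matrix} (matrices).
#' @param map \code{fragment_map} (profiles only).
#' @param n_boot Bootstrap replicates.
#' @return list(method, correlation, ci, n).
#' @export
score_recovery <- function(estimated, truth, map = NULL, n_boot = 200L) {
  if (inherits(estimated, "contact_matrix")) {
    stopifnot(inherits(truth, "contact_matrix"))
    ut <- upper.tri(estimated$values, diag = TRUE)
    x <- log1p(estimated$values[ut]); y <- log1p(truth$values[ut])
    return(list(method = "pearson_log1p", correlation = stats::cor(x, y),
                ci = NULL, n = sum(ut)))
  }
  stopifnot(inherits(estimated, "reporter_profile"))
  pv <- truth$probs[[estimated$viewpoint]]
  if (is.null(pv)) stop("no truth for viewpoint ", estimated$viewpoint,
                        call. = FALSE)
  fr <- map$fragments
  cis_ids <- fr[chrom == estimated$viewpoint_chrom, fragment_id]
  pv <- pv[fragment_id %in% cis_ids]
  if (!nrow(pv)) stop("disjoint supports", call. = FALSE)
  est <- estimated$normalised
  sig <- est$signal[match(pv$fragment_id, est$fragment_id)]
  sig[is.na(sig)] <- 0
  rho <- stats::cor(sig, pv$prob, method = "spearman")
  boots <- replicate(n_boot, {
    i <- sample(nrow(pv), replace = TRUE)
    suppressWarnings(stats::cor(sig[i], pv$prob[i], method = "spearman"))
  })
  list(method = "spearman", correlation = rho,
       ci = stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE),
       n = nrow(pv))
}

#' Write simulator truth tables and config echo
#' @param truth Truth list from \code{\link{simulate_reads}}.
#' @param dir Output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(truth$molecules, file.path(dir, "molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$reporters, file.path(dir, "reporters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$duplicates, file.path(dir, "duplicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  cfg$enzyme <- list(name = cfg$enzyme$name,
                     recognition = cfg$enzyme$recognition,
                     split_convention = cfg$enzyme$split_convention)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yml"))
  invisible(dir)
}
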