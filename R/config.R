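#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration (genome, restriction enzyme, experimental
#' method, viewpoints file, output directories, tuning parameters), fills
#' defaults, and validates everything up front: unknown keys are rejected,
#' the method must be one of \code{capture}/\code{tiled}/\code{tri}, paths
#' must exist, and the viewpoint BED must parse. All problems are reported
#' together.
#'
#' @param path YAML file.
#' @return A validated \code{run_config} list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  run_config_from_list(raw, base_dir = dirname(path))
}

#' @rdname validate_config
#' @param ... Configuration keys as named arguments (same keys as the YAML
#'   file).
#' @export
run_config <- function(...) {
  run_config_from_list(list(...), base_dir = ".")
}

run_config_from_list <- function(raw, base_dir = ".") {
  allowed <- c("genome", "viewpoints", "method", "enzyme", "fastq_dir",
               "output_dir", "public_dir", "exclusion_window", "bin_size",
               "scale", "seed", "aligner", "matrix_region", "min_mapq")
  required <- c("genome", "viewpoints", "method")
  errors <- character()
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", "),
                               " (allowed: ",
                               paste(allowed, collapse = ", "), ")"))
  missing <- setdiff(required, names(raw))
  if (length(missing))
    errors <- c(errors, paste0("missing required key(s): ",
                               paste(missing, collapse = ", ")))
  method <- raw$method
  if (!is.null(method) && !method %in% c("capture", "tiled", "tri"))
    errors <- c(errors, paste0("method '", method,
                               "' invalid; allowed: capture, tiled, tri"))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  cfg <- list(
    genome = resolve(raw$genome),
    viewpoints = resolve(raw$viewpoints),
    method = method,
    enzyme = raw$enzyme %||%
      (if (identical(method, "tri")) "NlaIII" else "DpnII"),
    fastq_dir = resolve(raw$fastq_dir),
    output_dir = raw$output_dir %||% "capture3C_output",
    public_dir = raw$public_dir,
    exclusion_window = as.integer(raw$exclusion_window %||% 1000L),
    bin_size = as.integer(raw$bin_size %||%
                            (if (identical(method, "tri")) 1000L
                             else 5000L)),
    scale = as.numeric(raw$scale %||% 1e5),
    seed = as.integer(raw$seed %||% 42L),
    aligner = raw$aligner %||% "builtin",
    matrix_region = raw$matrix_region,
    min_mapq = as.integer(raw$min_mapq %||% 30L))
  if (length(errors) == 0) {
    for (key in c("genome", "viewpoints")) {
      if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
        errors <- c(errors, paste0(key, " file not found: ", cfg[[key]]))
    }
    if (length(errors) == 0) {
      vp_err <- tryCatch({
        read_viewpoints(cfg$viewpoints, mode = cfg$method)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(vp_err)) errors <- c(errors, vp_err)
    }
  }
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# <sample>_rep<N>_R[12].fastq[.gz] replicate-grouping convention
discover_fastq <- function(fastq_dir) {
  r1 <- sort(list.files(fastq_dir, "_R1\\.fastq(\\.gz)?$",
                        full.names = TRUE))
  if (!length(r1)) stop("no *_R1.fastq[.gz] files in ", fastq_dir,
                        call. = FALSE)
  base <- sub("_R1\\.fastq(\\.gz)?$", "", basename(r1))
  r2 <- file.path(fastq_dir,
                  sub("_R1\\.", "_R2.", basename(r1)))
  if (!all(file.exists(r2)))
    stop("missing mate files: ",
         paste(basename(r2)[!file.exists(r2)], collapse = ", "),
         call. = FALSE)
  data.table::data.table(
    replicate = base,
    sample = sub("_rep[0-9]+$", "", base),
    r1 = r1, r2 = r2)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes restriction mapping, read processing, alignment, annotation,
#' deduplication and reporter quantification for every replicate found in
#' \code{fastq_dir} (or passed explicitly), then per-sample mean tracks,
#' a subtraction track when exactly two sample groups are present, contact
#' matrices for tri/tiled runs, per-replicate QC reports and UCSC hub
#' stanzas. All outputs are deterministic given the config.
#'
#' @param config \code{run_config}.
#' @param fastq Optional data.table(replicate, sample, r1, r2); defaults to
#'   discovery under \code{config$fastq_dir}.
#' @return Invisible list: per-replicate results (profiles, QC), mean
#'   tracks, subtraction tracks, matrices, output paths.
#' @export
run_pipeline <- function(config, fastq = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("capture3C %s | config hash %s",
       as.character(utils::packageVersion("capture3C")),
       substr(digest_config(config), 1, 12))
  genome <- read_genome(config$genome)
  enzyme <- enzyme_spec(config$enzyme)
  map <- digest_genome(genome, enzyme,
                       genome_id = basename(config$genome))
  write_fragment_map(map, file.path(out_dir, "fragment_map.bed"))
  viewpoints <- read_viewpoints(config$viewpoints, mode = config$method)
  logf("genome: %d contigs | %d fragments | %d viewpoints",
       length(genome), nrow(map$fragments), nrow(viewpoints$entries))
  if (is.null(fastq)) fastq <- discover_fastq(config$fastq_dir)
  results <- list()
  track_files <- character()
  for (i in seq_len(nrow(fastq))) {
    rep_name <- fastq$replicate[i]
    pairs <- read_paired_fastq(fastq$r1[i], fastq$r2[i])
    pr <- process_reads(pairs, enzyme)
    aligned <- align_slices(pr$slices, genome, aligner = config$aligner,
                            min_mapq = config$min_mapq)
    ann <- annotate_slices(aligned, map, viewpoints,
                           exclusion_window = config$exclusion_window)
    gf <- group_and_filter(ann, mode = config$method)
    dd <- dedup_groups(gf$groups)
    profiles <- count_reporters(ann, dd$groups, viewpoints, map)
    profiles <- lapply(profiles, normalise_cis, scale = config$scale)
    qc <- build_qc_report(pr$stats, gf$stats, dd$removed, profiles)
    write_qc_report(qc, file.path(out_dir,
                                  paste0(rep_name, "_qc.json")))
    for (nm in names(profiles)) {
      f <- file.path(out_dir, paste0(rep_name, "_", nm, ".bedgraph"))
      write_bedgraph(profiles[[nm]], f, name = paste0(rep_name, "_", nm))
      track_files <- c(track_files, f)
    }
    write_annotated_tsv(ann, file.path(out_dir,
                                       paste0(rep_name, "_slices.tsv")))
    results[[rep_name]] <- list(profiles = profiles, qc = qc,
                                annotated = ann, groups = dd$groups)
    logf("replicate %s: %d pairs -> %d unique informative groups",
         rep_name, nrow(pairs), sum(dd$groups$informative))
  }
  # per-sample mean tracks and (for exactly two samples) subtractions
  samples <- split(fastq$replicate, fastq$sample)
  means <- list()
  for (s in names(samples)) {
    means[[s]] <- list()
    vps <- names(results[[samples[[s]][1]]]$profiles)
    for (nm in vps) {
      reps <- lapply(samples[[s]], function(r) results[[r]]$profiles[[nm]])
      m <- mean_profiles(reps)
      f <- file.path(out_dir, paste0(s, "_mean_", nm, ".bedgraph"))
      write_bedgraph(m, f, name = paste0(s, "_mean_", nm))
      track_files <- c(track_files, f)
      means[[s]][[nm]] <- m
    }
  }
  subtractions <- list()
  if (length(means) == 2L) {
    sa <- names(means)[1]; sb <- names(means)[2]
    for (nm in names(means[[sa]])) {
      d <- subtract_profiles(means[[sa]][[nm]], means[[sb]][[nm]])
      f <- file.path(out_dir,
                     paste0(sa, "_minus_", sb, "_", nm, ".bedgraph"))
      write_bedgraph(d, f, name = paste0(sa, "_minus_", sb, "_", nm))
      track_files <- c(track_files, f)
      subtractions[[nm]] <- d
    }
  }
  # contact matrices for multi-way / tiled methods
  matrices <- list()
  if (config$method %in% c("tri", "tiled")) {
    vp <- resolve_viewpoints(viewpoints, map)
    for (rep_name in names(results)) {
      r <- results[[rep_name]]
      if (config$method == "tiled") {
        e <- viewpoints$entries[1]
        spec <- matrix_spec(e$chrom, e$start, e$end, config$bin_size)
        mat <- tiled_c_matrix(r$annotated, r$groups, spec, map)
      } else {
        region <- config$matrix_region %||% {
          v <- vp[1]
          w <- 100000L
          list(chrom = v$chrom,
               start = max(0L, v$start - w),
               end = min(map$seqlengths[[v$chrom]], v$end + w))
        }
        spec <- matrix_spec(region$chrom, region$start, region$end,
                            config$bin_size)
        mat <- tri_c_matrix(r$annotated, r$groups, vp$name[1], spec, map,
                            viewpoints)
      }
      write_contact_matrix(mat, file.path(out_dir,
                                          paste0(rep_name, "_matrix.tsv")))
      matrices[[rep_name]] <- mat
    }
  }
  if (!is.null(config$public_dir))
    write_ucsc_hub(config$public_dir, "capture3C",
                   map$genome_id, basename(track_files))
  logf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(results = results, means = means,
                 subtractions = subtractions, matrices = matrices,
                 map = map, output_dir = out_dir))
}

digest_config <- function(config) {
  flat <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = ";")
  # cheap stable hash (sum of char codes in rolling polynomial)
  h <- 0
  for (c in utf8ToInt(flat)) h <- (h * 31 + c) %% 2^31
  sprintf("%08x", h)
}
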