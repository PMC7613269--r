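#' Digestion efficiency from qPCR CT values
#'
#' 3C library quality control: qPCR with one primer pair amplifying across a
#' restriction cut site and one within a restriction fragment, on undigested
#' (Control 1) and digested-unligated (Control 2) DNA. With replicate CTs
#' averaged per (sample, assay):
#' \deqn{\Delta CT_s = CT_s(cut\mbox{-}site) - CT_s(fragment)}
#' \deqn{\Delta\Delta CT = \Delta CT_{C1} - \Delta CT_{C2}}
#' \deqn{Efficiency = 100 (1 - 2^{\Delta\Delta CT})}
#' A library passes when efficiency exceeds 70\% (strict), the minimum for
#' use: capture experiments do not select for successful digestion events, so
#' poorly digested libraries waste reads.
#'
#' For low-input samples genomic DNA may substitute Control 1 and the 3C
#' library itself Control 2 (\code{low_input = TRUE}); re-ligation then
#' depresses the apparent efficiency, which is noted in the result.
#'
#' @param assays data.frame/data.table with columns \code{sample}
#'   (\code{"control1"}/\code{"control2"}, aliases containing "1"/"2"
#'   accepted), \code{assay} (\code{"cut_site"}/\code{"fragment"}) and
#'   \code{ct} (one row per replicate). All four (sample, assay)
#'   combinations must be present.
#' @param threshold Pass threshold in percent.
#' @param low_input Low-input variant flag (affects only the caveat).
#' @return \code{digestion_result}: avg_ct (named list), delta_ct,
#'   delta_delta_ct, efficiency_percent, pass, notes.
#' @examples
#' cts <- data.frame(
#'   sample = rep(c("control1", "control2"), each = 2),
#'   assay = rep(c("cut_site", "fragment"), 2),
#'   ct = c(21.043, 21.211, 23.422, 20.884))
#' digestion_efficiency(cts)
#' @export
digestion_efficiency <- function(assays, threshold = 70, low_input = FALSE) {
  a <- data.table::as.data.table(assays)
  req <- c("sample", "assay", "ct")
  if (!all(req %in% names(a)))
    stop("assay table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  a[, sample := ifelse(grepl("1", sample), "control1", "control2")]
  a[, assay := ifelse(grepl("^cut", tolower(assay)) |
                        grepl("cut.site", tolower(assay)),
                      "cut_site", "fragment")]
  if (any(a$ct <= 0 | a$ct >= 45))
    stop("CT values must lie in (0, 45)", call. = FALSE)
  avg <- a[, .(avg_ct = mean(ct)), by = .(sample, assay)]
  need <- data.table::CJ(sample = c("control1", "control2"),
                         assay = c("cut_site", "fragment"))
  missing <- need[!avg, on = c("sample", "assay")]
  if (nrow(missing))
    stop("missing (sample, assay) combinations: ",
         paste(missing$sample, missing$assay, sep = "/", collapse = ", "),
         call. = FALSE)
  g <- function(s, as) avg[sample == s & assay == as, avg_ct]
  delta_ct <- c(control1 = g("control1", "cut_site") -
                  g("control1", "fragment"),
                control2 = g("control2", "cut_site") -
                  g("control2", "fragment"))
  ddct <- unname(delta_ct["control1"] - delta_ct["control2"])
  eff <- 100 * (1 - 2^ddct)
  notes <- character()
  if (eff < 0)
    notes <- c(notes, sprintf(
      "negative efficiency (%.2f%%): cut-site amplification stronger after digestion; check sample labelling",
      eff))
  if (low_input)
    notes <- c(notes,
               "low-input variant (gDNA vs 3C library): a lower digestion efficiency is expected")
  structure(
    list(avg_ct = stats::setNames(avg$avg_ct,
                                  paste(avg$sample, avg$assay, sep = ".")),
         delta_ct = delta_ct,
         delta_delta_ct = ddct,
         efficiency_percent = eff,
         pass = eff > threshold,
         threshold = threshold,
         notes = notes),
    class = "digestion_result")
}

#' @export
print.digestion_result <- function(x, ...) {
  cat("<digestion_result>\n")
  cat(sprintf("  dCT(C1) = %.3f   dCT(C2) = %.3f   ddCT = %.3f\n",
              x$delta_ct["control1"], x$delta_ct["control2"],
              x$delta_delta_ct))
  cat(sprintf("  efficiency = %.2f%%  [%s, threshold %g%%]\n",
              x$efficiency_percent, if (x$pass) "PASS" else "FAIL",
              x$threshold))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Read a digestion-QC CT table
#' @param path TSV with columns sample, assay, ct.
#' @export
read_ct_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE)
}

#' Write a digestion result as JSON
#' @param result \code{digestion_result}.
#' @param path Output path.
#' @export
write_digestion_result <- function(result, path) {
  jsonlite::write_json(
    list(avg_ct = as.list(result$avg_ct),
         delta_ct = as.list(result$delta_ct),
         delta_delta_ct = result$delta_delta_ct,
         efficiency_percent = result$efficiency_percent,
         pass = result$pass, threshold = result$threshold,
         notes = result$notes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reference qPCR primer panel for digestion QC
#'
#' Validated primer pairs for human (hg38), mouse (mm9) and fly (dm6)
#' digestion-efficiency assays, with each pair's role (cut-site or
#' within-fragment) per enzyme. Note the mouse pairs swap roles between
#' DpnII and NlaIII.
#'
#' @return data.table of the packaged panel.
#' @export
digestion_primer_panel <- function() {
  data.table::fread(system.file("extdata", "digestion_qpcr_primers.tsv",
                                package = "capture3C"), sep = "\t")
}
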