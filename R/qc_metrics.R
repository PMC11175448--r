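#' Panel QC metrics
#'
#' Raw-read base-quality fractions (Q20/Q30) and GC content; per-base depth
#' summaries with coverage breadth at a depth threshold; GC content of the
#' reference window surrounding a variant; and GC-bin summaries of read
#' depth at variant positions.
#'
#' @name qc_metrics
NULL

#' Q20/Q30 and GC summary of a FASTQ file
#'
#' Q20/Q30 are the fractions of base calls with Phred quality >= 20 / >= 30;
#' GC is the fraction of called A/C/G/T bases that are G or C (N is excluded
#' from the denominator).
#'
#' @param path FASTQ file, optionally gzipped.
#' @param phred_offset quality encoding offset (default 33).
#' @return list with `n_reads`, `n_bases`, `q20_fraction`, `q30_fraction`,
#'   `gc_fraction`.
#' @export
fastq_quality_summary <- function(path, phred_offset = 33L) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  # validate record structure first: the Biostrings reader tolerates (and
  # nul-pads) ragged sequence/quality pairs instead of erroring
  con <- gzfile(path, "rt")
  raw_lines <- readLines(con)
  close(con)
  if (length(raw_lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path)
  seq_len_ <- nchar(raw_lines[seq(2L, length(raw_lines), by = 4L)])
  qual_len <- nchar(raw_lines[seq(4L, length(raw_lines), by = 4L)])
  bad <- which(seq_len_ != qual_len)
  if (length(bad))
    stop(sprintf("FASTQ record %d: sequence and quality lengths differ", bad[1]))
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  q <- as(Biostrings::quality(reads), "IntegerList")
  qv <- unlist(q, use.names = FALSE)
  counts <- colSums(Biostrings::alphabetFrequency(reads)[, c("A", "C", "G", "T"), drop = FALSE])
  acgt <- sum(counts)
  list(n_reads = length(reads),
       n_bases = sum(Biostrings::width(reads)),
       q20_fraction = mean(qv >= 20L),
       q30_fraction = mean(qv >= 30L),
       gc_fraction = if (acgt > 0) unname((counts["G"] + counts["C"]) / acgt) else NA_real_)
}

#' GC percent of the window around a position
#'
#' The window covers `window` bases total: for even windows the variant base
#' plus `window/2 - 1` bases 5' and `window/2` bases 3' (the extra base goes
#' 3'). Windows truncated at a sequence end are computed on the truncated
#' span and flagged.
#'
#' @param ref a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param chrom sequence name.
#' @param pos 1-based position.
#' @param window window size in bases (default 200).
#' @return list with `gc_percent`, `n_bases` (window bases actually used)
#'   and `truncated`.
#' @export
window_gc <- function(ref, chrom, pos, window = 200L) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (!chrom %in% names(ref)) stop("sequence not in reference: ", chrom)
  len <- Biostrings::width(ref[chrom])
  if (pos < 1L || pos > len) stop("position outside reference sequence: ", pos)
  left <- floor((window - 1L) / 2L)
  lo <- pos - left
  hi <- pos + (window - 1L - left)
  truncated <- lo < 1L || hi > len
  lo <- max(1L, lo); hi <- min(len, hi)
  seqw <- Biostrings::subseq(ref[[chrom]], lo, hi)
  f <- Biostrings::alphabetFrequency(seqw)[c("A", "C", "G", "T")]
  acgt <- sum(f)
  list(gc_percent = if (acgt > 0) 100 * unname(f["G"] + f["C"]) / acgt else NA_real_,
       n_bases = hi - lo + 1L, truncated = truncated)
}

#' Coverage summary of a region
#'
#' @param depths per-base depth vector over the region.
#' @param threshold depth threshold for breadth (default 20).
#' @param region optional region label.
#' @return list with `region`, `n_bases`, `mean_depth`,
#'   `breadth_at_threshold` (fraction of bases with depth >= threshold) and
#'   `threshold`.
#' @export
coverage_breadth <- function(depths, threshold = 20L, region = NA_character_) {
  if (!length(depths)) stop("empty region: no depth values")
  if (any(depths < 0)) stop("negative depths")
  list(region = region, n_bases = length(depths),
       mean_depth = mean(depths),
       breadth_at_threshold = mean(depths >= threshold),
       threshold = threshold)
}

#' Read depth at variant positions, summarized by GC-content bin
#'
#' Bins are `(low, high]` except the first, which is closed on both sides.
#' Variants whose GC falls outside the overall range are reported in an
#' overflow bucket, never dropped.
#'
#' @param gc_percent GC percent per variant (see [window_gc()]).
#' @param depth read depth at each variant position.
#' @param edges increasing bin edges in percent (default `c(28, 45, 55, 68)`).
#' @return a data.frame with one row per bin (plus an `overflow` row when
#'   needed): `bin`, `low`, `high`, `n`, `mean_depth` (NA for empty bins).
#' @export
depth_by_gc_bins <- function(gc_percent, depth, edges = c(28, 45, 55, 68)) {
  stopifnot(length(gc_percent) == length(depth), !is.unsorted(edges))
  k <- length(edges) - 1L
  lab <- sprintf("(%g,%g]", edges[-length(edges)], edges[-1])
  lab[1] <- sprintf("[%g,%g]", edges[1], edges[2])
  idx <- rep(NA_integer_, length(gc_percent))
  for (j in seq_len(k)) {
    inb <- if (j == 1L) gc_percent >= edges[1] & gc_percent <= edges[2]
           else gc_percent > edges[j] & gc_percent <= edges[j + 1L]
    idx[is.na(idx) & inb] <- j
  }
  rows <- lapply(seq_len(k), function(j) {
    sel <- which(idx == j)
    data.frame(bin = lab[j], low = edges[j], high = edges[j + 1L],
               n = length(sel),
               mean_depth = if (length(sel)) mean(depth[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  overflow <- which(is.na(idx))
  if (length(overflow))
    out <- rbind(out, data.frame(bin = "overflow", low = NA_real_, high = NA_real_,
                                 n = length(overflow),
                                 mean_depth = mean(depth[overflow])))
  out
}
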