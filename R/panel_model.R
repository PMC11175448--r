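#' Panel data model: gene-annotated target regions and their fixed-length bins
#'
#' A `panel_definition` holds the BED-defined target regions of a capture
#' panel (0-based half-open coordinates), the set of gene symbols they
#' annotate, and the bin length used to tile the regions for read-depth
#' copy-number analysis.
#'
#' @name panel_model
NULL

new_panel_definition <- function(regions, bin_length = 50L) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "gene", "label") %in% names(regions)))
  bin_length <- as.integer(bin_length)
  if (is.na(bin_length) || bin_length < 1L)
    stop("bin_length must be a positive integer")
  if (any(regions$start >= regions$end))
    stop("invalid region: start must be < end")
  if (any(!nzchar(regions$chrom)))
    stop("invalid region: empty chromosome name")
  o <- order(chrom_rank(regions$chrom), regions$start)
  regions <- regions[o, , drop = FALSE]
  rownames(regions) <- NULL
  structure(
    list(regions = regions,
         genes = sort(unique(regions$gene)),
         bin_length = bin_length),
    class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("panel_definition: %d regions, %d genes, bin length %d bp, %s bp total\n",
              nrow(x$regions), length(x$genes), x$bin_length,
              format(sum(x$regions$end - x$regions$start), big.mark = ",")))
  invisible(x)
}

#' Read a panel definition from a BED file
#'
#' BED is interpreted in the standard 0-based half-open dialect. Column 4,
#' when present, is parsed as `gene|label` (e.g. `RHO|ex3`); absent gene
#' annotations become `"."`. Overlapping or bookended intervals of the same
#' gene are merged, and the merged region keeps the concatenated labels.
#'
#' @param path path to a BED file (3+ columns, tab or whitespace separated).
#' @param bin_length bin size in bases used when tiling the panel
#'   (default 50).
#' @return a `panel_definition` object.
#' @export
read_panel_bed <- function(path, bin_length = 50L) {
  if (!file.exists(path)) stop("panel BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("panel BED is empty: ", path)
  parts <- strsplit(lines, "[\t ]+")
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 columns", bad[1], path))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", bad[1], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("invalid BED line %d in %s: start >= end", bad[1], path))
  name <- vapply(seq_along(parts), function(i)
    if (n_fields[i] >= 4L) parts[[i]][4L] else ".", "")
  gene <- sub("\\|.*$", "", name)
  label <- ifelse(grepl("\\|", name), sub("^[^|]*\\|", "", name), "")
  regions <- merge_same_gene(
    data.frame(chrom = chrom, start = start, end = end,
               gene = gene, label = label, stringsAsFactors = FALSE))
  new_panel_definition(regions, bin_length = bin_length)
}

# Merge overlapping/bookended intervals belonging to one gene, pooling labels.
merge_same_gene <- function(regions) {
  pieces <- lapply(split(regions, regions$gene), function(df) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end))
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    lab <- vapply(seq_along(red), function(i) {
      l <- df$label[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == i]]
      paste(unique(l[nzchar(l)]), collapse = ",")
    }, "")
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red) - 1L,
               end = GenomicRanges::end(red),
               gene = df$gene[1L], label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a panel definition to BED
#'
#' @param panel a `panel_definition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  r <- panel$regions
  name <- ifelse(nzchar(r$label), paste0(r$gene, "|", r$label), r$gene)
  writeLines(paste(r$chrom, r$start, r$end, name, sep = "\t"), path)
  invisible(path)
}

#' Tile a panel into fixed-length bins
#'
#' Each target region is tiled left-to-right with bins of `bin_length`
#' bases. A terminal remainder shorter than the bin length is kept as a
#' partial bin and flagged; downstream consumers weight bins by width. The
#' union of bins equals the union of regions base-exactly. Bin ordinals are
#' panel-wide and strictly increasing in genome order.
#'
#' @param panel a `panel_definition`.
#' @return a data.frame with one row per bin: `chrom`, `start`, `end`
#'   (0-based half-open), `width`, `region_index`, `ordinal`, `partial`,
#'   `gene`, `label`.
#' @export
bin_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  r <- panel$regions
  bl <- panel$bin_length
  pieces <- lapply(seq_len(nrow(r)), function(i) {
    starts <- seq.int(r$start[i], r$end[i] - 1L, by = bl)
    ends <- pmin(starts + bl, r$end[i])
    data.frame(chrom = r$chrom[i], start = starts, end = ends,
               width = ends - starts, region_index = i,
               partial = (ends - starts) < bl,
               gene = r$gene[i], label = r$label[i],
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$ordinal <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  bins[, c("chrom", "start", "end", "width", "region_index", "ordinal",
           "partial", "gene", "label")]
}

#' Serialize / deserialize a panel definition as JSON
#'
#' @param panel a `panel_definition`.
#' @param path JSON file path.
#' @return `panel_to_json` returns `path` invisibly; `panel_from_json`
#'   returns a `panel_definition`.
#' @export
panel_to_json <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  write_json_report(list(bin_length = panel$bin_length,
                         regions = panel$regions), path)
}

#' @rdname panel_to_json
#' @export
panel_from_json <- function(path) {
  x <- read_json(path)
  new_panel_definition(as.data.frame(x$regions), bin_length = x$bin_length)
}

#' The bundled 82-gene retinal-dystrophy panel
#'
#' Loads the panel fixture shipped with the package: all 82 IRD-associated
#' gene symbols of the clinical panel, each with an exon-level target
#' structure, plus the deep-intronic *CEP290* intron 26/27 target. The gene
#' list is the real panel content; the genomic coordinates and exon
#' boundaries are synthetic stand-ins (true panel coordinates are not
#' public), constructed so that the exon spans relevant to the validation
#' studies (e.g. the 153-bp and 90-bp *PDE6B* exons 2-3, the 14-exon
#' *PRPF31* structure) are preserved.
#'
#' @param bin_length bin size passed through to [read_panel_bed()].
#' @return a `panel_definition` with exactly 82 genes.
#' @export
ird_panel <- function(bin_length = 50L) {
  path <- system.file("extdata", "ird_panel_82_synthetic.bed",
                      package = "panelscope", mustWork = TRUE)
  read_panel_bed(path, bin_length = bin_length)
}
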