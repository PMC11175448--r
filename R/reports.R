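#' Clinical report rendering
#'
#' Two reports are produced. The Summary report carries the QC pass/fail
#' status, the pathogenic and likely-pathogenic small variants (with
#' zygosity) and any detected copy-number losses. The Sequencing report
#' carries every observation with full audit fields plus the tool version
#' and effective parameters. Both are deterministic given their inputs.
#'
#' @param observations interpreted observations from [interpret_variants()].
#' @param cnv_events event table from [call_loss_events()] (may be empty).
#' @param qc_status list with at least `pass` (logical); additional metrics
#'   are carried through verbatim.
#' @param meta list of provenance fields (sample id, parameters, seeds);
#'   the package version and a config hash are added.
#' @return list with elements `summary` and `sequencing`.
#' @export
render_reports <- function(observations, cnv_events = NULL, qc_status = list(pass = TRUE),
                           meta = list()) {
  stopifnot(is.data.frame(observations))
  meta$tool <- "panelscope"
  meta$tool_version <- as.character(packageVersion("panelscope"))
  meta$config_hash <- substr(digest_obj(meta[setdiff(names(meta), "config_hash")]), 1, 12)
  reportable <- observations[observations$tier %in%
                               c("Pathogenic", "Likely pathogenic"), , drop = FALSE]
  summary_rep <- list(
    report = "summary",
    qc = qc_status,
    variants = df_records(reportable[, intersect(
      c("chrom", "pos", "ref", "alt", "vaf", "zygosity", "tier"),
      names(reportable)), drop = FALSE]),
    cnv_losses = df_records(cnv_events),
    meta = meta)
  sequencing_rep <- list(
    report = "sequencing",
    qc = qc_status,
    variants = df_records(observations),
    cnv_losses = df_records(cnv_events),
    meta = meta)
  list(summary = summary_rep, sequencing = sequencing_rep)
}

df_records <- function(df) {
  if (is.null(df) || !nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# dependency-free stable hash (FNV-1a over the deparsed object)
digest_obj <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x%04x", as.integer(h), length(bytes) %% 65536L)
}

#' Write a report bundle to disk as JSON and Markdown
#'
#' @param reports list from [render_reports()].
#' @param dir output directory (created).
#' @return paths written, invisibly.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_json_report(reports$summary, file.path(dir, "summary_report.json")),
    write_json_report(reports$sequencing, file.path(dir, "sequencing_report.json")))
  md <- c("# Summary report", "",
          sprintf("QC: %s", if (isTRUE(reports$summary$qc$pass)) "PASS" else "FAIL"),
          "", "## Reportable variants (Pathogenic / Likely pathogenic)", "")
  if (length(reports$summary$variants)) {
    md <- c(md, "| chrom | pos | ref | alt | VAF | zygosity | tier |",
            "|---|---|---|---|---|---|---|",
            vapply(reports$summary$variants, function(v)
              sprintf("| %s | %s | %s | %s | %.3f | %s | %s |",
                      v$chrom, v$pos, v$ref, v$alt, v$vaf, v$zygosity, v$tier), ""))
  } else md <- c(md, "none")
  md <- c(md, "", "## Copy-number losses", "")
  if (length(reports$summary$cnv_losses)) {
    md <- c(md, vapply(reports$summary$cnv_losses, function(e)
      sprintf("- %s:%d-%d (%s): copy number %d (log2 ratio %.2f)",
              e$chrom, e$start + 1L, e$end, e$genes, e$copy_number,
              e$log2_ratio), ""))
  } else md <- c(md, "none")
  md_path <- file.path(dir, "summary_report.md")
  writeLines(md, md_path)
  invisible(c(paths, md_path))
}
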