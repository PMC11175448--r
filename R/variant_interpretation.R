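#' Small-variant interpretation: VCF ingestion, depth gate, zygosity, tiers
#'
#' Candidate SNVs and small indels arrive as a VCF with per-sample allele
#' depth (AD) and total depth (DP). Sites must clear a minimum read depth
#' (20x by default) before interpretation; zygosity is then assigned from
#' the variant allele frequency (VAF), and ACMG/AMP evidence codes supplied
#' alongside the VCF are combined into a five-tier classification.
#'
#' @name variant_interpretation
NULL

variant_class_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
  ifelse(nchar(alt) > nchar(ref) & substr(alt, 1L, nchar(ref)) == ref, "insertion",
  ifelse(nchar(ref) > nchar(alt) & substr(ref, 1L, nchar(alt)) == alt, "deletion",
         "complex")))
}

# a record is minimal/left-aligned if ref and alt do not share a removable
# common suffix, nor a common prefix beyond the single anchor base
not_minimal <- function(ref, alt) {
  if (nchar(ref) > 1L && nchar(alt) > 1L &&
      substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)))
    return(TRUE)
  if (nchar(ref) > 1L && nchar(alt) > 1L && substr(ref, 1L, 2L) == substr(alt, 1L, 2L))
    return(TRUE)
  FALSE
}

#' Read candidate small variants from a VCF
#'
#' Multi-allelic records are split per ALT allele. Each observation carries
#' the alt-supporting read count (AD), the site depth (DP) and the derived
#' VAF. Records that are not left-aligned and minimal, or that have zero
#' total depth, are rejected with an error naming the record.
#'
#' @param path VCF 4.x file (plain or bgzipped) with AD and DP genotype
#'   fields.
#' @param sample sample name to use; required when the VCF has several.
#' @return a data.frame of variant observations: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `alt_depth`, `total_depth`, `vaf`, `variant_class`.
#' @export
read_variants_vcf <- function(path, sample = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "panel")
  vcf <- VariantAnnotation::expand(vcf)
  gn <- VariantAnnotation::geno(vcf)
  if (!all(c("AD", "DP") %in% names(gn)))
    stop("VCF ", path, " lacks AD and/or DP genotype fields")
  samples <- colnames(gn$DP)
  if (is.null(sample)) {
    if (length(samples) > 1L)
      stop("multi-sample VCF: pick one of ", paste(samples, collapse = ", "))
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    stop("sample ", sample, " not in VCF (has: ", paste(samples, collapse = ", "), ")")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  dp <- as.integer(gn$DP[, sample])
  # after expand(), AD per record is c(ref_count, alt_count); readVcf gives
  # either a 3-d array (uniform ploidy) or a matrix of integer vectors
  alt_depth <- if (is.array(gn$AD) && length(dim(gn$AD)) == 3L)
    as.integer(gn$AD[, sample, 2L])
  else
    vapply(gn$AD[, sample], function(v) as.integer(v[2L]), 0L)
  for (i in seq_along(ref)) {
    id <- sprintf("%s:%d %s>%s", chrom[i], pos[i], ref[i], alt[i])
    if (is.na(dp[i]) || dp[i] == 0L)
      stop("record ", id, " has zero/missing total depth (DP)")
    if (not_minimal(ref[i], alt[i]))
      stop("record ", id, " is not left-aligned and minimal")
    if (!is.na(alt_depth[i]) && alt_depth[i] > dp[i])
      stop("record ", id, ": alt depth exceeds total depth")
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             alt_depth = alt_depth, total_depth = dp,
             vaf = alt_depth / dp,
             variant_class = variant_class_of(ref, alt),
             stringsAsFactors = FALSE)
}

#' Minimum-depth gate for variant interpretation
#'
#' @param obs variant observation data.frame (needs `total_depth`).
#' @param min_depth minimum site depth (default 20, inclusive).
#' @return `obs` with a logical `depth_pass` column; failures are retained
#'   (reported as QC-failed sites downstream), never dropped.
#' @export
depth_gate <- function(obs, min_depth = 20L) {
  obs$depth_pass <- obs$total_depth >= min_depth
  obs
}

#' Assign zygosity from the variant allele frequency
#'
#' VAF below `t_low` is ambiguous (kept, flagged); between `t_low` and
#' `t_hom` heterozygous; at or above `t_hom` homozygous, or hemizygous on
#' the non-pseudoautosomal X/Y of a male sample. Thresholds default to
#' 0.20/0.80, comfortably separating the heterozygous (~0.4-0.55) and
#' homozygous (~0.93-1.0) VAF ranges seen in validated germline panel data.
#'
#' @param vaf numeric vector of VAFs in `[0, 1]`.
#' @param chrom chromosome name(s), recycled.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param par logical, is the site pseudoautosomal (recycled; default FALSE).
#' @param t_low,t_hom thresholds.
#' @return a data.frame with `zygosity` and `flag` (empty, `"low_vaf"`, or
#'   `"sex_unknown"` for X/Y sites of a sample of unknown sex).
#' @export
classify_zygosity <- function(vaf, chrom = "autosome", sex = "unknown",
                              par = FALSE, t_low = 0.20, t_hom = 0.80) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  sex <- match.arg(sex, c("male", "female", "unknown"))
  n <- length(vaf)
  chrom <- rep_len(chrom, n); par <- rep_len(par, n)
  hemi_ctx <- is_sex_chrom(chrom) & !par & sex == "male"
  zyg <- ifelse(vaf < t_low, "ambiguous",
         ifelse(vaf < t_hom, "heterozygous",
         ifelse(hemi_ctx, "hemizygous", "homozygous")))
  flag <- ifelse(vaf < t_low, "low_vaf",
          ifelse(is_sex_chrom(chrom) & sex == "unknown", "sex_unknown", ""))
  data.frame(zygosity = zyg, flag = flag, stringsAsFactors = FALSE)
}

#' Read per-variant evidence codes from JSON or TSV
#'
#' JSON: an object keyed by `chrom:pos:ref:alt` whose values are arrays of
#' codes. TSV: columns `chrom`, `pos`, `ref`, `alt`, `codes`
#' (comma-separated).
#'
#' @param path file path.
#' @return a named list of character vectors keyed by variant identity.
#' @export
read_evidence <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path)
    lapply(x, function(v) unlist(v, use.names = FALSE))
  } else {
    d <- data.table::fread(path, header = TRUE, colClasses = list(character = "codes"))
    keys <- sprintf("%s:%d:%s:%s", d$chrom, as.integer(d$pos), d$ref, d$alt)
    setNames(lapply(d$codes, function(s)
      trimws(strsplit(s, ",")[[1]])), keys)
  }
}

variant_key <- function(obs) sprintf("%s:%d:%s:%s", obs$chrom, obs$pos, obs$ref, obs$alt)

#' Interpret a set of variant observations end to end
#'
#' Applies the depth gate, assigns zygosity and combines the supplied
#' evidence codes per variant into an ACMG/AMP tier. Variants without
#' evidence are classified Uncertain significance.
#'
#' @param obs observations from [read_variants_vcf()].
#' @param evidence named list of evidence-code vectors keyed by
#'   `chrom:pos:ref:alt` (see [read_evidence()]).
#' @param sex sample sex.
#' @param min_depth depth gate (default 20).
#' @param t_low,t_hom zygosity thresholds.
#' @return `obs` extended with `depth_pass`, `zygosity`, `zygosity_flag`,
#'   `tier`, `fired_rules`.
#' @export
interpret_variants <- function(obs, evidence = list(), sex = "unknown",
                               min_depth = 20L, t_low = 0.20, t_hom = 0.80) {
  obs <- depth_gate(obs, min_depth)
  z <- classify_zygosity(obs$vaf, chrom = obs$chrom, sex = sex,
                         t_low = t_low, t_hom = t_hom)
  obs$zygosity <- ifelse(obs$depth_pass, z$zygosity, NA_character_)
  obs$zygosity_flag <- ifelse(obs$depth_pass, z$flag, "depth_fail")
  keys <- variant_key(obs)
  tiers <- lapply(keys, function(k) acmg_combine(evidence[[k]] %||% character()))
  obs$tier <- vapply(tiers, `[[`, "", "tier")
  obs$fired_rules <- vapply(tiers, function(t)
    paste(t$fired_rules, collapse = ","), "")
  obs
}
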