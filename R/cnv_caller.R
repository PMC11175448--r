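#' Copy-number loss calling from binned read depth
#'
#' The caller compares a test sample's binned mean depth of coverage with a
#' pool of reference samples. Depths are library-size normalized (divided by
#' the sample's panel-wide median), then divided per bin by the pool's median
#' normalized depth, giving a fold depth `f_b` with expectation 1 in
#' copy-neutral bins and 0.5 under a heterozygous loss. A bin is significant
#' when its z-score against the pool's fold distribution is below
#' `-z_threshold` and its fold is below `fold_ceiling`; maximal runs of at
#' least `min_consecutive_bins` significant bins become loss events, each
#' reported with a width-weighted median fold, log2 ratio and rounded copy
#' number. At the defaults (50-bp bins, 3 consecutive bins) the calling
#' resolution is 150 bp.
#'
#' @name cnv_caller
NULL

#' Default CNV-calling parameters
#'
#' @param z_threshold positive z cutoff; a bin is a loss candidate when its
#'   z-score is below `-z_threshold` (default 3).
#' @param fold_ceiling fold-change ceiling excluding marginal depth dips
#'   (default 0.75; a heterozygous loss sits near 0.5).
#' @param min_consecutive_bins minimum run length of significant bins
#'   (default 3, i.e. 150 bp at 50-bp bins).
#' @param sd_floor lower bound on the pool's per-bin fold standard deviation
#'   used for z-scoring (default 0.05), so that an unrealistically quiet pool
#'   cannot declare trivial dips significant.
#' @return a named list of parameters.
#' @export
cnv_params <- function(z_threshold = 3, fold_ceiling = 0.75,
                       min_consecutive_bins = 3L, sd_floor = 0.05) {
  if (z_threshold <= 0 || fold_ceiling <= 0 || min_consecutive_bins < 1 ||
      sd_floor <= 0)
    stop("CNV parameters must be positive")
  list(z_threshold = z_threshold, fold_ceiling = fold_ceiling,
       min_consecutive_bins = as.integer(min_consecutive_bins),
       sd_floor = sd_floor)
}

#' Read a per-base depth TSV
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `depth`.
#' @return a data.table of per-base depths.
#' @export
read_depth_tsv <- function(path) {
  d <- data.table::fread(path, header = TRUE)
  need <- c("chrom", "pos", "depth")
  if (!all(need %in% names(d)))
    stop("depth TSV ", path, " must have columns: ", paste(need, collapse = ", "))
  if (any(d$depth < 0)) stop("negative depth in ", path)
  d[, need, with = FALSE]
}

#' Collapse per-base depth onto panel bins
#'
#' @param depth per-base depth data.frame (`chrom`, `pos` 1-based, `depth`);
#'   bases absent from the table count as depth 0.
#' @param bins bin table from [bin_panel()].
#' @param sample_id sample identifier.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return a `bin_depths` object: list with `sample_id`, `sex` and `depths`
#'   (mean depth per bin, aligned to `bins$ordinal`).
#' @export
bin_depths <- function(depth, bins, sample_id = "sample", sex = "unknown") {
  sex <- match.arg(sex, c("male", "female", "unknown"))
  sums <- numeric(nrow(bins))
  pos0 <- depth$pos - 1L
  for (cn in unique(bins$chrom)) {
    bsel <- which(bins$chrom == cn)
    dsel <- which(depth$chrom == cn)
    if (!length(dsel)) next
    # bins within a chromosome are sorted and non-overlapping
    idx <- findInterval(pos0[dsel], bins$start[bsel])
    ok <- idx >= 1L & pos0[dsel] < bins$end[bsel][pmax(idx, 1L)]
    agg <- rowsum(depth$depth[dsel][ok], group = idx[ok])
    sums[bsel[as.integer(rownames(agg))]] <- agg[, 1L]
  }
  structure(list(sample_id = sample_id, sex = sex,
                 depths = sums / bins$width),
            class = "bin_depths")
}

#' Build a reference pool from binned depth profiles
#'
#' @param members list of `bin_depths` objects (at least 3), all aligned to
#'   the same panel bins.
#' @return a `reference_pool` object.
#' @export
reference_pool <- function(members) {
  if (length(members) < 3L) stop("reference pool needs at least 3 members")
  n <- lengths(lapply(members, `[[`, "depths"))
  if (length(unique(n)) != 1L)
    stop("pool members are not aligned to the same panel bins")
  structure(list(members = members), class = "reference_pool")
}

#' Load a reference pool from a directory of depth TSVs
#'
#' The directory holds one per-base depth TSV per member plus an optional
#' `manifest.json` (`[{"file": ..., "sample_id": ..., "sex": ...}, ...]`);
#' without a manifest every `*.tsv` is used with sex `"unknown"`.
#'
#' @param dir pool directory.
#' @param bins bin table from [bin_panel()].
#' @return a `reference_pool`.
#' @export
read_pool_dir <- function(dir, bins) {
  if (!dir.exists(dir)) stop("pool directory not found: ", dir)
  manifest <- file.path(dir, "manifest.json")
  if (file.exists(manifest)) {
    m <- read_json(manifest)
    files <- file.path(dir, m$file)
    ids <- m$sample_id %||% tools::file_path_sans_ext(m$file)
    sexes <- m$sex %||% rep("unknown", length(files))
  } else {
    files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
    ids <- tools::file_path_sans_ext(basename(files))
    sexes <- rep("unknown", length(files))
  }
  members <- Map(function(f, id, sx)
    bin_depths(read_depth_tsv(f), bins, sample_id = id, sex = sx),
    files, ids, sexes)
  reference_pool(unname(members))
}

# library-size normalization: per-bin depth / panel-wide median depth
normalize_library <- function(depths) {
  m <- median(depths)
  if (m <= 0) stop("sample median depth is zero; cannot normalize")
  depths / m
}

# recenter fold on sex chromosomes by the sample's own per-chromosome median,
# so male (hemizygous, ~0.5x) and female X baselines both sit at 1
recenter_sex_chroms <- function(fold, chrom) {
  out <- fold
  for (cn in unique(chrom[is_sex_chrom(chrom)])) {
    idx <- chrom == cn
    m <- median(fold[idx][fold[idx] > 0])
    if (is.finite(m) && m > 0) out[idx] <- fold[idx] / m
  }
  out
}

#' Normalized fold depth and z-scores against a reference pool
#'
#' @param sample a `bin_depths` object.
#' @param pool a `reference_pool`.
#' @param bins bin table from [bin_panel()].
#' @param params parameters from [cnv_params()].
#' @return a data.frame (`fold_depth_track`): one row per bin with `fold`
#'   (raw fold depth), `fold_adj` (sex-chromosome recentered fold used for
#'   testing), `z`, and `informative` (FALSE where the pool median depth is
#'   zero).
#' @export
normalize_fold_depth <- function(sample, pool, bins, params = cnv_params()) {
  stopifnot(inherits(sample, "bin_depths"), inherits(pool, "reference_pool"))
  if (length(sample$depths) != nrow(bins))
    stop("sample depths are not aligned to the panel bins")
  mem_norm <- vapply(pool$members, function(m) normalize_library(m$depths),
                     numeric(nrow(bins)))
  pool_med <- apply(mem_norm, 1L, median)
  informative <- pool_med > 0
  s_norm <- normalize_library(sample$depths)
  fold <- ifelse(informative, s_norm / ifelse(informative, pool_med, 1), NA_real_)
  # pool members' own folds (each recentered like the sample) give the null
  # per-bin dispersion used for z-scoring
  mem_fold <- mem_norm / ifelse(informative, pool_med, NA_real_)
  mem_fold_adj <- apply(mem_fold, 2L, recenter_sex_chroms, chrom = bins$chrom)
  pool_mean <- rowMeans(mem_fold_adj)
  pool_sd <- apply(mem_fold_adj, 1L, stats::sd)
  fold_adj <- if (sample$sex == "male" || any(is_sex_chrom(bins$chrom)))
    recenter_sex_chroms(fold, bins$chrom) else fold
  z <- (fold_adj - pool_mean) / pmax(pool_sd, params$sd_floor)
  out <- data.frame(bins[, c("chrom", "start", "end", "width", "ordinal",
                             "partial", "gene", "label")],
                    fold = fold, fold_adj = fold_adj, z = z,
                    informative = informative)
  attr(out, "sample_id") <- sample$sample_id
  attr(out, "sex") <- sample$sex
  class(out) <- c("fold_depth_track", "data.frame")
  out
}

#' Call copy-number loss events from a fold-depth track
#'
#' @param track output of [normalize_fold_depth()].
#' @param params parameters from [cnv_params()].
#' @return a data.frame of loss events (possibly zero rows): coordinates
#'   (0-based half-open, bin-aligned), bin ordinal range, number of bins,
#'   genomic span, width-weighted median fold, log2 ratio, continuous and
#'   rounded copy number, and the genes / exon labels overlapped.
#' @export
call_loss_events <- function(track, params = cnv_params()) {
  sig <- track$informative & !is.na(track$z) &
    track$z < -params$z_threshold & track$fold_adj < params$fold_ceiling
  sex <- attr(track, "sex") %||% "unknown"
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      bin_from = integer(), bin_to = integer(),
                      n_bins = integer(), span_bp = integer(),
                      median_fold = numeric(), log2_ratio = numeric(),
                      copy_number_estimate = numeric(), copy_number = integer(),
                      genes = character(), labels = character(),
                      stringsAsFactors = FALSE)
  if (!any(sig)) return(empty)
  # maximal runs of consecutive ordinals, not crossing chromosomes
  idx <- which(sig)
  brk <- c(TRUE, diff(track$ordinal[idx]) != 1L |
             track$chrom[idx][-1] != track$chrom[idx][-length(idx)])
  run_id <- cumsum(brk)
  events <- lapply(split(idx, run_id), function(ii) {
    if (length(ii) < params$min_consecutive_bins) return(NULL)
    tb <- track[ii, ]
    est <- estimate_copy_number(tb, sex = sex)
    data.frame(chrom = tb$chrom[1L], start = min(tb$start), end = max(tb$end),
               bin_from = min(tb$ordinal), bin_to = max(tb$ordinal),
               n_bins = length(ii), span_bp = max(tb$end) - min(tb$start),
               median_fold = est$median_fold, log2_ratio = est$log2_ratio,
               copy_number_estimate = est$copy_number_estimate,
               copy_number = est$copy_number,
               genes = paste(unique(tb$gene), collapse = ","),
               labels = paste(unique(tb$label[nzchar(tb$label)]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, events)
  if (is.null(events)) return(empty)
  rownames(events) <- NULL
  events
}

#' Summarize an event's copy number
#'
#' The event fold is the width-weighted median of the per-bin fold depth;
#' the copy-number estimate is `2 * fold` on autosomes and `1 * fold` (on
#' the recentered, hemizygous-baseline scale) on the male X/Y. Rounding is
#' to the nearest integer with exact halves going down, so a borderline loss
#' is not rounded up to copy-neutral.
#'
#' @param event_track rows of a `fold_depth_track` belonging to one event.
#' @param sex sample sex (`"male"`, `"female"`, `"unknown"`).
#' @return list with `median_fold`, `log2_ratio`, `copy_number_estimate`,
#'   `copy_number`. A zero fold reports `log2_ratio = -Inf` and copy
#'   number 0.
#' @export
estimate_copy_number <- function(event_track, sex = "unknown") {
  mf <- weighted_median(event_track$fold_adj, event_track$width)
  ploidy <- if (sex == "male" && all(is_sex_chrom(event_track$chrom))) 1 else 2
  est <- ploidy * mf
  list(median_fold = mf,
       log2_ratio = if (mf > 0) log2(mf) else -Inf,
       copy_number_estimate = est,
       copy_number = as.integer(max(0L, round_half_down(est))))
}

#' Run the full CNV-loss pipeline
#'
#' Normalizes a sample against the pool, calls loss events and returns both
#' the event table and the full per-bin fold/z audit track (the audit track
#' is what allows re-inspection of borderline or missed events).
#'
#' @param sample a `bin_depths` object, or a per-base depth data.frame/TSV
#'   path (then binned against `panel`).
#' @param pool a `reference_pool` or pool directory path.
#' @param panel a `panel_definition`.
#' @param params parameters from [cnv_params()].
#' @param sex sample sex, used when `sample` is not already a `bin_depths`.
#' @return list with `events`, `track`, `params`.
#' @export
cnv_pipeline <- function(sample, pool, panel, params = cnv_params(),
                         sex = "unknown") {
  bins <- bin_panel(panel)
  if (is.character(sample)) sample <- read_depth_tsv(sample)
  if (is.data.frame(sample)) sample <- bin_depths(sample, bins, sex = sex)
  if (is.character(pool)) pool <- read_pool_dir(pool, bins)
  track <- normalize_fold_depth(sample, pool, bins, params)
  events <- call_loss_events(track, params)
  list(events = events, track = track, params = params)
}

#' Write CNV events as TSV (1-based inclusive) and BED (0-based half-open)
#'
#' @param events event table from [call_loss_events()].
#' @param path_tsv,path_bed output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_cnv_events <- function(events, path_tsv = NULL, path_bed = NULL) {
  if (!is.null(path_tsv)) {
    human <- events
    human$start <- human$start + 1L  # 1-based inclusive for reports
    data.table::fwrite(human, path_tsv, sep = "\t")
  }
  if (!is.null(path_bed)) {
    bed <- events[, c("chrom", "start", "end", "genes")]
    data.table::fwrite(bed, path_bed, sep = "\t", col.names = FALSE)
  }
  invisible(c(path_tsv, path_bed))
}
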