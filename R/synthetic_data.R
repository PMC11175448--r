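#' Seeded generators for panel-shaped synthetic data
#'
#' These generators emulate the statistical structure the pipeline assumes
#' in hybrid-capture panel data: unimodal GC-dependent capture efficiency
#' (depth falls off at low and high GC), overdispersed per-base depth
#' (negative binomial) with bin-level capture noise, heterozygous /
#' homozygous deletions as 0.5x / 0x depth factors, hemizygous male-X
#' depth, and binomial allele-depth sampling around the theoretical VAFs of
#' 0.5 (heterozygous) and 1 minus a small base-error rate (homozygous /
#' hemizygous). Every generator is byte-deterministic under a fixed seed.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' @param seed master seed; all member/replicate seeds derive from it.
#' @param panel a `panel_definition` (default: the bundled 82-gene panel).
#' @param mean_depth mean on-target depth in x (default 500, typical of a
#'   clinical capture panel).
#' @param nb_size negative-binomial size (overdispersion) of per-base depth
#'   (default 60).
#' @param bin_noise_sdlog sdlog of the per-bin lognormal capture-efficiency
#'   noise (default 0.07, giving pool per-bin fold CVs in the 5-10% range).
#' @param gc_opt,gc_width,gc_floor unimodal GC response: a Gaussian-shaped
#'   multiplier peaking at `gc_opt` (default 0.50) with falloff `gc_width`
#'   (default 0.12) and floor `gc_floor` (default 0.2) at the extremes.
#' @param deletions list of planted losses; each element is either
#'   `list(gene=, exons=c(from, to), zygosity=)` or
#'   `list(chrom=, start=, end=, zygosity=)` with zygosity `"het"`/`"hom"`.
#' @param sex sample sex (default `"female"`).
#' @param pool_size reference-pool size (default 6).
#' @param hom_eps base-error rate subtracted from the homozygous/hemizygous
#'   allele fraction (default 0.005).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, panel = NULL, mean_depth = 500,
                       nb_size = 60, bin_noise_sdlog = 0.07,
                       gc_opt = 0.50, gc_width = 0.12, gc_floor = 0.2,
                       deletions = list(), sex = "female", pool_size = 6L,
                       hom_eps = 0.005) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (is.null(panel)) panel <- ird_panel()
  structure(list(seed = as.integer(seed), panel = panel,
                 mean_depth = mean_depth, nb_size = nb_size,
                 bin_noise_sdlog = bin_noise_sdlog, gc_opt = gc_opt,
                 gc_width = gc_width, gc_floor = gc_floor,
                 deletions = deletions,
                 sex = match.arg(sex, c("male", "female", "unknown")),
                 pool_size = as.integer(pool_size), hom_eps = hom_eps),
            class = "sim_config")
}

#' Unimodal GC response multiplier
#'
#' @param gc GC fraction in `[0, 1]`.
#' @param opt,width,floor curve parameters (see [sim_config()]).
#' @return multiplier in `[floor, 1]`.
#' @export
gc_response <- function(gc, opt = 0.50, width = 0.12, floor = 0.2) {
  floor + (1 - floor) * exp(-((gc - opt)^2) / (2 * width^2))
}

# Per-bin GC fraction: a property of the (synthetic) genome, so it is
# seeded independently of the simulation seed and identical across samples.
panel_gc_track <- function(bins, seed = 7L) {
  with_seed(seed, {
    gc <- numeric(nrow(bins))
    gc[1] <- 0.48
    steps <- rnorm(nrow(bins), 0, 0.02)
    for (i in seq_len(nrow(bins))[-1]) {
      gc[i] <- gc[i - 1] + steps[i]
      if (gc[i] > 0.68) gc[i] <- 0.68 - (gc[i] - 0.68)
      if (gc[i] < 0.28) gc[i] <- 0.28 + (0.28 - gc[i])
    }
    pmin(0.68, pmax(0.28, gc))
  })
}

# resolve a planted deletion to a genomic interval on the panel
resolve_deletion <- function(del, panel) {
  if (!is.null(del$gene)) {
    r <- panel$regions[panel$regions$gene == del$gene, ]
    if (!nrow(r)) stop("deletion gene not on panel: ", del$gene)
    wanted <- paste0("ex", seq(del$exons[1], del$exons[2]))
    hit <- r[r$label %in% wanted, ]
    if (nrow(hit) < length(wanted))
      stop("deletion exons ", del$exons[1], "-", del$exons[2],
           " not all present for gene ", del$gene)
    list(chrom = hit$chrom[1], start = min(hit$start), end = max(hit$end),
         zygosity = del$zygosity %||% "het",
         gene = del$gene, exons = del$exons)
  } else {
    on_panel <- any(panel$regions$chrom == del$chrom &
                    panel$regions$start < del$end &
                    panel$regions$end > del$start)
    if (!on_panel) stop("deletion interval is outside the panel")
    list(chrom = del$chrom, start = del$start, end = del$end,
         zygosity = del$zygosity %||% "het", gene = NA, exons = NA)
  }
}

#' Simulate a per-base depth profile over the panel
#'
#' Per-base depth is drawn from a negative binomial around
#' `mean_depth * gc_response(bin GC) * bin noise * ploidy factor`, where the
#' ploidy factor is 1 for copy-neutral bases, 0.5 under a heterozygous
#' deletion, 0 under a homozygous deletion, and 0.5 baseline on the
#' non-pseudoautosomal X of a male sample.
#'
#' @param config a [sim_config()].
#' @param sample_id sample identifier.
#' @return list with `depth` (data.frame `chrom`, `pos` 1-based, `depth`),
#'   `truth` (resolved planted deletions with expected copy numbers) and
#'   `sex`.
#' @export
simulate_depth_profile <- function(config, sample_id = "sample") {
  stopifnot(inherits(config, "sim_config"))
  bins <- bin_panel(config$panel)
  gc <- panel_gc_track(bins)
  dels <- lapply(config$deletions, resolve_deletion, panel = config$panel)
  with_seed(config$seed, {
    bin_mu <- config$mean_depth *
      gc_response(gc, config$gc_opt, config$gc_width, config$gc_floor) *
      exp(rnorm(nrow(bins), 0, config$bin_noise_sdlog))
    bin_idx <- rep.int(seq_len(nrow(bins)), bins$width)
    pos <- unlist(lapply(seq_len(nrow(bins)), function(i)
      seq.int(bins$start[i] + 1L, bins$end[i])), use.names = FALSE)
    chrom <- bins$chrom[bin_idx]
    ploidy <- rep(1, length(pos))
    if (config$sex == "male") ploidy[is_sex_chrom(chrom)] <- 0.5
    for (d in dels) {
      inside <- chrom == d$chrom & pos > d$start & pos <= d$end
      ploidy[inside] <- ploidy[inside] * if (d$zygosity == "hom") 0 else 0.5
    }
    mu <- bin_mu[bin_idx] * ploidy
    dp <- integer(length(pos))
    pos_mu <- mu > 0
    dp[pos_mu] <- rnbinom(sum(pos_mu), mu = mu[pos_mu], size = config$nb_size)
    depth <- data.frame(chrom = chrom, pos = pos, depth = dp)
    truth <- lapply(dels, function(d) {
      base_cn <- if (config$sex == "male" && is_sex_chrom(d$chrom)) 1L else 2L
      d$copy_number <- if (d$zygosity == "hom") 0L else base_cn - 1L
      d
    })
    list(depth = depth, truth = truth, sex = config$sex,
         sample_id = sample_id)
  })
}

#' Simulate a reference pool of deletion-free depth profiles
#'
#' Members share the panel GC-bias curve but have independent noise, with
#' per-member seeds derived from the master seed. Profiles are written as
#' per-base depth TSVs with a `manifest.json`.
#'
#' @param config a [sim_config()]; its `deletions` are ignored for the pool.
#' @param n pool size (default `config$pool_size`; must be >= 3).
#' @param dir output directory (created).
#' @param sexes member sexes, recycled (default `"female"`).
#' @return the directory path, invisibly; side effect: TSVs + manifest.
#' @export
simulate_reference_pool <- function(config, n = config$pool_size, dir,
                                    sexes = "female") {
  if (n < 3L) stop("reference pool needs n >= 3")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sexes <- rep_len(sexes, n)
  manifest <- lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    cfg_i$deletions <- list()
    cfg_i$sex <- sexes[i]
    prof <- simulate_depth_profile(cfg_i, sample_id = sprintf("ref%02d", i))
    f <- sprintf("ref%02d.depth.tsv", i)
    data.table::fwrite(prof$depth, file.path(dir, f), sep = "\t")
    list(file = f, sample_id = prof$sample_id, sex = sexes[i])
  })
  write_json_report(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Simulate replicate VCFs with binomial allele-depth sampling
#'
#' For each replicate, every truth variant gets a total depth drawn from a
#' negative binomial around `mean_depth` and an alt depth drawn from
#' `Binomial(total_depth, p)` with `p = 0.5` for heterozygous and
#' `p = 1 - hom_eps` for homozygous/hemizygous variants. Sites that draw
#' zero depth are omitted from that replicate's VCF (depth dropout).
#'
#' @param config a [sim_config()].
#' @param variants truth data.frame: `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity` (`het`/`hom`/`hemi`), `class` (`SNV`/`indel`).
#' @param replicates number of replicates (default 1).
#' @param dir output directory for the VCFs (created).
#' @return data.frame of simulated observations across replicates:
#'   `replicate`, `id`, `alt_depth`, `total_depth`, `vaf`, `vcf` (path).
#' @export
simulate_variant_vcf <- function(config, variants, replicates = 1L, dir) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1L)
  need <- c("id", "chrom", "pos", "ref", "alt", "zygosity", "class")
  if (!all(need %in% names(variants)))
    stop("variants needs columns: ", paste(need, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_of <- ifelse(variants$zygosity == "het", 0.5, 1 - config$hom_eps)
  out <- lapply(seq_len(replicates), function(r) {
    with_seed(derive_seed(config$seed, 100000L + r), {
      dp <- rnbinom(nrow(variants), mu = config$mean_depth, size = 50)
      ad <- rbinom(nrow(variants), dp, p_of)
      keep <- dp > 0L
      path <- file.path(dir, sprintf("replicate_%03d.vcf", r))
      write_sim_vcf(variants[keep, ], ad[keep], dp[keep], path,
                    sample_id = sprintf("rep%03d", r))
      data.frame(replicate = r, id = variants$id, class = variants$class,
                 zygosity = variants$zygosity,
                 alt_depth = ifelse(keep, ad, NA_integer_),
                 total_depth = ifelse(keep, dp, NA_integer_),
                 vaf = ifelse(keep, ad / dp, NA_real_),
                 emitted = keep, vcf = path,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, out)
}

# minimal, valid VCF 4.2 writer for simulated single-sample call sets
write_sim_vcf <- function(variants, ad, dp, path, sample_id = "sample") {
  o <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[o, ]; ad <- ad[o]; dp <- dp[o]
  gt <- ifelse(variants$zygosity == "het", "0/1",
        ifelse(variants$zygosity == "hemi", "1", "1/1"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelscope-simulator",
    sprintf("##contig=<ID=%s>", unique(variants$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
                  variants$chrom, variants$pos, variants$id, variants$ref,
                  variants$alt, gt, dp - ad, ad, dp)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a paired control/condition call set with class-wise dropout
#'
#' Models interference / storage-stability studies: the condition call set
#' is the control set thinned by a seeded per-class dropout probability.
#'
#' @param config a [sim_config()].
#' @param control data.frame of control-detected variants (`id`, `class`).
#' @param dropout named numeric vector of per-class dropout probabilities
#'   in `[0, 1]` (e.g. `c(SNV = 0.004, indel = 0)`).
#' @param label condition label.
#' @return list with `control`, `condition` (data.frame of retained
#'   variants) and `label`.
#' @export
simulate_condition_cohort <- function(config, control, dropout, label = "condition") {
  if (any(dropout < 0 | dropout > 1)) stop("dropout must be in [0, 1]")
  with_seed(derive_seed(config$seed, 900001L), {
    p <- dropout[control$class]
    p[is.na(p)] <- 0
    keep <- runif(nrow(control)) >= p
    list(control = control, condition = control[keep, , drop = FALSE],
         label = label)
  })
}

#' Truth set analog of the five validated heterozygous deletions
#'
#' The validation cohort's five heterozygous copy-number losses (in
#' *RP1L1*, *PDE6B*, *EYS* and twice *PRPF31*) are mapped onto the bundled
#' panel preserving their exon-range structure (exons 3-4, 2-3, 6-8, 1-14
#' and 2-3 respectively); true genomic breakpoints are not public.
#'
#' @return a list of deletion specifications usable in [sim_config()].
#' @export
validation_deletions <- function() {
  list(
    list(gene = "RP1L1",  exons = c(3L, 4L),  zygosity = "het", sample = "S884"),
    list(gene = "PDE6B",  exons = c(2L, 3L),  zygosity = "het", sample = "S952"),
    list(gene = "EYS",    exons = c(6L, 8L),  zygosity = "het", sample = "S983"),
    list(gene = "PRPF31", exons = c(1L, 14L), zygosity = "het", sample = "S1042"),
    list(gene = "PRPF31", exons = c(2L, 3L),  zygosity = "het", sample = "S1145"))
}

#' Truth set analog of the 15 precision-study variants
#'
#' Eleven SNVs and four small indels on panel genes, used by the
#' 144-replicate precision design (2 operators x 3 lots x 3 days x 8
#' replicates -> 1,584 expected SNV and 576 expected indel observations).
#' Positions are synthetic panel coordinates; zygosities follow the
#' reference-sample pattern (one homozygous SNV, the rest heterozygous).
#'
#' @param panel a `panel_definition` (default: bundled panel).
#' @return a data.frame suitable for [simulate_variant_vcf()].
#' @export
precision_truth_set <- function(panel = ird_panel()) {
  genes_snv <- c("ABCA4", "ABCA4", "ABCA4", "RHO", "RHO", "RP1L1", "RP1L1",
                 "RPGRIP1", "USH2A", "USH2A", "USH2A")
  genes_indel <- c("ADGRV1", "EYS", "MYO7A", "POC1B")
  pick_pos <- function(g, k) {
    r <- panel$regions[panel$regions$gene == g, ]
    as.integer(r$start[1L] + 10L + 7L * k)
  }
  snv <- data.frame(
    id = sprintf("snv%02d", seq_along(genes_snv)),
    chrom = vapply(genes_snv, function(g)
      panel$regions$chrom[panel$regions$gene == g][1L], ""),
    pos = vapply(seq_along(genes_snv), function(i)
      pick_pos(genes_snv[i], i), 0L),
    ref = rep(c("A", "C", "G", "T"), length.out = length(genes_snv)),
    alt = rep(c("G", "T", "A", "C"), length.out = length(genes_snv)),
    zygosity = c(rep("het", 7), "hom", rep("het", 3)),  # RPGRIP1 SNV is hom
    class = "SNV", stringsAsFactors = FALSE)
  indel_ref <- c("CTT", "ATTTT", "GAC", "TACACACACACAC")  # 1-22 bp changes
  indel_alt <- c("C", "A", "G", "T")
  indel <- data.frame(
    id = sprintf("indel%02d", seq_along(genes_indel)),
    chrom = vapply(genes_indel, function(g)
      panel$regions$chrom[panel$regions$gene == g][1L], ""),
    pos = vapply(seq_along(genes_indel), function(i)
      pick_pos(genes_indel[i], i + 20L), 0L),
    ref = indel_ref, alt = indel_alt,
    zygosity = "het", class = "indel", stringsAsFactors = FALSE)
  rbind(snv, indel)
}
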