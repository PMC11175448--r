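# a compact 3-gene panel keeps simulation tests fast
small_panel <- function() {
  make_panel(c("chr1\t0\t2000\tGENE1",
               paste0("chr2\t0\t500\tGENE2|ex1"),
               paste0("chr2\t2000\t2500\tGENE2|ex2"),
               "chrX\t0\t1500\tXGENE"))
}

test_that("depth simulation is deterministic and respects the null model", {
  p <- small_panel()
  cfg <- sim_config(seed = 21, panel = p, mean_depth = 400)
  a <- simulate_depth_profile(cfg)
  b <- simulate_depth_profile(cfg)
  expect_identical(a$depth, b$depth)
  expect_identical(nrow(a$depth), sum(p$regions$end - p$regions$start))
  # null model with bias and overdispersion switched off: flat depth at
  # mean_depth with only the Poisson noise floor (CV ~ 1/sqrt(mu) = 0.05)
  cfg0 <- sim_config(seed = 21, panel = p, mean_depth = 400, nb_size = 1e7,
                     bin_noise_sdlog = 1e-6, gc_width = 1e6)
  d0 <- simulate_depth_profile(cfg0)
  expect_equal(mean(d0$depth$depth), 400, tolerance = 0.01)
  expect_lt(sd(d0$depth$depth) / mean(d0$depth$depth), 0.07)
})

test_that("planted deletions scale depth by ploidy (ratio-of-means oracle)", {
  p <- small_panel()
  cfg <- sim_config(seed = 33, panel = p, mean_depth = 500,
                    deletions = list(list(gene = "GENE2", exons = c(1L, 2L),
                                          zygosity = "het")))
  prof <- simulate_depth_profile(cfg)
  # ratio oracle against the deletion-free profile at the same seed, so the
  # shared GC bias cancels
  prof0 <- simulate_depth_profile(sim_config(seed = 33, panel = p, mean_depth = 500))
  del <- prof$depth$chrom == "chr2"
  ratio <- mean(prof$depth$depth[del]) / mean(prof0$depth$depth[del])
  expect_equal(ratio, 0.5, tolerance = 0.05)
  expect_equal(prof$truth[[1]]$copy_number, 1L)

  cfg$deletions[[1]]$zygosity <- "hom"
  prof <- simulate_depth_profile(sim_config(seed = 33, panel = p, mean_depth = 500,
    deletions = list(list(gene = "GENE2", exons = c(1L, 2L), zygosity = "hom"))))
  expect_true(all(prof$depth$depth[prof$depth$chrom == "chr2"] == 0))
  expect_equal(prof$truth[[1]]$copy_number, 0L)

  # male X baseline halves depth relative to a female profile at same seed
  profm <- simulate_depth_profile(sim_config(seed = 34, panel = p, sex = "male"))
  proff <- simulate_depth_profile(sim_config(seed = 34, panel = p, sex = "female"))
  isx <- profm$depth$chrom == "chrX"
  rx <- mean(profm$depth$depth[isx]) / mean(proff$depth$depth[isx])
  expect_equal(rx, 0.5, tolerance = 0.05)

  expect_error(simulate_depth_profile(sim_config(panel = p,
    deletions = list(list(chrom = "chr9", start = 0, end = 100)))), "outside")
  expect_error(simulate_depth_profile(sim_config(panel = p,
    deletions = list(list(gene = "GENE2", exons = c(1L, 5L))))), "not all present")
})

test_that("reference pool: determinism, self-consistency, mixed sexes", {
  p <- small_panel()
  cfg <- sim_config(seed = 8, panel = p, mean_depth = 300)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_reference_pool(cfg, 4, d1)
  simulate_reference_pool(cfg, 4, d2)
  f1 <- list.files(d1, "\\.tsv$")
  expect_length(f1, 4L)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_error(simulate_reference_pool(cfg, 2, d1), "n >= 3")

  # a pool member re-normalized against its own pool sits at fold ~ 1
  bins <- bin_panel(p)
  pool <- read_pool_dir(d1, bins)
  tr <- normalize_fold_depth(pool$members[[1]], pool, bins)
  expect_equal(mean(tr$fold), 1, tolerance = 0.05)
  expect_equal(nrow(call_loss_events(tr)), 0L)

  # mixed sexes: male members show ~0.5 relative X depth
  d3 <- withr::local_tempdir()
  simulate_reference_pool(cfg, 4, d3, sexes = c("female", "female", "male", "male"))
  pool3 <- read_pool_dir(d3, bins)
  xm <- pool3$members[[3]]
  xr <- mean(xm$depths[bins$chrom == "chrX"]) / mean(xm$depths[bins$chrom == "chr1"])
  expect_equal(xr, 0.5, tolerance = 0.1)
  expect_equal(pool3$members[[3]]$sex, "male")
})

test_that("replicate VCF simulation: counts, binomial VAFs, valid VCF out", {
  p <- small_panel()
  cfg <- sim_config(seed = 99, panel = p, mean_depth = 500)
  truth <- data.frame(
    id = c("v1", "v2", "v3"),
    chrom = c("chr1", "chr1", "chrX"), pos = c(100L, 900L, 50L),
    ref = c("A", "CT", "G"), alt = c("G", "C", "A"),
    zygosity = c("het", "het", "hemi"),
    class = c("SNV", "indel", "SNV"), stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  sim <- simulate_variant_vcf(cfg, truth, replicates = 10, dir = dir)
  expect_equal(nrow(sim), 30L)
  expect_length(unique(sim$vcf), 10L)
  het <- sim$vaf[sim$id == "v1"]
  expect_equal(mean(het), 0.5, tolerance = 0.03)
  hemi <- sim$vaf[sim$id == "v3"]
  expect_gt(mean(hemi), 0.98)
  # VCF round-trips through the standard reader
  obs <- read_variants_vcf(sim$vcf[1])
  expect_equal(nrow(obs), 3L)
  expect_equal(obs$variant_class, c("SNV", "deletion", "SNV"))
  expect_equal(obs$total_depth,
               sim$total_depth[sim$replicate == 1][order(truth$chrom, truth$pos)])
  # determinism
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_variant_vcf(cfg, truth, replicates = 10, dir = dir2)
  expect_equal(sim$vaf, sim2$vaf)
})

test_that("condition cohorts thin the control set by class-wise dropout", {
  cfg <- sim_config(seed = 4, panel = small_panel())
  control <- data.frame(id = sprintf("v%03d", 1:200),
                        class = rep(c("SNV", "indel"), c(180, 20)))
  r0 <- simulate_condition_cohort(cfg, control, c(SNV = 0, indel = 0))
  expect_equal(nrow(r0$condition), 200L)
  r1 <- simulate_condition_cohort(cfg, control, c(SNV = 1, indel = 1))
  expect_equal(nrow(r1$condition), 0L)
  rmid <- simulate_condition_cohort(cfg, control, c(SNV = 0.5, indel = 0))
  dr <- detection_rate(control, rmid$condition$id)
  expect_equal(dr$rate[dr$class == "indel"], 1.0)
  expect_lt(dr$rate[dr$class == "SNV"], 1.0)
  expect_error(simulate_condition_cohort(cfg, control, c(SNV = 1.2)), "dropout")
})

test_that("VAF calibration across the replicate design (seeded property)", {
  cfg <- sim_config(seed = 606, panel = small_panel(), mean_depth = 500)
  truth <- data.frame(id = c("het1", "hom1"), chrom = "chr1",
                      pos = c(101L, 201L), ref = "A", alt = "G",
                      zygosity = c("het", "hom"), class = "SNV",
                      stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  sim <- simulate_variant_vcf(cfg, truth, replicates = 144, dir = dir)
  het <- 100 * sim$vaf[sim$id == "het1"]
  hom <- 100 * sim$vaf[sim$id == "hom1"]
  expect_lt(abs(mean(het) - 50), 2)      # mean within 50 +/- 2
  expect_lt(abs(mean(hom) - 99.5), 0.5)  # 100 - eps within +/- 0.5
  expect_lt(sd(hom), 1)                  # tight homozygote VAFs
  expect_gt(sd(het), 0.5)                # binomial spread at depth 500
})
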