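test_that("fold normalization: self, ratio arithmetic and library-size invariance", {
  panel <- flat_panel(1000)  # 20 bins
  bins <- bin_panel(panel)
  pool <- flat_pool(20)

  # sample identical to every pool member -> f = 1, z = 0
  tr <- normalize_fold_depth(bd(rep(500, 20)), pool, bins)
  expect_equal(tr$fold, rep(1, 20))
  expect_equal(tr$z, rep(0, 20))

  # half depth on bins 10-13 -> f = 0.5 there, 1 elsewhere (ratio oracle)
  d <- rep(500, 20); d[10:13] <- 250
  tr <- normalize_fold_depth(bd(d), pool, bins)
  expect_equal(tr$fold[10:13], rep(0.5, 4))
  expect_equal(tr$fold[-(10:13)], rep(1, 16))

  # global 2x scaling changes nothing (library-size invariance)
  tr2 <- normalize_fold_depth(bd(2 * d), pool, bins)
  expect_equal(tr2$fold, tr$fold)
  expect_equal(tr2$z, tr$z)
  expect_identical(nrow(call_loss_events(tr2)), nrow(call_loss_events(tr)))

  expect_error(normalize_fold_depth(bd(rep(0, 20)), pool, bins), "median depth")
})

test_that("uninformative pool bins are flagged and excluded", {
  panel <- flat_panel(500)
  bins <- bin_panel(panel)
  mem <- rep(500, 10); mem[4] <- 0
  pool <- reference_pool(lapply(1:4, function(i) bd(mem)))
  tr <- normalize_fold_depth(bd(rep(500, 10)), pool, bins)
  expect_false(tr$informative[4])
  expect_true(all(tr$informative[-4]))
  d <- rep(500, 10); d[3:5] <- 0   # drop overlapping the dead bin
  ev <- call_loss_events(normalize_fold_depth(bd(d), pool, bins))
  expect_true(all(vapply(seq_len(nrow(ev)), function(i)
    !(4 %in% seq(ev$bin_from[i], ev$bin_to[i])), TRUE)))
})

test_that("loss events require >= 3 consecutive significant bins (run-length oracle)", {
  panel <- flat_panel(2000)  # 40 bins
  bins <- bin_panel(panel)
  pool <- flat_pool(40)

  # null profile -> no events
  tr <- normalize_fold_depth(bd(rep(500, 40)), pool, bins)
  expect_equal(nrow(call_loss_events(tr)), 0L)

  # noise-free 3-bin drop (150 bp) -> exactly one event of span 150
  d <- rep(500, 40); d[5:7] <- 250
  tr <- normalize_fold_depth(bd(d), pool, bins)
  ev <- call_loss_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$span_bp, 150L)
  expect_equal(ev$n_bins, 3L)
  expect_equal(ev$copy_number, 1L)

  # 2-bin drop -> no event
  d <- rep(500, 40); d[5:6] <- 250
  expect_equal(nrow(call_loss_events(normalize_fold_depth(bd(d), pool, bins))), 0L)

  # random significance patterns agree with the exhaustive run scanner
  set.seed(99)
  for (k in 1:20) {
    d <- rep(500, 40)
    # at most 10 of 40 bins dropped, so the median library size stays put
    drop <- rep(FALSE, 40)
    drop[sample(40, sample(3:10, 1))] <- TRUE
    d[drop] <- 250
    tr <- normalize_fold_depth(bd(d), pool, bins)
    ev <- call_loss_events(tr)
    oracle <- runs_oracle(drop, bins$chrom, 3L)
    expect_equal(nrow(ev), length(oracle))
    if (length(oracle)) {
      expect_equal(ev$bin_from, vapply(oracle, `[`, 0L, 1L))
      expect_equal(ev$bin_to, vapply(oracle, `[`, 0L, 2L))
    }
  }
})

test_that("runs do not cross chromosome boundaries", {
  panel <- make_panel(c("chr1\t0\t200\tG1", "chr2\t0\t200\tG2"))
  bins <- bin_panel(panel)
  pool <- flat_pool(8)
  d <- rep(500, 8); d[3:6] <- 250  # 2 sig bins on chr1 + 2 on chr2
  ev <- call_loss_events(normalize_fold_depth(bd(d), pool, bins))
  expect_equal(nrow(ev), 0L)
})

test_that("copy-number estimation: halving, log2 ratios, homozygous zero", {
  panel <- flat_panel(2000)
  bins <- bin_panel(panel)
  pool <- flat_pool(40)

  d <- rep(500, 40); d[10:14] <- 250
  ev <- call_loss_events(normalize_fold_depth(bd(d), pool, bins))
  expect_equal(ev$median_fold, 0.5)
  expect_equal(ev$log2_ratio, -1.0)
  expect_equal(ev$copy_number_estimate, 1.0)
  expect_equal(ev$copy_number, 1L)

  # printed-style log2 ratios: median of {2^-1.06, 2^-1.12, 2^-1.04} -> -1.06
  folds <- 2^c(-1.06, -1.12, -1.04)
  est <- estimate_copy_number(
    data.frame(fold_adj = folds, width = rep(50L, 3), chrom = "chr1"))
  expect_equal(est$log2_ratio, -1.06, tolerance = 1e-12)
  expect_equal(est$copy_number, 1L)

  # homozygous deletion: fold 0 over 10 bins -> CN 0, log2 -Inf
  d <- rep(500, 40); d[20:29] <- 0
  ev <- call_loss_events(normalize_fold_depth(bd(d), pool, bins))
  expect_equal(ev$copy_number, 0L)
  expect_equal(ev$log2_ratio, -Inf)
  expect_equal(ev$copy_number_estimate, 0)

  # identity: fold 1 -> CN 2
  est <- estimate_copy_number(
    data.frame(fold_adj = 1, width = 50L, chrom = "chr1"))
  expect_equal(est$copy_number, 2L)
})

test_that("partial terminal bins are width-weighted in the event summary", {
  # a 153-bp exon (3 full bins + 3-bp partial) next to a 1000-bp neighbour
  panel <- make_panel(c("chr1\t0\t153\tPDE6B|ex2", "chr1\t10000\t11000\tOTHER"))
  bins <- bin_panel(panel)
  pool <- flat_pool(nrow(bins))
  d <- rep(500, nrow(bins)); d[1:4] <- 250  # whole exon deleted, partial too
  ev <- call_loss_events(normalize_fold_depth(bd(d), pool, bins))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_bins, 4L)
  expect_equal(ev$span_bp, 153L)
  expect_equal(ev$copy_number, 1L)
  # width-weighted median over mixed folds leans on the wide bins
  est <- estimate_copy_number(
    data.frame(fold_adj = c(0.5, 0.5, 0.5, 1.0), width = c(50, 50, 50, 3),
               chrom = "chr1"))
  expect_equal(est$median_fold, 0.5)
})

test_that("monotonicity: deepening a loss never removes or shrinks an event", {
  panel <- flat_panel(2000)
  bins <- bin_panel(panel)
  pool <- flat_pool(40)
  base <- rep(500, 40)
  spans <- list(5:8, 12:20, 30:34)
  for (sp in spans) {
    prev_span <- -1L
    for (f in c(0.6, 0.5, 0.3, 0.1, 0)) {
      d <- base; d[sp] <- 500 * f
      ev <- call_loss_events(normalize_fold_depth(bd(d), pool, bins))
      expect_equal(nrow(ev), 1L)
      expect_gte(ev$span_bp, prev_span)
      prev_span <- ev$span_bp
    }
  }
})

test_that("male X recentering: hemizygous baseline is not called, real loss is", {
  panel <- make_panel(c("chr1\t0\t1000\tAUT", "chrX\t0\t1000\tXG"))
  bins <- bin_panel(panel)  # 20 + 20 bins
  # mixed pool: 2 females (X at full depth) + 2 males (X at half depth)
  pool <- reference_pool(list(
    bd(rep(500, 40), sex = "female"), bd(rep(500, 40), sex = "female"),
    bd(c(rep(500, 20), rep(250, 20)), sex = "male"),
    bd(c(rep(500, 20), rep(250, 20)), sex = "male")))
  # male sample, no deletion: chrX sits at half depth but must not be called
  tr <- normalize_fold_depth(bd(c(rep(500, 20), rep(250, 20)), sex = "male"),
                             pool, bins)
  expect_equal(nrow(call_loss_events(tr)), 0L)
  expect_equal(tr$fold_adj[21:40], rep(1, 20))
  # male sample with a hemizygous deletion on X (depth 0 over 5 bins)
  d <- c(rep(500, 20), rep(250, 20)); d[25:29] <- 0
  tr <- normalize_fold_depth(bd(d, sex = "male"), pool, bins)
  ev <- call_loss_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$chrom, "chrX")
  expect_equal(ev$copy_number, 0L)  # ploidy-1 scale on male X
})

test_that("parameter validation and pipeline plumbing", {
  expect_error(cnv_params(z_threshold = 0), "positive")
  expect_error(cnv_params(min_consecutive_bins = 0), "positive")
  expect_error(reference_pool(list(bd(rep(1, 5)), bd(rep(1, 5)))), "at least 3")
  expect_error(reference_pool(list(bd(rep(1, 5)), bd(rep(1, 5)), bd(rep(1, 4)))),
               "aligned")
})

test_that("pipeline on simulated data recovers a planted loss with audit track", {
  panel <- ird_panel()
  cfg <- sim_config(seed = 11, mean_depth = 300,
                    deletions = list(list(gene = "EYS", exons = c(6L, 8L),
                                          zygosity = "het")))
  pool_dir <- withr::local_tempdir()
  simulate_reference_pool(cfg, 4, pool_dir)
  prof <- simulate_depth_profile(cfg)
  res <- cnv_pipeline(prof$depth, pool_dir, panel, sex = "female")
  expect_gte(nrow(res$events), 1L)
  hit <- grepl("EYS", res$events$genes)
  expect_true(any(hit))
  expect_equal(res$events$copy_number[hit], rep(1L, sum(hit)))
  expect_equal(nrow(res$track), nrow(bin_panel(panel)))
  # audit track supports re-inspection: fold near 0.5 inside the event
  ev <- res$events[hit, ][1, ]
  inside <- res$track$ordinal >= ev$bin_from & res$track$ordinal <= ev$bin_to
  expect_equal(median(res$track$fold[inside]), 0.5, tolerance = 0.1)
})
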