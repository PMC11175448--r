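# Shared fixtures and independent oracles for the test suite.

# write a BED and read it back as a panel
make_panel <- function(lines, bin_length = 50L) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  read_panel_bed(f, bin_length = bin_length)
}

# a single-region panel of the given length, handy for caller tests
flat_panel <- function(len, chrom = "chr1", gene = "GENE") {
  make_panel(sprintf("%s\t0\t%d\t%s|ex1", chrom, len, gene))
}

# bin_depths object straight from a per-bin depth vector
bd <- function(depths, sex = "unknown", id = "s") {
  structure(list(sample_id = id, sex = sex, depths = depths),
            class = "bin_depths")
}

# pool of n identical flat members
flat_pool <- function(n_bins, n = 4L, depth = 500) {
  reference_pool(lapply(seq_len(n), function(i) bd(rep(depth, n_bins))))
}

# ---- independent oracles -------------------------------------------------

# Clopper-Pearson by numeric inversion of the exact binomial tails
cp_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low = low, high = high)
}

# ACMG/AMP combining rules as a data-driven truth table (transcribed
# independently of the implementation's if-chain)
acmg_oracle <- function(codes) {
  strength_of <- function(code) {
    base <- sub("_.*", "", code)
    if (grepl("_", code)) return(sub("^[^_]*_", "", code))
    if (base == "PVS1") "very_strong"
    else if (grepl("^PS", base) || grepl("^BS", base)) "strong"
    else if (grepl("^PM", base)) "moderate"
    else if (grepl("^PP", base) || grepl("^BP", base)) "supporting"
    else if (base == "BA1") "stand_alone"
    else stop("bad code ", code)
  }
  side_of <- function(code) if (substr(code, 1, 1) == "P") "P" else "B"
  s <- vapply(codes, strength_of, "")
  sd <- vapply(codes, side_of, "")
  ct <- c(vs = sum(sd == "P" & s == "very_strong"),
          st = sum(sd == "P" & s == "strong"),
          mo = sum(sd == "P" & s == "moderate"),
          su = sum(sd == "P" & s == "supporting"),
          ba = sum(sd == "B" & s == "stand_alone"),
          bs = sum(sd == "B" & s == "strong"),
          bp = sum(sd == "B" & s == "supporting"))
  meets <- function(req) all(ct[names(req)] >= req)
  p_rules <- list(c(vs = 1, st = 1), c(vs = 1, mo = 2), c(vs = 1, mo = 1, su = 1),
                  c(vs = 1, su = 2), c(st = 2), c(st = 1, mo = 3),
                  c(st = 1, mo = 2, su = 2), c(st = 1, mo = 1, su = 4))
  lp_rules <- list(c(vs = 1, mo = 1), c(st = 1, mo = 1), c(st = 1, su = 2),
                   c(mo = 3), c(mo = 2, su = 2), c(mo = 1, su = 4))
  b_rules <- list(c(ba = 1), c(bs = 2))
  lb_rules <- list(c(bs = 1, bp = 1), c(bp = 2))
  p_side <- if (any(vapply(p_rules, meets, TRUE))) "Pathogenic"
            else if (any(vapply(lp_rules, meets, TRUE))) "Likely pathogenic" else NA
  b_side <- if (any(vapply(b_rules, meets, TRUE))) "Benign"
            else if (any(vapply(lb_rules, meets, TRUE))) "Likely benign" else NA
  if (!is.na(p_side) && !is.na(b_side)) "Uncertain significance"
  else if (!is.na(p_side)) p_side
  else if (!is.na(b_side)) b_side
  else "Uncertain significance"
}

# brute-force significant-run scanner (CNV caller run-length oracle)
runs_oracle <- function(sig, chrom, min_len) {
  out <- list()
  i <- 1L
  while (i <= length(sig)) {
    if (sig[i]) {
      j <- i
      while (j < length(sig) && sig[j + 1L] && chrom[j + 1L] == chrom[i]) j <- j + 1L
      if (j - i + 1L >= min_len) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

all_acmg_codes <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                    paste0("PP", 1:5), "BA1", paste0("BS", 1:4),
                    paste0("BP", 1:7))
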