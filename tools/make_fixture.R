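# Regenerates inst/extdata/ird_panel_82_synthetic.bed.
# Gene symbols are the real 82-gene panel content; coordinates are synthetic
# (deterministic, seeded) since the true capture coordinates are not public.
# Exon structures that matter downstream are pinned: PDE6B exons 2-3 span 153
# and 90 bases; PRPF31 has 14 exons; RP1L1 / EYS expose the exon ranges used
# in the copy-number validation analog; RPGR carries a large ORF15 terminal
# target; CEP290 carries the intron 26/27 deep-intronic target.

genes <- c(
  "ABCA4","ADGRV1","AIPL1","BEST1","C8orf37","CA4","CACNA1F","CDH23","CDHR1",
  "CEP290","CERKL","CFAP410","CHM","CLRN1","CNGA1","CNGA3","CNGB1","CNGB3",
  "CRB1","CRX","CYP4V2","DHDDS","DRAM2","EYS","FAM161A","FSCN2","GNAT2",
  "GRK1","GUCA1A","GUCY2D","IDH3B","IMPDH1","IMPG2","IQCB1","KCNV2","KLHL7",
  "LRAT","MAK","MERTK","MYO7A","NMNAT1","NR2E3","NRL","NYX","PCARE","PDE6A",
  "PDE6B","PDE6C","PDE6G","POC1B","PRCD","PROM1","PRPF3","PRPF31","PRPF6",
  "PRPF8","PRPH2","RBP3","RDH12","RDH5","RGR","RGS9BP","RHO","RLBP1","ROM1",
  "RP1","RP1L1","RP2","RP9","RPE65","RPGR","RPGRIP1","RS1","SAG","SEMA4A",
  "SNRNP200","SPATA7","TOPORS","TTC8","TULP1","USH2A","ZNF513")
stopifnot(length(genes) == 82, !anyDuplicated(genes))

x_genes <- c("RPGR", "RP2", "CHM", "RS1", "NYX", "CACNA1F")

# pinned exon-length vectors (bases)
pinned <- list(
  PDE6B  = c(210, 153, 90, 180, 140, 165, 130, 220),
  PRPF31 = c(160, 120, 140, 110, 180, 130, 150, 120, 140, 160, 110, 130, 170, 200),
  RP1L1  = c(250, 180, 160, 210, 300, 140),
  EYS    = c(220, 150, 170, 130, 190, 160, 140, 180, 210, 150),
  RPGR   = c(rep(c(150, 120, 180, 140), length.out = 14), 1706),  # last = ORF15
  CEP290 = rep(c(130, 150, 110, 170), length.out = 12)
)

set.seed(820503)
autosomes <- paste0("chr", 1:22)
chrom_of <- setNames(autosomes[(seq_along(genes) - 1L) %% 22L + 1L], genes)
chrom_of[x_genes] <- "chrX"

cursor <- setNames(rep(1e6, 24), c(autosomes, "chrX", "chrY"))
rows <- list()
for (g in genes) {
  if (!is.null(pinned[[g]])) {
    ex_len <- pinned[[g]]
  } else {
    n_ex <- sample(3:10, 1)
    ex_len <- sample(100:300, n_ex, replace = TRUE)
  }
  gaps <- sample(800:3000, length(ex_len), replace = TRUE)
  chrom <- chrom_of[[g]]
  pos <- cursor[[chrom]]
  for (i in seq_along(ex_len)) {
    lab <- if (g == "RPGR" && i == length(ex_len)) "ORF15" else paste0("ex", i)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = pos, end = pos + ex_len[i],
      name = paste0(g, "|", lab))
    pos <- pos + ex_len[i] + gaps[i]
  }
  if (g == "CEP290") {  # deep-intronic target between exons 26 and 27 analog
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = pos + 500, end = pos + 650,
      name = "CEP290|int26-27")
    pos <- pos + 1500
  }
  cursor[[chrom]] <- pos + 5e4
}
bed <- do.call(rbind, rows)
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  r <- suppressWarnings(as.numeric(x)); r[x == "X"] <- 23; r[x == "Y"] <- 24
  r
}
bed <- bed[order(chrom_rank(bed$chrom), bed$start), ]
bed$start <- as.integer(bed$start); bed$end <- as.integer(bed$end)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
out <- "inst/extdata/ird_panel_82_synthetic.bed"
writeLines(sprintf("%s\t%d\t%d\t%s", bed$chrom, bed$start, bed$end, bed$name), out)
cat(sprintf("wrote %s: %d regions, %d genes, %d bp\n", out, nrow(bed),
            length(unique(sub("\\|.*", "", bed$name))), sum(bed$end - bed$start)))
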