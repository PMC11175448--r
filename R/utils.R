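#' @importFrom stats median qbeta rbinom rnbinom rnorm runif setNames
#' @importFrom utils packageVersion head tail
NULL

# Natural chromosome ordering: chr1..chr22 < chrX < chrY < chrM < others
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  r <- suppressWarnings(as.numeric(x))
  r[x == "X"] <- 23
  r[x == "Y"] <- 24
  r[x %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26 + as.integer(factor(x[is.na(r)]))
  r
}

is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

#' Weighted median
#'
#' Lower weighted median: the smallest value at which the cumulative weight
#' reaches half the total. Used by the CNV caller to summarize per-bin fold
#' changes with bin-width weights, so a terminal partial bin contributes in
#' proportion to the bases it covers.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return a single numeric value.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Round to nearest integer with exact halves going DOWN (a borderline loss
# should not round up to normal copy number).
round_half_down <- function(x) ceiling(x - 0.5)

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

read_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

# Seed derivation: keep children well below .Machine$integer.max
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 10007 + k * 7919) %% 2147483L + k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
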