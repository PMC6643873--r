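# Shared fixtures, built in code at load time.

# A tiny two-marker map with one fully specified line, for closed-form HMM
# checks.
tiny_map <- function(d_cM = 20) {
  m <- data.frame(marker = c("a", "b"), chrom = "chr1", pos_cM = c(0, d_cM),
                  stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  m
}

tiny_geno <- function(calls = c("A", "B"), markers = c("a", "b")) {
  structure(list(
    calls = matrix(calls, 1, length(calls),
                   dimnames = list("L1", markers)),
    line_ids = "L1",
    cross_direction = "AxB"
  ), class = "ril_genotypes")
}

# Moderate shared panel reused across qtlmap tests (3 chromosomes keeps the
# scans fast while leaving unlinked chromosomes for null regions).
panel_map <- simulate_map(3, 60, 10, seed = 101)
panel_geno <- simulate_ril_genotypes(panel_map, 120, seed = 102)
panel_gp <- genotype_probabilities(panel_geno, panel_map,
                                   build_grid(panel_map, step = 1),
                                   error_rate = 0)

# marker-regression LOD oracle (explicit RSS computation)
lod_marker_oracle <- function(y, x) {
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
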