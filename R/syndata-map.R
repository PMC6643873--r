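# Synthetic genetic maps and RIL genotypes.
#
# A genetic map is a data.frame (marker, chrom, pos_cM) with positions
# non-decreasing within each chromosome; a genotype set is a list with a
# lines x markers character matrix of homozygous calls ("A"/"B"/NA) plus the
# reciprocal cross direction of each line, which determines its mitochondrial
# genotype.

#' Simulate a genetic map
#'
#' Places markers uniformly at random along each chromosome, then sorts them,
#' mimicking a SNP panel of known genetic positions. With six chromosomes the
#' chromosome names follow nematode convention (I-V, X); otherwise they are
#' `chr1`, `chr2`, ...
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths_cM Numeric vector of chromosome lengths in
#'   centimorgans, recycled to `n_chromosomes`.
#' @param markers_per_chromosome Integer number of markers per chromosome
#'   (recycled); at least 2.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return A `genetic_map` data.frame with columns `marker`, `chrom`,
#'   `pos_cM`.
#' @export
simulate_map <- function(n_chromosomes = 6,
                         chromosome_lengths_cM = 50,
                         markers_per_chromosome = 172,
                         seed = 1L) {
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1", call. = FALSE)
  lens <- rep_len(chromosome_lengths_cM, n_chromosomes)
  nm <- rep_len(as.integer(markers_per_chromosome), n_chromosomes)
  if (any(lens <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  if (any(nm < 2)) stop("markers_per_chromosome must be >= 2", call. = FALSE)
  chroms <- if (n_chromosomes == 6) c("I", "II", "III", "IV", "V", "X") else
    paste0("chr", seq_len(n_chromosomes))
  set.seed(as.integer(seed))
  pieces <- lapply(seq_len(n_chromosomes), function(i) {
    pos <- sort(stats::runif(nm[i], 0, lens[i]))
    data.frame(
      marker = sprintf("%s_m%03d", chroms[i], seq_len(nm[i])),
      chrom = chroms[i],
      pos_cM = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

chrom_lengths <- function(map) {
  vapply(split(map$pos_cM, map$chrom), max, numeric(1))
}

# -- haplotype mosaics -------------------------------------------------------
# A haplotype on one chromosome is a run-length mosaic: list(starts, alleles)
# where alleles[k] (1 = A, 2 = B) occupies [starts[k], starts[k+1]).

founder_hap <- function(allele) list(starts = 0, alleles = as.integer(allele))

hap_allele_at <- function(h, pos) h$alleles[findInterval(pos, h$starts)]

# One meiotic product of an individual (pair of haplotypes) under the Haldane
# model: crossover count ~ Poisson(L/100), positions uniform, no interference.
meiosis <- function(h1, h2, L) {
  n_xo <- stats::rpois(1L, L / 100)
  src <- if (stats::runif(1) < 0.5) 1L else 2L
  if (n_xo == 0L) return(if (src == 1L) h1 else h2)
  xo <- sort(stats::runif(n_xo, 0, L))
  haps <- list(h1, h2)
  bounds <- c(0, xo, L)
  starts <- numeric(0)
  alleles <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    h <- haps[[src]]
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    if (hi > lo) {
      i0 <- findInterval(lo, h$starts)
      i1 <- findInterval(hi, h$starts)
      idx <- i0:i1
      ss <- pmax(h$starts[idx], lo)
      aa <- h$alleles[idx]
      keep <- ss < hi
      starts <- c(starts, ss[keep])
      alleles <- c(alleles, aa[keep])
    }
    src <- 3L - src
  }
  keep <- c(TRUE, alleles[-1L] != alleles[-length(alleles)])
  list(starts = starts[keep], alleles = alleles[keep])
}

# Simulate one RIL's haplotype for one chromosome: F1 x F1 sib-intercross for
# g generations, s selfing generations, then fixation sampled directly as a
# final meiotic product (haplotype-coherent resolution of residual
# heterozygosity), doubled.
sim_line_chromosome <- function(L, n_intercross, n_selfing) {
  f1 <- list(founder_hap(1L), founder_hap(2L))
  p1 <- f1
  p2 <- f1
  for (g in seq_len(n_intercross)) {
    n1 <- list(meiosis(p1[[1]], p1[[2]], L), meiosis(p2[[1]], p2[[2]], L))
    n2 <- list(meiosis(p1[[1]], p1[[2]], L), meiosis(p2[[1]], p2[[2]], L))
    p1 <- n1
    p2 <- n2
  }
  ind <- p1
  for (s in seq_len(n_selfing)) {
    ind <- list(meiosis(ind[[1]], ind[[2]], L), meiosis(ind[[1]], ind[[2]], L))
  }
  meiosis(ind[[1]], ind[[2]], L)
}

#' Simulate advanced-intercross RIL genotypes
#'
#' Each line is an independent homozygous mosaic of the two parental genomes:
#' an F1 x F1 intercross is propagated for `n_intercross_generations`
#' meioses (expanding the effective map), selfed for
#' `n_selfing_generations`, and residual heterozygosity is resolved by
#' doubling a final meiotic product. Crossovers follow the Haldane model (no
#' interference). Transmission-ratio distortion, if requested, is imposed by
#' biased retention of lines carrying the favored allele at a focal position,
#' so the allele-frequency excess decays with genetic distance through
#' linkage. Cross directions alternate AxB / BxA to emulate reciprocal
#' crosses.
#'
#' @param map A `genetic_map`.
#' @param n_lines Number of RILs.
#' @param n_intercross_generations Intercross generations (default 10).
#' @param n_selfing_generations Selfing generations before direct fixation.
#' @param distortion `NULL`, or `list(chrom, pos_cM, favored, freq)` giving
#'   the focal position, the favored parental allele (`"A"`/`"B"`) and its
#'   target retention frequency in (0, 1).
#' @param missing_rate Fraction of calls masked to `NA` at random.
#' @param seed Integer seed.
#' @return A `ril_genotypes` list: `calls` (lines x markers character matrix,
#'   `"A"`/`"B"`/`NA`), `line_ids`, `cross_direction`.
#' @export
simulate_ril_genotypes <- function(map, n_lines,
                                   n_intercross_generations = 10,
                                   n_selfing_generations = 0,
                                   distortion = NULL,
                                   missing_rate = 0,
                                   seed = 1L) {
  if (n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  if (n_intercross_generations < 0 || n_selfing_generations < 0)
    stop("generation counts must be >= 0", call. = FALSE)
  if (!is.null(distortion)) {
    if (distortion$freq <= 0 || distortion$freq >= 1)
      stop("distortion frequency must lie strictly inside (0, 1)", call. = FALSE)
    if (!distortion$chrom %in% map$chrom)
      stop("distortion chromosome not in map", call. = FALSE)
  }
  set.seed(as.integer(seed))
  chroms <- unique(map$chrom)
  lens <- chrom_lengths(map)
  pos_by_chrom <- split(map$pos_cM, factor(map$chrom, levels = chroms))
  idx_by_chrom <- split(seq_len(nrow(map)), factor(map$chrom, levels = chroms))

  calls <- matrix(NA_character_, n_lines, nrow(map),
                  dimnames = list(sprintf("RIL%03d", seq_len(n_lines)),
                                  map$marker))
  for (i in seq_len(n_lines)) {
    for (attempt in seq_len(1000L)) {
      line_alleles <- rep(NA_integer_, nrow(map))
      focal_allele <- NA_integer_
      for (ci in seq_along(chroms)) {
        hap <- sim_line_chromosome(lens[[chroms[ci]]],
                                   n_intercross_generations,
                                   n_selfing_generations)
        line_alleles[idx_by_chrom[[ci]]] <- hap_allele_at(hap, pos_by_chrom[[ci]])
        if (!is.null(distortion) && chroms[ci] == distortion$chrom)
          focal_allele <- hap_allele_at(hap, distortion$pos_cM)
      }
      if (is.null(distortion)) break
      fav <- if (distortion$favored == "A") 1L else 2L
      p <- distortion$freq
      acc <- if (focal_allele == fav) min(1, p / (1 - p)) else min(1, (1 - p) / p)
      if (stats::runif(1) < acc) break
    }
    calls[i, ] <- c("A", "B")[line_alleles]
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < missing_rate, nrow(calls))
    # never blank out an entire line
    full_rows <- rowSums(!mask) == 0
    mask[full_rows, 1L] <- FALSE
    calls[mask] <- NA_character_
  }
  structure(list(
    calls = calls,
    line_ids = rownames(calls),
    cross_direction = rep_len(c("AxB", "BxA"), n_lines)
  ), class = "ril_genotypes")
}

#' Append mitochondrial pseudo-markers
#'
#' Adds two pseudo-markers on a synthetic linkage group `"mt"` (positions 0
#' and 1 cM, no recombination within the group) whose genotype is determined
#' solely by each line's reciprocal cross direction: the maternal parent
#' donates the mitochondrial genome, so AxB lines carry the A cytoplasm.
#'
#' @param genotypes A `ril_genotypes` object.
#' @param map The matching `genetic_map`.
#' @return `list(genotypes, map)` with the two extra columns/rows appended.
#' @export
add_mt_pseudomarkers <- function(genotypes, map) {
  mt_call <- ifelse(genotypes$cross_direction == "AxB", "A", "B")
  extra <- cbind(mt_1 = mt_call, mt_2 = mt_call)
  rownames(extra) <- genotypes$line_ids
  genotypes$calls <- cbind(genotypes$calls, extra)
  mt_map <- data.frame(marker = c("mt_1", "mt_2"), chrom = "mt",
                       pos_cM = c(0, 1), stringsAsFactors = FALSE)
  map2 <- rbind(as.data.frame(map), mt_map)
  class(map2) <- c("genetic_map", "data.frame")
  list(genotypes = genotypes, map = map2)
}

#' @export
print.ril_genotypes <- function(x, ...) {
  cat(sprintf("RIL genotypes: %d lines x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

# -- CSV I/O -----------------------------------------------------------------

#' Read/write genetic maps and genotype matrices as CSV
#'
#' Plain-text interchange: the map as `marker,chrom,pos_cM`; genotypes as a
#' lines x markers table of `A`/`B`/empty cells with the cross direction in a
#' `cross_direction` column. Lines starting with `#` are treated as comments
#' (the writers record the generator seed there when known).
#'
#' @param map,genotypes Objects to write.
#' @param path File path.
#' @param comment Optional character vector of comment lines (without `#`).
#' @name map_io
NULL

#' @rdname map_io
#' @export
write_genetic_map <- function(map, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(map), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname map_io
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "pos_cM") %in% names(map)))
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname map_io
#' @export
write_genotypes <- function(genotypes, path, comment = NULL) {
  df <- data.frame(line = genotypes$line_ids,
                   cross_direction = genotypes$cross_direction,
                   genotypes$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname map_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = "")
  calls <- as.matrix(df[, setdiff(names(df), c("line", "cross_direction")),
                        drop = FALSE])
  rownames(calls) <- df$line
  structure(list(calls = calls, line_ids = df$line,
                 cross_direction = df$cross_direction),
            class = "ril_genotypes")
}
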