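# Single-QTL genome scans, permutation thresholds, Bayes credible intervals
# and QTL heritability.
#
# For a single locus with intercept, the regression LOD has the closed form
# LOD = -(n/2) * log10(1 - r^2) with r the genotype-phenotype correlation,
# since RSS1 = RSS0 * (1 - r^2); the scans below exploit this to vectorize
# over grid positions (and over permutations).

LOD_RSS_FLOOR <- 1e-12  # caps LOD at (n/2)*12 when the alternative fits exactly

lod_vector <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sum(yc^2)
  if (sy == 0) return(rep(0, ncol(X)))
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.vector(crossprod(Xc, yc))
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * sy), 0)
  ratio <- 1 - r2
  if (any(ratio < LOD_RSS_FLOOR)) {
    warning("zero residual variance under the single-locus model; LOD capped")
    ratio <- pmax(ratio, LOD_RSS_FLOOR)
  }
  -(n / 2) * log10(ratio)
}

align_phenotype <- function(pheno, line_ids) {
  if (!is.null(names(pheno))) {
    if (!all(line_ids %in% names(pheno)))
      stop("phenotype names do not cover the genotyped lines", call. = FALSE)
    pheno <- pheno[line_ids]
  } else if (length(pheno) != length(line_ids)) {
    stop("phenotype length does not match number of lines", call. = FALSE)
  }
  as.numeric(pheno)
}

#' Single-QTL genome scan (Haley-Knott or multiple imputation)
#'
#' At every grid position, compares the single-locus regression to the
#' null (mean-only) model: `LOD = (n/2) * log10(RSS0 / RSS1)`. Haley-Knott
#' regresses the phenotype on the expected genotype (P(B) from the HMM);
#' the imputation method computes a marker-regression LOD within each
#' imputed genotype set and combines them on the `10^LOD` scale
#' (`log10` of the mean of `10^LOD`). Mitochondrial pseudo-markers are
#' scanned like any other position.
#'
#' @param pheno Numeric phenotype per line (named by line id, or in line
#'   order). Lines with missing phenotype are dropped.
#' @param geno_prob A `geno_prob` (required for `method = "hk"`).
#' @param method `"hk"` or `"imp"`.
#' @param imputations A `geno_imputations` (required for `method = "imp"`).
#' @return A `lod_profile` data.frame: `chrom`, `pos_cM`, `marker`,
#'   `is_marker`, `lod`.
#' @export
scanone <- function(pheno, geno_prob = NULL, method = c("hk", "imp"),
                    imputations = NULL) {
  method <- match.arg(method)
  src <- if (method == "hk") geno_prob else imputations
  if (is.null(src))
    stop(sprintf("method '%s' needs its genotype input", method), call. = FALSE)
  y <- align_phenotype(pheno, src$line_ids)
  keep <- is.finite(y)
  if (sum(keep) < 10)
    stop("need a finite phenotype for at least 10 lines", call. = FALSE)
  y <- y[keep]
  if (method == "hk") {
    X <- geno_prob$prob[keep, , 2, drop = TRUE]
    lod <- lod_vector(X, y)
    grid <- geno_prob$grid
  } else {
    dr <- imputations$draws[keep, , , drop = FALSE]
    acc <- 0
    for (k in seq_len(dim(dr)[3])) {
      acc <- acc + 10^lod_vector(dr[, , k, drop = TRUE], y)
    }
    lod <- log10(acc / dim(dr)[3])
    grid <- imputations$grid
  }
  out <- cbind(grid, lod = lod)
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Summarize the peak of a LOD profile
#'
#' @param profile A `lod_profile`.
#' @param chrom Optional chromosome to restrict to.
#' @return One-row data.frame `chrom`, `pos_cM`, `marker`, `lod` (ties at
#'   the peak broken by smallest cM position).
#' @export
peak_lod <- function(profile, chrom = NULL) {
  if (!is.null(chrom)) profile <- profile[profile$chrom == chrom, ,
                                          drop = FALSE]
  i <- which.max(profile$lod)  # first max = smallest position within chrom
  profile[i, c("chrom", "pos_cM", "marker", "lod")]
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the phenotype across lines (genotypes fixed), rescans, and takes
#' the empirical `1 - alpha` quantile of the genome-wide maximum LOD. The
#' default `alpha = 0.05 / 12` applies a Bonferroni correction for mapping
#' twelve phenotypes at a family-wise 5% level. One seed governs the whole
#' permutation set.
#'
#' @param pheno,geno_prob As in [scanone()] (Haley-Knott scans are used for
#'   the permutations).
#' @param n_perm Number of permutations (>= 100; default 2500).
#' @param alpha Genome-wide significance level (default 0.05/12).
#' @param seed Integer seed.
#' @return `list(threshold, alpha, n_perm, null_max)` where `null_max` is
#'   the vector of permutation maxima.
#' @export
permutation_threshold <- function(pheno, geno_prob, n_perm = 2500,
                                  alpha = 0.05 / 12, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  y <- align_phenotype(pheno, geno_prob$line_ids)
  keep <- is.finite(y)
  y <- y[keep]
  n <- length(y)
  X <- geno_prob$prob[keep, , 2, drop = TRUE]
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  set.seed(as.integer(seed))
  P <- replicate(n_perm, sample.int(n))
  Y <- matrix(y[P], n, n_perm)
  Yc <- sweep(Y, 2, colMeans(Y))
  sy <- colSums(Yc^2)
  num <- crossprod(Xc, Yc)^2                      # m x n_perm
  r2 <- sweep(num, 1, pmax(sxx, .Machine$double.eps), `/`)
  r2 <- sweep(r2, 2, pmax(sy, .Machine$double.eps), `/`)
  r2[sxx == 0, ] <- 0
  lod <- -(n / 2) * log10(pmax(1 - r2, LOD_RSS_FLOOR))
  null_max <- apply(lod, 2, max)
  list(threshold = unname(stats::quantile(null_max, 1 - alpha)),
       alpha = alpha, n_perm = n_perm, null_max = null_max)
}

#' 95% Bayes credible interval for a LOD peak
#'
#' Normalizes `10^LOD` over the chromosome's grid with trapezoid weights and
#' returns the narrowest contiguous interval containing the peak whose
#' posterior mass reaches `coverage` (exhaustive search over contiguous
#' windows), expanded outward to the nearest typed markers.
#'
#' @param profile A `lod_profile`.
#' @param chrom Chromosome to summarize.
#' @param coverage Posterior mass required (default 0.95).
#' @param expand_to_markers Expand the interval ends outward to typed
#'   markers (default TRUE).
#' @return `list(chrom, lo, hi, peak_pos, peak_lod, mass)` (closed interval
#'   in cM).
#' @export
bayes_interval <- function(profile, chrom, coverage = 0.95,
                           expand_to_markers = TRUE) {
  sub <- profile[profile$chrom == chrom, , drop = FALSE]
  if (!nrow(sub)) stop("chromosome not present in profile", call. = FALSE)
  sub <- sub[order(sub$pos_cM), , drop = FALSE]
  m <- nrow(sub)
  pos <- sub$pos_cM
  peak <- which.max(sub$lod)
  if (diff(range(sub$lod)) < 1e-9) {
    warning("flat LOD profile; returning the whole chromosome")
    return(list(chrom = chrom, lo = pos[1], hi = pos[m],
                peak_pos = pos[peak], peak_lod = sub$lod[peak], mass = 1))
  }
  w <- 10^(sub$lod - max(sub$lod))
  tz <- if (m == 1) 1 else {
    gaps <- diff(pos)
    c(gaps[1] / 2, (gaps[-1] + gaps[-length(gaps)]) / 2,
      gaps[length(gaps)] / 2)
  }
  # guard repeated positions: trapezoid weight 0 would erase a spike
  tz[tz == 0] <- min(tz[tz > 0], 1)
  if (all(tz == 0)) tz <- rep(1, m)
  mass <- w * tz
  mass <- mass / sum(mass)
  cum <- c(0, cumsum(mass))
  best <- NULL
  for (i in seq_len(peak)) {
    # smallest j >= peak with mass(i..j) >= coverage
    target <- coverage + cum[i]
    j <- findInterval(target, cum, left.open = TRUE)
    if (j > m) next
    j <- max(j, peak)
    span <- pos[j] - pos[i]
    got <- cum[j + 1] - cum[i]
    if (got + 1e-12 < coverage) next
    if (is.null(best) || span < best$span) {
      best <- list(i = i, j = j, span = span, mass = got)
    }
  }
  if (is.null(best)) best <- list(i = 1, j = m, mass = 1)
  lo <- pos[best$i]
  hi <- pos[best$j]
  if (expand_to_markers) {
    mk <- pos[sub$is_marker]
    if (any(mk <= lo)) lo <- max(mk[mk <= lo])
    if (any(mk >= hi)) hi <- min(mk[mk >= hi])
  }
  list(chrom = chrom, lo = lo, hi = hi, peak_pos = pos[peak],
       peak_lod = sub$lod[peak], mass = best$mass)
}

#' QTL broad-sense heritability from a LOD score
#'
#' `H^2 = 1 - 10^(-2 * LOD / n)` with `n` the number of lines; identical to
#' `1 - RSS1 / RSS0` of the underlying regression by construction of the
#' LOD.
#'
#' @param lod LOD score (>= 0).
#' @param n Number of lines (>= 1).
#' @export
heritability_from_lod <- function(lod, n) {
  if (any(lod < 0)) stop("lod must be >= 0", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  1 - 10^(-2 * lod / n)
}

#' Phenotype means by parental allele at the peak marker
#'
#' @param pheno Phenotype per line.
#' @param genotypes A `ril_genotypes`.
#' @param marker Marker id.
#' @return Data.frame with `allele`, `n`, `mean`, `se`.
#' @export
allele_means <- function(pheno, genotypes, marker) {
  y <- align_phenotype(pheno, genotypes$line_ids)
  g <- genotypes$calls[, marker]
  keep <- is.finite(y) & !is.na(g)
  out <- do.call(rbind, lapply(c("A", "B"), function(a) {
    v <- y[keep & g == a]
    data.frame(allele = a, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Conditional single-QTL scan with a fixed locus as covariate
#'
#' Rescans the genome with the genotype probability at `fixed_pos` included
#' in both null and alternative models, to ask whether a second peak remains
#' after accounting for a known QTL. Positions collinear with the fixed
#' locus give LOD ~ 0.
#'
#' @param pheno,geno_prob As in [scanone()].
#' @param fixed_chrom,fixed_pos Location of the conditioning locus (nearest
#'   grid position is used).
#' @return A `lod_profile`.
#' @export
conditional_scan <- function(pheno, geno_prob, fixed_chrom, fixed_pos) {
  y <- align_phenotype(pheno, geno_prob$line_ids)
  keep <- is.finite(y)
  y <- y[keep]
  grid <- geno_prob$grid
  on_ch <- which(grid$chrom == fixed_chrom)
  if (!length(on_ch)) stop("fixed chromosome not on grid", call. = FALSE)
  jfix <- on_ch[which.min(abs(grid$pos_cM[on_ch] - fixed_pos))]
  X <- geno_prob$prob[keep, , 2, drop = TRUE]
  qrc <- qr(cbind(1, X[, jfix]))
  ry <- qr.resid(qrc, y)
  RX <- qr.resid(qrc, X)
  n <- length(y)
  sy <- sum(ry^2)
  sxx <- colSums(RX^2)
  sxy <- as.vector(crossprod(RX, ry))
  r2 <- ifelse(sxx > 1e-12 & sy > 0, sxy^2 / (sxx * sy), 0)
  lod <- -(n / 2) * log10(pmax(1 - r2, LOD_RSS_FLOOR))
  out <- cbind(grid, lod = lod)
  class(out) <- c("lod_profile", "data.frame")
  out
}
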