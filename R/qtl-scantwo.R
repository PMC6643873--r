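# Two-dimensional QTL scans by Haley-Knott regression: full (two loci plus
# interaction), additive (two loci), and null models at every admissible
# position pair, with lod_int = lod_full - lod_add.

rss_fit <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  sum(f$residuals^2)
}

#' Two-dimensional QTL scan
#'
#' For every pair of scan positions (thinned to a minimum separation within
#' chromosomes), regresses the phenotype on the two expected genotypes with
#' and without their interaction. Reports `lod_full` (two loci +
#' interaction vs. null), `lod_add` (two additive loci vs. null) and
#' `lod_int = lod_full - lod_add` (the epistasis LOD).
#'
#' @param pheno Phenotype per line, as in [scanone()].
#' @param geno_prob A `geno_prob`.
#' @param min_separation Minimum cM between scanned positions on the same
#'   chromosome (default 5); positions are thinned greedily to satisfy it.
#' @param markers_only Restrict scan positions to typed markers (default
#'   TRUE).
#' @return A `scantwo_result`: `positions` (the thinned grid rows),
#'   `lod_full`, `lod_add`, `lod_int` (symmetric matrices, `NA` diagonal
#'   and inadmissible pairs), `n`.
#' @export
scantwo <- function(pheno, geno_prob, min_separation = 5,
                    markers_only = TRUE) {
  y <- align_phenotype(pheno, geno_prob$line_ids)
  keep <- is.finite(y)
  y <- y[keep]
  n <- length(y)
  grid <- geno_prob$grid
  cand <- if (markers_only) which(grid$is_marker) else seq_len(nrow(grid))
  sel <- integer(0)
  for (ch in unique(grid$chrom)) {
    idx <- cand[grid$chrom[cand] == ch]
    last <- -Inf
    for (j in idx) {
      if (grid$pos_cM[j] - last >= min_separation) {
        sel <- c(sel, j)
        last <- grid$pos_cM[j]
      }
    }
  }
  positions <- grid[sel, , drop = FALSE]
  X <- geno_prob$prob[keep, sel, 2, drop = FALSE][, , 1]
  p <- length(sel)
  rss0 <- sum((y - mean(y))^2)
  lod_full <- matrix(NA_real_, p, p)
  lod_add <- matrix(NA_real_, p, p)
  ones <- rep(1, n)
  for (i in seq_len(p - 1L)) {
    xi <- X[, i]
    for (j in (i + 1L):p) {
      xj <- X[, j]
      Xa <- cbind(ones, xi, xj)
      ra <- stats::.lm.fit(Xa, y)
      if (ra$rank < 3) next  # singular design at this pair
      rss_a <- sum(ra$residuals^2)
      rf <- stats::.lm.fit(cbind(Xa, xi * xj), y)
      rss_f <- sum(rf$residuals^2)
      la <- (n / 2) * log10(rss0 / max(rss_a, LOD_RSS_FLOOR * rss0))
      lf <- (n / 2) * log10(rss0 / max(rss_f, LOD_RSS_FLOOR * rss0))
      lod_add[i, j] <- lod_add[j, i] <- la
      lod_full[i, j] <- lod_full[j, i] <- lf
    }
  }
  structure(list(positions = positions, lod_full = lod_full,
                 lod_add = lod_add, lod_int = lod_full - lod_add, n = n),
            class = "scantwo_result")
}

#' @export
print.scantwo_result <- function(x, ...) {
  cat(sprintf("scantwo: %d positions, n = %d lines\n", nrow(x$positions), x$n))
  cat(sprintf("max lod_full %.2f, max lod_add %.2f, max lod_int %.2f\n",
              max(x$lod_full, na.rm = TRUE), max(x$lod_add, na.rm = TRUE),
              max(x$lod_int, na.rm = TRUE)))
  invisible(x)
}

#' Permutation thresholds for the two-dimensional scan
#'
#' Permutes the phenotype and records, per permutation, the maxima of
#' `lod_full`, `lod_add` and `lod_int` over all scanned pairs; thresholds
#' are the empirical `1 - alpha` quantiles.
#'
#' @inheritParams scantwo
#' @param n_perm Number of permutations.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return `list(thresholds, alpha, n_perm, null_max)`; `thresholds` has
#'   elements `full`, `add`, `int`.
#' @export
scantwo_permutations <- function(pheno, geno_prob, min_separation = 5,
                                 markers_only = TRUE, n_perm = 200,
                                 alpha = 0.05, seed = 1L) {
  y <- align_phenotype(pheno, geno_prob$line_ids)
  y <- y[is.finite(y)]
  set.seed(as.integer(seed))
  null_max <- matrix(NA_real_, n_perm, 3,
                     dimnames = list(NULL, c("full", "add", "int")))
  for (k in seq_len(n_perm)) {
    st <- scantwo(sample(y), geno_prob, min_separation, markers_only)
    null_max[k, ] <- c(max(st$lod_full, na.rm = TRUE),
                       max(st$lod_add, na.rm = TRUE),
                       max(st$lod_int, na.rm = TRUE))
  }
  list(thresholds = apply(null_max, 2, stats::quantile, probs = 1 - alpha),
       alpha = alpha, n_perm = n_perm, null_max = null_max)
}

#' Long-format export of a scantwo result
#'
#' @param x A `scantwo_result`.
#' @return Data.frame `chrom1, pos1, chrom2, pos2, lod_full, lod_add,
#'   lod_int` over the upper triangle.
#' @export
scantwo_table <- function(x) {
  p <- nrow(x$positions)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(
    chrom1 = x$positions$chrom[idx[, 1]],
    pos1 = x$positions$pos_cM[idx[, 1]],
    chrom2 = x$positions$chrom[idx[, 2]],
    pos2 = x$positions$pos_cM[idx[, 2]],
    lod_full = x$lod_full[idx],
    lod_add = x$lod_add[idx],
    lod_int = x$lod_int[idx],
    stringsAsFactors = FALSE
  )
}
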