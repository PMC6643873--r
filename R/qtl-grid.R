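# Evaluation grid and hidden-Markov genotype probabilities for homozygous
# biallelic RIL panels.
#
# RILs are modeled as a two-state (AA / BB) Markov chain along each
# chromosome. The recombination fraction between positions d cM apart uses
# the Haldane map function on an expanded distance,
# r = 0.5 * (1 - exp(-2 * k * d / 100)), where k is the map-expansion factor
# of the breeding design (advanced-intercross RILs accumulate crossovers
# over many meioses, so k > 1). The mitochondrial linkage group "mt" never
# recombines internally.

haldane_r <- function(d_cM, expansion = 1) {
  0.5 * (1 - exp(-2 * expansion * d_cM / 100))
}

#' Build an evaluation grid of markers plus pseudomarkers
#'
#' All typed markers, with pseudomarkers inserted between adjacent markers
#' at (at most) `step` cM spacing. The `"mt"` linkage group, which has no
#' internal recombination, receives no pseudomarkers.
#'
#' @param map A `genetic_map`.
#' @param step Pseudomarker spacing in cM (default 0.5).
#' @return Data.frame `chrom`, `pos_cM`, `marker` (`NA` at pseudomarkers),
#'   `is_marker`, ordered by chromosome then position.
#' @export
build_grid <- function(map, step = 0.5) {
  if (step <= 0) stop("grid step must be positive", call. = FALSE)
  pieces <- lapply(split(as.data.frame(map), factor(map$chrom,
                                                    unique(map$chrom))),
                   function(sub) {
    sub <- sub[order(sub$pos_cM), , drop = FALSE]
    pos <- sub$pos_cM
    out <- data.frame(chrom = sub$chrom, pos_cM = pos, marker = sub$marker,
                      is_marker = TRUE, stringsAsFactors = FALSE)
    if (nrow(sub) > 1 && sub$chrom[1] != "mt") {
      fills <- lapply(seq_len(nrow(sub) - 1L), function(i) {
        gap <- pos[i + 1L] - pos[i]
        if (gap <= step) return(NULL)
        k <- ceiling(gap / step) - 1L
        data.frame(chrom = sub$chrom[1],
                   pos_cM = pos[i] + gap * seq_len(k) / (k + 1L),
                   marker = NA_character_, is_marker = FALSE,
                   stringsAsFactors = FALSE)
      })
      out <- rbind(out, do.call(rbind, fills))
    }
    out[order(out$pos_cM), , drop = FALSE]
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  grid
}

# emission probabilities for one chromosome: list of two n x m matrices
# (P(obs | AA), P(obs | BB)); 1 where untyped or missing.
emission_mats <- function(calls, grid_sub, error_rate) {
  n <- nrow(calls)
  m <- nrow(grid_sub)
  eA <- matrix(1, n, m)
  eB <- matrix(1, n, m)
  typed <- which(grid_sub$is_marker)
  for (j in typed) {
    obs <- calls[, grid_sub$marker[j]]
    known <- !is.na(obs)
    eA[known, j] <- ifelse(obs[known] == "A", 1 - error_rate, error_rate)
    eB[known, j] <- ifelse(obs[known] == "B", 1 - error_rate, error_rate)
  }
  list(A = eA, B = eB)
}

#' Hidden-Markov genotype probabilities on the evaluation grid
#'
#' Forward-backward conditional probabilities of the two homozygous parental
#' genotypes at every grid position, given all typed markers on the
#' chromosome, under the two-state RIL model. At a typed, non-missing marker
#' the posterior equals 1/0 up to `error_rate`; at the midpoint between
#' informative flanking markers of opposite genotype it is 1/2 by symmetry.
#'
#' @param genotypes A `ril_genotypes`.
#' @param map The matching `genetic_map`.
#' @param grid Result of [build_grid()] (built from `map` if `NULL`).
#' @param error_rate Genotyping error probability (default 1e-4).
#' @param map_expansion Map-expansion factor of the breeding design applied
#'   to inter-position distances (default 3, calibrated to the package's
#'   default simulated advanced-intercross design).
#' @return A `geno_prob` object: `grid`, `prob` (array lines x positions x
#'   2, `[ , , "A"]` and `[ , , "B"]`), plus the call arguments.
#' @export
genotype_probabilities <- function(genotypes, map, grid = NULL,
                                   error_rate = 1e-4, map_expansion = 3) {
  if (is.null(grid)) grid <- build_grid(map)
  if (!all(grid$marker[grid$is_marker] %in% colnames(genotypes$calls)))
    stop("grid markers missing from genotype matrix", call. = FALSE)
  n <- nrow(genotypes$calls)
  m <- nrow(grid)
  prob <- array(NA_real_, c(n, m, 2),
                dimnames = list(genotypes$line_ids, NULL, c("A", "B")))
  for (ch in unique(grid$chrom)) {
    sel <- which(grid$chrom == ch)
    gsub <- grid[sel, , drop = FALSE]
    mm <- nrow(gsub)
    e <- emission_mats(genotypes$calls, gsub, error_rate)
    d <- diff(gsub$pos_cM)
    r <- if (ch == "mt") rep(0, max(0, mm - 1)) else haldane_r(d, map_expansion)
    # forward
    f <- vector("list", mm)
    f[[1]] <- cbind(0.5 * e$A[, 1], 0.5 * e$B[, 1])
    f[[1]] <- f[[1]] / rowSums(f[[1]])
    for (t in seq_len(mm - 1L)) {
      fa <- f[[t]][, 1] * (1 - r[t]) + f[[t]][, 2] * r[t]
      fb <- f[[t]][, 1] * r[t] + f[[t]][, 2] * (1 - r[t])
      nxt <- cbind(fa * e$A[, t + 1L], fb * e$B[, t + 1L])
      f[[t + 1L]] <- nxt / rowSums(nxt)
    }
    # backward
    b <- matrix(1, n, 2)
    post <- f[[mm]] * b
    prob[, sel[mm], ] <- post / rowSums(post)
    for (t in rev(seq_len(mm - 1L))) {
      ba <- (1 - r[t]) * e$A[, t + 1L] * b[, 1] + r[t] * e$B[, t + 1L] * b[, 2]
      bb <- r[t] * e$A[, t + 1L] * b[, 1] + (1 - r[t]) * e$B[, t + 1L] * b[, 2]
      b <- cbind(ba, bb)
      b <- b / rowSums(b)
      post <- f[[t]] * b
      prob[, sel[t], ] <- post / rowSums(post)
    }
  }
  structure(list(grid = grid, prob = prob, error_rate = error_rate,
                 map_expansion = map_expansion,
                 line_ids = genotypes$line_ids),
            class = "geno_prob")
}

#' Multiple imputation of complete grid genotypes
#'
#' Samples complete genotype paths per line from the conditional
#' distribution given the typed markers (forward-filter, backward-sample),
#' the standard fill-in for multiple-imputation interval mapping. Marginal
#' allele frequencies across imputations converge to
#' [genotype_probabilities()].
#'
#' @param genotypes,map,grid,error_rate,map_expansion As in
#'   [genotype_probabilities()].
#' @param n_imputations Number of sampled genotype sets (default 128).
#' @param seed Integer seed; the imputation set is deterministic given it.
#' @return A `geno_imputations` object: `grid`, `draws` (integer array lines
#'   x positions x imputations; 0 = A, 1 = B).
#' @export
impute_genotypes <- function(genotypes, map, grid = NULL,
                             n_imputations = 128, error_rate = 1e-4,
                             map_expansion = 3, seed = 1L) {
  if (is.null(grid)) grid <- build_grid(map)
  set.seed(as.integer(seed))
  n <- nrow(genotypes$calls)
  m <- nrow(grid)
  draws <- array(NA_integer_, c(n, m, n_imputations),
                 dimnames = list(genotypes$line_ids, NULL, NULL))
  for (ch in unique(grid$chrom)) {
    sel <- which(grid$chrom == ch)
    gsub <- grid[sel, , drop = FALSE]
    mm <- nrow(gsub)
    e <- emission_mats(genotypes$calls, gsub, error_rate)
    d <- diff(gsub$pos_cM)
    r <- if (ch == "mt") rep(0, max(0, mm - 1)) else haldane_r(d, map_expansion)
    f <- vector("list", mm)
    f[[1]] <- cbind(0.5 * e$A[, 1], 0.5 * e$B[, 1])
    f[[1]] <- f[[1]] / rowSums(f[[1]])
    for (t in seq_len(mm - 1L)) {
      fa <- f[[t]][, 1] * (1 - r[t]) + f[[t]][, 2] * r[t]
      fb <- f[[t]][, 1] * r[t] + f[[t]][, 2] * (1 - r[t])
      nxt <- cbind(fa * e$A[, t + 1L], fb * e$B[, t + 1L])
      f[[t + 1L]] <- nxt / rowSums(nxt)
    }
    for (k in seq_len(n_imputations)) {
      path <- matrix(NA_integer_, n, mm)
      path[, mm] <- as.integer(stats::runif(n) < f[[mm]][, 2])
      for (t in rev(seq_len(mm - 1L))) {
        # P(state_t = B | state_{t+1}) ∝ f_t(B) * T(B -> s_{t+1})
        nxt_is_b <- path[, t + 1L] == 1L
        t_a <- ifelse(nxt_is_b, r[t], 1 - r[t])
        t_b <- ifelse(nxt_is_b, 1 - r[t], r[t])
        pa <- f[[t]][, 1] * t_a
        pb <- f[[t]][, 2] * t_b
        path[, t] <- as.integer(stats::runif(n) < pb / (pa + pb))
      }
      draws[, sel, k] <- path
    }
  }
  structure(list(grid = grid, draws = draws, error_rate = error_rate,
                 map_expansion = map_expansion,
                 line_ids = genotypes$line_ids),
            class = "geno_imputations")
}
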