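# Genotype probabilities, imputation, single-QTL scans, permutation
# thresholds, Bayes intervals and heritability.

test_that("grid contains every typed marker once plus evenly spaced fill", {
  m <- tiny_map(20)
  grid <- build_grid(m, step = 0.5)
  expect_equal(sum(grid$is_marker), 2)
  expect_equal(grid$pos_cM[grid$is_marker], c(0, 20))
  gaps <- diff(grid$pos_cM)
  expect_true(all(gaps <= 0.5 + 1e-9))
  expect_error(build_grid(m, step = 0), "positive")
})

test_that("HMM posteriors match typed calls, symmetry, and the closed form", {
  m <- tiny_map(20)
  g <- tiny_geno()
  gp <- genotype_probabilities(g, m, error_rate = 0)
  grid <- gp$grid
  expect_equal(unname(gp$prob[1, 1, ]), c(1, 0))          # typed call A
  mid <- which.min(abs(grid$pos_cM - 10))
  expect_equal(unname(gp$prob[1, mid, ]), c(0.5, 0.5))    # midpoint symmetry
  # closed-form two-marker conditional with expanded Haldane fractions
  k <- gp$map_expansion
  for (j in which(!grid$is_marker)) {
    x <- grid$pos_cM[j]
    r1 <- 0.5 * (1 - exp(-2 * k * x / 100))
    r2 <- 0.5 * (1 - exp(-2 * k * (20 - x) / 100))
    pa <- (1 - r1) * r2 / ((1 - r1) * r2 + r1 * (1 - r2))
    expect_equal(gp$prob[1, j, "A"], pa, tolerance = 1e-12)
  }
  # probabilities always sum to one
  expect_true(all(abs(rowSums(gp$prob[1, , ]) - 1) < 1e-12))
})

test_that("missing calls are bridged by flanking information", {
  m <- data.frame(marker = c("a", "b", "c"), chrom = "chr1",
                  pos_cM = c(0, 10, 20), stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  g <- tiny_geno(c("A", NA, "A"), c("a", "b", "c"))
  gp <- genotype_probabilities(g, m, error_rate = 0)
  jb <- which(gp$grid$is_marker)[2]
  expect_gt(gp$prob[1, jb, "A"], 0.9)  # both flanks A
})

test_that("imputations agree with the marginal posterior and are reproducible", {
  m <- tiny_map(20)
  g <- tiny_geno()
  imp <- impute_genotypes(g, m, n_imputations = 128, error_rate = 0, seed = 7)
  grid <- imp$grid
  expect_true(all(imp$draws[1, 1, ] == 0))            # typed A in all draws
  expect_true(all(imp$draws[1, nrow(grid), ] == 1))   # typed B in all draws
  mid <- which.min(abs(grid$pos_cM - 10))
  frac_a <- mean(imp$draws[1, mid, ] == 0)
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 128))  # binomial oracle
  imp2 <- impute_genotypes(g, m, n_imputations = 128, error_rate = 0, seed = 7)
  expect_identical(imp$draws, imp2$draws)
})

test_that("scanone matches the brute-force marker regression oracle", {
  set.seed(50)
  x5 <- as.numeric(panel_geno$calls[, 5] == "B")
  y <- x5 + rnorm(120)
  prof <- scanone(y, panel_gp)
  j <- which(panel_gp$grid$is_marker)[5]
  expect_equal(prof$lod[j], lod_marker_oracle(y, x5), tolerance = 1e-8)
  # imputation-based scan agrees at fully typed markers too
  imp <- impute_genotypes(panel_geno, panel_map,
                          build_grid(panel_map, step = 1),
                          n_imputations = 32, error_rate = 0, seed = 51)
  prof_imp <- scanone(y, method = "imp", imputations = imp)
  expect_equal(prof_imp$lod[j], lod_marker_oracle(y, x5), tolerance = 1e-8)
  # constant phenotype: LOD identically zero
  expect_true(all(scanone(rep(1, 120), panel_gp)$lod == 0))
})

test_that("LOD is invariant to affine transformation of the phenotype", {
  set.seed(52)
  y <- as.numeric(panel_geno$calls[, 3] == "B") + rnorm(120)
  p1 <- scanone(y, panel_gp)
  p2 <- scanone(3.7 * y - 11, panel_gp)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
})

test_that("permutation thresholds honor quantile and monotonicity contracts", {
  set.seed(53)
  y <- rnorm(120)
  pt1 <- permutation_threshold(y, panel_gp, n_perm = 200, alpha = 1, seed = 3)
  expect_equal(pt1$threshold, min(pt1$null_max))
  pt2 <- permutation_threshold(y, panel_gp, n_perm = 200, alpha = 0.2, seed = 3)
  pt3 <- permutation_threshold(y, panel_gp, n_perm = 200, alpha = 0.05, seed = 3)
  expect_lte(pt2$threshold, pt3$threshold)
  # same seed, same permutations; permuted input, same threshold distribution
  pt4 <- permutation_threshold(y, panel_gp, n_perm = 200, alpha = 0.05, seed = 3)
  expect_equal(pt3$threshold, pt4$threshold)
  # exchangeability: a permuted phenotype has the same null max-LOD law, so
  # thresholds agree up to finite-sample Monte Carlo noise
  pt3b <- permutation_threshold(y, panel_gp, n_perm = 500, alpha = 0.05,
                                seed = 3)
  set.seed(54)
  pt5 <- permutation_threshold(sample(y), panel_gp, n_perm = 500,
                               alpha = 0.05, seed = 3)
  expect_equal(pt5$threshold, pt3b$threshold, tolerance = 0.15)
  expect_error(permutation_threshold(y, panel_gp, n_perm = 50), ">= 100")
})

test_that("Bayes interval matches the exhaustive minimal-window oracle", {
  grid <- panel_gp$grid
  sub <- grid[grid$chrom == "chr1", ]
  # single spike at a typed marker
  lodv <- rep(0, nrow(grid))
  jm <- which(grid$is_marker & grid$chrom == "chr1")[4]
  lodv[jm] <- 10
  prof <- cbind(grid, lod = lodv)
  class(prof) <- c("lod_profile", "data.frame")
  ci <- bayes_interval(prof, "chr1")
  expect_equal(ci$lo, grid$pos_cM[jm])
  expect_equal(ci$hi, grid$pos_cM[jm])
  # flat profile: whole chromosome with a warning
  prof$lod <- 1
  expect_warning(cif <- bayes_interval(prof, "chr1"), "flat")
  expect_equal(c(cif$lo, cif$hi), range(sub$pos_cM))
  # two-bump profile vs exhaustive search over contiguous peak-containing windows
  pos <- sub$pos_cM
  lod2 <- 3 * exp(-(pos - 15)^2 / 40) + 2.2 * exp(-(pos - 45)^2 / 30)
  prof2 <- cbind(grid, lod = 0)
  prof2$lod[grid$chrom == "chr1"] <- lod2
  class(prof2) <- c("lod_profile", "data.frame")
  ci2 <- bayes_interval(prof2, "chr1", expand_to_markers = FALSE)
  w <- 10^(lod2 - max(lod2))
  gaps <- diff(pos)
  tz <- c(gaps[1] / 2, (gaps[-1] + gaps[-length(gaps)]) / 2,
          gaps[length(gaps)] / 2)
  mass <- w * tz / sum(w * tz)
  peak <- which.max(lod2)
  best <- NULL
  for (i in seq_len(peak)) for (j in peak:length(pos)) {
    if (sum(mass[i:j]) >= 0.95) {
      span <- pos[j] - pos[i]
      if (is.null(best) || span < best$span)
        best <- list(lo = pos[i], hi = pos[j], span = span)
      break
    }
  }
  expect_equal(ci2$lo, best$lo)
  expect_equal(ci2$hi, best$hi)
  expect_true(ci2$lo <= ci2$peak_pos && ci2$peak_pos <= ci2$hi)
})

test_that("heritability formula obeys endpoints and the RSS identity", {
  expect_equal(heritability_from_lod(0, 153), 0)
  expect_equal(heritability_from_lod(10.73, 153), 1 - 10^(-2 * 10.73 / 153))
  expect_equal(heritability_from_lod(10.73, 153), 0.276, tolerance = 0.002)
  expect_gt(heritability_from_lod(1e6, 153), 1 - 1e-12)
  expect_error(heritability_from_lod(-1, 153), ">= 0")
  # identity: 1 - 10^(-2 LOD / n) == 1 - RSS1/RSS0 for the same regression
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(resid(lm(y ~ x))^2)
    lod <- (n / 2) * log10(rss0 / rss1)
    expect_equal(heritability_from_lod(lod, n), 1 - rss1 / rss0,
                 tolerance = 1e-12)
  }
})

test_that("allele means at the peak marker separate carrier classes", {
  set.seed(56)
  x <- as.numeric(panel_geno$calls[, 7] == "B")
  y <- stats::setNames(2 * x + rnorm(120, 0, 0.5), panel_geno$line_ids)
  am <- allele_means(y, panel_geno, colnames(panel_geno$calls)[7])
  expect_equal(am$allele, c("A", "B"))
  expect_equal(am$mean[2] - am$mean[1], 2, tolerance = 0.3)
  expect_true(all(am$se > 0))
})

test_that("conditional scan removes a true QTL and spares unlinked signal", {
  set.seed(57)
  grid <- panel_gp$grid
  x <- as.numeric(panel_geno$calls[, 5] == "B")  # chr1 QTL
  y <- 1.5 * x + rnorm(120, 0, 1)
  uncond <- scanone(y, panel_gp)
  pk <- peak_lod(uncond)
  cond <- conditional_scan(y, panel_gp, pk$chrom, pk$pos_cM)
  thr <- permutation_threshold(y, panel_gp, n_perm = 200, alpha = 0.05,
                               seed = 58)$threshold
  # residual profile flat on the QTL chromosome
  expect_lt(max(cond$lod[grid$chrom == pk$chrom]), thr)
  # conditioning on an unlinked locus leaves the scan essentially unchanged
  other <- grid$pos_cM[grid$chrom == "chr3"][3]
  cond2 <- conditional_scan(y, panel_gp, "chr3", other)
  on1 <- grid$chrom == "chr1"
  expect_equal(max(cond2$lod[on1]), max(uncond$lod[on1]), tolerance = 0.35)
  # conditioning position equals tested position: LOD ~ 0 there
  jfix <- which(grid$chrom == pk$chrom & abs(grid$pos_cM - pk$pos_cM) < 1e-9)
  expect_lt(cond$lod[jfix], 1e-6)
})

test_that("null phenotypes stay below the genome-wide threshold at rate alpha", {
  # null calibration at reduced scale: per-replicate 200-perm thresholds
  set.seed(59)
  hits <- vapply(1:60, function(i) {
    y <- rnorm(120)
    thr <- permutation_threshold(y, panel_gp, n_perm = 200, alpha = 0.05,
                                 seed = 600 + i)$threshold
    max(scanone(y, panel_gp)$lod) > thr
  }, logical(1))
  fpr <- mean(hits)
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / 60) + 0.01)
})
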