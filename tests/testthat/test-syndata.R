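# Synthetic map, RIL genotype and phenotype generators.

test_that("simulate_map places sorted markers inside bounds, deterministically", {
  m <- simulate_map(1, 100, 2, seed = 5)
  expect_equal(nrow(m), 2)
  expect_true(all(m$pos_cM >= 0 & m$pos_cM <= 100))
  expect_false(is.unsorted(m$pos_cM))
  expect_identical(m, simulate_map(1, 100, 2, seed = 5))

  big <- simulate_map(6, 50, 172, seed = 1)
  expect_equal(nrow(big), 1032)  # 6 x 172 emulates a ~1031-SNP panel
  expect_setequal(unique(big$chrom), c("I", "II", "III", "IV", "V", "X"))
  for (ch in unique(big$chrom))
    expect_false(is.unsorted(big$pos_cM[big$chrom == ch]))

  expect_error(simulate_map(1, -5, 10), "positive")
  expect_error(simulate_map(1, 100, 1), ">= 2")
})

test_that("coincident markers are perfectly correlated; genotypes homozygous mosaics", {
  m <- data.frame(marker = c("a", "b", "c"), chrom = "chr1",
                  pos_cM = c(10, 10, 40), stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  g <- simulate_ril_genotypes(m, 50, seed = 3)
  expect_identical(g$calls[, "a"], g$calls[, "b"])  # zero recombination
  expect_true(all(g$calls %in% c("A", "B")))
  expect_identical(g, simulate_ril_genotypes(m, 50, seed = 3))
  expect_equal(g$cross_direction, rep_len(c("AxB", "BxA"), 50))
})

test_that("allele frequencies are Mendelian without distortion", {
  m <- simulate_map(2, 50, 6, seed = 21)
  g <- simulate_ril_genotypes(m, 1000, seed = 22)
  freq_a <- colMeans(g$calls == "A")
  se <- sqrt(0.25 / 1000)  # lines are i.i.d., so each marker is Binomial(n, 1/2)
  expect_true(all(abs(freq_a - 0.5) < 3 * se))
  expect_lt(abs(mean(freq_a) - 0.5), 3 * se)
})

test_that("markers on different chromosomes are unlinked", {
  m <- simulate_map(2, 50, 2, seed = 31)
  g <- simulate_ril_genotypes(m, 1000, seed = 32)
  x1 <- as.numeric(g$calls[, 1] == "B")
  x2 <- as.numeric(g$calls[, 3] == "B")  # other chromosome
  r2 <- stats::cor(x1, x2)^2
  # permutation oracle for the null scale of r^2 at n = 1000
  set.seed(33)
  null_r2 <- replicate(200, stats::cor(x1, sample(x2))^2)
  expect_lt(r2, stats::quantile(null_r2, 0.999) + 0.01)
})

test_that("transmission-ratio distortion biases the focal region and decays", {
  m <- simulate_map(1, 80, 9, seed = 41)
  g <- simulate_ril_genotypes(m, 600, seed = 42,
                              distortion = list(chrom = "chr1",
                                                pos_cM = m$pos_cM[5],
                                                favored = "B", freq = 0.75))
  freq_b <- colMeans(g$calls == "B")
  expect_gt(freq_b[5], 0.65)                   # focal marker biased
  edge <- c(freq_b[1], freq_b[9])
  expect_true(all(abs(edge - 0.5) < abs(freq_b[5] - 0.5)))  # linkage decay
  expect_error(
    simulate_ril_genotypes(m, 10, distortion = list(chrom = "chr1",
                                                    pos_cM = 10,
                                                    favored = "B", freq = 1.2)),
    "inside")
})

test_that("mitochondrial pseudo-markers follow cross direction on their own group", {
  m <- simulate_map(2, 50, 3, seed = 51)
  g <- simulate_ril_genotypes(m, 10, seed = 52)
  mt <- add_mt_pseudomarkers(g, m)
  expect_equal(mt$map$chrom[mt$map$marker %in% c("mt_1", "mt_2")], c("mt", "mt"))
  expect_equal(mt$map$pos_cM[mt$map$chrom == "mt"], c(0, 1))
  expected <- ifelse(g$cross_direction == "AxB", "A", "B")
  expect_equal(unname(mt$genotypes$calls[, "mt_1"]), expected)
  expect_identical(mt$genotypes$calls[, "mt_1"], mt$genotypes$calls[, "mt_2"])
})

test_that("zero-noise phenotypes reproduce the logistic curve exactly", {
  m <- simulate_map(1, 50, 3, seed = 61)
  g <- simulate_ril_genotypes(m, 4, seed = 62)
  ph <- simulate_tpc_phenotypes(g, m, qtl_spec(), temps = 25:41,
                                n_individuals = 3, floor_offset = 0,
                                seed = 63)
  expected <- logistic_tpc(25:41, 0.6, -0.9, 35)
  for (s in unique(ph$strain)) {
    for (w in unique(ph$individual[ph$strain == s])) {
      sub <- ph[ph$individual == w, ]
      expect_equal(sub$li1[order(sub$assay_temp)], expected, tolerance = 1e-12)
    }
  }
})

test_that("raw series floor matches the configured offset", {
  m <- simulate_map(1, 50, 3, seed = 71)
  g <- simulate_ril_genotypes(m, 20, seed = 72)
  ph <- simulate_tpc_phenotypes(g, m,
                                qtl_spec(sd_within = 0.01),
                                baseline = c(alpha = 0.5, beta = -0.9, tau = 33),
                                n_individuals = 10, floor_offset = 0.08,
                                seed = 73)
  per_worm_min <- tapply(ph$li1, ph$individual, min)
  expect_between(stats::median(per_worm_min), 0.06, 0.12)
})

test_that("a planted tau QTL shifts fitted tau by its effect size", {
  m <- simulate_map(2, 60, 6, seed = 81)
  g <- simulate_ril_genotypes(m, 150, seed = 82)
  spec <- qtl_spec(data.frame(chrom = "chr1", pos_cM = m$pos_cM[3],
                              param = "tau", effect = 1.5),
                   sd_line = c(alpha = 0.02, beta = 0.05, tau = 0.2),
                   sd_within = 0.05)
  ph <- simulate_tpc_phenotypes(g, m, spec, n_individuals = 30, seed = 83)
  ph <- normalize_assay(ph)
  fits <- fit_strains(ph, metric = "li1", half = "hot")
  summ <- attr(fits, "summary")
  carrier <- g$calls[summ$strain, 3] == "A"
  shift <- mean(summ$tau[carrier]) - mean(summ$tau[!carrier])
  expect_equal(shift, 1.5, tolerance = 0.15)
})

test_that("mask pairs have exact overlap by construction", {
  p1 <- simulate_mask_pair(100, 1, seed = 1)
  expect_identical(p1$a, p1$b)
  p0 <- simulate_mask_pair(100, 0, seed = 2)
  expect_equal(sum(p0$a & p0$b), 0)
  p6 <- simulate_mask_pair(100, 0.6, seed = 3)
  expect_equal(sum(p6$a), 100)
  expect_equal(sum(p6$b), 100)
  expect_equal(sum(p6$a & p6$b), 60)
  expect_error(simulate_mask_pair(100, 0.0, frame_size = c(10, 10)), "fit")
  expect_error(simulate_mask_pair(10, 1.4), "overlap_fraction")
})

test_that("map/genotype/assay CSV round trips preserve content", {
  m <- simulate_map(2, 40, 4, seed = 91)
  g <- simulate_ril_genotypes(m, 8, missing_rate = 0.1, seed = 92)
  tmp <- tempfile(fileext = ".csv")
  write_genetic_map(m, tmp, comment = "seed: 91")
  m2 <- read_genetic_map(tmp)
  expect_equal(as.data.frame(m), as.data.frame(m2), tolerance = 1e-12)
  write_genotypes(g, tmp)
  g2 <- read_genotypes(tmp)
  expect_identical(unname(g$calls), unname(g2$calls))
  expect_equal(g$cross_direction, g2$cross_direction)
  ph <- simulate_tpc_phenotypes(g, m, qtl_spec(sd_within = 0.02),
                                n_individuals = 2, seed = 93)
  write_assay_table(ph, tmp, comment = "seed: 93")
  ph2 <- read_assay_table(tmp)
  expect_equal(ph2$li1, ph$li1, tolerance = 1e-6)
})
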