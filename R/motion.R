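# Locomotion metrics, per-individual normalization and quality control.

#' Changed-pixel locomotion index between two masks
#'
#' Movement score from two binary worm masks a fixed frame lag apart: 0 when
#' the masks coincide (no movement detected), 1 when they are disjoint
#' (complete displacement). The default is the Jaccard distance
#' `1 - |A∩B| / |A∪B|`; `method = "maxarea"` uses `1 - |A∩B| / max(|A|,|B|)`
#' instead. A lag of 1 frame gives LI1 semantics, 7 frames LI7.
#'
#' @param mask_a,mask_b Logical matrices (or vectors) of equal length.
#' @param method `"jaccard"` (default) or `"maxarea"`.
#' @return A value in [0, 1].
#' @export
locomotion_index <- function(mask_a, mask_b,
                             method = c("jaccard", "maxarea")) {
  method <- match.arg(method)
  na <- sum(mask_a)
  nb <- sum(mask_b)
  if (na == 0 || nb == 0)
    stop("locomotion index undefined for an empty mask", call. = FALSE)
  inter <- sum(mask_a & mask_b)
  denom <- if (method == "jaccard") na + nb - inter else max(na, nb)
  1 - inter / denom
}

#' Per-temperature-step locomotion metric from a frame window
#'
#' Averages the locomotion index over every pair of frames `lag` apart
#' within one recording window (e.g. the last 20 s of a temperature step at
#' 15 fps gives 300 frames and, at lag 7, 293 pairs).
#'
#' @param frame_masks List of binary masks, in frame order.
#' @param lag Frame lag (1 for LI1, 7 for LI7).
#' @param method Passed to [locomotion_index()].
#' @export
per_step_metric <- function(frame_masks, lag = 1,
                            method = c("jaccard", "maxarea")) {
  method <- match.arg(method)
  n <- length(frame_masks)
  if (n < lag + 1)
    stop(sprintf("need at least lag + 1 = %d frames, got %d", lag + 1, n),
         call. = FALSE)
  vals <- vapply(seq_len(n - lag), function(i) {
    locomotion_index(frame_masks[[i]], frame_masks[[i + lag]], method)
  }, numeric(1))
  mean(vals)
}

#' Center-of-mass displacement between lagged frames
#'
#' Euclidean distance (pixels) between mask centers of mass, averaged over
#' all frame pairs `lag` apart in the window.
#'
#' @inheritParams per_step_metric
#' @export
per_step_displacement <- function(frame_masks, lag = 1) {
  n <- length(frame_masks)
  if (n < lag + 1)
    stop(sprintf("need at least lag + 1 = %d frames, got %d", lag + 1, n),
         call. = FALSE)
  com <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) stop("empty mask", call. = FALSE)
    colMeans(idx)
  }
  centers <- t(vapply(frame_masks, com, numeric(2)))
  d <- sqrt(rowSums((centers[seq_len(n - lag), , drop = FALSE] -
                       centers[(lag + 1):n, , drop = FALSE])^2))
  mean(d)
}

#' Normalize a locomotion series by its minimum
#'
#' Subtracts the series minimum so immobile-frame pixel noise maps to zero;
#' the output minimum is exactly 0 and the operation is idempotent and
#' shift-invariant (all pairwise differences preserved).
#'
#' @param x Numeric series (one individual, across temperature steps).
#' @export
normalize_series <- function(x) {
  if (!length(x)) stop("series is empty", call. = FALSE)
  x - min(x)
}

#' Normalize every individual's series within an assay table
#'
#' Applies [normalize_series()] per individual and metric.
#'
#' @param table A `thermal_assay` data.frame.
#' @param metrics Columns to normalize (default LI1 and LI7).
#' @export
normalize_assay <- function(table, metrics = c("li1", "li7")) {
  key <- interaction(table$strain, table$individual, drop = TRUE)
  for (m in metrics) {
    table[[m]] <- table[[m]] - stats::ave(table[[m]], key, FUN = min)
  }
  table
}

#' Proportion of individuals moving at one temperature
#'
#' Binarizes each individual's (normalized) LI7 value at `threshold` and
#' returns the mean and sample SD of the resulting 0/1 vector.
#'
#' @param values Numeric LI7 values, one per individual.
#' @param threshold Movement threshold in (0, 1); default 0.1.
#' @return `list(mean, sd)` (`sd` is `NA` for a single individual).
#' @export
proportion_moving <- function(values, threshold = 0.1) {
  if (!length(values)) stop("no individuals supplied", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  moving <- as.numeric(values > threshold)
  list(mean = mean(moving), sd = stats::sd(moving))
}

#' Quality-control filtering of an assay table
#'
#' Drops (strain, temperature) cells with fewer than `min_per_temperature`
#' usable individuals, then drops strains whose remaining distinct individual
#' count falls below `min_per_strain` unless the strain is listed in
#' `exceptions`. Every exclusion is enumerated with a reason code; the filter
#' never adds rows and is idempotent.
#'
#' @param table A `thermal_assay` data.frame.
#' @param min_per_temperature Minimum individuals per (strain, temperature).
#' @param min_per_strain Minimum distinct individuals per strain.
#' @param exceptions Strain ids exempt from the per-strain rule.
#' @return `list(table, report)`; `report` has columns `strain`,
#'   `assay_temp` (`NA` for strain-level drops), `n`, `reason`.
#' @export
qc_filter <- function(table, min_per_temperature = 25, min_per_strain = 40,
                      exceptions = character()) {
  if (min_per_temperature < 1 || min_per_strain < 1)
    stop("QC thresholds must be >= 1", call. = FALSE)
  report <- data.frame(strain = character(), assay_temp = numeric(),
                       n = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  if (!nrow(table)) {
    report <- rbind(report, data.frame(strain = NA_character_,
                                       assay_temp = NA_real_, n = 0L,
                                       reason = "empty_input"))
    return(list(table = table, report = report))
  }
  cell <- stats::aggregate(individual ~ strain + assay_temp, table,
                           function(x) length(unique(x)))
  low_cells <- cell[cell$individual < min_per_temperature, , drop = FALSE]
  if (nrow(low_cells)) {
    drop_key <- paste(low_cells$strain, low_cells$assay_temp)
    table <- table[!(paste(table$strain, table$assay_temp) %in% drop_key), ,
                   drop = FALSE]
    report <- rbind(report, data.frame(strain = low_cells$strain,
                                       assay_temp = low_cells$assay_temp,
                                       n = low_cells$individual,
                                       reason = "below_min_per_temperature"))
  }
  if (nrow(table)) {
    per_strain <- stats::aggregate(individual ~ strain, table,
                                   function(x) length(unique(x)))
    low <- per_strain[per_strain$individual < min_per_strain &
                        !(per_strain$strain %in% exceptions), , drop = FALSE]
    if (nrow(low)) {
      table <- table[!table$strain %in% low$strain, , drop = FALSE]
      report <- rbind(report, data.frame(strain = low$strain,
                                         assay_temp = NA_real_,
                                         n = low$individual,
                                         reason = "below_min_per_strain"))
    }
  }
  if (!nrow(table))
    report <- rbind(report, data.frame(strain = NA_character_,
                                       assay_temp = NA_real_, n = 0L,
                                       reason = "empty_output"))
  rownames(table) <- NULL
  list(table = table, report = report)
}
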