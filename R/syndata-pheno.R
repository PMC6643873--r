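# Synthetic per-individual thermal assay phenotypes and mask fixtures.

#' Logistic thermal performance curve
#'
#' `LI(T) = alpha / (1 + exp(-beta * (T - tau)))`: `alpha` is the asymptote
#' (baseline locomotion, LI units), `beta` the signed slope (per degree C;
#' negative on the hot limb where activity declines as temperature rises) and
#' `tau` the inflection temperature at which `LI(tau) = alpha / 2`.
#'
#' @param temp Temperature (degrees C), vectorized.
#' @param alpha,beta,tau Curve parameters.
#' @export
logistic_tpc <- function(temp, alpha, beta, tau) {
  alpha / (1 + exp(-beta * (temp - tau)))
}

#' Gaussian peak performance curve
#'
#' `LI(T) = Pmax * exp(-0.5 * ((T - Topt) / c)^2)`: peak locomotion `Pmax`,
#' temperature of peak `Topt` and curvature `c` (degrees C).
#'
#' @param temp Temperature (degrees C), vectorized.
#' @param p_max,t_opt,curvature Curve parameters.
#' @export
gaussian_tpc <- function(temp, p_max, t_opt, curvature) {
  p_max * exp(-0.5 * ((temp - t_opt) / curvature)^2)
}

#' Specify a genetic architecture for simulated TPC parameters
#'
#' @param qtl Data frame with columns `chrom`, `pos_cM`, `param` (one of
#'   `"alpha"`, `"beta"`, `"tau"`) and `effect` (additive effect, in
#'   parameter units, carried by the A allele). May have zero rows.
#' @param sd_line Named numeric: between-line residual SD for each parameter
#'   (defaults 0 for any omitted parameter).
#' @param sd_within Within-line (per-individual, per-temperature) SD on the
#'   locomotion-index scale.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(qtl = data.frame(chrom = character(), pos_cM = numeric(),
                                      param = character(), effect = numeric()),
                     sd_line = c(alpha = 0, beta = 0, tau = 0),
                     sd_within = 0) {
  stopifnot(all(c("chrom", "pos_cM", "param", "effect") %in% names(qtl)))
  if (nrow(qtl) && !all(qtl$param %in% c("alpha", "beta", "tau")))
    stop("qtl$param must be alpha, beta or tau", call. = FALSE)
  if (nrow(qtl) && any(!is.finite(qtl$effect)))
    stop("qtl effects must be finite", call. = FALSE)
  full_sd <- c(alpha = 0, beta = 0, tau = 0)
  full_sd[names(sd_line)] <- sd_line
  if (any(full_sd < 0) || sd_within < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(qtl = qtl, sd_line = full_sd, sd_within = sd_within),
            class = "qtl_spec")
}

# nearest typed marker to a (chrom, pos) on the map
nearest_marker <- function(map, chrom, pos_cM) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (!nrow(sub)) stop("QTL chromosome not present in map", call. = FALSE)
  sub$marker[which.min(abs(sub$pos_cM - pos_cM))]
}

#' Per-line TPC parameters implied by genotype
#'
#' baseline + sum of allele-coded QTL effects (+ optional between-line
#' noise). Lines carrying the A allele at a QTL receive its effect; the QTL
#' genotype is read at the nearest typed marker.
#'
#' @keywords internal
line_parameters <- function(genotypes, map, spec, baseline, add_noise = TRUE) {
  n <- length(genotypes$line_ids)
  pars <- matrix(rep(baseline, each = n), n, 3,
                 dimnames = list(genotypes$line_ids, c("alpha", "beta", "tau")))
  if (nrow(spec$qtl)) {
    for (k in seq_len(nrow(spec$qtl))) {
      mk <- nearest_marker(map, spec$qtl$chrom[k], spec$qtl$pos_cM[k])
      carrier <- genotypes$calls[, mk] == "A"
      carrier[is.na(carrier)] <- FALSE
      pars[, spec$qtl$param[k]] <- pars[, spec$qtl$param[k]] +
        spec$qtl$effect[k] * carrier
    }
  }
  if (add_noise) {
    for (p in c("alpha", "beta", "tau")) {
      if (spec$sd_line[[p]] > 0)
        pars[, p] <- pars[, p] + stats::rnorm(n, 0, spec$sd_line[[p]])
    }
  }
  pars
}

#' Simulate a per-individual thermal assay table
#'
#' Generates the long-format observation table of a micro-droplet thermal
#' ramp: every individual of every line is scored at each temperature of the
#' assay grid. Each line's logistic parameters are baseline + allele-coded
#' QTL effects + Gaussian between-line noise; each individual observation is
#' the line's logistic curve plus Gaussian within-line noise and a constant
#' floor offset (mimicking the residual pixel noise of immobile worms that
#' per-individual normalization later removes), clipped to [0, 1].
#'
#' Companion metrics are generated for trait-table realism: LI7 as a
#' saturating amplification of the same latent curve, frame displacements
#' proportional to the LI values, and a per-individual pixel area.
#'
#' @param genotypes,map `ril_genotypes` and `genetic_map`.
#' @param spec A [qtl_spec()].
#' @param baseline Named numeric `c(alpha=, beta=, tau=)`; `alpha` in (0, 1],
#'   `beta` negative for the hot limb, `tau` inside the grid.
#' @param temps Assay temperature grid, degrees C (>= 4 points).
#' @param n_individuals Individuals scored per line.
#' @param floor_offset Raw-series floor (default 0.08, within the observed
#'   0.06-0.12 band for immobile animals).
#' @param rearing_temp Rearing temperature recorded in the table.
#' @param seed Integer seed.
#' @return A `thermal_assay` data.frame with columns `strain`, `individual`,
#'   `rearing_temp`, `assay_temp`, `li1`, `li7`, `disp1`, `disp7`, `area`;
#'   the matrix of true per-line parameters is attached as attribute
#'   `line_params`.
#' @export
simulate_tpc_phenotypes <- function(genotypes, map, spec = qtl_spec(),
                                    baseline = c(alpha = 0.6, beta = -0.9,
                                                 tau = 35),
                                    temps = 25:41,
                                    n_individuals = 45,
                                    floor_offset = 0.08,
                                    rearing_temp = 23,
                                    seed = 1L) {
  if (length(temps) < 4) stop("assay grid needs at least 4 points", call. = FALSE)
  if (baseline[["alpha"]] <= 0 || baseline[["alpha"]] > 1)
    stop("baseline alpha must lie in (0, 1]", call. = FALSE)
  if (baseline[["tau"]] < min(temps) || baseline[["tau"]] > max(temps))
    stop("baseline tau must lie inside the assay grid", call. = FALSE)
  set.seed(as.integer(seed))
  pars <- line_parameters(genotypes, map, spec, baseline)
  nT <- length(temps)
  rows <- vector("list", length(genotypes$line_ids))
  for (i in seq_along(genotypes$line_ids)) {
    latent <- outer(rep(1, n_individuals), logistic_tpc(temps, pars[i, 1],
                                                        pars[i, 2], pars[i, 3]))
    noise <- matrix(stats::rnorm(n_individuals * nT, 0, spec$sd_within),
                    n_individuals, nT)
    li1 <- pmin(1, pmax(0, latent + floor_offset + noise))
    li7 <- pmin(1, pmax(0, pmin(1, 1.4 * latent) + floor_offset +
                          matrix(stats::rnorm(n_individuals * nT, 0,
                                              spec$sd_within),
                                 n_individuals, nT)))
    area <- stats::rnorm(n_individuals, 2500, 150)
    rows[[i]] <- data.frame(
      strain = genotypes$line_ids[i],
      individual = rep(sprintf("%s_w%02d", genotypes$line_ids[i],
                               seq_len(n_individuals)), times = nT),
      rearing_temp = rearing_temp,
      assay_temp = rep(temps, each = n_individuals),
      li1 = as.vector(li1),
      li7 = as.vector(li7),
      disp1 = as.vector(li1) * 28 +
        abs(stats::rnorm(n_individuals * nT, 0, 1.5)),
      disp7 = as.vector(li7) * 110 +
        abs(stats::rnorm(n_individuals * nT, 0, 4)),
      area = rep(area, times = nT),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("thermal_assay", "data.frame")
  attr(out, "line_params") <- pars
  out
}

#' Simulate a pair of binary worm masks with controlled overlap
#'
#' Constructs two equal-size pixel sets inside a frame whose intersection is
#' exactly `round(overlap_fraction * n_pixels_worm)` pixels, for testing the
#' changed-pixel locomotion index. Pixel placement is randomized within the
#' frame; the overlap count is exact by construction.
#'
#' @param n_pixels_worm Pixels per mask.
#' @param overlap_fraction In [0, 1].
#' @param frame_size `c(rows, cols)`.
#' @param seed Integer seed.
#' @return `list(a, b)` of logical matrices.
#' @export
simulate_mask_pair <- function(n_pixels_worm, overlap_fraction,
                               frame_size = c(64, 64), seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n_pixels_worm)
  k <- as.integer(round(overlap_fraction * n))
  total <- 2L * n - k
  if (n < 1) stop("n_pixels_worm must be >= 1", call. = FALSE)
  if (total > prod(frame_size))
    stop("worms do not fit in the frame", call. = FALSE)
  set.seed(as.integer(seed))
  cells <- sample.int(prod(frame_size), total)
  a <- matrix(FALSE, frame_size[1], frame_size[2])
  b <- a
  a[cells[seq_len(n)]] <- TRUE                      # shared k + n-k private
  b_private <- if (total > n) (n + 1L):total else integer(0)
  b[cells[c(seq_len(k), b_private)]] <- TRUE
  list(a = a, b = b)
}

#' Read/write long-format thermal assay tables
#'
#' @param table A `thermal_assay` data.frame.
#' @param path File path.
#' @param comment Optional comment lines (written prefixed with `#`).
#' @name assay_io
NULL

#' @rdname assay_io
#' @export
write_assay_table <- function(table, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname assay_io
#' @export
read_assay_table <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(out) <- c("thermal_assay", "data.frame")
  out
}
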